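#' Synthetic dissociation-trajectory ensembles
#'
#' Generates three-subunit trajectory ensembles whose per-subunit escape
#' statistics follow a ground-truth logistic in the interaction-scaling
#' factor, in distance-series form by default (fast) or as coordinate
#' trajectories exercising the readers and distance computations.
#'
#' @name synthetic_trajectories
NULL

#' Ensemble specification
#'
#' Defaults reproduce the with-ion study conditions: the six-point lambda
#' grid (S = sqrt(lambda)), ground-truth logistic parameters m = 58.6,
#' n = 0.42, 20 replicas of 50-ns windows. Bound-state noise matches the
#' characteristic values D1 = 5.9 +/- 0.3 A and D2 = 3.2 +/- 0.1 A.
#'
#' @param lambda_grid solute scaling factors; the curve is parameterized on
#'   S = sqrt(lambda).
#' @param m_true,n_true ground-truth logistic parameters on the S scale.
#' @param n_replicas replicas per grid point (default 20).
#' @param window_ns window length in ns (default 50).
#' @param dt frame spacing in ns (default 0.1).
#' @param rebind_probability probability that a non-dissociating subunit
#'   shows a transient (sub-persistence) excursion above the dissociation
#'   threshold before re-binding, in [0, 1).
#' @param with_mg include the ion (D2 series present).
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(lambda_grid = c(0.12, 0.15, 0.175, 0.20, 0.25, 0.30),
                          m_true = 58.6, n_true = 0.42, n_replicas = 20L,
                          window_ns = 50, dt = 0.1,
                          rebind_probability = 0, with_mg = TRUE,
                          seed = 1L) {
  stopifnot(length(lambda_grid) >= 1L, all(lambda_grid > 0),
            n_replicas >= 1L, window_ns > 0, dt > 0,
            rebind_probability >= 0, rebind_probability < 1)
  S <- sqrt(lambda_grid)
  if (!is.finite(m_true) || !is.finite(n_true))
    stop("logistic parameters must be finite")
  f <- logistic_events(S, m_true, n_true)
  if (!all(is.finite(f)) || any(f < 0 | f > 3))
    stop("logistic out of [0, 3] on the grid")
  structure(list(lambda_grid = lambda_grid, S_grid = S, m_true = m_true,
                 n_true = n_true, n_replicas = as.integer(n_replicas),
                 window_ns = window_ns, dt = dt,
                 rebind_probability = rebind_probability,
                 with_mg = with_mg, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# One subunit's D1/D2 series. Escape times are exponential (mean window/3)
# conditioned on landing early enough (window - 2.5 ns) that the escape ramp
# (1 ns) plus the default persistence criterion (1 ns) always fit inside the
# window, so every drawn dissociation is detectable by all three estimators.
.simulate_subunit <- function(id, p, window_ns, dt, with_mg,
                              rebind_probability) {
  t <- seq(0, window_ns, by = dt)
  nf <- length(t)
  D1 <- stats::rnorm(nf, 5.9, 0.3)
  D2 <- if (with_mg) stats::rnorm(nf, 3.2, 0.1) else NULL
  dissociates <- stats::runif(1) < p
  ramp_ns <- 1
  if (dissociates) {
    tmax <- window_ns - 2.5
    mu <- window_ns / 3
    u <- stats::runif(1)
    tau <- -mu * log(1 - u * (1 - exp(-tmax / mu)))
    esc <- t >= tau & t < tau + ramp_ns
    gone <- t >= tau + ramp_ns
    D1[esc] <- 5.9 + (20 - 5.9) * (t[esc] - tau) / ramp_ns
    D1[gone] <- stats::rnorm(sum(gone), 20, 0.5)
    if (with_mg) {
      D2[esc] <- 3.2 + (8 - 3.2) * (t[esc] - tau) / ramp_ns
      D2[gone] <- stats::rnorm(sum(gone), 8, 0.4)
    }
  } else if (rebind_probability > 0 &&
             stats::runif(1) < rebind_probability) {
    # transient excursion: 0.4 ns above threshold, then re-binding
    t0 <- stats::runif(1, 2, window_ns - 2)
    exc <- t >= t0 & t < t0 + 0.4
    D1[exc] <- stats::rnorm(sum(exc), 13.5, 0.3)
  }
  D1 <- pmax(D1, 0.1)
  if (with_mg) D2 <- pmax(D2, 0.1)
  new_distance_series(id, t, D1, D2)
}

#' Simulate a trajectory ensemble
#'
#' Per grid point and replica, each of the three subunits dissociates with
#' probability `f(S)/3` where `f` is the ground-truth logistic; bound-state
#' distances fluctuate around the characteristic values and escape produces a
#' 1-ns ramp of D1 past the 12 A threshold (D2 past 5 A when the ion is
#' present). Fully reproducible from the spec seed.
#'
#' @param spec an [ensemble_spec()].
#' @param format `"distance_series"` (default; each replica is a list of
#'   three `distance_series`) or `"window"` (each replica is a coordinate
#'   [trajectory_window] realizing the same distances).
#' @return named list (by S value) of replica lists, ready for
#'   [dissociation_curve()].
#' @export
simulate_ensemble <- function(spec, format = c("distance_series", "window")) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "ensemble_spec"))
  f <- logistic_events(spec$S_grid, spec$m_true, spec$n_true)
  with_seed(spec$seed, {
    out <- lapply(seq_along(spec$S_grid), function(gi) {
      p <- f[gi] / 3
      lapply(seq_len(spec$n_replicas), function(r) {
        series <- lapply(c("A", "B", "C"), .simulate_subunit, p = p,
                         window_ns = spec$window_ns, dt = spec$dt,
                         with_mg = spec$with_mg,
                         rebind_probability = spec$rebind_probability)
        if (format == "window") series_to_window(series) else series
      })
    })
    names(out) <- format(spec$S_grid, digits = 10)
    out
  })
}

#' Shortcut count generator
#'
#' Draws per-replica event counts directly as binomial(3, f(S)/3) and returns
#' the resulting [dissociation_curve()]; fast surrogate for fit-recovery
#' studies.
#'
#' @param spec an [ensemble_spec()].
#' @return a `dissociation_curve` data.frame. With a single replica the SEM
#'   is undefined and flagged `NA` with a warning.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  f <- logistic_events(spec$S_grid, spec$m_true, spec$n_true)
  with_seed(spec$seed, {
    rows <- lapply(seq_along(spec$S_grid), function(gi) {
      counts <- stats::rbinom(spec$n_replicas, 3L, f[gi] / 3)
      sem <- if (spec$n_replicas < 2L) NA_real_
             else stats::sd(counts) / sqrt(spec$n_replicas)
      data.frame(S = spec$S_grid[gi], mean_events = mean(counts),
                 sem = sem, n_replicas = spec$n_replicas)
    })
    out <- do.call(rbind, rows)
    if (anyNA(out$sem)) warning("single replica: SEM undefined")
    class(out) <- c("dissociation_curve", "data.frame")
    out
  })
}

# Minimal coordinate topology realizing arbitrary D1/D2 series: per subunit,
# five CA "binding site" atoms symmetric about a center, a rigid 3-atom
# nucleotide whose center of mass is displaced along a subunit axis by D1,
# and an ion at distance D2 from the gamma-phosphorus. Chamber carboxylates
# sit at fixed positions near the site center.
.series_topology <- function(with_mg) {
  one_subunit <- function(chain, center) {
    # site: 5 CA symmetric about center -> site COM = center (equal masses)
    ca_off <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                    c(0, 0, 0))
    site <- data.frame(
      element = "C", name = "CA",
      x = center[1] + ca_off[, 1], y = center[2] + ca_off[, 2],
      z = center[3] + ca_off[, 3],
      resname = c("LYS", "LYS", "THR", "ARG", "ARG"),
      resno = c(63L, 65L, 172L, 281L, 299L), chain = chain, altloc = "",
      occupancy = 1, type = "ATOM", stringsAsFactors = FALSE)
    # chamber carboxylates at four corners ~8 A apart, so that "all" and
    # "any" cutoff semantics are geometrically distinguishable
    corners <- rbind(c(4, 4), c(-4, 4), c(-4, -4), c(4, -4))
    chamber <- do.call(rbind, lapply(seq_along(c(158L, 156L, 111L, 109L)),
      function(i) {
        rn <- c(158L, 156L, 111L, 109L)[i]
        nm <- if (rn == 158L) c("OD1", "OD2") else c("OE1", "OE2")
        data.frame(element = "O", name = nm,
                   x = center[1] + corners[i, 1],
                   y = center[2] + corners[i, 2],
                   z = center[3] + c(0, 1),
                   resname = if (rn == 158L) "ASP" else "GLU",
                   resno = rn, chain = chain, altloc = "", occupancy = 1,
                   type = "ATOM", stringsAsFactors = FALSE)
      }))
    # rigid pseudo-nucleotide: PG flanked by two oxygens; COM at its centroid
    atp <- data.frame(
      element = c("P", "O", "O"), name = c("PG", "O1G", "O2G"),
      x = center[1], y = center[2] + c(0, 1.5, -1.5), z = center[3],
      resname = "ATP", resno = 501L, chain = chain, altloc = "",
      occupancy = 1, type = "HETATM", stringsAsFactors = FALSE)
    mg <- if (with_mg) data.frame(
      element = "MG", name = "MG", x = center[1], y = center[2],
      z = center[3] + 3.2, resname = "MG", resno = 601L, chain = chain,
      altloc = "", occupancy = 1, type = "HETATM",
      stringsAsFactors = FALSE) else NULL
    rbind(site, chamber, atp, mg)
  }
  centers <- list(A = c(0, 0, 0), B = c(60, 0, 0), C = c(120, 0, 0))
  atoms <- do.call(rbind, lapply(names(centers), function(ch)
    one_subunit(ch, centers[[ch]])))
  new_structure_model("series_topology", atoms)
}

#' Realize distance series as a coordinate trajectory window
#'
#' Builds a minimal topology (per subunit: binding-site CA atoms, a rigid
#' pseudo-nucleotide, an ion, chamber carboxylates) and frames in which the
#' nucleotide's center of mass sits at exactly D1 from the site center along
#' the subunit axis, and the ion at exactly D2 from the gamma-phosphorus.
#' [compute_distances()] on the result reproduces the input series.
#'
#' @param series list of three `distance_series` (one per subunit). All must
#'   share the time base; D2 may be `NULL` (ion-free system).
#' @return a [trajectory_window].
#' @export
series_to_window <- function(series) {
  stopifnot(length(series) == 3L)
  with_mg <- !is.null(series[[1L]]$D2)
  topo <- .series_topology(with_mg)
  subus <- define_subunits(topo, chains = c("A", "B", "C"))
  t <- series[[1L]]$t
  nf <- length(t)
  dt <- diff(t)[1]
  nat <- nrow(topo$atoms)
  base <- as.vector(t(as.matrix(topo$atoms[, c("x", "y", "z")])))
  xyz <- matrix(rep(base, each = nf), nrow = nf)
  axis <- c(0, 0, 1)  # displacement axis (site plane is z = center z)
  for (k in 1:3) {
    su <- subus[[k]]
    s <- series[[k]]
    stopifnot(length(s$t) == nf)
    site_com <- .com(.xyz_at(base, su$site_idx), su$site_mass)
    atp0 <- .xyz_at(base, su$atp_idx)
    atp_com0 <- .com(atp0, su$atp_mass)
    for (i in seq_len(nf)) {
      target_com <- site_com + s$D1[i] * axis
      shift <- target_com - atp_com0
      moved <- sweep(atp0, 2L, shift, `+`)
      cols <- as.vector(rbind(3L * su$atp_idx - 2L, 3L * su$atp_idx - 1L,
                              3L * su$atp_idx))
      xyz[i, cols] <- as.vector(t(moved))
      if (with_mg) {
        gp <- moved[which(topo$atoms$name[su$atp_idx] == "PG"), ]
        mgpos <- gp + s$D2[i] * c(1, 0, 0)
        mcols <- c(3L * su$mg_idx - 2L, 3L * su$mg_idx - 1L, 3L * su$mg_idx)
        xyz[i, mcols] <- mgpos
      }
    }
  }
  stopifnot(ncol(xyz) == 3L * nat)
  new_trajectory_window(topo, xyz, dt, subus)
}

#' Write a trajectory window as a multi-model PDB
#'
#' @param window a [trajectory_window].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(window, path) {
  a <- window$topology$atoms
  name_field <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                       sprintf(" %-3s", a$name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   frame spacing %.6f ns", window$dt), con)
  for (i in seq_len(nrow(window$xyz))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    m <- matrix(window$xyz[i, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$type, seq_len(nrow(a)), name_field, "", a$resname,
                       a$chain, a$resno, "", m[, 1], m[, 2], m[, 3],
                       a$occupancy, 0, toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB files are read directly; DCD trajectories require a PDB
#' topology. Subunit definitions are built with [define_subunits()] using the
#' defaults unless `subunit_args` overrides them.
#'
#' @param path trajectory path (multi-model PDB, or DCD).
#' @param topology PDB topology path (required for DCD).
#' @param dt frame spacing in ns.
#' @param subunit_args list of extra arguments for [define_subunits()].
#' @return a [trajectory_window].
#' @export
read_trajectory <- function(path, topology = NULL, dt = 0.1,
                            subunit_args = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    if (is.null(topology)) stop("DCD trajectories need a PDB topology")
    topo <- parse_structure(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    topo <- parse_structure(path)  # first model + header
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    rem <- grep("frame spacing", readLines(path, n = 5L), value = TRUE)
    if (length(rem)) {
      v <- as.numeric(regmatches(rem[1], regexpr("[0-9.]+", rem[1])))
      if (is.finite(v) && v > 0) dt <- v
    }
  }
  subus <- do.call(define_subunits, c(list(model = topo), subunit_args))
  new_trajectory_window(topo, unclass(xyz), dt, subus)
}
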