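#' Trajectory windows and subunit definitions
#'
#' A `trajectory_window` holds a topology ([structure_model]), a frames
#' matrix (bio3d xyz convention: one row per frame, 3 columns per atom), the
#' frame spacing `dt` in ns, and three subunit definitions (atom index sets
#' for the nucleotide, the binding-site residues, the gamma-phosphorus, the
#' metal ion and the acidic-chamber carboxylates).
#'
#' @name trajectory_window
NULL

new_trajectory_window <- function(topology, xyz, dt, subunits) {
  stopifnot(is.matrix(xyz), nrow(xyz) >= 2L, dt > 0)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("frame width does not match topology atom count")
  structure(list(topology = topology, xyz = xyz, dt = dt, subunits = subunits),
            class = "trajectory_window")
}

#' Define per-subunit atom selections on a topology
#'
#' Builds, for each chain, the index sets the distance computations need:
#' all non-hydrogen nucleotide atoms, all non-hydrogen atoms of the
#' binding-site residues, the gamma-phosphorus, the metal ion (if present)
#' and the carboxylate oxygens of the acidic-chamber residues.
#'
#' @param model a [structure_model].
#' @param chains chain ids, one per subunit (default the chains carrying the
#'   ligand).
#' @param ligand_code nucleotide residue code (default `"ATP"`).
#' @param site_resnos author residue numbers of the binding-site residues
#'   (default `c(63, 65, 172, 281, 299)`).
#' @param metal_element element symbol of the ion (default `"MG"`).
#' @param chamber_resnos acidic-chamber residue numbers
#'   (default `c(158, 156, 111, 109)`).
#' @return list of subunit definitions.
#' @export
define_subunits <- function(model, chains = NULL, ligand_code = "ATP",
                            site_resnos = c(63, 65, 172, 281, 299),
                            metal_element = "MG",
                            chamber_resnos = c(158, 156, 111, 109)) {
  a <- model$atoms
  noH <- a$element != "H"
  if (is.null(chains))
    chains <- sort(unique(a$chain[a$resname == ligand_code]))
  if (length(chains) == 0L) stop("no chains carry ligand ", ligand_code)
  lapply(chains, function(ch) {
    in_ch <- a$chain == ch
    atp <- which(in_ch & a$resname == ligand_code & noH)
    if (length(atp) == 0L) stop("no ", ligand_code, " atoms in chain ", ch)
    site <- which(in_ch & a$resno %in% site_resnos &
                    a$resname %in% .aa3 & noH)
    missing <- setdiff(site_resnos, unique(a$resno[site]))
    if (length(missing))
      stop("binding-site residue(s) not found in chain ", ch, ": ",
           paste(missing, collapse = ", "))
    gp <- which(in_ch & a$resname == ligand_code & a$name == "PG")
    if (length(gp) != 1L) stop("gamma-phosphorus not resolved in chain ", ch)
    mg <- which(in_ch & toupper(a$element) == toupper(metal_element) &
                  !(a$resname %in% c(.aa3, ligand_code)))
    chamber <- lapply(chamber_resnos, function(rn)
      which(in_ch & a$resno == rn &
              a$name %in% c("OD1", "OD2", "OE1", "OE2")))
    names(chamber) <- as.character(chamber_resnos)
    site_ca <- which(in_ch & a$name == "CA" & a$resno %in% site_resnos)
    list(id = ch, atp_idx = atp, atp_mass = element_mass(a$element[atp]),
         site_idx = site, site_mass = element_mass(a$element[site]),
         gamma_p_idx = gp,
         mg_idx = if (length(mg)) mg[1L] else NULL,
         chamber = chamber, site_ca_idx = site_ca)
  })
}

.xyz_at <- function(frame_row, idx) {
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  matrix(frame_row[cols], ncol = 3L, byrow = TRUE)
}

.com <- function(coords, mass) colSums(coords * mass) / sum(mass)

new_distance_series <- function(subunit_id, t, D1, D2 = NULL) {
  stopifnot(length(t) == length(D1), all(D1 >= 0))
  if (!is.null(D2)) stopifnot(length(D2) == length(D1), all(D2 >= 0))
  structure(list(subunit_id = subunit_id, t = t, D1 = D1, D2 = D2),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series subunit %s: %d frames over %.2f ns; D1 %.2f-%.2f A%s\n",
              x$subunit_id, length(x$t), max(x$t) - min(x$t),
              min(x$D1), max(x$D1),
              if (is.null(x$D2)) "" else sprintf("; D2 %.2f-%.2f A",
                                                 min(x$D2), max(x$D2))))
  invisible(x)
}

#' Compute the D1/D2 distance series of each subunit
#'
#' D1 is the distance between the mass-weighted centers of the nucleotide and
#' of the binding-site residues (hydrogens excluded from both selections);
#' D2 is the distance between the nucleotide's gamma-phosphorus and the metal
#' ion, absent for metal-free systems.
#'
#' @param window a [trajectory_window].
#' @return list of `distance_series`, one per subunit.
#' @export
compute_distances <- function(window) {
  stopifnot(inherits(window, "trajectory_window"))
  n <- nrow(window$xyz)
  t <- (seq_len(n) - 1L) * window$dt
  lapply(window$subunits, function(su) {
    D1 <- numeric(n); D2 <- if (is.null(su$mg_idx)) NULL else numeric(n)
    for (i in seq_len(n)) {
      fr <- window$xyz[i, ]
      c_atp <- .com(.xyz_at(fr, su$atp_idx), su$atp_mass)
      c_site <- .com(.xyz_at(fr, su$site_idx), su$site_mass)
      D1[i] <- sqrt(sum((c_atp - c_site)^2))
      if (!is.null(D2)) {
        gp <- .xyz_at(fr, su$gamma_p_idx)
        mg <- .xyz_at(fr, su$mg_idx)
        D2[i] <- sqrt(sum((gp - mg)^2))
      }
    }
    new_distance_series(su$id, t, D1, D2)
  })
}

#' Detect an ATP dissociation event in one subunit's distance series
#'
#' Default estimator `"persistent"`: the subunit counts as dissociated iff D1
#' exceeds the threshold over a contiguous stretch of at least `persistence`
#' ns, which is robust to transiently dislodged nucleotides that re-bind.
#' `"any_crossing"` counts any excursion above the threshold; `"terminal"`
#' looks at the final frame only.
#'
#' @param series a `distance_series`.
#' @param d1_threshold dissociation threshold on D1 in Angstrom (default 12).
#' @param persistence minimum duration above threshold in ns (default 1),
#'   for the persistent estimator.
#' @param mode `"persistent"`, `"any_crossing"` or `"terminal"`.
#' @return integer 0 or 1.
#' @export
detect_dissociation <- function(series, d1_threshold = 12, persistence = 1,
                                mode = c("persistent", "any_crossing",
                                         "terminal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "distance_series"), length(series$t) >= 2L)
  above <- series$D1 > d1_threshold
  dt <- diff(series$t)[1]
  if (mode == "terminal") return(as.integer(above[length(above)]))
  if (mode == "any_crossing") return(as.integer(any(above)))
  window_ns <- max(series$t) - min(series$t)
  if (persistence > window_ns)
    stop("persistence (", persistence, " ns) exceeds the window (",
         window_ns, " ns)")
  r <- rle(above)
  runs <- r$lengths[r$values]
  as.integer(any((runs - 1L) * dt >= persistence))
}

#' Count dissociation events in a three-subunit window
#'
#' Sum of [detect_dissociation()] over the subunits; one nucleotide is bound
#' per subunit, so the count lies in 0..3 for a trimer.
#'
#' @param x a [trajectory_window] or a list of `distance_series`.
#' @param ... passed to [detect_dissociation()].
#' @return integer event count.
#' @export
count_events <- function(x, ...) {
  series <- if (inherits(x, "trajectory_window")) compute_distances(x)
            else x
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "distance_series")))
  sum(vapply(series, detect_dissociation, integer(1), ...))
}

#' Build the dissociation curve over an ensemble of scaled simulations
#'
#' For each value of the interaction-scaling factor S, computes the mean and
#' SEM (sample SD over replicas divided by sqrt of the replica count) of the
#' per-window event count.
#'
#' @param ensembles named list: scaling-factor value (as the name) to list of
#'   replicas, each a [trajectory_window] or a list of `distance_series`.
#' @param ... passed to [count_events()].
#' @return object of class `dissociation_curve`: data.frame with columns
#'   `S`, `mean_events`, `sem`, `n_replicas`.
#' @export
dissociation_curve <- function(ensembles, ...) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1L,
            !is.null(names(ensembles)))
  rows <- lapply(names(ensembles), function(sname) {
    reps <- ensembles[[sname]]
    if (length(reps) < 2L)
      stop("need >= 2 replicas at S = ", sname)
    counts <- vapply(reps, count_events, integer(1), ...)
    data.frame(S = as.numeric(sname),
               mean_events = mean(counts),
               sem = stats::sd(counts) / sqrt(length(counts)),
               n_replicas = length(counts))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$S), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dissociation_curve", "data.frame")
  out
}

#' The dissociation-probability model
#'
#' `f(S) = 3 / (1 + exp(m (S - n)))`: expected event count per three-subunit
#' window as a function of the interaction-scaling factor.
#'
#' @param S scaling factor(s).
#' @param m slope parameter.
#' @param n midpoint.
#' @return expected event count in (0, 3).
#' @export
logistic_events <- function(S, m, n) 3 / (1 + exp(m * (S - n)))

#' Canonical scaling-factor grids
#'
#' The per-ensemble interaction scaling factors: the solute's self-interaction
#' scaling lambda and the effective solute-environment scaling S = sqrt(lambda)
#' on which the dissociation curves are parameterized (the cross terms of the
#' tempered energy function scale as the square root of the solute scaling).
#'
#' @return list with elements `with_mg` and `without_mg`, each a data.frame
#'   with columns `lambda` and `S`.
#' @export
scaling_grids <- function() {
  wm <- c(0.12, 0.15, 0.175, 0.20, 0.25, 0.30)
  nm <- c(0.20, 0.25, 0.30, 0.35)
  list(with_mg = data.frame(lambda = wm, S = sqrt(wm)),
       without_mg = data.frame(lambda = nm, S = sqrt(nm)))
}

# Exact linearization of noiseless data: z = log(3/y - 1) = m (S - n).
.logit_start <- function(S, y) {
  y <- pmin(pmax(y, 1e-9), 3 - 1e-9)
  z <- log(3 / y - 1)
  fit <- stats::lm(z ~ S)
  m <- unname(stats::coef(fit)[2])
  n <- if (abs(m) > 1e-12) -unname(stats::coef(fit)[1]) / m else mean(S)
  c(m = m, n = n)
}

#' Fit the logistic dissociation model to a curve
#'
#' Nonlinear least squares of `f(S) = 3/(1 + exp(m (S - n)))` to the mean
#' event counts, via Levenberg-Marquardt with multistart: a logit-linearized
#' start (exact on noiseless data) plus a grid over the midpoint range and
#' slope magnitudes. Optionally weighted by 1/SEM^2.
#'
#' @param curve a [dissociation_curve()] (or data.frame with `S`,
#'   `mean_events`, optionally `sem`).
#' @param weighted if `TRUE`, weight points by 1/SEM^2 (zero SEMs get the
#'   largest finite weight present).
#' @return object of class `logistic_fit`: `m`, `n`, `cc` (Pearson r between
#'   observed and fitted means), `covariance` (2x2; a sandwich estimate using
#'   the binomial variance of mean event counts when replica counts are
#'   available, otherwise the plain NLS covariance), `se` (named), `fitted`,
#'   `converged`, `diagnostics`.
#' @export
fit_logistic <- function(curve, weighted = FALSE) {
  S <- curve$S; y <- curve$mean_events
  if (length(unique(S)) < 3L) stop("need >= 3 distinct S values")
  w <- NULL
  if (weighted && !is.null(curve$sem)) {
    w <- 1 / pmax(curve$sem, 1e-12)^2
    w <- w / mean(w)
  }
  dat <- data.frame(S = S, y = y)
  starts <- list(.logit_start(S, y))
  for (n0 in seq(min(S), max(S), length.out = 5))
    for (m0 in c(-100, -50, -10, 10, 50, 100))
      starts[[length(starts) + 1L]] <- c(m = m0, n = n0)
  best <- NULL; best_ss <- Inf
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 1024)
  for (st in starts) {
    args <- list(y ~ 3 / (1 + exp(m * (S - n))), data = dat,
                 start = as.list(st), control = ctrl)
    if (!is.null(w)) args$weights <- w
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (ss < best_ss) { best <- fit; best_ss <- ss }
  }
  if (is.null(best)) {
    return(structure(list(m = NA_real_, n = NA_real_, cc = NA_real_,
                          covariance = matrix(NA_real_, 2, 2),
                          se = c(m = NA_real_, n = NA_real_),
                          fitted = rep(NA_real_, length(S)),
                          converged = FALSE,
                          diagnostics = "no start converged (flat data?)"),
                     class = "logistic_fit"))
  }
  cf <- stats::coef(best)
  fitted <- logistic_events(S, cf[["m"]], cf[["n"]])
  vc <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("m", "n"), c("m", "n"))))
  # Event counts are binomial(3, f/3) per window, so the per-point means are
  # heteroscedastic with known model variance f (1 - f/3) / n_replicas; use
  # the corresponding sandwich covariance when replica counts are available.
  if (!is.null(curve$n_replicas) && all(is.finite(curve$n_replicas)) &&
      all(curve$n_replicas >= 1)) {
    g <- fitted * (1 - fitted / 3)            # d f / d (linear predictor)
    J <- cbind(m = -g * (S - cf[["n"]]), n = g * cf[["m"]])
    V <- pmax(fitted * (1 - fitted / 3), 1e-12) / curve$n_replicas
    A <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(A)) {
      vc_s <- A %*% t(J) %*% (V * J) %*% A
      dimnames(vc_s) <- list(c("m", "n"), c("m", "n"))
      vc <- vc_s
    }
  }
  cc <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
    stats::cor(y, fitted) else NA_real_
  flat <- stats::sd(y) < 1e-12
  structure(list(m = cf[["m"]], n = cf[["n"]], cc = cc, covariance = vc,
                 se = c(m = sqrt(vc[1, 1]), n = sqrt(vc[2, 2])),
                 fitted = fitted, converged = !flat,
                 diagnostics = if (flat) "flat data: parameters unidentified"
                               else sprintf("SSR = %.3e", best_ss)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) cat("logistic_fit: NOT converged -", x$diagnostics, "\n")
  else cat(sprintf("logistic_fit: m = %.4g, n = %.4g (C.C. = %.4f)\n",
                   x$m, x$n, x$cc))
  invisible(x)
}

#' Select dissociated-state snapshots
#'
#' Frames in which the nucleotide has left the site (D1 > `d1_min`) and the
#' ion has detached from the gamma-phosphate (D2 > `d2_min`), per subunit.
#'
#' @param x a [trajectory_window] or list of `distance_series` (D2 required).
#' @param d1_min,d2_min thresholds in Angstrom (defaults 12 and 5).
#' @return named list (by subunit) of frame index vectors.
#' @export
select_dissociated_snapshots <- function(x, d1_min = 12, d2_min = 5) {
  series <- if (inherits(x, "trajectory_window")) compute_distances(x) else x
  out <- lapply(series, function(s) {
    if (is.null(s$D2)) stop("D2 absent for subunit ", s$subunit_id,
                            ": no metal ion in the system")
    which(s$D1 > d1_min & s$D2 > d2_min)
  })
  names(out) <- vapply(series, function(s) as.character(s$subunit_id),
                       character(1))
  out
}

#' Select acidic-chamber snapshots
#'
#' Frames of a coordinate trajectory in which the metal ion sits inside the
#' acidic chamber: the minimum distance from the ion to the carboxylate
#' oxygens of each chamber residue is at most `cutoff`. With
#' `semantics = "all"` (default) every chamber residue must satisfy the
#' cutoff simultaneously; `"any"` requires at least one. Composes with
#' [select_dissociated_snapshots()] via `frames`.
#'
#' @param window a [trajectory_window] with chamber residues resolved.
#' @param cutoff distance cutoff in Angstrom (default 6).
#' @param semantics `"all"` or `"any"`.
#' @param frames optional named list (by subunit) restricting the candidate
#'   frames (e.g. the dissociated-state selection).
#' @return named list (by subunit) of frame index vectors.
#' @export
select_chamber_snapshots <- function(window, cutoff = 6,
                                     semantics = c("all", "any"),
                                     frames = NULL) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(window, "trajectory_window"))
  out <- lapply(window$subunits, function(su) {
    if (is.null(su$mg_idx)) stop("no metal ion for subunit ", su$id)
    if (any(vapply(su$chamber, length, integer(1)) == 0L))
      stop("chamber carboxylates unresolved for subunit ", su$id)
    cand <- if (is.null(frames)) seq_len(nrow(window$xyz))
            else frames[[as.character(su$id)]]
    keep <- vapply(cand, function(i) {
      fr <- window$xyz[i, ]
      mg <- as.numeric(.xyz_at(fr, su$mg_idx))
      dmin <- vapply(su$chamber, function(idx)
        min(dist3(.xyz_at(fr, idx), mg)), numeric(1))
      if (semantics == "all") all(dmin <= cutoff) else any(dmin <= cutoff)
    }, logical(1))
    cand[keep]
  })
  names(out) <- vapply(window$subunits, function(su) as.character(su$id),
                       character(1))
  out
}
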