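#' 3D occupancy density maps from trajectory samples
#'
#' Sample positions are deposited on a regular grid by cloud-in-cell
#' (tri-linear) weighting, which conserves total mass exactly: the sum of the
#' grid equals the number of deposited samples. Grid nodes sit at
#' `origin + (0:(n-1)) * spacing` along each axis.
#'
#' @name density_map
NULL

new_density_map <- function(counts, origin, spacing, n_samples,
                            n_subunits = 1L, selection_label = "") {
  structure(list(counts = counts, origin = origin, spacing = spacing,
                 n_samples = n_samples, n_subunits = n_subunits,
                 selection_label = selection_label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map '%s': %s grid, spacing %.2f A, %d samples (%d subunit(s)), mass %.6g\n",
              x$selection_label, paste(dim(x$counts), collapse = "x"),
              x$spacing, x$n_samples, x$n_subunits, sum(x$counts)))
  invisible(x)
}

# Cloud-in-cell deposition of points (n x 3) onto a grid. Returns the counts
# array; grid must already cover all points with one node to spare.
.cic_deposit <- function(points, origin, spacing, dims) {
  rel <- sweep(points, 2L, origin) / spacing
  i0 <- floor(rel)
  f <- rel - i0
  i0 <- i0 + 1L  # 1-based node index of the lower corner
  if (any(i0 < 1L) || any(sweep(i0 + 1L, 2L, dims) > 0L))
    stop("grid does not cover all samples")
  nx <- dims[1]; ny <- dims[2]
  cv <- numeric(prod(dims))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    idx <- (i0[, 1] + cx) + (i0[, 2] + cy - 1L) * nx +
           (i0[, 3] + cz - 1L) * nx * ny
    agg <- rowsum(w, idx)
    ii <- as.integer(rownames(agg))
    cv[ii] <- cv[ii] + agg[, 1]
  }
  array(cv, dim = dims)
}

#' Deposit sample positions as a density map
#'
#' @param points numeric matrix (n x 3) of positions in Angstrom.
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param padding margin added around the samples in Angstrom (default 2).
#' @param origin,dims optional explicit grid (origin of the first node and
#'   node counts per axis); when given, the samples must fall inside.
#' @param selection_label free-text label stored on the map.
#' @return a [density_map].
#' @export
deposit_density <- function(points, spacing = 0.5, padding = 2,
                            origin = NULL, dims = NULL,
                            selection_label = "") {
  points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) stop("empty selection: no positions to deposit")
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(points, 2L, min) - padding
    hi <- apply(points, 2L, max) + padding
    origin <- lo
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 2L)
  }
  counts <- .cic_deposit(points, origin, spacing, dims)
  new_density_map(counts, origin, spacing, nrow(points),
                  selection_label = selection_label)
}

#' Subunit-averaged density map from trajectory windows
#'
#' Collects the positions of the selected atoms over all frames of all
#' windows, per subunit; when `average_subunits` is set, each subunit's
#' samples are first superposed onto the first subunit by least-squares
#' (Kabsch) fitting of the binding-site CA atoms of the topology, then all
#' samples are deposited on one grid. The stored counts are the raw
#' accumulation (mass = total samples); [averaged_counts()] divides by the
#' number of subunits.
#'
#' @param windows list of [trajectory_window] (sharing one topology).
#' @param selection which atoms to deposit per subunit: `"mg"`, `"atp"`,
#'   `"gamma_p"`, or a function of a subunit definition returning atom
#'   indices.
#' @param spacing,padding grid geometry in Angstrom.
#' @param average_subunits superpose and pool the three subunits
#'   (default `TRUE`).
#' @param frames optional named list (by subunit) of frame indices to use
#'   (e.g. from [select_dissociated_snapshots()]).
#' @return a [density_map] with `n_subunits` set.
#' @export
density_map <- function(windows, selection = "mg", spacing = 0.5,
                        padding = 2, average_subunits = TRUE, frames = NULL) {
  if (inherits(windows, "trajectory_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1L)
  sel_fun <- if (is.function(selection)) selection else switch(
    selection,
    mg = function(su) su$mg_idx,
    atp = function(su) su$atp_idx,
    gamma_p = function(su) su$gamma_p_idx,
    stop("unknown selection: ", selection))
  topo <- windows[[1L]]$topology
  subus <- windows[[1L]]$subunits
  n_sub <- length(subus)
  topo_xyz <- as.vector(t(as.matrix(topo$atoms[, c("x", "y", "z")])))
  # per-subunit sample pools
  pools <- lapply(seq_len(n_sub), function(k) {
    su <- subus[[k]]
    idx <- sel_fun(su)
    if (is.null(idx) || length(idx) == 0L)
      stop("empty selection for subunit ", su$id)
    p <- do.call(rbind, lapply(windows, function(w) {
      fr_idx <- if (is.null(frames)) seq_len(nrow(w$xyz))
                else frames[[as.character(su$id)]]
      do.call(rbind, lapply(fr_idx, function(i) .xyz_at(w$xyz[i, ], idx)))
    }))
    # a subunit may contribute no frames (e.g. no dissociated snapshots)
    if (is.null(p)) matrix(numeric(0), ncol = 3L) else p
  })
  if (average_subunits && n_sub > 1L) {
    ref <- subus[[1L]]
    for (k in 2L:n_sub) {
      if (nrow(pools[[k]]) == 0L) next
      su <- subus[[k]]
      if (length(su$site_ca_idx) != length(ref$site_ca_idx) ||
          length(ref$site_ca_idx) < 3L)
        stop("need >= 3 matched binding-site CA atoms for superposition")
      fit <- bio3d::fit.xyz(fixed = topo_xyz, mobile = topo_xyz,
                            fixed.inds = bio3d::atom2xyz(ref$site_ca_idx),
                            mobile.inds = bio3d::atom2xyz(su$site_ca_idx),
                            full.pdbs = FALSE)
      # recover the rigid transform from the fitted CA coordinates
      from <- matrix(topo_xyz[bio3d::atom2xyz(su$site_ca_idx)],
                     ncol = 3L, byrow = TRUE)
      to <- matrix(fit[bio3d::atom2xyz(su$site_ca_idx)],
                   ncol = 3L, byrow = TRUE)
      tr <- .rigid_transform(from, to)
      pools[[k]] <- sweep(pools[[k]] %*% tr$R, 2L, tr$t, `+`)
    }
  }
  all_pts <- do.call(rbind, pools)
  map <- deposit_density(all_pts, spacing = spacing, padding = padding,
                         selection_label = if (is.function(selection))
                           "custom" else selection)
  map$n_subunits <- if (average_subunits) n_sub else 1L
  map
}

# Least-squares rigid transform mapping 'from' onto 'to' (Kabsch via SVD on
# the already-superposed coordinate pair returned by bio3d::fit.xyz).
.rigid_transform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2L, cf)) %*% sweep(to, 2L, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = as.numeric(ct - cf %*% R))
}

#' Subunit-averaged grid values
#'
#' @param map a [density_map].
#' @return the counts array divided by the number of pooled subunits.
#' @export
averaged_counts <- function(map) {
  stopifnot(inherits(map, "density_map"))
  map$counts / map$n_subunits
}

#' Gaussian-smooth a density map
#'
#' Separable Gaussian convolution; the grid is first extended by the kernel
#' radius on every side so that total mass is preserved (to rounding error).
#'
#' @param map a [density_map].
#' @param sigma kernel SD in Angstrom.
#' @return a new [density_map] on the extended grid.
#' @export
smooth_density <- function(map, sigma) {
  stopifnot(inherits(map, "density_map"), sigma >= 0)
  if (sigma == 0) return(map)
  sp <- map$spacing
  r <- max(1L, as.integer(ceiling(4 * sigma / sp)))
  k <- stats::dnorm(seq(-r, r) * sp, sd = sigma)
  k <- k / sum(k)
  d <- dim(map$counts)
  nd <- d + 2L * r
  a <- array(0, nd)
  a[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- map$counts
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      sh <- j - r - 1L
      idx_src <- pmax(1L, 1L - sh):pmin(dim(a)[axis], dim(a)[axis] - sh)
      idx_dst <- idx_src + sh
      if (axis == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * a[idx_src, , ]
      if (axis == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * a[, idx_src, ]
      if (axis == 3L) out[, , idx_dst] <- out[, , idx_dst] + k[j] * a[, , idx_src]
    }
    out
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  out <- map
  out$counts <- a
  out$origin <- map$origin - r * sp
  out
}

#' Weighted centroid of a density map
#'
#' @param map a [density_map].
#' @return length-3 position in Angstrom (grid-value-weighted mean of node
#'   positions).
#' @export
density_centroid <- function(map) {
  d <- dim(map$counts)
  tot <- sum(map$counts)
  vapply(1:3, function(ax) {
    coords <- map$origin[ax] + (seq_len(d[ax]) - 1L) * map$spacing
    marg <- apply(map$counts, ax, sum)
    sum(coords * marg) / tot
  }, numeric(1))
}

#' Write a density map as a CCP4/MRC volume
#'
#' Minimal mode-2 (float32) MRC writer for visualization of computed maps.
#'
#' @param map a [density_map].
#' @param path output path.
#' @param averaged write the subunit-averaged values (default `TRUE`).
#' @return the path, invisibly.
#' @export
write_mrc <- function(map, path, averaged = TRUE) {
  vals <- if (averaged) averaged_counts(map) else map$counts
  d <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)              # NX NY NZ
  wi(2L)             # MODE float32
  wi(c(0L, 0L, 0L))  # NXSTART..
  wi(d)              # MX MY MZ
  wf(d * map$spacing)        # cell lengths
  wf(c(90, 90, 90))          # cell angles
  wi(c(1L, 2L, 3L))          # axis order
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))              # ISPG, NSYMBT
  wi(rep(0L, 25L))           # extra (words 25-49)
  wf(map$origin)             # ORIGIN x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(vals)))
  wi(0L)                     # NLABL
  writeBin(raw(800L), con)   # labels
  wf(as.vector(vals))
  invisible(path)
}
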