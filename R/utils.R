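#' Overflow-safe log-sum-exp
#'
#' Computes log(sum(exp(x))) with the usual max-shift so that large exponents
#' (e.g. R/d with R = 1000 A and d ~ 2-3 A) do not overflow.
#'
#' @param x numeric vector, finite.
#' @return log(sum(exp(x))) as a scalar.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Euclidean distance between rows of two coordinate matrices
#' @param a,b numeric matrices with 3 columns (or length-3 vectors).
#' @return numeric vector of pairwise (row-wise broadcast) distances.
#' @keywords internal
dist3 <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

# Standard atomic masses for the elements this package encounters.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  MG = 24.305, CA = 40.078, "NA" = 22.990, K = 39.098, MN = 54.938,
  ZN = 65.38, FE = 55.845, NI = 58.693, CO = 58.933, CD = 112.414,
  CU = 63.546, CL = 35.45
)

#' Atomic masses for element symbols
#' @param elements character vector of element symbols (any case).
#' @return numeric vector of masses in Da; unknown elements get 12.011 with a
#'   warning (treated as carbon-like; only affects center-of-mass weighting).
#' @keywords internal
element_mass <- function(elements) {
  key <- toupper(trimws(elements))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    warning("unknown element(s): ", paste(unique(key[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

#' Run a function with a locally seeded RNG
#'
#' Saves and restores the caller's RNG state so generators are reproducible
#' from their own seed without touching global randomness.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
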