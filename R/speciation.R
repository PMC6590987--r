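#' Equilibrium speciation of metal-ATP recording solutions
#'
#' Models 1:1 metal-nucleotide complexation for several cations competing for
#' ATP, with association (stability) constants given as log10 values in
#' M^-1. For each cation M, [M.ATP] = K_M [M]_free [ATP]_free; mass balance
#' closes the system. Protonation equilibria and activity corrections are not
#' modeled.
#'
#' @param totals named numeric of total concentrations in molar; must include
#'   `ATP`, other names are cations (subset of the constants' names).
#' @param log10_K named numeric of log10 stability constants (M^-1); defaults
#'   are the values tabulated for ATP: Mg 4.10, Ca 3.76, Na 0.83, K 1.17.
#' @return object of class `speciation_system`.
#' @export
speciation_system <- function(totals,
                              log10_K = c(Mg = 4.10, Ca = 3.76,
                                          Na = 0.83, K = 1.17)) {
  stopifnot(is.numeric(totals), !is.null(names(totals)),
            "ATP" %in% names(totals), all(totals >= 0),
            !anyNA(log10_K), all(log10_K < Inf))  # -Inf = no binding
  cations <- setdiff(names(totals), "ATP")
  missing_K <- setdiff(cations, names(log10_K))
  if (length(missing_K))
    stop("no stability constant for: ", paste(missing_K, collapse = ", "))
  structure(list(totals = totals, log10_K = log10_K, cations = cations),
            class = "speciation_system")
}

#' Solve the competitive-binding mass balance
#'
#' Finds the free concentrations satisfying, for every cation,
#' `[M.ATP] = K_M [M]_free [ATP]_free` and mass conservation of ATP and of
#' each cation. The ATP balance is solved by damped Newton iteration on free
#' ATP with a guaranteed bisection fallback (the balance function is strictly
#' increasing in free ATP).
#'
#' @param system a [speciation_system()].
#' @param tol relative residual tolerance (default 1e-12).
#' @return object of class `speciation_result`: `free` (named, M),
#'   `complexes` (named by cation, M), `residuals` (named mass-balance
#'   residuals, M).
#' @export
solve_speciation <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "speciation_system"))
  totals <- system$totals
  Tatp <- totals[["ATP"]]
  cats <- system$cations
  K <- 10^system$log10_K[cats]
  Tm <- totals[cats]
  # ATP balance: g(x) = x + sum_M K T_M x / (1 + K x) - T_ATP, increasing in x
  g <- function(x) x + sum(K * Tm * x / (1 + K * x)) - Tatp
  gprime <- function(x) 1 + sum(K * Tm / (1 + K * x)^2)
  lo <- 0; hi <- Tatp
  x <- if (Tatp > 0) Tatp / 2 else 0
  if (Tatp > 0) {
    floor_c <- 1e-18
    for (it in 1:200) {
      gx <- g(x)
      if (gx > 0) hi <- x else lo <- x
      step <- gx / gprime(x)
      xn <- x - step
      if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
      xn <- max(xn, floor_c)
      if (abs(g(xn)) <= tol * max(Tatp, 1e-300)) { x <- xn; break }
      x <- xn
    }
  }
  mfree <- Tm / (1 + K * x)
  cx <- K * mfree * x
  free <- c(ATP = x, mfree)
  residuals <- c(ATP = (x + sum(cx)) - Tatp, (mfree + cx) - Tm)
  names(residuals) <- c("ATP", cats)
  if (Tatp > 0 && abs(residuals[["ATP"]]) > 1e-9 * max(Tatp, 1e-300))
    stop("speciation solver did not converge; ATP residual ",
         format(residuals[["ATP"]]))
  structure(list(free = free, complexes = cx, residuals = residuals),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("free (M):\n"); print(signif(x$free, 6))
  cat("complexes with ATP (M):\n"); print(signif(x$complexes, 6))
  invisible(x)
}

#' Design totals achieving target free ATP and metal-ATP concentrations
#'
#' Given a target free-ATP concentration and a target concentration of one
#' cation's ATP complex, computes the total cation and total ATP that realize
#' them in the presence of fixed background cations. The 1:1 model admits an
#' exact inversion: free metal = target complex / (K x), totals follow from
#' mass balance; the result is verified against [solve_speciation()].
#'
#' @param target_free_ATP target free ATP (M), > 0.
#' @param target_complex target concentration (M) of `cation`-ATP, >= 0.
#' @param cation name of the designed cation (default `"Mg"`).
#' @param background a [speciation_system()] holding the fixed totals of the
#'   other cations (its `ATP` and `cation` totals are ignored) and the
#'   constants.
#' @return named numeric of required totals (ATP and all cations), with the
#'   verified [speciation_result] as attribute `"solution"`.
#' @export
design_free_atp_solution <- function(target_free_ATP, target_complex,
                                     cation = "Mg", background = NULL) {
  stopifnot(target_free_ATP > 0, target_complex >= 0)
  if (is.null(background))
    background <- speciation_system(c(ATP = 0))
  log10_K <- background$log10_K
  if (!cation %in% names(log10_K))
    stop("no stability constant for ", cation)
  K <- 10^log10_K[[cation]]
  x <- target_free_ATP
  m_free <- target_complex / (K * x)
  total_cat <- m_free + target_complex
  bg <- setdiff(background$cations, cation)
  Kbg <- 10^log10_K[bg]
  Tbg <- background$totals[bg]
  cx_bg <- if (length(bg)) Kbg * (Tbg / (1 + Kbg * x)) * x else numeric(0)
  total_atp <- x + target_complex + sum(cx_bg)
  totals <- c(ATP = total_atp, stats::setNames(total_cat, cation),
              if (length(bg)) Tbg)
  sol <- solve_speciation(speciation_system(totals, log10_K))
  if (abs(sol$free[["ATP"]] - x) > 1e-9 * x ||
      (target_complex > 0 &&
       abs(sol$complexes[[cation]] - target_complex) > 1e-9 * target_complex))
    stop("infeasible targets: forward solution does not reproduce them")
  attr(totals, "solution") <- sol
  totals
}
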