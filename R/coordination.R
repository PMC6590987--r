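#' Soft-minimum ion-coordination number
#'
#' For one phosphate group, summarizes the distances between its non-backbone
#' oxygen atoms and a metal ion as a single number
#' \deqn{N^s = R / \ln \sum_i \exp(R / d_i)}
#' a smooth lower bound on the minimum oxygen-ion distance. For large `R`
#' (default 1000 A) the value converges to `min(d)` from below; values under
#' the 3.2 A threshold indicate direct coordination by that phosphate group.
#' Computed with a shifted log-sum-exp so that `exp(R/d)` never overflows.
#'
#' @param distances numeric vector of oxygen-ion distances in Angstrom,
#'   all positive.
#' @param R smoothing parameter in Angstrom (default 1000).
#' @return the coordination number in Angstrom; always `<= min(distances)`.
#' @examples
#' softmin_coordination_number(c(3.0, 4.0, 5.0))    # ~ 3.0
#' softmin_coordination_number(c(2.0, 2.0))         # 1000 / (500 + ln 2)
#' @export
softmin_coordination_number <- function(distances, R = 1000) {
  if (length(distances) == 0L) stop("no coordinating oxygens")
  if (!all(is.finite(distances)) || any(distances <= 0))
    stop("distances must be finite and positive")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  R / logsumexp(R / distances)
}

# Phosphate labels, in order; "a"/"b"/"g" stand for the alpha-, beta- and
# gamma-phosphate groups. A coordination mode is the concatenation of the
# labels of the groups whose N^s falls below the threshold ("none" if empty).
.phosphate_labels <- c("a", "b", "g")

#' All possible coordination-mode labels
#' @return character vector of the 8 mode labels.
#' @export
coordination_modes <- function() {
  c("a", "b", "g", "ab", "ag", "bg", "abg", "none")
}

.mode_from_N <- function(N, threshold) {
  hit <- .phosphate_labels[N < threshold]
  if (length(hit) == 0L) "none" else paste(hit, collapse = "")
}

#' Classify the coordination mode of a metal ion at a nucleotide site
#'
#' Computes the per-phosphate coordination number from each group's
#' non-backbone oxygens and assigns the mode as the set of groups whose
#' value falls below the direct-coordination threshold.
#'
#' @param site a `nucleotide_site` from [extract_sites()] or
#'   [make_structure_fixture()].
#' @param metal one row of an atom table (the ion), or a length-3 numeric
#'   position in Angstrom.
#' @param threshold direct-coordination cutoff in Angstrom (default 3.2).
#' @param R soft-min smoothing parameter in Angstrom (default 1000).
#' @return object of class `coordination_result`: list with `N` (named
#'   numeric, labels `a`, `b`, `g`), `mode`, `metal`, `R_parameter`,
#'   `threshold`.
#' @export
classify_mode <- function(site, metal, threshold = 3.2, R = 1000) {
  stopifnot(inherits(site, "nucleotide_site"))
  if (!isTRUE(site$complete)) stop("incomplete site: ", site$flag_reason)
  pos <- metal_position(metal)
  N <- vapply(.phosphate_labels, function(s) {
    ox <- site$phosphate_oxygens[[s]]
    softmin_coordination_number(dist3(atom_xyz(ox), pos), R = R)
  }, numeric(1))
  structure(
    list(N = N, mode = .mode_from_N(N, threshold), metal = metal,
         R_parameter = R, threshold = threshold),
    class = "coordination_result"
  )
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination mode: %s  (N^a=%.3f, N^b=%.3f, N^g=%.3f A; threshold %.2f A)\n",
              x$mode, x$N["a"], x$N["b"], x$N["g"], x$threshold))
  invisible(x)
}

metal_position <- function(metal) {
  if (is.numeric(metal) && length(metal) == 3L) return(as.numeric(metal))
  if (is.data.frame(metal)) return(as.numeric(metal[1L, c("x", "y", "z")]))
  stop("metal must be an atom-table row or a length-3 position")
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# min-over-phosphates N^s of one candidate ion at a site
.best_N <- function(site, pos, R) {
  min(vapply(.phosphate_labels, function(s) {
    softmin_coordination_number(dist3(atom_xyz(site$phosphate_oxygens[[s]]), pos), R = R)
  }, numeric(1)))
}

#' Select the bound metal ion of a given element at a site
#'
#' Among candidate ions of `target_element`, returns the one whose best
#' (minimum over the three phosphate groups) coordination number is smallest,
#' provided it falls below the threshold; otherwise `NULL` (no bound ion).
#'
#' @inheritParams classify_mode
#' @param target_element element symbol, e.g. `"MG"` or `"CA"`.
#' @return one atom-table row, or `NULL`.
#' @export
select_bound_metal <- function(site, target_element, threshold = 3.2, R = 1000) {
  stopifnot(inherits(site, "nucleotide_site"))
  cand <- site$candidate_metals
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[toupper(cand$element) == toupper(target_element), , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  best <- vapply(seq_len(nrow(cand)), function(i)
    .best_N(site, as.numeric(cand[i, c("x", "y", "z")]), R), numeric(1))
  i <- which.min(best)
  if (best[i] < threshold) cand[i, , drop = FALSE] else NULL
}

#' Check for a concurrently bound cation of another element
#'
#' `TRUE` (the structure should be excluded from the survey) iff any candidate
#' ion whose element differs from the target is itself directly coordinated
#' (best N^s below the threshold).
#'
#' @inheritParams select_bound_metal
#' @return logical scalar.
#' @export
concurrent_cation_check <- function(site, target_element, threshold = 3.2, R = 1000) {
  stopifnot(inherits(site, "nucleotide_site"))
  cand <- site$candidate_metals
  if (is.null(cand) || nrow(cand) == 0L) return(FALSE)
  other <- cand[toupper(cand$element) != toupper(target_element), , drop = FALSE]
  if (nrow(other) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(other)), function(i)
    .best_N(site, as.numeric(other[i, c("x", "y", "z")]), R), numeric(1)) < threshold)
}
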