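#' Redundancy filtering and the coordination-mode survey
#'
#' The survey applies, in order: an experimental filter (X-ray, resolution at
#' or better than 2.5 A), sequence-redundancy elimination at 70% identity,
#' nucleotide-site extraction, bound-ion selection, concurrent-cation
#' exclusion, and coordination-mode classification, producing a mode
#' occurrence table plus a per-entry audit log.
#'
#' @name coordination_survey
NULL

# identity of the chain(s) contacting the nucleotide: chains with any CA
# within contact_radius of a ligand atom (all chains if no ligand resolved),
# concatenated in chain-id order.
.survey_sequence <- function(model, ligand_codes, contact_radius = 8) {
  a <- model$atoms
  seqs <- model$chain_sequences
  if (length(seqs) == 0L) return(NA_character_)
  lig <- a[a$resname %in% ligand_codes, , drop = FALSE]
  chains <- names(seqs)
  if (nrow(lig) > 0L) {
    ca <- a[a$name == "CA" & a$resname %in% .aa3, , drop = FALSE]
    touching <- vapply(chains, function(ch) {
      cc <- ca[ca$chain == ch, , drop = FALSE]
      if (nrow(cc) == 0L) return(FALSE)
      any(vapply(seq_len(nrow(cc)), function(i)
        min(dist3(atom_xyz(lig), as.numeric(cc[i, c("x", "y", "z")]))) <=
          contact_radius, logical(1)))
    }, logical(1))
    if (any(touching)) chains <- chains[touching]
  }
  paste(seqs[sort(chains)], collapse = "")
}

.pairwise_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  # PID1: matches / alignment length
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Eliminate redundant structures by sequence identity
#'
#' Greedy clustering in order of resolution quality (best first): a model is
#' kept iff its nucleotide-contacting chain sequence has less than
#' `identity_cutoff` global-alignment identity (matches over alignment
#' length, BLOSUM62 scoring) to every model already kept. Ties in resolution
#' are broken by entry id, so the result is deterministic.
#'
#' @param models list of [structure_model].
#' @param identity_cutoff redundancy threshold as a fraction (default 0.70).
#' @param ligand_codes nucleotide residue codes used to pick the contacting
#'   chains.
#' @return list of retained models, with the per-model decisions as
#'   attribute `"log"` (data.frame: entry, decision, identity_to).
#' @export
filter_redundancy <- function(models, identity_cutoff = 0.70,
                              ligand_codes = c("ATP", "ANP")) {
  stopifnot(length(models) >= 1L)
  seqs <- vapply(models, .survey_sequence, character(1),
                 ligand_codes = ligand_codes)
  ids <- vapply(models, function(m) m$entry_id, character(1))
  res <- vapply(models, function(m)
    if (is.na(m$resolution)) Inf else m$resolution, numeric(1))
  ord <- order(res, ids)
  kept <- integer(0)
  log <- data.frame(entry = character(0), decision = character(0),
                    identity_to = character(0), stringsAsFactors = FALSE)
  for (i in ord) {
    if (is.na(seqs[i]) || nchar(seqs[i]) == 0L) {
      log <- rbind(log, data.frame(entry = ids[i], decision = "excluded_no_sequence",
                                   identity_to = NA_character_))
      next
    }
    hit <- NA_character_
    for (j in kept) {
      if (.pairwise_identity(seqs[i], seqs[j]) > identity_cutoff) {
        hit <- ids[j]; break
      }
    }
    if (is.na(hit)) {
      kept <- c(kept, i)
      log <- rbind(log, data.frame(entry = ids[i], decision = "kept",
                                   identity_to = NA_character_))
    } else {
      log <- rbind(log, data.frame(entry = ids[i],
                                   decision = "excluded_redundant",
                                   identity_to = hit))
    }
  }
  out <- models[sort(kept)]
  attr(out, "log") <- log
  out
}

#' Run the coordination-mode survey over a directory of structures
#'
#' @param structure_dir directory of PDB/mmCIF files.
#' @param ligand nucleotide residue code (default `"ATP"`).
#' @param metal target ion element symbol (default `"MG"`).
#' @param threshold direct-coordination cutoff in Angstrom (default 3.2).
#' @param R soft-min parameter in Angstrom (default 1000).
#' @param max_resolution inclusion cutoff in Angstrom (default 2.5).
#' @param identity_cutoff redundancy threshold (default 0.70).
#' @param require_xray keep only X-ray entries (default `TRUE`).
#' @param per_site count one row per site instead of per entry (majority
#'   mode, ties broken by the site with the lowest best N; default `FALSE`).
#' @return object of class `survey_table`: `rows` (data.frame mode, count,
#'   percent), `n_entries`, exclusion counters, and `audit` (per-file log).
#' @export
run_survey <- function(structure_dir, ligand = "ATP", metal = "MG",
                       threshold = 3.2, R = 1000, max_resolution = 2.5,
                       identity_cutoff = 0.70, require_xray = TRUE,
                       per_site = FALSE) {
  files <- sort(list.files(structure_dir,
                           pattern = "\\.(pdb|ent|cif|mmcif)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no structure files in ", structure_dir)
  audit <- data.frame(entry = character(0), decision = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  note <- function(entry, decision, detail = "") {
    audit <<- rbind(audit, data.frame(entry = entry, decision = decision,
                                      detail = detail,
                                      stringsAsFactors = FALSE))
  }
  models <- list()
  n_res <- 0L
  for (f in files) {
    m <- tryCatch(parse_structure(f), error = function(e) e)
    if (inherits(m, "error")) {
      note(basename(f), "skipped_unparseable", conditionMessage(m))
      next
    }
    if (require_xray && !is.na(m$method) && !grepl("X-RAY", m$method)) {
      note(m$entry_id, "excluded_method", m$method)
      next
    }
    if (is.na(m$resolution) || m$resolution > max_resolution) {
      note(m$entry_id, "excluded_resolution",
           sprintf("%.2f A", m$resolution))
      n_res <- n_res + 1L
      next
    }
    models[[length(models) + 1L]] <- m
  }
  n_red <- 0L
  if (length(models) > 0L) {
    kept <- filter_redundancy(models, identity_cutoff,
                              ligand_codes = ligand)
    rlog <- attr(kept, "log")
    for (i in seq_len(nrow(rlog))) {
      if (rlog$decision[i] != "kept") {
        note(rlog$entry[i], rlog$decision[i],
             ifelse(is.na(rlog$identity_to[i]), "", rlog$identity_to[i]))
        n_red <- n_red + 1L
      }
    }
    models <- kept
  }
  n_conc <- 0L
  tallies <- character(0)
  for (m in models) {
    sites <- extract_sites(m, ligand_codes = ligand)
    if (length(sites) == 0L) {
      note(m$entry_id, "excluded_no_site", "")
      next
    }
    site_modes <- character(0)
    site_bestN <- numeric(0)
    concurrent <- FALSE
    for (site in sites) {
      if (concurrent_cation_check(site, metal, threshold, R)) {
        concurrent <- TRUE
        break
      }
      # classify against the nearest candidate ion of the target element;
      # a site whose best ion sits above the threshold contributes "none"
      ion <- select_bound_metal(site, metal, threshold = Inf, R = R)
      if (is.null(ion)) next
      cr <- classify_mode(site, ion, threshold, R)
      site_modes <- c(site_modes, cr$mode)
      site_bestN <- c(site_bestN, min(cr$N))
    }
    if (concurrent) {
      note(m$entry_id, "excluded_concurrent_cation", "")
      n_conc <- n_conc + 1L
      next
    }
    if (length(site_modes) == 0L) {
      note(m$entry_id, "excluded_no_metal", "")
      next
    }
    if (per_site) {
      tallies <- c(tallies, site_modes)
      note(m$entry_id, "classified",
           paste(site_modes, collapse = ","))
    } else {
      tab <- table(site_modes)
      top <- names(tab)[tab == max(tab)]
      mode <- if (length(top) == 1L) top
              else site_modes[site_modes %in% top][
                which.min(site_bestN[site_modes %in% top])]
      tallies <- c(tallies, mode)
      note(m$entry_id, "classified", mode)
    }
  }
  counts <- table(factor(tallies, levels = coordination_modes()))
  n_entries <- length(tallies)
  rows <- data.frame(mode = names(counts), count = as.integer(counts),
                     percent = if (n_entries > 0)
                       100 * as.integer(counts) / n_entries else
                       rep(0, length(counts)),
                     stringsAsFactors = FALSE)
  structure(list(rows = rows, n_entries = n_entries,
                 n_excluded_resolution = n_res,
                 n_excluded_redundant = n_red,
                 n_excluded_concurrent = n_conc,
                 ligand = ligand, metal = metal, audit = audit),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("survey of %s-%s coordination modes: %d classified entries\n",
              x$metal, x$ligand, x$n_entries))
  cat(sprintf("excluded: %d resolution, %d redundant, %d concurrent cation\n",
              x$n_excluded_resolution, x$n_excluded_redundant,
              x$n_excluded_concurrent))
  print(x$rows[x$rows$count > 0 | x$rows$mode == "none", ], row.names = FALSE)
  invisible(x)
}

#' Write a survey table and its audit log as TSV
#'
#' @param table a `survey_table`.
#' @param path output TSV path for the mode table; the audit log goes to
#'   `<path>.audit.tsv`.
#' @return the path, invisibly.
#' @export
write_survey <- function(table, path) {
  utils::write.table(table$rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$audit, paste0(path, ".audit.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
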