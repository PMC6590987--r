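#' Structure models and nucleotide-metal site extraction
#'
#' A `structure_model` is a plain list: `entry_id`, `atoms` (a data.frame with
#' columns `element`, `name`, `x`, `y`, `z`, `resname`, `resno`, `chain`,
#' `altloc`, `occupancy`, `type`), `resolution` (A, or NA), `method` (string,
#' or NA) and `chain_sequences` (named character, one-letter codes per chain).
#'
#' @name structure_model
NULL

new_structure_model <- function(entry_id, atoms, resolution = NA_real_,
                                method = NA_character_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  structure(
    list(entry_id = entry_id, atoms = atoms, resolution = resolution,
         method = method, chain_sequences = .chain_sequences(atoms)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d chain(s), resolution %s A, method %s\n",
              x$entry_id, nrow(x$atoms), length(unique(x$atoms$chain)),
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              ifelse(is.na(x$method), "NA", x$method)))
  invisible(x)
}

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

.aa3to1 <- stats::setNames(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                             "I", "L", "K", "M", "F", "P", "S", "T", "W",
                             "Y", "V"), .aa3)

.chain_sequences <- function(atoms) {
  ca <- atoms[atoms$name == "CA" & atoms$resname %in% .aa3, , drop = FALSE]
  if (nrow(ca) == 0L) return(character(0))
  vapply(split(ca, ca$chain), function(df) {
    df <- df[order(df$resno), , drop = FALSE]
    df <- df[!duplicated(df$resno), , drop = FALSE]
    paste(.aa3to1[df$resname], collapse = "")
  }, character(1))
}

# Keep a single altloc per atom: highest occupancy, ties broken alphabetically.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, , drop = FALSE]
    idx[order(-sub$occupancy, sub$altloc)][1L]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

.scan_pdb_header <- function(lines) {
  res <- NA_real_
  met <- NA_character_
  r <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(r)) {
    tail_str <- sub(".*RESOLUTION\\.+", "", r[1])
    num <- regmatches(tail_str, regexpr("[0-9]+\\.?[0-9]*", tail_str))
    if (length(num)) res <- as.numeric(num)
  }
  e <- grep("^EXPDTA", lines, value = TRUE)
  if (length(e)) met <- trimws(sub("^EXPDTA\\s*", "", e[1]))
  list(resolution = res, method = met)
}

.scan_cif_header <- function(lines) {
  res <- NA_real_
  met <- NA_character_
  r <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(r)) {
    tail_str <- sub(".*_refine\\.ls_d_res_high", "", r[1])
    num <- regmatches(tail_str, regexpr("[0-9]+\\.?[0-9]*", tail_str))
    if (length(num)) res <- as.numeric(num)
  }
  e <- grep("_exptl\\.method", lines, value = TRUE)
  if (length(e)) met <- gsub("['\"]", "", trimws(sub(".*_exptl\\.method", "", e[1])))
  list(resolution = res, method = met)
}

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates (via bio3d), keeping the first model of
#' multi-model files (with a warning) and resolving alternate locations to
#' the highest-occupancy conformer (ties broken alphabetically). Resolution
#' and experimental method are taken from the header when present.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param entry_id identifier recorded on the model; defaults to the file
#'   base name.
#' @return a [structure_model].
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif"),
                            entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (is.null(entry_id))
    entry_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  a <- pdb$atom
  xyz <- pdb$xyz
  n_models <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (n_models > 1L) {
    warning("multi-model file ", basename(path), ": keeping first model")
    m1 <- matrix(xyz[1L, ], ncol = 3L, byrow = TRUE)
    a$x <- m1[, 1L]; a$y <- m1[, 2L]; a$z <- m1[, 3L]
  }
  elem <- toupper(trimws(a$elesy))
  blank <- is.na(elem) | elem == ""
  if (any(blank))  # fall back to the leading letter(s) of the atom name
    elem[blank] <- toupper(gsub("[^A-Za-z].*$", "", trimws(a$elety[blank])))
  atoms <- data.frame(
    element = elem,
    name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    resname = trimws(a$resid),
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    type = a$type,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms <- .resolve_altlocs(atoms)
  hdr <- if (format == "pdb") .scan_pdb_header(lines) else .scan_cif_header(lines)
  new_structure_model(entry_id, atoms, hdr$resolution, hdr$method)
}

# Non-backbone phosphate oxygen names for ATP and AMP-PNP (residue code ANP).
# Bridging atoms (O5', O3A and O3B -- N3B in AMP-PNP) are excluded.
.phosphate_oxygen_names <- list(
  a = c("O1A", "O2A"),
  b = c("O1B", "O2B"),
  g = c("O1G", "O2G", "O3G")
)

#' Extract nucleotide-metal sites from a structure
#'
#' Locates each nucleotide instance (by residue code), collects the
#' non-backbone phosphate oxygens of the alpha-, beta- and gamma-groups
#' (2/2/3 atoms for intact ATP or AMP-PNP), the gamma-phosphorus, and every
#' metal ion of the requested elements within a generous capture radius of
#' any phosphate oxygen. Sites with missing phosphate atoms are excluded
#' with a message.
#'
#' @param model a [structure_model].
#' @param ligand_codes residue codes treated as nucleotides
#'   (default `c("ATP", "ANP")`).
#' @param metal_elements element symbols of candidate ions.
#' @param capture_radius candidate-ion capture radius in Angstrom
#'   (default 10); actual binding is decided by [select_bound_metal()].
#' @return list of `nucleotide_site` objects.
#' @export
extract_sites <- function(model,
                          ligand_codes = c("ATP", "ANP"),
                          metal_elements = c("MG", "CA", "NA", "K", "MN", "ZN",
                                             "FE", "NI", "CO", "CD", "CU"),
                          capture_radius = 10) {
  stopifnot(inherits(model, "structure_model"),
            length(ligand_codes) > 0L, length(metal_elements) > 0L)
  atoms <- model$atoms
  lig <- atoms[atoms$resname %in% ligand_codes, , drop = FALSE]
  if (nrow(lig) == 0L) return(list())
  metals <- atoms[toupper(atoms$element) %in% toupper(metal_elements) &
                    !(atoms$resname %in% c(.aa3, "HOH", ligand_codes)), ,
                  drop = FALSE]
  keys <- unique(lig[, c("chain", "resno", "resname")])
  # deterministic order regardless of file atom order
  keys <- keys[order(keys$chain, keys$resno), , drop = FALSE]
  sites <- list()
  for (i in seq_len(nrow(keys))) {
    la <- lig[lig$chain == keys$chain[i] & lig$resno == keys$resno[i], ,
              drop = FALSE]
    ox <- lapply(.phosphate_oxygen_names, function(nm)
      la[la$name %in% nm, , drop = FALSE])
    pg <- la[la$name == "PG", , drop = FALSE]
    sizes_ok <- nrow(ox$a) == 2L && nrow(ox$b) == 2L && nrow(ox$g) == 3L &&
      nrow(pg) == 1L
    if (!sizes_ok) {
      message("site ", keys$resname[i], " ", keys$chain[i], keys$resno[i],
              " in ", model$entry_id,
              ": missing phosphate atoms; excluded")
      next
    }
    allox <- do.call(rbind, ox)
    cm <- metals
    if (nrow(cm) > 0L) {
      near <- vapply(seq_len(nrow(cm)), function(k)
        min(dist3(atom_xyz(allox), as.numeric(cm[k, c("x", "y", "z")]))) <=
          capture_radius, logical(1))
      cm <- cm[near, , drop = FALSE]
    }
    sites[[length(sites) + 1L]] <- structure(
      list(ligand_code = keys$resname[i],
           chain = keys$chain[i], resno = keys$resno[i],
           phosphate_oxygens = ox,
           gamma_phosphorus = pg,
           all_ligand_atoms = la,
           candidate_metals = cm,
           complete = TRUE, flag_reason = NA_character_),
      class = "nucleotide_site"
    )
  }
  sites
}

#' @export
print.nucleotide_site <- function(x, ...) {
  cat(sprintf("nucleotide_site %s %s%d: %d candidate metal(s)\n",
              x$ligand_code, x$chain, x$resno,
              if (is.null(x$candidate_metals)) 0L else nrow(x$candidate_metals)))
  invisible(x)
}
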