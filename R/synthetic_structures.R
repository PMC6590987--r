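#' Synthetic structure fixtures with prescribed coordination geometry
#'
#' The fixture generator builds an idealized nucleotide (correct atom names;
#' three non-backbone gamma oxygens, two alpha and two beta) whose three
#' phosphate groups each point one oxygen toward a common chelation pocket,
#' so that every one of the eight coordination modes is geometrically
#' realizable, then solves for a metal position realizing the requested
#' per-phosphate distances. The spec of the fixture is its own classification
#' oracle.
#'
#' @name synthetic_structures
NULL

# Idealized triphosphate + token ribose tail. One oxygen per group (O1A, O1B,
# O1G) points into a chelation pocket at the origin; the remaining oxygens
# point outward. Bond lengths are approximate: only the oxygen-metal
# distances matter for classification.
.atp_template_base <- data.frame(
  name = c("PA", "O1A", "O2A", "O3A", "PB", "O1B", "O2B", "O3B",
           "PG", "O1G", "O2G", "O3G", "O5'", "C5'", "C4'", "C1'", "N9"),
  element = c("P", "O", "O", "O", "P", "O", "O", "O",
              "P", "O", "O", "O", "O", "C", "C", "C", "N"),
  x = c(3.40, 2.10, 4.60, 0.85, -1.70, -1.05, -2.45, -1.70,
        -1.70, -1.05, -2.45, -1.90, 4.40, 5.60, 6.80, 8.00, 9.00),
  y = c(0.00, 0.00, 0.00, 1.47, 2.94, 1.82, 4.23, 0.00,
        -2.94, -1.82, -4.24, -3.60, 0.00, 0.00, 0.80, 0.40, 1.20),
  z = c(0.80, 0.00, 1.70, 0.80, 0.80, 0.00, 1.15, 0.80,
        0.80, 0.00, 1.10, 2.30, -0.40, -1.00, -0.60, 0.20, 0.40),
  stringsAsFactors = FALSE)

.atp_template <- function(ligand_code = "ATP") {
  tab <- .atp_template_base
  if (ligand_code == "ANP") {  # imido beta-gamma bridge
    i <- tab$name == "O3B"
    tab$name[i] <- "N3B"
    tab$element[i] <- "N"
  }
  tab
}

#' Fixture specification
#'
#' @param mode target coordination mode, one of [coordination_modes()].
#' @param distances named numeric: target nearest-oxygen distance (A) for each
#'   phosphate group in the mode (names among `a`, `b`, `g`); default 2.3 A
#'   for every coordinating group (the smallest value realizable for every
#'   mode: the chelation-pocket circumradius is ~2.1 A, so a tridentate ion
#'   cannot sit closer than that to all three groups at once).
#' @param far_distance minimum nearest-oxygen distance (A) kept to
#'   non-coordinating groups (default 4.0, comfortably above the 3.2 A
#'   threshold; the pocket geometry caps it near 4.3 for two-group modes).
#' @param jitter positional noise SD (A) applied to the nucleotide atoms
#'   before the metal is placed, so the realized geometry always classifies
#'   to the requested mode (default 0.02).
#' @param seed integer seed for the jitter.
#' @param ligand_code `"ATP"` or `"ANP"`.
#' @param metal_element element symbol of the ion (default `"MG"`).
#' @param resolution,method header metadata written to the fixture.
#' @param sequence one-letter protein sequence for a CA-trace chain placed
#'   near the ligand (gives the survey's redundancy filter something to
#'   align); `NULL` for the default 20-mer.
#' @param entry_id identifier recorded in the file.
#' @param extra_cation optional `list(element =, distance =)`: adds a second,
#'   different cation directly coordinated at the given distance from a
#'   gamma-oxygen (for concurrent-cation exclusion fixtures).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(mode, distances = NULL, far_distance = 4.0,
                         jitter = 0.02, seed = 1L, ligand_code = "ATP",
                         metal_element = "MG", resolution = 2.0,
                         method = "X-RAY DIFFRACTION",
                         sequence = NULL, entry_id = "fixture",
                         extra_cation = NULL) {
  mode <- match.arg(mode, coordination_modes())
  groups <- if (mode == "none") character(0) else strsplit(mode, "")[[1]]
  if (is.null(distances)) {
    distances <- stats::setNames(rep(2.3, length(groups)), groups)
  } else {
    if (!setequal(names(distances), groups))
      stop("distances must be named exactly for the groups in mode '", mode, "'")
    distances <- distances[groups]
  }
  if (any(distances >= 3.2 - 0.05) || any(distances < 2.2))
    stop("coordinating distances must lie in [2.2, 3.15) A: safely below the",
         " 3.2 A threshold and outside the pocket circumradius")
  if (far_distance <= 3.5)
    stop("far_distance must exceed 3.5 A to keep non-coordinating groups clear")
  if (is.null(sequence))
    sequence <- "ACDEFGHIKLMNPQRSTVWY"
  structure(list(mode = mode, groups = groups, distances = distances,
                 far_distance = far_distance, jitter = jitter, seed = seed,
                 ligand_code = ligand_code, metal_element = metal_element,
                 resolution = resolution, method = method,
                 sequence = sequence, entry_id = entry_id,
                 extra_cation = extra_cation),
            class = "fixture_spec")
}

# Solve for a metal position realizing the per-group nearest-oxygen targets.
# ox: list a/b/g of coordinate matrices. Returns position or stops.
.place_metal <- function(ox, groups, distances, far_distance) {
  oxt <- lapply(ox, t)  # 3 x n, for fast column-wise distances
  nearest <- function(p, g) {
    d2 <- colSums((oxt[[g]] - p)^2)
    sqrt(min(d2))
  }
  obj <- function(p) {
    s <- 0
    for (g in names(ox)) {
      d <- nearest(p, g)
      # target distances dominate; the clearance term only nudges
      s <- s + if (g %in% groups) 10 * (d - distances[[g]])^2
               else max(0, (far_distance + 0.15) - d)^2
    }
    s
  }
  cent_all <- colMeans(do.call(rbind, ox))
  starts <- list()
  if (length(groups) == 0L) {
    # unbound but inside the 10 A candidate capture radius
    starts[[1]] <- cent_all + 7 * c(1, 1, 1) / sqrt(3)
  } else {
    pocket <- colMeans(do.call(rbind, lapply(groups, function(g) ox[[g]])))
    starts[[length(starts) + 1L]] <- pocket
    dir <- pocket - cent_all
    nd <- sqrt(sum(dir^2))
    if (nd > 1e-6) starts[[length(starts) + 1L]] <- pocket + 2.5 * dir / nd
    for (g in groups) for (i in seq_len(nrow(ox[[g]]))) {
      o <- ox[[g]][i, ]
      dir <- o - cent_all
      dir <- dir / sqrt(sum(dir^2))
      starts[[length(starts) + 1L]] <- o + distances[[g]] * dir
    }
    starts[[length(starts) + 1L]] <- pocket + c(0, 0, 3)
    starts[[length(starts) + 1L]] <- pocket - c(0, 0, 3)
  }
  for (p0 in starts) {
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-9))
    p <- fit$par
    ok_in <- all(vapply(groups, function(g)
      abs(nearest(p, g) - distances[[g]]) < 0.05, logical(1)))
    ok_out <- all(vapply(setdiff(names(ox), groups), function(g)
      nearest(p, g) >= far_distance, logical(1)))
    if (ok_in && ok_out) return(p)
  }
  stop("geometrically unrealizable fixture spec")
}

.aa1to3 <- stats::setNames(.aa3, c("A", "R", "N", "D", "C", "Q", "E", "G",
                                   "H", "I", "L", "K", "M", "F", "P", "S",
                                   "T", "W", "Y", "V"))

.ca_trace <- function(sequence, chain, start = c(9, 4, 0), resno0 = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  aa1to3 <- .aa1to3
  n <- length(aa)
  data.frame(
    element = "C", name = "CA",
    x = start[1], y = start[2] + 3.8 * (seq_len(n) - 1L), z = start[3],
    resname = unname(aa1to3[aa]), resno = resno0 + seq_len(n) - 1L,
    chain = chain, altloc = "", occupancy = 1, type = "ATOM",
    stringsAsFactors = FALSE
  )
}

#' Generate a structure fixture with a prescribed coordination mode
#'
#' Builds the idealized nucleotide, jitters its atoms, places the metal to
#' realize the requested per-phosphate distances, adds a CA-trace protein
#' chain, and (optionally) writes the model as a minimal PDB file. The
#' returned model classifies to `spec$mode` by construction.
#'
#' @param spec a [fixture_spec()].
#' @param path output PDB path, or `NULL` to skip writing.
#' @return a [structure_model] (invisibly the written path as attribute
#'   `"path"` when `path` is given).
#' @export
make_structure_fixture <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  lig <- .atp_template(spec$ligand_code)
  lig <- with_seed(spec$seed, {
    lig$x <- lig$x + stats::rnorm(nrow(lig), 0, spec$jitter)
    lig$y <- lig$y + stats::rnorm(nrow(lig), 0, spec$jitter)
    lig$z <- lig$z + stats::rnorm(nrow(lig), 0, spec$jitter)
    lig
  })
  ox <- lapply(.phosphate_oxygen_names, function(nm)
    as.matrix(lig[lig$name %in% nm, c("x", "y", "z")]))
  mpos <- .place_metal(ox, spec$groups, spec$distances, spec$far_distance)
  lig_atoms <- data.frame(
    element = lig$element, name = lig$name, x = lig$x, y = lig$y, z = lig$z,
    resname = spec$ligand_code, resno = 501L, chain = "A", altloc = "",
    occupancy = 1, type = "HETATM", stringsAsFactors = FALSE)
  metal_atom <- data.frame(
    element = spec$metal_element, name = spec$metal_element,
    x = mpos[1], y = mpos[2], z = mpos[3],
    resname = spec$metal_element, resno = 601L, chain = "A", altloc = "",
    occupancy = 1, type = "HETATM", stringsAsFactors = FALSE)
  extra_atom <- NULL
  if (!is.null(spec$extra_cation)) {
    # second cation bound at a gamma-oxygen, pointing away from the ligand
    o3g <- as.numeric(lig[lig$name == "O3G", c("x", "y", "z")])
    cent <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
    u <- o3g - cent; u <- u / sqrt(sum(u^2))
    ep <- o3g + spec$extra_cation$distance * u
    el <- toupper(spec$extra_cation$element)
    extra_atom <- data.frame(
      element = el, name = el, x = ep[1], y = ep[2], z = ep[3],
      resname = el, resno = 602L, chain = "A", altloc = "", occupancy = 1,
      type = "HETATM", stringsAsFactors = FALSE)
  }
  atoms <- rbind(.ca_trace(spec$sequence, "A"), lig_atoms, metal_atom,
                 extra_atom)
  model <- new_structure_model(spec$entry_id, atoms, spec$resolution,
                               spec$method)
  if (!is.null(path)) {
    write_fixture_pdb(model, path)
    attr(model, "path") <- path
  }
  model
}

#' Write a structure model as a minimal PDB file
#'
#' Emits REMARK 2 (resolution), EXPDTA and ATOM/HETATM records sufficient for
#' re-parsing by [parse_structure()]. Fixture output only; not a general PDB
#' writer.
#'
#' @param model a [structure_model].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fixture_pdb <- function(model, path) {
  a <- model$atoms
  lines <- c(
    sprintf("HEADER    SYNTHETIC FIXTURE                       01-JAN-26   %s",
            substr(toupper(model$entry_id), 1, 4)),
    if (!is.na(model$method)) paste0("EXPDTA    ", model$method),
    if (!is.na(model$resolution))
      sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", model$resolution)
  )
  name_field <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                       sprintf(" %-3s", a$name))
  rec <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 a$type, seq_len(nrow(a)), name_field, "", a$resname,
                 a$chain, a$resno, "", a$x, a$y, a$z, a$occupancy, 0,
                 toupper(a$element))
  writeLines(c(lines, rec, "END"), path)
  invisible(path)
}

#' Write a structure model as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop plus resolution/method tags; used to
#' exercise the mmCIF reading path on generated fixtures.
#'
#' @inheritParams write_fixture_pdb
#' @return the path, invisibly.
#' @export
write_fixture_cif <- function(model, path) {
  a <- model$atoms
  hdr <- c(
    paste0("data_", model$entry_id),
    if (!is.na(model$method)) sprintf("_exptl.method '%s'", model$method),
    if (!is.na(model$resolution))
      sprintf("_refine.ls_d_res_high %.2f", model$resolution),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf('%s %d %s "%s" . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s "%s" 1',
                  a$type, seq_len(nrow(a)), toupper(a$element), a$name,
                  a$resname, a$chain, a$resno,
                  a$x, a$y, a$z, a$occupancy, 0,
                  a$resno, a$resname, a$chain, a$name)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

# Rotation about z by angle (radians)
.rotz <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}

# Place a point at given distances from two anchors, in the plane through the
# anchors and a reference direction (law of cosines).
.bilaterate <- function(p1, p2, d1, d2, up = c(0, 0, 1)) {
  v <- p2 - p1
  L <- sqrt(sum(v^2))
  stopifnot(d1 + d2 > L, abs(d1 - d2) < L)
  ex <- v / L
  x <- (L^2 + d1^2 - d2^2) / (2 * L)
  h <- sqrt(max(0, d1^2 - x^2))
  ey <- up - sum(up * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  p1 + x * ex + h * ey
}

#' Synthetic trimeric receptor binding-site model
#'
#' A three-fold symmetric stand-in for the ATP- and Mg-bound trimeric receptor
#' site: each of the three subunits carries an idealized ATP with the metal
#' ion in the gamma-only coordination mode (directly coordinating a
#' gamma-phosphate oxygen, ~3.2 A from the gamma-phosphorus), a coordinating
#' aspartate carboxylate (D158), nearby glutamates E156 and E111, and E109
#' placed with its carboxylate ~9 A from the ion, plus CA traces of the
#' binding-site residues (T172, K63, K65, R281, R299). Entirely synthetic:
#' geometry realizes the distances the deposited structures are described to
#' have, for exercising the measurement pipeline offline.
#'
#' @param path output PDB path, or `NULL`.
#' @param mg_e109 target minimum Mg-to-E109-carboxylate-oxygen distance in A
#'   (default 9.0).
#' @param resolution header resolution written to the file (default 3.8 A).
#' @return a [structure_model] with three chains (A, B, C), one ATP and one
#'   Mg per chain.
#' @export
make_trimer_site_fixture <- function(path = NULL, mg_e109 = 9.0,
                                     resolution = 3.8) {
  lig <- .atp_template("ATP")
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  o2g <- xyz[lig$name == "O2G", ]
  pg <- xyz[lig$name == "PG", ]
  # Mg: 2.05 A from O2G, 3.2 A from PG (the bound-state D2 value), on the
  # outward side of the gamma group
  mg <- .bilaterate(pg, o2g, 3.2, 2.05, up = c(0, -1, 0.5))
  outward <- mg - pg; outward <- outward / sqrt(sum(outward^2))
  # D158 carboxylate coordinating Mg from the far side
  od1 <- mg + 2.05 * outward
  od2 <- od1 + c(0.0, -1.6, 1.2); od2 <- od1 + 2.2 * (od2 - od1) / sqrt(sum((od2 - od1)^2))
  cg158 <- (od1 + od2) / 2 + 0.7 * outward
  side_res <- function(resname, resno, ca, cb, cx, o1, o2, onames) {
    data.frame(
      element = c("C", "C", "C", "O", "O"),
      name = c("CA", "CB", if (resname == "ASP") "CG" else "CD", onames),
      x = c(ca[1], cb[1], cx[1], o1[1], o2[1]),
      y = c(ca[2], cb[2], cx[2], o1[2], o2[2]),
      z = c(ca[3], cb[3], cx[3], o1[3], o2[3]),
      resname = resname, resno = resno, chain = "A", altloc = "",
      occupancy = 1, type = "ATOM", stringsAsFactors = FALSE)
  }
  d158 <- side_res("ASP", 158L, mg + 5.5 * outward, mg + 4.2 * outward,
                   cg158, od1, od2, c("OD1", "OD2"))
  # E156 carboxylate ~4.5 A from Mg; E111 ~6.5 A; E109 at the requested ~9 A
  e_dir <- function(theta) as.numeric(.rotz(theta) %*% outward)
  place_glu <- function(resno, dist, theta, onames = c("OE1", "OE2")) {
    u <- e_dir(theta)
    oe1 <- mg + dist * u
    oe2 <- oe1 + c(0, 0, 2.2)
    cd <- oe1 + 1.3 * u
    side_res("GLU", resno, mg + (dist + 4.5) * u, mg + (dist + 3) * u,
             cd, oe1, oe2, onames)
  }
  e156 <- place_glu(156L, 4.5, 0.6)
  e111 <- place_glu(111L, 6.5, -0.6)
  e109 <- place_glu(109L, mg_e109, 1.2)
  bs_ca <- data.frame(
    element = "C", name = "CA",
    x = c(8, 10, 10, 6, 7), y = c(6, 2, -2, 8, -6), z = c(3, 3, 3, -2, 4),
    resname = c("THR", "LYS", "LYS", "ARG", "ARG"),
    resno = c(172L, 63L, 65L, 281L, 299L),
    chain = "A", altloc = "", occupancy = 1, type = "ATOM",
    stringsAsFactors = FALSE)
  lig_atoms <- data.frame(
    element = lig$element, name = lig$name, x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], resname = "ATP", resno = 501L, chain = "A", altloc = "",
    occupancy = 1, type = "HETATM", stringsAsFactors = FALSE)
  mg_atom <- data.frame(
    element = "MG", name = "MG", x = mg[1], y = mg[2], z = mg[3],
    resname = "MG", resno = 601L, chain = "A", altloc = "", occupancy = 1,
    type = "HETATM", stringsAsFactors = FALSE)
  sub <- rbind(d158, e156, e111, e109, bs_ca, lig_atoms, mg_atom)
  # shift the subunit off the symmetry axis, then generate C3 copies
  sub$x <- sub$x + 22
  copies <- lapply(0:2, function(k) {
    s <- sub
    rot <- .rotz(2 * pi * k / 3)
    v <- as.matrix(s[, c("x", "y", "z")]) %*% t(rot)
    s$x <- v[, 1]; s$y <- v[, 2]; s$z <- v[, 3]
    s$chain <- c("A", "B", "C")[k + 1L]
    s
  })
  atoms <- do.call(rbind, copies)
  model <- new_structure_model("trimer_site_synthetic", atoms, resolution,
                               "X-RAY DIFFRACTION")
  if (!is.null(path)) {
    write_fixture_pdb(model, path)
    attr(model, "path") <- path
  }
  model
}

#' Minimum distance from a site's bound metal to a residue's side-chain oxygens
#'
#' Convenience measurement used when checking ion placement against acidic
#' side chains (e.g. the Mg-to-E109 distance): the minimum over the named
#' residue's carboxylate oxygens of the distance to the given position.
#'
#' @param model a [structure_model].
#' @param position length-3 numeric (A).
#' @param resno residue number.
#' @param chain chain id.
#' @return distance in Angstrom.
#' @export
min_carboxylate_distance <- function(model, position, resno, chain) {
  a <- model$atoms
  sel <- a$resno == resno & a$chain == chain & a$element == "O" &
    a$name %in% c("OD1", "OD2", "OE1", "OE2")
  if (!any(sel)) stop("no carboxylate oxygens for residue ", resno, chain)
  min(dist3(atom_xyz(a[sel, , drop = FALSE]), as.numeric(position)))
}

#' Generate the mini-survey fixture set
#'
#' Writes eight structures with known ground truth into a directory: five
#' classifiable entries (modes g, bg, bg, abg, none), one excluded by the
#' 2.5 A resolution cutoff, one sequence-redundant duplicate of the g entry
#' at worse resolution, and one excluded for a concurrently bound sodium ion.
#' The expected survey outcome over the five classified entries is bg 40%,
#' g 20%, abg 20%, none 20%.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the per-fixture jitter.
#' @return data.frame of ground truth (file, entry, expected decision/mode),
#'   invisibly.
#' @export
make_survey_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- c(
    g1    = "ACDEFGHIKLMNPQRSTVWY",
    bg1   = "MKTAYIAKQRQISFVKSHFS",
    bg2   = "GSHMLEDPVANQWERTYLKC",
    abg1  = "QQWNATPGHRDDLCVMFYIS",
    none1 = "LLPPGGSSTTKKRRAAEEDN",
    low1  = "VVIIMMFFWWYYHHCCNNQQ",
    conc1 = "ADGKMPSVYCEHLNRTWFIQ"
  )
  specs <- list(
    list(file = "g_entry.pdb", mode = "g", res = 2.0, seq = seqs[["g1"]],
         extra = NULL, expect = "classified"),
    list(file = "bg_entry1.pdb", mode = "bg", res = 1.8, seq = seqs[["bg1"]],
         extra = NULL, expect = "classified"),
    list(file = "bg_entry2.pdb", mode = "bg", res = 2.2, seq = seqs[["bg2"]],
         extra = NULL, expect = "classified"),
    list(file = "abg_entry.pdb", mode = "abg", res = 2.1,
         seq = seqs[["abg1"]], extra = NULL, expect = "classified"),
    list(file = "none_entry.pdb", mode = "none", res = 2.3,
         seq = seqs[["none1"]], extra = NULL, expect = "classified"),
    list(file = "lowres_entry.pdb", mode = "bg", res = 2.6,
         seq = seqs[["low1"]], extra = NULL, expect = "excluded_resolution"),
    list(file = "redundant_entry.pdb", mode = "g", res = 2.4,
         seq = seqs[["g1"]], extra = NULL, expect = "excluded_redundant"),
    list(file = "concurrent_entry.pdb", mode = "bg", res = 2.0,
         seq = seqs[["conc1"]],
         extra = list(element = "NA", distance = 2.4),
         expect = "excluded_concurrent_cation")
  )
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fs <- fixture_spec(sp$mode, seed = seed + i, resolution = sp$res,
                       sequence = sp$seq,
                       entry_id = tools::file_path_sans_ext(sp$file),
                       extra_cation = sp$extra)
    make_structure_fixture(fs, file.path(dir, sp$file))
  }
  invisible(data.frame(
    file = vapply(specs, `[[`, character(1), "file"),
    mode = vapply(specs, `[[`, character(1), "mode"),
    resolution = vapply(specs, `[[`, numeric(1), "res"),
    expected = vapply(specs, `[[`, character(1), "expect"),
    stringsAsFactors = FALSE))
}
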