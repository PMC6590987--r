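# Shared fixture builders for the test suite.

# distance series with explicit values
make_series <- function(D1, D2 = NULL, dt = 0.1, id = "A") {
  t <- (seq_along(D1) - 1) * dt
  nucmet:::new_distance_series(id, t, D1, D2)
}

# constant-distance three-subunit replica (list of series)
constant_replica <- function(D1 = 5.9, D2 = 3.2, n_frames = 501, dt = 0.1) {
  lapply(c("A", "B", "C"), function(id)
    make_series(rep(D1, n_frames), rep(D2, n_frames), dt = dt, id = id))
}

# a nucleotide site built from a mode fixture
site_from_fixture <- function(mode, seed = 1L, ...) {
  model <- make_structure_fixture(fixture_spec(mode, seed = seed, ...))
  extract_sites(model)[[1L]]
}

# append an extra candidate ion at a given position to a site
add_candidate <- function(site, element, position) {
  row <- data.frame(element = element, name = element,
                    x = position[1], y = position[2], z = position[3],
                    resname = element, resno = 699L, chain = "A",
                    altloc = "", occupancy = 1, type = "HETATM",
                    stringsAsFactors = FALSE)
  site$candidate_metals <- rbind(site$candidate_metals, row)
  site
}

# a point at a prescribed distance from the nearest oxygen of one group
point_near_group <- function(site, group, distance) {
  ox <- as.matrix(site$phosphate_oxygens[[group]][, c("x", "y", "z")])
  cent <- colMeans(as.matrix(site$all_ligand_atoms[, c("x", "y", "z")]))
  o <- ox[1L, ]
  u <- o - cent
  u <- u / sqrt(sum(u^2))
  o + distance * u
}
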