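test_that("fixture files round-trip through the PDB reader", {
  path <- withr::local_tempfile(fileext = ".pdb")
  model <- make_structure_fixture(fixture_spec("bg", seed = 7), path)
  parsed <- parse_structure(path)
  expect_equal(nrow(parsed$atoms), nrow(model$atoms))
  expect_identical(parsed$atoms$name, model$atoms$name)
  expect_equal(as.matrix(parsed$atoms[, c("x", "y", "z")]),
               as.matrix(model$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(parsed$resolution, 2.0)
  expect_match(parsed$method, "X-RAY")
  expect_identical(parsed$chain_sequences[["A"]], "ACDEFGHIKLMNPQRSTVWY")
})

test_that("mmCIF fixtures parse with header metadata", {
  model <- make_structure_fixture(fixture_spec("g", seed = 4,
                                               resolution = 1.9))
  path <- withr::local_tempfile(fileext = ".cif")
  write_fixture_cif(model, path)
  parsed <- parse_structure(path)
  expect_equal(nrow(parsed$atoms), nrow(model$atoms))
  expect_equal(parsed$resolution, 1.9)
  expect_equal(as.matrix(parsed$atoms[, c("x", "y", "z")]),
               as.matrix(model$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       3.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  parsed <- parse_structure(path)
  expect_equal(nrow(parsed$atoms), 2L)
  # residue 1: occupancy 0.6 wins; residue 2: tie broken alphabetically (A)
  expect_equal(parsed$atoms$x[parsed$atoms$resno == 1], 1.0)
  expect_equal(parsed$atoms$x[parsed$atoms$resno == 2], 2.0)
})

test_that("multi-model files keep the first model with a warning", {
  es <- ensemble_spec(lambda_grid = 0.175, n_replicas = 2, window_ns = 1,
                      dt = 0.5, seed = 8)
  w <- series_to_window(simulate_ensemble(es)[[1]][[1]])
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(w, path)
  expect_warning(parsed <- parse_structure(path), "first model")
  expect_equal(nrow(parsed$atoms), nrow(w$topology$atoms))
})

test_that("site extraction finds the phosphate oxygens and candidate ions", {
  model <- make_structure_fixture(fixture_spec("g", seed = 5))
  sites <- extract_sites(model)
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_equal(nrow(s$phosphate_oxygens$g), 3L)
  expect_equal(nrow(s$phosphate_oxygens$a), 2L)
  expect_equal(nrow(s$phosphate_oxygens$b), 2L)
  expect_identical(s$gamma_phosphorus$element, "P")
  expect_equal(nrow(s$candidate_metals), 1L)
})

test_that("the AMP-PNP analog also satisfies the 3/2/2 oxygen rule", {
  model <- make_structure_fixture(fixture_spec("bg", seed = 6,
                                               ligand_code = "ANP"))
  s <- extract_sites(model, ligand_codes = "ANP")[[1]]
  expect_equal(vapply(s$phosphate_oxygens, nrow, integer(1)),
               c(a = 2L, b = 2L, g = 3L))
  # the bridging imido nitrogen is never collected as an oxygen
  expect_false("N3B" %in% unlist(lapply(s$phosphate_oxygens, `[[`, "name")))
})

test_that("sites with missing phosphate atoms are excluded with a reason", {
  model <- make_structure_fixture(fixture_spec("g", seed = 2))
  broken <- model$atoms[model$atoms$name != "O1G", ]
  model2 <- nucmet:::new_structure_model("broken", broken)
  expect_message(sites <- extract_sites(model2), "missing phosphate")
  expect_length(sites, 0L)
})

test_that("extraction is independent of atom order in the file", {
  model <- make_structure_fixture(fixture_spec("abg", seed = 13))
  set.seed(1)
  shuffled <- nucmet:::new_structure_model(
    "shuffled", model$atoms[sample(nrow(model$atoms)), ])
  s1 <- extract_sites(model)[[1]]
  s2 <- extract_sites(shuffled)[[1]]
  for (g in c("a", "b", "g")) {
    o1 <- s1$phosphate_oxygens[[g]]
    o2 <- s2$phosphate_oxygens[[g]]
    expect_setequal(o1$name, o2$name)
    expect_equal(sort(o1$x), sort(o2$x))
  }
  r1 <- classify_mode(s1, s1$candidate_metals[1, , drop = FALSE])
  r2 <- classify_mode(s2, s2$candidate_metals[1, , drop = FALSE])
  expect_identical(r1$mode, r2$mode)
})

test_that("ions beyond the capture radius are not candidates", {
  model <- make_structure_fixture(fixture_spec("g", seed = 5))
  a <- model$atoms
  a[a$element == "MG", c("x", "y", "z")] <- c(50, 50, 50)
  model2 <- nucmet:::new_structure_model("far", a)
  s <- extract_sites(model2)[[1]]
  expect_equal(nrow(s$candidate_metals), 0L)
})
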