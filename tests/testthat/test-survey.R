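make_entry <- function(mode, seq, res, id, seed = 1L) {
  make_structure_fixture(fixture_spec(mode, seed = seed, sequence = seq,
                                      resolution = res, entry_id = id))
}

test_that("redundancy filter keeps the best-resolution member of a cluster", {
  s <- "MKTAYIAKQRQISFVKSHFS"
  m1 <- make_entry("g", s, 2.0, "better")
  m2 <- make_entry("g", s, 2.4, "worse")
  kept <- filter_redundancy(list(m2, m1))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$entry_id, "better")
  log <- attr(kept, "log")
  expect_identical(log$decision[log$entry == "worse"], "excluded_redundant")
})

test_that("dissimilar sequences are both kept", {
  m1 <- make_entry("g", "MKTAYIAKQRQISFVKSHFS", 2.0, "e1")
  m2 <- make_entry("bg", "GGHHPPLLCCWWDDNNEEQQ", 2.2, "e2")
  expect_length(filter_redundancy(list(m1, m2)), 2L)
})

test_that("transitive near-identity clusters collapse to one entry", {
  # three sequences, each pair >= 90% identical: brute-force single-linkage
  # at 70% says one cluster -> exactly one survivor
  s0 <- "MKTAYIAKQRQISFVKSHFS"
  s1 <- sub("A", "G", s0)            # 1 mismatch of 20 = 95%
  s2 <- sub("K", "R", s1)            # 2 mismatches from s0 = 90%
  ms <- list(make_entry("g", s0, 2.1, "a0"),
             make_entry("g", s1, 2.0, "a1"),
             make_entry("g", s2, 2.2, "a2"))
  kept <- filter_redundancy(ms)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$entry_id, "a1")  # best resolution
})

test_that("the mini-survey reproduces its constructed mode table", {
  dir <- withr::local_tempdir()
  truth <- make_survey_fixture_set(dir, seed = 5)
  st <- run_survey(dir)
  expect_equal(st$n_entries, 5L)
  expect_equal(st$n_excluded_resolution, 1L)
  expect_equal(st$n_excluded_redundant, 1L)
  expect_equal(st$n_excluded_concurrent, 1L)
  pct <- setNames(st$rows$percent, st$rows$mode)
  expect_equal(pct[["bg"]], 40)
  expect_equal(pct[["g"]], 20)
  expect_equal(pct[["abg"]], 20)
  expect_equal(pct[["none"]], 20)
  expect_equal(sum(st$rows$percent), 100, tolerance = 0.01)
  expect_equal(sum(st$rows$count), st$n_entries)
  # every file scanned appears in the audit log
  expect_setequal(st$audit$entry,
                  tools::file_path_sans_ext(truth$file))
  # each exclusion is logged with its reason
  expect_identical(
    st$audit$decision[st$audit$entry == "lowres_entry"],
    "excluded_resolution")
  expect_identical(
    st$audit$decision[st$audit$entry == "redundant_entry"],
    "excluded_redundant")
  expect_identical(
    st$audit$decision[st$audit$entry == "concurrent_entry"],
    "excluded_concurrent_cation")
})

test_that("the survey is deterministic end to end", {
  dir <- withr::local_tempdir()
  make_survey_fixture_set(dir, seed = 5)
  s1 <- run_survey(dir)
  s2 <- run_survey(dir)
  expect_identical(s1$rows, s2$rows)
  expect_identical(s1$audit, s2$audit)
})

test_that("survey rejects an empty directory and logs unparseable files", {
  dir <- withr::local_tempdir()
  expect_error(run_survey(dir), "no structure files")
  make_survey_fixture_set(dir, seed = 5)
  writeLines("this is not a structure", file.path(dir, "junk.pdb"))
  st <- run_survey(dir)
  expect_true(any(grepl("skipped_unparseable", st$audit$decision)))
  expect_equal(st$n_entries, 5L)
})
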