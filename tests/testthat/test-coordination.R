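test_that("soft-min coordination number matches closed forms", {
  # single distance: the soft-min is the distance itself
  expect_equal(softmin_coordination_number(3.0), 3.0, tolerance = 1e-12)
  # exact tie: N = R / (R/d + ln k) for k equal distances
  expect_equal(softmin_coordination_number(c(2.0, 2.0)),
               1000 / (500 + log(2)), tolerance = 1e-12)
  expect_equal(softmin_coordination_number(c(2.0, 2.0)), 1.99723,
               tolerance = 1e-5)
  # converges to the minimum for well-separated distances
  expect_equal(softmin_coordination_number(c(3.0, 4.0, 5.0)), 3.0,
               tolerance = 1e-2)
})

test_that("soft-min is bounded by the minimum and tightens with R", {
  set.seed(101)
  for (i in 1:50) {
    d <- runif(sample(1:8, 1), 1.5, 9)
    gaps <- vapply(c(10, 100, 1000, 10000), function(R) {
      N <- softmin_coordination_number(d, R)
      expect_lte(N, min(d) + 1e-12)
      min(d) - N
    }, numeric(1))
    # equality gap shrinks monotonically as R grows
    expect_true(all(diff(gaps) <= 1e-12))
  }
})

test_that("appending a distance never increases the coordination number", {
  set.seed(102)
  for (i in 1:50) {
    d <- runif(sample(1:6, 1), 1.5, 9)
    extra <- runif(1, 1.5, 9)
    expect_lte(softmin_coordination_number(c(d, extra), 1000),
               softmin_coordination_number(d, 1000) + 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(softmin_coordination_number(numeric(0)), "no coordinating")
  expect_error(softmin_coordination_number(c(2, -1)), "positive")
  expect_error(softmin_coordination_number(2, R = 0), "R must be positive")
})

test_that("classification is the set of groups below the threshold", {
  # geometry constructed per mode: the fixture spec is the oracle
  for (mode in coordination_modes()) {
    site <- site_from_fixture(mode, seed = 11)
    ion <- site$candidate_metals[1, , drop = FALSE]
    res <- classify_mode(site, ion)
    expect_s3_class(res, "coordination_result")
    expect_identical(res$mode, mode)
    expect_true(all(res$N > 0))
    hit <- names(res$N)[res$N < res$threshold]
    expect_identical(if (length(hit)) paste(hit, collapse = "") else "none",
                     res$mode)
  }
})

test_that("bound-metal selection takes the closest ion under the threshold", {
  site <- site_from_fixture("g", seed = 3)
  best <- select_bound_metal(site, "MG")
  expect_false(is.null(best))
  # an unbound second Mg (the verified "none"-mode placement, ~4+ A from
  # every group) does not displace the bound one
  none_site <- site_from_fixture("none", seed = 3)
  far <- as.numeric(none_site$candidate_metals[1, c("x", "y", "z")])
  site2 <- add_candidate(site, "MG", far)
  best2 <- select_bound_metal(site2, "MG")
  expect_equal(as.numeric(best2[1, c("x", "y", "z")]),
               as.numeric(best[1, c("x", "y", "z")]))
  # no candidate below the threshold -> absent
  expect_null(select_bound_metal(none_site, "MG"))
  # no candidates at all -> absent
  site4 <- site
  site4$candidate_metals <- site$candidate_metals[0, , drop = FALSE]
  expect_null(select_bound_metal(site4, "MG"))
})

test_that("concurrent-cation exclusion fires only on bound foreign ions", {
  site <- site_from_fixture("bg", seed = 9)
  expect_false(concurrent_cation_check(site, "MG"))
  near <- point_near_group(site, "g", 2.4)
  expect_true(concurrent_cation_check(add_candidate(site, "NA", near), "MG"))
  far <- point_near_group(site, "g", 6.0)
  expect_false(concurrent_cation_check(add_candidate(site, "NA", far), "MG"))
  # a second ion of the same element never triggers the exclusion
  expect_false(concurrent_cation_check(add_candidate(site, "MG", near), "MG"))
})
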