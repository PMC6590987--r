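test_that("generated fixtures classify to their specified mode", {
  set.seed(21)
  for (i in 1:150) {
    mode <- sample(coordination_modes(), 1)
    groups <- if (mode == "none") character(0) else strsplit(mode, "")[[1]]
    d <- stats::setNames(runif(length(groups), 2.2, 2.8), groups)
    spec <- fixture_spec(mode, distances = if (length(groups)) d else NULL,
                         seed = i)
    model <- make_structure_fixture(spec)
    site <- extract_sites(model)[[1]]
    res <- classify_mode(site, site$candidate_metals[1, , drop = FALSE])
    expect_identical(res$mode, mode)
  }
})

test_that("unrealizable fixture specs are refused", {
  expect_error(fixture_spec("g", distances = c(g = 3.3)), "threshold")
  # coordinating two groups while demanding huge clearance cannot work
  expect_error(
    make_structure_fixture(fixture_spec("bg", far_distance = 8)),
    "unrealizable")
})

test_that("ensembles are reproducible from their seed", {
  spec <- ensemble_spec(lambda_grid = c(0.15, 0.25), n_replicas = 3,
                        window_ns = 5, seed = 99)
  e1 <- simulate_ensemble(spec)
  e2 <- simulate_ensemble(spec)
  expect_identical(e1, e2)
  e3 <- simulate_ensemble(ensemble_spec(lambda_grid = c(0.15, 0.25),
                                        n_replicas = 3, window_ns = 5,
                                        seed = 100))
  expect_false(identical(e1, e3))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_counts(ensemble_spec(seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("ensemble statistics follow the ground-truth logistic", {
  # law of large numbers at the distance-series level, mid-grid
  spec <- ensemble_spec(lambda_grid = 0.175, n_replicas = 400,
                        window_ns = 50, dt = 0.5, seed = 31)
  cur <- dissociation_curve(simulate_ensemble(spec))
  f <- logistic_events(sqrt(0.175), 58.6, 0.42)
  expect_equal(cur$mean_events, f, tolerance = 0.1)
  # and at n = 2000 with the count shortcut, within 2% of f across the grid
  spec2 <- ensemble_spec(n_replicas = 2000, seed = 32)
  cur2 <- simulate_counts(spec2)
  f2 <- logistic_events(spec2$S_grid, 58.6, 0.42)
  expect_true(all(abs(cur2$mean_events - f2) <= 0.02 * 3))
})

test_that("saturated and degenerate count curves behave as specified", {
  # probability pinned near 1 everywhere: curve constant at 3, SEM 0
  spec <- ensemble_spec(lambda_grid = c(0.01, 0.02, 0.03), m_true = 1000,
                        n_true = 5, n_replicas = 10, seed = 12)
  cur <- simulate_counts(spec)
  expect_true(all(cur$mean_events == 3))
  expect_true(all(cur$sem == 0))
  # a single replica leaves the SEM undefined, with a warning
  expect_warning(
    cur1 <- simulate_counts(ensemble_spec(n_replicas = 1, seed = 2)),
    "SEM undefined")
  expect_true(all(is.na(cur1$sem)))
})

test_that("rebinding excursions split the persistent and crossing counters", {
  spec <- ensemble_spec(lambda_grid = 0.35, m_true = 58.6, n_true = 0.42,
                        n_replicas = 30, rebind_probability = 0.8, seed = 17)
  # essentially no true dissociation at this lambda; excursions only
  ens <- simulate_ensemble(spec)
  cur_p <- dissociation_curve(ens)
  cur_a <- dissociation_curve(ens, mode = "any_crossing")
  expect_lt(cur_p$mean_events, 0.2)
  expect_gt(cur_a$mean_events, cur_p$mean_events + 0.5)
})

test_that("the full pipeline recovers the generator's parameters", {
  spec <- ensemble_spec(n_replicas = 20, window_ns = 50, dt = 0.5, seed = 11)
  fit <- fit_logistic(dissociation_curve(simulate_ensemble(spec)))
  expect_true(fit$converged)
  expect_lt(abs(fit$m - spec$m_true), 3 * fit$se[["m"]])
  expect_lt(abs(fit$n - spec$n_true), 3 * fit$se[["n"]])
  expect_gt(fit$cc, 0.99)
})
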