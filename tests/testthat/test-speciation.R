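test_that("zero affinity leaves everything free", {
  sys <- speciation_system(c(ATP = 1e-3, Mg = 2e-3, Na = 0.14),
                           log10_K = c(Mg = -Inf, Na = -Inf))
  # K = 10^-Inf = 0: no complexation
  r <- solve_speciation(sys)
  expect_equal(r$free[["ATP"]], 1e-3)
  expect_equal(r$free[["Mg"]], 2e-3)
  expect_true(all(r$complexes == 0))
})

test_that("excess metal reproduces the closed-form bound fraction", {
  K <- 10^4.10
  r <- solve_speciation(speciation_system(c(ATP = 1e-6, Mg = 0.05)))
  closed <- K * 0.05 / (1 + K * 0.05)
  expect_equal(r$complexes[["Mg"]] / 1e-6, closed, tolerance = 1e-6)
  # generalized: metal total >= 1000 x ATP total
  set.seed(4)
  for (i in 1:20) {
    atp <- 10^runif(1, -8, -5)
    mg <- atp * 10^runif(1, 3, 5)
    rr <- solve_speciation(speciation_system(c(ATP = atp, Mg = mg)))
    Keff <- 10^4.10
    expect_equal(rr$complexes[["Mg"]] / atp,
                 Keff * mg / (1 + Keff * mg), tolerance = 1e-3)
  }
})

test_that("mass is conserved to 1e-10 on randomized systems", {
  set.seed(11)
  for (i in 1:50) {
    totals <- c(ATP = 10^runif(1, -7, -2), Mg = 10^runif(1, -7, -1),
                Ca = 10^runif(1, -7, -1), Na = runif(1, 0, 0.2),
                K = runif(1, 0, 0.2))
    r <- solve_speciation(speciation_system(totals))
    expect_true(all(r$free >= 0))
    expect_true(all(r$complexes >= 0))
    rel <- abs(r$residuals) / pmax(totals[names(r$residuals)], 1e-300)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("two cations with equal constants bind symmetrically", {
  sys <- speciation_system(c(ATP = 1e-3, Mg = 5e-3, Ca = 5e-3),
                           log10_K = c(Mg = 4.0, Ca = 4.0))
  r <- solve_speciation(sys)
  expect_equal(r$complexes[["Mg"]], r$complexes[["Ca"]], tolerance = 1e-12)
})

test_that("raising total Mg monotonically depletes free ATP", {
  mg_grid <- c(0, 1e-5, 1e-4, 1e-3, 1e-2, 5e-2, 0.2)
  free_atp <- vapply(mg_grid, function(mg)
    solve_speciation(speciation_system(c(ATP = 1e-3, Mg = mg,
                                         Na = 0.14)))$free[["ATP"]],
    numeric(1))
  expect_true(all(diff(free_atp) < 0))
})

test_that("solution design round-trips through the forward solver", {
  bg <- speciation_system(c(ATP = 0, Na = 0.14))
  totals <- design_free_atp_solution(70e-9, 100e-6, "Mg", bg)
  sol <- attr(totals, "solution")
  expect_equal(sol$free[["ATP"]], 70e-9, tolerance = 1e-9)
  expect_equal(sol$complexes[["Mg"]], 100e-6, tolerance = 1e-9)
  # vanishing target complex needs vanishing total metal
  t0 <- design_free_atp_solution(1e-6, 1e-15, "Mg", bg)
  expect_lt(t0[["Mg"]], 1e-12)
})
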