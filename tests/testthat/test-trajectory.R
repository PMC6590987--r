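test_that("distance series reproduce the constructed geometry exactly", {
  # windows realized from known series give those series back
  rep1 <- constant_replica(D1 = 12.5, D2 = 4.0, n_frames = 3)
  w <- series_to_window(rep1)
  ds <- compute_distances(w)
  for (s in ds) {
    expect_equal(s$D1, rep(12.5, 3), tolerance = 1e-9)
    expect_equal(s$D2, rep(4.0, 3), tolerance = 1e-9)
  }
  # bound-state characteristic values
  rep2 <- constant_replica(D1 = 5.9, D2 = 3.2, n_frames = 2)
  ds2 <- compute_distances(series_to_window(rep2))
  expect_equal(ds2[[1]]$D1, c(5.9, 5.9), tolerance = 1e-9)
  expect_equal(ds2[[1]]$D2, c(3.2, 3.2), tolerance = 1e-9)
  # time base: two frames at dt = 0.1 -> t = {0, 0.1} ns
  expect_equal(ds2[[1]]$t, c(0, 0.1))
})

test_that("dissociation detection distinguishes the three estimators", {
  t_len <- 501  # 50 ns at 0.1 ns/frame
  bound <- make_series(rep(5.9, t_len))
  expect_identical(detect_dissociation(bound), 0L)
  ramp <- make_series(c(rep(5.9, 250), seq(5.9, 15, length.out = 11),
                        rep(15, 240)))
  expect_identical(detect_dissociation(ramp), 1L)
  expect_identical(detect_dissociation(ramp, mode = "terminal"), 1L)
  # a transient 0.2-ns excursion: persistent says no, any-crossing says yes
  spike <- rep(5.9, t_len)
  spike[250:252] <- 13
  s <- make_series(spike)
  expect_identical(detect_dissociation(s), 0L)
  expect_identical(detect_dissociation(s, mode = "any_crossing"), 1L)
  expect_identical(detect_dissociation(s, mode = "terminal"), 0L)
  expect_error(detect_dissociation(bound, persistence = 100),
               "exceeds the window")
})

test_that("event counts are per-subunit sums in 0..3", {
  gone <- constant_replica(D1 = 20, D2 = 8, n_frames = 501)
  expect_identical(count_events(gone), 3L)
  bound <- constant_replica(D1 = 5.9, D2 = 3.2, n_frames = 501)
  expect_identical(count_events(bound), 0L)
  one <- bound
  one[[2]] <- gone[[2]]
  expect_identical(count_events(one), 1L)
})

test_that("event count is monotone in the D1 threshold", {
  set.seed(7)
  for (i in 1:20) {
    reps <- lapply(c("A", "B", "C"), function(id) {
      base <- runif(1, 5, 14)
      make_series(pmax(0.1, base + cumsum(rnorm(301, 0, 0.3))), id = id)
    })
    counts <- vapply(c(8, 10, 12, 14, 16), function(th)
      count_events(reps, d1_threshold = th), integer(1))
    expect_true(all(diff(counts) <= 0))
    expect_true(all(counts >= 0 & counts <= 3))
  }
})

test_that("dissociation curves report means and the n-1 SEM", {
  gone <- constant_replica(D1 = 20, D2 = 8, n_frames = 301)
  bound <- constant_replica(D1 = 5.9, D2 = 3.2, n_frames = 301)
  # 20 replicas all at 3 events -> mean 3, SEM 0
  ens <- list("0.35" = rep(list(gone), 20))
  cur <- dissociation_curve(ens)
  expect_equal(cur$mean_events, 3)
  expect_equal(cur$sem, 0)
  expect_equal(cur$n_replicas, 20L)
  # replicas split 10/10 between 0 and 3: SEM from the sample SD
  ens2 <- list("0.4" = c(rep(list(gone), 10), rep(list(bound), 10)))
  cur2 <- dissociation_curve(ens2)
  expect_equal(cur2$mean_events, 1.5)
  expect_equal(cur2$sem, stats::sd(rep(c(3, 0), each = 10)) / sqrt(20))
  # single replica is refused
  expect_error(dissociation_curve(list("0.3" = list(gone))), ">= 2 replicas")
})

test_that("noiseless logistic curves are recovered to solver precision", {
  grids <- scaling_grids()
  cases <- list(list(S = grids$with_mg$S, m = 58.6, n = 0.42),
                list(S = grids$without_mg$S, m = 29.1, n = 0.51))
  for (cs in cases) {
    curve <- data.frame(S = cs$S,
                        mean_events = logistic_events(cs$S, cs$m, cs$n))
    fit <- fit_logistic(curve)
    expect_true(fit$converged)
    expect_equal(fit$m, cs$m, tolerance = 1e-6)
    expect_equal(fit$n, cs$n, tolerance = 1e-6)
    expect_gt(fit$cc, 0.99)
  }
})

test_that("flat curves yield a flagged non-converged fit", {
  curve <- data.frame(S = c(0.3, 0.4, 0.5, 0.6),
                      mean_events = rep(3, 4), n_replicas = 20)
  fit <- fit_logistic(curve)
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "flat|no start")
  expect_error(fit_logistic(data.frame(S = c(0.3, 0.4),
                                       mean_events = c(1, 2))),
               "3 distinct")
})

test_that("dissociated-state snapshots need both criteria", {
  D1 <- c(13, 13, 5.9, 13)
  D2 <- c(4, 6, 3.2, 8)
  series <- list(make_series(D1, D2))
  sel <- select_dissociated_snapshots(series)
  expect_identical(sel[["A"]], c(2L, 4L))
  # bound-state window -> empty selection
  sel2 <- select_dissociated_snapshots(constant_replica(5.9, 3.2, 10))
  expect_true(all(lengths(sel2) == 0L))
  # idempotent on the same input
  expect_identical(sel, select_dissociated_snapshots(series))
})

test_that("chamber selection supports all-versus-any carboxylate semantics", {
  w <- series_to_window(constant_replica(D1 = 15, D2 = 8, n_frames = 3))
  su <- w$subunits[[1]]
  a <- w$topology$atoms
  # move the ion: frame 1 within 4 A of all four chamber carboxylates,
  # frame 2 within 4 A of three but 8+ A from the fourth, frame 3 far away
  ch_pos <- do.call(rbind, lapply(su$chamber, function(idx)
    colMeans(nucmet:::atom_xyz(a[idx, , drop = FALSE]))))
  mcols <- c(3 * su$mg_idx - 2, 3 * su$mg_idx - 1, 3 * su$mg_idx)
  w$xyz[1, mcols] <- colMeans(ch_pos)   # centroid: close to all four
  w$xyz[2, mcols] <- ch_pos[1, ]        # on one corner: close to one only
  w$xyz[3, mcols] <- c(500, 500, 500)   # far from everything
  sel_all <- select_chamber_snapshots(w, semantics = "all")
  sel_any <- select_chamber_snapshots(w, semantics = "any")
  expect_true(1L %in% sel_all[["A"]])
  expect_false(3L %in% sel_any[["A"]])
  expect_true(all(sel_all[["A"]] %in% sel_any[["A"]]))
  expect_gt(length(sel_any[["A"]]), length(sel_all[["A"]]))
  # composition with the dissociated-state selection
  dis <- select_dissociated_snapshots(w)
  both <- select_chamber_snapshots(w, semantics = "any", frames = dis)
  expect_true(all(both[["A"]] %in% dis[["A"]]))
})

test_that("trajectory files round-trip through the multi-model reader", {
  es <- ensemble_spec(lambda_grid = 0.175, n_replicas = 2, window_ns = 2,
                      dt = 0.1, seed = 3)
  w <- series_to_window(simulate_ensemble(es)[[1]][[1]])
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(w, path)
  w2 <- suppressWarnings(read_trajectory(path))
  expect_equal(nrow(w2$xyz), nrow(w$xyz))
  expect_equal(w2$dt, w$dt)
  d1 <- compute_distances(w)
  d2 <- compute_distances(w2)
  expect_equal(d2[[1]]$D1, d1[[1]]$D1, tolerance = 2e-3)
  expect_equal(d2[[3]]$D2, d1[[3]]$D2, tolerance = 2e-3)
})
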