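test_that("degenerate single-population mixture labels every event", {
  ev <- simulate_matrix(single_pop_profile(), 1000, seed = 1)
  expect_identical(n_events(ev), 1000L)
  expect_true(all(ev$label == "lymphocyte"))
})

test_that("population counts are multinomial around profile fractions", {
  prof <- default_matrix_profile("PB")
  n <- 500000
  ev <- simulate_matrix(prof, n, seed = 42)
  # label conservation
  expect_identical(sum(table(ev$label)), as.integer(n))
  p <- prof$populations[["lymphocyte"]]$fraction
  bound <- 4 * sqrt(n * p * (1 - p))
  expect_lt(abs(sum(ev$label == "lymphocyte") - n * p), bound)
})

test_that("dead_fraction 0 leaves no event above the viability threshold", {
  prof <- default_matrix_profile("LN", dead_fraction = 0)
  ev <- simulate_matrix(prof, 200000, seed = 3)
  gate <- default_gate_config()
  expect_identical(sum(ev$fl3_7aad >= gate$viability_max_fl3), 0L)
})

test_that("viability gate retains ~1 - dead_fraction of gated events", {
  prof <- default_matrix_profile("LN", dead_fraction = 0.1,
                                 debris_fraction = 0)
  n <- 100000
  ev <- simulate_matrix(prof, n, seed = 5)
  gate <- default_gate_config()
  cells <- apply_morphology_gate(ev, gate)
  viable <- apply_viability_gate(cells, gate)
  p <- 0.9
  bound <- 4 * sqrt(nrow(cells) * p * (1 - p))
  expect_lt(abs(nrow(viable) - nrow(cells) * p), bound)
})

test_that("spiking at 0% only shuffles; at 50% the count is binomial", {
  ev <- simulate_matrix(single_pop_profile(), 5000, seed = 9)
  blank <- spike_mast_cells(ev, default_mast_spec(), 0, seed = 10)
  expect_identical(blank$truth$realized_count, 0L)
  expect_identical(n_events(blank$events), 5000L)
  expect_equal(sort(blank$events$fsc), sort(ev$fsc))

  big <- simulate_matrix(single_pop_profile(), 100000, seed = 11)
  sp <- spike_mast_cells(big, default_mast_spec(), 50, seed = 12)
  expect_lt(abs(sp$truth$realized_count - 100000), 4 * sqrt(100000 * 0.25))

  expect_error(spike_mast_cells(ev, default_mast_spec(), 100, seed = 1),
               "\\[0, 100\\)")
})

test_that("gated quantification recovers the nominal spike fraction", {
  prof <- default_matrix_profile("PB")
  ev <- simulate_matrix(prof, 120000, seed = 21)
  for (f in c(10, 1)) {
    sp <- spike_mast_cells(ev, default_mast_spec(), f, seed = 22 + f)
    g <- quantify_mast_cells(sp$events, default_gate_config())
    p <- f / 100
    sd_pct <- 100 * sqrt(p * (1 - p) / g$n_viable)
    expect_lt(abs(g$mast_pct - f), 4 * sd_pct + 100 * prof$background_dp_rate)
  }
})

test_that("dilution series has the right shape, minima and determinism", {
  design <- experiment_design("LN", nominal_fractions = c(5, 1, 0.5),
                              repeats_per_level = 2, n_blanks = 3,
                              min_events = 5000, rng_seed = 99)
  prof <- default_matrix_profile("LN")
  series <- generate_dilution_series(design, prof)
  expect_length(series, 3 * 2 + 3)
  gate <- default_gate_config()
  for (tube in series) {
    expect_gte(nrow(apply_morphology_gate(tube$events, gate)),
               design$min_events)
  }
  series2 <- generate_dilution_series(design, prof)
  expect_identical(series[[1]]$events$fsc, series2[[1]]$events$fsc)
  expect_identical(series[[7]]$truth$realized_count,
                   series2[[7]]$truth$realized_count)
  # distinct tubes get distinct streams
  expect_false(identical(series[[1]]$events$fsc, series[[2]]$events$fsc))
})

test_that("expected mast events scale as n * p at the lowest level", {
  design <- experiment_design("PB", nominal_fractions = c(0.1),
                              repeats_per_level = 3, n_blanks = 0,
                              min_events = 500000, rng_seed = 7)
  series <- generate_dilution_series(design, default_matrix_profile("PB"))
  counts <- vapply(series, function(t) t$truth$realized_count, integer(1))
  # expected = 0.001 * viable events; viable = raw * (1 - dead - debris)
  raw <- ceiling(500000 * 1.03 / (1 - 0.05))
  expected <- 0.001 * raw * 0.90
  for (k in counts) expect_lt(abs(k - expected), 4 * sqrt(expected) + 20)
})

test_that("mean measured fraction is monotone in nominal fraction", {
  design <- experiment_design("LN", nominal_fractions = c(10, 1, 0.3),
                              repeats_per_level = 3, n_blanks = 0,
                              min_events = 20000, rng_seed = 13)
  prof <- default_matrix_profile("LN")
  series <- generate_dilution_series(design, prof)
  gate <- default_gate_config()
  meas <- vapply(series, function(t) {
    quantify_mast_cells(t$events, gate)$mast_pct
  }, numeric(1))
  lv <- vapply(series, `[[`, numeric(1), "level")
  means <- tapply(meas, lv, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})

test_that("blank double-positive rate stays near background_dp_rate", {
  prof <- default_matrix_profile("LN")
  ev <- simulate_matrix(prof, 200000, seed = 31)
  g <- quantify_mast_cells(ev, default_gate_config())
  rate <- g$quadrant_counts[["pp"]] / g$n_viable
  expect_lte(rate, 2 * prof$background_dp_rate)
  expect_gt(rate, 0)
})

test_that("profile validation catches inconsistent fractions", {
  expect_error(matrix_profile("PB", list(
    population_spec("lymphocyte", 0.6, log(c(200, 80, 3, 3, 4)),
                    rep(0.2, 5)),
    population_spec("monocyte", 0.3, log(c(350, 150, 3, 3, 4)),
                    rep(0.2, 5))
  )), "sum to 1")
  expect_error(population_spec("lymphocyte", 0.5,
                               log(c(200, 80, 3, 3, 4)),
                               c(0.2, 0.2, 0, 0.2, 0.2)), "> 0")
})

test_that("derive_seed is deterministic, distinct and in range", {
  s1 <- derive_seed(1, 2, 3, 4)
  expect_identical(s1, derive_seed(1, 2, 3, 4))
  grid <- expand.grid(m = 1:3, l = 0:9, r = 1:10)
  seeds <- mapply(function(m, l, r) derive_seed(123, m, l, r),
                  grid$m, grid$l, grid$r)
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})
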