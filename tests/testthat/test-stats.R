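test_that("compute_cv matches hand-computed values and guards its domain", {
  expect_equal(compute_cv(c(1, 1, 1)), 0)
  expect_equal(compute_cv(c(9, 10, 11)), 10)
  expect_equal(compute_cv(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-12)
  expect_error(compute_cv(c(5)), "at least 2")
  expect_error(compute_cv(c(-2, 2)), "not positive")
})

test_that("cv is scale-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    v <- abs(rnorm(5, 10, 2))
    c_ <- runif(1, 0.1, 50)
    expect_equal(compute_cv(v), compute_cv(c_ * v), tolerance = 1e-10)
  }
})

test_that("LOB/LLoD reproduce their worked relationships", {
  expect_equal(compute_lob(c(0, 0, 0))$lob, 0)
  expect_error(compute_lob(0.01), "at least 2")
  # 10 blanks constructed to have mean 0.004 and sample sd 0.00182
  z <- scale(seq_len(10))[, 1]
  blanks <- 0.004 + 0.00182 * z
  lb <- compute_lob(blanks)
  expect_equal(lb$blank_mean, 0.004, tolerance = 1e-12)
  expect_equal(lb$blank_sd, 0.00182, tolerance = 1e-12)
  expect_equal(round(lb$lob, 3), 0.007)
  expect_equal(round(compute_llod(lb$lob, lb$blank_sd), 3), 0.01)
  expect_equal(round(compute_llod(0.025, 0.0103), 3), 0.042)
  expect_equal(compute_llod(0.5, 0), 0.5)
  expect_error(compute_llod(-1, 0.1), ">= 0")
  # ordering invariant on random blank sets
  set.seed(8)
  for (i in 1:20) {
    b <- abs(rnorm(10, 0.005, 0.002))
    lb <- compute_lob(b)
    llod <- compute_llod(lb$lob, lb$blank_sd)
    expect_gte(lb$lob, lb$blank_mean)
    expect_gte(llod, lb$lob)
  }
})

test_that("overall precision is the RMS of the per-dilution CVs", {
  ref <- reference_validation_values()$precision
  pb <- ref$cv_a[ref$matrix == "PB"]
  ln <- ref$cv_a[ref$matrix == "LN"]
  bm <- ref$cv_a[ref$matrix == "BM"]
  expect_equal(round(compute_overall_precision(pb), 1), 5.7)
  expect_equal(round(compute_overall_precision(ln), 1), 8.4)
  expect_equal(round(compute_overall_precision(bm), 0), 9)
  expect_equal(compute_overall_precision(rep(4.2, 6)), 4.2)
  # RMS dominance over the arithmetic mean, bounded by min/max
  set.seed(9)
  for (i in 1:20) {
    cvs <- runif(9, 0, 20)
    o <- compute_overall_precision(cvs)
    expect_gte(o, mean(cvs))
    expect_gte(o, min(cvs)); expect_lte(o, max(cvs))
  }
  expect_error(compute_overall_precision(numeric(0)), "at least one")
})

test_that("precision tables sort, summarise and propagate errors", {
  pt <- build_precision_table(list(
    list(nominal_fraction = 0.5, measurements = c(0.45, 0.5, 0.55)),
    list(nominal_fraction = 5, measurements = c(5, 5, 5))
  ))
  expect_identical(nrow(pt), 2L)
  expect_equal(pt$nominal_fraction, c(5, 0.5)) # descending
  expect_equal(pt$cv_a[1], 0)
  expect_equal(pt$cv_a[2], compute_cv(c(0.45, 0.5, 0.55)))
  # data.frame input path
  df <- data.frame(nominal_fraction = rep(c(1, 2), each = 3),
                   mast_pct = c(1, 1.1, 0.9, 2, 2.2, 1.8))
  pt2 <- build_precision_table(df)
  expect_equal(pt2$nominal_fraction, c(2, 1))
  expect_error(build_precision_table(list(
    list(nominal_fraction = 1, measurements = 1))), "at least 2")
})

test_that("select_lloq applies the CV-below-threshold-above-LLoD rule", {
  ref <- reference_validation_values()
  for (m in c("PB", "BM", "LN")) {
    cvs <- ref$precision[ref$precision$matrix == m, ]
    pt <- data.frame(nominal_fraction = cvs$nominal_fraction,
                     n = 3, mean = cvs$nominal_fraction, sd = NA,
                     cv_a = cvs$cv_a)
    llod <- ref$limits$llod[ref$limits$matrix == m]
    sel <- select_lloq(pt, llod)
    expect_equal(sel$lloq, 0.1)
  }
  ln <- ref$precision[ref$precision$matrix == "LN", ]
  pt <- data.frame(nominal_fraction = ln$nominal_fraction, n = 3,
                   mean = ln$nominal_fraction, sd = NA, cv_a = ln$cv_a)
  expect_equal(select_lloq(pt, 0.042)$lloq_cv, 9.5)

  # no qualifying level
  pt$cv_a <- rep(40, nrow(pt))
  expect_true(is.na(select_lloq(pt, 0.042)$lloq))
  # llod excludes the lowest level
  pt$cv_a <- rep(5, nrow(pt))
  expect_equal(select_lloq(pt, 0.2)$lloq, 0.3)
  # linearity option rejects poor recovery
  pt$mean <- pt$nominal_fraction * 2
  expect_equal(select_lloq(pt, 0.042, check_linearity = TRUE)$lloq,
               NA_real_)
})

test_that("EMU and uncertainty reporting follow x ± (x·EMU)", {
  expect_equal(round(compute_emu(8.4), 2), 0.17)
  expect_equal(compute_emu(0), 0)
  expect_equal(compute_emu(5), 0.10)
  expect_error(compute_emu(-1), ">= 0")

  r <- report_with_uncertainty(0.3, compute_emu(8.4))
  expect_equal(r$formatted, "0.3 ± 0.05%")
  expect_equal(r$interval, c(0.3 - r$half_width, 0.3 + r$half_width))
  expect_equal(report_with_uncertainty(0, 0.17)$half_width, 0)
  expect_equal(report_with_uncertainty(4, 0.168)$half_width, 0.672)
})

test_that("nodal cut-offs classify with strict 'higher than' semantics", {
  expect_equal(classify_nodal_infiltration(0.2)$category, "below_cutoff")
  expect_equal(classify_nodal_infiltration(0.3)$category, "below_cutoff")
  expect_equal(classify_nodal_infiltration(1.0)$category,
               "metastatic_HN2_HN3")
  expect_equal(classify_nodal_infiltration(4)$category,
               "metastatic_HN2_HN3")
  expect_equal(classify_nodal_infiltration(5)$category, "HN3")
  expect_error(classify_nodal_infiltration(101), "\\[0, 100\\]")
})

test_that("per-level CV recovers injected spike noise at many repeats", {
  # 100 repeats of a high level with multiplicative noise of known CV;
  # fitted CV must land within ±20% relative
  noise_cv <- 0.05
  prof <- single_pop_profile()
  meas <- vapply(1:100, function(r) {
    ev <- simulate_matrix(prof, 20000, seed = derive_seed(500, r, 1))
    sp <- spike_mast_cells(ev, default_mast_spec(), 20,
                           seed = derive_seed(500, r, 2),
                           noise_cv = noise_cv)
    quantify_mast_cells(sp$events, default_gate_config())$mast_pct
  }, numeric(1))
  cv_hat <- compute_cv(meas)
  expect_gt(cv_hat, 100 * noise_cv * 0.8)
  expect_lt(cv_hat, 100 * noise_cv * 1.2 + 2) # + counting-noise allowance
})
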