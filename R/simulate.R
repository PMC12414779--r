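# Synthetic listmode generator: labelled mixtures of log-normal populations
# per matrix, with mast-cell spike-ins at known nominal fractions.

#' Construct a population specification
#'
#' One cell population of a matrix, modelled as a multivariate log-normal
#' over the five channels: `location`/`spread` are the log-scale mean and SD
#' per channel, `correlation` an optional 5x5 log-scale correlation matrix
#' (identity if omitted). Log-normal intensities are strictly positive and
#' right-skewed, matching uncompensated linear cytometry channels.
#'
#' @param name A label from [population_labels()].
#' @param fraction Proportion of events in `[0, 1]`.
#' @param location Numeric length-5 log-scale means, channel order
#'   [event_channels()].
#' @param spread Numeric length-5 log-scale SDs, all > 0.
#' @param correlation Optional 5x5 correlation matrix.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, fraction, location, spread,
                            correlation = NULL) {
  if (!name %in% population_labels()) {
    stop("unknown population name '", name, "'", call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  stopifnot(length(location) == 5, length(spread) == 5)
  if (any(spread <= 0)) stop("spreads must be > 0", call. = FALSE)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    stopifnot(nrow(correlation) == 5, ncol(correlation) == 5)
  }
  structure(list(name = name, fraction = fraction,
                 location = as.numeric(location),
                 spread = as.numeric(spread),
                 correlation = correlation),
            class = "population_spec")
}

#' Construct a matrix profile
#'
#' Generative parameters for one specimen matrix (peripheral blood, bone
#' marrow or lymph node): its cell populations (which must include any
#' `dead` and `debris` components and sum to 1), and the background
#' double-positive rate — the expected proportion of viable in-gate events
#' that spuriously land in the IgE+/CD117+ quadrant, emulating negative
#' matrices in which mast cells are rarer than 1 in 10,000 cells.
#'
#' @param matrix `"PB"`, `"BM"` or `"LN"`.
#' @param populations List of [population_spec()]s; fractions must sum to 1.
#' @param background_dp_rate Proportion in `[0, 0.001]`.
#' @return A list of class `matrix_profile` (with `dead_fraction` taken from
#'   the `dead` population, 0 if absent).
#' @export
matrix_profile <- function(matrix = c("PB", "BM", "LN"), populations,
                           background_dp_rate = 1e-4) {
  matrix <- match.arg(matrix)
  stopifnot(is.list(populations), length(populations) >= 1)
  ok <- vapply(populations, inherits, logical(1), "population_spec")
  if (!all(ok)) stop("populations must all be population_spec objects",
                     call. = FALSE)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", sum(fr), ")",
         call. = FALSE)
  }
  if (background_dp_rate < 0 || background_dp_rate > 0.001) {
    stop("background_dp_rate must be in [0, 0.001]", call. = FALSE)
  }
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  dead <- if ("dead" %in% names(populations))
    populations[["dead"]]$fraction else 0
  structure(list(matrix = matrix, populations = populations,
                 dead_fraction = dead,
                 background_dp_rate = background_dp_rate),
            class = "matrix_profile")
}

# log-scale locations chosen so the default gate_config separates the
# populations cleanly: debris sits below the FSC gate floor (100), dead
# cells sit far above the 7-AAD cut (50), and autofluorescence on FL1/FL2
# stays orders of magnitude below the quadrant thresholds (20).
pop_defaults <- function(name, fraction,
                         fsc, ssc, fl1 = 3, fl2 = 3, fl3 = 4,
                         s = c(0.15, 0.2, 0.4, 0.4, 0.4)) {
  population_spec(name, fraction,
                  location = log(c(fsc, ssc, fl1, fl2, fl3)),
                  spread = s)
}

#' Default generative profile for a matrix
#'
#' Plausible population geometries for post-lysis peripheral blood (PB),
#' bone marrow (BM) and lymph-node (LN) cell suspensions: granulocyte-rich
#' blood and marrow (marrow with a precursor compartment), lymphocyte-rich
#' nodes, plus small debris and dead fractions. Background double-positive
#' rates default to 5e-5 (PB), 1.3e-4 (BM) and 2.5e-4 (LN) — below the
#' 1-in-10,000 mast-cell purity bound required of negative matrices, and
#' ordered PB < BM < LN like the matrices' blank signals.
#'
#' @inheritParams default_dilution_scheme
#' @param dead_fraction Proportion of dead (7-AAD bright) events.
#' @param debris_fraction Proportion of sub-cellular debris events.
#' @return A [matrix_profile()].
#' @export
default_matrix_profile <- function(matrix = c("PB", "BM", "LN"),
                                   dead_fraction = 0.05,
                                   debris_fraction = 0.05) {
  matrix <- match.arg(matrix)
  live <- 1 - dead_fraction - debris_fraction
  mk <- function(name, share, fsc, ssc) {
    pop_defaults(name, live * share, fsc, ssc)
  }
  pops <- switch(matrix,
    PB = list(mk("lymphocyte", 0.27, 200, 80),
              mk("monocyte", 0.06, 350, 150),
              mk("granulocyte", 0.67, 300, 400)),
    BM = list(mk("lymphocyte", 0.16, 200, 80),
              mk("monocyte", 0.05, 350, 150),
              mk("granulocyte", 0.51, 300, 400),
              mk("precursor", 0.28, 400, 250)),
    LN = list(mk("lymphocyte", 0.88, 200, 80),
              mk("monocyte", 0.05, 350, 150),
              mk("granulocyte", 0.07, 300, 400))
  )
  if (debris_fraction > 0) {
    pops <- c(pops, list(population_spec(
      "debris", debris_fraction,
      location = log(c(40, 20, 2, 2, 3)),
      spread = c(0.4, 0.5, 0.4, 0.4, 0.4))))
  }
  if (dead_fraction > 0) {
    pops <- c(pops, list(population_spec(
      "dead", dead_fraction,
      location = log(c(180, 90, 3, 3, 300)),
      spread = c(0.2, 0.25, 0.4, 0.4, 0.4))))
  }
  dp <- switch(matrix, PB = 5e-5, BM = 1.3e-4, LN = 2.5e-4)
  matrix_profile(matrix, pops, background_dp_rate = dp)
}

#' Default mast-cell population specification
#'
#' The spiked cultured mast-cell line: large, granular (high FSC/SSC) and
#' brightly double positive for surface IgE (FL1) and CD117 (FL2), viable
#' (7-AAD dim). `fraction` is irrelevant for spiking and set to 0.
#'
#' @return A [population_spec()] named `mast_cell`.
#' @export
default_mast_spec <- function() {
  population_spec("mast_cell", 0,
                  location = log(c(450, 500, 200, 250, 4)),
                  spread = c(0.15, 0.2, 0.3, 0.3, 0.4))
}

draw_population <- function(spec, n) {
  if (n == 0) {
    m <- matrix(numeric(0), ncol = 5)
  } else if (is.null(spec$correlation)) {
    m <- exp(matrix(rnorm(n * 5), ncol = 5) %*% diag(spec$spread) +
               matrix(spec$location, n, 5, byrow = TRUE))
  } else {
    L <- chol(spec$correlation)
    z <- matrix(rnorm(n * 5), ncol = 5) %*% L
    m <- exp(z %*% diag(spec$spread) +
               matrix(spec$location, n, 5, byrow = TRUE))
  }
  df <- as.data.frame(m)
  names(df) <- event_channels()
  df$label <- rep(spec$name, n)
  df
}

#' Simulate a blank (mast-cell free) matrix sample
#'
#' Draws `n_events` labelled events from the profile's population mixture
#' (multinomial counts around the nominal fractions), then converts a
#' Bernoulli(`background_dp_rate`) subset of viable non-debris events into
#' spurious double positives (dim FL1/FL2 positivity, labels unchanged) so
#' blanks carry a realistic false-positive signal. Event order is shuffled.
#'
#' @param profile A [matrix_profile()].
#' @param n_events Number of events (>= 1).
#' @param seed Integer seed for this tube's private RNG stream.
#' @return A labelled [event_table()] with no `mast_cell` events.
#' @export
simulate_matrix <- function(profile, n_events, seed) {
  stopifnot(inherits(profile, "matrix_profile"), n_events >= 1)
  with_seed(seed, {
    fr <- vapply(profile$populations, `[[`, numeric(1), "fraction")
    counts <- as.vector(rmultinom(1, n_events, fr))
    parts <- Map(draw_population, profile$populations, counts)
    df <- do.call(rbind, parts)
    viable <- !(df$label %in% c("dead", "debris"))
    if (profile$background_dp_rate > 0 && any(viable)) {
      flip <- viable & (runif(nrow(df)) < profile$background_dp_rate)
      k <- sum(flip)
      if (k > 0) {
        # dim double positives just above the quadrant thresholds
        df$fl1_ige[flip] <- rlnorm(k, log(80), 0.35)
        df$fl2_cd117[flip] <- rlnorm(k, log(80), 0.35)
      }
    }
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    event_table(df)
  })
}

#' Spike mast-cell events into a matrix sample at a nominal fraction
#'
#' Inserts simulated mast-cell events so that the expected mast fraction
#' among viable events (the denominator the gating pipeline uses) equals
#' `nominal_fraction`. The realized count is binomially sampled — with
#' viable matrix count V and p = fraction/100, the spiked tube notionally
#' holds T = round(V / (1 - p)) viable cells of which Binomial(T, p) are
#' mast cells — so repeat-to-repeat variation exists before any measurement
#' noise. An optional per-repeat multiplicative log-normal factor
#' (`noise_cv`, unit mean) scales the realized count to emulate pipetting
#' variation; it defaults to 0 (off).
#'
#' @param matrix_events Labelled [event_table()] from [simulate_matrix()].
#' @param mast_spec A [population_spec()] for the spiked cells.
#' @param nominal_fraction Percentage in `[0, 100)`.
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation (fraction, e.g. 0.05) of the
#'   per-repeat multiplicative factor; 0 disables it.
#' @return A list with `events` (shuffled [event_table()]) and `truth`
#'   (`spike_truth`: `nominal_fraction`, `realized_count`, `total_events`).
#' @export
spike_mast_cells <- function(matrix_events, mast_spec, nominal_fraction,
                             seed, noise_cv = 0) {
  if (nominal_fraction < 0 || nominal_fraction >= 100) {
    stop("nominal_fraction must be in [0, 100)", call. = FALSE)
  }
  if (!"label" %in% names(matrix_events)) {
    stop("matrix_events must be labelled", call. = FALSE)
  }
  with_seed(seed, {
    p <- nominal_fraction / 100
    v <- sum(!(matrix_events$label %in% c("dead", "debris")))
    m <- 0L
    if (p > 0) {
      total <- round(v / (1 - p))
      m <- rbinom(1, total, p)
      if (noise_cv > 0) {
        s2 <- log(1 + noise_cv^2)
        m <- round(m * rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2)))
      }
    }
    df <- as.data.frame(matrix_events)
    if (m > 0) df <- rbind(df, draw_population(mast_spec, m))
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    list(
      events = event_table(df),
      truth = structure(list(nominal_fraction = nominal_fraction,
                             realized_count = as.integer(m),
                             total_events = nrow(df)),
                        class = "spike_truth")
    )
  })
}

#' Generate a full spike-in dilution series plus blanks
#'
#' One tube per (dilution level x repeat) plus `n_blanks` blank tubes. Each
#' tube's raw event count is inflated above `design$min_events` to offset the
#' expected debris loss, so the morphology gate retains at least the
#' acquisition minimum. Tube seeds derive deterministically from
#' `design$rng_seed` via [derive_seed()] (blanks use level index 0), making
#' the whole series reproducible tube by tube.
#'
#' @param design An [experiment_design()].
#' @param profile A [matrix_profile()] for the blank matrix.
#' @param mast_spec A [population_spec()] for the spiked cells.
#' @param noise_cv Passed to [spike_mast_cells()].
#' @return A list of `list(events, truth, level, repeat_index)` entries;
#'   blanks have `level = 0`.
#' @export
generate_dilution_series <- function(design, profile,
                                     mast_spec = default_mast_spec(),
                                     noise_cv = 0) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(profile, "matrix_profile"))
  tubes <- dilution_series_plan(design)
  lapply(tubes, function(tb) {
    sim <- simulate_dilution_tube(design, profile, mast_spec,
                                  tb$level, tb$level_index, tb$repeat_index,
                                  noise_cv)
    c(sim, list(level = tb$level, repeat_index = tb$repeat_index))
  })
}

dilution_series_plan <- function(design) {
  tubes <- list()
  for (b in seq_len(design$n_blanks)) {
    tubes[[length(tubes) + 1L]] <-
      list(level = 0, level_index = 0L, repeat_index = b)
  }
  for (li in seq_along(design$nominal_fractions)) {
    for (r in seq_len(design$repeats_per_level)) {
      tubes[[length(tubes) + 1L]] <-
        list(level = design$nominal_fractions[li], level_index = li,
             repeat_index = r)
    }
  }
  tubes
}

matrix_code <- function(matrix) match(matrix, c("PB", "BM", "LN"))

raw_events_needed <- function(design, profile) {
  debris <- 0
  if ("debris" %in% names(profile$populations)) {
    debris <- profile$populations[["debris"]]$fraction
  }
  as.integer(ceiling(design$min_events * 1.03 / (1 - debris)))
}

simulate_dilution_tube <- function(design, profile, mast_spec,
                                   level, level_index, repeat_index,
                                   noise_cv = 0) {
  n_raw <- raw_events_needed(design, profile)
  seed_m <- derive_seed(design$rng_seed, matrix_code(design$matrix),
                        level_index, repeat_index, 1)
  seed_s <- derive_seed(design$rng_seed, matrix_code(design$matrix),
                        level_index, repeat_index, 2)
  ev <- simulate_matrix(profile, n_raw, seed_m)
  spike_mast_cells(ev, mast_spec, level, seed_s, noise_cv = noise_cv)
}
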