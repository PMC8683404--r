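cfg <- analysis_config()

mk_curve <- function(x, y, mode = "PAM", fixed = 1, id = "c") {
  structure(list(cell_id = id, mode = mode, fixed_value = fixed,
                 x = x, y_relative = y),
            class = "response_curve")
}

test_that("threshold_from_curve interpolates, extrapolates and censors", {
  # linear interpolation between bracketing points
  th <- threshold_from_curve(mk_curve(c(10, 15), c(1.0, 2.0)))
  expect_equal(th$threshold_value, 12.5)
  expect_equal(th$method, "interpolated")
  # already above the level with a rising start: line through first two points
  th2 <- threshold_from_curve(mk_curve(c(10, 15, 20), c(2.0, 2.5, 3.0)))
  expect_equal(th2$threshold_value, 5)
  expect_equal(th2$method, "extrapolated")
  # extrapolation floor at 0.1 x smallest tested stimulus
  th3 <- threshold_from_curve(mk_curve(c(10, 15), c(1.6, 20)))
  expect_gte(th3$threshold_value, 1)
  # never reaches the level -> censored
  th4 <- threshold_from_curve(mk_curve(c(10, 15, 20), c(0.9, 1.0, 1.2)))
  expect_equal(th4$method, "censored")
  expect_true(is.na(th4$threshold_value))
  # noisy initial exceedance that the rest of the curve contradicts -> censored
  th5 <- threshold_from_curve(mk_curve(c(10, 15, 20, 25, 30),
                                       c(2.6, 1.2, 1.3, 0.9, 1.1)))
  expect_equal(th5$method, "censored")
  # supra-threshold everywhere with flat start -> floored extrapolation
  th6 <- threshold_from_curve(mk_curve(c(10, 15, 20), c(3.0, 2.9, 3.2)))
  expect_equal(th6$threshold_value, 1)
  expect_equal(th6$method, "extrapolated")
  # non-monotone multi-crossing uses the first upward crossing, with warning
  expect_warning(
    th7 <- threshold_from_curve(mk_curve(c(10, 15, 20, 25, 30),
                                         c(1.0, 2.0, 1.0, 2.0, 3.0))),
    "first upward crossing")
  expect_equal(th7$threshold_value, 12.5)
  # infinite sentinels are capped (message) and the curve still evaluated
  expect_message(
    th8 <- threshold_from_curve(mk_curve(c(10, 15), c(1.0, Inf))),
    "capped")
  expect_equal(th8$method, "interpolated")
  # PDM curves are labelled as duration thresholds
  th9 <- threshold_from_curve(mk_curve(c(0.5, 1, 2), c(1.0, 2.0, 3.0),
                                       mode = "PDM", fixed = 20))
  expect_equal(th9$mode, "duration_at_fixed_amplitude")
  expect_equal(th9$threshold_value, 0.75)
})

test_that("interpolated thresholds agree with a dense-grid crossing oracle", {
  set.seed(31)
  for (k in 1:10) {
    m <- synthetic_cell_model("c", spont_rate = runif(1, 3, 10),
                              rheobase = runif(1, 3, 7),
                              chronaxie = runif(1, 0.5, 2),
                              evoked_max = runif(1, 5, 15))
    d <- sample(c(0.5, 1, 2), 1)
    coarse <- c(10, 15, 20, 25, 30)
    y <- vapply(coarse, expected_relative, numeric(1), model = m, duration = d)
    th <- threshold_from_curve(mk_curve(coarse, y, fixed = d))
    # brute force: first upward crossing of the analytic curve on a fine grid
    fine <- seq(10, 30, by = 0.001)
    yf <- vapply(fine, expected_relative, numeric(1), model = m, duration = d)
    cross <- fine[which(yf >= 1.5)[1]]
    if (th$method == "interpolated" && !is.na(cross)) {
      expect_lt(abs(th$threshold_value - cross), 5)  # within one coarse cell
    }
  }
})

test_that("fit_sd recovers exact and noisy hyperbolae", {
  # noiseless identifiability: R = 3, C = 4 recovered exactly
  d <- c(0.5, 1, 2)
  i <- 3 * (1 + 4 / d)
  f <- fit_sd(d, i, "exact")
  expect_equal(f$rheobase, 3, tolerance = 1e-6)
  expect_equal(f$chronaxie, 4, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
  # two points: exact solve through both
  f2 <- fit_sd(c(0.5, 2), 3 * (1 + 4 / c(0.5, 2)), "two")
  expect_equal(f2$rheobase, 3, tolerance = 1e-6)
  expect_equal(f2$chronaxie, 4, tolerance = 1e-6)
  # fewer than 2 usable pairs -> refused with warning
  expect_warning(f0 <- fit_sd(2, 9, "one"), "refused")
  expect_null(f0)
  expect_warning(f1 <- fit_sd(c(1, 1), c(9, 9.5), "same_d"), "refused")
  expect_null(f1)
  # 5% multiplicative noise on a design spanning the hyperbola knee:
  # oracle-computed median rheobase error is 0.050 (500 replicates)
  set.seed(5)
  dd <- c(0.5, 1, 2, 4, 8)
  errs <- replicate(200, {
    ii <- 3 * (1 + 4 / dd) * exp(rnorm(length(dd), 0, 0.05))
    abs(fit_sd(dd, ii)$rheobase - 3) / 3
  })
  expect_lt(median(errs), 0.1)
})

test_that("fit_sd equals the dense-grid brute-force minimiser", {
  set.seed(32)
  for (k in 1:50) {
    R <- runif(1, 2, 8)
    C <- runif(1, 0.5, 4)
    d <- c(0.5, 1, 2, 4)
    i <- R * (1 + C / d) * exp(rnorm(4, 0, runif(1, 0.02, 0.1)))
    f <- fit_sd(d, i)
    bf <- brute_force_sd(d, i, weighting = "charge")
    expect_equal(f$rheobase, unname(bf["R"]), tolerance = 0.01)
    expect_equal(f$chronaxie, unname(bf["C"]), tolerance = 0.01)
  }
})

test_that("charge arithmetic and density conversion match the worked values", {
  expect_equal(charge_per_phase(8, 0.5), 4)        # 4 nC per phase
  expect_equal(charge_per_phase(1, 1), 1)
  expect_equal(charge_per_phase(7.93, 0.5), 3.965)
  expect_equal(electrode_area_cm2(30), pi * (15e-4)^2)
  expect_equal(round(charge_density(3.965, 30), 2), 0.56)
  expect_equal(round(charge_density(4, 30), 3), 0.566)
  expect_equal(charge_density(0, 30), 0)
  expect_error(charge_per_phase(-1, 1), "non-negative")
  # density is linear in amplitude and duration separately
  set.seed(33)
  for (k in 1:10) {
    a <- runif(1, 1, 30); d <- runif(1, 0.1, 3); s <- runif(1, 0.5, 4)
    expect_equal(charge_density(charge_per_phase(a * s, d)),
                 s * charge_density(charge_per_phase(a, d)))
    expect_equal(charge_density(charge_per_phase(a, d * s)),
                 s * charge_density(charge_per_phase(a, d)))
  }
})

test_that("group_summary runs ANOVA with Tukey post-hoc and stars", {
  # identical groups -> F = 0, p = 1, no significance
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  gs <- group_summary(v, g)
  expect_equal(gs$anova$p, 1)
  expect_equal(gs$anova$stars, "n.s")
  # well-separated groups -> p < 0.001 in >= 99% of seeded runs
  set.seed(34)
  hits <- mean(replicate(200, {
    x <- c(rnorm(30, 0, 1), rnorm(30, 3, 1))
    group_summary(x, rep(c("a", "b"), each = 30))$anova$p < 0.001
  }))
  expect_gte(hits, 0.99)
  # groups at the reported rheobase means and SEMs: mostly non-significant
  set.seed(35)
  ns <- mean(replicate(100, {
    x <- c(rnorm(75, 3.37, 0.36 * sqrt(75)),
           rnorm(58, 3.94, 0.40 * sqrt(58)),
           rnorm(12, 4.80, 1.05 * sqrt(12)))
    g <- rep(c("normal", "non_severe", "severe"), c(75, 58, 12))
    suppressWarnings(group_summary(x, g)$anova$p) > 0.05
  }))
  expect_gt(ns, 0.5)
  # a group with n < 2 is excluded with a warning
  expect_warning(gs2 <- group_summary(c(1, 2, 3, 10), c("a", "a", "a", "b")),
                 "n < 2")
  expect_equal(gs2$summary$group, "a")
})

test_that("report formatting reproduces the percentage convention", {
  expect_equal(format_percent_count(75, 432), "17.36% (75/432)")
  expect_equal(format_percent_count(12, 174), "6.90% (12/174)")
  expect_equal(format_percent_count(0, 10), "0.00% (0/10)")
  expect_error(format_percent_count(1, 0), "positive")
})

test_that("report_tables summarises thresholds, fits and labels per group", {
  thr <- data.frame(
    cell_id = c("a", "b", "c", "d"),
    group = c("normal", "normal", "normal", "normal"),
    mode = "amplitude_at_fixed_duration",
    fixed_value = 0.5,
    threshold_value = c(7, 8, 9, NA),
    method = c("interpolated", "interpolated", "extrapolated", "censored"))
  fits <- data.frame(cell_id = c("a", "b"), group = "normal",
                     rheobase = c(3, 4), chronaxie = c(1, 2))
  labels <- data.frame(cell_id = c("a", "b", "c", "d"), group = "normal",
                       label = c("well", "well", "poor", "unmodulated"))
  rt <- report_tables(thr, fits, labels)
  expect_equal(rt$well_modulated$formatted, "50.00% (2/4)")
  row <- rt$thresholds[1, ]
  expect_equal(row$n, 3L)
  expect_equal(row$n_censored, 1L)
  expect_equal(row$mean, 8)
  # density of the mean threshold: 8 uA x 0.5 ms over the 30-um disc
  expect_equal(round(row$density_of_mean, 3), 0.566)
  # mean of per-cell densities equals density of mean here by linearity
  expect_equal(row$density_mean_cells, row$density_of_mean)
  expect_equal(rt$sd_fits$rheobase_mean, 3.5)
})
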