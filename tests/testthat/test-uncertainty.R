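test_that("dist_spec validates family parameters before any sampling", {
  expect_s3_class(dist_spec("beta", alpha = 2, beta = 3), "amt_dist")
  expect_error(dist_spec("beta", alpha = -1, beta = 3), "> 0")
  expect_error(dist_spec("gamma", shape = 2), "scale")
  expect_error(dist_spec("uniform", min = 1, max = 0), "min > max")
  expect_error(dist_spec("beta_pert", min = 0, max = 1), "mode")
  # beta_pert can derive its shapes from the mode
  sp <- dist_spec("beta_pert", min = 0.04, max = 0.3, mode = 0.2)
  expect_equal(sp$params$alpha, 3.462, tolerance = 0.001)
  expect_equal(sp$params$beta, 2.538, tolerance = 0.001)
})

test_that("sampling is deterministic under a fixed seed", {
  sp <- default_psa_specs()
  draw <- function() {
    set.seed(123)
    vapply(sp, sample_dist, numeric(5), n = 5)
  }
  expect_identical(draw(), draw())
})

test_that("Beta-PERT draws stay inside the published support", {
  sp <- default_psa_specs()$hb_sd_reduction
  set.seed(5)
  x <- sample_dist(sp, 5000)
  expect_true(all(x >= 0.04 & x <= 0.30))
})

test_that("empirical moments match closed forms within 3 SE at 1e5 draws", {
  n <- 1e5
  specs <- default_psa_specs()
  set.seed(2024)
  for (key in c("utility_hd", "hospitalization_cost", "medicare_share_under65",
                "hr_mortality_per_sd", "hb_sd_reduction", "esa_dose_reduction")) {
    x <- sample_dist(specs[[key]], n)
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - dist_mean(specs[[key]])), 3 * se,
              label = sprintf("mean of %s", key))
  }
  # spot values of the closed forms themselves
  expect_equal(dist_mean(specs$utility_hd), 50.737 / (50.737 + 22.795))
  expect_equal(round(dist_mean(specs$utility_hd), 3), 0.690)
  expect_equal(dist_mean(specs$hospitalization_cost), 1002 * 18.23)
  expect_equal(dist_mean(specs$medicare_share_under65), 0.55)
  expect_equal(round(dist_mean(specs$hr_mortality_per_sd), 4), 1.0907)
})

test_that("all-fixed specs reproduce the base-case parameter set and NMB", {
  p <- load_parameters()
  fixed <- list(utility_hd = dist_spec("fixed", value = p$economic$utility_hd),
                hb_sd_reduction = dist_spec("fixed", value = p$clinical$hb_sd_reduction))
  s <- sample_parameter_set(p, fixed, n = 3)
  for (d in s) expect_equal(d$params, p)
  psa <- run_psa(p, fixed, n = 5, seed = 1)
  base <- run_cea(p)
  expect_equal(psa$draws$nmb, rep(base$nmb_lifetime, 5), tolerance = 1e-9)
  expect_equal(psa$summary$prop_nmb_nonneg, 1)
})

test_that("sampled parameter sets respect the registry and validation", {
  expect_error(
    sample_parameter_set(load_parameters(), list(bogus = dist_spec("fixed", value = 1))),
    "bogus")
  set.seed(77)
  s <- sample_parameter_set(n = 4)
  expect_length(s, 4)
  for (d in s) {
    expect_s3_class(d$params, "amt_parameters")
    expect_true(d$params$economic$utility_hd >= 0 && d$params$economic$utility_hd <= 1)
    expect_identical(names(d$draws), names(default_psa_specs()))
  }
})

test_that("run_psa is reproducible and summarizes the NMB distribution", {
  p <- load_parameters()
  a <- run_psa(p, n = 25, seed = 11)
  b <- run_psa(p, n = 25, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c2 <- run_psa(p, n = 25, seed = 12)
  expect_false(identical(a$draws$nmb, c2$draws$nmb))
  expect_equal(nrow(a$draws), 25)
  expect_equal(a$summary$n, 25)
  expect_equal(a$summary$seed, 11)
  qs <- unname(stats::quantile(a$draws$nmb, c(0.025, 0.975)))
  expect_equal(c(a$summary$ci_lower, a$summary$ci_upper), qs)
  expect_true(a$summary$ci_lower <= a$summary$mean_nmb &&
              a$summary$mean_nmb <= a$summary$ci_upper)
})

test_that("run_psa does not disturb the caller's RNG stream", {
  set.seed(314)
  before <- runif(1)
  set.seed(314)
  invisible(run_psa(n = 2, seed = 9))
  expect_identical(runif(1), before)
})

test_that("tornado entries hold others fixed, bracket the base case, sort by spread", {
  p <- load_parameters()
  tor <- one_way_dsa(p)
  expect_s3_class(tor, "amt_tornado")
  expect_true(all(diff(tor$spread) <= 0))
  base_nmb <- attr(tor, "nmb_base")
  # the model is monotone over each published range: low/high NMB bracket base
  for (i in seq_len(nrow(tor))) {
    lohi <- range(tor$nmb_at_low[i], tor$nmb_at_high[i])
    expect_true(base_nmb >= lohi[1] - 1e-6 && base_nmb <= lohi[2] + 1e-6,
                label = sprintf("bracketing for %s", tor$parameter[i]))
  }
  # parameters at their base value reproduce the base-case NMB (others fixed)
  deg <- one_way_dsa(p, ranges = list(utility_hd = c(0.69, 0.69)))
  expect_equal(deg$spread, 0, tolerance = 1e-9)
  expect_equal(deg$nmb_at_low, base_nmb, tolerance = 1e-9)
  expect_error(one_way_dsa(p, ranges = list(utility_hd = c(0.8, 0.6))), "low, high")
  expect_error(one_way_dsa(p, ranges = list(nope = c(0, 1))), "nope")
})

test_that("a linear stub confirms spread = |slope| * (high - low)", {
  # hospitalization cost enters the NMB linearly; its tornado spread must be
  # |dNMB/dcost| * width.  Estimate the slope by finite difference.
  p <- load_parameters()
  tor <- one_way_dsa(p, ranges = list(hospitalization_cost = c(16160, 17226)))
  f <- function(v) {
    pp <- load_parameters(overrides = list(hospitalization_cost = v))
    res <- run_cea(pp)
    nmb(attr(tor, "wtp"), res$delta_qalys, res$delta_cost)
  }
  slope <- (f(17000) - f(16000)) / 1000
  expect_equal(tor$spread, abs(slope) * (17226 - 16160), tolerance = 1e-6)
})
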