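test_that("hyperparameter sampling is uniform within ranges and seed-stable", {
  cfg <- default_lhs_config()
  set.seed(101)
  d1 <- sample_hyperparameters(cfg)
  set.seed(101)
  d2 <- sample_hyperparameters(cfg)
  expect_identical(d1, d2)
  rng <- cfg$monte_carlo$hyper_ranges
  expect_true(d1$params$a >= rng$a[1] && d1$params$a <= rng$a[2])
  expect_true(d1$params$m0 >= rng$m0[1] && d1$params$m0 <= rng$m0[2])
  # degenerate range pins the parameter
  cfg2 <- cfg
  cfg2$monte_carlo$hyper_ranges$a <- c(9, 9)
  expect_equal(sample_hyperparameters(cfg2)$params$a, 9)
  # uniform moments: mean of a in [6, 14] near 10
  withr::with_seed(7, {
    draws <- replicate(10000, sample_hyperparameters(cfg)$params$a)
  })
  se <- (14 - 6) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(draws) - 10), 3 * se)
})

test_that("coupling scale enforces stability at spectral radius 0.95", {
  K <- default_coupling_matrix()
  expect_equal(as.numeric(scale_coupling(K, 1)), as.numeric(K),
               tolerance = 1e-12)
  expect_false(attr(scale_coupling(K, 1), "stability_enforced"))
  K0 <- scale_coupling(K, 0)
  expect_equal(spectral_radius(K0), 0)
  # build a base with known radius 0.5 and scale it past instability
  base <- coupling_matrix(0.5 * diag(4)[c(2, 3, 4, 1), ])
  scaled <- scale_coupling(base, 4)
  expect_true(attr(scaled, "stability_enforced"))
  expect_equal(spectral_radius(scaled), 0.95, tolerance = 1e-9)
})

test_that("a simulated portfolio carries every project-level invariant", {
  p <- simulate_portfolio(200, seed = 8)
  expect_equal(nrow(p), 200)
  expect_true(all(p$cti >= 0 & p$cti <= 1))
  f <- as.matrix(p[paste0("f", 1:4)])
  v <- as.matrix(p[paste0("v", 1:4)])
  expect_true(all(f > 0))
  expect_true(all(v >= f - 1e-12))       # nonnegative coupling amplifies
  expect_true(all(p$tei_g >= 1 - 1e-12)) # hence gain at least 1
  expect_true(all(p$tei_b > 0 & p$tei_b <= 1))
  expect_equal(p$tei, p$tei_g * p$tei_b, tolerance = 1e-12)
  expect_equal(p$roi, p$revenue / p$expense, tolerance = 1e-12)
  expect_equal(p$revenue, p$R1 + p$R2 + p$R3 + p$R4, tolerance = 1e-9)
  expect_equal(p$expense, p$E1 + p$E2 + p$E3 + p$E4, tolerance = 1e-9)
  expect_false(anyNA(p$state))
  expect_equal(as.character(p$band), as.character(classify_cti_band(p$cti)))
})

test_that("an empty portfolio request returns a typed empty table", {
  p <- simulate_portfolio(0)
  expect_equal(nrow(p), 0)
  expect_true(all(c("cti", "tei_g", "tei_b", "tei", "roi") %in% names(p)))
})

test_that("identical seeds reproduce the portfolio exactly", {
  p1 <- simulate_portfolio(50, seed = 123)
  p2 <- simulate_portfolio(50, seed = 123)
  expect_identical(p1, p2)
})

test_that("a high-CTI portfolio outperforms a low-CTI portfolio", {
  cfg_hi <- default_lhs_config()
  cfg_hi$cti_beta <- list(shape1 = 200, shape2 = 2)   # CTI near 1
  cfg_lo <- default_lhs_config()
  cfg_lo$cti_beta <- list(shape1 = 2, shape2 = 200)   # CTI near 0
  hi <- simulate_portfolio(300, cfg_hi, seed = 77)
  lo <- simulate_portfolio(300, cfg_lo, seed = 77)
  expect_gt(mean(hi$tei), mean(lo$tei))
  expect_gt(mean(hi$vmean), mean(lo$vmean))
  expect_gt(mean(hi$roi), mean(lo$roi))
})

test_that("monte carlo runs are reproducible and iteration-order independent", {
  cfg <- default_lhs_config()
  suppressMessages({
    m1 <- run_monte_carlo(cfg, seed = 5, n_iterations = 4, n_projects = 30)
    m2 <- run_monte_carlo(cfg, seed = 5, n_iterations = 4, n_projects = 30)
  })
  expect_identical(m1$projects, m2$projects)
  expect_identical(m1$iterations, m2$iterations)
  expect_identical(m1$summary, m2$summary)
  # the first iterations of a longer run coincide with the shorter run
  suppressMessages(
    m3 <- run_monte_carlo(cfg, seed = 5, n_iterations = 6, n_projects = 30))
  expect_equal(dplyr::filter(m3$projects, iteration <= 4), m1$projects)
})

test_that("monte carlo summaries are internally consistent", {
  suppressMessages(
    mc <- run_monte_carlo(seed = 31, n_iterations = 20, n_projects = 40))
  expect_equal(sum(mc$state_proportions$proportion), 1, tolerance = 1e-12)
  props <- mc$iterations |>
    dplyr::select(dplyr::starts_with("prop_")) |>
    rowSums()
  expect_equal(unname(props), rep(1, 20), tolerance = 1e-12)
  # every sampled parameter set respects its type invariants
  expect_true(all(mc$iterations$a > 0))
  expect_true(all(mc$iterations$r_max >= 0 & mc$iterations$r_max < 1))
  expect_true(all(mc$iterations$eta > 0 & mc$iterations$c > 0))
  # 95% simulation interval brackets the cross-iteration median
  expect_true(all(mc$summary$q025 <= mc$summary$median + 1e-12))
  expect_true(all(mc$summary$median <= mc$summary$q975 + 1e-12))
  # rounded-normal portfolio sizes in the default config stay near 25
  expect_true(all(mc$iterations$n_projects == 40))
  suppressMessages(mc25 <- run_monte_carlo(seed = 3, n_iterations = 10))
  expect_true(all(mc25$iterations$n_projects >= 1))
  expect_lt(abs(mean(mc25$iterations$n_projects) - 25), 5)
})

test_that("a single iteration collapses intervals and flags the SD", {
  suppressMessages(expect_warning(
    mc <- run_monte_carlo(seed = 9, n_iterations = 1, n_projects = 25),
    "single iteration"))
  expect_true(all(is.na(mc$summary$sd)))
  expect_equal(mc$summary$q025, mc$summary$q975, tolerance = 1e-12)
})

test_that("CTI-ROI association stays positive with zero coupling and flat costs", {
  cfg <- default_lhs_config()
  cfg$coupling$K <- lapply(1:4, function(i) as.list(rep(0, 4)))
  cfg$monte_carlo$k_scale_range <- c(0, 0)
  p <- simulate_portfolio(1000, cfg, seed = 55)
  expect_gt(cor(p$cti, p$roi, method = "spearman"), 0)
  expect_equal(p$tei_g, rep(1, 1000), tolerance = 1e-12)
})
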