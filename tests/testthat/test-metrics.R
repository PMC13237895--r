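v_example <- c(0.59, 0.55, 0.6208, 0.5)

test_that("velocity is the inverse of latency to sustainment", {
  expect_equal(velocity_from_latency(1), 1)
  expect_equal(velocity_from_latency(5), 0.2)
  expect_equal(velocity_from_latency(2), 0.5)
  expect_error(velocity_from_latency(0), "positive")
  expect_error(velocity_from_latency(-3), "positive")
})

test_that("TEI-G is the ratio of weighted norms of coupled to direct drives", {
  f <- rep(0.5, 4)
  expect_equal(tei_gain(f, f), 1)
  expect_equal(tei_gain(2 * f, f), 2)
  expect_equal(tei_gain(v_example, f), 1.13402, tolerance = 1e-5)
  # with the weighted 1-norm TEI-G is a ratio of weighted means
  expect_equal(tei_gain(v_example, f, norm = "l1"),
               mean(v_example) / mean(f))
  expect_error(tei_gain(v_example, rep(0, 4)), "zero weighted norm")
})

test_that("TEI-B is bounded by 1 with equality iff velocities are equal", {
  expect_equal(tei_bottleneck(rep(0.7, 4)), 1)
  expect_equal(tei_bottleneck(v_example), 0.88465, tolerance = 1e-5)
  expect_error(tei_bottleneck(c(1, 1, 0, 1)), "positive")
  withr::with_seed(23, {
    for (i in 1:50) {
      v <- runif(4, 0.1, 2)
      b <- tei_bottleneck(v)
      expect_lte(b, 1)
      if (max(v) - min(v) > 1e-9) expect_lt(b, 1)
    }
  })
  # widening the gap to the slowest wheel decreases TEI-B monotonically
  gaps <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(gaps, function(g) tei_bottleneck(c(1 - g, 1, 1, 1)), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("global TEI is the product of gain and bottleneck indices", {
  expect_equal(tei(1, 1), 1)
  expect_equal(tei(1.495, 0.833), 1.245, tolerance = 5e-4)
  expect_equal(tei(3, 0), 0)
  expect_error(tei(-1, 0.5), "nonnegative")
})

test_that("system velocities report the bottleneck and mission-weighted mean", {
  s <- system_velocities(c(0.753, 0.591, 0.729, 0.601))
  expect_equal(s$weighted_mean, 0.6685)
  expect_equal(s$bottleneck, 0.591)
  s2 <- system_velocities(v_example)
  expect_equal(s2$bottleneck, 0.5)
  expect_lte(s2$bottleneck, s2$weighted_mean)
  s3 <- system_velocities(rep(0.4, 4))
  expect_equal(s3$bottleneck, s3$weighted_mean)
})

test_that("percentile scaling is affine with flagged out-of-range values", {
  expect_equal(as.numeric(scale_percentile(0.2, 0.2, 0.8)), 0)
  expect_equal(as.numeric(scale_percentile(0.8, 0.2, 0.8)), 1)
  expect_equal(as.numeric(scale_percentile(0.5, 0.2, 0.8)), 0.5)
  expect_warning(out <- scale_percentile(c(0.1, 0.5, 0.9), 0.2, 0.8),
                 "outside")
  expect_equal(attr(out, "out_of_range"), c(TRUE, FALSE, TRUE))
  expect_lt(as.numeric(out)[1], 0)  # unclamped
  expect_error(scale_percentile(0.5, 0.8, 0.2), "degenerate")
  # order preservation
  x <- sort(runif(20))
  expect_true(all(diff(as.numeric(suppressWarnings(
    scale_percentile(x, 0.3, 0.6)))) >= 0))
})

test_that("typology classification partitions the efficiency plane", {
  thr <- typology_thresholds(teig_cut = 1.2, teib_cut = 0.8, mode = "fixed")
  sc <- tidyr::expand_grid(tei_g = seq(0.5, 2, by = 0.1),
                           tei_b = seq(0.1, 1, by = 0.05))
  out <- classify_typology(sc, thr)
  expect_false(anyNA(out$state))
  expect_equal(as.character(out$state[out$tei_g >= 1.2 & out$tei_b >= 0.8][1]),
               "FullyIntegrated")
  # boundary convention: values at the cut classify as high
  b <- classify_typology(tibble::tibble(tei_g = 1.2, tei_b = 0.8), thr)
  expect_equal(as.character(b$state), "FullyIntegrated")
  e <- classify_typology(tibble::tibble(tei_g = 1.5, tei_b = 0.5), thr)
  expect_equal(as.character(e$state), "Emerging")
  f <- classify_typology(tibble::tibble(tei_g = 1.0, tei_b = 0.9), thr)
  expect_equal(as.character(f$state), "Functional")
  g <- classify_typology(tibble::tibble(tei_g = 1.0, tei_b = 0.5), thr)
  expect_equal(as.character(g$state), "Fragmented")
})

test_that("median-split typology uses cohort medians and needs a cohort", {
  sc <- tibble::tibble(tei_g = c(1, 2, 3, 4), tei_b = c(0.9, 0.8, 0.7, 0.6))
  out <- classify_typology(sc)
  expect_equal(as.character(out$state),
               c("Functional", "Functional", "Emerging", "Emerging"))
  expect_error(classify_typology(sc[1, ]), "at least 2")
})

test_that("hub TEI-G is the median over projects and periods", {
  expect_equal(hub_tei_g(3.2), 3.2)
  expect_equal(hub_tei_g(c(1, 2, 4)), 2)
  expect_equal(hub_tei_g(c(1, 2, 3, 4)), 2.5)
  expect_error(hub_tei_g(numeric(0)), "nonempty")
})

test_that("the shipped milestone matrix is row-stochastic with the printed values", {
  mw <- milestone_weights()
  expect_equal(nrow(mw), 8)
  m <- as.matrix(mw[c("clinical", "education", "research", "governance")])
  expect_equal(unname(rowSums(m)), rep(1, 8), tolerance = 1e-12)
  expect_equal(mw$governance[mw$milestone == "K1"], 0.40)
  expect_equal(mw$research[mw$milestone == "K3"], 0.70)
  expect_equal(mw$clinical[mw$milestone == "K7"], 0.50)
})

test_that("milestone attribution conserves total latency", {
  mw <- milestone_weights()
  # unit latencies: each wheel receives its column sum; clinical = 2.20
  att <- attribute_milestones(rep(1, 8), mw)
  expect_equal(att[["clinical"]], 2.20)
  expect_equal(sum(att), 8)
  expect_equal(unname(attribute_milestones(rep(0, 8), mw)), rep(0, 4))
  withr::with_seed(5, {
    lat <- rexp(8, rate = 0.1)
    att <- attribute_milestones(lat, mw)
    expect_equal(sum(att), sum(lat), tolerance = 1e-9)
  })
  bad <- mw
  bad$clinical[1] <- 0.5
  expect_error(attribute_milestones(rep(1, 8), bad), "sum to 1")
})
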