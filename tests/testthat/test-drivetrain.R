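test_that("transmission is logistic with the midpoint identity", {
  p <- transmission_params(a = 10, m0 = 0.5)
  expect_equal(transmission(0.5, p), 0.5)
  expect_equal(transmission(1, p), 1 / (1 + exp(-5)), tolerance = 1e-10)
  expect_equal(transmission(0, p), 1 / (1 + exp(5)), tolerance = 1e-10)
  expect_equal(transmission(1, p), 0.99331, tolerance = 1e-5)
  expect_equal(transmission(0, p), 0.00669, tolerance = 1e-3)
})

test_that("friction reduction is Hill-form with half-saturation at M = c", {
  p <- transmission_params(r_max = 0.6, eta = 2, c = 0.5)
  expect_equal(friction_reduction(0, p), 0)
  expect_equal(friction_reduction(0.5, p), 0.3)  # r_max / 2 at M = c
  expect_equal(friction_reduction(1, p), 0.48)   # 0.6 * 1 / (1 + 0.25)
})

test_that("T and R are strictly increasing in M for random valid parameters", {
  withr::with_seed(21, {
    grid <- seq(0.001, 1, length.out = 200)
    for (i in 1:20) {
      p <- transmission_params(a = runif(1, 1, 20), m0 = runif(1),
                               r_max = runif(1, 0.1, 0.9),
                               eta = runif(1, 0.5, 4), c = runif(1, 0.1, 0.9))
      expect_true(all(diff(transmission(grid, p)) > 0))
      expect_true(all(diff(friction_reduction(grid, p)) > 0))
    }
  })
})

test_that("parameter validation rejects out-of-range constants", {
  expect_error(transmission_params(a = -1), "`a`")
  expect_error(transmission_params(m0 = 1.5), "m0")
  expect_error(transmission_params(r_max = 1), "r_max")
  expect_error(transmission_params(eta = 0), "eta")
  expect_error(transmission_params(c = 0), "`c`")
})

test_that("wheel drive follows the saturating contest form", {
  # E*T = F*(1-R) gives exactly half the velocity cap
  p <- transmission_params(a = 10, m0 = 0.5, r_max = 0.6, eta = 2, c = 0.5)
  TT <- transmission(0.5, p)       # 0.5
  RR <- friction_reduction(0.5, p) # 0.3
  alloc <- wheel_allocation(rep(1, 4) * (1 - RR), rep(TT, 4), rep(1, 4))
  expect_equal(unname(wheel_drive(0.5, alloc, p)), rep(0.5, 4))
  # v_max 1, E 2, T 0.5, F 1, R 0.5 -> f = 1/(1 + 0.5) = 2/3
  p2 <- transmission_params(a = 1e-9, m0 = 0.5, r_max = 0.5, eta = 1,
                            c = 1e-9)
  # T -> 0.5 for any M with a ~ 0; R -> r_max with c ~ 0
  f <- wheel_drive(0.7, wheel_allocation(rep(2, 4), rep(1, 4), rep(1, 4)), p2)
  expect_equal(unname(f), rep(2 / 3, 4), tolerance = 1e-6)
  # saturation limit: enormous engine power drives f to v_max
  f_big <- wheel_drive(0.5, wheel_allocation(rep(1e9, 4), rep(1, 4),
                                             c(1, 2, 3, 4)), p)
  expect_equal(unname(f_big), c(1, 2, 3, 4), tolerance = 1e-6)
})

test_that("wheel drive is monotone in engine power, friction and CTI", {
  p <- transmission_params()
  withr::with_seed(31, {
    for (i in 1:20) {
      E <- runif(4, 0.5, 3)
      F_ <- runif(4, 0.5, 3)
      vmax <- runif(4, 0.5, 2)
      M <- runif(1, 0.05, 0.9)
      f0 <- wheel_drive(M, wheel_allocation(E, F_, vmax), p)
      expect_true(all(wheel_drive(M, wheel_allocation(E * 1.1, F_, vmax), p) > f0))
      expect_true(all(wheel_drive(M, wheel_allocation(E, F_ * 1.1, vmax), p) < f0))
      expect_true(all(wheel_drive(M + 0.05, wheel_allocation(E, F_, vmax), p) > f0))
      expect_true(all(f0 > 0 & f0 < vmax))
    }
  })
})

test_that("spectral radius handles zero, nilpotent and permutation cases", {
  expect_equal(spectral_radius(matrix(0, 4, 4)), 0)
  # the four reported spillovers alone form an acyclic (nilpotent) graph
  K <- matrix(0, 4, 4)
  K[1, 4] <- 0.18; K[2, 4] <- 0.10; K[3, 4] <- 0.10; K[3, 1] <- 0.12
  expect_equal(spectral_radius(K), 0)
  # scaled 4-cycle permutation has spectral radius equal to the scale
  P <- 0.5 * diag(4)[c(2, 3, 4, 1), ]
  expect_equal(spectral_radius(P), 0.5, tolerance = 1e-12)
})

test_that("coupled velocities solve (I-K)v = f and amplify", {
  f <- rep(0.5, 4)
  expect_equal(unname(coupled_velocities(f, matrix(0, 4, 4))), f)
  # the four printed spillovers, forward-substituted by hand
  K <- matrix(0, 4, 4)
  K[1, 4] <- 0.18; K[2, 4] <- 0.10; K[3, 4] <- 0.10; K[3, 1] <- 0.12
  v <- coupled_velocities(f, K)
  expect_equal(unname(v), c(0.59, 0.55, 0.6208, 0.5), tolerance = 1e-12)
})

test_that("coupled velocities match the Neumann-series oracle", {
  withr::with_seed(13, {
    for (i in 1:200) {
      K <- random_stable_K()
      f <- runif(4, 0, 2)
      expect_equal(unname(coupled_velocities(f, K)),
                   neumann_oracle(f, K, terms = 300), tolerance = 1e-10)
    }
  })
})

test_that("nonnegative coupling never attenuates: v >= f elementwise", {
  withr::with_seed(17, {
    for (i in 1:50) {
      K <- random_stable_K()
      f <- runif(4, 0, 1)
      v <- coupled_velocities(f, K)
      expect_true(all(v >= f - 1e-12))
    }
  })
})

test_that("unstable coupling matrices are rejected by every consumer", {
  K_bad <- matrix(0.5, 4, 4)
  diag(K_bad) <- 0
  expect_gte(spectral_radius(K_bad), 1)
  expect_error(coupling_matrix(K_bad), "spectral radius")
  expect_error(coupled_velocities(rep(1, 4), K_bad), "spectral radius")
  expect_error(coupling_matrix(matrix(0.1, 4, 4)), "diagonal")
  K_neg <- matrix(0, 4, 4)
  K_neg[1, 2] <- -0.1
  expect_error(coupling_matrix(K_neg), "nonnegative")
})

test_that("the default coupling matrix carries the reported spillovers", {
  K <- default_coupling_matrix()
  expect_equal(K["clinical", "governance"], 0.18)
  expect_equal(K["education", "governance"], 0.10)
  expect_equal(K["research", "governance"], 0.10)
  expect_equal(K["research", "clinical"], 0.12)
  expect_true(all(K[K > 0 & K != 0.18 & K != 0.12] <= 0.10))
  expect_lt(spectral_radius(K), 1)
  expect_true(all(diag(K) == 0))
})
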