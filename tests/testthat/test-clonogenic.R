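test_that("surviving fractions normalize by the 0 Gy plating efficiency", {
  plate <- data.frame(dose_gy = c(0, 0, 4, 4), seeded = 250,
                      colonies = c(125, 125, 25, 25))
  sf <- surviving_fractions(plate, per_well = FALSE)
  expect_equal(attr(sf, "plating_efficiency"), 0.5)
  expect_equal(sf$sf[sf$dose_gy == 0], 1)
  expect_equal(sf$sf[sf$dose_gy == 4], 0.2)

  # equal counts at every dose -> SF identically 1
  plate2 <- data.frame(dose_gy = rep(c(0, 2, 4), each = 3), seeded = 100,
                       colonies = 40)
  expect_true(all(surviving_fractions(plate2)$sf == 1))

  # zero colonies at 0 Gy -> PE undefined
  plate3 <- data.frame(dose_gy = c(0, 2), seeded = 100, colonies = c(0, 5))
  expect_error(surviving_fractions(plate3), "plating efficiency")

  # zero colonies at positive dose -> flagged, not an error
  plate4 <- data.frame(dose_gy = c(0, 8), seeded = 100, colonies = c(50, 0))
  sf4 <- surviving_fractions(plate4)
  expect_true(sf4$zero_count[sf4$dose_gy == 8])
})

test_that("lq_sf evaluates the linear-quadratic model", {
  expect_equal(lq_sf(0, 0, c(0, 3, 10)), c(1, 1, 1))
  expect_equal(lq_sf(0.3, 0.05, 0), 1)
  expect_equal(lq_sf(0.2, 0.02, 4), exp(-1.12))
  expect_error(lq_sf(0.1, 0.1, -1), ">= 0")
  # monotone non-increasing in dose
  d <- seq(0, 12, by = 0.25)
  expect_true(all(diff(lq_sf(0.15, 0.03, d)) <= 0))
})

test_that("fit_lq recovers noiseless parameters and honors constraints", {
  d <- c(0, 2, 4, 6, 8)
  pts <- data.frame(dose_gy = d, sf = lq_sf(0.2, 0.02, d))
  f <- fit_lq(pts)
  expect_equal(f$alpha, 0.2, tolerance = 1e-8)
  expect_equal(f$beta, 0.02, tolerance = 1e-8)
  expect_lt(f$rss, 1e-20)
  expect_equal(f$df, length(d) - 2L)

  # SF == 1 everywhere -> alpha = beta = 0, RSS = 0
  f1 <- fit_lq(data.frame(dose_gy = d, sf = 1))
  expect_equal(c(f1$alpha, f1$beta, f1$rss), c(0, 0, 0))

  # pure-linear truth: fitted beta at/near zero, vs brute-force grid oracle
  pts2 <- data.frame(dose_gy = d, sf = lq_sf(0.3, 0, d))
  f2 <- fit_lq(pts2)
  expect_equal(f2$alpha, 0.3, tolerance = 1e-8)
  expect_equal(f2$beta, 0, tolerance = 1e-8)
  grid <- expand.grid(a = seq(0, 0.6, 0.005), b = seq(0, 0.1, 0.001))
  rss_g <- mapply(function(a, b) sum((log(pts2$sf) + a * d + b * d^2)^2),
                  grid$a, grid$b)
  best <- grid[which.min(rss_g), ]
  expect_equal(f2$alpha, best$a, tolerance = 0.01)
  expect_equal(f2$beta, best$b, tolerance = 0.002)

  # negative-trending data is clipped to the constraint, flagged
  pts3 <- data.frame(dose_gy = d, sf = pmin(exp(0.05 * d), 1 + 0 * d) + 0.5)
  f3 <- fit_lq(pts3)
  expect_gte(f3$alpha, 0)
  expect_gte(f3$beta, 0)
  expect_true(f3$constrained)

  expect_error(fit_lq(data.frame(dose_gy = c(0, 2), sf = c(1, 0.5))),
               "3 distinct doses")
  expect_warning(fit_lq(data.frame(dose_gy = c(0, 2, 4, 6),
                                   sf = c(1, 0.5, 0.2, 0))),
                 "SF = 0")
})

test_that("dose_for_sf inverts the model", {
  expect_equal(dose_for_sf(list(alpha = 0.5, beta = 0), 0.1),
               log(10) / 0.5)
  expect_equal(dose_for_sf(list(alpha = 0.2, beta = 0.02), 1), 0)
  # numeric root-finder oracle
  f <- list(alpha = 0.2, beta = 0.02)
  d <- dose_for_sf(f, 0.1)
  oracle <- uniroot(function(x) lq_sf(f$alpha, f$beta, x) - 0.1,
                    c(0, 50), tol = 1e-12)$root
  expect_equal(d, oracle, tolerance = 1e-9)
  expect_equal(d, 6.838, tolerance = 1e-3)
  expect_error(dose_for_sf(list(alpha = 0, beta = 0), 0.1), "no dose")
  # round trip identity on random doses
  set.seed(1)
  ds <- runif(50, 0.01, 10)
  back <- dose_for_sf(f, lq_sf(f$alpha, f$beta, ds))
  expect_equal(back, ds, tolerance = 1e-9)
})

test_that("curve comparison F-test: identity, exact-fit branch, symmetry", {
  d <- c(0, 2, 4, 6, 8)
  pts <- data.frame(dose_gy = d, sf = lq_sf(0.2, 0.02, d))
  noisy <- data.frame(dose_gy = rep(d, 3),
                      sf = exp(-0.2 * rep(d, 3) - 0.02 * rep(d, 3)^2 +
                                 c(0.01, -0.02, 0.03, 0, -0.01, 0.02, 0.01,
                                   -0.03, 0.02, 0, 0.01, -0.01, 0.02, 0.01,
                                   -0.02)))
  # identical groups: pooled fit equals individual fits, F = 0, p = 1
  same <- compare_curves_ftest(noisy, noisy)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # two noiseless groups from different parameters: exact-fit branch
  pts_b <- data.frame(dose_gy = d, sf = lq_sf(0.4, 0.01, d))
  exact <- compare_curves_ftest(pts, pts_b)
  expect_true(is.infinite(exact$F))
  expect_equal(exact$p, 0)
  expect_true(exact$exact_complex_fit)

  # symmetry in the two groups
  set.seed(3)
  a <- lq_model_points(0.2, 0.02)
  b <- lq_model_points(0.25, 0.02)
  ab <- compare_curves_ftest(a, b)
  ba <- compare_curves_ftest(b, a)
  expect_equal(ab$F, ba$F)
  expect_equal(ab$p, ba$p)
  expect_gte(ab$rss_simple, ab$rss_complex)
})
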