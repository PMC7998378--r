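test_that("preprocess_stack equalizes channel strengths", {
  px <- 2
  mk <- function(a) {
    arr <- array(0, c(40, 40, 4))
    for (s in 1:4) arr[15:25, 15:25, s] <- a
    arr
  }
  st <- spheroid_stack(mk(50), mk(50), c(0, 10, 20, 30), px)
  pp <- preprocess_stack(st, rollball_um = 20)
  expect_equal(pp$norm_factor, 1)
  # green twice the red pattern -> factor 0.5, equalized means
  st2 <- spheroid_stack(mk(100), mk(50), c(0, 10, 20, 30), px)
  pp2 <- preprocess_stack(st2, rollball_um = 20)
  expect_equal(pp2$norm_factor, 0.5)
  expect_equal(mean(pp2$green[pp2$green > 0]),
               mean(pp2$red[pp2$red > 0]))
  # combined stack dominates each channel pointwise
  expect_true(all(pp2$combined >= pp2$green - 1e-12))
  expect_true(all(pp2$combined >= pp2$red - 1e-12))
})

test_that("slice_outline handles disks and blanks", {
  px <- 2
  sl <- matrix(0, 80, 80)
  for (i in 1:80) for (j in 1:80)
    if ((i - 40)^2 + (j - 40)^2 <= 30^2) sl[i, j] <- 60
  sl <- sl + matrix(abs(rnorm(6400, 0, 1)), 80, 80)
  m <- slice_outline(sl, px)
  truth <- matrix(FALSE, 80, 80)
  for (i in 1:80) for (j in 1:80)
    if ((i - 40)^2 + (j - 40)^2 <= 30^2) truth[i, j] <- TRUE
  expect_gt(sum(m & truth) / sum(m | truth), 0.95)
  expect_null(slice_outline(matrix(2, 30, 30), px))
  # mask area monotone in disk radius
  areas <- vapply(c(10, 18, 26), function(r) {
    s <- matrix(0, 80, 80)
    for (i in 1:80) for (j in 1:80)
      if ((i - 40)^2 + (j - 40)^2 <= r^2) s[i, j] <- 60
    sum(slice_outline(s + matrix(abs(rnorm(6400, 0, 1)), 80, 80), px))
  }, 1.0)
  expect_true(all(diff(areas) > 0))
})

test_that("fit_sphere recovers exact geometry from circle areas", {
  px <- 1
  R <- 200; zc <- 150
  z <- seq(10, 290, 20)
  # algebraic identity: ideal areas -> radii -> linear fit is exact
  r_um <- sqrt(R^2 - (z - zc)^2)
  y <- r_um^2 + z^2
  fit <- lm(y ~ z)
  zc_hat <- coef(fit)[["z"]] / 2
  R_hat <- sqrt(coef(fit)[["(Intercept)"]] + zc_hat^2)
  expect_equal(c(R_hat, zc_hat), c(R, zc), tolerance = 1e-9)
  # and through the exported function with pixel-perfect disk masks
  mk_disk <- function(r_px, n = 431) {
    m <- matrix(FALSE, n, n)
    ctr <- (n + 1) / 2
    for (i in 1:n) for (j in 1:n)
      if ((i - ctr)^2 + (j - ctr)^2 <= r_px^2) m[i, j] <- TRUE
    m
  }
  outl <- lapply(z, function(zz) mk_disk(sqrt(R^2 - (zz - zc)^2)))
  g <- fit_sphere(outl, z, px)
  expect_equal(g$R_um, R, tolerance = 0.01)
  expect_equal(g$zc_um, zc, tolerance = 0.05 * R)
  expect_error(fit_sphere(outl[1:2], z[1:2], px), ">= 3")
  expect_error(fit_sphere(rep(outl[1], 3), rep(10, 3), px), "degenerate")
})

test_that("distance_3d matches geometry examples and brute force", {
  g <- structure(list(R_um = 100, zc_um = 0), class = "sphere_geometry")
  # equatorial rim point -> 0; equatorial center -> R
  expect_equal(as.numeric(distance_3d(0, 0, g)), 0)
  expect_equal(as.numeric(distance_3d(100, 0, g)), 100)
  # printed example: z = 60 (r_z = 80), d2 = 30 -> 100 - sqrt(6100)
  d <- as.numeric(distance_3d(30, 60, g))
  expect_equal(d, 100 - sqrt(50^2 + 60^2), tolerance = 1e-12)
  expect_equal(d, 21.90, tolerance = 1e-3)
  # brute-force nearest-surface-point oracle, 200 random cases
  set.seed(23)
  for (i in 1:200) {
    z <- runif(1, -95, 95)
    rz <- sqrt(100^2 - z^2)
    d2 <- runif(1, 0, rz)
    mine <- as.numeric(distance_3d(d2, z, g))
    bf <- brute_surface_distance(rz - d2, z, 100, n = 2e4)
    expect_lt(abs(mine - bf), 0.1)
  }
  # monotone increasing in d2 within a slice; equals d2 on the equator
  d2s <- seq(0, 80, 5)
  v <- as.numeric(distance_3d(d2s, 60, g))
  expect_true(all(diff(v) > 0))
  expect_equal(as.numeric(distance_3d(d2s, 0, g)), d2s)
  expect_error(distance_3d(0, 150, g), "outside")
})

test_that("classify_green uses the strict 0.225 normalized-green rule", {
  expect_equal(as.character(classify_green(0.3, 0.7)), "green")
  expect_equal(as.character(classify_green(0, 1)), "red")
  # exactly at the threshold -> red (strictly larger than)
  expect_equal(as.character(classify_green(0.225, 0.775)), "red")
  expect_equal(as.character(classify_green(0.226, 0.774)), "green")
  expect_true(is.na(classify_green(0, 0)))
})

test_that("radial_histogram bins at 10 um with complementary fractions", {
  d3 <- c(5, 15, 15, 25, 34, 36)
  cl <- factor(c("green", "green", "red", "red", "green", "red"),
               levels = c("red", "green"))
  h <- radial_histogram(d3, cl)
  expect_equal(h$bin, 0:3)
  expect_equal(h$n, c(1L, 2L, 1L, 2L))
  expect_equal(h$green_fraction, c(1, 0.5, 0, 0.5))
  expect_equal(h$green_fraction + h$red_fraction, rep(1, 4))
  # all-green input -> fraction 1 in every nonempty bin
  h1 <- radial_histogram(c(3, 12, 40), factor(rep("green", 3),
                                              levels = c("red", "green")))
  expect_true(all(h1$green_fraction[h1$n > 0] == 1))
})
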