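test_that("classify_state implements the red/green gating logic", {
  g <- cc_gates(30, 30)
  # red high / green low -> G1; both low -> early G1 (gating definition)
  expect_equal(as.character(classify_state(100, 5, g)), "G1")
  expect_equal(as.character(classify_state(5, 5, g)), "earlyG1")
  expect_equal(as.character(classify_state(5, 100, g)), "G2")
  expect_equal(as.character(classify_state(100, 100, g)), "S")
  # values exactly at the gate are "low" (declared tie rule)
  expect_equal(as.character(classify_state(30, 30, g)), "earlyG1")
  expect_equal(as.character(classify_state(30.0001, 30, g)), "G1")
  # the plane is partitioned: exactly one state for any pair
  set.seed(8)
  st <- classify_state(runif(500, 0, 100), runif(500, 0, 100), g)
  expect_true(all(!is.na(st)))
})

test_that("calibrate_gates is deterministic, scale-equivariant, and falls back", {
  set.seed(9)
  red <- exp(c(rnorm(400, log(10), 0.3), rnorm(400, log(100), 0.3)))
  green <- exp(c(rnorm(400, log(8), 0.3), rnorm(400, log(80), 0.3)))
  g1 <- calibrate_gates(red, green)
  expect_gt(g1$red, quantile(red, 0.4))
  expect_lt(g1$red, quantile(red, 0.6))
  # misclassification of the known mixture < 5%
  lab <- rep(c(FALSE, TRUE), each = 400)
  expect_lt(mean((red > g1$red) != lab), 0.05)
  # scale equivariance (log-domain Otsu bins shift exactly)
  g10 <- calibrate_gates(red * 10, green * 10)
  expect_equal(g10$red / g1$red, 10, tolerance = 1e-6)
  # all-constant channel takes the fallback path
  expect_warning(calibrate_gates(rep(2, 200), green), "unimodal")
  expect_error(calibrate_gates(red[1:50], green[1:50]), ">= 100")
})

test_that("trace_durations applies the non-cycling rules", {
  g <- cc_gates(50, 50)
  dt <- 0.5
  mk <- function(states, mit_at = NA) {
    lv <- list(earlyG1 = c(10, 10), G1 = c(100, 10), S = c(100, 100),
               G2 = c(10, 100))
    m <- do.call(rbind, lv[states])
    data.frame(t_h = (seq_along(states) - 1) * dt, red = m[, 1],
               green = m[, 2],
               mitosis = seq_along(states) == mit_at)
  }
  # 30 h of red -> stall (the > 24 h rule)
  tr <- mk(rep("G1", 61))
  expect_equal(trace_durations(tr, g)$status, "noncycling_stall")
  # green then red without a mitosis flag -> slip
  tr2 <- mk(c(rep("G2", 10), rep("G1", 10)))
  expect_equal(trace_durations(tr2, g)$status, "noncycling_slip")
  # same with a mitosis flag between: cycling
  tr3 <- mk(c(rep("earlyG1", 4), rep("G1", 16), rep("S", 14),
              rep("G2", 6)), mit_at = 40)
  d3 <- trace_durations(tr3, g)
  expect_equal(d3$status, "cycling")
  expect_equal(d3$total_h, 20)
  expect_equal(d3$G1_h, 8)
  expect_equal(d3$S_h, 7)
  # short trace ending mid-phase without exceeding the threshold: censored
  tr4 <- mk(c(rep("earlyG1", 4), rep("G1", 10)))
  expect_equal(trace_durations(tr4, g)$status, "censored")
  # "always" movie-end rule stalls the same trace
  expect_equal(trace_durations(tr4, g, movie_end_rule = "always")$status,
               "noncycling_stall")
  expect_error(trace_durations(mk(c("G1", "G1"))[c(1, 1), ], g),
               "strictly increasing")
})

test_that("Kruskal-Wallis H matches the rank-formula and stats oracle", {
  # hand rank-sum computation: {1,2,3} vs {4,5,6} -> H = 3.857
  kw <- compare_durations(list(a = 1:3, b = 4:6))
  expect_equal(kw$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  # identical groups -> H = 0
  expect_equal(compare_durations(list(a = rep(2, 5), b = rep(2, 5)))$H, 0)
  # invariance under group relabeling
  set.seed(10)
  gs <- list(x = rnorm(12), y = rnorm(12, 1), z = rnorm(12, 2))
  expect_equal(compare_durations(gs)$H,
               compare_durations(gs[c(3, 1, 2)])$H)
  # tie-corrected H and p agree with stats::kruskal.test
  vals <- list(a = c(1, 2, 2, 3, 7), b = c(2, 5, 5, 6), c = c(3, 3, 8, 9))
  kw2 <- compare_durations(vals)
  ref <- kruskal.test(unlist(vals),
                      factor(rep(seq_along(vals), lengths(vals))))
  expect_equal(kw2$H, unname(ref$statistic))
  expect_equal(kw2$p, ref$p.value)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
  r <- cycling_association(c(10, 0), c(0, 10))
  expect_equal(r$p, 2 / choose(20, 10))
  expect_equal(cycling_association(c(5, 5), c(5, 5))$p, 1)
  # row swap inverts the odds ratio, p unchanged
  a <- cycling_association(c(12, 3), c(5, 9))
  b <- cycling_association(c(5, 9), c(12, 3))
  expect_equal(a$p, b$p)
  expect_equal(a$odds_ratio, 1 / b$odds_ratio)
  # Haldane correction engages on zero cells
  z <- cycling_association(c(10, 0), c(5, 5))
  expect_true(is.finite(z$odds_ratio))
  expect_error(cycling_association(c(0, 0), c(5, 5)), "empty margin")
  # spot agreement with enumeration on random tables
  set.seed(11)
  for (i in 1:100) {
    t <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(cycling_association(t[1, ], t[2, ])$p,
                 enum_fisher_p(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  }
})
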