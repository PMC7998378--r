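test_that("CFA counts follow the planted LQ Poisson law", {
  cfg <- sim_config(seed = 2)
  # SF = 1 identity: alpha = beta = 0, PE = 1 -> mean 250 at every dose
  p0 <- simulate_cfa_counts(0, 0, c(0, 2, 8), 250, 1, 2000, cfg)
  for (d in c(0, 2, 8)) {
    m <- mean(p0$colonies[p0$dose_gy == d])
    expect_lt(abs(m - 250), 3 * sqrt(250 / 2000))
  }
  # PE = 0 -> all zero
  expect_true(all(simulate_cfa_counts(0.1, 0.01, c(0, 2), 250, 0, 4,
                                      cfg)$colonies == 0))
  # direct evaluation of the LQ mean at D = 4, within 3 SE at 10^4 wells
  p4 <- simulate_cfa_counts(0.2, 0.02, c(0, 4), 250, 1, 1e4, cfg)
  mu <- 250 * exp(-1.12)
  x <- p4$colonies[p4$dose_gy == 4]
  expect_lt(abs(mean(x) - mu), 3 * sqrt(mu / 1e4))
  # Poisson mean/variance ratio -> 1 within 3 SE
  expect_lt(abs(var(x) / mean(x) - 1), 3 * sqrt(2 / 1e4))
  expect_error(simulate_cfa_counts(-0.1, 0, c(0, 2), cfg = cfg), ">= 0")
  expect_error(simulate_cfa_counts(0.1, 0, c(2, 4), cfg = cfg), "0 Gy")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 123)
  expect_identical(simulate_cfa_counts(0.2, 0.02, c(0, 2), cfg = cfg),
                   simulate_cfa_counts(0.2, 0.02, c(0, 2), cfg = cfg))
  a <- generate_foci_image(6, 5, cfg)
  b <- generate_foci_image(6, 5, cfg)
  expect_identical(a$channels, b$channels)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  expect_identical(generate_fucci_traces(20, cfg = cfg),
                   generate_fucci_traces(20, cfg = cfg))
  r1 <- generate_reporter_image(0.7, 9, cfg)
  r2 <- generate_reporter_image(0.7, 9, cfg)
  expect_identical(r1$channels, r2$channels)
  s1 <- generate_section_image(100, 40, 30, cfg)
  s2 <- generate_section_image(100, 40, 30, cfg)
  expect_identical(s1, s2)
  # different seeds diverge
  expect_false(identical(
    generate_fucci_traces(20, cfg = sim_config(seed = 1)),
    generate_fucci_traces(20, cfg = sim_config(seed = 2))))
})

test_that("foci image bookkeeping: planted spots match the truth table", {
  cfg <- sim_config(seed = 11)
  img <- generate_foci_image(20, 10, cfg)
  truth <- attr(img, "truth")
  expect_equal(sum(truth$nuclei$count), nrow(truth$foci))
  expect_equal(max(img$labels), 20L)
  # zero-focus nucleus leaves its focus channel empty inside the nucleus
  img0 <- generate_foci_image(1, 0, cfg, noise_sd = 0)
  inside <- img0$labels == 1L
  expect_lt(diff(range(img0$channels$foci[inside])), 1e-9)
  # coordinates inside image bounds
  expect_true(all(truth$foci$row >= 0 &
                    truth$foci$row <= nrow(img$channels$foci) - 1))
})

test_that("fucci trace generator honors phase structure and modes", {
  cfg <- sim_config(seed = 21)
  tr <- generate_fucci_traces(40, noncycling_fraction = 0, cfg = cfg,
                              noise_cv = 0)
  truth <- attr(tr, "truth")
  expect_true(all(truth$status == "cycling" | truth$status == "censored"))
  # noiseless recovery of planted durations, exact at frame resolution
  gates <- cc_gates(50, 50)
  cyc <- truth$cell_id[truth$status == "cycling"]
  for (id in cyc[1:5]) {
    d <- trace_durations(tr[tr$cell_id == id, ], gates)
    expect_equal(d$total_h, truth$total_h[truth$cell_id == id])
  }
  # stall mode: all flagged non-cycling
  tr_st <- generate_fucci_traces(30, noncycling_fraction = 1, cfg = cfg,
                                 noncycling_mode = "stall")
  expect_true(all(attr(tr_st, "truth")$status == "noncycling_stall"))
  dur <- trace_durations_table(tr_st, gates = cc_gates(50, 50))
  expect_true(all(dur$status == "noncycling_stall"))
  # frame interval above the shortest phase warns
  expect_warning(
    generate_fucci_traces(2, cfg = sim_config(seed = 1,
                                              frame_interval_h = 3)),
    "quantized")
})

test_that("reporter image plants the requested ratio exactly in means", {
  cfg <- sim_config(seed = 31)
  img <- generate_reporter_image(0.5, 4, cfg, noise_sd = 0)
  truth <- attr(img, "truth")
  expect_equal(truth$ratio, rep(0.5, 4))
  lab <- img$labels
  rep_ch <- img$channels$reporter
  # nucleus interior at background + 100, ring at background + 50
  expect_equal(median(rep_ch[lab == 1]), 108)
  band <- cytoplasm_band(lab, 1.5, img$pixel_size_um)
  expect_equal(median(rep_ch[band == 1]), 58)
})

test_that("section generator geometry matches its truth masks", {
  cfg <- sim_config(seed = 41, pixel_size_um = 1.3)
  # hypoxia onset just inside the rim -> truth positive only in center disk
  gen <- generate_section_image(100, 95, 0, cfg)
  t <- gen$truth
  expect_true(all(!t$brdu))
  area_frac <- sum(t$hypoxia) / sum(t$section)
  expect_equal(area_frac, (5 / 100)^2, tolerance = 0.5)
  # proliferation depth 0 -> no BrdU anywhere
  expect_warning(prof <- section_pipeline(gen$pimo, gen$brdu, 1.3),
                 "empty mask")
  expect_true(all(prof$brdu_fraction == 0, na.rm = TRUE))
  expect_error(generate_section_image(100, 120, 10, cfg), "must be <")
})

test_that("spheroid stack truth covers both rim classes correctly", {
  cfg <- sim_config(seed = 51, pixel_size_um = 2)
  st0 <- generate_spheroid_stack(80, 0, 10, cfg)
  expect_true(all(attr(st0, "truth")$cells$class == "red"))
  st1 <- generate_spheroid_stack(80, 80, 10, cfg)
  expect_true(all(attr(st1, "truth")$cells$class == "green"))
  tr <- attr(st1, "truth")$cells
  expect_true(all(tr$d_surface_um >= 0 & tr$d_surface_um <= 80))
  expect_error(generate_spheroid_stack(15, 5, 10, cfg), "too small")
})
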