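test_that("stain matrix is unit-norm and deconvolution inverts mixing", {
  M <- stain_matrix_haec()
  expect_equal(colSums(M^2), c(H = 1, AEC = 1, residual = 1))
  expect_gt(abs(det(M)), 1e-3)
  # pure white -> OD ~ 0 in both stain channels
  white <- array(255, c(4, 4, 3))
  dec <- deconvolve_haec(white)
  expect_lt(max(abs(dec$H)), 1e-2)
  expect_lt(max(abs(dec$AEC)), 1e-2)
  # pixel synthesized from the AEC vector only -> H channel ~ 0
  od_aec <- M[, "AEC"] * 0.7
  px <- array(rep(256 * exp(-od_aec) - 1, each = 1), c(1, 1, 3))
  d1 <- deconvolve_haec(px)
  expect_equal(d1$AEC[1, 1], 0.7, tolerance = 1e-10)
  expect_lt(abs(d1$H[1, 1]), 1e-10)
  # unmix-after-mix on a noiseless synthetic section: < 1e-6 OD
  gen <- generate_section_image(60, 25, 15, sim_config(seed = 18,
                                                       pixel_size_um = 1.3))
  dec2 <- deconvolve_haec(gen$pimo)
  truth_aec <- ifelse(gen$truth$hypoxia, 0.8,
                      ifelse(gen$truth$section, 0.02, 0))
  expect_lt(max(abs(dec2$AEC - truth_aec)), 1e-6)
  expect_error(deconvolve_haec(white, matrix(1, 3, 3)), "singular")
})

test_that("outline_section finds the tissue disk and rejects blanks", {
  gen <- generate_section_image(80, 30, 20, sim_config(seed = 19,
                                                       pixel_size_um = 1.3))
  mask <- outline_section(gen$pimo)
  t <- gen$truth$section
  iou <- sum(mask & t) / sum(mask | t)
  expect_gt(iou, 0.98)
  expect_equal(max(hypoxiq:::cpp_label(mask, 4L)), 1L)  # single component
  expect_error(outline_section(array(255, c(10, 10, 3))), "blank")
})

test_that("hypoxia_mask: exact 1D 2-means split", {
  # bimodal OD -> mask equals the high population exactly
  od <- matrix(c(rep(0.1, 60), rep(0.9, 40)), 10, 10)
  sec <- matrix(TRUE, 10, 10)
  m <- hypoxia_mask(od, sec)
  expect_identical(m, od > 0.5)
  # constant OD -> empty mask with warning
  expect_warning(m0 <- hypoxia_mask(matrix(0.3, 5, 5), matrix(TRUE, 5, 5)),
                 "constant")
  expect_false(any(m0))
  # the split minimizes within-class SS (oracle by grid search)
  set.seed(20)
  v <- c(rnorm(150, 1, 0.2), rnorm(100, 3, 0.3))
  thr <- hypoxiq:::kmeans2_threshold(v)
  sv <- sort(v)
  ss <- vapply(seq_len(length(sv) - 1), function(k) {
    lo <- sv[1:k]; hi <- sv[(k + 1):length(sv)]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, 1.0)
  kbest <- which.min(ss)
  expect_equal(thr, (sv[kbest] + sv[kbest + 1]) / 2)
})

test_that("distance zones: arithmetic, partition and annulus areas", {
  sec <- matrix(FALSE, 81, 81)
  for (i in 1:81) for (j in 1:81)
    if ((i - 41)^2 + (j - 41)^2 <= 38^2) sec[i, j] <- TRUE
  z <- distance_zones(sec, zone_width_um = 10, pixel_size_um = 1)
  # boundary pixels are zone 0; 5 um depth -> zone 0; 15 um -> zone 1
  expect_equal(z[41, 41 + 38], 0L)
  expect_equal(z[41, 41 + 33], 0L)   # ~5 um deep
  expect_equal(z[41, 41 + 23], 1L)   # ~15 um deep
  # the zone raster partitions the section: no unlabeled section pixels
  expect_true(all(z[sec] >= 0))
  expect_true(all(z[!sec] == -1L))
  # zone areas decrease toward the center (annulus-area oracle)
  areas <- table(z[z >= 0])
  expect_true(all(diff(as.numeric(areas)) < 0))
})

test_that("zonal_profile aggregates fractions with conservation", {
  sec <- matrix(FALSE, 61, 61)
  for (i in 1:61) for (j in 1:61)
    if ((i - 31)^2 + (j - 31)^2 <= 28^2) sec[i, j] <- TRUE
  z <- distance_zones(sec, 10, 1)
  # marker == section -> fraction 1 in every zone
  p1 <- zonal_profile(list(m = sec), z)
  expect_true(all(p1$m_fraction == 1))
  # empty marker -> all zero
  p0 <- zonal_profile(list(m = sec & FALSE), z)
  expect_true(all(p0$m_fraction == 0))
  # pixel counts sum to the section area exactly
  expect_equal(sum(p1$pixels), sum(sec))
  # positive-pixel conservation across zones
  set.seed(21)
  mk <- sec & matrix(runif(61 * 61) > 0.5, 61, 61)
  pr <- zonal_profile(list(m = mk), z)
  expect_equal(sum(pr$pixels * pr$m_fraction), sum(mk))
})

test_that("align_sections recovers translations by phase correlation", {
  sec <- matrix(FALSE, 90, 90)
  for (i in 1:90) for (j in 1:90)
    if ((i - 40)^2 + (j - 45)^2 <= 625) sec[i, j] <- TRUE
  # identity on itself
  self <- align_sections(sec, sec)
  expect_equal(c(self$dy, self$dx), c(0L, 0L))
  # known 20-px shift recovered within 1 px
  moved <- hypoxiq:::shift_matrix(sec, 20, -8)
  al <- align_sections(sec, moved)
  expect_equal(al$dy, -20L)
  expect_equal(al$dx, 8L)
  # applying the transform undoes the shift (composition ~ identity)
  expect_equal(al$registered, sec)
  # degenerate input falls back to identity with a warning
  expect_warning(align_sections(sec & FALSE, sec & FALSE), "peak")
})

test_that("full section closed loop: onset zone, rim confinement", {
  cfg <- sim_config(seed = 22, pixel_size_um = 1.3)
  gen <- generate_section_image(150, 60, 40, cfg)
  prof <- section_pipeline(gen$pimo, gen$brdu, 1.3)
  first_hyp <- min(prof$zone[prof$pimonidazole_fraction > 0.5])
  expect_true(abs(first_hyp - 6) <= 1)
  expect_true(all(prof$brdu_fraction[prof$zone > 6] < 0.1))
  # anti-correlation when proliferation_depth < hypoxia_onset
  expect_lt(cor(prof$pimonidazole_fraction, prof$brdu_fraction), 0)
})
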