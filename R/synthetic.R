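#' Synthetic-data generators with known ground truth
#'
#' Every input the pipeline consumes can be generated here with planted
#' ground truth, emulating the statistical and geometric structure the
#' analyses assume: Poisson colony counts under a linear-quadratic
#' dose-response, two-channel nuclear images with punctate foci, FUCCI
#' red/green traces with phase structure and a non-cycling subpopulation,
#' CDK2-reporter images with a known cytoplasm/nucleus ratio, AEC/
#' hematoxylin section images with a hypoxic core and a proliferative rim,
#' and spherical two-channel FUCCI stacks with a proliferation gradient.
#' All generators are byte-deterministic given the `sim_config` seed, and
#' every planted quantity is recoverable by the corresponding analysis
#' module (closed-loop tests).
#'
#' @name synthetic
NULL

#' Simulate colony-forming-assay counts
#'
#' Each well count is Poisson with mean
#' `seeded * plating_efficiency * exp(-alpha*D - beta*D^2)`.
#'
#' @param alpha,beta LQ parameters (>= 0; 1/Gy and 1/Gy^2).
#' @param doses Dose levels in Gy (must include 0).
#' @param seeded_per_well Cells seeded per well (default 250).
#' @param plating_efficiency Fraction in (0, 1].
#' @param replicates Technical replicates per dose (default 6).
#' @param cfg A [sim_config()].
#' @param condition Condition label carried in the table.
#' @return Plate table: `condition`, `dose_gy`, `replicate`, `seeded`,
#'   `colonies`; attribute `truth` carries the generating parameters.
#' @export
simulate_cfa_counts <- function(alpha, beta, doses,
                                seeded_per_well = 250,
                                plating_efficiency = 1,
                                replicates = 6,
                                cfg = sim_config(),
                                condition = "synthetic") {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (plating_efficiency < 0 || plating_efficiency > 1)
    stop("plating_efficiency must be in [0, 1]")
  if (!0 %in% doses) stop("doses must include 0 Gy")
  tab <- expand.grid(replicate = seq_len(replicates), dose_gy = doses)
  mu <- seeded_per_well * plating_efficiency *
    lq_sf(alpha, beta, tab$dose_gy)
  counts <- with_seed(derive_seed(cfg$seed, "cfa"), rpois(nrow(tab), mu))
  out <- data.frame(condition = condition, dose_gy = tab$dose_gy,
                    replicate = tab$replicate, seeded = seeded_per_well,
                    colonies = counts)
  attr(out, "truth") <- list(alpha = alpha, beta = beta,
                             plating_efficiency = plating_efficiency)
  out[order(out$dose_gy, out$replicate), ]
}

# Jittered-grid placement of n centers with guaranteed minimum separation.
place_centers <- function(n, pitch_px, jitter_px, margin_px) {
  side <- ceiling(sqrt(n))
  coords <- expand.grid(gy = seq_len(side), gx = seq_len(side))
  coords <- coords[seq_len(n), ]
  cy <- margin_px + (coords$gy - 0.5) * pitch_px +
    runif(n, -jitter_px, jitter_px)
  cx <- margin_px + (coords$gx - 0.5) * pitch_px +
    runif(n, -jitter_px, jitter_px)
  size <- ceiling(2 * margin_px + side * pitch_px)
  list(cy = cy, cx = cx, size = size)
}

# Paint a filled disk (1-based center) into img.
draw_disk <- function(img, cy, cx, r_px, value, mode = c("set", "add")) {
  mode <- match.arg(mode)
  r <- ceiling(r_px)
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r_px^2
  if (mode == "set") img[ys, xs][sub] <- value
  else img[ys, xs][sub] <- img[ys, xs][sub] + value
  img
}

# Paint a 2D Gaussian spot.
draw_spot <- function(img, cy, cx, sigma_px, amplitude) {
  r <- ceiling(4 * sigma_px)
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  g <- exp(-outer((ys - cy)^2, (xs - cx)^2, `+`) / (2 * sigma_px^2))
  img[ys, xs] <- img[ys, xs] + amplitude * g
  img
}

#' Generate a two-channel nuclear/foci image
#'
#' Channel `dapi`: non-overlapping elliptical-ish nuclei (disks with
#' per-nucleus intensity variation) on a dim background; channel `foci`:
#' Gaussian puncta planted inside the nuclei. In `well_separated` mode the
#' puncta of one nucleus keep a mutual distance of at least two focus
#' diameters (the regime where exact count recovery is expected).
#'
#' @param n_nuclei Number of nuclei.
#' @param foci_mean Poisson mean focus count per nucleus, or a vector of
#'   exact per-nucleus counts.
#' @param cfg A [sim_config()].
#' @param nucleus_radius_um,focus_sigma_um Geometry (defaults 10 and 0.375 um;
#'   a focus "diameter" is taken as 4 sigma, i.e. 1.5 um by default,
#'   matching the default merge distance of [count_foci()]).
#' @param well_separated Keep puncta >= 2 focus diameters apart
#'   (default TRUE).
#' @param noise_sd Additive Gaussian readout noise (default 2).
#' @param max_tries Retry bound for the separation sampler.
#' @return A [labeled_image()] with channels `dapi`, `foci`, the planted
#'   label mask, and attribute `truth` (per-nucleus centers and focus
#'   counts, plus per-focus coordinates).
#' @export
generate_foci_image <- function(n_nuclei, foci_mean = 10, cfg = sim_config(),
                                nucleus_radius_um = 10, focus_sigma_um = 0.375,
                                well_separated = TRUE, noise_sd = 2,
                                max_tries = 5000) {
  px <- cfg$pixel_size_um
  r_px <- nucleus_radius_um / px
  with_seed(derive_seed(cfg$seed, "foci_image"), {
    pitch <- 2 * r_px + 8 / px
    pl <- place_centers(n_nuclei, pitch, jitter_px = 2 / px,
                        margin_px = r_px + 4 / px)
    counts <- if (length(foci_mean) == n_nuclei) as.integer(foci_mean)
              else rpois(n_nuclei, foci_mean)
    dapi <- matrix(10, pl$size, pl$size)
    fch <- matrix(5, pl$size, pl$size)
    labels <- matrix(0L, pl$size, pl$size)
    focus_rows <- list()
    min_sep_px <- if (well_separated) 2 * (4 * focus_sigma_um) / px else 0
    for (k in seq_len(n_nuclei)) {
      amp <- runif(1, 90, 110)
      dapi <- draw_disk(dapi, pl$cy[k], pl$cx[k], r_px, amp)
      labels <- draw_disk(labels, pl$cy[k], pl$cx[k], r_px, k)
      if (counts[k] == 0) next
      # rejection-sample focus positions inside the nucleus; a jammed
      # configuration is restarted from scratch a bounded number of times
      placed <- NULL
      for (restart in seq_len(25)) {
        placed <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(placed) < counts[k] && tries <= max_tries) {
          tries <- tries + 1
          a <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * (r_px - 3 * focus_sigma_um / px - 1)
          p <- c(pl$cy[k] + rad * sin(a), pl$cx[k] + rad * cos(a))
          if (nrow(placed) > 0 && min_sep_px > 0 &&
              min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) <
                min_sep_px^2) next
          placed <- rbind(placed, p)
        }
        if (nrow(placed) == counts[k]) break
      }
      if (nrow(placed) < counts[k])
        stop("focus density too high for the separation constraint")
      for (i in seq_len(nrow(placed)))
        fch <- draw_spot(fch, placed[i, 1], placed[i, 2],
                         focus_sigma_um / px, 150)
      focus_rows[[length(focus_rows) + 1L]] <-
        data.frame(nucleus = k, row = placed[, 1] - 1, col = placed[, 2] - 1)
    }
    dapi <- dapi + matrix(rnorm(length(dapi), 0, noise_sd),
                          nrow(dapi), ncol(dapi))
    fch <- fch + matrix(rnorm(length(fch), 0, noise_sd / 2),
                        nrow(fch), ncol(fch))
    storage.mode(labels) <- "integer"
    img <- labeled_image(list(dapi = dapi, foci = fch), labels,
                         pixel_size_um = px)
    attr(img, "truth") <- list(
      nuclei = data.frame(nucleus = seq_len(n_nuclei),
                          row = pl$cy - 1, col = pl$cx - 1,
                          radius_um = nucleus_radius_um, count = counts),
      foci = if (length(focus_rows)) do.call(rbind, focus_rows) else
        data.frame(nucleus = integer(), row = numeric(), col = numeric()))
    img
  })
}

#' Generate FUCCI time-lapse traces
#'
#' Per-cell red/green intensities follow the FUCCI succession (colorless
#' early G1, red G1, red+green S, green G2/M) with multiplicative log-normal
#' intensity noise. Phase durations are gamma-distributed around the given
#' means (CV `duration_cv`) and quantized to the frame grid; the mitosis
#' flag is set on the final G2 frame (the metaphase). A `noncycling_fraction`
#' of cells is non-cycling: "stall" cells remain in a uniformly chosen phase
#' until the movie end; "slip" cells run to G2 and then switch green-to-red
#' at a uniform random G2 frame without a mitosis.
#'
#' @param n_cells Number of traces.
#' @param phase_means_h Named vector `earlyG1`, `G1`, `S`, `G2` (hours);
#'   default `c(2, 8, 7, 3)`.
#' @param noncycling_fraction Fraction in [0, 1] (default 0).
#' @param cfg A [sim_config()] (frame interval from
#'   `cfg$frame_interval_h`).
#' @param movie_h Movie length (default 120 h).
#' @param noise_cv Log-normal intensity CV (default 0.1).
#' @param duration_cv Gamma CV of phase durations (default 0.2).
#' @param noncycling_mode `"both"` (default, 50/50), `"stall"` or `"slip"`.
#' @param low,high Mean intensities of the "low" and "high" reporter states.
#' @return Trace table (`cell_id`, `t_h`, `red`, `green`, `mitosis`) with
#'   attribute `truth`: per-cell planted status and quantized durations.
#' @export
generate_fucci_traces <- function(n_cells,
                                  phase_means_h = c(earlyG1 = 2, G1 = 8,
                                                    S = 7, G2 = 3),
                                  noncycling_fraction = 0,
                                  cfg = sim_config(), movie_h = 120,
                                  noise_cv = 0.1, duration_cv = 0.2,
                                  noncycling_mode = c("both", "stall",
                                                      "slip"),
                                  low = 10, high = 100) {
  noncycling_mode <- match.arg(noncycling_mode)
  if (any(phase_means_h <= 0)) stop("phase means must be > 0")
  if (noncycling_fraction < 0 || noncycling_fraction > 1)
    stop("noncycling_fraction must be in [0, 1]")
  dt <- cfg$frame_interval_h
  if (dt > min(phase_means_h))
    warning("frame interval exceeds the shortest phase: durations quantized")
  n_frames <- floor(movie_h / dt) + 1L
  phase_names <- c("earlyG1", "G1", "S", "G2")
  phase_means_h <- unlist(phase_means_h)
  means <- if (is.null(names(phase_means_h))) {
    if (length(phase_means_h) != 4) stop("need 4 phase means")
    setNames(phase_means_h, phase_names)
  } else phase_means_h[phase_names]
  if (any(is.na(means))) stop("phase means must be named earlyG1/G1/S/G2")
  # per-phase mean red/green intensity
  ch_mean <- rbind(earlyG1 = c(low, low), G1 = c(high, low),
                   S = c(high, high), G2 = c(low, high))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(derive_seed(cfg$seed, "fucci_traces"), {
    n_nc <- rbinom(1, n_cells, noncycling_fraction)
    status <- c(rep("noncycling", n_nc), rep("cycling", n_cells - n_nc))
    mode_of <- function(i) switch(noncycling_mode,
                                  both = if (i %% 2 == 0) "stall" else "slip",
                                  noncycling_mode)
    rows <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      shape <- 1 / duration_cv^2
      dur <- rgamma(4, shape = shape, scale = means * duration_cv^2)
      frames <- pmax(1L, as.integer(round(dur / dt)))
      if (status[i] == "cycling") {
        states <- rep(phase_names, frames)
        nf <- length(states)
        if (nf > n_frames) { # does not fit: censor at movie end
          states <- states[seq_len(n_frames)]
          mit <- rep(FALSE, n_frames)
          st_true <- "censored"
          frames_out <- NA
        } else {
          mit <- rep(FALSE, nf)
          mit[nf] <- TRUE   # metaphase on the final G2 frame
          st_true <- "cycling"
          frames_out <- frames
        }
      } else if (mode_of(i) == "stall") {
        k <- sample.int(4, 1)
        pre <- if (k > 1) rep(phase_names[seq_len(k - 1)],
                              frames[seq_len(k - 1)]) else character(0)
        states <- c(pre, rep(phase_names[k], max(0, n_frames - length(pre))))
        states <- states[seq_len(n_frames)]
        mit <- rep(FALSE, n_frames)
        st_true <- "noncycling_stall"
        frames_out <- NA
      } else { # slip
        g2_len <- max(2L, frames[4])
        pre <- rep(phase_names, c(frames[1:3], g2_len))
        slip_at <- length(pre) - g2_len + sample.int(g2_len - 1L, 1)
        states <- c(pre[seq_len(slip_at)],
                    rep("G1", max(0, n_frames - slip_at)))
        states <- states[seq_len(n_frames)]
        mit <- rep(FALSE, length(states))
        st_true <- "noncycling_slip"
        frames_out <- NA
      }
      nf <- length(states)
      mu <- ch_mean[states, , drop = FALSE]
      red <- mu[, 1] * rlnorm(nf, -sdlog^2 / 2, sdlog)
      green <- mu[, 2] * rlnorm(nf, -sdlog^2 / 2, sdlog)
      rows[[i]] <- data.frame(cell_id = i, t_h = (seq_len(nf) - 1) * dt,
                              red = red, green = green, mitosis = mit)
      truth[[i]] <- data.frame(
        cell_id = i, status = st_true,
        earlyG1_h = if (st_true == "cycling") frames_out[1] * dt else NA,
        G1_h = if (st_true == "cycling") frames_out[2] * dt else NA,
        S_h = if (st_true == "cycling") frames_out[3] * dt else NA,
        G2_h = if (st_true == "cycling") frames_out[4] * dt else NA,
        total_h = if (st_true == "cycling") sum(frames_out) * dt else NA)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Generate a CDK2-reporter image pair
#'
#' Nuclear-stain channel plus a reporter channel in which the cytoplasmic
#' ring intensity is `ratio` times the nuclear intensity, over a constant
#' background (which the rolling-ball step removes).
#'
#' @param ratio Planted cytoplasm/nucleus ratio, scalar or per-cell vector.
#' @param n_cells Number of cells.
#' @param cfg A [sim_config()].
#' @param nucleus_radius_um,ring_width_um Geometry (defaults 7 and 1.5 um).
#' @param nuclear_intensity Mean nuclear reporter level (default 100).
#' @param background Constant background (default 8).
#' @param noise_sd Additive noise (default 1).
#' @return A [labeled_image()] with channels `nuclei`, `reporter`, planted
#'   labels, and attribute `truth` (per-cell planted ratio).
#' @export
generate_reporter_image <- function(ratio, n_cells, cfg = sim_config(),
                                    nucleus_radius_um = 7,
                                    ring_width_um = 1.5,
                                    nuclear_intensity = 100,
                                    background = 8, noise_sd = 1) {
  if (any(ratio < 0)) stop("ratio must be >= 0")
  ratios <- rep_len(ratio, n_cells)
  px <- cfg$pixel_size_um
  r_px <- nucleus_radius_um / px
  ring_px <- ring_width_um / px
  with_seed(derive_seed(cfg$seed, "reporter_image"), {
    pitch <- 2 * (r_px + ring_px) + 8 / px
    pl <- place_centers(n_cells, pitch, jitter_px = 2 / px,
                        margin_px = r_px + ring_px + 4 / px)
    nuc <- matrix(10, pl$size, pl$size)
    rep_ch <- matrix(background, pl$size, pl$size)
    labels <- matrix(0L, pl$size, pl$size)
    for (k in seq_len(n_cells)) {
      nuc <- draw_disk(nuc, pl$cy[k], pl$cx[k], r_px, 100)
      labels <- draw_disk(labels, pl$cy[k], pl$cx[k], r_px, k)
      # ring first, then nucleus on top
      rep_ch <- draw_disk(rep_ch, pl$cy[k], pl$cx[k], r_px + ring_px + 1,
                          background + nuclear_intensity * ratios[k])
      rep_ch <- draw_disk(rep_ch, pl$cy[k], pl$cx[k], r_px,
                          background + nuclear_intensity)
    }
    nuc <- nuc + matrix(rnorm(length(nuc), 0, noise_sd), nrow(nuc))
    rep_ch <- rep_ch + matrix(rnorm(length(rep_ch), 0, noise_sd),
                              nrow(rep_ch))
    storage.mode(labels) <- "integer"
    img <- labeled_image(list(nuclei = nuc, reporter = rep_ch), labels, px)
    attr(img, "truth") <- data.frame(cell = seq_len(n_cells),
                                     row = pl$cy - 1, col = pl$cx - 1,
                                     ratio = ratios)
    img
  })
}

#' Generate a stained cross-section image pair
#'
#' A circular spheroid section with an AEC-positive hypoxic core
#' (pimonidazole beyond `hypoxia_onset_um` from the edge) and BrdU-positive
#' nuclei within `proliferation_depth_um` of the rim, composited with a
#' hematoxylin counterstain using the same stain-vector matrix the
#' deconvolution inverts (so unmix-after-mix is exact on noiseless output).
#'
#' @param radius_um Section radius.
#' @param hypoxia_onset_um Depth at which pimonidazole becomes positive
#'   (must be < radius).
#' @param proliferation_depth_um BrdU-positive nuclei live within this depth
#'   of the rim (0 = none).
#' @param cfg A [sim_config()].
#' @param noise_sd Additive RGB noise post-mixing (default 0: noiseless,
#'   float RGB, exactly invertible).
#' @param brdu_nucleus_um,brdu_density Nucleus radius and per-um^2 rate of
#'   BrdU-positive nuclei in the rim.
#' @return List with RGB arrays `pimo`, `brdu` (0-255 float scale), and
#'   `truth` (logical masks `section`, `hypoxia`, `brdu`; the parameters).
#' @export
generate_section_image <- function(radius_um, hypoxia_onset_um,
                                   proliferation_depth_um,
                                   cfg = sim_config(), noise_sd = 0,
                                   brdu_nucleus_um = 3,
                                   brdu_density = 0.01) {
  if (hypoxia_onset_um >= radius_um)
    stop("hypoxia_onset_um must be < radius_um")
  px <- cfg$pixel_size_um
  r_px <- radius_um / px
  size <- ceiling(2 * r_px + 8)
  ctr <- (size + 1) / 2
  dist_c <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2,
                       `+`)) * px
  section <- dist_c <= radius_um
  depth <- pmax(radius_um - dist_c, 0)
  hypoxic <- section & depth >= hypoxia_onset_um
  stains <- stain_matrix_haec()
  mix <- function(cH, cAEC) {
    conc <- cbind(as.vector(cH), as.vector(cAEC), 0)
    od <- conc %*% t(stains)
    arr <- array(0, c(size, size, 3))
    for (k in 1:3) arr[, , k] <- matrix(od_to_rgb(od[, k]), size, size)
    arr
  }
  with_seed(derive_seed(cfg$seed, "section_image"), {
    cH <- ifelse(section, 0.5, 0)
    # pimonidazole image: AEC in the hypoxic core, faint elsewhere in tissue
    cA_pimo <- ifelse(hypoxic, 0.8, ifelse(section, 0.02, 0))
    # BrdU image: AEC-positive nuclei within the proliferative rim
    brdu_mask <- matrix(FALSE, size, size)
    rim <- section & depth <= proliferation_depth_um
    if (proliferation_depth_um > 0 && any(rim)) {
      n_pos <- rpois(1, sum(rim) * px^2 * brdu_density)
      if (n_pos > 0) {
        idx <- sample(which(rim), min(n_pos, sum(rim)))
        nr_px <- brdu_nucleus_um / px
        for (ii in idx) {
          cy <- (ii - 1) %% size + 1
          cx <- (ii - 1) %/% size + 1
          brdu_mask <- draw_disk(brdu_mask, cy, cx, nr_px, TRUE)
        }
        brdu_mask <- brdu_mask & section
      }
    }
    cA_brdu <- ifelse(brdu_mask, 0.9, ifelse(section, 0.02, 0))
    pimo <- mix(cH, cA_pimo)
    brdu <- mix(cH, cA_brdu)
    if (noise_sd > 0) {
      pimo <- pimo + array(rnorm(length(pimo), 0, noise_sd), dim(pimo))
      brdu <- brdu + array(rnorm(length(brdu), 0, noise_sd), dim(brdu))
      pimo <- pmin(pmax(pimo, 0), 255)
      brdu <- pmin(pmax(brdu, 0), 255)
    }
    list(pimo = pimo, brdu = brdu,
         truth = list(section = section, hypoxia = hypoxic,
                      brdu = brdu_mask, radius_um = radius_um,
                      hypoxia_onset_um = hypoxia_onset_um,
                      proliferation_depth_um = proliferation_depth_um,
                      pixel_size_um = px))
  })
}

#' Generate a two-channel 3D FUCCI spheroid stack
#'
#' Nuclei are packed inside a sphere on a per-slice jittered grid (so every
#' nucleus lies on an imaged plane and same-slice nuclei stay resolvable);
#' each nucleus is rendered as an additive Gaussian blob in both channels.
#' Cells within `green_rim_depth_um` of the spherical surface are
#' green-dominant, deeper cells red-dominant. The truth records every
#' nucleus's exact 3D distance to the surface and its class.
#'
#' @param radius_um Sphere radius R.
#' @param green_rim_depth_um Proliferative (green) rim depth.
#' @param z_step_um Slice spacing (default 10 um).
#' @param cfg A [sim_config()].
#' @param nucleus_sigma_um Gaussian radius of a rendered nucleus
#'   (default 2.5 um, i.e. a ~5 um-radius blob).
#' @param pitch_um In-plane packing pitch (default 11 um).
#' @param jitter_um Uniform jitter of each grid position (default 1.5 um).
#' @param high,low Dominant/recessive channel peak intensities.
#' @param noise_sd Additive noise (default 1).
#' @return A [spheroid_stack()] with attribute `truth`: per-nucleus
#'   position, slice, exact surface distance and class.
#' @export
generate_spheroid_stack <- function(radius_um, green_rim_depth_um,
                                    z_step_um = 10, cfg = sim_config(),
                                    nucleus_sigma_um = 2.5, pitch_um = 11,
                                    jitter_um = 1.5,
                                    high = 100, low = 10, noise_sd = 1) {
  if (z_step_um <= 0) stop("z_step_um must be > 0")
  if (radius_um < 3 * z_step_um) stop("radius too small for the z sampling")
  px <- cfg$pixel_size_um
  z_um <- seq(0, 2 * radius_um, by = z_step_um)
  zc <- radius_um
  size <- ceiling(2 * radius_um / px + 8)
  ctr <- (size + 1) / 2
  sig_px <- nucleus_sigma_um / px
  with_seed(derive_seed(cfg$seed, "spheroid_stack"), {
    cells <- list()
    for (s in seq_along(z_um)) {
      dz <- z_um[s] - zc
      r_z2 <- radius_um^2 - dz^2
      if (r_z2 <= (2 * nucleus_sigma_um)^2) next
      r_eff <- sqrt(r_z2) - 2 * nucleus_sigma_um
      gpts <- expand.grid(x = seq(-radius_um, radius_um, by = pitch_um),
                          y = seq(-radius_um, radius_um, by = pitch_um))
      gpts$x <- gpts$x + runif(nrow(gpts), -jitter_um, jitter_um)
      gpts$y <- gpts$y + runif(nrow(gpts), -jitter_um, jitter_um)
      keep <- gpts$x^2 + gpts$y^2 <= r_eff^2
      if (!any(keep)) next
      cells[[length(cells) + 1L]] <-
        data.frame(x_um = gpts$x[keep], y_um = gpts$y[keep],
                   z_um = z_um[s] - zc, slice = s)
    }
    cells <- do.call(rbind, cells)
    d_surf <- radius_um -
      sqrt(cells$x_um^2 + cells$y_um^2 + cells$z_um^2)
    cls <- ifelse(d_surf <= green_rim_depth_um, "green", "red")
    g <- array(0, c(size, size, length(z_um)))
    r <- array(0, c(size, size, length(z_um)))
    amp <- runif(nrow(cells), 0.9, 1.1)
    for (s in unique(cells$slice)) {
      gs <- g[, , s]
      rs <- r[, , s]
      for (i in which(cells$slice == s)) {
        cy <- ctr + cells$y_um[i] / px
        cx <- ctr + cells$x_um[i] / px
        ga <- if (cls[i] == "green") high else low
        ra <- if (cls[i] == "green") low else high
        gs <- draw_spot(gs, cy, cx, sig_px, ga * amp[i])
        rs <- draw_spot(rs, cy, cx, sig_px, ra * amp[i])
      }
      g[, , s] <- gs
      r[, , s] <- rs
    }
    if (noise_sd > 0) {
      g <- g + array(abs(rnorm(length(g), 0, noise_sd)), dim(g))
      r <- r + array(abs(rnorm(length(r), 0, noise_sd)), dim(r))
    }
    st <- spheroid_stack(g, r, z_um, px)
    attr(st, "truth") <- list(
      cells = data.frame(x_um = cells$x_um, y_um = cells$y_um,
                         z_um = cells$z_um, slice = cells$slice,
                         d_surface_um = d_surf, class = cls),
      R_um = radius_um, zc_um = zc,
      green_rim_depth_um = green_rim_depth_um)
    st
  })
}
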