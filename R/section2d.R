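#' Zonal analysis of stained spheroid cross-sections
#'
#' IHC cross-sections of multicellular spheroids (AEC chromogen on a
#' hematoxylin counterstain) are analyzed by: automatic outlining of the
#' section rim, H-AEC color deconvolution in optical-density (OD) space,
#' a k-means threshold of the pimonidazole (hypoxia) signal, concentric
#' 10 um distance zones from the section edge, and per-zone positive-pixel
#' fractions for the hypoxia (pimonidazole) and proliferation (BrdU)
#' markers.
#'
#' @name section2d
NULL

#' Default H-AEC stain matrix
#'
#' Columns are the unit optical-density vectors (R, G, B) for hematoxylin
#' and AEC in the Ruifrok-Johnston convention, with a third residual vector
#' (normalized cross product) completing the basis.
#'
#' @return 3x3 matrix with unit-norm columns `H`, `AEC`, `residual`.
#' @export
stain_matrix_haec <- function() {
  h <- c(0.650, 0.704, 0.286)
  aec <- c(0.2743, 0.6796, 0.6803)
  h <- h / sqrt(sum(h^2))
  aec <- aec / sqrt(sum(aec^2))
  res <- c(h[2] * aec[3] - h[3] * aec[2],
           h[3] * aec[1] - h[1] * aec[3],
           h[1] * aec[2] - h[2] * aec[1])
  res <- res / sqrt(sum(res^2))
  m <- cbind(H = h, AEC = aec, residual = res)
  rownames(m) <- c("R", "G", "B")
  m
}

rgb_to_od <- function(rgb) -log((rgb + 1) / 256)
od_to_rgb <- function(od) 256 * exp(-od) - 1

#' Outline a stained section
#'
#' Total optical density (summed over RGB) is smoothed and thresholded, the
#' largest connected component kept and its holes filled. The threshold is
#' the lesser of the Otsu value and a fixed tissue floor (default 0.15
#' summed OD): on strongly stained sections the histogram is trimodal
#' (background / counterstained tissue / chromogen) and plain Otsu would
#' latch onto the stain contrast instead of the tissue edge. Tissue must be
#' darker than the background.
#'
#' @param rgb h x w x 3 array, 0-255 scale.
#' @param smooth_sigma_px Gaussian sigma in pixels (default 2).
#' @param od_floor Fixed tissue-detection OD threshold cap (default 0.15).
#' @return Logical section mask (single connected component).
#' @export
outline_section <- function(rgb, smooth_sigma_px = 2, od_floor = 0.15) {
  od <- rgb_to_od(rgb)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  if (diff(range(tot)) == 0) stop("blank image: no section found")
  sm <- gaussian_blur(tot, smooth_sigma_px)
  t0 <- min(threshold_otsu(sm), od_floor)
  tent <- sm > t0
  if (!any(tent)) stop("empty section mask")
  # second pass: half the typical tissue OD trims the blur halo
  thr <- max(t0, median(sm[tent]) / 2)
  mask <- sm > thr
  if (!any(mask)) stop("empty section mask")
  fill_holes(largest_component(mask))
}

#' H-AEC color deconvolution
#'
#' Beer-Lambert unmixing: per-pixel OD vector `o = -log((I+1)/256)` is
#' solved against the stain matrix, giving per-stain OD rasters clipped
#' at 0.
#'
#' @param rgb h x w x 3 array, 0-255 scale.
#' @param stains 3x3 stain matrix (default [stain_matrix_haec()]).
#' @return List of matrices `H`, `AEC`, `residual`.
#' @export
deconvolve_haec <- function(rgb, stains = stain_matrix_haec()) {
  if (abs(det(stains)) < 1e-12) stop("singular stain matrix")
  inv <- solve(stains)
  d <- dim(rgb)
  od <- matrix(rgb_to_od(as.vector(rgb)), d[1] * d[2], 3)
  conc <- od %*% t(inv)
  conc[conc < 0] <- 0
  setNames(lapply(1:3, function(k) matrix(conc[, k], d[1], d[2])),
           colnames(stains))
}

# Exact 1D 2-means: optimal contiguous split of the sorted values
# minimizing within-class sum of squares. Returns the split threshold
# (midpoint) or NA for constant input. Deterministic, no RNG.
kmeans2_threshold <- function(values) {
  v <- sort(values)
  n <- length(v)
  if (n < 2 || v[1] == v[n]) return(NA_real_)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ss_lo + ss_hi)
  (v[best] + v[best + 1]) / 2
}

#' Hypoxia mask by k-means thresholding
#'
#' Two-cluster k-means on the AEC OD values inside the section; the cluster
#' with the higher mean OD is positive. For 1D data the global optimum is a
#' contiguous split of the sorted values, computed exactly (deterministic,
#' no seeds needed). A 2-means split always exists even on marker-free
#' sections, so the positive class is only accepted when the two cluster
#' means differ by at least `min_contrast` OD (chromogen deposits are far
#' above that); otherwise the mask is empty.
#'
#' @param aec_od AEC OD matrix from [deconvolve_haec()].
#' @param section_mask Logical section mask.
#' @param min_contrast Minimum between-cluster mean OD difference
#'   (default 0.1).
#' @return Logical positive mask (within the section).
#' @export
hypoxia_mask <- function(aec_od, section_mask, min_contrast = 0.1) {
  if (!any(section_mask)) stop("section mask is empty")
  v <- aec_od[section_mask]
  thr <- kmeans2_threshold(v)
  if (is.na(thr)) {
    warning("constant OD inside section: empty mask")
    return(section_mask & FALSE)
  }
  if (mean(v[v > thr]) - mean(v[v <= thr]) < min_contrast) {
    warning("no marker-level OD contrast inside section: empty mask")
    return(section_mask & FALSE)
  }
  aec_od > thr & section_mask
}

#' Concentric distance zones from the section edge
#'
#' Euclidean distance transform from the boundary inward; a boundary pixel
#' has depth 0 and zone index `floor(depth_um / zone_width_um)`.
#'
#' @param section_mask Logical mask.
#' @param zone_width_um Zone thickness (default 10 um).
#' @param pixel_size_um Micrometers per pixel.
#' @return Integer matrix of zone indices (-1 outside the section).
#' @export
distance_zones <- function(section_mask, zone_width_um = 10, pixel_size_um) {
  if (!any(section_mask)) stop("section mask is empty")
  depth_um <- (edt_px(section_mask) - 1) * pixel_size_um
  z <- matrix(-1L, nrow(section_mask), ncol(section_mask))
  z[section_mask] <- as.integer(floor(pmax(depth_um[section_mask], 0) /
                                        zone_width_um))
  z
}

#' Per-zone marker profile
#'
#' @param markers Named list of logical positive masks (aligned with the
#'   zone raster).
#' @param zones Zone index matrix from [distance_zones()].
#' @param od Optional named list of OD rasters for per-zone mean intensity.
#' @param zone_width_um Zone thickness used (for the distance columns).
#' @return data.frame, one row per zone: `zone`, `inner_um`, `outer_um`,
#'   `pixels`, `<marker>_fraction` and optionally `<marker>_mean_od`.
#' @export
zonal_profile <- function(markers, zones, od = NULL, zone_width_um = 10) {
  zmax <- max(zones)
  zi <- 0:zmax
  inside <- zones >= 0
  pixels <- vapply(zi, function(z) sum(zones == z), 1L)
  out <- data.frame(zone = zi,
                    inner_um = zi * zone_width_um,
                    outer_um = (zi + 1) * zone_width_um,
                    pixels = pixels)
  for (nm in names(markers)) {
    pos <- markers[[nm]] & inside
    frac <- vapply(zi, function(z) {
      n <- pixels[z + 1]
      if (n == 0) NA_real_ else sum(pos[zones == z]) / n
    }, 1.0)
    out[[paste0(nm, "_fraction")]] <- frac
  }
  for (nm in names(od)) {
    mo <- vapply(zi, function(z) {
      n <- pixels[z + 1]
      if (n == 0) NA_real_ else mean(od[[nm]][zones == z])
    }, 1.0)
    out[[paste0(nm, "_mean_od")]] <- mo
  }
  out
}

#' Align two section images by phase correlation
#'
#' Whole-pixel translation between the two section masks via the phase
#' correlation peak. If the normalized peak is below `min_peak` the identity
#' transform is returned with a warning.
#'
#' @param fixed,moving Logical section masks (same size).
#' @param min_peak Minimum normalized correlation peak (default 0.03).
#' @return List with `dy`, `dx` (shift applied to `moving` to match
#'   `fixed`), `peak`, and `registered` (the shifted moving mask).
#' @export
align_sections <- function(fixed, moving, min_peak = 0.03) {
  a <- fixed * 1.0
  b <- moving * 1.0
  Fa <- fft(a)
  Fb <- fft(b)
  cross <- Fa * Conj(Fb)
  denom <- Mod(cross)
  denom[denom == 0] <- 1
  r <- Re(fft(cross / denom, inverse = TRUE)) / length(a)
  pk <- which.max(r)
  peak <- max(r)
  nr <- nrow(a)
  dy <- (pk - 1) %% nr
  dx <- (pk - 1) %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  if (peak < min_peak) {
    warning("correlation peak below threshold: returning identity")
    dy <- 0L; dx <- 0L
  }
  list(dy = as.integer(dy), dx = as.integer(dx), peak = peak,
       registered = shift_matrix(moving, as.integer(dy), as.integer(dx)))
}

# Integer-shift a matrix, filling vacated pixels with `fill`.
shift_matrix <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Full cross-section pipeline
#'
#' Outlines both sections, aligns the moving (BrdU) image to the fixed
#' (pimonidazole) image, deconvolves both, thresholds both markers with the
#' exact 2-means rule, assigns 10 um distance zones and returns the zonal
#' profile (with the masks as attributes).
#'
#' @param pimo_rgb,brdu_rgb h x w x 3 arrays, 0-255 scale.
#' @param pixel_size_um Micrometers per pixel.
#' @param zone_width_um Zone thickness (default 10 um).
#' @param stains Stain matrix (default [stain_matrix_haec()]).
#' @return [zonal_profile()] data.frame with attributes `section_mask`,
#'   `hypoxia_mask`, `brdu_mask`, `shift`.
#' @export
section_pipeline <- function(pimo_rgb, brdu_rgb, pixel_size_um,
                             zone_width_um = 10,
                             stains = stain_matrix_haec()) {
  mask_p <- outline_section(pimo_rgb)
  mask_b <- outline_section(brdu_rgb)
  al <- align_sections(mask_p, mask_b)
  brdu_shifted <- array(0, dim(brdu_rgb))
  for (k in 1:3)
    brdu_shifted[, , k] <- shift_matrix(brdu_rgb[, , k], al$dy, al$dx,
                                        fill = 255)
  dec_p <- deconvolve_haec(pimo_rgb, stains)
  dec_b <- deconvolve_haec(brdu_shifted, stains)
  hyp <- hypoxia_mask(dec_p$AEC, mask_p)
  brdu <- hypoxia_mask(dec_b$AEC, mask_p)  # same 2-means rule, by symmetry
  zones <- distance_zones(mask_p, zone_width_um, pixel_size_um)
  prof <- zonal_profile(list(pimonidazole = hyp, brdu = brdu), zones,
                        od = list(pimonidazole = dec_p$AEC,
                                  brdu = dec_b$AEC),
                        zone_width_um = zone_width_um)
  attr(prof, "section_mask") <- mask_p
  attr(prof, "hypoxia_mask") <- hyp
  attr(prof, "brdu_mask") <- brdu
  attr(prof, "shift") <- al[c("dy", "dx", "peak")]
  prof
}
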