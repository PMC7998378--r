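#' 3D FUCCI spheroid analysis
#'
#' Two-channel (green = S/G2/M, red = G1/G0) 3D stacks of multicellular
#' spheroids are processed slice-wise: rolling-ball background subtraction
#' (100 um), red-normalization of the green channel, Huang outlining of each
#' section, nuclear segmentation per slice, a sphere fit to the per-slice
#' section radii, recalculation of each nucleus's 2D rim distance to its
#' shortest 3D distance to the spheroid surface, green/red classification at
#' normalized green g/(g+r) > 0.225, and 10 um radial histograms.
#'
#' @name spheroid3d
NULL

#' Spheroid stack container
#'
#' @param green,red 3D arrays (rows x cols x slices), same shape.
#' @param z_um Strictly increasing slice positions in micrometers
#'   (default 10 um steps).
#' @param pixel_size_um In-plane micrometers per pixel.
#' @return Object of class `spheroid_stack`.
#' @export
spheroid_stack <- function(green, red, z_um = NULL, pixel_size_um) {
  if (!all(dim(green) == dim(red))) stop("channel shapes differ")
  ns <- dim(green)[3]
  if (is.null(z_um)) z_um <- (seq_len(ns) - 1) * 10
  if (length(z_um) != ns || any(diff(z_um) <= 0))
    stop("z positions must be strictly increasing, one per slice")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(green = green, red = red, z_um = z_um,
                 pixel_size_um = pixel_size_um),
            class = "spheroid_stack")
}

#' Preprocess a spheroid stack
#'
#' Rolling-ball background subtraction (per slice, both channels), then the
#' green channel is scaled so that its mean over green-positive voxels
#' (global Otsu on the green stack) matches the red mean over red-positive
#' voxels, and the two channels are added into a combined stack.
#'
#' @param stack A [spheroid_stack()].
#' @param rollball_um Rolling-ball radius (default 100 um).
#' @return List with `green`, `red` (background-subtracted, green scaled),
#'   `combined`, `norm_factor`, `z_um`, `pixel_size_um`.
#' @export
preprocess_stack <- function(stack, rollball_um = 100) {
  r_px <- max(1L, floor(rollball_um / stack$pixel_size_um))
  ns <- dim(stack$green)[3]
  g <- stack$green
  r <- stack$red
  for (s in seq_len(ns)) {
    g[, , s] <- pmax(g[, , s] - gray_open_disk(g[, , s], r_px), 0)
    r[, , s] <- pmax(r[, , s] - gray_open_disk(r[, , s], r_px), 0)
  }
  thr_r <- threshold_otsu(r)
  thr_g <- threshold_otsu(g)
  pos_r <- if (is.na(thr_r)) numeric(0) else r[r > thr_r]
  pos_g <- if (is.na(thr_g)) numeric(0) else g[g > thr_g]
  if (length(pos_r) == 0 || length(pos_g) == 0 || mean(pos_g) == 0) {
    warning("empty positive set: normalization factor 1")
    f <- 1
  } else {
    f <- mean(pos_r) / mean(pos_g)
  }
  g <- g * f
  list(green = g, red = r, combined = g + r, norm_factor = f,
       z_um = stack$z_um, pixel_size_um = stack$pixel_size_um)
}

#' Outline one combined slice
#'
#' Median filter (5 um radius), Gaussian blur (5 um sigma), Huang threshold,
#' largest component, hole filling.
#'
#' @param slice Numeric matrix (combined channel).
#' @param pixel_size_um Micrometers per pixel.
#' @param filter_um Radius/sigma of the two filters (default 5 um).
#' @return Logical mask, or `NULL` if the slice is unusable (blank).
#' @export
slice_outline <- function(slice, pixel_size_um, filter_um = 5) {
  if (diff(range(slice)) == 0) return(NULL)
  r_px <- max(1L, as.integer(round(filter_um / pixel_size_um)))
  sm <- gaussian_blur(cpp_median_disk(slice, r_px), filter_um / pixel_size_um)
  thr <- threshold_huang(sm)
  if (is.na(thr)) return(NULL)
  mask <- sm > thr
  if (!any(mask)) return(NULL)
  fill_holes(largest_component(mask))
}

#' Segment nuclei in one slice and measure channel intensities
#'
#' Classic nuclear segmentation (see [segment_nuclei()]) restricted to the
#' section mask; per-label mean green and red from the preprocessed
#' channels. A CNN backend can be plugged via `backend`.
#'
#' @param combined_slice Combined-channel matrix.
#' @param green_slice,red_slice Preprocessed channel matrices.
#' @param mask Section mask from [slice_outline()].
#' @param pixel_size_um Micrometers per pixel.
#' @param backend Passed to [segment_nuclei()].
#' @param min_sep_um,min_area_um2,smooth_sigma_um Segmentation parameters.
#' @return data.frame (`label`, `row`, `col`, `g`, `r`) with 0-based
#'   centroids; attribute `labels` holds the label matrix.
#' @export
segment_slice_nuclei <- function(combined_slice, green_slice, red_slice,
                                 mask, pixel_size_um, backend = "classic",
                                 min_sep_um = 6, min_area_um2 = 30,
                                 smooth_sigma_um = 1,
                                 marker_source = "intensity") {
  img <- combined_slice
  img[!mask] <- 0
  labels <- segment_nuclei(img, pixel_size_um, backend = backend,
                           min_sep_um = min_sep_um,
                           min_area_um2 = min_area_um2,
                           smooth_sigma_um = smooth_sigma_um,
                           marker_source = marker_source)
  labels[!mask] <- 0L
  labels <- filter_relabel(labels, 1)
  st <- label_stats(labels)
  if (nrow(st) == 0) {
    out <- data.frame(label = integer(), row = numeric(), col = numeric(),
                      g = numeric(), r = numeric())
    attr(out, "labels") <- labels
    return(out)
  }
  g <- tapply(green_slice[labels > 0], labels[labels > 0], mean)
  r <- tapply(red_slice[labels > 0], labels[labels > 0], mean)
  out <- data.frame(label = st$label, row = st$row, col = st$col,
                    g = as.numeric(g), r = as.numeric(r))
  attr(out, "labels") <- labels
  out
}

#' Fit a sphere to per-slice section outlines
#'
#' Each usable slice contributes an equivalent section radius
#' `r_i = sqrt(area/pi)`; the sphere follows from the linear least-squares
#' fit of `r_i^2 + z_i^2 = (R^2 - z_c^2) + 2 z_c z_i`, exact on noiseless
#' circles.
#'
#' @param outlines List of section masks (or `NULL` for unusable slices).
#' @param z_um Slice positions (same length).
#' @param pixel_size_um Micrometers per pixel.
#' @return Object of class `sphere_geometry`: `R_um`, `zc_um`, per-slice
#'   `slice` table (`z_um`, `r_um`, centroid `row`/`col`), `rss`.
#' @export
fit_sphere <- function(outlines, z_um, pixel_size_um) {
  usable <- which(!vapply(outlines, is.null, TRUE))
  if (length(usable) < 3) stop("need >= 3 usable slices")
  z <- z_um[usable]
  r_um <- vapply(usable, function(s)
    sqrt(sum(outlines[[s]]) / pi) * pixel_size_um, 1.0)
  cent <- t(vapply(usable, function(s) {
    st <- which(outlines[[s]], arr.ind = TRUE) - 1L
    colMeans(st)
  }, c(row = 0, col = 0)))
  g <- fit_sphere_radii(r_um, z)
  g$slice <- data.frame(slice = usable, z_um = z, r_um = r_um,
                        row = cent[, "row"], col = cent[, "col"])
  g
}

#' Fit a sphere to per-slice section radii
#'
#' The algebraic core of [fit_sphere()]: exact on noiseless circle radii.
#'
#' @param r_um Per-slice section radii (micrometers).
#' @param z_um Slice positions (same length, not all equal).
#' @return A `sphere_geometry` (without the per-slice centroid table).
#' @export
fit_sphere_radii <- function(r_um, z_um) {
  if (length(unique(z_um)) < 2) stop("degenerate fit: all z equal")
  y <- r_um^2 + z_um^2
  fit <- lm(y ~ z_um)
  zc <- coef(fit)[["z_um"]] / 2
  R2 <- coef(fit)[["(Intercept)"]] + zc^2
  if (R2 <= 0) stop("sphere fit failed: non-positive radius")
  structure(list(R_um = sqrt(R2), zc_um = zc, slice = NULL,
                 rss = sum(residuals(fit)^2)),
            class = "sphere_geometry")
}

#' @export
print.sphere_geometry <- function(x, ...) {
  ns <- if (is.null(x$slice)) NA_integer_ else nrow(x$slice)
  cat(sprintf("<sphere_geometry> R = %.4g um, z_c = %.4g um (%s slices, RSS %.3g)\n",
              x$R_um, x$zc_um, ns, x$rss))
  invisible(x)
}

#' Shortest 3D distance to the spheroid surface
#'
#' A nucleus at in-plane rim distance `d2` in the slice at height `z` sits at
#' in-plane radius `rho = r_z - d2`; under the spherical assumption its
#' shortest distance to the surface is `R - sqrt(rho^2 + (z - z_c)^2)`,
#' clamped to `[0, R]` (segmentation noise can put centroids marginally
#' outside the fitted sphere; those are clamped to 0 and flagged).
#'
#' @param d2_um In-plane distance(s) to the section rim.
#' @param z_um Slice height(s).
#' @param geom A `sphere_geometry`.
#' @param r_z_um Section radius of the slice; defaults to the spherical
#'   value `sqrt(R^2 - (z - z_c)^2)`.
#' @return Numeric vector of 3D distances; attribute `clamped` marks cells
#'   outside the fitted sphere.
#' @export
distance_3d <- function(d2_um, z_um, geom, r_z_um = NULL) {
  dz <- z_um - geom$zc_um
  if (any(abs(dz) > geom$R_um + 1e-9)) stop("slice lies outside the sphere")
  if (is.null(r_z_um)) r_z_um <- sqrt(pmax(geom$R_um^2 - dz^2, 0))
  rho <- r_z_um - d2_um
  s <- sqrt(rho^2 + dz^2)
  out <- geom$R_um - s
  clamped <- out < 0
  out <- pmin(pmax(out, 0), geom$R_um)
  attr(out, "clamped") <- clamped
  out
}

#' Classify a cell as green or red
#'
#' Green iff the normalized green signal `g/(g+r)` is strictly larger than
#' the threshold (default 0.225); `g + r = 0` cells are excluded (`NA`).
#'
#' @param g,r Nonnegative intensity vectors.
#' @param threshold Normalized-green threshold (default 0.225).
#' @return factor with levels `red`, `green` (`NA` where `g + r = 0`).
#' @export
classify_green <- function(g, r, threshold = 0.225) {
  tot <- g + r
  cls <- ifelse(tot <= 0, NA_character_,
                ifelse(g / tot > threshold, "green", "red"))
  factor(cls, levels = c("red", "green"))
}

#' Radial green/red histogram
#'
#' @param d3_um 3D surface distances per cell.
#' @param class Factor from [classify_green()].
#' @param bin_um Bin width (default 10 um).
#' @return data.frame per bin: `bin`, `inner_um`, `outer_um`, `n`,
#'   `green_fraction`, `red_fraction` (`NA` fractions where `n = 0`).
#' @export
radial_histogram <- function(d3_um, class, bin_um = 10) {
  ok <- !is.na(class)
  d3_um <- d3_um[ok]
  class <- class[ok]
  if (length(d3_um) == 0) stop("no classified cells")
  b <- floor(d3_um / bin_um)
  bmax <- max(b)
  bi <- 0:bmax
  n <- vapply(bi, function(k) sum(b == k), 1L)
  gf <- vapply(bi, function(k)
    if (sum(b == k) == 0) NA_real_ else mean(class[b == k] == "green"), 1.0)
  data.frame(bin = bi, inner_um = bi * bin_um, outer_um = (bi + 1) * bin_um,
             n = n, green_fraction = gf, red_fraction = 1 - gf)
}

#' Full 3D spheroid pipeline
#'
#' @param stack A [spheroid_stack()].
#' @param rollball_um,bin_um,green_threshold Stage parameters (defaults
#'   100 um, 10 um, 0.225).
#' @param min_cells_per_slice Optional filter dropping slices with fewer
#'   segmented nuclei (default 0 = off); deep-slice red-light background can
#'   otherwise contribute spurious cells.
#' @param ... Passed to [segment_slice_nuclei()].
#' @return List with `cells` (per-cell table: slice, centroid, g, r,
#'   normalized green, d2_um, d3_um, class), `geometry`, `histogram`,
#'   `norm_factor`.
#' @export
spheroid3d_pipeline <- function(stack, rollball_um = 100, bin_um = 10,
                                green_threshold = 0.225,
                                min_cells_per_slice = 0, ...) {
  pp <- preprocess_stack(stack, rollball_um)
  ns <- dim(pp$combined)[3]
  outlines <- vector("list", ns)
  per_slice <- vector("list", ns)
  for (s in seq_len(ns)) {
    m <- slice_outline(pp$combined[, , s], pp$pixel_size_um)
    outlines[[s]] <- m
    if (is.null(m)) next
    cells <- segment_slice_nuclei(pp$combined[, , s], pp$green[, , s],
                                  pp$red[, , s], m, pp$pixel_size_um, ...)
    if (nrow(cells) == 0 || nrow(cells) < min_cells_per_slice) {
      per_slice[[s]] <- NULL
      next
    }
    d_px <- edt_px(m)
    d2 <- (d_px[cbind(round(cells$row) + 1L, round(cells$col) + 1L)] - 1) *
      pp$pixel_size_um
    cells$d2_um <- pmax(d2, 0)
    cells$slice <- s
    per_slice[[s]] <- cells
  }
  geom <- fit_sphere(outlines, pp$z_um, pp$pixel_size_um)
  cells <- do.call(rbind, per_slice)
  if (is.null(cells) || nrow(cells) == 0) stop("no cells segmented")
  # drop cells in slices the fitted sphere does not cover (cap overshoot)
  cells <- cells[abs(pp$z_um[cells$slice] - geom$zc_um) <= geom$R_um, ,
                 drop = FALSE]
  if (nrow(cells) == 0) stop("no cells inside the fitted sphere")
  r_z <- vapply(cells$slice, function(s) {
    i <- match(s, geom$slice$slice)
    geom$slice$r_um[i]
  }, 1.0)
  cells$d3_um <- as.numeric(distance_3d(cells$d2_um, pp$z_um[cells$slice],
                                        geom, r_z_um = r_z))
  cells$norm_green <- ifelse(cells$g + cells$r > 0,
                             cells$g / (cells$g + cells$r), NA_real_)
  cells$class <- classify_green(cells$g, cells$r, green_threshold)
  hist <- radial_histogram(cells$d3_um, cells$class, bin_um)
  list(cells = cells, geometry = geom, histogram = hist,
       norm_factor = pp$norm_factor)
}
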