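#' Labeled image container
#'
#' The backbone container of the image modules: one or more channel rasters
#' (numeric matrices, row/col = y/x, origin top-left, 0-based pixel
#' coordinates in all reported centroids), an integer nucleus label mask
#' (0 = background, k = nucleus k, labels contiguous from 1) and the physical
#' pixel size.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param labels Integer matrix of the same dimension (may be all-zero).
#' @param pixel_size_um Micrometers per pixel.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(channels, labels = NULL, pixel_size_um) {
  if (is.matrix(channels)) channels <- list(ch1 = channels)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    stop("all channels must share one dimension")
  d <- dims[[1]]
  if (is.null(labels)) labels <- matrix(0L, d[1], d[2])
  if (!all(dim(labels) == d)) stop("label mask dimension must equal raster dimension")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(channels = channels, labels = labels,
                 pixel_size_um = pixel_size_um),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<labeled_image> %d x %d px (%.3g um/px), channels: %s, %d labels\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", "),
              max(x$labels)))
  invisible(x)
}

# ---- elementary raster operations --------------------------------------

# Separable Gaussian blur, reflected borders.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx <- abs(idx - 1L)                     # reflect low edge
    idx <- n - 1L - abs(n - 1L - idx) + 1L   # reflect high edge
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * m[idx[, t], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

img_hist <- function(x, nbins = 256L) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(NULL)
  mids <- seq(rng[1], rng[2], length.out = nbins)
  width <- mids[2] - mids[1]
  cuts <- pmin(pmax(floor((x - rng[1]) / width) + 1L, 1L), nbins)
  counts <- tabulate(cuts, nbins)
  list(mids = mids, counts = counts)
}

#' Otsu threshold
#'
#' Classic between-class-variance-maximizing global threshold on a 256-bin
#' histogram. Returns a threshold value; "foreground" is `> threshold`.
#'
#' @param x Numeric vector or matrix of intensities.
#' @param nbins Number of histogram bins.
#' @return Scalar threshold, or `NA` for constant input.
#' @export
threshold_otsu <- function(x, nbins = 256L) {
  h <- img_hist(x, nbins)
  if (is.null(h)) return(NA_real_)
  w <- h$counts / sum(h$counts)
  mu <- cumsum(w * h$mids)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  h$mids[which.max(sigma_b)]
}

#' Huang fuzzy threshold
#'
#' Huang & Wang's minimum-fuzziness threshold (the "Huang" auto-threshold of
#' common image-analysis software), computed on a 256-bin histogram.
#'
#' @inheritParams threshold_otsu
#' @return Scalar threshold, or `NA` for constant input.
#' @export
threshold_huang <- function(x, nbins = 256L) {
  h <- img_hist(x, nbins)
  if (is.null(h)) return(NA_real_)
  counts <- h$counts
  mids <- h$mids
  n <- length(mids)
  csum <- cumsum(counts)
  wsum <- cumsum(counts * mids)
  total <- csum[n]
  tw <- wsum[n]
  crng <- diff(range(mids))
  if (crng == 0) return(NA_real_)
  best <- Inf
  best_t <- mids[1]
  for (t in seq_len(n - 1)) {
    if (csum[t] == 0 || csum[t] == total) next
    mu0 <- wsum[t] / csum[t]
    mu1 <- (tw - wsum[t]) / (total - csum[t])
    # membership of each bin to its class; fuzziness via Shannon entropy
    mu <- ifelse(seq_len(n) <= t,
                 1 / (1 + abs(mids - mu0) / crng),
                 1 / (1 + abs(mids - mu1) / crng))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    s <- sum(counts * (-mu * log(mu) - (1 - mu) * log(1 - mu)))
    if (s < best) { best <- s; best_t <- mids[t] }
  }
  best_t
}

# Fill holes: background components not touching the border are holes.
fill_holes <- function(mask) {
  bg <- cpp_label(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- matrix(bg > 0 & !(bg %in% border), nrow(bg), ncol(bg))
  mask | hole
}

largest_component <- function(mask, connectivity = 4L) {
  lab <- cpp_label(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], max(lab))
  lab == which.max(sizes)
}

# Exact Euclidean distance (pixels) to the nearest background pixel.
edt_px <- function(mask) sqrt(cpp_edt_sq(mask))

# Grayscale opening with a disk: the background estimate of the classic
# rolling-ball subtraction at the stated physical radius. For very large
# balls the estimate is computed on a block-min-reduced image and
# re-expanded (the standard large-radius shortcut), clipped to stay a
# lower envelope of the input; deterministic either way.
gray_open_disk <- function(img, radius_px, shrink_threshold = 32L) {
  r <- as.integer(radius_px)
  if (r <= shrink_threshold)
    return(cpp_dilate_disk(cpp_erode_disk(img, r), r))
  k <- 4L
  nr <- nrow(img); nc <- ncol(img)
  nrp <- ceiling(nr / k) * k; ncp <- ceiling(nc / k) * k
  padded <- matrix(Inf, nrp, ncp)
  padded[seq_len(nr), seq_len(nc)] <- img
  # block minimum, k x k
  a <- array(padded, c(k, nrp / k, k, ncp / k))
  small <- apply(a, c(2, 4), min)
  rs <- as.integer(ceiling(r / k))
  bg_small <- cpp_dilate_disk(cpp_erode_disk(small, rs), rs)
  bg <- bg_small[rep(seq_len(nrp / k), each = k),
                 rep(seq_len(ncp / k), each = k)][seq_len(nr), seq_len(nc)]
  pmin(bg, img)
}

# Local maxima of img (within mask) with a minimum mutual distance.
# merge = TRUE resolves plateaus/close maxima greedily by value then scan
# order (use for sparse detections); merge = FALSE relies on a tiny
# deterministic tie-break ramp so each plateau yields one candidate (fast
# path for dense marker fields). 0-based (row, col) coordinates.
local_maxima <- function(img, min_dist_px, mask = NULL, threshold = -Inf,
                         merge = TRUE) {
  if (!merge) {
    # ramp small enough never to reorder distinct pixel values of interest
    eps <- max(abs(img)) * 1e-9 + 1e-12
    img <- img + matrix(seq_along(img), nrow(img)) * (eps / length(img))
  }
  maxf <- cpp_dilate_disk(img, as.integer(max(1, floor(min_dist_px))))
  cand <- img >= maxf & img > threshold
  if (!is.null(mask)) cand <- cand & mask
  idx <- which(cand)
  if (length(idx) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  nr <- nrow(img)
  ri <- (idx - 1L) %% nr
  ci <- (idx - 1L) %/% nr
  v <- img[idx]
  if (!merge)
    return(data.frame(row = ri, col = ci, value = v))
  o <- order(-v, ri, ci)
  ri <- ri[o]; ci <- ci[o]; v <- v[o]
  keep <- logical(length(v))
  kr <- numeric(0); kc <- numeric(0)
  for (t in seq_along(v)) {
    if (length(kr) == 0 ||
        min((kr - ri[t])^2 + (kc - ci[t])^2) >= min_dist_px^2) {
      keep[t] <- TRUE
      kr <- c(kr, ri[t]); kc <- c(kc, ci[t])
    }
  }
  data.frame(row = ri[keep], col = ci[keep], value = v[keep])
}

# Per-label centroids (0-based pixel coordinates) and areas.
label_stats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area_px = integer()))
  nr <- nrow(labels)
  l <- labels[idx]
  ri <- (idx - 1L) %% nr
  ci <- (idx - 1L) %/% nr
  data.frame(label = sort(unique(l)),
             row = tapply(ri, l, mean),
             col = tapply(ci, l, mean),
             area_px = as.integer(table(l)),
             row.names = NULL)
}

# Drop labels below a minimum area and relabel contiguously from 1.
filter_relabel <- function(labels, min_area_px = 0) {
  if (max(labels) == 0) return(labels)
  sizes <- tabulate(labels[labels > 0], max(labels))
  keep <- which(sizes >= min_area_px)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}
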