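# Independent oracles and small fixture builders shared across tests.

# Brute-force squared Euclidean distance to the nearest background pixel.
brute_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      if (mask[i, j])
        out[i, j] <- min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)
  out
}

# Full hypergeometric enumeration for a 2x2 table (two-sided p).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  dens <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- dens[xs == a]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

# Brute-force shortest distance from an interior point to the sphere
# surface, by dense sampling of surface points in the meridian plane.
brute_surface_distance <- function(rho, dz, R, n = 1e5) {
  th <- seq(0, pi, length.out = n)
  sqrt(min((R * sin(th) - rho)^2 + (R * cos(th) - dz)^2))
}

# Survival points drawn from one LQ curve under the fit's error model
# (iid Gaussian noise in log-SF space).
lq_model_points <- function(alpha, beta, doses = rep(c(0, 2, 4, 6, 8), 6),
                            sd_log = 0.1) {
  data.frame(dose_gy = doses,
             sf = exp(-alpha * doses - beta * doses^2 +
                        rnorm(length(doses), 0, sd_log)))
}

# Match planted nuclei to segmented labels via the label under each truth
# centroid; returns per-nucleus detected counts aligned with truth order.
match_counts <- function(labels, truth_nuclei, foci_table) {
  lab_at <- labels[cbind(round(truth_nuclei$row) + 1L,
                         round(truth_nuclei$col) + 1L)]
  foci_table$count[match(lab_at, foci_table$label)]
}
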