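#' Clonogenic-assay survival statistics
#'
#' Tools for colony-forming assay (CFA) data: plating efficiency and
#' surviving fractions, linear-quadratic (LQ) dose-response fitting
#' `SF(D) = exp(-alpha*D - beta*D^2)`, nested-model comparison of survival
#' curves by the extra-sum-of-squares F-test, and iso-effect dose inversion.
#'
#' A plate table is a data.frame with columns `condition`, `dose_gy`,
#' `seeded`, `colonies`; each row is one well.
#'
#' @name clonogenic
NULL

#' Surviving fractions from a plate table
#'
#' Plating efficiency (PE) is the mean `colonies/seeded` over the 0 Gy wells
#' of the same condition; SF(D) is the (per-well or per-dose mean) plating
#' ratio divided by PE, so SF(0) = 1 by construction.
#'
#' @param data Plate table (single condition): columns `dose_gy`, `seeded`,
#'   `colonies`.
#' @param per_well If `TRUE` (default) each well contributes one survival
#'   point, so downstream fits carry the true replication in their degrees of
#'   freedom; if `FALSE`, one averaged point per dose.
#' @return data.frame with `dose_gy`, `sf`, `sf_sd` (replicate SD of the
#'   per-well SFs at that dose) and `zero_count` flag for wells with 0
#'   colonies at positive dose.
#' @export
surviving_fractions <- function(data, per_well = TRUE) {
  need <- c("dose_gy", "seeded", "colonies")
  if (!all(need %in% names(data))) stop("plate table needs columns: ",
                                        paste(need, collapse = ", "))
  if (any(data$colonies < 0) || any(data$seeded <= 0))
    stop("counts must be >= 0 and seeded > 0")
  d0 <- data[data$dose_gy == 0, ]
  if (nrow(d0) == 0) stop("no 0 Gy wells: plating efficiency undefined")
  pe <- mean(d0$colonies / d0$seeded)
  if (pe == 0) stop("zero colonies at 0 Gy: plating efficiency undefined")
  pr <- data$colonies / data$seeded
  sf_well <- pr / pe
  sd_by_dose <- tapply(sf_well, data$dose_gy, sd)
  if (per_well) {
    out <- data.frame(dose_gy = data$dose_gy, sf = sf_well)
    out$sf_sd <- as.numeric(sd_by_dose[as.character(out$dose_gy)])
  } else {
    m <- tapply(sf_well, data$dose_gy, mean)
    out <- data.frame(dose_gy = as.numeric(names(m)), sf = as.numeric(m),
                      sf_sd = as.numeric(sd_by_dose))
  }
  out$zero_count <- out$sf == 0 & out$dose_gy > 0
  attr(out, "plating_efficiency") <- pe
  out[order(out$dose_gy), , drop = FALSE]
}

#' Linear-quadratic surviving fraction
#'
#' @param alpha Linear coefficient (1/Gy), >= 0.
#' @param beta Quadratic coefficient (1/Gy^2), >= 0.
#' @param dose Dose(s) in Gy, >= 0.
#' @return `exp(-alpha*D - beta*D^2)`.
#' @export
lq_sf <- function(alpha, beta, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-alpha * dose - beta * dose^2)
}

#' Fit the linear-quadratic model to survival points
#'
#' Ordinary least squares in log-SF space: `ln SF = -alpha*D - beta*D^2`,
#' constrained to `alpha, beta >= 0` (active-set over the two parameters;
#' negative survival coefficients are unphysical). Points with SF = 0 are
#' excluded with a warning (the log is undefined).
#'
#' @param points data.frame with `dose_gy` and `sf`.
#' @return Object of class `lq_fit`: `alpha`, `beta`, `rss` (log space),
#'   `df` (= n - 2), `cov` (parameter covariance from the unconstrained OLS
#'   normal equations), `n`, `constrained` flag.
#' @export
fit_lq <- function(points) {
  pts <- points[points$sf > 0, , drop = FALSE]
  if (nrow(pts) < nrow(points))
    warning(sprintf("%d point(s) with SF = 0 excluded from log-space fit",
                    nrow(points) - nrow(pts)))
  if (length(unique(pts$dose_gy)) < 3)
    stop("need >= 3 distinct doses with SF > 0")
  y <- log(pts$sf)
  X <- cbind(-pts$dose_gy, -pts$dose_gy^2)
  xtx <- crossprod(X)
  xty <- crossprod(X, y)
  solve_sub <- function(active) {
    # least squares with the given subset of {1,2} free, others fixed at 0
    th <- c(0, 0)
    if (length(active) > 0)
      th[active] <- solve(xtx[active, active, drop = FALSE],
                          xty[active, , drop = FALSE])
    th
  }
  cand <- list(c(1L, 2L), 1L, 2L, integer(0))
  best <- NULL
  for (a in cand) {
    th <- solve_sub(a)
    if (any(th < -1e-12)) next
    th <- pmax(th, 0)
    rss <- sum((y - X %*% th)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(theta = th, rss = rss, active = a)
  }
  n <- nrow(pts)
  df <- n - 2L
  s2 <- if (df > 0) best$rss / df else NA_real_
  covm <- tryCatch(s2 * solve(xtx), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(alpha = best$theta[1], beta = best$theta[2],
                 rss = best$rss, df = df, cov = covm, n = n,
                 constrained = length(best$active) < 2),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("LQ fit: alpha = %.6g /Gy, beta = %.6g /Gy^2 (RSS %.4g, df %d%s)\n",
              x$alpha, x$beta, x$rss, x$df,
              if (x$constrained) ", non-negativity active" else ""))
  invisible(x)
}

#' Compare two survival curves (extra-sum-of-squares F-test)
#'
#' Null: one LQ curve fits the pooled points (simple model, 2 parameters);
#' alternative: separate curves per group (4 parameters).
#' `F = ((RSS_simple - RSS_complex)/2) / (RSS_complex/df_complex)` with
#' `df_complex = n_a + n_b - 4`.
#'
#' @param group_a,group_b Survival point data.frames (`dose_gy`, `sf`).
#' @return Object of class `lq_ftest`: `F`, `df1`, `df2`, `p`,
#'   `rss_simple`, `rss_complex`, plus both separate fits.
#' @export
compare_curves_ftest <- function(group_a, group_b) {
  fa <- fit_lq(group_a)
  fb <- fit_lq(group_b)
  pooled <- rbind(group_a[c("dose_gy", "sf")], group_b[c("dose_gy", "sf")])
  fp <- fit_lq(pooled)
  rss_c <- fa$rss + fb$rss
  rss_s <- fp$rss
  df1 <- 2L
  df2 <- fa$n + fb$n - 4L
  extra <- rss_s - rss_c
  if (rss_c <= .Machine$double.eps * max(1, rss_s)) {
    f <- if (extra <= .Machine$double.eps) 0 else Inf
    p <- if (is.infinite(f)) 0 else 1
    flag <- is.infinite(f)
  } else if (extra <= 64 * .Machine$double.eps * rss_s) {
    # identical (or numerically indistinguishable) groups
    f <- 0
    p <- 1
    flag <- FALSE
  } else {
    f <- max(0, extra / df1 / (rss_c / df2))
    p <- pf(f, df1, df2, lower.tail = FALSE)
    flag <- FALSE
  }
  structure(list(F = f, df1 = df1, df2 = df2, p = p,
                 rss_simple = rss_s, rss_complex = rss_c,
                 fit_a = fa, fit_b = fb, fit_pooled = fp,
                 exact_complex_fit = flag),
            class = "lq_ftest")
}

#' @export
print.lq_ftest <- function(x, ...) {
  cat(sprintf("Extra-sum-of-squares F-test: F = %.4g (df %d, %d), p = %.4g\n",
              x$F, x$df1, x$df2, x$p))
  invisible(x)
}

#' Iso-effect dose for a target surviving fraction
#'
#' Positive root of `beta*D^2 + alpha*D + ln(SF) = 0`; with `beta = 0` this
#' reduces to `D = -ln(SF)/alpha`.
#'
#' @param fit An `lq_fit`, or a list with `alpha` and `beta`.
#' @param target_sf Target surviving fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_for_sf <- function(fit, target_sf) {
  if (any(target_sf <= 0) || any(target_sf > 1))
    stop("target_sf must be in (0, 1]")
  a <- fit$alpha
  b <- fit$beta
  if (a == 0 && b == 0) stop("alpha = beta = 0: no dose achieves the target")
  L <- -log(target_sf)
  if (b == 0) return(L / a)
  (-a + sqrt(a^2 + 4 * b * L)) / (2 * b)
}
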