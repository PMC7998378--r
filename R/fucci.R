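#' FUCCI cell-cycle classification and phase-duration tracing
#'
#' The FUCCI system marks G1 with a red (Cdt1 fragment) and S/G2/M with a
#' green (Geminin fragment) reporter: red-high/green-low = G1,
#' green-high/red-low = G2(/M), double-high = S, double-low = early G1.
#' Traces of cells followed from one mitosis to the next yield per-phase
#' residence times; cells that stall in one phase longer than a threshold
#' (default 24 h) or that turn from green back to red without a mitosis are
#' scored non-cycling.
#'
#' @name fucci
NULL

#' Cell-cycle gates
#'
#' @param red,green Per-dataset "high" thresholds (> 0). An intensity is
#'   "high" when strictly above its gate (values at the gate count as low).
#' @return Object of class `cc_gates`.
#' @export
cc_gates <- function(red, green) {
  stopifnot_scalar_pos(red, "red")
  stopifnot_scalar_pos(green, "green")
  structure(list(red = red, green = green), class = "cc_gates")
}

#' Classify FUCCI state from red/green intensities
#'
#' Partitions the intensity plane: exactly one state for every (red, green).
#' Ties at the gate are "low".
#'
#' @param red,green Intensity vectors.
#' @param gates A [cc_gates()] object.
#' @return factor with levels `earlyG1`, `G1`, `S`, `G2`.
#' @export
classify_state <- function(red, green, gates) {
  rh <- red > gates$red
  gh <- green > gates$green
  out <- ifelse(rh & !gh, "G1",
         ifelse(!rh & gh, "G2",
         ifelse(rh & gh, "S", "earlyG1")))
  factor(out, levels = c("earlyG1", "G1", "S", "G2"))
}

#' Calibrate red/green gates from pooled measurements
#'
#' Per-channel 2-class Otsu threshold on log intensities (deterministic,
#' scale-equivariant: scaling intensities by c scales the gate by c).
#' A channel whose log-intensity spread is too small to be bimodal falls
#' back to `median * fallback_factor` with a warning.
#'
#' @param red,green Pooled intensity vectors (>= 100 measurements).
#' @param fallback_factor Multiplier for the unimodal fallback (default 2).
#' @return A [cc_gates()] object.
#' @export
calibrate_gates <- function(red, green, fallback_factor = 2) {
  if (length(red) < 100 || length(green) < 100)
    stop("need >= 100 measurements per channel")
  gate1 <- function(x, nm) {
    lx <- log(pmax(x, .Machine$double.eps))
    if (sd(lx) < 0.05) {
      warning(sprintf("%s channel looks unimodal: median-based fallback", nm))
      return(max(median(x), .Machine$double.eps) * fallback_factor)
    }
    exp(threshold_otsu(lx))
  }
  cc_gates(gate1(red, "red"), gate1(green, "green"))
}

majority_filter <- function(x, window = 3L) {
  if (window < 3 || length(x) < window) return(x)
  h <- window %/% 2
  out <- x
  for (t in seq_along(x)) {
    lo <- max(1L, t - h)
    hi <- min(length(x), t + h)
    tb <- table(x[lo:hi])
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1) out[t] <- top else out[t] <- x[t]
  }
  out
}

#' Phase durations and cycling status from a single FUCCI trace
#'
#' States are classified per frame, smoothed with a 3-frame majority filter,
#' and contiguous runs timed. Scoring rules: a green-to-red transition with
#' no mitosis flag in between marks `noncycling_slip` (cell-cycle exit);
#' otherwise any single-phase residence above `noncycling_hours` (or reaching
#' the movie end mid-phase with residence already above it, under the default
#' `movie_end_rule = "threshold"`) marks `noncycling_stall`; a trace ending
#' before mitosis without triggering either rule is `censored`; else the cell
#' is `cycling` and per-phase durations are returned.
#'
#' @param trace data.frame with `t_h`, `red`, `green`, `mitosis` (logical or
#'   0/1), starting at a post-mitosis frame; `t_h` strictly increasing.
#' @param gates A [cc_gates()] object.
#' @param noncycling_hours Stall threshold in hours (default 24).
#' @param movie_end_rule `"threshold"` (default): a cell mid-phase at the
#'   last frame is a stall only if that residence already exceeds
#'   `noncycling_hours`, else censored; `"always"`: any cell mid-phase at the
#'   movie end is a stall.
#' @param smooth_window Majority-filter window in frames (default 3).
#' @return Object of class `phase_durations`: per-phase hours (`earlyG1`,
#'   `G1`, `S`, `G2`), `total_h`, `status`.
#' @export
trace_durations <- function(trace, gates, noncycling_hours = 24,
                            movie_end_rule = c("threshold", "always"),
                            smooth_window = 3L) {
  movie_end_rule <- match.arg(movie_end_rule)
  if (any(diff(trace$t_h) <= 0)) stop("timestamps must be strictly increasing")
  st <- as.character(classify_state(trace$red, trace$green, gates))
  st <- majority_filter(st, smooth_window)
  mflag <- as.logical(trace$mitosis)
  mflag[is.na(mflag)] <- FALSE
  trace$mitosis <- mflag
  mit <- which(mflag)
  n <- length(st)
  end_frame <- if (length(mit) > 0) mit[1] else n
  seg <- rle(st[seq_len(end_frame)])
  phases <- c(earlyG1 = 0, G1 = 0, S = 0, G2 = 0)
  bounds <- cumsum(seg$lengths)
  starts <- c(1L, head(bounds, -1) + 1L)
  # run k spans frames starts[k]..bounds[k]; duration = frames * interval
  dur_h <- seg$lengths * mean(diff(trace$t_h))
  for (k in seq_along(seg$values))
    phases[seg$values[k]] <- phases[seg$values[k]] + dur_h[k]
  # slip: green followed (not necessarily adjacently) by red, no mitosis flag
  slip <- FALSE
  g_seen <- FALSE
  for (k in seq_along(seg$values)) {
    if (seg$values[k] == "G2") g_seen <- TRUE
    if (g_seen && seg$values[k] %in% c("G1", "earlyG1")) {
      f_trans <- starts[k]
      if (!any(as.logical(trace$mitosis[seq_len(f_trans)]))) slip <- TRUE
      break
    }
  }
  has_mitosis <- length(mit) > 0
  longest <- max(dur_h)
  last_run <- dur_h[length(dur_h)]
  status <-
    if (slip) "noncycling_slip"
    else if (longest > noncycling_hours) "noncycling_stall"
    else if (!has_mitosis) {
      if (movie_end_rule == "always") "noncycling_stall"
      else if (last_run > noncycling_hours) "noncycling_stall"
      else "censored"
    } else "cycling"
  total <- if (status == "cycling") sum(phases) else NA_real_
  structure(list(earlyG1_h = phases[["earlyG1"]], G1_h = phases[["G1"]],
                 S_h = phases[["S"]], G2_h = phases[["G2"]],
                 total_h = total, status = status),
            class = "phase_durations")
}

#' Trace a whole table of FUCCI traces
#'
#' @param traces data.frame with `cell_id`, `t_h`, `red`, `green`, `mitosis`.
#' @param gates A [cc_gates()] object; if `NULL`, calibrated from the pooled
#'   intensities with [calibrate_gates()].
#' @param ... Passed to [trace_durations()].
#' @return data.frame with one row per cell: phase durations, total, status.
#' @export
trace_durations_table <- function(traces, gates = NULL, ...) {
  if (is.null(gates)) gates <- calibrate_gates(traces$red, traces$green)
  ids <- unique(traces$cell_id)
  rows <- lapply(ids, function(id) {
    d <- trace_durations(traces[traces$cell_id == id, , drop = FALSE],
                         gates, ...)
    data.frame(cell_id = id, earlyG1_h = d$earlyG1_h, G1_h = d$G1_h,
               S_h = d$S_h, G2_h = d$G2_h, total_h = d$total_h,
               status = d$status)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis comparison of phase durations
#'
#' Tie-corrected H statistic with the chi-square approximation,
#' `H = [12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)] / (1 - sum(t^3-t)/(N^3-N))`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @return List with `H`, `df`, `p`.
#' @export
compare_durations <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  vals <- unlist(groups, use.names = FALSE)
  ni <- vapply(groups, length, 1L)
  N <- length(vals)
  r <- rank(vals)
  Rj <- tapply(r, rep(seq_along(groups), ni), sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / ni) - 3 * (N + 1)
  ties <- table(vals)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(list(H = 0, df = length(groups) - 1L, p = 1))
  H <- H / corr
  df <- length(groups) - 1L
  list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

#' Fisher's exact test for cycling-status association
#'
#' Two-sided exact hypergeometric p-value (sum over all tables with the same
#' margins whose probability does not exceed the observed one, with the
#' customary (1 + 1e-7) tolerance) and the sample odds ratio with the Haldane
#' correction (+0.5 to every cell) when any cell is 0.
#'
#' @param group_a,group_b Length-2 integer vectors `(cycling, noncycling)`.
#' @return List with `p`, `odds_ratio`, `table`.
#' @export
cycling_association <- function(group_a, group_b) {
  tab <- rbind(a = as.integer(group_a), b = as.integer(group_b))
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin")
  m <- sum(tab[, 1]); nn <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- tab[1, 1]
  support <- max(0, k - nn):min(k, m)
  dens <- dhyper(support, m, nn, k)
  p <- sum(dens[dens <= dens[support == x] * (1 + 1e-7)])
  p <- min(1, p)
  or_tab <- tab
  if (any(tab == 0)) or_tab <- tab + 0.5
  orat <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  list(p = p, odds_ratio = orat, table = tab)
}
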