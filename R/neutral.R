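## Sloan neutral community model: occurrence-frequency vs abundance profiles,
## migration-rate estimation by bounded least squares, generalized R-squared,
## and per-OTU neutrality classes against a 95% confidence band.

#' Occurrence-frequency / abundance profiles for the neutral model
#'
#' For each OTU, `p` is the mean across samples of its within-sample relative
#' abundance and `freq` is the fraction of samples in which it is detected
#' (`count >= detection`). OTUs never detected are dropped. The community
#' size `N` is the rounded mean number of reads per sample.
#'
#' @param x An `otu_table` with at least 2 samples.
#' @param detection Detection threshold in reads (default 1).
#' @return List of class `otu_profiles`: `profiles` (data.frame `otu_id`,
#'   `p`, `freq`), `N`, `n_samples`, `detection`.
#' @export
occurrence_profiles <- function(x, detection = 1) {
  counts <- .values(x)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("all-zero sample column(s) present")
  rel <- sweep(counts, 2L, totals, "/")
  p <- rowMeans(rel)
  freq <- rowMeans(counts >= detection)
  keep <- freq > 0
  structure(list(
    profiles = data.frame(otu_id = rownames(counts)[keep],
                          p = unname(p[keep]), freq = unname(freq[keep]),
                          stringsAsFactors = FALSE),
    N = round(mean(totals)),
    n_samples = ncol(counts),
    detection = detection
  ), class = "otu_profiles")
}

#' Neutral-model predicted occurrence frequency
#'
#' The Sloan neutral model predicts the frequency with which a taxon of
#' metacommunity relative abundance `p` occurs across local communities of
#' size `N` at migration rate `m`:
#' `Freq = 1 - I(detection_limit; N m p, N m (1 - p))`,
#' where `I` is the regularized incomplete beta function (the beta CDF) and
#' the detection limit defaults to one individual, `1/N`.
#'
#' @param p Taxon relative abundance(s) in (0, 1).
#' @param N Community size (individuals, i.e. reads, per community).
#' @param m Migration rate in (0, 1].
#' @param detection_limit Abundance detection limit (default `1/N`).
#' @return Predicted frequency(ies) in \[0, 1\].
#' @export
predict_frequency <- function(p, N, m, detection_limit = 1 / N) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  a <- N * m * p
  b <- N * m * (1 - p)
  if (any(a <= 0) || any(b <= 0)) {
    stop("degenerate beta shape parameters: need N*m*p > 0 and N*m*(1-p) > 0")
  }
  1 - pbeta(detection_limit, a, b)
}

## Sum of squared residuals of observed vs predicted frequency at a given m.
.neutral_sse <- function(m, p, freq, N, detection_limit) {
  sum((freq - predict_frequency(p, N, m, detection_limit))^2)
}

#' Fit the Sloan neutral model
#'
#' Estimates the migration rate `m` by bounded least squares on the
#' occurrence-frequency vs abundance relationship: a coarse log-spaced grid
#' over `m_bounds` locates the basin and `stats::optimize` refines the
#' minimum of the residual sum of squares. The fit quality is the generalized
#' R-squared `1 - SS_err / SS_total`, with `SS_total` taken around the mean
#' observed frequency (it can be negative for fits worse than the mean). Each
#' OTU gets a 95% Wilson score band around its predicted frequency (binomial
#' n = number of samples) and a neutrality class: `"above"` (occurs more
#' often than predicted), `"within"`, or `"below"`.
#'
#' @param profiles An `otu_profiles` object from [occurrence_profiles()], or
#'   a data.frame with columns `p` and `freq` (then `N` and `n_samples` are
#'   required).
#' @param N Community size; taken from `profiles` when available.
#' @param n_samples Number of samples behind each frequency; taken from
#'   `profiles` when available.
#' @param m_bounds Search bounds for `m` (default `c(1e-6, 1)`).
#' @param conf Confidence level of the band (default 0.95).
#' @param detection_limit Abundance detection limit (default `1/N`).
#' @param grid_size Points in the coarse log-spaced bracketing grid.
#' @return List of class `neutral_fit`: `m`, `N`, `n_samples`, `r2`,
#'   `ss_err`, `ss_total`, and `otus` (per-OTU data.frame with `p`, `freq`,
#'   `freq_pred`, `lower`, `upper`, `class`).
#' @export
fit_neutral_model <- function(profiles, N = NULL, n_samples = NULL,
                              m_bounds = c(1e-6, 1), conf = 0.95,
                              detection_limit = NULL, grid_size = 64) {
  if (inherits(profiles, "otu_profiles")) {
    if (is.null(N)) N <- profiles$N
    if (is.null(n_samples)) n_samples <- profiles$n_samples
    if (is.null(detection_limit)) detection_limit <- profiles$detection / N
    profiles <- profiles$profiles
  }
  if (is.null(N) || is.null(n_samples)) {
    stop("N and n_samples are required when profiles is a plain data.frame")
  }
  if (is.null(detection_limit)) detection_limit <- 1 / N
  stopifnot(all(c("p", "freq") %in% colnames(profiles)))
  p <- profiles$p
  freq <- profiles$freq
  if (nrow(profiles) < 10L) {
    warning("fewer than 10 OTU profiles; the fit will be unstable")
  }
  ss_total <- sum((freq - mean(freq))^2)
  if (ss_total == 0) stop("all observed frequencies identical; SS_total = 0")

  grid <- exp(seq(log(m_bounds[1L]), log(m_bounds[2L]), length.out = grid_size))
  sse_grid <- vapply(grid, .neutral_sse, numeric(1L),
                     p = p, freq = freq, N = N,
                     detection_limit = detection_limit)
  i <- which.min(sse_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(.neutral_sse, interval = c(lo, hi), p = p, freq = freq,
                  N = N, detection_limit = detection_limit, tol = 1e-10)
  m_hat <- opt$minimum
  ss_err <- opt$objective
  if (sse_grid[i] < ss_err) {   # guard against a refine step losing the basin
    m_hat <- grid[i]
    ss_err <- sse_grid[i]
  }

  freq_pred <- predict_frequency(p, N, m_hat, detection_limit)
  band <- wilson_interval(freq_pred, n_samples, conf = conf)
  cls <- ifelse(freq > band$upper, "above",
                ifelse(freq < band$lower, "below", "within"))
  otus <- data.frame(profiles, freq_pred = freq_pred,
                     lower = band$lower, upper = band$upper, class = cls,
                     stringsAsFactors = FALSE)
  structure(list(m = m_hat, N = N, n_samples = n_samples,
                 r2 = 1 - ss_err / ss_total,
                 ss_err = ss_err, ss_total = ss_total,
                 conf = conf, detection_limit = detection_limit,
                 otus = otus),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: m = %.4g, N = %d, R2 = %.3f (%d OTUs)\n",
              x$m, x$N, x$r2, nrow(x$otus)))
  tab <- table(factor(x$otus$class, levels = c("below", "within", "above")))
  cat(sprintf("  classes: below %d / within %d / above %d\n",
              tab["below"], tab["within"], tab["above"]))
  invisible(x)
}

#' Wilson score interval for a proportion
#'
#' @param p_hat Proportion(s).
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return List with vectors `lower` and `upper`, clamped to \[0, 1\].
#' @export
wilson_interval <- function(p_hat, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Tabulate neutral fits across groups
#'
#' @param fits Named list of `neutral_fit` objects (names like
#'   `"habitat:layer"`), or a list with `habitat`/`layer` given separately
#'   via `groups`.
#' @param groups Optional data.frame with columns `habitat` and `layer`
#'   aligned with `fits`.
#' @return Data frame `(group, habitat, layer, m, r2, n_otus)` sorted by
#'   decreasing `r2`.
#' @export
compare_fits <- function(fits, groups = NULL) {
  if (length(fits) < 2L) stop("need at least 2 groups to compare")
  nm <- names(fits)
  if (is.null(nm)) nm <- as.character(seq_along(fits))
  if (is.null(groups)) {
    parts <- strsplit(nm, ":", fixed = TRUE)
    groups <- data.frame(
      habitat = vapply(parts, `[`, character(1L), 1L),
      layer = vapply(parts, function(z) if (length(z) > 1L) z[2L] else NA_character_,
                     character(1L)),
      stringsAsFactors = FALSE)
  }
  out <- data.frame(
    group = nm,
    habitat = groups$habitat,
    layer = groups$layer,
    m = vapply(fits, function(f) f$m, numeric(1L)),
    r2 = vapply(fits, function(f) f$r2, numeric(1L)),
    n_otus = vapply(fits, function(f) nrow(f$otus), integer(1L)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
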