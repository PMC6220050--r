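# Spike-train statistics: interspike intervals, PSTH, Blackburn-Sachs
# regularity analysis, and base-interval estimation.

#' Interspike intervals of a train
#'
#' Per trial, consecutive spike-time differences paired with the onset time
#' (the earlier spike of each pair), pooled across trials.
#'
#' @param train a [spike_train()].
#' @return data frame with columns `onset_time`, `isi`, `trial` (ms).
#' @export
#' @examples
#' isis(spike_train(list(c(1, 2, 4)), t_stop = 10))
isis <- function(train) {
  out <- lapply(seq_along(train$trials), function(i) {
    tt <- train$trials[[i]]
    if (length(tt) < 2) return(NULL)
    data.frame(onset_time = tt[-length(tt)], isi = diff(tt), trial = i)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(onset_time = numeric(0), isi = numeric(0),
                      trial = integer(0))
  out
}

#' Histogram of interspike intervals
#'
#' @param train a [spike_train()] (or a numeric vector of ISIs).
#' @param bin_width bin width (ms).
#' @param t_max upper edge (ms); defaults to the largest ISI.
#' @return object of class `isi_histogram`: `bin_edges`, `counts`, `n_isis`.
#' @export
isi_histogram <- function(train, bin_width = 0.1, t_max = NULL) {
  vals <- if (inherits(train, "spike_train")) isis(train)$isi else as.numeric(train)
  if (is.null(t_max)) t_max <- if (length(vals)) max(vals) else bin_width
  edges <- seq(0, t_max + bin_width, by = bin_width)
  counts <- as.integer(table(cut(vals, edges, right = FALSE)))
  structure(list(bin_edges = edges, counts = counts, n_isis = length(vals)),
            class = "isi_histogram")
}

#' Peri-stimulus time histogram
#'
#' Trial-pooled spike counts in time bins relative to stimulus onset.  Total
#' count equals the total number of spikes (count conservation).
#'
#' @param train a [spike_train()].
#' @param bin_width bin width (ms); 0.3 ms in the chopper protocol.
#' @param t_max histogram end (ms); defaults to `t_stop`.
#' @return object of class `psth`: `bin_edges`, `counts`, `rate` (spikes/s
#'   per trial), `n_trials`, `bin_width`.
#' @export
psth <- function(train, bin_width = 0.3, t_max = train$t_stop) {
  check_scalar(bin_width, "bin_width", positive = TRUE)
  tt <- unlist(train$trials)
  edges <- seq(0, t_max + bin_width, by = bin_width)
  counts <- as.integer(table(cut(tt, edges, right = FALSE)))
  n_trials <- length(train$trials)
  structure(list(bin_edges = edges, counts = counts,
                 rate = counts / n_trials / (bin_width * 1e-3),
                 n_trials = n_trials, bin_width = bin_width),
            class = "psth")
}

#' Locate peaks of a histogram
#'
#' Local maxima above `frac` of the global maximum, with a minimum
#' separation; used to read chopping peaks off a PSTH or ISI histogram.
#'
#' @param h a `psth` or `isi_histogram`.
#' @param frac minimum height relative to the maximum bin.
#' @param min_separation minimum distance between reported peaks (ms).
#' @return numeric vector of peak bin centers (ms).
#' @export
histogram_peaks <- function(h, frac = 0.25, min_separation = 2 * h$bin_edges[2]) {
  counts <- h$counts
  centers <- h$bin_edges[-length(h$bin_edges)] + diff(h$bin_edges) / 2
  if (!any(counts > 0)) return(numeric(0))
  thr <- frac * max(counts)
  n <- length(counts)
  is_peak <- counts >= thr &
    counts >= c(-Inf, counts[-n]) & counts >= c(counts[-1], -Inf)
  cand <- centers[is_peak]
  heights <- counts[is_peak]
  ord <- order(heights, decreasing = TRUE)
  keep <- numeric(0)
  for (i in ord) {
    if (!length(keep) || all(abs(cand[i] - keep) >= min_separation))
      keep <- c(keep, cand[i])
  }
  sort(keep)
}

#' Blackburn-Sachs regularity analysis
#'
#' Each interspike interval is assigned to the time bin containing its onset
#' spike; per bin the mean, population standard deviation and coefficient of
#' variation (CV = sd/mean) of the ISIs are computed as functions of time.
#' Sustained choppers are characterized by a small CV.  Bins with fewer than
#' `min_count` ISIs are flagged undefined (`NA`), not zero-filled.
#'
#' @param train a [spike_train()].
#' @param bin_width bin width (ms).
#' @param min_count minimum ISIs per bin for the statistics to be defined.
#' @param t_max analysis end (ms); defaults to `t_stop`.
#' @return object of class `regularity_curve`: data frame with columns
#'   `bin_center`, `mean_isi`, `sd_isi`, `cv`, `n`, `defined`.
#' @export
regularity <- function(train, bin_width = 1, min_count = 5,
                       t_max = train$t_stop) {
  check_scalar(bin_width, "bin_width", positive = TRUE)
  df <- isis(train)
  edges <- seq(0, t_max + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  bin <- cut(df$onset_time, edges, right = FALSE, labels = FALSE)
  n <- mu <- sd_ <- rep(NA_real_, length(centers))
  for (b in unique(bin[!is.na(bin)])) {
    v <- df$isi[which(bin == b)]
    n[b] <- length(v)
    mu[b] <- mean(v)
    sd_[b] <- sqrt(mean((v - mu[b])^2))  # population SD
  }
  defined <- !is.na(n) & n >= min_count & mu > 0
  out <- data.frame(bin_center = centers,
                    mean_isi = ifelse(defined, mu, NA_real_),
                    sd_isi = ifelse(defined, sd_, NA_real_),
                    cv = ifelse(defined, sd_ / mu, NA_real_),
                    n = ifelse(is.na(n), 0, n),
                    defined = defined)
  class(out) <- c("regularity_curve", "data.frame")
  out
}

#' Estimate the base interval underlying a set of ISIs
#'
#' Searches a grid of candidate base intervals for the one minimizing the
#' RMS deviation of the ISIs from their nearest positive integer multiples
#' of the base.  Ties are broken toward the largest base, which excludes the
#' degenerate tiny-base solutions (any base divides everything as the base
#' tends to 0; candidates below the grid minimum are not searched).  For a
#' pacemaker-driven chopper bank the estimate recovers the 0.4 ms population
#' clock from the pooled intervals.
#'
#' @param isi_values numeric vector of ISIs (ms), at least 2 values (a
#'   single value is accepted and returns its largest exact divisor on the
#'   grid).
#' @param search_grid `c(min, max, step)` in ms; the grid must lie below
#'   `min(isi_values)`.
#' @return object of class `base_interval_fit`: `base` (ms),
#'   `rms_deviation` (ms), `multiples` (integer vector, one per ISI).
#' @export
#' @examples
#' base_interval(c(0.8, 1.2, 2.0))$base  # 0.4
base_interval <- function(isi_values, search_grid = c(0.1, 0.45, 0.01)) {
  isi_values <- as.numeric(isi_values)
  if (!length(isi_values)) stopf("'isi_values' must be non-empty")
  if (any(isi_values <= 0)) stopf("ISIs must be positive")
  grid <- seq(search_grid[1], search_grid[2], by = search_grid[3])
  grid <- grid[grid > 0 & grid <= min(isi_values) + 1e-12]
  if (!length(grid)) stopf("search grid lies entirely above min(isi)")
  rms <- vapply(grid, function(b) {
    m <- pmax(1, round(isi_values / b))
    sqrt(mean((isi_values - m * b)^2))
  }, 0)
  best <- max(grid[rms <= min(rms) + 1e-12])  # largest base wins ties
  m <- pmax(1, round(isi_values / best))
  structure(list(base = best,
                 rms_deviation = sqrt(mean((isi_values - m * best)^2)),
                 multiples = as.integer(m)),
            class = "base_interval_fit")
}

#' @export
print.base_interval_fit <- function(x, ...) {
  cat(sprintf("<base_interval_fit> base %.3f ms, rms %.4f ms, multiples {%s}\n",
              x$base, x$rms_deviation,
              paste(sort(unique(x$multiples)), collapse = ", ")))
  invisible(x)
}
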