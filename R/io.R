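# Serialization: waveforms as two-column delimited text, spike trains as
# (trial, time_ms) tables with a JSON sidecar.

#' Write / read a waveform as two-column delimited text
#'
#' Columns `time_ms`, `amplitude`, tab-separated with a header line.
#'
#' @param w a [waveform()].
#' @param path output file.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns a [waveform()].
#' @export
write_waveform <- function(w, path) {
  df <- data.frame(time_ms = waveform_times(w), amplitude = w$samples)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  si <- if (nrow(df) > 1) (df$time_ms[2] - df$time_ms[1]) * 1e-3 else 25e-6
  waveform(df$amplitude, si, label = basename(path))
}

#' Write / read a spike train
#'
#' Spikes go to a tab-separated file with columns `trial`, `time_ms` (times
#' printed with 6 decimals, finer than the engine step, so round-trips are
#' exact), and a JSON sidecar `<path>.json` carries `unit_id`, `t_stop`,
#' `n_trials` and the declared refractory period.
#'
#' @param train a [spike_train()].
#' @param path output file.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()`
#'   returns a [spike_train()].
#' @export
write_spikes <- function(train, path) {
  rows <- lapply(seq_along(train$trials), function(i) {
    tt <- train$trials[[i]]
    if (!length(tt)) return(NULL)
    data.frame(trial = i, time_ms = sprintf("%.6f", tt))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(trial = integer(0), time_ms = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(unit_id = train$unit_id, t_stop = train$t_stop,
               n_trials = length(train$trials),
               refractory = train$refractory)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stopf("missing sidecar '%s'", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  n_trials <- max(side$n_trials, if (nrow(df)) max(df$trial) else 0L, 1L)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tt <- df$time_ms[df$trial == i]
    if (length(tt) && is.unsorted(tt, strictly = TRUE)) {
      bad <- which(diff(tt) <= 0)[1]
      row <- which(df$trial == i)[bad + 1]
      stopf("non-monotone spike times in trial %d at line %d of '%s'",
            i, row + 1L, path)
    }
    trials[[i]] <- tt
  }
  spike_train(trials, t_stop = side$t_stop, unit_id = side$unit_id,
              refractory = side$refractory)
}

#' Write all spike trains of a simulation result
#'
#' One `<unit>.spikes` file per unit plus a `manifest.json` echoing the
#' configuration (seed, topology, counts), so a rerun from the manifest
#' reproduces deterministic outputs exactly.
#'
#' @param result a `sim_result` from [simulate_network()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_sim_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(result$spikes))
    write_spikes(result$spikes[[id]], file.path(dir, paste0(id, ".spikes")))
  manifest <- c(result$config_echo,
                list(units = names(result$spikes),
                     total_spikes = vapply(result$spikes, n_spikes, 0L)))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(mpath)
}

#' Write a response matrix as a delimited table
#'
#' Rows are characteristic frequencies, columns modulation frequencies.
#'
#' @param rm a `response_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(rm, path) {
  df <- as.data.frame(rm$response)
  names(df) <- sprintf("fm_%.1f", rm$mod_freqs)
  df <- cbind(cf = rm$carrier_freqs, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
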