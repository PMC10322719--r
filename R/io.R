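# Plain-text interchange: feature tables (TSV with a units header row),
# spike datasets (two TSVs), sweep sets (voltage matrix + JSON sidecar).

#' Write / read a feature table
#'
#' Tab-separated text with a second header line (`# units:`) carrying the
#' unit of every numeric column.
#'
#' @param df feature data.frame from [extract_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(df, path) {
  units <- attr(df, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (!is.null(units)) {
    u <- units$unit[match(names(df), units$feature)]
    u[is.na(u)] <- "-"
    writeLines(paste0("# units:\t", paste(u, collapse = "\t")), con)
  }
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}

#' @rdname write_feature_table
#' @return `read_feature_table`: the data.frame with a `units` attribute.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, n = 2)
  header <- strsplit(lines[1], "\t")[[1]]
  has_units <- startsWith(lines[2], "# units:")
  df <- read.delim(path, skip = if (has_units) 2 else 1, header = FALSE,
                   col.names = header, check.names = FALSE)
  if (has_units) {
    u <- strsplit(lines[2], "\t")[[1]][-1]
    attr(df, "units") <- data.frame(feature = header, unit = u)
  }
  df
}

#' Write / read a spike dataset as delimited text
#'
#' Two tab-separated files: `<stem>_spikes.tsv` (`unit_id`, `time_s`) and
#' `<stem>_trials.tsv` (the events table: `trial_id`, `block`, `event`,
#' `onset_s`, `duration_s`); unit metadata and the session duration travel
#' in a JSON sidecar `<stem>_meta.json`.
#'
#' @param dataset a `spike_dataset`.
#' @param stem output path stem.
#' @export
write_spike_dataset <- function(dataset, stem) {
  write.table(dataset$spikes, paste0(stem, "_spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ev <- merge(dataset$events,
              dataset$trials[, c("trial_id", "block")], by = "trial_id")
  ev <- ev[order(ev$onset_s), c("trial_id", "block", "event", "onset_s",
                                "duration_s")]
  write.table(ev, paste0(stem, "_trials.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(duration_s = dataset$duration_s, units = dataset$units,
               trials = dataset$trials)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), digits = NA,
                       auto_unbox = TRUE)
}

#' @rdname write_spike_dataset
#' @return `read_spike_dataset`: a `spike_dataset` (without ground truth).
#' @export
read_spike_dataset <- function(stem) {
  spikes <- read.delim(paste0(stem, "_spikes.tsv"))
  ev <- read.delim(paste0(stem, "_trials.tsv"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  structure(list(spikes = spikes,
                 units = as.data.frame(meta$units),
                 trials = as.data.frame(meta$trials),
                 events = ev[, c("trial_id", "event", "onset_s", "duration_s")],
                 duration_s = meta$duration_s, truth = NULL),
            class = "spike_dataset")
}

#' Write a sweep set as delimited text with a JSON sidecar
#'
#' The voltage matrix (samples x sweeps) goes to `<stem>_voltage.tsv`; the
#' sampling rate, step timing, per-sweep amplitudes, spontaneous spike
#' times and metadata go to `<stem>_meta.json`.
#'
#' @param ss a `sweep_set`.
#' @param stem output path stem.
#' @export
write_sweep_set <- function(ss, stem) {
  write.table(ss$voltage, paste0(stem, "_voltage.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(amp_pA = ss$amp_pA, fs_hz = ss$fs_hz, pre_s = ss$pre_s,
               step_s = ss$step_s, post_s = ss$post_s,
               spont_spike_times_s = ss$spont$spike_times_s,
               spont_fs_hz = ss$spont$fs_hz,
               spont_duration_s = ss$spont$duration_s,
               archetype = ss$meta$archetype, seed = ss$meta$seed)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), digits = NA,
                       auto_unbox = TRUE)
}
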