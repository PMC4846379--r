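#' Write a generated population to tidy CSV files
#'
#' Emits the tidy trace table (cell_id, frame, time_s, F_meas, F_np), a
#' sidecar annotation table (cell_id, event_type, time_s, value) holding
#' spike times and the stimulus schedule, and a key/value run manifest.
#'
#' @param pop output of [generate_tuned_population()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param manifest named list of generator parameters recorded alongside.
#' @return invisibly, the paths written.
#' @export
write_population_csv <- function(pop, dir, prefix = "population",
                                 manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- do.call(rbind, lapply(pop$recordings, function(rec) {
    n <- length(rec$f_meas$samples)
    data.frame(cell_id = rec$cell_id, frame = seq_len(n),
               time_s = trace_times(rec$f_meas),
               F_meas = rec$f_meas$samples, F_np = rec$f_np$samples)
  }))
  ann <- do.call(rbind, lapply(pop$recordings, function(rec) {
    if (!length(rec$spikes$times)) return(NULL)
    data.frame(cell_id = rec$cell_id, event_type = "spike",
               time_s = rec$spikes$times, value = 1)
  }))
  sched <- data.frame(cell_id = NA_integer_, event_type = "stim_on",
                      time_s = pop$schedule$stim_start,
                      value = pop$schedule$direction)
  ann <- rbind(ann, sched)
  p1 <- file.path(dir, paste0(prefix, "_traces.csv"))
  p2 <- file.path(dir, paste0(prefix, "_annotations.csv"))
  p3 <- file.path(dir, paste0(prefix, "_manifest.txt"))
  utils::write.csv(traces, p1, row.names = FALSE)
  utils::write.csv(ann, p2, row.names = FALSE)
  writeLines(paste(names(manifest), vapply(manifest, format, character(1)),
                   sep = " = "), p3)
  invisible(c(traces = p1, annotations = p2, manifest = p3))
}

#' Read the tidy trace CSV back into recordings
#'
#' @param path path to a `*_traces.csv` written by [write_population_csv()].
#' @param fs frame rate of the stored traces, frames/s.
#' @return list of per-cell recordings with `f_meas` and `f_np` traces.
#' @export
read_population_csv <- function(path, fs) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "frame", "time_s", "F_meas", "F_np")
  if (!all(need %in% names(df))) stop("not a tidy trace table")
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    list(cell_id = d$cell_id[1],
         f_meas = ca_trace(d$F_meas, fs, d$time_s[1]),
         f_np = ca_trace(d$F_np, fs, d$time_s[1]))
  })
}
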