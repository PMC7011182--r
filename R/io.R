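# Plain-text sweep container.
#
# Layout (all comma-separated, header row):
#   <stem>.csv           time_ms plus one column per sweep (sweep_000, ...)
#   <stem>_protocol.csv  onset_ms, width_ms, modality, train_rate_hz
#   <stem>_meta.csv      key,value pairs: sampling_rate_hz, kind,
#                        holding_potential_mv, leak_current_pa,
#                        series_resistance_mohm, cell_class, t0_ms
# Units in files are pA/mV/ms, matching the in-memory canonical units.

.sidecar <- function(path, suffix) {
  sub("\\.csv$", paste0("_", suffix, ".csv"), path)
}

#' Write a sweep set to CSV
#'
#' Writes the sweep data plus protocol and metadata sidecar files
#' (`<stem>_protocol.csv`, `<stem>_meta.csv`).
#'
#' @param s A [sweep_set()].
#' @param path Output path ending in `.csv`.
#' @param digits Decimal digits for samples; the round trip is lossless to
#'   `10^-digits` in the trace units.
#' @return Invisibly, `path`.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(s, path, digits = 6) {
  stopifnot(inherits(s, "sweep_set"))
  if (!dir.exists(dirname(path)))
    stop("cannot write to '", path, "': directory does not exist",
         call. = FALSE)
  mat <- vapply(s$sweeps, function(x) x$samples,
                numeric(length(s$sweeps[[1L]]$samples)))
  df <- data.frame(time_ms = round(trace_times(s$sweeps[[1L]]), digits),
                   round(mat, digits))
  names(df)[-1L] <- sprintf("sweep_%03d", seq_along(s$sweeps) - 1L)
  utils::write.csv(df, path, row.names = FALSE)

  p <- s$protocol
  utils::write.csv(
    data.frame(onset_ms = p$onsets, width_ms = p$width,
               modality = p$modality,
               train_rate_hz = if (is.null(p$train_rate)) NA else p$train_rate),
    .sidecar(path, "protocol"), row.names = FALSE)

  meta <- list(
    sampling_rate_hz = s$sweeps[[1L]]$sampling_rate,
    kind = s$sweeps[[1L]]$kind,
    t0_ms = s$sweeps[[1L]]$t0,
    holding_potential_mv = if (is.null(s$holding_potential)) NA
                           else s$holding_potential)
  if (!is.null(s$qc)) {
    meta$leak_current_pa <- s$qc$leak_current
    meta$series_resistance_mohm <- s$qc$series_resistance
    meta$cell_class <- s$qc$cell_class
  }
  utils::write.csv(
    data.frame(key = names(meta),
               value = vapply(meta, function(v) as.character(v), character(1))),
    .sidecar(path, "meta"), row.names = FALSE)
  invisible(path)
}

#' Read a sweep set from CSV
#'
#' Reads the layout written by [write_sweepset()]. Missing required metadata
#' (e.g. the sampling rate) raises a format error naming the field.
#'
#' @param path Path to the main `.csv` file.
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  for (side in c("protocol", "meta"))
    if (!file.exists(.sidecar(path, side)))
      stop("missing sidecar file: ", .sidecar(path, side), call. = FALSE)

  meta_df <- utils::read.csv(.sidecar(path, "meta"),
                             colClasses = "character")
  meta <- stats::setNames(as.list(meta_df$value), meta_df$key)
  for (field in c("sampling_rate_hz", "kind"))
    if (is.null(meta[[field]]))
      stop("sweep container is missing required metadata field '",
           field, "'", call. = FALSE)
  rate <- as.numeric(meta$sampling_rate_hz)
  if (!is.finite(rate) || rate <= 0)
    stop("invalid sampling_rate_hz in metadata", call. = FALSE)
  t0 <- if (!is.null(meta$t0_ms)) as.numeric(meta$t0_ms) else 0

  df <- utils::read.csv(path, check.names = FALSE)
  sweep_cols <- grep("^sweep_", names(df), value = TRUE)
  if (!length(sweep_cols))
    stop("sweep container has no sweep_* columns", call. = FALSE)
  sweeps <- lapply(df[sweep_cols], function(col) {
    if (anyNA(col))
      stop("sweep columns differ in length (NA padding found)", call. = FALSE)
    trace(col, rate, meta$kind, t0)
  })

  pr <- utils::read.csv(.sidecar(path, "protocol"))
  for (field in c("onset_ms", "width_ms", "modality"))
    if (is.null(pr[[field]]))
      stop("protocol sidecar is missing field '", field, "'", call. = FALSE)
  tr_rate <- if (!is.null(pr$train_rate_hz) && all(!is.na(pr$train_rate_hz)))
    pr$train_rate_hz[1L] else NULL
  protocol <- stimulus_protocol(pr$onset_ms, width = pr$width_ms[1L],
                                modality = as.character(pr$modality[1L]),
                                train_rate = tr_rate,
                                sample_period_ms = 1000 / rate)

  hp <- if (!is.null(meta$holding_potential_mv) &&
            !is.na(suppressWarnings(as.numeric(meta$holding_potential_mv))))
    as.numeric(meta$holding_potential_mv) else NULL
  qc <- if (!is.null(meta$cell_class))
    qc_record(as.numeric(meta$leak_current_pa),
              as.numeric(meta$series_resistance_mohm),
              meta$cell_class) else NULL

  sweep_set(unname(sweeps), protocol, holding_potential = hp, qc = qc)
}
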