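#' Read a raw-acceleration CSV
#'
#' Parses the documented dialect (`timestamp,x,y,z`; ISO-8601 timestamps; g
#' units). Unknown extra columns are ignored with a message. Timestamps must
#' be strictly increasing; the first offending line (1-based, counting the
#' header) is named otherwise.
#'
#' @param path CSV file path.
#' @return data.frame with `time_s` (seconds from the first sample), `x`,
#'   `y`, `z`; the start time is kept in the `"start_time"` attribute.
#' @export
read_raw_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- c("timestamp", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(d), need)
  if (length(extra))
    message("ignoring unknown columns: ", paste(extra, collapse = ", "))
  tt <- parse_iso_times(d$timestamp, path)
  out <- data.frame(time_s = tt$secs, x = d$x, y = d$y, z = d$z)
  attr(out, "start_time") <- tt$start
  out
}

#' Read a breath-by-breath CSV
#'
#' Dialect `timestamp,vo2_lpm,vco2_lpm,rr` (rr optional). Negative gas values
#' and non-monotone timestamps are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @return data.frame with `time_s`, `vo2_lpm`, `vco2_lpm` (and `rr` if
#'   present); start time in the `"start_time"` attribute.
#' @export
read_breath_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- c("timestamp", "vo2_lpm", "vco2_lpm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  bad <- which(d$vo2_lpm < 0 | d$vco2_lpm < 0)
  if (length(bad)) stop("negative gas value at line ", bad[1] + 1L,
                        " of ", path)
  tt <- parse_iso_times(d$timestamp, path)
  out <- data.frame(time_s = tt$secs, vo2_lpm = d$vo2_lpm,
                    vco2_lpm = d$vco2_lpm)
  if ("rr" %in% names(d)) out$rr <- d$rr
  attr(out, "start_time") <- tt$start
  out
}

# ISO-8601 timestamps -> seconds from the first sample; enforces strict
# monotonicity and reports the first offending data line
parse_iso_times <- function(ts, path) {
  t <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) stop("unparseable timestamp at line ",
                     which(is.na(t))[1] + 1L, " of ", path)
  secs <- as.numeric(t) - as.numeric(t[1])
  if (length(secs) > 1L) {
    bad <- which(diff(secs) <= 0)
    if (length(bad)) stop("non-monotone timestamp at line ", bad[1] + 2L,
                          " of ", path)
  }
  list(secs = secs, start = t[1])
}

#' Read a session written by [write_session()] back into memory
#'
#' @param dir directory holding the files.
#' @param id participant id (file prefix).
#' @return list with `hip`, `wrist`, `breaths`, `truth_ee`, `participant`.
#' @export
read_session <- function(dir, id) {
  truth <- data.table::fread(file.path(dir, paste0(id, "_truth_ee.csv")),
                             data.table = FALSE, showProgress = FALSE)
  tt <- parse_iso_times(truth$timestamp, "truth_ee")
  list(hip = read_raw_csv(file.path(dir, paste0(id, "_hip.csv"))),
       wrist = read_raw_csv(file.path(dir, paste0(id, "_wrist.csv"))),
       breaths = read_breath_csv(file.path(dir, paste0(id, "_breaths.csv"))),
       truth_ee = data.frame(start_s = tt$secs,
                             ee_kcal_min = truth$ee_kcal_min),
       participant = data.table::fread(
         file.path(dir, paste0(id, "_participant.csv")),
         data.table = FALSE, showProgress = FALSE))
}
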