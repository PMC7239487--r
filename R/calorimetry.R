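#' Convert gas exchange to energy expenditure (abbreviated Weir equation)
#'
#' EE (kcal/min) = 3.941 * VO2 + 1.106 * VCO2, with VO2 and VCO2 in L/min.
#' The urinary-nitrogen term is omitted, as is standard for portable
#' calorimetry.
#'
#' @param vo2,vco2 numeric vectors, L/min, non-negative.
#' @return kcal/min, same length as the inputs.
#' @export
weir_ee <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    stop("VO2 and VCO2 must be non-negative")
  3.941 * vo2 + 1.106 * vco2
}

#' Schofield resting energy expenditure for children aged 3-10 y
#'
#' Weight-and-height equations (W in kg, H in m), BMR in MJ/day:
#' male 0.082 W + 0.545 H + 1.736; female 0.071 W + 0.677 H + 1.553.
#' Converted to kcal/day (x 239.006) and kcal/min (/1440).
#'
#' @param sex "male" or "female".
#' @param height_m height in metres (> 0).
#' @param mass_kg body mass in kg (> 0).
#' @return list with `mj_day`, `ree_kcal_day`, `ree_kcal_min`.
#' @export
schofield_ree <- function(sex, height_m, mass_kg) {
  if (!sex %in% c("male", "female")) stop("`sex` must be 'male' or 'female'")
  if (height_m <= 0 || mass_kg <= 0) stop("height and mass must be positive")
  mj <- if (sex == "male") 0.082 * mass_kg + 0.545 * height_m + 1.736
        else 0.071 * mass_kg + 0.677 * height_m + 1.553
  kcal_day <- mj * 239.006
  list(mj_day = mj, ree_kcal_day = kcal_day, ree_kcal_min = kcal_day / 1440)
}

#' Express energy expenditure in METs
#'
#' MET = EE / predicted resting EE (both kcal/min).
#'
#' @param ee kcal/min.
#' @param ree a [schofield_ree()] result, or a kcal/min scalar.
#' @return MET values.
#' @export
to_mets <- function(ee, ree) {
  r <- if (is.list(ree)) ree$ree_kcal_min else ree
  if (!is.numeric(r) || r <= 0) stop("resting EE must be positive")
  ee / r
}

#' Bin and smooth breath-by-breath gas exchange
#'
#' Breaths are assigned to consecutive left-closed, right-open bins of `bin`
#' seconds by timestamp; per-bin mean VO2/VCO2 are computed; empty interior
#' bins are linearly interpolated from their neighbours (edges carried from
#' the nearest non-empty bin); then a centred moving average of `ma` seconds
#' (`ma / bin` bins) is applied with shrinking windows at the series edges.
#' A trailing-average variant is available for sensitivity analyses.
#'
#' @param breaths data.frame with columns `time_s`, `vo2_lpm`, `vco2_lpm`
#'   (time in seconds from session start, strictly ordered).
#' @param bin bin width, seconds (default 10).
#' @param ma moving-average span, seconds (default 60); must be a multiple of
#'   `bin`.
#' @param align "centred" (default) or "trailing".
#' @param span total span in seconds to bin over; defaults to
#'   `floor(max(time)/bin)*bin` so only complete bins are produced.
#' @return data.frame with columns `start_s`, `vo2_lpm`, `vco2_lpm`.
#' @export
smooth_gas <- function(breaths, bin = 10, ma = 60,
                       align = c("centred", "trailing"), span = NULL) {
  align <- match.arg(align)
  if (is.null(breaths) || nrow(breaths) < 1L) stop("no breaths to smooth")
  if (ma %% bin != 0) stop("`bin` must divide `ma`")
  tmax <- span %||% max(breaths$time_s)
  nbin <- floor(tmax / bin)
  if (nbin < 1L) stop("span shorter than one bin")
  idx <- floor(breaths$time_s / bin) + 1L
  keep <- idx >= 1L & idx <= nbin
  idx <- idx[keep]
  vo2 <- vapply(seq_len(nbin), function(i) {
    s <- breaths$vo2_lpm[keep][idx == i]
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  vco2 <- vapply(seq_len(nbin), function(i) {
    s <- breaths$vco2_lpm[keep][idx == i]
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  if (all(is.na(vo2))) stop("all bins empty")
  vo2 <- fill_na_linear(vo2)
  vco2 <- fill_na_linear(vco2)
  w <- as.integer(ma / bin)
  data.frame(start_s = (seq_len(nbin) - 1L) * bin,
             vo2_lpm = moving_average(vo2, w, align),
             vco2_lpm = moving_average(vco2, w, align))
}

# linear interpolation of interior NAs; edge NAs carried from nearest value
fill_na_linear <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

# moving average over w points; centred (window [i - floor(w/2), i + w - 1 -
# floor(w/2)]) or trailing, with shrinking windows at the edges
moving_average <- function(x, w, align = "centred") {
  n <- length(x)
  if (w <= 1L) return(x)
  off_lo <- if (align == "centred") floor(w / 2) else w - 1L
  off_hi <- if (align == "centred") w - 1L - floor(w / 2) else 0L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - off_lo):min(n, i + off_hi)])
  }, numeric(1))
}

#' Smoothed energy-expenditure criterion series from breath records
#'
#' Applies [smooth_gas()] then [weir_ee()], and optionally MET-normalizes by a
#' participant's Schofield resting EE. This is the criterion (ground-truth
#' measurement) series the models are trained against.
#'
#' @param breaths breath data.frame (see [smooth_gas()]).
#' @param ree optional [schofield_ree()] result for MET output.
#' @inheritParams smooth_gas
#' @return data.frame `start_s`, `ee_kcal_min` (and `met` if `ree` given).
#' @export
ee_criterion <- function(breaths, ree = NULL, bin = 10, ma = 60,
                         align = c("centred", "trailing"), span = NULL) {
  g <- smooth_gas(breaths, bin = bin, ma = ma, align = match.arg(align),
                  span = span)
  out <- data.frame(start_s = g$start_s,
                    ee_kcal_min = weir_ee(g$vo2_lpm, g$vco2_lpm))
  if (!is.null(ree)) out$met <- to_mets(out$ee_kcal_min, ree)
  out
}
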