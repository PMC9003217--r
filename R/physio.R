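# Physiological route: time-domain HRV features over sliding windows,
# per-subject calibrated thresholds, Grade of Attention (GA) accumulation,
# binary Attention Array (AAp).

#' Time-domain heart-rate-variability features
#'
#' Standard beat-to-beat (BB/RR) interval summaries, all in ms except
#' `pnn50` (percent):
#' * `sdnn(bb)` — sample standard deviation (denominator n-1) of the
#'   intervals; needs at least 2 intervals.
#' * `sdsd(bb)` — sample standard deviation of the successive differences
#'   `bb[i+1] - bb[i]`; needs at least 3 intervals.
#' * `rmssd(bb)` — root mean square of the successive differences; needs at
#'   least 2 intervals.
#' * `pnn50(bb)` — percentage of successive differences whose absolute value
#'   strictly exceeds 50 ms; needs at least 2 intervals.
#'
#' @param bb Numeric vector of beat-to-beat intervals in ms.
#' @return A single numeric value.
#' @name hrv_features
NULL

#' @rdname hrv_features
#' @export
sdnn <- function(bb) {
  if (length(bb) < 2) stop("sdnn needs at least 2 intervals", call. = FALSE)
  stats::sd(bb)
}

#' @rdname hrv_features
#' @export
sdsd <- function(bb) {
  if (length(bb) < 3) stop("sdsd needs at least 3 intervals", call. = FALSE)
  stats::sd(diff(bb))
}

#' @rdname hrv_features
#' @export
rmssd <- function(bb) {
  if (length(bb) < 2) stop("rmssd needs at least 2 intervals", call. = FALSE)
  sqrt(mean(diff(bb)^2))
}

#' @rdname hrv_features
#' @export
pnn50 <- function(bb) {
  if (length(bb) < 2) stop("pnn50 needs at least 2 intervals", call. = FALSE)
  100 * mean(abs(diff(bb)) > 50)
}

#' Subject demographics used by level-1 calibration
#'
#' @param age Years, positive.
#' @param gender Free-form category (recorded, not used numerically).
#' @param weight_kg Kilograms, positive.
#' @param height_cm Centimetres, positive.
#' @return A list of class `subject_info`.
#' @export
subject_info <- function(age, gender = NA_character_, weight_kg = 70,
                         height_cm = 170) {
  stopifnot(age > 0, weight_kg > 0, height_cm > 0)
  structure(list(age = age, gender = gender, weight_kg = weight_kg,
                 height_cm = height_cm),
            class = "subject_info")
}

#' Age-banded plausibility bounds for HRV thresholds
#'
#' Level-1 (demographic) calibration: wide physiological ranges, in ms, used
#' only to clamp the level-2 (baseline-derived) thresholds and to supply a
#' default when no baseline recording exists. Short-term SDNN/RMSSD decline
#' with age, hence the lower ceiling for older subjects. The bands are
#' deliberately loose; they guard against degenerate baselines (for example
#' a constant BB series giving a 0 ms threshold), not against individual
#' variation.
#'
#' @param info A [subject_info()].
#' @return A list with numeric `lo` and `hi` bounds (ms), applied to all
#'   three thresholded features.
#' @export
demographic_bands <- function(info) {
  hi <- if (info$age < 40) 250 else if (info$age < 60) 200 else 150
  list(lo = 5, hi = hi)
}

#' Calibrate per-subject HRV thresholds
#'
#' Two-level calibration preceding a session. Level 2 computes
#' SDNN/RMSSD/SDSD over a baseline (initial-condition) recording; level 1
#' clamps those values into the subject's demographic plausibility band
#' ([demographic_bands()]) and supplies the band midpoint when no baseline
#' is available. `direction` states which side of each threshold counts
#' toward attention; the default `"below"` encodes that focused mental
#' effort suppresses short-term HRV relative to rest.
#'
#' @param info A [subject_info()].
#' @param baseline A [physio_stream()] covering at least `baseline_s`
#'   seconds, or `NULL` to fall back on demographic defaults.
#' @param direction `"below"` or `"above"`.
#' @param baseline_s Baseline window length in seconds (default 120); only
#'   the first `baseline_s` samples are used.
#' @param subject Subject id recorded in the profile.
#' @return A list of class `calibration_profile` with elements
#'   `threshold_sdnn`, `threshold_rmssd`, `threshold_sdsd` (ms),
#'   `direction`, `baseline_s`, `clamped` (logical per feature) and
#'   `from_baseline`.
#' @export
calibrate <- function(info, baseline, direction = c("below", "above"),
                      baseline_s = 120, subject = NA_character_) {
  direction <- match.arg(direction)
  bands <- demographic_bands(info)
  if (is.null(baseline)) {
    raw <- rep((bands$lo + bands$hi) / 2, 3)
    from_baseline <- FALSE
  } else {
    if (nrow(baseline) < baseline_s) {
      stop("baseline covers ", nrow(baseline), " s, need ", baseline_s,
           call. = FALSE)
    }
    bb <- baseline$bb_ms[seq_len(baseline_s)]
    raw <- c(sdnn(bb), rmssd(bb), sdsd(bb))
    from_baseline <- TRUE
  }
  clamped <- raw < bands$lo | raw > bands$hi
  val <- pmin(pmax(raw, bands$lo), bands$hi)
  structure(
    list(subject = subject,
         threshold_sdnn = val[1], threshold_rmssd = val[2],
         threshold_sdsd = val[3],
         direction = direction, baseline_s = baseline_s,
         clamped = stats::setNames(clamped, c("sdnn", "rmssd", "sdsd")),
         from_baseline = from_baseline,
         info = info),
    class = "calibration_profile"
  )
}

#' Parameters of the Grade-of-Attention classifier
#'
#' @param ws Sliding-window size in samples at 1 Hz (the common WS).
#'   Default 100.
#' @param inner_len Sub-window length, in samples, over which the punctual
#'   SDNN/RMSSD/SDSD values are computed for each second. Default 30.
#' @param tp_factor Multiplier giving the attention threshold
#'   `t_p = tp_factor * ws`. The default 3/2 is the midpoint of GA's
#'   attainable range `[0, 3 ws]` (three feature comparisons per sample).
#' @param t_p Explicit threshold override.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(ws = 100, inner_len = 30, tp_factor = 1.5,
                      t_p = tp_factor * ws) {
  stopifnot(inner_len >= 2, ws >= inner_len, t_p >= 0)
  structure(list(ws = as.integer(ws), inner_len = as.integer(inner_len),
                 tp_factor = tp_factor, t_p = t_p),
            class = "ga_params")
}

# Punctual SDNN/RMSSD/SDSD at every sample of a session: feature f at sample
# s is computed over the inner_len samples ending at s; the first
# inner_len - 1 samples reuse the first full inner window. Returns an
# n x 3 matrix (sdnn, rmssd, sdsd).
.inner_stats <- function(bb, inner_len) {
  n <- length(bb)
  if (n < inner_len) {
    stop("stream length ", n, " shorter than inner window ", inner_len,
         call. = FALSE)
  }
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("sdnn", "rmssd", "sdsd")))
  for (s in inner_len:n) {
    w <- bb[(s - inner_len + 1L):s]
    out[s, ] <- c(sdnn(w), rmssd(w), sdsd(w))
  }
  out[seq_len(inner_len - 1L), ] <-
    matrix(out[inner_len, ], inner_len - 1L, 3, byrow = TRUE)
  out
}

# Per-sample attention votes in 0..3: how many of the three punctual
# features lie on the profile's attention side of their threshold (strict).
.attention_votes <- function(bb, profile, params) {
  st <- .inner_stats(bb, params$inner_len)
  thr <- c(profile$threshold_sdnn, profile$threshold_rmssd,
           profile$threshold_sdsd)
  hit <- if (profile$direction == "below") {
    sweep(st, 2, thr, "<")
  } else {
    sweep(st, 2, thr, ">")
  }
  rowSums(hit)
}

#' Grade of Attention of one window
#'
#' For each of the `ws` samples in the window, the punctual SDNN, RMSSD and
#' SDSD are computed over the `inner_len` samples ending at that sample
#' (the first `inner_len - 1` samples reuse the first full inner window),
#' and GA gains one point for every feature lying strictly on the profile's
#' attention side of its calibrated threshold. GA therefore ranges over
#' `[0, 3 ws]`, with the attention threshold `t_p = 1.5 ws` at its midpoint.
#'
#' @param segment A [physio_stream()] (or bare numeric BB vector) of exactly
#'   `params$ws` samples.
#' @param profile A [calibrate()]d profile.
#' @param params A [ga_params()] object.
#' @return Integer GA in `[0, 3 ws]`.
#' @export
grade_of_attention <- function(segment, profile, params = ga_params()) {
  bb <- if (is.data.frame(segment)) segment$bb_ms else as.numeric(segment)
  if (length(bb) != params$ws) {
    stop("segment length ", length(bb), " != ws ", params$ws, call. = FALSE)
  }
  sum(.attention_votes(bb, profile, params))
}

#' Physiological Attention Array (AAp)
#'
#' Slides the WS window over the session with a one-second step; each window
#' end from `t = ws` onward yields one label: `Attention` when the window's
#' Grade of Attention strictly exceeds `t_p`, else `Distraction`. Punctual
#' feature values are computed once per session sample over the `inner_len`
#' samples ending at it (session-start samples reuse the first full inner
#' window); each window's GA is the rolling sum of the per-sample votes, so
#' the whole array costs one pass over the session.
#'
#' @param stream A [physio_stream()] of at least `ws` samples.
#' @param profile A [calibrate()]d profile.
#' @param params A [ga_params()] object.
#' @param subject Optional subject id recorded in the array.
#' @return An [attention_array()] with `nrow(stream) - ws + 1` labels,
#'   `source = "physio"`.
#' @export
physio_attention_array <- function(stream, profile, params = ga_params(),
                                   subject = NA_character_) {
  n <- nrow(stream)
  ws <- params$ws
  if (n < ws) {
    stop("stream length ", n, " shorter than window ", ws, call. = FALSE)
  }
  votes <- .attention_votes(stream$bb_ms, profile, params)
  cs <- cumsum(c(0, votes))
  ends <- ws:n
  ga <- cs[ends + 1L] - cs[ends - ws + 1L]
  attention_array(t_s = ends, attention = ga > params$t_p,
                  source = "physio", subject = subject)
}
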