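# Regime-switching lecture simulator. Generates the three stream types the
# pipeline consumes (2 Hz emotion labels, 1 Hz HR/BB, prompt logs are
# trivial to build by hand) plus per-second ground truth, so every stage is
# testable without recordings.

#' Define a regime schedule
#'
#' An ordered sequence of attention regimes covering the whole session.
#'
#' @param duration_s Positive numeric vector of segment lengths in seconds.
#' @param state Character vector, `"attentive"` or `"distracted"`, one per
#'   segment.
#' @return A data frame of class `regime_schedule` with columns
#'   `duration_s`, `state`, `start_s`, `end_s`; attribute `total_s`.
#' @export
regime_schedule <- function(duration_s, state) {
  stopifnot(length(duration_s) == length(state), all(duration_s > 0),
            all(state %in% c("attentive", "distracted")))
  end <- cumsum(duration_s)
  structure(
    data.frame(duration_s = duration_s, state = state,
               start_s = c(0, utils::head(end, -1)), end_s = end),
    total_s = sum(duration_s),
    class = c("regime_schedule", "data.frame")
  )
}

# regime state at (possibly fractional) time t, vectorised
.state_at <- function(schedule, t) {
  i <- findInterval(t, schedule$start_s, rightmost.closed = FALSE)
  i[i < 1] <- 1L
  i[i > nrow(schedule)] <- nrow(schedule)
  schedule$state[i]
}

#' Default per-state emotion distributions
#'
#' Attentive students show mostly active moods (happiness, surprise) with a
#' realistic share of neutral frames; distracted students show mostly
#' passive moods (sadness, contempt, disgust) and more neutrality. A
#' `neutrality_inflation` factor > 1 multiplies the neutrality mass and
#' rescales the rest, emulating the weakly expressive faces of remote
#' lectures where the facial source becomes less predictive.
#'
#' @param state `"attentive"` or `"distracted"`.
#' @param neutrality_inflation Multiplier (>= 0) on the neutrality
#'   probability, default 1.
#' @return Named numeric probability vector over [emotion_labels].
#' @export
default_emotion_dist <- function(state, neutrality_inflation = 1) {
  p <- switch(
    match.arg(state, c("attentive", "distracted")),
    attentive = c(anger = 0.05, contempt = 0.01, disgust = 0.01,
                  fear = 0.05, happiness = 0.35, neutrality = 0.35,
                  sadness = 0.03, surprise = 0.15),
    distracted = c(anger = 0.02, contempt = 0.10, disgust = 0.10,
                   fear = 0.02, happiness = 0.05, neutrality = 0.40,
                   sadness = 0.30, surprise = 0.01)
  )
  if (neutrality_inflation != 1) {
    neu <- min(1, p[["neutrality"]] * neutrality_inflation)
    rest <- p[names(p) != "neutrality"]
    p <- c(rest * (1 - neu) / sum(rest), neutrality = neu)
    p <- p[emotion_labels]
  }
  p
}

#' Define a simulated subject
#'
#' Bundles everything the generators need for one subject: demographics,
#' per-state emotion distributions, per-state beat-to-beat AR(1) models and
#' a seed. The default BB models share a mean of 800 ms (75 bpm) and differ
#' only in variability: attention (mental effort) suppresses short-term HRV
#' below its resting level, distraction relaxes it above. Calibration
#' baselines are drawn from the `rest` model, so the resting thresholds sit
#' between the two lecture regimes.
#'
#' @param id Subject id string.
#' @param info A [subject_info()].
#' @param emotion_dists Named list (`attentive`, `distracted`) of
#'   probability vectors over [emotion_labels].
#' @param bb_models Named list (`attentive`, `distracted`, `rest`) of lists
#'   `(mean_ms, sd_ms, ar)` — stationary mean and sd of the AR(1) BB
#'   process and its lag-1 autocorrelation.
#' @param neutrality_inflation Passed to [default_emotion_dist()].
#' @param seed Integer RNG seed for this subject's streams.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(id = "s01",
                         info = subject_info(age = 25),
                         emotion_dists = NULL,
                         bb_models = NULL,
                         neutrality_inflation = 1,
                         seed = 1L) {
  if (is.null(emotion_dists)) {
    emotion_dists <- list(
      attentive = default_emotion_dist("attentive", neutrality_inflation),
      distracted = default_emotion_dist("distracted", neutrality_inflation)
    )
  }
  for (d in emotion_dists) {
    if (abs(sum(d) - 1) > 1e-8 || any(d < 0)) {
      stop("emotion distribution must be a probability vector",
           call. = FALSE)
    }
  }
  if (is.null(bb_models)) {
    bb_models <- list(
      attentive = list(mean_ms = 800, sd_ms = 15, ar = 0.5),
      distracted = list(mean_ms = 800, sd_ms = 50, ar = 0.5),
      rest = list(mean_ms = 800, sd_ms = 30, ar = 0.5)
    )
  }
  for (m in bb_models) {
    if (m$mean_ms <= 0 || m$sd_ms < 0 || abs(m$ar) >= 1) {
      stop("bb model needs mean_ms > 0, sd_ms >= 0, |ar| < 1",
           call. = FALSE)
    }
  }
  structure(
    list(id = id, info = info, emotion_dists = emotion_dists,
         bb_models = bb_models,
         neutrality_inflation = neutrality_inflation,
         seed = as.integer(seed)),
    class = "subject_spec"
  )
}

#' Simulate a facial-expression label stream
#'
#' Draws one label per sample, i.i.d. within a regime, from the regime's
#' emotion distribution, at the camera's nominal rate.
#'
#' @param schedule A [regime_schedule()].
#' @param spec A [subject_spec()].
#' @param rate_hz Sampling rate, default 2 (the classifier's frame rate).
#' @return An [emotion_stream()] covering the schedule; deterministic under
#'   the spec's seed.
#' @export
simulate_emotion_stream <- function(schedule, spec, rate_hz = 2) {
  total <- attr(schedule, "total_s")
  t <- seq(0, total - 1 / rate_hz, by = 1 / rate_hz)
  states <- .state_at(schedule, t)
  set.seed(spec$seed)
  labs <- character(length(t))
  for (st in unique(states)) {
    i <- states == st
    d <- spec$emotion_dists[[st]]
    labs[i] <- sample(names(d), sum(i), replace = TRUE, prob = d)
  }
  emotion_stream(t, labs)
}

#' Simulate a 1 Hz beat-to-beat / heart-rate stream
#'
#' Beat-to-beat intervals follow a regime-switching AR(1):
#' `BB(t) = mu_s + ar * (BB(t-1) - mu_s) + e(t)` with
#' `e(t) ~ N(0, sd_s * sqrt(1 - ar^2))`, so `sd_s` is the stationary
#' standard deviation within regime `s`. The autocorrelation makes
#' successive-difference statistics (RMSSD/SDSD) controllable separately
#' from SDNN. Heart rate is derived as `60000 / BB`.
#'
#' @param schedule A [regime_schedule()]; the states map to the spec's
#'   `bb_models` (use a single-segment schedule with the `rest` model for
#'   calibration baselines, see [simulate_baseline_stream()]).
#' @param spec A [subject_spec()].
#' @param model_for Optional function mapping a regime state to a model
#'   name in `spec$bb_models` (identity by default).
#' @return A [physio_stream()] at 1 Hz covering the schedule;
#'   deterministic under `spec$seed + 1`.
#' @export
simulate_bb_stream <- function(schedule, spec, model_for = identity) {
  total <- attr(schedule, "total_s")
  t <- 0:(ceiling(total) - 1)
  states <- .state_at(schedule, t)
  set.seed(spec$seed + 1L)
  bb <- numeric(length(t))
  for (k in seq_along(t)) {
    m <- spec$bb_models[[model_for(states[k])]]
    innov_sd <- m$sd_ms * sqrt(1 - m$ar^2)
    if (k == 1) {
      bb[k] <- m$mean_ms + stats::rnorm(1, 0, m$sd_ms)
    } else {
      bb[k] <- m$mean_ms + m$ar * (bb[k - 1] - m$mean_ms) +
        stats::rnorm(1, 0, innov_sd)
    }
  }
  bb <- pmax(bb, 300)  # physiological floor, keeps hr finite and positive
  physio_stream(t, 60000 / bb, bb)
}

#' Simulate a resting calibration baseline
#'
#' A single-regime recording drawn from the subject's `rest` BB model,
#' emulating the initial-condition estimation performed before a lecture.
#'
#' @param spec A [subject_spec()].
#' @param duration_s Baseline length in seconds, default 120.
#' @return A [physio_stream()]; deterministic under `spec$seed + 2`.
#' @export
simulate_baseline_stream <- function(spec, duration_s = 120) {
  sched <- regime_schedule(duration_s, "attentive")
  spec2 <- spec
  spec2$seed <- spec$seed + 1L  # simulate_bb_stream adds 1 -> seed + 2
  simulate_bb_stream(sched, spec2, model_for = function(...) "rest")
}

#' Simulate a full multi-subject classroom session
#'
#' Generates, for each subject, an independent 2 Hz emotion stream, a 1 Hz
#' BB/HR stream and a resting calibration baseline, all sharing the
#' classroom-level regime schedule (ground truth). Per-subject seeds are
#' derived deterministically from the master seed, so two runs with the
#' same master seed are identical down to the byte when written out.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param schedule A [regime_schedule()] shared by all subjects.
#' @param master_seed Integer master seed.
#' @param neutrality_inflation Passed to every subject's
#'   [default_emotion_dist()] (use > 1 for remote-lecture emulation).
#' @param baseline_s Calibration baseline length per subject, default 120.
#' @param mode Lecture mode tag recorded in the manifest.
#' @param dir If non-`NULL`, write the bundle there as canonical CSVs, a
#'   YAML manifest (`manifest.yaml`) and a ground-truth CSV (`truth.csv`).
#' @return A list of class `classroom_bundle`: `subjects` (each with `id`,
#'   `info`, `spec`, `emotion` raw 2 Hz stream, `physio`, `baseline`),
#'   `truth` (data frame `t_s`, `state`), `schedule`, `mode`.
#' @export
simulate_classroom <- function(n_subjects, schedule, master_seed = 1L,
                               neutrality_inflation = 1, baseline_s = 120,
                               mode = "in-presence", dir = NULL) {
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 2L, n_subjects)
  ages <- sample(21:35, n_subjects, replace = TRUE)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    spec <- subject_spec(
      id = sprintf("s%02d", i),
      info = subject_info(age = ages[i]),
      neutrality_inflation = neutrality_inflation,
      seed = seeds[i]
    )
    subjects[[i]] <- list(
      id = spec$id, info = spec$info, spec = spec,
      emotion = simulate_emotion_stream(schedule, spec),
      physio = simulate_bb_stream(schedule, spec),
      baseline = simulate_baseline_stream(spec, baseline_s)
    )
  }
  total <- attr(schedule, "total_s")
  truth <- data.frame(t_s = 0:(ceiling(total) - 1))
  truth$state <- .state_at(schedule, truth$t_s)
  bundle <- structure(
    list(subjects = subjects, truth = truth, schedule = schedule,
         mode = mode),
    class = "classroom_bundle"
  )
  if (!is.null(dir)) write_classroom(bundle, dir)
  bundle
}

#' Write a classroom bundle to disk
#'
#' @param bundle A `classroom_bundle` (see [simulate_classroom()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_classroom <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    session_s = attr(bundle$schedule, "total_s"),
    mode = bundle$mode,
    subjects = lapply(bundle$subjects, function(s) {
      em <- paste0(s$id, "_emotion.csv")
      ph <- paste0(s$id, "_physio.csv")
      bl <- paste0(s$id, "_baseline.csv")
      write_emotion_csv(s$emotion, file.path(dir, em))
      write_physio_csv(s$physio, file.path(dir, ph))
      write_physio_csv(s$baseline, file.path(dir, bl))
      list(id = s$id, emotion = em, physio = ph, baseline = bl,
           age = s$info$age)
    })
  )
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Score attention predictions against simulator ground truth
#'
#' Binarises the prediction (fraction > 0.5, or the `Attention` label) and
#' compares it with the true regime of the last second inside each window
#' (a prediction stamped at elapsed time `t` covers up to second `t - 1`).
#' The warm-up — the first `max(WS, 300)` seconds, where WS is inferred
#' from the first prediction — is excluded.
#'
#' @param predicted A `fraction_series` or [attention_array()].
#' @param truth Ground-truth data frame `(t_s, state)` from
#'   [simulate_classroom()].
#' @param warmup_s Seconds to exclude from the start; default
#'   `max(first prediction time, 300)`.
#' @return A list: `agreement` (percent), `confusion` (2x2 table of truth
#'   state vs predicted state), `n` (seconds scored).
#' @export
evaluate_recovery <- function(predicted, truth, warmup_s = NULL) {
  if (inherits(predicted, "attention_array")) {
    pred_attn <- predicted$label == "Attention"
  } else {
    pred_attn <- predicted$value > 0.5
  }
  t_pred <- predicted$t_s
  if (is.null(warmup_s)) warmup_s <- max(min(t_pred), 300)
  keep <- t_pred > warmup_s
  t_pred <- t_pred[keep]; pred_attn <- pred_attn[keep]
  if (length(t_pred) == 0) stop("no predictions after warm-up",
                                call. = FALSE)
  idx <- match(t_pred - 1L, truth$t_s)
  if (anyNA(idx)) stop("prediction times outside truth support",
                       call. = FALSE)
  true_attn <- truth$state[idx] == "attentive"
  pred_f <- factor(ifelse(pred_attn, "attentive", "distracted"),
                   levels = c("attentive", "distracted"))
  true_f <- factor(ifelse(true_attn, "attentive", "distracted"),
                   levels = c("attentive", "distracted"))
  list(
    agreement = 100 * mean(pred_attn == true_attn),
    confusion = table(truth = true_f, predicted = pred_f),
    n = length(t_pred)
  )
}
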