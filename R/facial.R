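# Facial route: 8-class labels -> active/passive moods -> windowed
# activation level normalised to WsNN -> binary Attention Array (AAfe).

#' Map an emotion label to its mood class
#'
#' Arousal-only grouping of the circumplex model: high-arousal labels are
#' `active` (anger, fear, happiness, surprise), low-arousal labels are
#' `passive` (contempt, disgust, sadness), and `neutrality` is `neutral` —
#' it sits at the origin of the arousal axis and is excluded from the
#' active/passive classification.
#'
#' @param label Character vector of emotion labels (see [emotion_labels]).
#' @return Character vector of `"active"`, `"passive"` or `"neutral"`.
#' @export
mood_of <- function(label) {
  bad <- which(!label %in% emotion_labels)
  if (length(bad) > 0) {
    stop("unknown emotion label ", sQuote(label[bad[1]]), call. = FALSE)
  }
  out <- rep("neutral", length(label))
  out[label %in% .active_labels] <- "active"
  out[label %in% .passive_labels] <- "passive"
  out
}

#' Parameters of the facial activation-level classifier
#'
#' @param ws_nn Normalisation constant for the activation level; the score of
#'   an all-active window. Default 300.
#' @param window_s Sliding-window length in samples at 1 Hz (the common
#'   window size WS). Default 100.
#' @param t_fe Attention threshold on the activation level; defaults to
#'   `ws_nn / 3`.
#' @param denominator Either `"nonneutral"` (default: normalise by the count
#'   of active + passive samples, so an all-active window always scores
#'   `ws_nn`) or `"window"` (normalise by the full window length, so neutral
#'   samples dilute the score).
#' @return A list of class `activation_params`.
#' @export
activation_params <- function(ws_nn = 300, window_s = 100,
                              t_fe = ws_nn / 3,
                              denominator = c("nonneutral", "window")) {
  denominator <- match.arg(denominator)
  stopifnot(ws_nn > 0, window_s >= 1, t_fe >= 0)
  structure(list(ws_nn = ws_nn, window_s = as.integer(window_s),
                 t_fe = t_fe, denominator = denominator),
            class = "activation_params")
}

#' Windowed activation level of a mood sequence
#'
#' Counts the active-mood readouts in the window and normalises the count to
#' `ws_nn`: `ws_nn` means an interval of only active moods, 0 an interval of
#' only passive moods. Neutral samples are excluded from both numerator and
#' denominator (under the default normalisation); a window with no
#' non-neutral sample scores 0.
#'
#' @param moods Character vector of mood classes (`"active"`, `"passive"`,
#'   `"neutral"`) of length `params$window_s`.
#' @param params An [activation_params()] object.
#' @return Activation score in `[0, ws_nn]`.
#' @export
activation_level <- function(moods, params = activation_params()) {
  if (length(moods) != params$window_s) {
    stop("window length ", length(moods), " != window_s ", params$window_s,
         call. = FALSE)
  }
  n_active <- sum(moods == "active")
  denom <- if (params$denominator == "window") length(moods)
           else n_active + sum(moods == "passive")
  if (denom == 0) return(0)
  params$ws_nn * n_active / denom
}

#' Facial Attention Array (AAfe)
#'
#' Slides a `window_s`-sample window over a 1 Hz emotion stream and
#' thresholds each window's activation level at `t_fe` (strict): windows
#' with activation strictly greater than `t_fe` are labelled `Attention`,
#' the rest `Distraction`. Output timestamps are elapsed seconds at the
#' window end, so the first label appears at `t = window_s`.
#'
#' @param stream A 1 Hz [emotion_stream()] (see
#'   [resample_emotion_to_1hz()]), at least `window_s` samples long.
#' @param params An [activation_params()] object.
#' @param subject Optional subject id recorded in the array.
#' @return An `attention_array` data frame with columns `t_s` and `label`
#'   (factor `Attention`/`Distraction`), of length
#'   `nrow(stream) - window_s + 1`; attributes `source = "facial"` and
#'   `subject`.
#' @export
facial_attention_array <- function(stream, params = activation_params(),
                                   subject = NA_character_) {
  n <- nrow(stream)
  ws <- params$window_s
  if (n < ws) {
    stop("stream length ", n, " shorter than window ", ws, call. = FALSE)
  }
  moods <- mood_of(stream$label)
  act <- cumsum(c(0, moods == "active"))
  pas <- cumsum(c(0, moods == "passive"))
  ends <- ws:n
  n_active  <- act[ends + 1L] - act[ends - ws + 1L]
  n_passive <- pas[ends + 1L] - pas[ends - ws + 1L]
  denom <- if (params$denominator == "window") rep(ws, length(ends))
           else n_active + n_passive
  score <- ifelse(denom == 0, 0, params$ws_nn * n_active / denom)
  attention_array(t_s = ends, attention = score > params$t_fe,
                  source = "facial", subject = subject)
}

#' Construct an Attention Array
#'
#' Per-second binary attention labels from one source for one subject.
#'
#' @param t_s Integer seconds (elapsed time at window end).
#' @param attention Logical: `TRUE` = Attention, `FALSE` = Distraction.
#' @param source `"facial"` or `"physio"`.
#' @param subject Subject id.
#' @return An `attention_array` data frame.
#' @export
attention_array <- function(t_s, attention, source, subject = NA_character_) {
  stopifnot(source %in% c("facial", "physio"))
  structure(
    data.frame(
      t_s = as.integer(t_s),
      label = factor(ifelse(attention, "Attention", "Distraction"),
                     levels = .attention_levels)
    ),
    source = source, subject = subject,
    class = c("attention_array", "data.frame")
  )
}
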