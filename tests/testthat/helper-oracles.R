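# Independent brute-force oracles: first-principles arithmetic only, no
# calls into the code paths they check.

naive_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}
naive_sdnn <- function(bb) naive_sd(bb)
naive_sdsd <- function(bb) naive_sd(bb[-1] - bb[-length(bb)])
naive_rmssd <- function(bb) {
  d <- bb[-1] - bb[-length(bb)]
  sqrt(sum(d^2) / length(d))
}
naive_pnn50 <- function(bb) {
  d <- bb[-1] - bb[-length(bb)]
  100 * sum(abs(d) > 50) / length(d)
}

# per-window recount of the facial activation score
naive_activation <- function(moods, ws_nn = 300) {
  a <- sum(moods == "active")
  p <- sum(moods == "passive")
  if (a + p == 0) 0 else ws_nn * a / (a + p)
}

# naive trailing moving average of width span over consecutive values
naive_trailing_mean <- function(v, span) {
  vapply(span:length(v), function(t) sum(v[(t - span + 1):t]) / span,
         numeric(1))
}

random_emotion_stream_1hz <- function(n, seed) {
  set.seed(seed)
  emotion_stream(0:(n - 1), sample(emotion_labels, n, replace = TRUE))
}

# constant-interval physio stream helper
flat_physio <- function(n, bb = 800) {
  physio_stream(0:(n - 1), rep(60000 / bb, n), rep(bb, n))
}

# minimal session with one subject built from in-memory streams
session_of <- function(emotion = NULL, physio = NULL, profile = NULL,
                       id = "s01") {
  list(subjects = list(list(id = id, emotion = emotion, physio = physio,
                            profile = profile)))
}

# prompt log matching the remote-campaign worked example: n_yes yes answers
# (n_late of them beyond max_rt) and n_no no answers
example_prompt_log <- function(n_yes = 20, n_no = 5, n_late = 2,
                               max_rt = 10) {
  n <- n_yes + n_no
  shown <- seq(0, by = 60, length.out = n)
  answer <- c(rep("yes", n_yes), rep("no", n_no))
  delta <- c(rep(max_rt + 5, n_late), rep(2, n - n_late))
  structure(
    data.frame(t_shown = shown, t_answered = shown + delta,
               answer = answer, delta_s = delta),
    class = c("prompt_log", "data.frame")
  )
}
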