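# Canonical on-disk dialects (the upstream tools define no schema, so the
# package fixes one): comma separator, dot decimal, UTF-8, mandatory header.
#   emotion stream : t_s,label
#   physio stream  : t_s,hr_bpm,bb_ms
#   prompt log     : t_shown,t_answered,answer,delta_s
# All timestamps are seconds since session start (0-based), never wall clock.

.fmt_num <- function(x) {
  # canonical number rendering so write(read(x)) is byte-stable
  formatC(x, format = "fg", digits = 15, width = 1)
}

.read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Construct an emotion stream object
#'
#' A data frame of timestamped facial-expression labels with class
#' `emotion_stream`. Timestamps must be strictly increasing and every
#' label must be one of [emotion_labels].
#'
#' @param t_s Numeric vector, seconds since session start (non-negative).
#' @param label Character vector of emotion labels.
#' @param filled_s Integer vector of seconds whose label was imputed
#'   (populated by [resample_emotion_to_1hz()]).
#' @return An `emotion_stream` data frame with columns `t_s`, `label` and
#'   attributes `rate_hz` (estimated nominal rate) and `filled_s`.
#' @export
emotion_stream <- function(t_s, label, filled_s = integer(0)) {
  t_s <- as.numeric(t_s)
  label <- as.character(label)
  if (length(t_s) != length(label)) {
    stop("t_s and label must have the same length", call. = FALSE)
  }
  bad <- which(!label %in% emotion_labels)
  if (length(bad) > 0) {
    stop("unknown emotion label ", sQuote(label[bad[1]]),
         " at row ", bad[1], call. = FALSE)
  }
  if (any(t_s < 0)) stop("timestamps must be non-negative", call. = FALSE)
  if (length(t_s) > 1 && any(diff(t_s) <= 0)) {
    i <- which(diff(t_s) <= 0)[1] + 1L
    stop("timestamps not strictly increasing at row ", i, call. = FALSE)
  }
  rate <- if (length(t_s) > 1) 1 / stats::median(diff(t_s)) else NA_real_
  structure(
    data.frame(t_s = t_s, label = label, stringsAsFactors = FALSE),
    rate_hz = rate, filled_s = as.integer(filled_s),
    class = c("emotion_stream", "data.frame")
  )
}

#' Read an emotion-label CSV stream
#'
#' Parses the canonical `t_s,label` dialect exported by the facial-expression
#' classifier front end (nominally 2 samples/s). Unknown labels and
#' non-monotone timestamps are errors, never silently coerced.
#'
#' @param path Path to a CSV file with header `t_s,label`.
#' @return An [emotion_stream()] sorted by time, with the nominal sampling
#'   rate estimated from the median inter-sample gap in attribute `rate_hz`.
#' @export
read_emotion_csv <- function(path) {
  df <- .read_csv_checked(path, c("t_s", "label"))
  t_s <- suppressWarnings(as.numeric(df$t_s))
  if (anyNA(t_s)) {
    stop("unparsable t_s at row ", which(is.na(t_s))[1], " of ", path,
         call. = FALSE)
  }
  emotion_stream(t_s, df$label)
}

#' Write an emotion stream in the canonical dialect
#'
#' @param stream An [emotion_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_emotion_csv <- function(stream, path) {
  lines <- c("t_s,label", paste0(.fmt_num(stream$t_s), ",", stream$label))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a physiological stream object
#'
#' 1 Hz samples of heart rate (beats/min) and beat-to-beat (BB/RR) interval
#' (ms) as exported by consumer smartwatches. Gaps larger than 1.5 s between
#' consecutive samples are recorded in the `gaps` attribute rather than
#' rejected.
#'
#' @param t_s Numeric, seconds since session start.
#' @param hr_bpm Positive numeric, heart rate.
#' @param bb_ms Positive numeric, beat-to-beat interval.
#' @return A `physio_stream` data frame; attribute `gaps` is a data frame
#'   `(from_s, to_s, gap_s)` of flagged acquisition gaps.
#' @export
physio_stream <- function(t_s, hr_bpm, bb_ms) {
  t_s <- as.numeric(t_s); hr_bpm <- as.numeric(hr_bpm)
  bb_ms <- as.numeric(bb_ms)
  n <- length(t_s)
  if (length(hr_bpm) != n || length(bb_ms) != n) {
    stop("t_s, hr_bpm, bb_ms must have equal length", call. = FALSE)
  }
  if (any(hr_bpm <= 0, na.rm = TRUE)) {
    stop("non-positive heart rate at row ", which(hr_bpm <= 0)[1],
         call. = FALSE)
  }
  if (any(bb_ms <= 0, na.rm = TRUE)) {
    stop("non-positive BB interval at row ", which(bb_ms <= 0)[1],
         call. = FALSE)
  }
  if (n > 1 && any(diff(t_s) <= 0)) {
    stop("timestamps not strictly increasing at row ",
         which(diff(t_s) <= 0)[1] + 1L, call. = FALSE)
  }
  gaps <- data.frame(from_s = numeric(0), to_s = numeric(0),
                     gap_s = numeric(0))
  if (n > 1) {
    d <- diff(t_s)
    gi <- which(d > 1.5)
    if (length(gi) > 0) {
      gaps <- data.frame(from_s = t_s[gi], to_s = t_s[gi + 1L], gap_s = d[gi])
    }
  }
  structure(
    data.frame(t_s = t_s, hr_bpm = hr_bpm, bb_ms = bb_ms),
    gaps = gaps,
    class = c("physio_stream", "data.frame")
  )
}

#' Read a smartwatch physiological log
#'
#' Parses the canonical `t_s,hr_bpm,bb_ms` dialect (1 Hz heart rate +
#' beat-to-beat interval). Acquisition gaps > 1.5 s are flagged in the
#' returned stream's `gaps` attribute.
#'
#' @param path Path to the log file.
#' @return A [physio_stream()].
#' @export
read_physio_log <- function(path) {
  df <- .read_csv_checked(path, c("t_s", "hr_bpm", "bb_ms"))
  physio_stream(df$t_s, df$hr_bpm, df$bb_ms)
}

#' Write a physiological stream in the canonical dialect
#'
#' @param stream A [physio_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physio_csv <- function(stream, path) {
  lines <- c("t_s,hr_bpm,bb_ms",
             paste(.fmt_num(stream$t_s), .fmt_num(stream$hr_bpm),
                   .fmt_num(stream$bb_ms), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a reaction-time prompt log
#'
#' Each row is one attention prompt: when the question window was shown,
#' when it was answered, the yes/no answer and the logged reaction time.
#' The reaction time is recomputed from the two timestamps; if the logged
#' value disagrees by more than 1 ms a warning is raised and the recomputed
#' value is used (timestamps are the primary record).
#'
#' @param path Path to the prompt-log CSV
#'   (`t_shown,t_answered,answer,delta_s`).
#' @return A data frame of class `prompt_log` with columns `t_shown`,
#'   `t_answered`, `answer` (`"yes"`/`"no"`) and `delta_s` (recomputed).
#'   An empty log (header only) yields zero rows, not an error.
#' @export
read_prompt_log <- function(path) {
  df <- .read_csv_checked(path, c("t_shown", "t_answered", "answer",
                                  "delta_s"))
  if (nrow(df) > 0) {
    df$answer <- tolower(as.character(df$answer))
    bad <- which(!df$answer %in% c("yes", "no"))
    if (length(bad) > 0) {
      stop("answer must be yes/no at row ", bad[1], " of ", path,
           call. = FALSE)
    }
    if (any(df$t_answered < df$t_shown)) {
      stop("answer precedes prompt at row ",
           which(df$t_answered < df$t_shown)[1], call. = FALSE)
    }
    delta <- df$t_answered - df$t_shown
    if (any(abs(delta - df$delta_s) > 1e-3)) {
      warning("logged delta_s disagrees with timestamps by > 1 ms; ",
              "recomputed values used", call. = FALSE)
    }
    df$delta_s <- delta
  }
  structure(df[c("t_shown", "t_answered", "answer", "delta_s")],
            class = c("prompt_log", "data.frame"))
}

#' Write a prompt log in the canonical dialect
#'
#' @param events A `prompt_log` data frame (see [read_prompt_log()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prompt_log <- function(events, path) {
  lines <- c("t_shown,t_answered,answer,delta_s",
             if (nrow(events) > 0)
               paste(.fmt_num(events$t_shown), .fmt_num(events$t_answered),
                     events$answer, .fmt_num(events$delta_s), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session manifest
#'
#' The YAML manifest binds subjects to their stream files and carries
#' session-level timing. Structure:
#' ```yaml
#' session_s: 3600
#' mode: in-presence      # or remote
#' subjects:
#'   - id: s01
#'     emotion: s01_emotion.csv     # optional
#'     physio: s01_physio.csv       # optional
#'     baseline: s01_baseline.csv   # optional calibration recording
#'     prompts: s01_prompts.csv     # optional
#' ```
#' Relative paths are resolved against the manifest's directory; every
#' referenced path must exist.
#'
#' @param path Path to the YAML manifest.
#' @return A list with elements `session_s`, `mode`, `subjects` (each subject
#'   a list with `id` and resolved file paths or `NULL`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  if (is.null(m$subjects) || length(m$subjects) == 0) {
    stop("manifest lists no subjects", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  m$subjects <- lapply(m$subjects, function(s) {
    if (is.null(s$id)) stop("manifest subject without id", call. = FALSE)
    for (k in c("emotion", "physio", "baseline", "prompts")) {
      if (!is.null(s[[k]])) {
        p <- s[[k]]
        if (!file.exists(p)) p <- file.path(base, s[[k]])
        if (!file.exists(p)) {
          stop("manifest path not resolvable for subject ", s$id, ": ",
               s[[k]], call. = FALSE)
        }
        s[[k]] <- p
      }
    }
    s
  })
  m$mode <- m$mode %||% "in-presence"
  m
}

#' Write a session manifest
#'
#' @param manifest A manifest list (see [read_manifest()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample an emotion stream to 1 Hz
#'
#' Aligns the nominally 2 Hz facial stream with the 1 Hz physiological
#' stream so a window size means the same number of samples for both
#' sources. The label of second `k` is the modal label among samples with
#' `k <= t < k+1`; ties go to the earliest sample in the second. Seconds
#' with no source sample (face not found, dropped frames) inherit
#' `neutrality` and are listed in the `filled_s` attribute.
#'
#' @param stream A non-empty [emotion_stream()].
#' @param duration_s Session length in seconds; defaults to
#'   `floor(max(t)) + 1` so the last observed second is covered.
#' @return A 1 Hz [emotion_stream()] with one sample per whole second
#'   (`t_s = 0, 1, ...`), of length `ceiling(duration_s)`.
#' @export
resample_emotion_to_1hz <- function(stream, duration_s = NULL) {
  if (nrow(stream) == 0) stop("empty emotion stream", call. = FALSE)
  if (is.null(duration_s)) duration_s <- floor(max(stream$t_s)) + 1
  n <- as.integer(ceiling(duration_s))
  sec <- floor(stream$t_s)
  out <- character(n)
  filled <- integer(0)
  idx <- split(seq_len(nrow(stream)), factor(sec, levels = 0:(n - 1)))
  for (k in seq_len(n)) {
    rows <- idx[[k]]
    if (length(rows) == 0) {
      out[k] <- "neutrality"
      filled <- c(filled, k - 1L)
    } else {
      labs <- stream$label[rows]
      tab <- table(labs)
      winners <- names(tab)[tab == max(tab)]
      # tie break: earliest sample in the second whose label is a winner
      out[k] <- labs[which(labs %in% winners)[1]]
    }
  }
  emotion_stream(0:(n - 1), out, filled_s = filled)
}
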