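# Classroom-level fusion: cross-subject averaging, 5-minute attention
# counter (Attention Behavior), Attention Gain per source, RMSE-driven
# window-size selection, merged session report. Per-subject binary arrays
# never leave this layer (aggregation is the privacy contract).

#' Average Attention Arrays across subjects
#'
#' Per-second arithmetic mean of the binary labels (`Attention` = 1,
#' `Distraction` = 0) over the subjects present at each second. All arrays
#' must come from the same source; the series is defined on the union of
#' the arrays' time supports, each second averaging the subjects observed
#' there.
#'
#' @param arrays A non-empty list of [attention_array()] objects sharing a
#'   source.
#' @return A `fraction_series` data frame with columns `t_s` and `value`
#'   (in `[0, 1]`); attributes `source` and `n_subjects`.
#' @export
average_across_subjects <- function(arrays) {
  if (length(arrays) == 0) stop("no attention arrays given", call. = FALSE)
  src <- unique(vapply(arrays, function(a) attr(a, "source"), character(1)))
  if (length(src) != 1) {
    stop("arrays mix sources: ", paste(src, collapse = ", "), call. = FALSE)
  }
  t_all <- sort(unique(unlist(lapply(arrays, `[[`, "t_s"))))
  num <- den <- numeric(length(t_all))
  for (a in arrays) {
    i <- match(a$t_s, t_all)
    num[i] <- num[i] + (a$label == "Attention")
    den[i] <- den[i] + 1
  }
  structure(
    data.frame(t_s = t_all, value = num / den),
    source = src, n_subjects = length(arrays),
    class = c("fraction_series", "data.frame")
  )
}

#' Attention Behavior: trailing 5-minute attention counter
#'
#' Smooths the fast-varying per-second classroom fraction with a trailing
#' moving average over the half-open window `(t - span_s, t]`, emitting one
#' value per second once a full window exists. With the default
#' `span_s = 300` the series effectively starts 5 minutes after the first
#' defined second.
#'
#' @param series A `fraction_series` (see [average_across_subjects()]) on
#'   consecutive seconds, longer than `span_s`.
#' @param span_s Filter span in seconds, default 300 (5 min).
#' @return An `attention_behavior` data frame with columns `t_s` and
#'   `value` in `[0, 1]`.
#' @export
attention_behavior <- function(series, span_s = 300) {
  n <- nrow(series)
  if (n <= span_s) {
    stop("series length ", n, " must exceed span ", span_s, call. = FALSE)
  }
  if (any(diff(series$t_s) != 1)) {
    stop("series must be on consecutive seconds", call. = FALSE)
  }
  cs <- cumsum(c(0, series$value))
  ends <- span_s:n
  ab <- (cs[ends + 1L] - cs[ends - span_s + 1L]) / span_s
  structure(
    data.frame(t_s = series$t_s[ends], value = ab),
    source = attr(series, "source"), span_s = span_s,
    class = c("attention_behavior", "data.frame")
  )
}

#' Attention Gain of a source
#'
#' Percentage of attention states detected over the whole session from the
#' raw (unfiltered by the 5-minute counter) classroom series:
#' `100 * mean(series)`.
#'
#' @param series A non-empty `fraction_series`.
#' @param binarize If `TRUE`, threshold the classroom fraction at 0.5
#'   before averaging (majority-of-class reading); default `FALSE` uses the
#'   raw fraction mean.
#' @return Attention Gain in percent, in `[0, 100]`.
#' @export
attention_gain <- function(series, binarize = FALSE) {
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  v <- if (binarize) as.numeric(series$value > 0.5) else series$value
  100 * mean(v)
}

#' RMSE between the two sources' Attention Gains
#'
#' With the reference taken as the mean of the two gains,
#' `m = (ag_p + ag_fe) / 2`, the root mean square error
#' `sqrt(((m - ag_p)^2 + (m - ag_fe)^2) / 2)` reduces algebraically to
#' `|ag_p - ag_fe| / 2`; the full formula is evaluated so the identity can
#' be verified independently.
#'
#' @param ag_p Physiological-source Attention Gain, percent in `[0, 100]`.
#' @param ag_fe Facial-source Attention Gain, percent in `[0, 100]`.
#' @return Non-negative RMSE, zero iff the gains are equal.
#' @export
rmse_sources <- function(ag_p, ag_fe) {
  if (ag_p < 0 || ag_p > 100 || ag_fe < 0 || ag_fe > 100) {
    stop("attention gains must lie in [0, 100]", call. = FALSE)
  }
  m <- (ag_p + ag_fe) / 2
  sqrt(((m - ag_p)^2 + (m - ag_fe)^2) / 2)
}

# Run both per-subject pipelines of a loaded session at one window size and
# return the classroom fraction series per source. A session is a list of
# subjects, each with (optionally) `emotion` (1 Hz emotion_stream),
# `physio` (physio_stream), `profile` (calibration_profile) and `id`.
.classroom_series <- function(session, ws, ws_nn = 300, t_fe = ws_nn / 3,
                              inner_len = 30, tp_factor = 1.5) {
  fe <- list(); ph <- list()
  for (s in session$subjects) {
    if (!is.null(s$emotion)) {
      p <- activation_params(ws_nn = ws_nn, window_s = ws, t_fe = t_fe)
      fe[[length(fe) + 1L]] <- facial_attention_array(s$emotion, p,
                                                      subject = s$id)
    }
    if (!is.null(s$physio) && !is.null(s$profile)) {
      # the inner HRV window cannot exceed the outer window it serves
      p <- ga_params(ws = ws, inner_len = min(inner_len, ws),
                     tp_factor = tp_factor)
      ph[[length(ph) + 1L]] <- physio_attention_array(s$physio, s$profile, p,
                                                      subject = s$id)
    }
  }
  list(
    facial = if (length(fe) > 0) average_across_subjects(fe) else NULL,
    physio = if (length(ph) > 0) average_across_subjects(ph) else NULL
  )
}

#' Select the window size minimising inter-source disagreement
#'
#' Reruns both pipelines (facial and physiological Attention Arrays,
#' classroom averaging, Attention Gain) for every candidate window size and
#' returns the candidate whose [rmse_sources()] between the two gains is
#' minimal, ties broken toward the smaller window. Candidates longer than
#' the shortest subject stream are skipped with a warning.
#'
#' @param session A loaded session: list with element `subjects`, each
#'   subject a list with `id`, `emotion` (1 Hz [emotion_stream()]),
#'   `physio` ([physio_stream()]) and `profile` ([calibrate()]d).
#' @param candidates Integer vector of at least 2 candidate window sizes
#'   (a single candidate is returned trivially).
#' @param ... Passed to the pipelines: `ws_nn`, `t_fe`, `inner_len`,
#'   `tp_factor`.
#' @return A list with `ws` (the selected size) and `table`, a data frame
#'   `(ws, ag_fe, ag_p, rmse)` over the evaluated candidates.
#' @export
select_window_size <- function(session,
                               candidates = c(25, 50, 75, 100, 150,
                                              200, 300),
                               ...) {
  candidates <- sort(unique(as.integer(candidates)))
  rows <- list()
  for (ws in candidates) {
    res <- tryCatch(.classroom_series(session, ws, ...),
                    error = function(e) e)
    if (inherits(res, "error") || is.null(res$facial) ||
        is.null(res$physio)) {
      warning("window size ", ws, " skipped: ",
              if (inherits(res, "error")) conditionMessage(res)
              else "a source is unavailable", call. = FALSE)
      next
    }
    ag_fe <- attention_gain(res$facial)
    ag_p <- attention_gain(res$physio)
    rows[[length(rows) + 1L]] <-
      data.frame(ws = ws, ag_fe = ag_fe, ag_p = ag_p,
                 rmse = rmse_sources(ag_p, ag_fe))
  }
  if (length(rows) == 0) {
    stop("no candidate window size is feasible for this session",
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  # candidates ascend, so which.min lands on the smallest tied window
  list(ws = tab$ws[which.min(tab$rmse)], table = tab)
}

#' Build the merged session report
#'
#' Runs both pipelines at the given window size and assembles the session
#' deliverable: per-source Attention Gain, their RMSE, the Attention
#' Behavior series, a neutrality-fraction diagnostic (share of neutrality
#' labels in the 1 Hz facial streams — a high value marks the facial source
#' as weakly predictive) and the subject count. Per-subject binary arrays
#' are deliberately absent: only aggregated quantities are reported.
#'
#' @param session A loaded session (see [select_window_size()]).
#' @param ws Window size in samples.
#' @param span_s Attention-counter span in seconds, default 300.
#' @param ... Passed to the pipelines (`ws_nn`, `t_fe`, `inner_len`,
#'   `tp_factor`).
#' @return A list of class `session_report` with elements `ws`, `span_s`,
#'   `n_subjects`, `redundant`, `ag_fe`, `ag_p`, `rmse`,
#'   `neutrality_fraction`, `ab_facial`, `ab_physio` and `params`.
#' @export
build_report <- function(session, ws = 100, span_s = 300, ...) {
  series <- .classroom_series(session, ws, ...)
  if (is.null(series$facial) && is.null(series$physio)) {
    stop("no usable source in session", call. = FALSE)
  }
  neut <- vapply(session$subjects, function(s) {
    if (is.null(s$emotion)) NA_real_ else mean(s$emotion$label == "neutrality")
  }, numeric(1))
  ab_of <- function(sr) {
    if (is.null(sr) || nrow(sr) <= span_s) NULL
    else {
      ab <- attention_behavior(sr, span_s)
      data.frame(t_s = ab$t_s, value = ab$value)
    }
  }
  ag_fe <- if (is.null(series$facial)) NA_real_
           else attention_gain(series$facial)
  ag_p <- if (is.null(series$physio)) NA_real_
          else attention_gain(series$physio)
  redundant <- !is.na(ag_fe) && !is.na(ag_p)
  structure(
    list(
      ws = as.integer(ws), span_s = as.integer(span_s),
      n_subjects = length(session$subjects),
      redundant = redundant,
      ag_fe = ag_fe, ag_p = ag_p,
      rmse = if (redundant) rmse_sources(ag_p, ag_fe) else NA_real_,
      neutrality_fraction = mean(neut, na.rm = TRUE),
      ab_facial = ab_of(series$facial),
      ab_physio = ab_of(series$physio),
      params = list(...)
    ),
    class = "session_report"
  )
}

#' Serialise / deserialise a session report
#'
#' Reports are written as canonical JSON (ordered keys, fixed numeric
#' rendering) so identical inputs and configuration give byte-identical
#' files.
#'
#' @param report A `session_report` (see [build_report()]).
#' @param path Output path.
#' @return `path` (write) or the report list (read).
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                           null = "null", dataframe = "columns",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("ab_facial", "ab_physio")) {
    if (!is.null(rep[[k]])) rep[[k]] <- as.data.frame(rep[[k]])
  }
  structure(rep, class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session report (", x$n_subjects, " subjects, WS = ", x$ws,
      ", span = ", x$span_s, " s)\n", sep = "")
  cat(sprintf("  AG facial : %s\n",
              if (is.na(x$ag_fe)) "unavailable"
              else sprintf("%.2f%%", x$ag_fe)))
  cat(sprintf("  AG physio : %s\n",
              if (is.na(x$ag_p)) "unavailable"
              else sprintf("%.2f%%", x$ag_p)))
  if (!is.na(x$rmse)) {
    cat(sprintf("  RMSE      : %.4f\n", x$rmse))
  } else {
    cat("  RMSE      : unavailable (no redundancy)\n")
  }
  cat(sprintf("  neutrality fraction: %.3f\n", x$neutrality_fraction))
  invisible(x)
}
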