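# Self-report baseline: reaction-time prompt logs -> reclassified yes/no
# counts -> self-assessed attention level.

#' Reclassify prompt answers by reaction time
#'
#' Affirmative answers given with an excessive reaction time are not
#' credible evidence of attention: every `yes` whose reaction time strictly
#' exceeds `max_rt` is counted as a `no`. The attention level is the share
#' of effective `yes` answers among all prompts.
#'
#' @param events A `prompt_log` data frame (see [read_prompt_log()]) with at
#'   least one row.
#' @param max_rt Reaction-time limit in seconds, positive. No limit is
#'   empirically established; the default 10 s is an arbitrary but
#'   conservative upper bound for reading and clicking a two-button prompt.
#' @return A list of class `selfreport_summary`: `n_prompts`, `n_yes_raw`,
#'   `n_no_raw`, `n_yes_reclassified`, `n_yes_effective`, `n_no_effective`,
#'   `attention_level` (percent), `max_rt`.
#' @export
reclassify <- function(events, max_rt = 10) {
  if (max_rt <= 0) stop("max_rt must be positive", call. = FALSE)
  if (nrow(events) == 0) stop("empty prompt log", call. = FALSE)
  yes <- events$answer == "yes"
  late_yes <- yes & events$delta_s > max_rt
  n <- nrow(events)
  n_yes_eff <- sum(yes) - sum(late_yes)
  structure(
    list(
      n_prompts = n,
      n_yes_raw = sum(yes),
      n_no_raw = sum(!yes),
      n_yes_reclassified = sum(late_yes),
      n_yes_effective = n_yes_eff,
      n_no_effective = n - n_yes_eff,
      attention_level = 100 * n_yes_eff / n,
      max_rt = max_rt
    ),
    class = "selfreport_summary"
  )
}

#' Pool self-report summaries across volunteers
#'
#' Prompt-weighted pooled attention level: the effective yes counts and
#' prompt counts are summed before the ratio is taken, so volunteers with
#' more prompts weigh more.
#'
#' @param summaries A non-empty list of `selfreport_summary` objects.
#' @return Pooled attention level in percent.
#' @export
pooled_attention_level <- function(summaries) {
  if (length(summaries) == 0) stop("no summaries to pool", call. = FALSE)
  yes <- sum(vapply(summaries, `[[`, numeric(1), "n_yes_effective"))
  n <- sum(vapply(summaries, `[[`, numeric(1), "n_prompts"))
  100 * yes / n
}

#' @export
print.selfreport_summary <- function(x, ...) {
  cat(sprintf(
    "Self-report: %d prompts, %d yes (%d reclassified as no at rt > %g s)\n",
    x$n_prompts, x$n_yes_raw, x$n_yes_reclassified, x$max_rt))
  cat(sprintf("  attention level: %.1f%%\n", x$attention_level))
  invisible(x)
}
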