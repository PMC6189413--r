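#' Reference summary tables from a two-experiment dyadic Simon study
#'
#' Published-style group summary tables of a two-experiment go/no-go Simon
#' study in which dyads performed the task individually and jointly under
#' cooperative (experiment 1) or competitive (experiment 2) instructions:
#' mean correct RTs (ms) by condition and correspondence, and by trial
#' transition, previous-trial and current-trial correspondence. These cells
#' serve as worked-example inputs: [transition_table()] recomputes the
#' rowwise sequential effects from them, and [marginal_mean()] their
#' marginal means. One SD cell of the competitive transition table is not
#' reliably legible in the source material and is left missing; SDs play no
#' computational role here.
#'
#' @return A list with data frames `condition_means` (experiment,
#'   condition, correspondence, mean_ms, sd_ms) and `transitions`
#'   (experiment, transition, prev_correspondence, correspondence, mean_ms,
#'   sd_ms).
#' @examples
#' ref <- reference_summary_tables()
#' subset(ref$condition_means, experiment == "cooperative")
#' @export
reference_summary_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "jointcoord",
                                  mustWork = TRUE)
  list(
    condition_means = read.csv(path("reference_condition_means.csv"),
                               stringsAsFactors = FALSE),
    transitions = read.csv(path("reference_transition_means.csv"),
                           stringsAsFactors = FALSE))
}

#' Transition table from reference cells
#'
#' Convenience: builds a [transition_table()] (with its derived sequential
#' effect column) from one experiment's reference transition cells.
#'
#' @param experiment `"cooperative"` or `"competitive"`.
#' @return A `transition_table`.
#' @examples
#' reference_transition_table("cooperative")$se  # 24 -9 6 4
#' @export
reference_transition_table <- function(experiment = c("cooperative",
                                                      "competitive")) {
  experiment <- match.arg(experiment)
  tr <- reference_summary_tables()$transitions
  tr <- tr[tr$experiment == experiment, ]
  wide <- merge(tr[tr$correspondence == "C",
                   c("transition", "prev_correspondence", "mean_ms")],
                tr[tr$correspondence == "NC",
                   c("transition", "prev_correspondence", "mean_ms")],
                by = c("transition", "prev_correspondence"),
                suffixes = c("_C", "_NC"))
  transition_table(data.frame(transition = wide$transition,
                              prev_correspondence = wide$prev_correspondence,
                              C = wide$mean_ms_C, NC = wide$mean_ms_NC,
                              stringsAsFactors = FALSE))
}

#' Effect table from reference cells
#'
#' @param experiment `"cooperative"` or `"competitive"`.
#' @return An `effect_table`-shaped data frame usable with [simon_effect()]
#'   and [marginal_mean()].
#' @examples
#' simon_effect(reference_effect_table("cooperative"), "joint")  # 10
#' @export
reference_effect_table <- function(experiment = c("cooperative",
                                                  "competitive")) {
  experiment <- match.arg(experiment)
  cm <- reference_summary_tables()$condition_means
  cm <- cm[cm$experiment == experiment, ]
  out <- data.frame(condition = cm$condition, correspondence = cm$correspondence,
                    mean_rt = cm$mean_ms, sd_rt = cm$sd_ms,
                    stringsAsFactors = FALSE)
  structure(out, class = c("effect_table", "data.frame"))
}
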