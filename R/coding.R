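## Trial coding: correspondence, trial transitions, the filtering rules for
## mean/sequential RT analyses, and Tukey-fence participant exclusion.

#' Code spatial correspondence of stimulus and response
#'
#' A trial is corresponding (`"C"`) when the stimulus appears on the same
#' side as the response key, non-corresponding (`"NC"`) otherwise.
#'
#' @param stimulus_side,response_side Character vectors with values
#'   `"left"`/`"right"`. A `response_side` of `"none"` is an error: only
#'   response-defined trials can be coded from the responder's mapping.
#' @return Character vector of `"C"`/`"NC"`.
#' @examples
#' code_correspondence(c("left", "left"), c("left", "right"))
#' @export
code_correspondence <- function(stimulus_side, response_side) {
  ok <- c("left", "right")
  if (!all(stimulus_side %in% ok)) {
    stop("stimulus_side must be 'left' or 'right'", call. = FALSE)
  }
  if (!all(response_side %in% ok)) {
    stop("response_side must be 'left' or 'right' (trials without a defined ",
         "response side cannot be correspondence-coded)", call. = FALSE)
  }
  ifelse(stimulus_side == response_side, "C", "NC")
}

#' Infer each agent's response-key side from a trial log
#'
#' The key side of an agent is read off their correct responses. Agents that
#' never responded (e.g. the absent partner role in an individual session)
#' are assigned the side opposite to their pair mate.
#'
#' @param trials Trial-log data frame.
#' @return Named character vector mapping agent id to `"left"`/`"right"`.
#' @export
infer_agent_sides <- function(trials) {
  resp <- trials[trials$accuracy == "correct" & trials$response_side != "none", ]
  sides <- vapply(split(resp$response_side, resp$required_responder), function(s) {
    names(sort(table(s), decreasing = TRUE))[1]
  }, character(1))
  all_agents <- unique(c(trials$required_responder, trials$agent_id))
  missing <- setdiff(all_agents, names(sides))
  for (a in missing) {
    mate <- trials$pair_id[match(a, trials$required_responder)]
    mate_sides <- sides[names(sides) %in%
                          unique(trials$required_responder[trials$pair_id == mate])]
    sides[a] <- if (length(mate_sides)) {
      if (mate_sides[1] == "left") "right" else "left"
    } else "right"
  }
  sides
}

#' Code trial transitions from one agent's perspective
#'
#' Takes the ordered trial stream of a single session and annotates it from
#' the perspective of `agent_id`: the pair-level correspondence of every
#' trial (coded from the required responder's key side, regardless of who
#' actually responded), whether each trial is a go trial for the agent, the
#' trial transition (`"Go/go"` if trial n-1 required this agent's response,
#' `"Nogo/go"` otherwise, `"undefined"` on the first trial of each block),
#' the correspondence of the preceding trial, and the preceding trial's
#' accuracy (used by the sequential filter).
#'
#' @param session Data frame with the rows of one session, ordered by
#'   `trial_index` (strictly increasing, or an error is raised).
#' @param agent_id The perspective agent.
#' @param sides Optional named vector of agent key sides; inferred with
#'   [infer_agent_sides()] when `NULL`.
#' @return The session with columns `correspondence`, `is_go`, `transition`,
#'   `prev_correspondence`, `prev_accuracy` added.
#' @export
code_transitions <- function(session, agent_id, sides = NULL) {
  if (is.unsorted(session$trial_index, strictly = TRUE)) {
    stop("session trials must be strictly ordered by trial_index", call. = FALSE)
  }
  if (is.null(sides)) sides <- infer_agent_sides(session)
  resp_side <- unname(sides[session$required_responder])
  if (anyNA(resp_side)) {
    stop("no key side known for required responder(s): ",
         paste(unique(session$required_responder[is.na(resp_side)]),
               collapse = ", "), call. = FALSE)
  }
  out <- session
  out$correspondence <- code_correspondence(session$stimulus_side, resp_side)
  out$is_go <- session$required_responder == agent_id

  n <- nrow(out)
  first_of_block <- c(TRUE, out$block[-1] != out$block[-n])
  prev_resp <- c(NA_character_, out$required_responder[-n])
  out$transition <- ifelse(first_of_block, "undefined",
                           ifelse(prev_resp == agent_id, "Go/go", "Nogo/go"))
  out$prev_correspondence <- ifelse(first_of_block, "undefined",
                                    c(NA_character_, out$correspondence[-n]))
  out$prev_accuracy <- ifelse(first_of_block, NA_character_,
                              c(NA_character_, out$accuracy[-n]))
  out
}

#' Code every session of a trial log from its responders' perspectives
#'
#' Convenience wrapper: splits a trial log by session, codes each session
#' once per participating agent, and stacks the participants' go trials.
#' The resulting `participant` column identifies the perspective agent.
#'
#' @param trials Trial-log data frame (possibly many sessions/pairs).
#' @param go_only If `TRUE` (default) keep only each perspective agent's go
#'   trials; otherwise keep full coded streams.
#' @return Coded data frame with a `participant` column.
#' @export
code_experiment <- function(trials, go_only = TRUE) {
  sides <- infer_agent_sides(trials)
  pieces <- lapply(split(trials, trials$session_id), function(sess) {
    sess <- sess[order(sess$trial_index), ]
    agents <- unique(sess$agent_id)
    # joint sessions carry both agents; individual sessions a single owner
    do.call(rbind, lapply(agents, function(a) {
      coded <- code_transitions(sess, a, sides)
      coded$participant <- a
      if (go_only) coded[coded$is_go, ] else coded
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Keep correct go-trial responses for mean-RT analyses
#'
#' @param coded Coded trials (see [code_transitions()]).
#' @return The subset of correct go trials of the perspective agent; a
#'   warning is issued when nothing survives.
#' @export
filter_for_rt_analysis <- function(coded) {
  out <- coded[coded$is_go & coded$accuracy == "correct", , drop = FALSE]
  if (nrow(out) == 0L) warning("no correct go trials retained", call. = FALSE)
  out
}

#' Filtering rule for sequential (trial-transition) analyses
#'
#' Removes, on top of [filter_for_rt_analysis()], the first trial of each
#' block and any trial immediately preceded by an incorrect response. The
#' preceding trial is taken from the pair's full trial stream, so in a joint
#' session an error by either member poisons the following trial.
#'
#' @param coded Coded trials with transition fields.
#' @return Subset suitable for transition tables.
#' @export
filter_for_sequential_analysis <- function(coded) {
  out <- filter_for_rt_analysis(coded)
  keep <- out$transition != "undefined" &
    !is.na(out$prev_accuracy) & out$prev_accuracy == "correct"
  out[keep, , drop = FALSE]
}

#' Tukey-fence outlier flags on error counts
#'
#' Flags participants whose number of erroneous trials falls outside
#' `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed by linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param error_counts Numeric vector (optionally named by participant) of
#'   per-participant error counts; at least 4 values are required for the
#'   quartiles to be stable.
#' @param k Fence multiplier (default 1.5).
#' @param side Flag on both fences (default) or on the upper fence only.
#'   Error screening in practice targets excessive error counts: with small
#'   discrete counts the IQR can collapse and the lower fence would flag
#'   highly accurate participants, so [exclude_pairs()] uses `"upper"`.
#' @return Logical vector of flags, named like the input.
#' @examples
#' tukey_error_outliers(c(1, 1, 2, 2, 3, 30))
#' @export
tukey_error_outliers <- function(error_counts, k = 1.5,
                                 side = c("both", "upper")) {
  side <- match.arg(side)
  if (length(error_counts) < 4L) {
    stop("need at least 4 participants for stable quartiles", call. = FALSE)
  }
  if (any(error_counts < 0)) stop("error counts must be >= 0", call. = FALSE)
  q <- quantile(error_counts, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  flags <- error_counts > q[2] + k * iqr
  if (side == "both") flags <- flags | error_counts < q[1] - k * iqr
  names(flags) <- names(error_counts)
  flags
}

#' Pair-level exclusion from per-condition error counts
#'
#' Applies [tukey_error_outliers()] to each condition's per-participant
#' error counts (errors and misses pooled) and excludes a whole pair when
#' either member is flagged in either condition.
#'
#' @param trials Trial-log data frame.
#' @param k Fence multiplier.
#' @param per_condition Apply the fences within each condition separately
#'   (default) or on pooled counts.
#' @return A list with `flags` (per participant x condition), and
#'   `excluded_pairs` (character vector of pair ids).
#' @export
exclude_pairs <- function(trials, k = 1.5, per_condition = TRUE) {
  go <- trials[trials$required_responder == trials$agent_id, , drop = FALSE]
  is_err <- go$accuracy %in% c("error", "miss")
  key <- if (per_condition) {
    interaction(go$required_responder, go$condition, drop = TRUE)
  } else {
    factor(go$required_responder)
  }
  counts <- tapply(is_err, key, sum)
  groups <- if (per_condition) {
    sub("^.*\\.", "", names(counts))
  } else rep("pooled", length(counts))
  flags <- unlist(lapply(unique(groups), function(g) {
    tukey_error_outliers(counts[groups == g], k = k, side = "upper")
  }))
  flagged_agents <- sub("\\.(individual|joint)$", "", names(flags)[flags])
  pair_of <- trials$pair_id[match(unique(trials$required_responder),
                                  trials$required_responder)]
  names(pair_of) <- unique(trials$required_responder)
  excluded <- unique(unname(pair_of[unique(flagged_agents)]))
  list(flags = flags, excluded_pairs = excluded[!is.na(excluded)])
}
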