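## Descriptive decompositions of the (joint) Simon effect: condition x
## correspondence mean tables, quartile-bin distributional analysis, and the
## 2x2x2 trial-transition table. All group-level cells use two-stage
## averaging: participant cell means first, then an unweighted average
## across participants.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# participant-level cell means for arbitrary grouping columns
participant_cell_means <- function(trials, by) {
  stopifnot(all(c("participant", "rt_ms", by) %in% names(trials)))
  f <- lapply(trials[c("participant", by)], factor)
  ag <- aggregate(trials$rt_ms, f, mean)
  names(ag) <- c("participant", by, "mean_rt")
  ag$n_trials <- aggregate(trials$rt_ms, f, length)$x
  ag
}

#' Condition x correspondence mean RT table
#'
#' Computes the classical Simon-effect summary: for every participant the
#' mean correct RT in each condition x correspondence cell, then the
#' unweighted average and SD of those participant means across participants.
#'
#' @param trials Correct go trials with `participant`, `condition`,
#'   `correspondence` and `rt_ms` columns (see [filter_for_rt_analysis()]).
#' @return An `effect_table`: data frame with columns `condition`,
#'   `correspondence`, `mean_rt`, `sd_rt`, `n_participants`; the
#'   participant-level cell means are kept in `attr(, "participants")` for
#'   inference.
#' @examples
#' trials <- data.frame(participant = rep(c("a", "b"), each = 4),
#'                      condition = "joint",
#'                      correspondence = rep(c("C", "NC"), 4),
#'                      rt_ms = c(300, 320, 310, 330, 290, 300, 310, 320))
#' condition_means(trials)
#' @export
condition_means <- function(trials) {
  pm <- participant_cell_means(trials, c("condition", "correspondence"))
  # every participant must contribute to both correspondence cells of each
  # condition they appear in
  grid <- unique(trials[c("participant", "condition")])
  for (i in seq_len(nrow(grid))) {
    for (corr in c("C", "NC")) {
      hit <- pm$participant == grid$participant[i] &
        pm$condition == grid$condition[i] & pm$correspondence == corr
      if (!any(hit)) {
        stop(sprintf("participant '%s' has no trials in cell %s/%s",
                     grid$participant[i], grid$condition[i], corr),
             call. = FALSE)
      }
    }
  }
  grp <- aggregate(pm$mean_rt,
                   list(condition = pm$condition,
                        correspondence = pm$correspondence),
                   function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(condition = as.character(grp$condition),
                    correspondence = as.character(grp$correspondence),
                    mean_rt = grp$x[, "mean"],
                    sd_rt = grp$x[, "sd"],
                    n_participants = grp$x[, "n"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$correspondence), ]
  rownames(out) <- NULL
  structure(out, participants = pm, class = c("effect_table", "data.frame"))
}

#' Simon effect from an effect table
#'
#' The correspondence effect NC - C (positive = standard effect) for one
#' condition of an [condition_means()] table.
#'
#' @param table An `effect_table` or a data frame with `condition`,
#'   `correspondence` and `mean_rt` columns.
#' @param condition Which condition's effect to return.
#' @return The effect in ms.
#' @export
simon_effect <- function(table, condition) {
  nc <- table$mean_rt[table$condition == condition & table$correspondence == "NC"]
  cc <- table$mean_rt[table$condition == condition & table$correspondence == "C"]
  if (length(nc) != 1L || length(cc) != 1L) {
    stop("condition '", condition, "' must have exactly one C and one NC cell",
         call. = FALSE)
  }
  nc - cc
}

#' Per-participant Simon effects
#'
#' @param table An `effect_table` from [condition_means()].
#' @return Data frame with `participant`, `condition`, `simon_effect` (ms).
#' @export
simon_effect_by_participant <- function(table) {
  pm <- attr(table, "participants")
  if (is.null(pm)) stop("table carries no participant-level means", call. = FALSE)
  wide <- merge(pm[pm$correspondence == "NC", c("participant", "condition", "mean_rt")],
                pm[pm$correspondence == "C", c("participant", "condition", "mean_rt")],
                by = c("participant", "condition"), suffixes = c("_nc", "_c"))
  data.frame(participant = as.character(wide$participant),
             condition = as.character(wide$condition),
             simon_effect = wide$mean_rt_nc - wide$mean_rt_c,
             stringsAsFactors = FALSE)
}

# split n sorted values into n_bins equal-count bins, extras to earliest bins
bin_assignments <- function(n, n_bins) {
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_bins), times = sizes)
}

#' Quartile-bin (Vincentized) RT means
#'
#' Distributional analysis of the correspondence effect: within each
#' participant x condition x correspondence cell, RTs are rank ordered and
#' split into `n_bins` equal-count bins (remainders go to the earliest
#' bins); bin means are then averaged across participants with equal
#' weights.
#'
#' @param trials Correct go trials (as for [condition_means()]).
#' @param n_bins Number of bins (default 4: quartiles).
#' @param by_correspondence Bin within correspondence (default) or pool C
#'   and NC before binning, in which case the output has
#'   `correspondence = "all"`.
#' @return A `quartile_table`: data frame with `condition`,
#'   `correspondence`, `bin`, `mean_rt`, plus participant-level bin means in
#'   `attr(, "participants")`.
#' @export
quartile_bin_means <- function(trials, n_bins = 4L, by_correspondence = TRUE) {
  by <- if (by_correspondence) c("condition", "correspondence") else "condition"
  df <- trials
  if (!by_correspondence) df$correspondence <- "all"
  key <- interaction(df$participant, df$condition, df$correspondence, drop = TRUE)
  pieces <- lapply(split(df, key), function(cell) {
    if (nrow(cell) < n_bins) {
      stop(sprintf("cell %s/%s/%s has fewer than %d RTs",
                   cell$participant[1], cell$condition[1],
                   cell$correspondence[1], n_bins), call. = FALSE)
    }
    rt <- sort(cell$rt_ms)
    bins <- bin_assignments(length(rt), n_bins)
    data.frame(participant = cell$participant[1],
               condition = cell$condition[1],
               correspondence = cell$correspondence[1],
               bin = seq_len(n_bins),
               mean_rt = as.numeric(tapply(rt, bins, mean)),
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, pieces)
  rownames(pm) <- NULL
  grp <- aggregate(pm$mean_rt,
                   list(condition = pm$condition,
                        correspondence = pm$correspondence, bin = pm$bin),
                   mean)
  out <- data.frame(condition = as.character(grp$condition),
                    correspondence = as.character(grp$correspondence),
                    bin = grp$bin, mean_rt = grp$x, stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$correspondence, out$bin), ]
  rownames(out) <- NULL
  structure(out, participants = pm, class = c("quartile_table", "data.frame"))
}

#' Build a trial-transition table from cell means
#'
#' Assembles the 2 (transition) x 2 (previous correspondence) x 2 (current
#' correspondence) summary and derives the per-row sequential effect
#' `se = NC - C`. Used both by [sequential_effect_table()] and directly on
#' externally reported cell means.
#'
#' @param cells Data frame with columns `transition`, `prev_correspondence`,
#'   `C` and `NC` (mean RT in ms).
#' @return A `transition_table` with an added `se` column.
#' @examples
#' transition_table(data.frame(transition = "Nogo/go",
#'                             prev_correspondence = c("C", "NC"),
#'                             C = c(334, 350), NC = c(358, 341)))
#' @export
transition_table <- function(cells) {
  stopifnot(all(c("transition", "prev_correspondence", "C", "NC") %in% names(cells)))
  cells$se <- cells$NC - cells$C
  ord <- order(factor(cells$transition, levels = c("Nogo/go", "Go/go")),
               factor(cells$prev_correspondence, levels = c("C", "NC")))
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, class = c("transition_table", "data.frame"))
}

#' Sequential-effect (trial-transition) table
#'
#' Two-stage mean RTs as a function of trial transition, previous-trial
#' correspondence and current-trial correspondence, with the rowwise
#' sequential effect `se = NC - C`. Inputs should be filtered with
#' [filter_for_sequential_analysis()].
#'
#' @param trials Sequential-filtered correct go trials carrying
#'   `transition` and `prev_correspondence` codes.
#' @return A `transition_table` with columns `transition`,
#'   `prev_correspondence`, `C`, `NC`, `sd_C`, `sd_NC`, `se`; participant
#'   cell means in `attr(, "participants")`.
#' @export
sequential_effect_table <- function(trials) {
  pm <- participant_cell_means(trials,
                               c("transition", "prev_correspondence",
                                 "correspondence"))
  combos <- expand.grid(transition = c("Nogo/go", "Go/go"),
                        prev_correspondence = c("C", "NC"),
                        correspondence = c("C", "NC"),
                        stringsAsFactors = FALSE)
  cell_stats <- lapply(seq_len(nrow(combos)), function(i) {
    v <- pm$mean_rt[pm$transition == combos$transition[i] &
                      pm$prev_correspondence == combos$prev_correspondence[i] &
                      pm$correspondence == combos$correspondence[i]]
    if (length(v) == 0L) {
      stop(sprintf("empty transition cell %s / n-1 %s / n %s",
                   combos$transition[i], combos$prev_correspondence[i],
                   combos$correspondence[i]), call. = FALSE)
    }
    c(mean = mean(v), sd = sd(v))
  })
  combos$mean <- vapply(cell_stats, `[[`, numeric(1), "mean")
  combos$sd <- vapply(cell_stats, `[[`, numeric(1), "sd")
  wide <- merge(combos[combos$correspondence == "C",
                       c("transition", "prev_correspondence", "mean", "sd")],
                combos[combos$correspondence == "NC",
                       c("transition", "prev_correspondence", "mean", "sd")],
                by = c("transition", "prev_correspondence"),
                suffixes = c("_C", "_NC"))
  out <- transition_table(data.frame(transition = wide$transition,
                                     prev_correspondence = wide$prev_correspondence,
                                     C = wide$mean_C, NC = wide$mean_NC,
                                     sd_C = wide$sd_C, sd_NC = wide$sd_NC,
                                     stringsAsFactors = FALSE))
  attr(out, "participants") <- pm
  out
}

#' Equal-weight marginal mean of table cells
#'
#' Averages the mean-RT cells of an [condition_means()] or
#' [transition_table()] object matching the given factor levels, with equal
#' weight per cell — the convention used for marginal means reported
#' alongside such tables.
#'
#' @param table An `effect_table` or `transition_table`.
#' @param condition,correspondence,transition,prev_correspondence Optional
#'   level filters; omitted factors are averaged over.
#' @return The marginal mean in ms.
#' @export
marginal_mean <- function(table, condition = NULL, correspondence = NULL,
                          transition = NULL, prev_correspondence = NULL) {
  if (inherits(table, "transition_table")) {
    rows <- rep(TRUE, nrow(table))
    if (!is.null(transition)) rows <- rows & table$transition == transition
    if (!is.null(prev_correspondence))
      rows <- rows & table$prev_correspondence == prev_correspondence
    cells <- c(if (is.null(correspondence) || correspondence == "C")
      table$C[rows],
      if (is.null(correspondence) || correspondence == "NC")
        table$NC[rows])
  } else {
    rows <- rep(TRUE, nrow(table))
    if (!is.null(condition)) rows <- rows & table$condition == condition
    if (!is.null(correspondence))
      rows <- rows & table$correspondence == correspondence
    cells <- table$mean_rt[rows]
  }
  if (length(cells) == 0L) stop("no cells match the requested margin", call. = FALSE)
  mean(cells)
}

#' @export
print.effect_table <- function(x, digits = 0, ...) {
  cat("Mean correct RT (ms) by condition and correspondence\n")
  y <- as.data.frame(x)
  y$mean_rt <- round_half_away(y$mean_rt * 10^digits) / 10^digits
  y$sd_rt <- round(y$sd_rt, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.transition_table <- function(x, digits = 0, ...) {
  cat("Mean correct RT (ms) by transition, n-1 and n correspondence\n")
  y <- as.data.frame(x)
  for (col in intersect(c("C", "NC", "se"), names(y))) {
    y[[col]] <- round_half_away(y[[col]] * 10^digits) / 10^digits
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Quartile-curve plot
#'
#' Base-graphics plot of bin means per correspondence level, one panel per
#' condition.
#'
#' @param x A `quartile_table`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.quartile_table <- function(x, ...) {
  conds <- unique(x$condition)
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  for (cond in conds) {
    sub <- x[x$condition == cond, ]
    m <- tapply(sub$mean_rt, list(sub$bin, sub$correspondence), mean)
    graphics::matplot(as.numeric(rownames(m)), m, type = "b", pch = 19,
                      lty = 1, xlab = "RT quartile", ylab = "mean RT (ms)",
                      main = cond, ...)
    graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
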