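## Trial-log CSV dialect, run configuration, and the pipeline driver that
## ties the stages together: filtering -> effect tables -> quartile tables ->
## transition tables -> coordination indices -> tests -> model comparison.

trial_log_columns <- c("pair_id", "agent_id", "condition", "design", "block",
                       "trial_index", "stimulus_side", "stimulus_color",
                       "required_responder", "response_side", "rt_ms",
                       "accuracy")

#' Write a trial log as CSV
#'
#' Emits the canonical trial-log dialect: UTF-8 CSV, one row per trial,
#' missing RTs as empty fields, 1-based block/trial indices. Extra columns
#' (e.g. `session_id`) are preserved after the dialect columns.
#'
#' @param trials Trial-log data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  missing_cols <- setdiff(trial_log_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(trials), trial_log_columns)
  out <- trials[c(trial_log_columns, extra)]
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads the trial-log CSV dialect (see [write_trial_log()]), validates its
#' structural invariants, and returns the trials grouped into sessions. A
#' `session_id` column is derived when absent (pair x condition, plus the
#' session owner for individual sessions). Violations are reported with the
#' offending data row numbers.
#'
#' @param path CSV file path.
#' @return Validated trial-log data frame with a `session_id` column.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(trials) == 0L) stop("trial log is empty: ", path, call. = FALSE)
  missing_cols <- setdiff(trial_log_columns, names(trials))
  if (length(missing_cols)) {
    stop("header does not match trial-log dialect; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials$rt_ms <- suppressWarnings(as.numeric(trials$rt_ms))

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop("invalid trial log: ", what, " at row(s) ",
           paste(head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "", call. = FALSE)
    }
  }
  bad(!trials$condition %in% c("individual", "joint"), "unknown condition label")
  bad(!trials$stimulus_side %in% c("left", "right"), "unknown stimulus_side")
  bad(!trials$response_side %in% c("left", "right", "none"), "unknown response_side")
  bad(!trials$accuracy %in% c("correct", "error", "miss"), "unknown accuracy")
  bad(trials$block < 1 | trials$trial_index < 1, "indices must be 1-based")
  bad(trials$accuracy == "miss" & !is.na(trials$rt_ms),
      "rt recorded on a miss row")
  bad(trials$accuracy == "miss" & trials$response_side != "none",
      "response side recorded on a miss row")
  bad(trials$response_side != "none" & is.na(trials$rt_ms),
      "response without rt")

  if (!"session_id" %in% names(trials)) {
    trials$session_id <- ifelse(
      trials$condition == "joint",
      paste(trials$pair_id, "joint", sep = "_"),
      paste(trials$pair_id, "ind", trials$agent_id, sep = "_"))
  }
  for (sess in split(seq_len(nrow(trials)), trials$session_id)) {
    idx <- trials$trial_index[sess]
    if (is.unsorted(idx, strictly = TRUE)) {
      stop("invalid trial log: trial_index not strictly increasing in session ",
           trials$session_id[sess[1]], call. = FALSE)
    }
  }
  trials
}

#' Analysis run configuration
#'
#' All analysis parameters of the pipeline with defaults matching the
#' canonical design: filter `eta` 0.1, lags -9..+9, r threshold 0.25, 4
#' quartile bins, Tukey fence multiplier 1.5, and 4 blocks of 96 trials in
#' the simulator.
#'
#' @param corr A [corr_config()].
#' @param sim A [sim_config()] used when the pipeline simulates its input.
#' @param n_pairs Number of dyads to simulate.
#' @param design Simulated context (`"cooperative"`/`"competitive"`).
#' @param n_bins Quartile bins for the distributional analysis.
#' @param tukey_k Fence multiplier for participant exclusion.
#' @param seed Root seed (overrides `sim$seed` when not `NULL`).
#' @param out_dir Output directory for tables and the JSON summary
#'   (`NULL` = don't write files).
#' @param verbose Print progress.
#' @return A `run_config` list.
#' @export
run_config <- function(corr = corr_config(), sim = sim_config(),
                       n_pairs = 10L, design = "cooperative", n_bins = 4L,
                       tukey_k = 1.5, seed = NULL, out_dir = NULL,
                       verbose = FALSE) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(corr = corr, sim = sim, n_pairs = as.integer(n_pairs),
                 design = design, n_bins = as.integer(n_bins),
                 tukey_k = tukey_k, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat keys mirror the [sim_config()] and [corr_config()] field names;
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_keys <- names(formals(sim_config))
  corr_keys <- names(formals(corr_config))
  run_keys <- c("n_pairs", "design", "n_bins", "tukey_k", "seed", "out_dir",
                "verbose")
  unknown <- setdiff(names(y), c(sim_keys, corr_keys, run_keys))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sim <- do.call(sim_config, y[intersect(names(y), sim_keys)])
  corr <- do.call(corr_config, y[intersect(names(y), corr_keys)])
  do.call(run_config, c(list(corr = corr, sim = sim),
                        y[intersect(names(y), run_keys)]))
}

#' Participant cell means joined with coordination covariates
#'
#' Builds the long data frame consumed by [compare_models_lrt()]: one row
#' per participant x condition x correspondence with the mean correct RT,
#' the pair id and the pair's coordination index in that condition.
#'
#' @param coded Correct go trials (from [filter_for_rt_analysis()]) with a
#'   `participant` column.
#' @param indices Output of [coordination_indices()].
#' @return Data frame with `participant`, `pair`, `condition`,
#'   `correspondence`, `rt`, `coordination`.
#' @export
pipeline_cell_means <- function(coded, indices) {
  pm <- participant_cell_means(coded, c("condition", "correspondence"))
  pair_of <- unique(coded[c("participant", "pair_id")])
  out <- merge(pm, pair_of, by = "participant")
  out <- merge(out, indices,
               by.x = c("pair_id", "condition"),
               by.y = c("pair_id", "condition"))
  data.frame(participant = as.character(out$participant),
             pair = out$pair_id,
             condition = as.character(out$condition),
             correspondence = as.character(out$correspondence),
             rt = out$mean_rt,
             coordination = out$index,
             stringsAsFactors = FALSE)
}

stage <- function(name, expr, verbose = FALSE) {
  if (verbose) message("stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the whole workflow on a trial log (or on freshly simulated
#' data): participant exclusion by Tukey fences on error counts, trial
#' coding and filtering, the condition x correspondence table, the
#' quartile-bin table, the trial-transition table, coordination indices
#' for joint pairs and individual pseudo-pairs, the paired tests and
#' repeated-measures ANOVA, and the mixed-model comparison with
#' coordination as a random effect. When `config$out_dir` is set, all
#' tables are written as CSV together with a versioned JSON summary and a
#' decision log; reruns with the same seed and configuration produce
#' byte-identical output.
#'
#' @param config A [run_config()].
#' @param input Path to a trial-log CSV, or `"simulate"` to generate
#'   `config$n_pairs` dyads from `config$sim`.
#' @return A list with elements `trials`, `excluded_pairs`, `effects`
#'   (effect/quartile/transition tables), `coordination` (indices and the
#'   joint vs pseudo-pair test), `tests` (t-tests and ANOVA), and `models`
#'   (the mixed-model comparison).
#' @export
run_pipeline <- function(config = run_config(), input = "simulate") {
  v <- config$verbose
  trials <- stage("input", {
    if (identical(input, "simulate")) {
      generate_experiment(config$sim, config$n_pairs, config$design)$trials
    } else {
      read_trial_log(input)
    }
  }, v)

  excl <- stage("exclusion", {
    if (length(unique(trials$agent_id)) >= 4L) {
      exclude_pairs(trials, k = config$tukey_k)
    } else {
      list(flags = logical(), excluded_pairs = character())
    }
  }, v)
  kept <- trials[!trials$pair_id %in% excl$excluded_pairs, , drop = FALSE]

  coded <- stage("coding", code_experiment(kept), v)
  rt_trials <- stage("rt filter", filter_for_rt_analysis(coded), v)
  seq_trials <- stage("sequential filter", filter_for_sequential_analysis(coded), v)

  eff <- stage("condition means", condition_means(rt_trials), v)
  quart <- stage("quartile bins", quartile_bin_means(rt_trials, config$n_bins), v)
  trans <- stage("transition table", sequential_effect_table(seq_trials), v)

  indices <- stage("coordination", coordination_indices(kept, config$corr), v)
  wide_idx <- merge(indices[indices$condition == "joint", c("pair_id", "index")],
                    indices[indices$condition == "individual", c("pair_id", "index")],
                    by = "pair_id", suffixes = c("_joint", "_individual"))
  coord_test <- if (nrow(wide_idx) >= 2L) {
    paired_t(wide_idx$index_joint, wide_idx$index_individual)
  } else NULL

  se_part <- simon_effect_by_participant(eff)
  t_tests <- stage("t tests", {
    conds <- unique(se_part$condition)
    setNames(lapply(conds, function(cn) {
      sub <- se_part[se_part$condition == cn, ]
      paired_t(sub$simon_effect, rep(0, nrow(sub)),
               n_comparisons = length(conds))
    }), conds)
  }, v)
  anova_tab <- stage("ANOVA", {
    pm <- attr(eff, "participants")
    if (length(unique(pm$condition)) > 1L) {
      rm_anova(pm, "mean_rt", "participant", c("condition", "correspondence"))
    } else NULL
  }, v)

  models <- stage("model comparison", {
    if (nrow(wide_idx) >= 3L && length(unique(coded$condition)) > 1L) {
      compare_models_lrt(pipeline_cell_means(rt_trials, indices))
    } else NULL
  }, v)

  result <- list(
    trials = trials,
    excluded_pairs = excl$excluded_pairs,
    effects = list(condition_means = eff, quartiles = quart,
                   transitions = trans,
                   simon_effects = se_part),
    coordination = list(indices = indices, joint_vs_pseudo = coord_test),
    tests = list(simon_t = t_tests, anova = anova_tab),
    models = models)

  if (!is.null(config$out_dir)) {
    stage("write outputs", write_pipeline_outputs(result, config), v)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_trial_log(result$trials, p("trial_log.csv"))
  write.csv(as.data.frame(result$effects$condition_means),
            p("condition_means.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$effects$quartiles),
            p("quartile_means.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$effects$transitions),
            p("transition_table.csv"), row.names = FALSE)
  write.csv(result$coordination$indices, p("coordination_indices.csv"),
            row.names = FALSE)

  summary <- list(
    schema_version = "1.0",
    config = list(
      corr = unclass(config$corr), sim = unclass(config$sim),
      n_pairs = config$n_pairs, design = config$design,
      n_bins = config$n_bins, tukey_k = config$tukey_k),
    excluded_pairs = result$excluded_pairs,
    simon_effect = lapply(
      setNames(nm = unique(result$effects$condition_means$condition)),
      function(cn) simon_effect(result$effects$condition_means, cn)),
    coordination = list(
      mean_index = lapply(split(result$coordination$indices$index,
                                result$coordination$indices$condition), mean),
      joint_vs_pseudo = if (!is.null(result$coordination$joint_vs_pseudo)) {
        unclass(result$coordination$joint_vs_pseudo)
      }),
    model_comparison = if (!is.null(result$models)) {
      m <- result$models
      list(chisq = m$chisq, df = m$df, p = m$p,
           df_model1 = m$df_model1, df_model2 = m$df_model2,
           notes = m$status_model2)
    })
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("excluded pairs: %s",
            if (length(result$excluded_pairs)) {
              paste(result$excluded_pairs, collapse = ", ")
            } else "none"),
    sprintf("sessions analysed: %d", length(unique(result$trials$session_id))),
    if (!is.null(result$models)) {
      paste("model notes:", paste(result$models$status_model2, collapse = "; "))
    })
  writeLines(log_lines, p("log.txt"))
  invisible(config$out_dir)
}
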