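## Synthetic dyad generator: balanced go/no-go Simon schedules with a coupled
## AR(1) latent process, controllable correspondence and sequential effects,
## and a pooled error/miss process. Ground truth is returned alongside the
## trial log so downstream estimators can be validated by parameter recovery.

# AR(1) series with given autocorrelation and *stationary* SD
ar1_series <- function(n, phi, sd_stationary) {
  if (sd_stationary <= 0) return(numeric(n))
  innov <- rnorm(n, 0, sd_stationary * sqrt(1 - phi^2))
  if (phi == 0) return(innov)
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sd_stationary)))
}

# Balanced stimulus schedule over one session: exactly half the trials per
# block belong to each agent, and within each agent's trials a fixed share is
# corresponding. Shuffling a fixed multiset per block removes binomial noise.
make_schedule <- function(cfg, agent_ids) {
  half <- cfg$trials_per_block / 2L
  n_corr <- as.integer(round(cfg$p_corresponding * half))
  block_combo <- data.frame(
    required_responder = rep(agent_ids, each = half),
    correspondence = rep(c(rep("C", n_corr), rep("NC", half - n_corr)), 2L),
    stringsAsFactors = FALSE
  )
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    sched <- block_combo[sample.int(nrow(block_combo)), , drop = FALSE]
    sched$block <- b
    sched
  })
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

agent_side_map <- function(agent_ids) {
  setNames(c("left", "right"), agent_ids)
}

agent_color_map <- function(agent_ids) {
  setNames(c("green", "red"), agent_ids)
}

# Sequential (conflict-adaptation) term for each trial of a schedule, from
# the perspective of the trial's required responder. First trial of each
# block has no defined transition and gets 0.
seq_term_for_schedule <- function(sched, cfg) {
  n <- nrow(sched)
  s_corr <- ifelse(sched$correspondence == "NC", 1, -1)
  term <- numeric(n)
  if (n < 2L) return(term)
  idx <- 2:n
  same_block <- sched$block[idx] == sched$block[idx - 1L]
  prev_c <- sched$correspondence[idx - 1L]
  gate <- if (cfg$seq_transition_gate) {
    sched$required_responder[idx - 1L] != sched$required_responder[idx]
  } else rep(TRUE, length(idx))
  amp <- ifelse(prev_c == "C", cfg$lambda_seq / 2, -cfg$lambda_seq_rev / 2)
  term[idx] <- ifelse(same_block & gate, amp * s_corr[idx], 0)
  term
}

# Emit trial rows for one session given the schedule, the responder's latent
# values, and the error draws. `owner` is NA for joint sessions (each row is
# observed by its required responder) or the session owner for individual
# sessions (no-go rows belong to the owner, who correctly withholds).
emit_session <- function(sched, cfg, pair_id, condition, design, session_id,
                         sides, colors, latent, owner = NA_character_) {
  n <- nrow(sched)
  s_corr <- ifelse(sched$correspondence == "NC", 1, -1)
  seq_term <- seq_term_for_schedule(sched, cfg)
  responder <- sched$required_responder
  resp_side <- unname(sides[responder])
  stim_side <- ifelse(sched$correspondence == "C", resp_side,
                      ifelse(resp_side == "left", "right", "left"))

  is_go <- if (is.na(owner)) rep(TRUE, n) else responder == owner
  eps <- rnorm(n, 0, cfg$sigma_rt)
  rt <- cfg$mu_rt + (cfg$beta_simon / 2) * s_corr + seq_term + latent + eps
  rt <- pmax(rt, cfg$rt_floor)

  err_u <- runif(n)
  type_u <- runif(n)
  err <- is_go & err_u < cfg$p_error
  err_type <- rep("none", n)
  err_type[err & type_u < 0.5] <- "miss"
  err_type[err & type_u >= 0.5] <- "wrong_key"

  accuracy <- rep("correct", n)
  response_side <- rep("none", n)
  rt_out <- rep(NA_real_, n)
  response_side[is_go] <- resp_side[is_go]
  rt_out[is_go] <- rt[is_go]
  accuracy[err_type == "miss"] <- "miss"
  response_side[err_type == "miss"] <- "none"
  rt_out[err_type == "miss"] <- NA_real_
  accuracy[err_type == "wrong_key"] <- "error"
  response_side[err_type == "wrong_key"] <-
    ifelse(resp_side[err_type == "wrong_key"] == "left", "right", "left")

  trials <- data.frame(
    pair_id = pair_id,
    agent_id = if (is.na(owner)) responder else owner,
    condition = condition,
    design = design,
    block = sched$block,
    trial_index = sched$trial_index,
    stimulus_side = stim_side,
    stimulus_color = unname(colors[responder]),
    required_responder = responder,
    response_side = response_side,
    rt_ms = round(rt_out, 3),
    accuracy = accuracy,
    session_id = session_id,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    session_id = session_id,
    trial_index = sched$trial_index,
    required_responder = responder,
    correspondence = sched$correspondence,
    latent = latent,
    seq_term = seq_term,
    error_type = err_type,
    stringsAsFactors = FALSE
  )
  list(trials = trials, truth = truth)
}

#' Generate one pair's session (joint or individual)
#'
#' Simulates a complete go/no-go Simon session for one dyad. In the joint
#' condition both agents share a single stimulus schedule and each responds
#' only on the trials assigned to their color (half of all trials); their
#' latent RT fluctuations share a common AR(1) component weighted by
#' `config$coupling`. In the individual condition each agent gets an
#' independent schedule and an independent latent process (coupling is
#' forced to 0 across agents), and withholds on the no-go trials that would
#' have belonged to the partner.
#'
#' @param config A [sim_config()].
#' @param condition `"joint"` or `"individual"`.
#' @param pair_id Identifier for the dyad.
#' @param design Label stored in the trial log (`"cooperative"` or
#'   `"competitive"`); does not change the generative model here.
#' @return A list with `trials` (a trial-log data frame, one row per trial
#'   per session, see [read_trial_log()] for the column dialect), `truth`
#'   (per-trial latent values, sequential terms and error types, aligned
#'   one-to-one with the emitted trials) and `agents` (the two agent ids,
#'   left-seat first).
#' @examples
#' sess <- generate_pair_session(sim_config(seed = 1), "joint")
#' nrow(sess$trials)   # 384
#' table(sess$trials$required_responder)
#' @export
generate_pair_session <- function(config, condition = c("joint", "individual"),
                                  pair_id = "pair01", design = "cooperative") {
  validate_sim_config(config)
  condition <- match.arg(condition)
  agent_ids <- paste0(pair_id, c("_L", "_R"))
  sides <- agent_side_map(agent_ids)
  colors <- agent_color_map(agent_ids)
  set.seed(config$seed)

  n_total <- config$n_blocks * config$trials_per_block
  if (condition == "joint") {
    sched <- make_schedule(config, agent_ids)
    shared <- ar1_series(n_total, config$phi, config$sigma_latent)
    cpl <- config$coupling
    latent_by_agent <- lapply(agent_ids, function(a) {
      private <- ar1_series(n_total, config$phi, config$sigma_latent)
      sqrt(cpl) * shared + sqrt(1 - cpl) * private
    })
    names(latent_by_agent) <- agent_ids
    # each trial carries the required responder's latent value
    latent <- numeric(n_total)
    for (a in agent_ids) {
      sel <- sched$required_responder == a
      latent[sel] <- latent_by_agent[[a]][sel]
    }
    out <- emit_session(sched, config, pair_id, condition, design,
                        paste(pair_id, "joint", sep = "_"),
                        sides, colors, latent)
    res <- list(trials = out$trials, truth = out$truth, agents = agent_ids,
                latent = latent_by_agent)
  } else {
    parts <- lapply(agent_ids, function(a) {
      sched <- make_schedule(config, agent_ids)
      latent <- ar1_series(n_total, config$phi, config$sigma_latent)
      emit_session(sched, config, pair_id, condition, design,
                   paste(pair_id, "ind", a, sep = "_"),
                   sides, colors, latent, owner = a)
    })
    res <- list(trials = do.call(rbind, lapply(parts, `[[`, "trials")),
                truth = do.call(rbind, lapply(parts, `[[`, "truth")),
                agents = agent_ids)
  }
  rownames(res$trials) <- NULL
  res
}

#' Design presets for batch simulation
#'
#' Returns a [sim_config()] whose coupling and correspondence-effect defaults
#' mimic the two canonical joint-task contexts: under `"cooperative"`
#' instructions co-agents couple strongly (`coupling = 0.8`) and show a full
#' ~10 ms joint Simon effect; under `"competitive"` instructions coupling is
#' absent (`coupling = 0`) and the correspondence effect is halved.
#'
#' @param design `"cooperative"` or `"competitive"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
design_preset <- function(design = c("cooperative", "competitive"), ...) {
  design <- match.arg(design)
  defaults <- if (design == "cooperative") {
    list(coupling = 0.8, beta_simon = 10)
  } else {
    list(coupling = 0, beta_simon = 5)
  }
  do.call(sim_config, modifyList(defaults, list(...)))
}

#' Generate a full synthetic experiment
#'
#' Simulates `n_pairs` dyads, each performing an individual session (both
#' members in parallel, independent latents) followed by a joint session.
#' Per-pair child seeds are drawn once from the root seed, so the whole batch
#' is reproducible from `config$seed` and pairs are mutually independent.
#'
#' @param config A [sim_config()]; typically from [design_preset()].
#' @param n_pairs Number of dyads (>= 1).
#' @param design Context label recorded in the log.
#' @return A list with `trials` (trial log for all sessions of all pairs),
#'   `truth` (row-aligned ground truth), and `pairs` (pair ids).
#' @examples
#' exp <- generate_experiment(design_preset("cooperative", seed = 7), n_pairs = 2)
#' table(exp$trials$condition) / 384
#' @export
generate_experiment <- function(config, n_pairs,
                                design = c("cooperative", "competitive")) {
  validate_sim_config(config)
  design <- match.arg(design)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  set.seed(config$seed)
  child_seeds <- matrix(sample.int(2147483646L, n_pairs * 2L), ncol = 2L)
  pair_ids <- sprintf("pair%02d", seq_len(n_pairs))
  runs <- lapply(seq_len(n_pairs), function(i) {
    cfg_i <- config
    cfg_i$seed <- child_seeds[i, 1L]
    ind <- generate_pair_session(cfg_i, "individual", pair_ids[i], design)
    cfg_j <- config
    cfg_j$seed <- child_seeds[i, 2L]
    joint <- generate_pair_session(cfg_j, "joint", pair_ids[i], design)
    list(trials = rbind(ind$trials, joint$trials),
         truth = rbind(ind$truth, joint$truth))
  })
  trials <- do.call(rbind, lapply(runs, `[[`, "trials"))
  rownames(trials) <- NULL
  list(trials = trials,
       truth = do.call(rbind, lapply(runs, `[[`, "truth")),
       pairs = pair_ids)
}
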