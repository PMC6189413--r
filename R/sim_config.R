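#' Simulation configuration for synthetic dyad sessions
#'
#' Bundles every parameter of the synthetic go/no-go Simon generator. The
#' defaults emulate the design of a two-agent experiment: 384 trials in 4
#' blocks of 96, exactly half of the trials spatially corresponding, baseline
#' reaction times around 340 ms with per-trial noise of about 30 ms, a slow
#' AR(1) latent fluctuation, error rates below about 1%, and a correspondence
#' (Simon) effect plus a sequential modulation concentrated on Nogo/go
#' transitions.
#'
#' The trial-level model for a go trial of agent *a* at schedule position *t*
#' is
#' \deqn{RT = \mu + (\beta/2) s(t) + seq(t) + z_a(t) + \epsilon,}
#' where `s(t)` is +1 for non-corresponding and -1 for corresponding trials,
#' `seq(t)` is the sequential term (see below), `z_a` is the latent AR(1)
#' component and `\epsilon ~ N(0, sigma_rt)`. The symmetric `±beta/2`
#' parameterisation keeps the grand mean independent of the Simon effect, so
#' `beta_simon` is exactly the expected NC - C difference.
#'
#' The latent process is defined over the full pair schedule (all trials,
#' both agents' colors) and sampled by each agent on their go trials, so
#' inter-agent coupling survives the go-trial subsetting done by the
#' analysis. Each agent's latent is
#' \eqn{z_a = \sqrt{c}\, u + \sqrt{1-c}\, v_a} with a shared AR(1) process
#' `u`, private AR(1) processes `v_a`, and `c = coupling`; all AR(1)
#' processes have autocorrelation `phi` and *stationary* SD `sigma_latent`
#' (innovation SD `sigma_latent * sqrt(1 - phi^2)`), so the marginal SD of
#' correct RTs is approximately `sqrt(sigma_rt^2 + sigma_latent^2)`
#' regardless of `phi` or `coupling`.
#'
#' The sequential term implements conflict adaptation:
#' \deqn{seq(t) = g(t)\,[(\lambda/2) s(t) I(n\!-\!1 = C) -
#'   (\lambda_{rev}/2) s(t) I(n\!-\!1 = NC)],}
#' i.e. an enlarged correspondence effect after corresponding trials and a
#' reversed one after non-corresponding trials, with the gate `g(t)` equal to
#' 1 only on Nogo/go transitions when `seq_transition_gate` is `TRUE` (the
#' empirically typical pattern). On a transition table this yields
#' `SE(after C) - SE(after NC) = lambda_seq + lambda_seq_rev` in the gated
#' rows, which is what the parameter-recovery checks exploit.
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials per block (must be even).
#' @param p_corresponding Proportion of corresponding trials (balanced
#'   exactly within agent and block, not Bernoulli-sampled).
#' @param mu_rt Baseline mean RT in ms.
#' @param sigma_rt SD of independent trial noise, ms.
#' @param beta_simon Correspondence effect NC - C, ms.
#' @param lambda_seq Sequential-modulation amplitude after corresponding
#'   n-1 trials, ms.
#' @param lambda_seq_rev Amplitude of the reversed effect after
#'   non-corresponding n-1 trials, ms; defaults to `lambda_seq`.
#' @param seq_transition_gate If `TRUE` (default) the sequential term applies
#'   only on Nogo/go transitions.
#' @param phi AR(1) coefficient of the latent fluctuation, in \[0, 1).
#' @param sigma_latent Stationary SD of the latent fluctuation, ms.
#' @param coupling Share of latent variance common to the two agents, in
#'   \[0, 1\]. Forced to 0 for individual sessions.
#' @param p_error Probability that a go trial is answered wrongly or missed
#'   (pooled error/miss process; the two are distinguished in the ground
#'   truth).
#' @param rt_floor Lower clip for generated RTs, ms.
#' @param seed Root RNG seed for the generator.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(beta_simon = 10, coupling = 0.8, seed = 1)
#' cfg$n_blocks * cfg$trials_per_block  # 384 trials
#' @export
sim_config <- function(n_blocks = 4,
                       trials_per_block = 96,
                       p_corresponding = 0.5,
                       mu_rt = 340,
                       sigma_rt = 30,
                       beta_simon = 10,
                       lambda_seq = 15,
                       lambda_seq_rev = lambda_seq,
                       seq_transition_gate = TRUE,
                       phi = 0.8,
                       sigma_latent = 10,
                       coupling = 0,
                       p_error = 0.005,
                       rt_floor = 100,
                       seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    p_corresponding = p_corresponding,
    mu_rt = mu_rt,
    sigma_rt = sigma_rt,
    beta_simon = beta_simon,
    lambda_seq = lambda_seq,
    lambda_seq_rev = lambda_seq_rev,
    seq_transition_gate = isTRUE(seq_transition_gate),
    phi = phi,
    sigma_latent = sigma_latent,
    coupling = coupling,
    p_error = p_error,
    rt_floor = rt_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$n_blocks >= 1L, "n_blocks must be >= 1")
  chk(cfg$trials_per_block >= 2L, "trials_per_block must be >= 2")
  chk(cfg$trials_per_block %% 2L == 0L, "trials_per_block must be even")
  chk((cfg$n_blocks * cfg$trials_per_block) %% 2L == 0L, "total trials must be even")
  for (p in c("p_corresponding", "coupling", "p_error"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  chk(cfg$phi >= 0 && cfg$phi < 1, "phi must be in [0, 1)")
  chk(cfg$sigma_rt >= 0, "sigma_rt must be >= 0")
  chk(cfg$sigma_latent >= 0, "sigma_latent must be >= 0")
  chk(cfg$rt_floor > 0, "rt_floor must be > 0")
  # balanced schedules need whole per-agent, per-block correspondence counts
  half_block <- cfg$trials_per_block / 2
  n_corr <- cfg$p_corresponding * half_block
  chk(abs(n_corr - round(n_corr)) < 1e-9,
      "p_corresponding * trials_per_block / 2 must be a whole number")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  schedule : %d blocks x %d trials, P(corresponding) = %g\n",
              x$n_blocks, x$trials_per_block, x$p_corresponding))
  cat(sprintf("  RT model : mu = %g ms, sigma = %g ms, beta_simon = %g ms\n",
              x$mu_rt, x$sigma_rt, x$beta_simon))
  cat(sprintf("  sequence : lambda = %g / %g ms (gated: %s)\n",
              x$lambda_seq, x$lambda_seq_rev, x$seq_transition_gate))
  cat(sprintf("  latent   : phi = %g, sigma = %g ms, coupling = %g\n",
              x$phi, x$sigma_latent, x$coupling))
  cat(sprintf("  errors   : p = %g, rt floor = %g ms, seed = %d\n",
              x$p_error, x$rt_floor, x$seed))
  invisible(x)
}
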