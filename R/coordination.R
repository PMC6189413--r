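## Inter-agent response coordination: centered RT time-series, zero-phase
## exponential smoothing, instantaneous (time- and lag-resolved) cross-
## correlation, the coordination index, and pseudo-pair baselines.

#' Configuration of the instantaneous cross-correlation
#'
#' @param eta Smoothing factor of the non-causal exponential filter, in
#'   (0, 1]. The default 0.1 is conservative: the effective two-sided
#'   window spans roughly `2/eta - 1 ~ 19` trials.
#' @param lag_min,lag_max Trial offsets over which the correlation is
#'   evaluated (defaults -9 and +9).
#' @param r_threshold Correlation cutoff defining "coordinated" cells for
#'   [coordination_index()] (default 0.25).
#' @return A `corr_config` list.
#' @export
corr_config <- function(eta = 0.1, lag_min = -9L, lag_max = 9L,
                        r_threshold = 0.25) {
  if (!(eta > 0 && eta <= 1)) stop("eta must be in (0, 1]", call. = FALSE)
  if (!(lag_min <= 0 && lag_max >= 0)) {
    stop("lag range must contain 0 (lag_min <= 0 <= lag_max)", call. = FALSE)
  }
  if (!(r_threshold >= 0 && r_threshold < 1)) {
    stop("r_threshold must be in [0, 1)", call. = FALSE)
  }
  structure(list(eta = eta, lag_min = as.integer(lag_min),
                 lag_max = as.integer(lag_max), r_threshold = r_threshold),
            class = "corr_config")
}

#' Build a centered RT series for one agent
#'
#' Takes the agent's go trials of one session in collection order,
#' substitutes RTs of missed/incorrect responses with the mean of that
#' participant's correct RTs in the session, and centers the series on that
#' same mean (so imputed points sit exactly at zero).
#'
#' @param session Data frame with the rows of one session.
#' @param agent_id Agent whose go trials form the series.
#' @return An `rt_series`: list with `values` (centered ms), `imputed`
#'   (logical), `agent_id`, `condition`, `center` (the correct-RT mean used).
#' @examples
#' # raw RTs 300, miss, 320 with correct mean 310 -> centered -10, 0, +10
#' @export
build_rt_series <- function(session, agent_id) {
  go <- session[session$required_responder == agent_id, , drop = FALSE]
  go <- go[order(go$trial_index), ]
  if (nrow(go) == 0L) stop("agent '", agent_id, "' has no go trials", call. = FALSE)
  correct <- go$accuracy == "correct" & !is.na(go$rt_ms)
  if (!any(correct)) {
    stop("agent '", agent_id, "' has no correct responses to impute from",
         call. = FALSE)
  }
  center <- mean(go$rt_ms[correct])
  values <- ifelse(correct, go$rt_ms - center, 0)
  structure(list(values = as.numeric(values), imputed = !correct,
                 agent_id = agent_id, condition = go$condition[1],
                 center = center),
            class = "rt_series")
}

#' @export
print.rt_series <- function(x, ...) {
  cat(sprintf("<rt_series> agent %s (%s): %d points, %d imputed, mean %.2g\n",
              x$agent_id, x$condition, length(x$values), sum(x$imputed),
              mean(x$values)))
  invisible(x)
}

#' Zero-phase (non-causal) first-order exponential smoothing
#'
#' Applies the recursion `y[t] = eta*x[t] + (1-eta)*y[t-1]` forward over the
#' series and then backward over the forward output, yielding a zero-phase
#' smoother whose effective impulse response is the normalized two-sided
#' exponential `(1-eta)^|k|`. Each pass is initialised with the first value
#' it sees, which is equivalent to extending the series as a constant past
#' the edge. `eta = 1` returns the input unchanged.
#'
#' @param x Finite numeric vector (non-empty).
#' @param eta Smoothing factor in (0, 1].
#' @return Smoothed vector of the same length.
#' @examples
#' smooth_noncausal(c(0, 0, 1, 0, 0), 0.5)
#' @export
smooth_noncausal <- function(x, eta) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  if (!(eta > 0 && eta <= 1)) stop("eta must be in (0, 1]", call. = FALSE)
  if (eta == 1) return(as.numeric(x))
  fwd <- as.numeric(stats::filter(eta * x, 1 - eta, method = "recursive",
                                  init = x[1]))
  rev_in <- rev(fwd)
  bwd <- as.numeric(stats::filter(eta * rev_in, 1 - eta, method = "recursive",
                                  init = rev_in[1]))
  rev(bwd)
}

#' Instantaneous cross-correlation of two RT series
#'
#' Computes a time-resolved, lag-resolved local Pearson correlation: for
#' each trial offset `delta` in `[lag_min, lag_max]` the lagged pairs
#' `(x[t], y[t + delta])` are formed, the five local moment series (means of
#' x, y, x^2, y^2 and x*y) are smoothed with [smooth_noncausal()], and
#' \deqn{r(t, \delta) = \frac{\langle xy\rangle_t - \langle x\rangle_t
#'   \langle y\rangle_t}{\sqrt{(\langle x^2\rangle_t - \langle x\rangle_t^2)
#'   (\langle y^2\rangle_t - \langle y\rangle_t^2)}}.}
#' Filtering the moments (rather than r itself) keeps every defined cell a
#' genuine local correlation bounded in \[-1, 1\] (values are additionally
#' clipped against floating-point overshoot). Cells whose lagged partner
#' falls outside the series, or whose local variance denominator is below
#' 1e-12, are marked invalid; there is no padding.
#'
#' @param x,y Equal-length numeric vectors or [build_rt_series()] objects.
#'   Unequal lengths are truncated to the shorter with a warning.
#' @param config A [corr_config()].
#' @return An `inst_corr` object: list with `r` (time x lag matrix),
#'   `valid` (logical matrix), `lags`, and `config`.
#' @export
instantaneous_crosscorr <- function(x, y, config = corr_config()) {
  if (inherits(x, "rt_series")) x <- x$values
  if (inherits(y, "rt_series")) y <- y$values
  if (length(x) != length(y)) {
    warning("series lengths differ (", length(x), " vs ", length(y),
            "); truncating to the shorter", call. = FALSE)
    n <- min(length(x), length(y))
    x <- x[seq_len(n)]
    y <- y[seq_len(n)]
  }
  n <- length(x)
  lags <- config$lag_min:config$lag_max
  if (n < length(lags) + 2L) {
    stop("series too short (", n, ") for lag range ", config$lag_min, "..",
         config$lag_max, call. = FALSE)
  }
  r <- matrix(NA_real_, n, length(lags), dimnames = list(NULL, lags))
  valid <- matrix(FALSE, n, length(lags))
  for (j in seq_along(lags)) {
    d <- lags[j]
    t0 <- max(1L, 1L - d)
    t1 <- min(n, n - d)
    if (t1 - t0 < 1L) next
    ts <- t0:t1
    xs <- x[ts]
    ys <- y[ts + d]
    mx <- smooth_noncausal(xs, config$eta)
    my <- smooth_noncausal(ys, config$eta)
    mxx <- smooth_noncausal(xs^2, config$eta)
    myy <- smooth_noncausal(ys^2, config$eta)
    mxy <- smooth_noncausal(xs * ys, config$eta)
    vx <- pmax(mxx - mx^2, 0)
    vy <- pmax(myy - my^2, 0)
    denom <- sqrt(vx * vy)
    ok <- denom >= 1e-12
    rj <- rep(NA_real_, length(ts))
    rj[ok] <- pmin(1, pmax(-1, (mxy[ok] - mx[ok] * my[ok]) / denom[ok]))
    r[ts, j] <- rj
    valid[ts, j] <- ok
  }
  structure(list(r = r, valid = valid, lags = lags, config = config),
            class = "inst_corr")
}

#' @export
print.inst_corr <- function(x, ...) {
  cat(sprintf("<inst_corr> %d time points x %d lags (%d..%d), eta = %g\n",
              nrow(x$r), length(x$lags), min(x$lags), max(x$lags),
              x$config$eta))
  cat(sprintf("  valid cells: %d/%d; mean r = %.3f\n", sum(x$valid),
              length(x$valid), mean(x$r[x$valid])))
  invisible(x)
}

#' Coordination index: proportion of correlated activity
#'
#' The fraction of valid (time, lag) cells of an instantaneous
#' cross-correlation whose local r strictly exceeds the threshold. The
#' comparison is signed by default (`r > threshold`, not `|r|`).
#'
#' @param m An `inst_corr` from [instantaneous_crosscorr()].
#' @param r_threshold Cutoff; defaults to the threshold stored in the
#'   matrix's configuration.
#' @param absolute Use `|r|` instead of signed r.
#' @return Proportion in \[0, 1\].
#' @export
coordination_index <- function(m, r_threshold = m$config$r_threshold,
                               absolute = FALSE) {
  vals <- m$r[m$valid]
  if (length(vals) == 0L) stop("no valid cells in correlation matrix", call. = FALSE)
  if (absolute) vals <- abs(vals)
  mean(vals > r_threshold)
}

#' Export an instantaneous correlation matrix as tidy text
#'
#' @param x An `inst_corr`.
#' @param ... Unused.
#' @return Data frame with `time`, `lag`, `r`, `valid` columns.
#' @export
as.data.frame.inst_corr <- function(x, ...) {
  data.frame(time = rep(seq_len(nrow(x$r)), times = ncol(x$r)),
             lag = rep(x$lags, each = nrow(x$r)),
             r = as.vector(x$r),
             valid = as.vector(x$valid))
}

#' Pair individual sessions into pseudo-pairs
#'
#' Pseudo-pairs are the no-interaction baseline: the two members of each
#' dyad performed their individual sessions in parallel rooms, and their RT
#' series are aligned post hoc by ordinal go-trial index. Series of unequal
#' length are truncated to the shorter member; a difference above 10% draws
#' a warning.
#'
#' @param trials Trial log containing the individual sessions (rows with
#'   `condition == "individual"` are selected automatically).
#' @return List of pseudo-pairs, each a list with `pair_id`, `x` and `y`
#'   ([build_rt_series()] objects, possibly truncated).
#' @export
make_pseudo_pairs <- function(trials) {
  ind <- trials[trials$condition == "individual", , drop = FALSE]
  if (nrow(ind) == 0L) stop("no individual sessions in input", call. = FALSE)
  if (!all(c("pair_id", "session_id") %in% names(ind)) || anyNA(ind$pair_id)) {
    stop("individual sessions must carry pair_id metadata", call. = FALSE)
  }
  sess_owner <- unique(ind[c("session_id", "pair_id", "agent_id")])
  if (nrow(sess_owner) %% 2L != 0L) {
    stop("odd number of individual sessions; cannot form pseudo-pairs",
         call. = FALSE)
  }
  lapply(split(sess_owner, sess_owner$pair_id), function(so) {
    if (nrow(so) != 2L) {
      stop("pair '", so$pair_id[1], "' has ", nrow(so),
           " individual sessions (need exactly 2)", call. = FALSE)
    }
    series <- lapply(seq_len(2L), function(i) {
      sess <- ind[ind$session_id == so$session_id[i], ]
      build_rt_series(sess, so$agent_id[i])
    })
    n1 <- length(series[[1]]$values)
    n2 <- length(series[[2]]$values)
    if (n1 != n2) {
      if (abs(n1 - n2) / max(n1, n2) > 0.1) {
        warning("pseudo-pair ", so$pair_id[1], ": series lengths differ by >10% (",
                n1, " vs ", n2, "); truncating", call. = FALSE)
      }
      n <- min(n1, n2)
      for (i in 1:2) {
        series[[i]]$values <- series[[i]]$values[seq_len(n)]
        series[[i]]$imputed <- series[[i]]$imputed[seq_len(n)]
      }
    }
    list(pair_id = so$pair_id[1], x = series[[1]], y = series[[2]])
  })
}

#' Coordination indices for every pair and condition
#'
#' For each dyad, computes the coordination index of the joint session
#' (both members' series over their own go trials, aligned by ordinal
#' index) and of the individual pseudo-pair baseline.
#'
#' @param trials Trial log with joint and/or individual sessions.
#' @param config A [corr_config()].
#' @param absolute Passed to [coordination_index()].
#' @return Data frame with `pair_id`, `condition`, `index` (proportion).
#' @export
coordination_indices <- function(trials, config = corr_config(),
                                 absolute = FALSE) {
  out <- list()
  joint <- trials[trials$condition == "joint", , drop = FALSE]
  if (nrow(joint)) {
    for (sess in split(joint, joint$session_id)) {
      agents <- sort(unique(sess$required_responder))
      if (length(agents) != 2L) next
      x <- build_rt_series(sess, agents[1])
      y <- build_rt_series(sess, agents[2])
      idx <- coordination_index(instantaneous_crosscorr(x, y, config),
                                absolute = absolute)
      out[[length(out) + 1L]] <- data.frame(pair_id = sess$pair_id[1],
                                            condition = "joint", index = idx,
                                            stringsAsFactors = FALSE)
    }
  }
  if (any(trials$condition == "individual")) {
    for (pp in make_pseudo_pairs(trials)) {
      idx <- coordination_index(instantaneous_crosscorr(pp$x, pp$y, config),
                                absolute = absolute)
      out[[length(out) + 1L]] <- data.frame(pair_id = pp$pair_id,
                                            condition = "individual",
                                            index = idx,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no analysable sessions in input", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
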