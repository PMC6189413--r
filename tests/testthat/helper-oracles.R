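# Independent oracles and small fixture builders used across test files.

# Closed-form weight matrix of the forward-backward exponential smoother:
# forward rows F[t, j] = eta (1-eta)^(t-j) with the first column carrying the
# constant-extension initial condition, backward pass is its mirror image.
# The combined rows are the (edge-renormalized) two-sided exponential weights.
fb_weight_matrix <- function(n, eta) {
  Fm <- matrix(0, n, n)
  for (t in seq_len(n)) {
    Fm[t, 1] <- (1 - eta)^(t - 1)
    if (t >= 2) for (j in 2:t) Fm[t, j] <- eta * (1 - eta)^(t - j)
  }
  Bm <- matrix(0, n, n)
  for (t in seq_len(n)) {
    Bm[t, n] <- (1 - eta)^(n - t)
    if (t <= n - 1) for (j in t:(n - 1)) Bm[t, j] <- eta * (1 - eta)^(j - t)
  }
  Bm %*% Fm
}

# Direct weighted-Pearson instantaneous cross-correlation using the explicit
# two-sided exponential weights; independent of the recursive implementation.
oracle_crosscorr <- function(x, y, eta, lag_min, lag_max) {
  n <- length(x)
  lags <- lag_min:lag_max
  r <- matrix(NA_real_, n, length(lags))
  for (j in seq_along(lags)) {
    d <- lags[j]
    t0 <- max(1L, 1L - d)
    t1 <- min(n, n - d)
    if (t1 - t0 < 1L) next
    ts <- t0:t1
    xs <- x[ts]
    ys <- y[ts + d]
    W <- fb_weight_matrix(length(ts), eta)
    for (i in seq_along(ts)) {
      w <- W[i, ]
      mx <- sum(w * xs); my <- sum(w * ys)
      vx <- sum(w * xs^2) - mx^2
      vy <- sum(w * ys^2) - my^2
      if (sqrt(max(vx, 0) * max(vy, 0)) >= 1e-12) {
        r[ts[i], j] <- (sum(w * xs * ys) - mx * my) / sqrt(vx * vy)
      }
    }
  }
  r
}

# Hand-built trial log: one pair, one joint session, explicit trial stream.
# `spec_rows` is a data.frame with columns block, responder ("L"/"R"),
# corr ("C"/"NC"), rt (NA for miss), acc.
tiny_joint_log <- function(spec_rows, pair_id = "p1") {
  agents <- paste0(pair_id, c("_L", "_R"))
  sides <- c(L = "left", R = "right")
  responder <- agents[match(spec_rows$responder, c("L", "R"))]
  resp_side <- sides[spec_rows$responder]
  stim_side <- ifelse(spec_rows$corr == "C", resp_side,
                      ifelse(resp_side == "left", "right", "left"))
  acc <- spec_rows$acc
  data.frame(
    pair_id = pair_id,
    agent_id = responder,
    condition = "joint",
    design = "cooperative",
    block = spec_rows$block,
    trial_index = seq_len(nrow(spec_rows)),
    stimulus_side = unname(stim_side),
    stimulus_color = ifelse(spec_rows$responder == "L", "green", "red"),
    required_responder = responder,
    response_side = ifelse(acc == "miss", "none",
                           ifelse(acc == "error",
                                  ifelse(resp_side == "left", "right", "left"),
                                  unname(resp_side))),
    rt_ms = ifelse(acc == "miss", NA_real_, spec_rows$rt),
    accuracy = acc,
    session_id = paste0(pair_id, "_joint"),
    stringsAsFactors = FALSE)
}

# Long participant x cell data with exact cell means (one "trial" per cell
# mean repeated, so participant means hit the target cells exactly).
cells_to_trials <- function(cell_df) {
  cell_df$participant <- as.character(cell_df$participant)
  cell_df$rt_ms <- cell_df$mean
  cell_df
}
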