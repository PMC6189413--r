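test_that("RT series are imputed and centered on the correct-trial mean", {
  rows <- data.frame(block = 1, responder = "L", corr = "C",
                     rt = c(300, NA, 320), acc = c("correct", "miss", "correct"))
  log <- tiny_joint_log(rows)
  s <- build_rt_series(log, "p1_L")
  expect_equal(s$values, c(-10, 0, 10))
  expect_equal(s$imputed, c(FALSE, TRUE, FALSE))
  expect_equal(s$center, 310)

  sess <- generate_pair_session(sim_config(p_error = 0, seed = 13), "joint")
  s2 <- build_rt_series(sess$trials, sess$agents[1])
  expect_length(s2$values, 192L)
  expect_false(any(s2$imputed))
  expect_lt(abs(mean(s2$values)), 1e-9)

  allmiss <- tiny_joint_log(data.frame(block = 1, responder = "L", corr = "C",
                                       rt = NA, acc = "miss"))
  expect_error(build_rt_series(allmiss, "p1_L"), "no correct responses")
})

test_that("the zero-phase smoother has exponential-kernel semantics", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_identical(smooth_noncausal(x, 1), x)
  expect_equal(smooth_noncausal(rep(7, 20), 0.3), rep(7, 20))
  expect_error(smooth_noncausal(numeric(0), 0.5), "empty")
  expect_error(smooth_noncausal(c(1, NA), 0.5), "finite")

  # linearity
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(smooth_noncausal(2 * a - 3 * b, 0.2),
               2 * smooth_noncausal(a, 0.2) - 3 * smooth_noncausal(b, 0.2),
               tolerance = 1e-10)

  # exact closed-form weight-matrix equivalence
  for (eta in c(0.1, 0.5)) {
    W <- fb_weight_matrix(length(a), eta)
    expect_equal(as.numeric(W %*% a), smooth_noncausal(a, eta),
                 tolerance = 1e-10)
  }

  # away from the edges the weights converge to the ideal two-sided kernel
  eta <- 0.5
  ramp <- as.numeric(1:64)
  ideal <- vapply(1:64, function(t) {
    k <- -300:300
    w <- (1 - eta)^abs(k)
    sum(w * pmax(pmin(t + k, 64), 1)) / sum(w)
  }, numeric(1))
  interior <- 25:40
  expect_lt(max(abs(ideal[interior] - smooth_noncausal(ramp, eta)[interior])),
            1e-6)
})

test_that("instantaneous cross-correlation has local-Pearson semantics", {
  set.seed(4)
  x <- rnorm(60)
  cfg <- corr_config(eta = 0.2, lag_min = -4, lag_max = 4)
  m_self <- instantaneous_crosscorr(x, x, cfg)
  lag0 <- which(m_self$lags == 0)
  expect_true(all(abs(m_self$r[m_self$valid[, lag0], lag0] - 1) < 1e-9))
  m_anti <- instantaneous_crosscorr(x, -x, cfg)
  expect_true(all(abs(m_anti$r[m_anti$valid[, lag0], lag0] + 1) < 1e-9))
  expect_true(all(abs(m_self$r[m_self$valid]) <= 1))

  # symmetry: r_xy(t, d) = r_yx(t + d, -d)
  y <- rnorm(60)
  mxy <- instantaneous_crosscorr(x, y, cfg)
  myx <- instantaneous_crosscorr(y, x, cfg)
  for (d in c(-3, 0, 2)) {
    jx <- which(mxy$lags == d)
    jy <- which(myx$lags == -d)
    for (t in 10:50) {
      if (mxy$valid[t, jx] && myx$valid[t + d, jy]) {
        expect_equal(unname(mxy$r[t, jx]), unname(myx$r[t + d, jy]),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(instantaneous_crosscorr(rnorm(10), rnorm(10), corr_config()),
               "too short")
  expect_warning(instantaneous_crosscorr(rnorm(40), rnorm(42), cfg),
                 "truncating")
})

test_that("recursive cross-correlation equals the weighted-Pearson oracle", {
  set.seed(6)
  n <- 48
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  cfg <- corr_config(eta = 0.15, lag_min = -3, lag_max = 3)
  m <- instantaneous_crosscorr(x, y, cfg)
  ref <- oracle_crosscorr(x, y, cfg$eta, cfg$lag_min, cfg$lag_max)
  expect_lt(max(abs(m$r[m$valid] - ref[m$valid])), 1e-6)
})

test_that("the coordination index counts signed supra-threshold cells", {
  m <- structure(list(r = matrix(1, 5, 3), valid = matrix(TRUE, 5, 3),
                      lags = -1:1, config = corr_config()),
                 class = "inst_corr")
  expect_equal(coordination_index(m), 1)
  m$r[] <- 0
  expect_equal(coordination_index(m), 0)
  m$r[] <- -0.9
  expect_equal(coordination_index(m), 0)
  expect_equal(coordination_index(m, absolute = TRUE), 1)
  m$valid[] <- FALSE
  expect_error(coordination_index(m), "no valid cells")

  # invariance under common positive rescaling of both series
  set.seed(8)
  x <- rnorm(60); y <- rnorm(60)
  cfg <- corr_config(eta = 0.2, lag_min = -4, lag_max = 4, r_threshold = 0.2)
  i1 <- coordination_index(instantaneous_crosscorr(x, y, cfg))
  i2 <- coordination_index(instantaneous_crosscorr(7.3 * x, 7.3 * y, cfg))
  expect_equal(i1, i2)
})

test_that("a shared slow component raises local correlations", {
  mean_abs_r <- function(seed, shared_sd) {
    set.seed(seed)
    n <- 192
    u <- as.numeric(stats::filter(rnorm(n, 0, shared_sd * sqrt(1 - 0.8^2)),
                                  0.8, method = "recursive"))
    x <- rnorm(n) + u
    y <- rnorm(n) + u
    m <- instantaneous_crosscorr(x, y, corr_config())
    mean(abs(m$r[m$valid]))
  }
  white <- vapply(1:20, mean_abs_r, numeric(1), shared_sd = 0)
  coupled <- vapply(1:20, mean_abs_r, numeric(1), shared_sd = 1)
  expect_gt(mean(coupled), mean(white))
})

test_that("pseudo-pairs partition the individual sessions by dyad", {
  exp <- generate_experiment(sim_config(seed = 17), n_pairs = 10)
  pp <- make_pseudo_pairs(exp$trials)
  expect_length(pp, 10L)
  members <- unname(unlist(lapply(pp, function(p) c(p$x$agent_id, p$y$agent_id))))
  expect_setequal(members, unique(exp$trials$agent_id))
  expect_equal(anyDuplicated(members), 0L)

  # unequal series lengths are truncated with a warning above 10%
  ind <- exp$trials[exp$trials$condition == "individual" &
                      exp$trials$pair_id == "pair01", ]
  one <- unique(ind$session_id)[1]
  owner <- ind$agent_id[ind$session_id == one][1]
  drop_go <- which(ind$session_id == one & ind$required_responder == owner)
  short <- ind[-drop_go[41:192], ]
  expect_warning(pp2 <- make_pseudo_pairs(short), "differ by >10%")
  expect_equal(length(pp2[[1]]$x$values), length(pp2[[1]]$y$values))

  expect_error(make_pseudo_pairs(exp$trials[exp$trials$condition == "joint", ]),
               "no individual sessions")
  solo <- exp$trials[exp$trials$session_id == one, ]
  expect_error(make_pseudo_pairs(solo), "individual sessions")
})
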