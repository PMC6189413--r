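## Hypothesis-testing layer: paired t-tests with Bonferroni correction,
## within-subject (repeated-measures) ANOVA with partial eta squared, and
## the mixed-model comparison that adds response coordination as a
## pair-level random effect.

#' Paired-samples t-test with Bonferroni correction and Cohen's d
#'
#' Classical paired t on participant-matched values. Cohen's d (d_z) is the
#' mean difference divided by the SD of the differences; the corrected p is
#' `min(1, p * n_comparisons)`. Degenerate inputs are handled explicitly:
#' all-equal pairs give t = 0 and p = 1; zero variance of the differences
#' with a nonzero mean gives an infinite t with p = 0.
#'
#' @param a,b Numeric vectors of equal length >= 2, paired by participant.
#' @param n_comparisons Size of the comparison family for the Bonferroni
#'   correction (default 1: no correction).
#' @return A `jc_test` list: `statistic`, `df`, `p`, `p_corrected`, `d`,
#'   `mean_diff`, `n`.
#' @examples
#' paired_t(c(5, 6, 7, 9), c(4, 4, 4, 5), n_comparisons = 2)
#' @export
paired_t <- function(a, b, n_comparisons = 1L) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) {
      stat <- 0; p <- 1; dz <- 0
    } else {
      stat <- sign(md) * Inf; p <- 0; dz <- sign(md) * Inf
    }
  } else {
    stat <- md / (sdd / sqrt(n))
    p <- 2 * pt(-abs(stat), n - 1)
    dz <- md / sdd
  }
  structure(list(statistic = stat, df = n - 1L, p = p,
                 p_corrected = min(1, p * n_comparisons), d = dz,
                 mean_diff = md, n = n),
            class = "jc_test")
}

#' @export
print.jc_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g (corrected %.4g), d = %.2f, mean diff = %.2f\n",
              x$df, x$statistic, x$p, x$p_corrected, x$d, x$mean_diff))
  invisible(x)
}

# Greenhouse-Geisser epsilon for the main effect of one within factor
gg_epsilon <- function(data, dv, id, factor_name) {
  m <- tapply(data[[dv]], list(data[[id]], data[[factor_name]]), mean)
  k <- ncol(m)
  S <- stats::cov(m)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  V <- t(C) %*% S %*% C
  sum(diag(V))^2 / ((k - 1) * sum(V^2))
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Fits a fully-crossed within-subject ANOVA (optionally with one
#' between-subject factor) via the standard error-stratum decomposition
#' (`stats::aov` with an `Error(id/...)` term) and reports F, degrees of
#' freedom, p and partial eta squared (`SS_effect / (SS_effect +
#' SS_error)`, taken within each term's own error stratum) per main effect
#' and interaction.
#'
#' @param data Long data frame of participant x cell means.
#' @param dv Name of the response column.
#' @param id Name of the participant identifier column.
#' @param within Character vector of within-subject factor names (1-4).
#' @param between Optional name of one between-subject factor.
#' @param gg Character vector of within factors whose main effect should
#'   additionally get a Greenhouse-Geisser-corrected p (`p_gg`); useful for
#'   factors with more than 2 levels.
#' @return Data frame with one row per term: `term`, `df1`, `df2`, `F`,
#'   `p`, `pes` (and `p_gg` where requested).
#' @export
rm_anova <- function(data, dv, id, within, between = NULL, gg = character()) {
  stopifnot(length(within) >= 1L, length(within) <= 4L)
  df <- data
  df[[id]] <- factor(df[[id]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (!is.null(between)) df[[between]] <- factor(df[[between]])
  if (stats::var(df[[dv]]) < 1e-20) {
    stop("response has no variance; F ratios are undefined", call. = FALSE)
  }
  # complete crossing check
  counts <- table(df[[id]], interaction(df[within], drop = FALSE))
  if (any(counts == 0L)) {
    stop("design not fully crossed: some participant x cell combinations are empty",
         call. = FALSE)
  }
  fixed <- paste(c(between, within), collapse = " * ")
  fml <- as.formula(sprintf("%s ~ %s + Error(%s/(%s))", dv, fixed, id,
                            paste(within, collapse = " * ")))
  fit <- aov(fml, data = df)
  smry <- summary(fit)
  rows <- list()
  for (stratum in smry) {
    tab <- stratum[[1]]
    terms_here <- trimws(rownames(tab))
    res_i <- which(terms_here == "Residuals")
    if (!length(res_i)) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), res_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms_here[i],
        df1 = tab[i, "Df"], df2 = df_err,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        pes = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$F))) {
    stop("some F ratios are undefined (zero error variance in a stratum)",
         call. = FALSE)
  }
  if (length(gg)) {
    out$p_gg <- NA_real_
    for (g in gg) {
      i <- match(g, out$term)
      if (is.na(i)) next
      eps <- gg_epsilon(df, dv, id, g)
      out$p_gg[i] <- stats::pf(out$F[i], out$df1[i] * eps, out$df2[i] * eps,
                               lower.tail = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

fit_lmm <- function(fml, data) {
  status <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = FALSE),
    warning = function(w) {
      status <<- c(status, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      status <<- c(status, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (lme4::isSingular(fit)) status <- c(status, "boundary (singular) fit")
  list(fit = fit, status = status)
}

lrt_between <- function(full, reduced) {
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df = max(df, 1L), lower.tail = FALSE))
}

#' Mixed-model comparison with coordination as a random effect
#'
#' Re-analyses participant x cell mean RTs with linear mixed models fitted
#' by maximum likelihood. Model 1 has fixed effects of condition,
#' correspondence and their interaction plus a random intercept per
#' participant; Model 2 adds a pair-level random effect scaled by the
#' (centered) coordination covariate, i.e. `(0 + coordination | pair)`. The
#' two models are compared by a likelihood-ratio chi-square on 1 df (the
#' boundary problem of testing a variance component makes this test
#' conservative; the plain 1-df chi-square is reported as primary). Fixed
#' effects are then re-estimated under Model 2 with term-wise
#' likelihood-ratio chi-squares.
#'
#' A coordination covariate with no between-unit variance carries no
#' information: the random-effect variance is 0 by construction and the
#' comparison is reported with chi-square 0 without refitting.
#'
#' @param data Long data frame of participant x cell means with columns for
#'   the response, condition, correspondence, participant and pair ids, and
#'   the coordination covariate (one value per pair, or per pair x
#'   condition).
#' @param dv,condition,correspondence,participant,pair,coordination Column
#'   names (defaults match [pipeline_cell_means()] output).
#' @param structure `"slope"` (default): pair-level random effect scaled by
#'   the covariate; `"intercept_by_level"`: random intercept grouped by the
#'   covariate's distinct levels.
#' @param center Center the coordination covariate before building the
#'   random term (default `TRUE`).
#' @return A `model_comparison` list: fitted models, their log-likelihoods
#'   and df, the chi-square/df/p of the comparison, convergence/singularity
#'   notes, and the term-wise chi-squares under Model 2.
#' @export
compare_models_lrt <- function(data, dv = "rt", condition = "condition",
                               correspondence = "correspondence",
                               participant = "participant", pair = "pair",
                               coordination = "coordination",
                               structure = c("slope", "intercept_by_level"),
                               center = TRUE) {
  structure_kind <- match.arg(structure)
  df <- data.frame(.rt = data[[dv]],
                   .cond = factor(data[[condition]]),
                   .corr = factor(data[[correspondence]]),
                   .id = factor(data[[participant]]),
                   .pair = factor(data[[pair]]),
                   .coord = as.numeric(data[[coordination]]))
  if (center) df$.coord <- df$.coord - mean(df$.coord)

  m1 <- fit_lmm(.rt ~ .cond * .corr + (1 | .id), df)
  no_info <- sd(df$.coord) == 0
  if (no_info) {
    cmp <- list(chisq = 0, df = 1L, p = 1)
    m2 <- m1
    status2 <- c("coordination covariate is constant across units; ",
                 "random-effect variance 0 by construction, model not refitted")
  } else {
    fml2 <- if (structure_kind == "slope") {
      .rt ~ .cond * .corr + (1 | .id) + (0 + .coord | .pair)
    } else {
      df$.coord_level <- factor(df$.coord)
      .rt ~ .cond * .corr + (1 | .id) + (1 | .coord_level)
    }
    m2 <- fit_lmm(fml2, df)
    cmp <- lrt_between(m2$fit, m1$fit)
    status2 <- m2$status
  }

  # term-wise chi-squares under the Model 2 random structure
  fixed_terms <- NULL
  if (!no_info) {
    re2 <- if (structure_kind == "slope") "(1 | .id) + (0 + .coord | .pair)"
    else "(1 | .id) + (1 | .coord_level)"
    f_full <- as.formula(paste(".rt ~ .cond * .corr +", re2))
    f_main <- as.formula(paste(".rt ~ .cond + .corr +", re2))
    f_nocond <- as.formula(paste(".rt ~ .corr +", re2))
    f_nocorr <- as.formula(paste(".rt ~ .cond +", re2))
    full <- fit_lmm(f_full, df)
    main <- fit_lmm(f_main, df)
    tests <- list(
      condition = lrt_between(main$fit, fit_lmm(f_nocond, df)$fit),
      correspondence = lrt_between(main$fit, fit_lmm(f_nocorr, df)$fit),
      `condition:correspondence` = lrt_between(full$fit, main$fit))
    fixed_terms <- data.frame(
      term = names(tests),
      chisq = vapply(tests, `[[`, numeric(1), "chisq"),
      df = vapply(tests, `[[`, numeric(1), "df"),
      p = vapply(tests, `[[`, numeric(1), "p"),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  res <- list(
    model1 = m1$fit, model2 = if (no_info) NULL else m2$fit,
    logLik1 = as.numeric(logLik(m1$fit)),
    logLik2 = if (no_info) as.numeric(logLik(m1$fit)) else as.numeric(logLik(m2$fit)),
    df_model1 = attr(logLik(m1$fit), "df"),
    df_model2 = attr(logLik(m1$fit), "df") + 1L,
    chisq = cmp$chisq, df = cmp$df, p = cmp$p,
    status_model1 = m1$status, status_model2 = status2,
    fixed_effects = fixed_terms,
    structure = structure_kind)
  class(res) <- "model_comparison"
  res
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Mixed-model comparison (ML): coordination as a random effect\n")
  cat(sprintf("  Model 1: df = %d, logLik = %.1f\n", x$df_model1, x$logLik1))
  cat(sprintf("  Model 2: df = %d, logLik = %.1f  [%s structure]\n",
              x$df_model2, x$logLik2, x$structure))
  cat(sprintf("  LRT: chi-square(%d) = %.3f, p = %.4g\n", x$df, x$chisq, x$p))
  if (length(x$status_model2)) {
    cat("  notes:", paste(x$status_model2, collapse = "; "), "\n")
  }
  if (!is.null(x$fixed_effects)) {
    cat("  fixed effects under Model 2:\n")
    print.data.frame(x$fixed_effects, row.names = FALSE)
  }
  invisible(x)
}
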