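test_that("paired t matches the textbook formula and handles degeneracies", {
  a <- c(5, 7, 9, 11)
  b <- a - c(1, 2, 3, 4)  # differences 1..4
  res <- paired_t(a, b)
  d <- a - b
  expect_equal(res$statistic, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$d, mean(d) / sd(d), tolerance = 1e-12)

  same <- paired_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)

  shifted <- paired_t(a + 2, a)
  expect_equal(shifted$statistic, Inf)
  expect_equal(shifted$p, 0)

  expect_equal(paired_t(a, b, n_comparisons = 200)$p_corrected, 1)
  expect_error(paired_t(a, b[1:3]), "paired")
  expect_error(paired_t(1, 2), "at least 2")
})

make_2x2_within <- function(n = 20, seed = 5, effect_a = 6, effect_b = 0,
                            inter = 0, sigma = 8) {
  set.seed(seed)
  grid <- expand.grid(id = sprintf("s%02d", 1:n), A = c("a1", "a2"),
                      B = c("b1", "b2"), stringsAsFactors = FALSE)
  subj <- rnorm(n, 0, 10)
  grid$y <- 300 + subj[match(grid$id, unique(grid$id))] +
    effect_a * (grid$A == "a2") + effect_b * (grid$B == "b2") +
    inter * (grid$A == "a2") * (grid$B == "b2") + rnorm(nrow(grid), 0, sigma)
  grid
}

test_that("repeated-measures ANOVA reproduces F = t^2 for 2-level factors", {
  d <- make_2x2_within()
  res <- rm_anova(d, "y", "id", c("A", "B"))
  marg <- tapply(d$y, list(d$id, d$A), mean)
  tt <- paired_t(marg[, "a2"], marg[, "a1"])
  i <- match("A", res$term)
  expect_equal(res$F[i], tt$statistic^2, tolerance = 1e-9)
  expect_equal(res$p[i], tt$p, tolerance = 1e-9)
  expect_equal(res$df1[i], 1)
  expect_equal(res$df2[i], 19)
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("ANOVA terms match a direct sums-of-squares oracle", {
  d <- make_2x2_within(n = 12, seed = 6, effect_a = 4, effect_b = 3, inter = 5)
  res <- rm_anova(d, "y", "id", c("A", "B"))
  # direct within-subject decomposition for factor A
  cellA <- tapply(d$y, list(d$id, d$A), mean)
  diffs <- cellA[, 2] - cellA[, 1]
  n <- nrow(cellA)
  F_a <- (mean(diffs) / (sd(diffs) / sqrt(n)))^2
  i <- match("A", res$term)
  expect_equal(res$F[i], F_a, tolerance = 1e-9)
  # interaction via the double-difference contrast
  cells <- tapply(d$y, list(d$id, d$A, d$B), mean)
  dd <- (cells[, 2, 2] - cells[, 1, 2]) - (cells[, 2, 1] - cells[, 1, 1])
  F_ab <- (mean(dd) / (sd(dd) / sqrt(n)))^2
  j <- match("A:B", res$term)
  expect_equal(res$F[j], F_ab, tolerance = 1e-9)
})

test_that("ANOVA rejects degenerate or incomplete designs", {
  d <- make_2x2_within(n = 6)
  expect_error(rm_anova(d[-1, ], "y", "id", c("A", "B")), "not fully crossed")
  d0 <- d
  d0$y <- 5
  expect_error(rm_anova(d0, "y", "id", c("A", "B")), "no variance")
})

test_that("between-subject factors and GG correction are supported", {
  d <- make_2x2_within(n = 16, seed = 8, effect_a = 6)
  d$grp <- ifelse(d$id %in% sprintf("s%02d", 1:8), "g1", "g2")
  res <- rm_anova(d, "y", "id", c("A", "B"), between = "grp")
  expect_true("grp" %in% res$term)
  expect_true("grp:A" %in% res$term)
  # two-level within factor: GG epsilon is 1, corrected p equals raw p
  res_gg <- rm_anova(d, "y", "id", c("A", "B"), gg = "A")
  i <- match("A", res_gg$term)
  expect_equal(res_gg$p_gg[i], res_gg$p[i], tolerance = 1e-9)
})

make_lmm_data <- function(n_pairs = 15, seed = 1, slope_sd = 30,
                          coord_per_condition = TRUE) {
  set.seed(seed)
  pairs <- sprintf("p%02d", seq_len(n_pairs))
  coord <- if (coord_per_condition) {
    expand.grid(pair = pairs, condition = c("individual", "joint"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(pair = pairs, condition = "joint", stringsAsFactors = FALSE)
  }
  coord$coordination <- runif(nrow(coord), 0.05, 0.25)
  b_pair <- rnorm(n_pairs, 0, slope_sd)
  grid <- expand.grid(member = c("L", "R"), pair = pairs,
                      condition = c("individual", "joint"),
                      correspondence = c("C", "NC"), stringsAsFactors = FALSE)
  grid$participant <- paste(grid$pair, grid$member, sep = "_")
  grid <- merge(grid, coord, by = c("pair", "condition"))
  subj <- rnorm(n_pairs * 2, 0, 6)
  grid$rt <- 340 + subj[match(grid$participant, unique(grid$participant))] +
    10 * (grid$correspondence == "NC") - 4 * (grid$condition == "joint") +
    (grid$coordination - mean(grid$coordination)) *
      b_pair[match(grid$pair, pairs)] +
    rnorm(nrow(grid), 0, 3)
  grid
}

test_that("model comparison detects a real coordination random effect", {
  d <- make_lmm_data(seed = 3, slope_sd = 40)
  cmp <- compare_models_lrt(d)
  expect_equal(cmp$df_model2, cmp$df_model1 + 1)
  expect_gte(cmp$chisq, 0)
  expect_gt(cmp$chisq, 3.84)
  expect_lt(cmp$p, 0.05)
  expect_s3_class(cmp$fixed_effects, "data.frame")
  expect_true(all(cmp$fixed_effects$chisq >= 0))
  # correspondence effect (10 ms injected) survives under Model 2
  expect_lt(cmp$fixed_effects$p[cmp$fixed_effects$term == "correspondence"],
            0.001)
})

test_that("a constant coordination covariate carries no information", {
  d <- make_lmm_data(seed = 4, slope_sd = 0)
  d$coordination <- 0.15
  cmp <- compare_models_lrt(d)
  expect_equal(cmp$chisq, 0)
  expect_equal(cmp$p, 1)
  expect_match(paste(cmp$status_model2, collapse = " "), "constant")
})

test_that("the alternative random-intercept structure is available", {
  d <- make_lmm_data(seed = 5, slope_sd = 40)
  cmp <- compare_models_lrt(d, structure = "intercept_by_level")
  expect_gte(cmp$chisq, -1e-6)
  expect_equal(cmp$structure, "intercept_by_level")
})
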