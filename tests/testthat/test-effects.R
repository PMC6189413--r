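make_cell_trials <- function(n_participants = 4, conditions = c("individual", "joint"),
                             mean_fun, n_per_cell = 5, sd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(participant = sprintf("s%02d", seq_len(n_participants)),
                      condition = conditions, correspondence = c("C", "NC"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    data.frame(participant = g$participant, condition = g$condition,
               correspondence = g$correspondence,
               rt_ms = rnorm(n_per_cell, mean_fun(g), sd),
               stringsAsFactors = FALSE)
  }))
}

test_that("condition means use two-stage averaging and flag empty cells", {
  const <- make_cell_trials(mean_fun = function(g) 300)
  tab <- condition_means(const)
  expect_true(all(tab$mean_rt == 300))
  expect_true(all(tab$sd_rt == 0))

  # cells constructed at 340 (joint C) / 350 (joint NC) are reproduced
  tab2 <- condition_means(make_cell_trials(
    mean_fun = function(g) {
      if (g$condition == "joint") ifelse(g$correspondence == "NC", 350, 340)
      else 345
    }))
  expect_equal(tab2$mean_rt[tab2$condition == "joint" &
                              tab2$correspondence == "C"], 340)
  expect_equal(simon_effect(tab2, "joint"), 10)
  expect_equal(simon_effect(tab2, "individual"), 0)

  # unbalanced trial counts: participant means first, then unweighted average
  tr <- make_cell_trials(mean_fun = function(g) 300, sd = 25, seed = 3)
  extra <- tr[1:7, ]
  extra$rt_ms <- extra$rt_ms + 120
  tr <- rbind(tr, extra)
  tab3 <- condition_means(tr)
  oracle <- sapply(split(tr, tr[c("condition", "correspondence")]), function(cell) {
    mean(tapply(cell$rt_ms, cell$participant, mean))
  })
  expect_equal(sort(tab3$mean_rt), sort(unname(oracle)), tolerance = 1e-12)

  expect_error(condition_means(tr[tr$correspondence == "NC" |
                                    tr$participant != "s01", ]),
               "s01")
  expect_error(simon_effect(tab2[-1, ], "individual"), "exactly one")
})

test_that("grand mean equals the mean of participant grand means", {
  tr <- make_cell_trials(mean_fun = function(g) 320, sd = 40, seed = 9)
  tab <- condition_means(tr)
  pm <- attr(tab, "participants")
  expect_equal(mean(tab$mean_rt),
               mean(tapply(pm$mean_rt, pm$participant, mean)),
               tolerance = 1e-12)
})

test_that("quartile bins split sorted RTs with remainders to early bins", {
  tr <- data.frame(participant = "s1", condition = "joint",
                   correspondence = "C", rt_ms = sample(1:8),
                   stringsAsFactors = FALSE)
  qt <- quartile_bin_means(tr)
  expect_equal(qt$mean_rt, c(1.5, 3.5, 5.5, 7.5))

  # remainder rule: 10 values -> bins of 3, 3, 2, 2
  tr10 <- data.frame(participant = "s1", condition = "joint",
                     correspondence = "C", rt_ms = sample(1:10),
                     stringsAsFactors = FALSE)
  qt10 <- quartile_bin_means(tr10)
  expect_equal(qt10$mean_rt, c(2, 5, 7.5, 9.5))

  expect_error(quartile_bin_means(tr[1:3, ]), "fewer than")
})

test_that("quartile table matches the brute-force oracle and is consistent", {
  tr <- make_cell_trials(mean_fun = function(g) 330, n_per_cell = 13, sd = 35,
                         seed = 11)
  qt <- quartile_bin_means(tr)
  # monotone within cells
  for (key in split(qt, qt[c("condition", "correspondence")])) {
    expect_true(all(diff(key$mean_rt[order(key$bin)]) >= 0))
  }
  # brute-force recomputation
  oracle <- aggregate(
    rt_ms ~ bin + condition + correspondence,
    do.call(rbind, lapply(split(tr, tr[c("participant", "condition",
                                         "correspondence")]), function(cell) {
      rt <- sort(cell$rt_ms)
      b <- rep(1:4, c(4, 3, 3, 3))  # 13 values: extras to earliest bins
      data.frame(condition = cell$condition[1],
                 correspondence = cell$correspondence[1],
                 participant = cell$participant[1],
                 bin = 1:4, rt_ms = as.numeric(tapply(rt, b, mean)))
    })), mean)
  merged <- merge(qt, oracle, by = c("condition", "correspondence", "bin"))
  expect_equal(merged$mean_rt, merged$rt_ms, tolerance = 1e-9)

  # partition consistency: bin sizes weight back to the cell mean
  pm <- attr(qt, "participants")
  one <- pm[pm$participant == "s01" & pm$condition == "joint" &
              pm$correspondence == "C", ]
  cell_rts <- tr$rt_ms[tr$participant == "s01" & tr$condition == "joint" &
                         tr$correspondence == "C"]
  expect_equal(sum(one$mean_rt * c(4, 3, 3, 3)) / 13, mean(cell_rts),
               tolerance = 1e-9)
})

test_that("pooled-correspondence binning is selectable", {
  tr <- make_cell_trials(mean_fun = function(g) 330, n_per_cell = 8, sd = 20,
                         seed = 12)
  qt <- quartile_bin_means(tr, by_correspondence = FALSE)
  expect_true(all(qt$correspondence == "all"))
  expect_equal(nrow(qt), 8L)  # 2 conditions x 4 bins
})

test_that("transition tables derive the rowwise sequential effect", {
  tt <- transition_table(data.frame(
    transition = c("Nogo/go", "Nogo/go", "Go/go", "Go/go"),
    prev_correspondence = c("C", "NC", "C", "NC"),
    C = c(334, 350, 342, 341), NC = c(358, 341, 348, 345)))
  expect_equal(tt$se, c(24, -9, 6, 4))

  # constant RTs give all-zero sequential effects
  grid <- expand.grid(participant = c("a", "b"),
                      transition = c("Nogo/go", "Go/go"),
                      prev_correspondence = c("C", "NC"),
                      correspondence = c("C", "NC"),
                      stringsAsFactors = FALSE)
  grid$rt_ms <- 300
  tt0 <- sequential_effect_table(grid)
  expect_true(all(tt0$se == 0))
  expect_error(sequential_effect_table(grid[grid$correspondence == "C", ]),
               "empty transition cell")
})

test_that("marginal means average cells with equal weights", {
  tab <- reference_effect_table("competitive")
  expect_equal(marginal_mean(tab, correspondence = "C"), 320)
  expect_equal(marginal_mean(tab, condition = "joint"), 305)
  tt <- reference_transition_table("cooperative")
  expect_equal(marginal_mean(tt, correspondence = "NC"), 348)
  expect_error(marginal_mean(tab, condition = "absent"), "no cells")
})
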