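# helpers to assemble per-map inputs without running the full imaging chain
fake_map_result <- function(status, scores, label = "DNA-m") {
  corr <- list()
  corr[[label]] <- fake_corr_map(scores, status$x, status$y, label)
  list(status = status, corr = corr)
}

fake_status <- function(x, y, base_pos, base = "DNA") {
  tbl <- data.frame(x = x, y = y)
  for (l in c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m"))
    tbl[[l]] <- 0L
  tbl[[base]] <- as.integer(base_pos)
  structure(tbl, cutoffs = numeric(0), quantile = 0.75,
            class = c("status_table", "data.frame"))
}

test_that("level collection applies the nucleus-and-base-positive filter exactly", {
  x <- 0:4; y <- rep(0L, 5)
  st <- fake_status(x, y, c(1, 0, 1, 1, 0))
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  gm <- list(G1 = list(fake_map_result(st, sc)))
  lv <- collect_levels(gm, "DNA-m")
  expect_equal(lv$G1$n, 3L)
  expect_equal(lv$G1$scores, sc[c(1, 3, 4)])   # brute-force filter oracle

  # pooling across two maps is additive
  st2 <- fake_status(0:3, rep(1L, 4), c(1, 1, 1, 1))
  gm2 <- list(G1 = list(fake_map_result(st, sc),
                        fake_map_result(st2, c(0.4, 0.3, 0.2, 0.1))))
  expect_equal(collect_levels(gm2, "DNA-m")$G1$n, 7L)

  # all-base-negative group errors by name
  st0 <- fake_status(x, y, rep(0, 5))
  expect_error(collect_levels(list(BAD = list(fake_map_result(st0, sc))), "DNA-m"),
               "'BAD'")
})

test_that("relative levels are anchored at control = 1 with exact scaling", {
  mk <- function(g, s) structure(list(group_label = g, modification = "DNA-m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  groups <- list(CTRL = mk("CTRL", c(0.2, 0.4, 0.6)),
                 X = mk("X", 2 * c(0.2, 0.4, 0.6)))
  rl <- relative_levels(groups)
  expect_equal(rl$ratio_to_ctrl[rl$group == "CTRL"], 1)
  expect_equal(rl$ratio_to_ctrl[rl$group == "X"], 2)
  expect_error(relative_levels(groups, ctrl_label = "NOPE"), "NOPE")
  zero <- list(CTRL = mk("CTRL", c(0, 0, 0)), X = mk("X", c(1, 2, 3)))
  expect_error(relative_levels(zero), "undefined ratio")
})

test_that("the Z-DNA score is 1 for symmetric groups and scale-invariant", {
  mk <- function(g, s, mod) structure(list(group_label = g, modification = mod,
                                           scores = s, n = length(s)),
                                      class = "group_levels")
  z <- list(CTRL = mk("CTRL", c(0.3, 0.5), "Z-DNA"), X = mk("X", c(0.3, 0.5), "Z-DNA"))
  b <- list(CTRL = mk("CTRL", c(0.3, 0.5), "B-DNA"), X = mk("X", c(0.3, 0.5), "B-DNA"))
  sc <- zdna_score(z, b)
  expect_equal(sc$score, c(1, 1))
  expect_equal(sc$score[sc$group == "CTRL"], 1)

  z2 <- lapply(z, function(g) { g$scores <- g$scores * 7.3; g })
  b2 <- lapply(b, function(g) { g$scores <- g$scores * 7.3; g })
  expect_equal(zdna_score(z2, b2)$score, sc$score, tolerance = 1e-12)

  b0 <- b; b0$X$scores <- c(0, 0)
  expect_error(zdna_score(z, b0), "zero B-DNA")
})

test_that("the omnibus H statistic matches the closed-form rank-sum formula", {
  mk <- function(g, s) structure(list(group_label = g, modification = "m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  groups <- list(A = mk("A", c(1, 4, 7)), B = mk("B", c(2, 5, 8)),
                 C = mk("C", c(3, 6, 9)))   # distinct ranks, no ties
  res <- group_tests(groups)
  vals <- c(1, 4, 7, 2, 5, 8, 3, 6, 9)
  r <- rank(vals); N <- 9
  rbars <- c(mean(r[1:3]), mean(r[4:6]), mean(r[7:9]))
  H <- 12 / (N * (N + 1)) * sum(3 * rbars^2) - 3 * (N + 1)
  expect_equal(res$omnibus$H, H, tolerance = 1e-12)
  expect_equal(res$omnibus$df, 2)
})

test_that("completely separated groups are flagged far below q = 0.01", {
  mk <- function(g, s) structure(list(group_label = g, modification = "m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  res <- group_tests(list(LO = mk("LO", 1:10 / 100), HI = mk("HI", 1:10 / 100 + 10)))
  expect_lt(res$pairwise$q[1], 0.01)
  expect_lt(res$pairwise$p[1], res$pairwise$q[1] + 1e-15)
})

test_that("Holm q-values dominate raw p and are rank-monotone", {
  set.seed(9)
  mk <- function(g, s) structure(list(group_label = g, modification = "m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  groups <- lapply(stats::setNames(1:5, paste0("G", 1:5)), function(i)
    mk(paste0("G", i), rnorm(8, mean = i * 0.1)))
  res <- group_tests(groups)
  expect_true(all(res$pairwise$q >= res$pairwise$p - 1e-15))
  expect_true(all(res$pairwise$q <= 1))
  ord <- order(res$pairwise$p)
  expect_true(all(diff(res$pairwise$q[ord]) >= -1e-15))
  expect_equal(res$pairwise$q, p.adjust(res$pairwise$p, "holm"))
})

test_that("degenerate and undersized group inputs are rejected", {
  mk <- function(g, s) structure(list(group_label = g, modification = "m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  expect_error(group_tests(list(A = mk("A", 1:3))), "at least 2 groups")
  expect_error(group_tests(list(A = mk("A", 1:3), B = mk("B", 2))), "n >= 2")
  expect_error(group_tests(list(A = mk("A", c(1, 1)), B = mk("B", c(1, 1)))),
               "degenerate")
})

test_that("the omnibus test holds its nominal size under the null", {
  set.seed(10)
  mk <- function(g, s) structure(list(group_label = g, modification = "m",
                                      scores = s, n = length(s)),
                                 class = "group_levels")
  rej <- replicate(250, {
    groups <- lapply(stats::setNames(1:3, c("A", "B", "C")), function(i)
      mk(paste0("G", i), rnorm(10)))
    group_tests(groups)$omnibus$p < 0.05
  })
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.085)
})
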