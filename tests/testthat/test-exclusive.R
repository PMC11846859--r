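test_that("status cutoffs equal the sort-based quartile oracle over nucleus pixels", {
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  x <- 0:7; y <- rep(0L, 8)
  cmaps <- list("DNA-m" = fake_corr_map(scores, x, y, "DNA-m"))
  cm <- class_map(rep(1L, 8), x, y)
  st <- call_status(cmaps, cm, 0.75)
  # linear-interpolation (type 7) quartile on the sorted values
  srt <- sort(scores)
  h <- (8 - 1) * 0.75 + 1
  q3 <- srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  expect_equal(unname(attr(st, "cutoffs")["DNA-m"]), q3)
  expect_equal(st[["DNA-m"]], as.integer(scores >= q3))
  expect_equal(sum(st[["DNA-m"]]), sum(scores >= q3))
  expect_equal(attr(st, "quantile"), 0.75)
})

test_that("cutoffs are estimated among nucleus pixels only and default to the 3rd quartile", {
  set.seed(2)
  n <- 30L
  x <- rep(0:5, 5); y <- rep(0:4, each = 6)
  raw <- runif(n)
  labels <- rep(c(1L, 0L, 2L), times = c(10, 10, 10))
  st <- call_status(list("DNA" = fake_corr_map(raw, x, y)), class_map(labels, x, y))
  expect_equal(nrow(st), 10L)
  expect_equal(unname(attr(st, "cutoffs")["DNA"]),
               unname(quantile(raw[labels == 1L], 0.75, type = 7)))
  expect_error(call_status(list("DNA" = fake_corr_map(raw, x, y)),
                           class_map(rep(0L, n), x, y)),
               "no nucleus")
})

test_that("tied scores are all called positive and flagged degenerate upstream", {
  x <- 0:5; y <- rep(0L, 6)
  st <- call_status(list("Lys" = fake_corr_map(rep(0.4, 6), x, y, "Lys")),
                    class_map(rep(1L, 6), x, y))
  expect_true(all(st[["Lys"]] == 1L))
})

test_that("exclusive membership equals the row-by-row predicate oracle", {
  st <- random_status_fixture(n_pix = 48, seed = 13)
  for (mod in c("DNA-m", "Lys-m", "Lys-a", "Arg-m")) {
    ex <- extract_exclusive(st, mod)
    base <- base_species(mod)
    others <- setdiff(c("DNA-m", "Lys-m", "Lys-a", "Arg-m"), mod)
    oracle <- vapply(seq_len(nrow(st)), function(i) {
      st[[mod]][i] == 1L && st[[base]][i] == 1L &&
        all(vapply(others, function(o) st[[o]][i] == 0L, logical(1)))
    }, logical(1))
    expect_equal(ex$n, sum(oracle))
    expect_equal(paste(ex$pixels$x, ex$pixels$y),
                 paste(st$x[oracle], st$y[oracle]))
  }
  expect_error(extract_exclusive(st, "H3K27me3"), "unknown modification")
  st2 <- st; st2[["Arg"]] <- NULL
  expect_error(extract_exclusive(st2, "Arg-m"), "missing labels")
})

test_that("the worked examples of the exclusivity rule hold", {
  x <- 0:1; y <- c(0L, 0L)
  mk <- function(v) fake_corr_map(v, x, y)
  # pixel 1: Lys+, Lys-a+ only -> exclusive Lys-a
  # pixel 2: Lys+, Lys-a+, DNA-m+ -> excluded
  tbl <- data.frame(x = x, y = y,
                    "DNA" = c(0L, 0L), "DNA-m" = c(0L, 1L),
                    "Lys" = c(1L, 1L), "Lys-m" = c(0L, 0L),
                    "Lys-a" = c(1L, 1L), "Arg" = c(0L, 0L),
                    "Arg-m" = c(0L, 0L), check.names = FALSE)
  st <- structure(tbl, cutoffs = numeric(0), quantile = 0.75,
                  class = c("status_table", "data.frame"))
  ex <- extract_exclusive(st, "Lys-a")
  expect_equal(ex$n, 1L)
  expect_equal(ex$pixels$x, 0L)
  # empty exclusive sets are a valid outcome
  ex_d <- extract_exclusive(st, "DNA-m")
  expect_equal(ex_d$n, 0L)
})

test_that("exclusive sets are pairwise disjoint and shrink as the cutoff rises", {
  st <- random_status_fixture(n_pix = 64, seed = 29)
  mods <- c("DNA-m", "Lys-m", "Lys-a", "Arg-m")
  sets <- lapply(mods, function(m)
    paste(extract_exclusive(st, m)$pixels$x, extract_exclusive(st, m)$pixels$y))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(sets[[i]], sets[[j]]), 0)

  set.seed(31)
  n <- 40L
  x <- rep(0:7, 5); y <- rep(0:4, each = 8)
  cmaps <- lapply(c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m"),
                  function(l) fake_corr_map(runif(n), x, y, l))
  names(cmaps) <- c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m")
  cm <- class_map(rep(1L, n), x, y)
  sizes <- sapply(c(0.5, 0.75, 0.9), function(q) {
    st_q <- call_status(cmaps, cm, q)
    sapply(mods, function(m) extract_exclusive(st_q, m)$n)
  })
  # within each modification, a higher quantile can only lose base+mod pixels
  cutpos <- sapply(c(0.5, 0.75, 0.9), function(q) {
    st_q <- call_status(cmaps, cm, q)
    sapply(mods, function(m) sum(st_q[[m]] & st_q[[base_species(m)]]))
  })
  for (i in seq_along(mods)) expect_true(all(diff(cutpos[i, ]) <= 0))
})

test_that("status calls are invariant under strictly increasing score transforms", {
  set.seed(37)
  n <- 30L
  x <- rep(0:5, 5); y <- rep(0:4, each = 6)
  raw <- runif(n)
  cm <- class_map(rep(1L, n), x, y)
  s1 <- call_status(list("DNA" = fake_corr_map(raw, x, y)), cm, 0.6)
  s2 <- call_status(list("DNA" = fake_corr_map(exp(3 * raw), x, y)), cm, 0.6)
  expect_equal(s1[["DNA"]], s2[["DNA"]])
})

test_that("multiplexed overlays are transparent at zero level and rank-faithful", {
  n <- 9L
  x <- rep(0:2, 3); y <- rep(0:2, each = 3)
  base <- fake_corr_map(seq(0, 1, length.out = n), x, y, "DNA")
  set.seed(41)
  labs7 <- c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m")
  cmaps <- lapply(labs7, function(l) fake_corr_map(runif(n), x, y, l))
  names(cmaps) <- labs7
  st <- call_status(cmaps, class_map(rep(1L, n), x, y))
  zero <- fake_corr_map(rep(0.3, n), x, y, "Lys-a")   # degenerate -> norm 0.5
  zero$norm <- rep(0, n)                              # zero-level modification
  ov <- overlay_multiplex(base, st, list("Lys-a" = zero))
  expect_true(all(ov$alpha[["Lys-a"]] == 0))

  lv <- fake_corr_map(seq_len(n) / n, x, y, "Lys-a")
  st1 <- st
  for (l in c("Lys", "Lys-a")) st1[[l]] <- rep(0L, n)
  st1[["Lys"]][4] <- 1L; st1[["Lys-a"]][4] <- 1L
  ov1 <- overlay_multiplex(base, st1, list("Lys-a" = lv))
  a <- ov1$alpha[["Lys-a"]]
  expect_equal(sum(a > 0), 1L)
  expect_gt(a[st1$y[4] + 1L, st1$x[4] + 1L], 0)

  st_all <- st
  for (l in c("Lys", "Lys-a")) st_all[[l]] <- rep(1L, n)
  ov2 <- overlay_multiplex(base, st_all, list("Lys-a" = lv))
  got <- ov2$alpha[["Lys-a"]][cbind(y + 1L, x + 1L)]
  expect_identical(order(got), order(lv$norm))
})
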