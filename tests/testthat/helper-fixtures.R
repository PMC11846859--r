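# Shared fixtures: everything is generated in code at test time.

# short fingerprint-window grid used where full resolution is not the point
grid_small <- function() seq(800, 1200, by = 4)   # 101 points

# a tiny valid hypermap with deterministic content
tiny_map <- function(n_x = 3L, n_y = 2L, grid = grid_small(), seed = 42L) {
  set.seed(seed)
  n <- n_x * n_y
  hypermap(grid,
           matrix(runif(n * length(grid)), n, length(grid)),
           x = rep(seq_len(n_x) - 1L, times = n_y),
           y = rep(seq_len(n_y) - 1L, each = n_x))
}

# three synthetic classes with disjoint differentiating peaks, for classifier
# tests: class 0 (stroma-like), 1 (nucleus-like), 2 (cytoplasm-like)
separable_classes <- function(n_per_class, grid = grid_small(), seed = 1L,
                              noise_sd = 0.05) {
  set.seed(seed)
  centers <- list(`0` = c(850, 940, 1150), `1` = c(820, 1000, 1100),
                  `2` = c(880, 1050, 1180))
  X <- NULL; y <- integer(0)
  for (k in 0:2) {
    base <- rowSums(sapply(centers[[as.character(k)]], function(cc)
      1 / (1 + ((grid - cc) / 8)^2)))
    cls <- t(replicate(n_per_class,
                       base * runif(1, 0.7, 1.3) + rnorm(length(grid), sd = noise_sd)))
    X <- rbind(X, cls)
    y <- c(y, rep(k, n_per_class))
  }
  X <- t(apply(X, 1L, function(s) (s - min(s)) / (max(s) - min(s))))
  list(X = X, labels = y, centers = centers)
}

# fabricate a corr_map object without running correlation (for status tests)
fake_corr_map <- function(raw, x, y, label = "DNA", width = max(x) + 1L,
                          height = max(y) + 1L) {
  oriented <- raw
  rng <- range(oriented)
  norm <- if (diff(rng) <= 0) rep(0.5, length(raw))
          else (oriented - rng[1L]) / diff(rng)
  structure(list(reference_label = label, metric = "pearson",
                 raw = raw, norm = norm, x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height),
                 grid_range = c(600, 1900), higher_is_similar = TRUE,
                 degenerate = diff(rng) <= 0),
            class = "corr_map")
}

# a complete random status input (seven labels) over one nucleus blob
random_status_fixture <- function(n_pix = 40L, seed = 7L, quantile = 0.75) {
  set.seed(seed)
  x <- rep(0:7, length.out = n_pix)
  y <- rep(0:((n_pix - 1) %/% 8), each = 8L)[seq_len(n_pix)]
  labels <- rep(1L, n_pix)
  cmaps <- lapply(c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m"),
                  function(l) fake_corr_map(runif(n_pix), x, y, l))
  names(cmaps) <- c("DNA", "DNA-m", "Lys", "Lys-m", "Lys-a", "Arg", "Arg-m")
  cm <- class_map(labels, x, y)
  call_status(cmaps, cm, quantile)
}

# brute-force two-sided exact Mann-Whitney p by full enumeration (combn)
brute_mw <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  sums <- colSums(matrix(r[sets], nrow = n1))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  list(U = w_obs - n1 * (n1 + 1) / 2, p = min(1, 2 * min(p_le, p_ge)))
}
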