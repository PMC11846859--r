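test_that("similarity metrics honour their algebraic identities", {
  set.seed(1)
  s <- runif(50)
  expect_equal(similarity(s, s, "pearson"), 1)
  expect_equal(similarity(s, 2.5 * s + 3, "pearson"), 1)
  expect_equal(similarity(s, s, "spearman"), 1)
  expect_equal(similarity(s, s, "euclidean-unit-norm"), 0)
  expect_equal(similarity(s, 4 * s, "cosine-squared"), 1)
  expect_error(similarity(rep(1, 50), s, "pearson"), "constant")
  # direct covariance / sigma-sigma formula on a 10-point pair
  a <- c(0.2, 1.4, 0.7, 2.2, 1.9, 0.1, 0.5, 2.8, 1.1, 0.9)
  b <- c(1.0, 0.3, 2.1, 1.7, 0.4, 2.6, 0.8, 1.2, 0.6, 2.0)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(similarity(a, b, "pearson"), hand, tolerance = 1e-12)
})

test_that("correlation maps match a brute-force per-pixel loop for every metric", {
  m <- tiny_map(5, 4, seed = 12)
  ref <- ref_spectrum("DNA", m$wavenumber, abs(sin(seq_along(m$wavenumber) / 9)))
  for (met in similarity_metrics()) {
    cm <- correlation_map(m, ref, met, window = range(m$wavenumber))
    oracle <- vapply(seq_len(n_pixels(m)), function(i)
      similarity(m$intensity[i, ], ref$intensity, met), numeric(1))
    expect_equal(cm$raw, oracle, tolerance = 1e-12)
    expect_identical(order(cm$raw), order(oracle))
    expect_true(all(cm$norm >= 0 & cm$norm <= 1))
    expect_equal(max(cm$norm), 1)
    expect_equal(min(cm$norm), 0)
  }
})

test_that("pure reference pixels top a noiseless correlation map", {
  g <- default_grid()
  lib <- default_species_library()
  dna <- make_reference(lib$DNA, g)
  prot <- make_reference(lib$protein, g)
  mix <- rbind(dna$intensity,                       # pure DNA
               0.5 * dna$intensity + 0.5 * prot$intensity,
               prot$intensity)
  m <- hypermap(g, mix, x = 0:2, y = c(0L, 0L, 0L))
  cm <- correlation_map(m, dna)
  expect_equal(cm$norm[1], 1)
  expect_equal(which.max(cm$raw), 1L)
})

test_that("degenerate score maps normalise to 0.5 and are flagged", {
  g <- grid_small()
  one <- abs(cos(seq_along(g) / 5))
  m <- hypermap(g, rbind(one, one, one), x = 0:2, y = rep(0L, 3))
  ref <- ref_spectrum("DNA", g, abs(sin(seq_along(g) / 7)))
  cm <- correlation_map(m, ref, window = range(g))
  expect_true(cm$degenerate)
  expect_equal(cm$norm, rep(0.5, 3))
})

test_that("pearson scoring is invariant to per-spectrum 0-1 normalisation", {
  m <- tiny_map(4, 3, seed = 20)
  ref <- ref_spectrum("X", m$wavenumber, abs(sin(seq_along(m$wavenumber) / 4)))
  m2 <- m
  m2$intensity <- t(apply(m$intensity, 1, normalize01))
  c1 <- correlation_map(m, ref, "pearson", range(m$wavenumber))
  c2 <- correlation_map(m2, ref, "pearson", range(m$wavenumber))
  expect_equal(c1$raw, c2$raw, tolerance = 1e-12)
})

test_that("raw pearson rises monotonically with the mixing coefficient", {
  g <- default_grid()
  lib <- default_species_library()
  dna <- make_reference(lib$DNA, g)$intensity
  prot <- make_reference(lib$protein, g)$intensity
  cc <- seq(0, 1, by = 0.1)
  X <- t(sapply(cc, function(a) a * dna + 1 * prot))
  m <- hypermap(g, X, x = seq_along(cc) - 1L, y = rep(0L, length(cc)))
  cm <- correlation_map(m, ref_spectrum("DNA", g, dna))
  expect_true(all(diff(cm$raw) > -1e-12))
})

test_that("the metric comparison reports all five metrics with honest contrasts", {
  scn <- make_scene(20, 20, n_nuclei = 2, truth = c("DNA-m" = 0.4), seed = 41,
                    nucleus_frac = 0.2)
  r <- render_map(scn, noise = noise_model(0, 0, 0), seed = 42)
  pp <- preprocess_map(r$map, despike = FALSE, baseline = FALSE)
  dna <- make_reference(default_species_library()$DNA, default_grid())
  tab <- compare_metrics(pp$map, dna, r$truth)
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$metric, similarity_metrics())
  expect_true(all(tab$separation > 0))
  expect_error(compare_metrics(pp$map, dna), "ground-truth")

  # null control: a pure-noise map carries no nucleus contrast
  for (sd_seed in c(1, 2, 3)) {
    set.seed(sd_seed)
    noise_map <- hypermap(default_grid(),
                          t(apply(matrix(rnorm(400 * 651), 400), 1, normalize01)),
                          x = rep(0:19, 20), y = rep(0:19, each = 20))
    truth0 <- class_map(rep(c(1L, 0L), each = 200), noise_map$x, noise_map$y)
    tab0 <- compare_metrics(noise_map, dna, truth0)
    expect_true(all(abs(tab0$separation) < 0.05))
  }
})
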