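test_that("baseline removal is exact on pure polynomials and flat input", {
  t <- seq(0, 1, length.out = 200)
  cubic <- 2 + 0.5 * t - 1.2 * t^2 + 0.8 * t^3
  r <- remove_baseline(cubic)
  expect_lt(max(abs(r$corrected)), 1e-6 * max(abs(cubic)))
  z <- remove_baseline(rep(0, 50))
  expect_equal(z$corrected, rep(0, 50))
  expect_equal(z$baseline, rep(0, 50))
  expect_error(remove_baseline(1:5), "too few points")
})

test_that("baseline recovery under sparse peaks tracks the generating cubic", {
  g <- default_grid()
  t <- (g - min(g)) / diff(range(g))
  true_base <- 0.4 + 0.3 * t + 0.2 * t^2 - 0.1 * t^3
  peaks <- rowSums(sapply(c(700, 1000, 1300, 1600), function(cc)
    1 / (1 + ((g - cc) / 8)^2)))        # narrow: well under 30% coverage
  r <- remove_baseline(peaks + true_base)
  expect_lt(max(abs(r$baseline - true_base)), 0.05 * diff(range(true_base)))
})

test_that("despiking removes exactly the injected single-bin spikes", {
  g <- grid_small()
  smooth <- 1 / (1 + ((g - 1000) / 30)^2)
  clean <- remove_spikes(smooth)
  expect_identical(clean$intensity, smooth)
  expect_equal(clean$n_removed, 0L)

  spiked <- smooth
  pos <- c(12L, 50L, 88L)
  spiked[pos] <- spiked[pos] + 8 * max(smooth)
  r <- remove_spikes(spiked)
  expect_equal(r$positions, pos)
  expect_equal(r$n_removed, 3L)
  expect_identical(r$intensity[-pos], spiked[-pos])
  expect_lt(max(abs(r$intensity - smooth)), 0.05 * max(smooth))
})

test_that("a genuine band a few bins wide is not mistaken for a spike", {
  g <- default_grid()                    # 2 cm^-1 steps
  band <- 1 / (1 + ((g - 1200) / 10)^2)  # ~5-bin half width
  r <- remove_spikes(band)
  expect_equal(r$n_removed, 0L)
  expect_equal(r$intensity[which.min(abs(g - 1200))],
               band[which.min(abs(g - 1200))])
})

test_that("0-1 normalisation is an idempotent affine map that rejects constants", {
  expect_equal(normalize01(c(2, 4, 6)), c(0, 0.5, 1))
  x <- normalize01(rnorm(20))
  expect_equal(normalize01(x), x)
  expect_error(normalize01(c(5, 5, 5)), "degenerate")
})

test_that("map preprocessing audits spikes and baselines per pixel", {
  scn <- make_scene(16, 16, n_nuclei = 2, truth = c("DNA-m" = 0.4), seed = 31,
                    nucleus_frac = 0.2)
  r <- render_map(scn, noise = noise_model(0.4, 0.03, spike_rate = 0.3), seed = 32)
  pp <- preprocess_map(r$map)
  expect_equal(nrow(pp$report), n_pixels(r$map))
  expect_true(all(pp$report$n_spikes_removed >= 0))
  # most injected spikes are caught (they are 8x the max signal)
  expect_gt(sum(pp$report$n_spikes_removed), 0.8 * nrow(r$spikes))
  expect_false(any(pp$report$denoise_applied))
  expect_equal(unname(apply(pp$map$intensity, 1, min)), rep(0, n_pixels(r$map)))
  expect_equal(unname(apply(pp$map$intensity, 1, max)), rep(1, n_pixels(r$map)))
})

test_that("autoencoder training is deterministic and its output bounded in [0,1]", {
  set.seed(5)
  g <- grid_small()
  base <- 1 / (1 + ((g - 1000) / 20)^2)
  X <- t(replicate(120, normalize01(base * runif(1, 0.5, 1.5) +
                                      rnorm(length(g), sd = 0.05))))
  spec <- autoencoder_spec(epochs = 4, seed = 11)
  d1 <- train_autoencoder(X, spec)
  d2 <- train_autoencoder(X, spec)
  expect_identical(denoise(d1, X[1:5, ]), denoise(d2, X[1:5, ]))
  out <- denoise(d1, X)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(dim(out), dim(X))
  expect_error(denoise(d1, X[, 1:50]), "length")
  expect_error(train_autoencoder(X[1:50, ], spec), "batch_size")
  expect_error(train_autoencoder(X * 3, spec), "\\[0, 1\\]")
})

test_that("the autoencoder smooths pure noise", {
  set.seed(6)
  g <- grid_small()
  base <- 1 / (1 + ((g - 1000) / 20)^2) + 0.5 / (1 + ((g - 900) / 10)^2)
  X <- t(replicate(210, normalize01(base * runif(1, 0.5, 1.5) +
                                      rnorm(length(g), sd = 0.05))))
  den <- train_autoencoder(X, autoencoder_spec(epochs = 25, seed = 13))
  noise_in <- t(replicate(20, normalize01(rnorm(length(g)))))
  out <- denoise(den, noise_in)
  expect_lt(mean(apply(out, 1, var)), mean(apply(noise_in, 1, var)))
})
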