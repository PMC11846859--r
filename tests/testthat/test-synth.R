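test_that("rendered references are unimodal where built unimodal and 0-1 scaled", {
  g <- default_grid()
  one <- species_model("one", data.frame(center = c(1000, 1000, 1000),
                                         width = c(10, 10, 10),
                                         height = c(1, 1, 1)))
  ref <- make_reference(one, g)
  expect_equal(range(ref$intensity), c(0, 1))
  expect_equal(g[which.max(ref$intensity)], g[which.min(abs(g - 1000))])

  two <- species_model("two", data.frame(center = c(800, 1400, 1400),
                                         width = c(8, 8, 8),
                                         height = c(1, 1, 0.5)))
  r2 <- make_reference(two, g)
  at <- function(w) r2$intensity[which.min(abs(g - w))]
  expect_gt(at(800), at(1100))
  expect_gt(at(1400), at(1100))
})

test_that("species model validation enforces the peak-table contract", {
  expect_error(species_model("x", data.frame(center = 1000, width = 5, height = 1)),
               ">= 3 peaks")
  expect_error(species_model("x", data.frame(center = c(100, 1000, 1100),
                                             width = 5, height = 1)),
               "600-1900")
  m <- species_model("x", data.frame(center = c(900, 1000, 1100),
                                     width = 5, height = 1))
  m$peaks <- m$peaks[0, ]
  expect_error(make_reference(m), "empty peak list")
})

test_that("modified species are similar but distinguishable from their base species", {
  lib <- default_species_library()
  g <- default_grid()
  pairs <- list(c("DNA", "DNA-m"), c("Lys", "Lys-m"), c("Lys", "Lys-a"),
                c("Arg", "Arg-m"), c("B-DNA", "Z-DNA"))
  for (pr in pairs) {
    base <- lib[[pr[1]]]; mod <- lib[[pr[2]]]
    shared <- intersect(base$peaks$center, mod$peaks$center)
    expect_gte(length(shared), ceiling(nrow(mod$peaks) / 2))
    differing <- length(setdiff(mod$peaks$center, base$peaks$center)) +
      length(setdiff(base$peaks$center, mod$peaks$center))
    expect_gte(differing, 2L)
    r <- cor(make_reference(base, g)$intensity, make_reference(mod, g)$intensity)
    expect_gt(r, 0.3); expect_lt(r, 0.99)
  }
})

test_that("scenes are reproducible, respect truth levels, and stay in the nucleus band", {
  s1 <- make_scene(32, 32, n_nuclei = 4, truth = c("Lys-a" = 0.5), seed = 9)
  s2 <- make_scene(32, 32, n_nuclei = 4, truth = c("Lys-a" = 0.5), seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$mixing >= 0))
  expect_gt(mean(s1$region == 1L), 0.10)
  expect_lt(mean(s1$region == 1L), 0.34)
  # nucleus blobs are spatially coherent: nearly every nucleus pixel touches
  # another nucleus pixel
  nuc <- matrix(s1$region == 1L, s1$height, s1$width, byrow = FALSE)
  nuc <- matrix(FALSE, s1$height, s1$width)
  nuc[cbind(s1$y + 1L, s1$x + 1L)] <- s1$region == 1L
  pad <- rbind(FALSE, cbind(FALSE, nuc, FALSE), FALSE)
  h <- nrow(pad); w <- ncol(pad)
  neigh <- pad[2:(h-1), 1:(w-2)] | pad[2:(h-1), 3:w] |
    pad[1:(h-2), 2:(w-1)] | pad[3:h, 2:(w-1)]
  expect_gt(mean(neigh[nuc]), 0.95)

  s0 <- make_scene(32, 32, n_nuclei = 4, truth = c("Lys-a" = 0), seed = 9)
  expect_true(all(s0$mixing[, "Lys-a"] == 0))
  lo <- make_scene(32, 32, n_nuclei = 4, truth = c("Lys-a" = 0.2), seed = 9)
  hi <- make_scene(32, 32, n_nuclei = 4, truth = c("Lys-a" = 0.8), seed = 9)
  nl <- lo$region == 1L; nh <- hi$region == 1L
  expect_gt(mean(hi$mixing[nh, "Lys-a"]), mean(lo$mixing[nl, "Lys-a"]))
  expect_error(make_scene(20, 20, n_nuclei = 200, truth = c("Lys-a" = 0.5)),
               "layout error")
  expect_error(make_scene(8, 8), ">= 16 x 16")
})

test_that("noiseless rendering reproduces the exact mixture and anchors self-correlation", {
  scn <- make_scene(16, 16, n_nuclei = 1, truth = c("DNA-m" = 0.5), seed = 2,
                    nucleus_frac = 0.2)
  r <- render_map(scn, noise = noise_model(0, 0, 0), seed = 3)
  expect_equal(max(abs(r$map$intensity - r$clean)), 0)
  expect_equal(nrow(r$spikes), 0L)
  # a pure-species pixel correlates exactly 1 with its own reference
  g <- default_grid()
  dna <- make_reference(default_species_library()$DNA, g)
  pure <- hypermap(g, matrix(3 * dna$intensity + 0.2, 1), 0, 0)
  expect_equal(similarity(pure$intensity[1, ], dna$intensity, "pearson"), 1,
               tolerance = 1e-12)
})

test_that("cosmic-spike injection is Poisson at the configured rate", {
  scn <- make_scene(32, 32, n_nuclei = 4, truth = c("DNA-m" = 0.5), seed = 21)
  r <- render_map(scn, noise = noise_model(0.3, 0.03, spike_rate = 0.5), seed = 22)
  lambda <- 0.5 * n_pixels(r$map)
  expect_lt(abs(nrow(r$spikes) - lambda), 3 * sqrt(lambda))
})

test_that("a 100 x 100 scene renders the map scale used for whole slides", {
  scn <- make_scene(100, 100, n_nuclei = 10, truth = c("DNA-m" = 0.4), seed = 5)
  r <- render_map(scn, seed = 6)
  expect_equal(n_pixels(r$map), 10000L)
  expect_equal(length(r$truth$labels), 10000L)
})

test_that("fixed seeds make rendering byte-reproducible", {
  scn <- make_scene(16, 16, n_nuclei = 2, truth = c("DNA-m" = 0.4), seed = 4,
                    nucleus_frac = 0.2)
  r1 <- render_map(scn, seed = 8)
  r2 <- render_map(scn, seed = 8)
  expect_identical(r1$map$intensity, r2$map$intensity)
  expect_identical(r1$spikes, r2$spikes)
})
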