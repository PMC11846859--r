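## Synthetic reference spectra and hyperspectral maps with known ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## fingerprint-range spectra built from Lorentzian (or Gaussian) bands,
## tissue scenes with connected nuclear blobs surrounded by cytoplasm within
## stroma, pixel spectra as nonnegative mixtures of species references plus a
## cubic baseline, Gaussian noise and sparse single-bin cosmic-ray spikes.
## Modification levels are encoded as mixing-coefficient multipliers of the
## modified species inside nuclei; those multipliers are the ground truth the
## quantification stage must recover ordinally.

#' Default fingerprint wavenumber grid
#'
#' 600-1900 cm^-1 at 2 cm^-1 resolution, the fingerprint range at the
#' resolution typical of a 600 gr/mm grating.
#'
#' @return numeric grid vector (651 points).
#' @export
default_grid <- function() seq(600, 1900, by = 2)

#' Describe a synthetic molecular species
#'
#' @param label species identifier.
#' @param peaks data frame with columns `center` (cm^-1), `width` (FWHM-like
#'   half-width, cm^-1) and `height` (>= 0); at least 3 peaks, centers within
#'   600-1900 cm^-1.
#' @param shape band profile, `"lorentzian"` (the typical Raman lineshape) or
#'   `"gaussian"`.
#' @return an object of class `species_model`.
#' @export
species_model <- function(label, peaks, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  peaks <- as.data.frame(peaks)
  if (!all(c("center", "width", "height") %in% names(peaks)))
    stop("peaks need columns center, width, height")
  if (nrow(peaks) < 3L) stop("species '", label, "' needs >= 3 peaks")
  if (any(peaks$center < 600 | peaks$center > 1900))
    stop("peak centers must lie within 600-1900 cm^-1")
  if (any(peaks$height < 0) || any(peaks$width <= 0))
    stop("peak heights must be >= 0 and widths > 0")
  structure(list(label = label, peaks = peaks, shape = shape),
            class = "species_model")
}

peak_profile <- function(grid, center, width, height, shape) {
  if (shape == "lorentzian") height * width^2 / ((grid - center)^2 + width^2)
  else height * exp(-(grid - center)^2 / (2 * (width / 2.355)^2))
}

#' Render a species model into a reference spectrum
#'
#' Sum of the band profiles evaluated on `grid`, min-max scaled to `[0, 1]`.
#'
#' @param model a [species_model()].
#' @param grid wavenumber grid.
#' @return a [ref_spectrum()] labelled as the model.
#' @export
make_reference <- function(model, grid = default_grid()) {
  if (!inherits(model, "species_model")) stop("model must be a species_model")
  if (nrow(model$peaks) == 0L) stop("degenerate species model: empty peak list")
  validate_grid(grid)
  y <- rowSums(mapply(function(c, w, h) peak_profile(grid, c, w, h, model$shape),
                      model$peaks$center, model$peaks$width, model$peaks$height))
  rng <- range(y)
  if (diff(rng) == 0) stop("degenerate species model: flat curve")
  ref_spectrum(model$label, grid, (y - rng[1L]) / diff(rng))
}

#' Built-in species library
#'
#' Peak tables for the seven modification-related species (DNA, DNA-m, Lys,
#' Lys-m, Lys-a, Arg, Arg-m), the two DNA conformers (B-DNA, Z-DNA) and two
#' matrix species used for cytoplasm (`protein`) and stroma (`collagen`).
#' Band positions are loosely modelled on published assignments (e.g. the
#' 785 cm^-1 O-P-O backbone and ~1095 cm^-1 PO2- stretch for DNA, the
#' 1003 cm^-1 phenylalanine ring breathing for protein, 855/938 cm^-1
#' proline/hydroxyproline for collagen, 625/745 cm^-1 markers for the
#' Z-conformer); they are synthetic stand-ins, not measured curves. Each
#' modified species shares at least half of its peak centers with its base
#' species and differs in at least two bands, so pairs are similar but
#' distinguishable.
#'
#' @return named list of [species_model()] objects.
#' @export
default_species_library <- function() {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], height = m[, 3])
  }
  lst <- list(
    "DNA"   = pk(680, 8, 0.35, 785, 9, 1.00, 1095, 10, 0.75, 1340, 11, 0.55,
                 1485, 10, 0.80, 1578, 10, 0.65, 1668, 12, 0.40),
    # shares 785/1095/1485/1578 with DNA; gains 5mC-like bands, loses 680
    "DNA-m" = pk(785, 9, 0.95, 1005, 9, 0.45, 1095, 10, 0.70, 1252, 10, 0.50,
                 1485, 10, 0.75, 1578, 10, 0.60, 1765, 10, 0.30),
    "Lys"   = pk(850, 9, 0.60, 1050, 10, 0.45, 1320, 10, 0.55, 1445, 11, 1.00,
                 1605, 10, 0.50),
    # shares 850/1445/1605; new N-CH3 bands
    "Lys-m" = pk(850, 9, 0.55, 970, 9, 0.50, 1410, 10, 0.60, 1445, 11, 0.95,
                 1605, 10, 0.45, 1480, 9, 0.40),
    # shares 850/1320/1445; new acetyl carbonyl/amide bands
    "Lys-a" = pk(850, 9, 0.55, 1240, 10, 0.55, 1320, 10, 0.50, 1445, 11, 0.90,
                 1650, 11, 0.60, 1370, 9, 0.35),
    "Arg"   = pk(980, 9, 0.55, 1090, 10, 0.40, 1175, 10, 0.45, 1450, 11, 0.90,
                 1585, 10, 0.60),
    # shares 980/1450/1585; new guanidinium-methyl bands
    "Arg-m" = pk(980, 9, 0.50, 1390, 10, 0.55, 1450, 11, 0.85, 1540, 10, 0.45,
                 1585, 10, 0.55, 1125, 9, 0.35),
    "B-DNA" = pk(790, 9, 1.00, 835, 10, 0.45, 1095, 10, 0.70, 1490, 10, 0.75,
                 1580, 10, 0.60),
    # shares 835/1095/1490/1580; Z-form markers at 625/745/1318
    "Z-DNA" = pk(625, 8, 0.50, 745, 8, 0.80, 835, 9, 0.60, 1095, 10, 0.60,
                 1318, 10, 0.50, 1490, 10, 0.70, 1580, 10, 0.55),
    "protein"  = pk(935, 10, 0.45, 1003, 7, 1.00, 1250, 12, 0.55, 1450, 11, 0.80,
                    1660, 12, 0.70),
    "collagen" = pk(816, 9, 0.40, 855, 9, 0.70, 938, 9, 0.65, 1248, 12, 0.60,
                    1454, 11, 0.75, 1668, 12, 0.55, 1032, 9, 0.35)
  )
  mapply(species_model, names(lst), lst, SIMPLIFY = FALSE)
}

## base species for each modification; used by exclusive/quantify too
#' Base species of a modification label
#' @param modification one of `DNA-m`, `Lys-m`, `Lys-a`, `Arg-m`.
#' @return the base species label (`DNA`, `Lys` or `Arg`).
#' @export
base_species <- function(modification) {
  tab <- c("DNA-m" = "DNA", "Lys-m" = "Lys", "Lys-a" = "Lys", "Arg-m" = "Arg")
  if (!modification %in% names(tab)) stop("unknown modification label: ", modification)
  unname(tab[modification])
}

## smoothed uniform random field on a width x height raster, scaled to [-1, 1]
smooth_field <- function(width, height, sigma = 3) {
  f <- matrix(stats::rnorm(width * height), height, width)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * sigma + 1))
  k <- k / sum(k)
  f <- apply(f, 2, function(col) stats::filter(c(rev(col), col, rev(col)), k, sides = 2)[(height + 1):(2 * height)])
  f <- t(apply(f, 1, function(row) stats::filter(c(rev(row), row, rev(row)), k, sides = 2)[(width + 1):(2 * width)]))
  f <- f - mean(f)
  f / max(abs(f))
}

#' Generate a synthetic tissue scene
#'
#' Lays out `n_nuclei` connected nuclear blobs (noise-distorted discs) with a
#' cytoplasm rim inside a stroma background, and assigns every pixel a
#' nonnegative mixing coefficient over the species library. Coefficients of
#' modified species inside nuclei scale linearly with the scene's truth
#' level for that modification, which is the recoverable ground truth.
#'
#' @param width,height scene dimensions in pixels (>= 16 each).
#' @param n_nuclei number of nuclear blobs.
#' @param truth named numeric vector of modification levels in `[0, 1]`
#'   (names among `DNA-m`, `Lys-m`, `Lys-a`, `Arg-m`) optionally including a
#'   `Z-DNA` multiplier (>= 0, 1 = control-like) for the Z-conformer
#'   coefficient.
#' @param group_label simulated subtype name carried through to statistics.
#' @param seed integer; the scene is fully reproducible given the seed.
#' @param nucleus_frac target nucleus pixel fraction (band checked +/- 0.12).
#' @return an object of class `tissue_scene` with per-pixel `region` labels
#'   (0 stroma, 1 nucleus, 2 cytoplasm), a `mixing` matrix (pixels x
#'   species) and the `truth` levels.
#' @export
make_scene <- function(width, height, n_nuclei = 6, truth = c("DNA-m" = 0.4),
                       group_label = "GRP", seed = 1, nucleus_frac = 0.22) {
  if (width < 16 || height < 16) stop("scene dimensions must be >= 16 x 16")
  mods <- setdiff(names(truth), "Z-DNA")
  if (length(mods) && (any(truth[mods] < 0) || any(truth[mods] > 1)))
    stop("truth levels must lie in [0, 1]")
  set.seed(seed)
  ## disc radius from the requested nucleus fraction
  r <- sqrt(nucleus_frac * width * height / (n_nuclei * pi))
  if (r < 1 || 2 * r + 2 > min(width, height) ||
      n_nuclei * (2 * r)^2 > 2 * width * height)
    stop("layout error: ", n_nuclei, " nuclei of radius ", round(r, 1),
         " cannot fit in ", width, " x ", height)
  cx <- stats::runif(n_nuclei, r, width - 1 - r)
  cy <- stats::runif(n_nuclei, r, height - 1 - r)
  field <- smooth_field(width, height, sigma = max(2L, as.integer(r / 2)))
  px <- rep(0:(width - 1L), times = height)
  py <- rep(0:(height - 1L), each = width)
  ## distance to nearest nucleus center, disc boundary distorted by the field
  dmin <- rep(Inf, width * height)
  for (i in seq_len(n_nuclei))
    dmin <- pmin(dmin, sqrt((px - cx[i])^2 + (py - cy[i])^2))
  fld <- field[cbind(py + 1L, px + 1L)]
  region <- integer(width * height)             # 0 = stroma
  region[dmin <= r * (1 + 0.25 * fld)] <- 1L    # nucleus
  region[region == 0L & dmin <= 1.7 * r * (1 + 0.15 * fld)] <- 2L  # cytoplasm

  species <- names(default_species_library())
  mixing <- matrix(0, width * height, length(species),
                   dimnames = list(NULL, species))
  jit <- function(n, lo = 0.8, hi = 1.2) stats::runif(n, lo, hi)
  nuc <- region == 1L; cyt <- region == 2L; str <- region == 0L
  nn <- sum(nuc); nc <- sum(cyt); ns <- sum(str)
  zmult <- if ("Z-DNA" %in% names(truth)) unname(truth[["Z-DNA"]]) else 1
  ## nucleus: DNA-family concentrated here, histone-bearing protein present
  mixing[nuc, "DNA"] <- 1.0 * jit(nn)
  mixing[nuc, "B-DNA"] <- 0.5 * jit(nn)
  mixing[nuc, "Z-DNA"] <- 0.15 * zmult * jit(nn)
  mixing[nuc, "Lys"] <- 0.6 * jit(nn)
  mixing[nuc, "Arg"] <- 0.4 * jit(nn)
  mixing[nuc, "protein"] <- 0.3 * jit(nn)
  for (m in mods)
    mixing[nuc, m] <- unname(truth[m]) * 0.6 * mixing[nuc, base_species(m)] * jit(nn)
  ## cytoplasm: protein-dominated, trace DNA
  mixing[cyt, "protein"] <- 1.0 * jit(nc)
  mixing[cyt, "Lys"] <- 0.25 * jit(nc)
  mixing[cyt, "Arg"] <- 0.15 * jit(nc)
  mixing[cyt, "DNA"] <- 0.05 * jit(nc)
  ## stroma: collagen-dominated
  mixing[str, "collagen"] <- 1.0 * jit(ns)
  mixing[str, "protein"] <- 0.2 * jit(ns)

  frac <- mean(nuc)
  if (abs(frac - nucleus_frac) > 0.12)
    stop("layout error: nucleus fraction ", round(frac, 3),
         " outside requested band around ", nucleus_frac)
  structure(list(width = as.integer(width), height = as.integer(height),
                 x = px, y = py, region = region, mixing = mixing,
                 group_label = group_label, truth = truth, seed = seed),
            class = "tissue_scene")
}

#' @export
print.tissue_scene <- function(x, ...) {
  cat(sprintf("<tissue_scene> '%s' %d x %d px, %.1f%% nucleus, truth: %s\n",
              x$group_label, x$width, x$height, 100 * mean(x$region == 1L),
              paste(names(x$truth), x$truth, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Describe the measurement-noise model
#'
#' @param baseline_scale amplitude of the random per-pixel cubic baseline,
#'   relative to unit reference intensity (each of the four polynomial
#'   coefficients is drawn uniformly from `[0, baseline_scale]` on a
#'   normalised wavenumber axis).
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param spike_rate expected cosmic-ray spikes per spectrum (Poisson).
#' @param spike_height spike amplitude as a multiple of the pixel's maximum
#'   signal (>= 5 keeps despiking unambiguous).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(baseline_scale = 0.5, noise_sd = 0.05,
                        spike_rate = 0.05, spike_height = 8) {
  if (noise_sd < 0 || spike_rate < 0 || baseline_scale < 0)
    stop("noise parameters must be >= 0")
  structure(list(baseline_scale = baseline_scale, noise_sd = noise_sd,
                 spike_rate = spike_rate, spike_height = spike_height),
            class = "noise_model")
}

#' Render a scene into a hyperspectral map
#'
#' Each pixel spectrum is the scene's nonnegative mixture of reference
#' curves, plus a random cubic baseline, Gaussian noise, and Poisson-count
#' single-bin cosmic-ray spikes. The ground-truth class map, the clean
#' (noiseless) signal and the spike injection log are returned alongside for
#' validation.
#'
#' @param scene a [make_scene()] result.
#' @param species species library; labels must cover the scene's mixing
#'   columns.
#' @param noise a [noise_model()].
#' @param grid wavenumber grid.
#' @param seed integer seed for the noise draws.
#' @return list with elements `map` ([hypermap()]), `truth` ([class_map()]),
#'   `clean` (noiseless intensity matrix), `baseline` (baseline matrix) and
#'   `spikes` (data frame of injected pixel/bin positions).
#' @export
render_map <- function(scene, species = default_species_library(),
                       noise = noise_model(), grid = default_grid(), seed = 1) {
  validate_grid(grid)
  labs <- colnames(scene$mixing)
  if (!all(labs %in% names(species)))
    stop("scene mixes species absent from the library: ",
         paste(setdiff(labs, names(species)), collapse = ", "))
  refs <- t(vapply(labs, function(l) make_reference(species[[l]], grid)$intensity,
                   numeric(length(grid))))
  clean <- scene$mixing %*% refs
  n <- nrow(clean); m <- length(grid)
  set.seed(seed)
  tnorm <- (grid - min(grid)) / diff(range(grid))
  basis <- cbind(1, tnorm, tnorm^2, tnorm^3)
  bc <- matrix(stats::runif(n * 4L, 0, noise$baseline_scale), n, 4L)
  baseline <- bc %*% t(basis)
  noisy <- clean + baseline +
    matrix(stats::rnorm(n * m, sd = noise$noise_sd), n, m)
  nsp <- stats::rpois(n, noise$spike_rate)
  spikes <- data.frame(pixel = integer(0), bin = integer(0))
  if (sum(nsp) > 0) {
    pix <- rep(seq_len(n), nsp)
    bin <- as.integer(sapply(pix, function(i) sample.int(m, 1L)))
    amp <- noise$spike_height * pmax(apply(clean[pix, , drop = FALSE], 1, max), 1)
    noisy[cbind(pix, bin)] <- noisy[cbind(pix, bin)] + amp
    spikes <- data.frame(pixel = pix, bin = bin)
  }
  map <- hypermap(grid, noisy, scene$x, scene$y, scene$width, scene$height,
                  metadata = list(group_label = scene$group_label))
  truth <- class_map(scene$region, scene$x, scene$y, scene$width, scene$height)
  list(map = map, truth = truth, clean = clean, baseline = baseline,
       spikes = spikes)
}
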