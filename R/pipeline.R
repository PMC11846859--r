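## End-to-end pipeline: configuration, a self-contained synthetic demo
## corpus, and a staged runner that writes CSV artifacts plus a checksum
## manifest. Every stage draws its seed from the single configured seed, so
## rerunning an identical configuration reproduces identical checksums.

#' Build a validated pipeline configuration
#'
#' @param corpus_dir directory holding `references/`, `maps/`, `labels/` and
#'   `truth.json` (see [make_demo_corpus()]).
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; all stage seeds derive from it.
#' @param use_autoencoder apply autoencoder denoising during preprocessing.
#' @param autoencoder,classify,correlate,exclusive,vspa,quantify,embed named
#'   lists overriding per-stage defaults (see the returned object for the
#'   documented defaults).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_dir, out_dir, seed = 1L,
                            use_autoencoder = FALSE,
                            autoencoder = list(), classify = list(),
                            correlate = list(), exclusive = list(),
                            vspa = list(), quantify = list(),
                            embed = list()) {
  merge_block <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- structure(list(
    corpus_dir = corpus_dir, out_dir = out_dir, seed = as.integer(seed),
    use_autoencoder = isTRUE(use_autoencoder),
    autoencoder = merge_block(list(epochs = 12L, batch_size = 105L,
                                   loss = "crossentropy", n_train = 315L),
                              autoencoder),
    classify = merge_block(list(epochs = 25L, min_epochs = 10L,
                                batch_size = 105L, n_per_class = 400L),
                           classify),
    correlate = merge_block(list(metric = "pearson", window = c(600, 1900)),
                            correlate),
    exclusive = merge_block(list(quantile = 0.75), exclusive),
    vspa = merge_block(list(alpha = 0.01, mode = "peaks"), vspa),
    quantify = merge_block(list(ctrl = "CTRL"), quantify),
    embed = merge_block(list(enable = TRUE, perplexity = 20,
                             n_spectra = 150L, n_iter = 400L), embed)),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!dir.exists(cfg$corpus_dir)) stop("corpus directory not found: ", cfg$corpus_dir)
  for (d in c("references", "maps", "labels"))
    if (!dir.exists(file.path(cfg$corpus_dir, d)))
      stop("corpus is missing its '", d, "' directory")
  truth_path <- file.path(cfg$corpus_dir, "truth.json")
  if (!file.exists(truth_path)) stop("corpus is missing truth.json")
  truth <- jsonlite::read_json(truth_path)
  if (!cfg$quantify$ctrl %in% names(truth$groups))
    stop("control group '", cfg$quantify$ctrl,
         "' absent from the corpus but quantification is enabled")
  q <- cfg$exclusive$quantile
  if (q <= 0 || q >= 1) stop("exclusive quantile must lie in (0, 1)")
  if (cfg$vspa$alpha <= 0 || cfg$vspa$alpha >= 1) stop("vspa alpha must lie in (0, 1)")
  if (!cfg$correlate$metric %in% similarity_metrics())
    stop("unknown correlation metric: ", cfg$correlate$metric)
  cfg
}

#' Read a pipeline configuration from a YAML document
#'
#' @param path YAML file with at least `corpus_dir` and `out_dir`.
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Generate a self-contained synthetic demo corpus on disk
#'
#' Writes the full reference library (seven modification species, the B/Z
#' conformers and the two matrix species), several maps per simulated
#' subtype group with per-pixel ground-truth class labels, and a
#' `truth.json` recording the generating modification levels. Two default
#' tumour-like groups differ from control in modification level (0.8 vs the
#' control 0.4) and Z-DNA content (doubled in one group).
#'
#' @param out_dir writable output directory.
#' @param seed integer; the corpus is byte-reproducible given the seed.
#' @param map_px side length of each square map in pixels.
#' @param maps_per_group maps generated per group.
#' @param groups named list of truth-level vectors (see [make_scene()]).
#' @return the corpus directory, invisibly.
#' @export
make_demo_corpus <- function(out_dir, seed = 1L, map_px = 32L,
                             maps_per_group = 2L,
                             groups = list(
                               "CTRL"  = c("DNA-m" = 0.4, "Lys-m" = 0.4,
                                           "Lys-a" = 0.4, "Arg-m" = 0.4,
                                           "Z-DNA" = 1.0),
                               "TUM_A" = c("DNA-m" = 0.8, "Lys-m" = 0.8,
                                           "Lys-a" = 0.8, "Arg-m" = 0.8,
                                           "Z-DNA" = 2.0),
                               "TUM_B" = c("DNA-m" = 0.4, "Lys-m" = 0.4,
                                           "Lys-a" = 0.4, "Arg-m" = 0.4,
                                           "Z-DNA" = 1.0))) {
  for (d in c("references", "maps", "labels"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create corpus directory: ", out_dir)
  species <- default_species_library()
  grid <- default_grid()
  for (sp in names(species))
    write_reference(make_reference(species[[sp]], grid),
                    file.path(out_dir, "references", paste0(sp, ".csv")))
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(maps_per_group)) {
      k <- k + 1L
      scn <- make_scene(map_px, map_px, n_nuclei = max(3L, map_px %/% 10L),
                        truth = groups[[g]], group_label = g,
                        seed = seed * 1000L + k)
      rm_ <- render_map(scn, species, noise_model(), grid,
                        seed = seed * 1000L + 500L + k)
      stem <- sprintf("%s_%02d", g, i)
      write_map(rm_$map, file.path(out_dir, "maps", paste0(stem, ".csv")))
      utils::write.csv(data.frame(x = rm_$truth$x, y = rm_$truth$y,
                                  label = rm_$truth$labels),
                       file.path(out_dir, "labels", paste0(stem, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(
    list(seed = seed, map_px = map_px, maps_per_group = maps_per_group,
         groups = lapply(groups, as.list)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a corpus
#'
#' Chains preprocessing, classifier training and prediction, correlation
#' heatmaps for every reference, quartile status calling, exclusive-spectra
#' volcano analysis, group semi-quantification with Kruskal-Wallis /
#' Dunn / Holm statistics, the Z-DNA score and (optionally) PCA/t-SNE
#' embeddings, writing every numeric artifact as CSV plus a run manifest
#' with MD5 checksums. A failed stage aborts with the stage name; artifacts
#' already written are preserved.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return the manifest, invisibly (artifact paths, checksums, log).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("seed: %d", cfg$seed),
           sprintf("correlation metric: %s", cfg$correlate$metric),
           sprintf("status quantile: %g", cfg$exclusive$quantile),
           sprintf("vspa alpha: %g (mode %s)", cfg$vspa$alpha, cfg$vspa$mode),
           sprintf("autoencoder denoising: %s", cfg$use_autoencoder))
  artifacts <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }

  refs <- stage("load", {
    paths <- list.files(file.path(cfg$corpus_dir, "references"),
                        full.names = TRUE, pattern = "\\.csv$")
    rl <- lapply(paths, read_reference)
    names(rl) <- vapply(rl, `[[`, "", "label")
    rl
  })
  truth <- jsonlite::read_json(file.path(cfg$corpus_dir, "truth.json"))
  map_files <- list.files(file.path(cfg$corpus_dir, "maps"), pattern = "\\.csv$")
  corpus <- stage("load", lapply(map_files, function(f) {
    stem <- sub("\\.csv$", "", f)
    lab <- utils::read.csv(file.path(cfg$corpus_dir, "labels", f))
    map <- read_map(file.path(cfg$corpus_dir, "maps", f))
    idx <- match(paste(map$x, map$y), paste(lab$x, lab$y))
    list(stem = stem, group = sub("_\\d+$", "", stem), map = map,
         labels = class_map(lab$label[idx], map$x, map$y, map$width, map$height))
  }))

  denoiser <- NULL
  if (cfg$use_autoencoder) denoiser <- stage("preprocess", {
    pool <- do.call(rbind, lapply(corpus, function(m) m$map$intensity))
    set.seed(cfg$seed + 11L)
    sub <- pool[sample.int(nrow(pool), min(cfg$autoencoder$n_train, nrow(pool))), ]
    sub <- t(apply(sub, 1L, function(s) {
      s <- remove_spikes(s)$intensity
      normalize01(remove_baseline(s)$corrected)
    }))
    train_autoencoder(sub, autoencoder_spec(
      epochs = cfg$autoencoder$epochs, batch_size = cfg$autoencoder$batch_size,
      loss = cfg$autoencoder$loss, seed = cfg$seed + 12L))
  })
  corpus <- stage("preprocess", lapply(corpus, function(m) {
    m$map <- preprocess_map(m$map, denoiser = denoiser)$map
    m
  }))

  classifier <- stage("classify", {
    X <- do.call(rbind, lapply(corpus, function(m) m$map$intensity))
    y <- unlist(lapply(corpus, function(m) m$labels$labels))
    set.seed(cfg$seed + 21L)
    keep <- unlist(lapply(0:2, function(k) {
      i <- which(y == k)
      sample(i, min(cfg$classify$n_per_class, length(i)))
    }))
    tr <- train_classifier(X[keep, ], y[keep], classifier_spec(
      epochs = cfg$classify$epochs, min_epochs = cfg$classify$min_epochs,
      batch_size = cfg$classify$batch_size, seed = cfg$seed + 22L))
    log <- c(log, sprintf("classifier validation accuracy: %.4f",
                          tr$report$validation_accuracy))
    tr$model
  })
  corpus <- stage("classify", lapply(corpus, function(m) {
    m$classmap <- predict_map(classifier, m$map)
    emit(data.frame(x = m$classmap$x, y = m$classmap$y,
                    label = m$classmap$labels),
         sprintf("classmap_%s.csv", m$stem))
    m
  }))

  corpus <- stage("correlate", lapply(corpus, function(m) {
    m$corr <- lapply(refs, function(r)
      correlation_map(m$map, r, cfg$correlate$metric, cfg$correlate$window))
    sc <- data.frame(x = m$map$x, y = m$map$y)
    for (lab in names(m$corr)) {
      sc[[paste0(gsub("-", "_", lab), "_raw")]] <- m$corr[[lab]]$raw
      sc[[paste0(gsub("-", "_", lab), "_norm")]] <- m$corr[[lab]]$norm
    }
    emit(sc, sprintf("scores_%s.csv", m$stem))
    m
  }))

  corpus <- stage("exclusive", lapply(corpus, function(m) {
    m$status <- call_status(m$corr[ALL_STATUS_LABELS], m$classmap,
                            cfg$exclusive$quantile)
    emit(as.data.frame(m$status), sprintf("status_%s.csv", m$stem))
    m
  }))

  stage("vspa", for (mod in MOD_LABELS) {
    A <- do.call(rbind, lapply(corpus, function(m)
      extract_exclusive(m$status, mod, m$map)$spectra))
    B <- do.call(rbind, lapply(corpus, function(m)
      extract_base_only(m$status, base_species(mod), m$map)$spectra))
    if (is.null(A) || is.null(B) || nrow(A) < 3L || nrow(B) < 3L) {
      log <- c(log, sprintf("vspa: skipped %s (too few exclusive spectra)", mod))
      next
    }
    wn <- corpus[[1L]]$map$wavenumber
    res <- volcano(A, B, wn, alpha = cfg$vspa$alpha,
                   positions = detect_test_positions(A, B, wn, cfg$vspa$mode))
    emit(res, sprintf("vspa_%s.csv", gsub("-", "_", mod)))
  })

  stage("quantify", {
    by_group <- split(lapply(corpus, function(m) m[c("status", "corr")]),
                      vapply(corpus, `[[`, "", "group"))
    all_levels <- list()
    tests <- list()
    for (mod in MOD_LABELS) {
      lv <- collect_levels(by_group, mod)
      all_levels[[mod]] <- relative_levels(lv, cfg$quantify$ctrl)
      gt <- group_tests(lv)
      tests[[mod]] <- cbind(modification = mod, gt$pairwise)
    }
    emit(do.call(rbind, all_levels), "levels.csv")
    emit(do.call(rbind, tests), "tests.csv")
    zg <- collect_levels(by_group, "Z-DNA")
    bg <- collect_levels(by_group, "B-DNA")
    emit(zdna_score(zg, bg, cfg$quantify$ctrl), "zdna_score.csv")
  })

  if (cfg$embed$enable) stage("embed", {
    pool <- list(); gl <- character(0)
    for (m in corpus) {
      s <- m$status
      keep <- s$DNA == 1L
      if (!any(keep)) next
      idx <- match(paste(s$x[keep], s$y[keep]), paste(m$map$x, m$map$y))
      pool[[length(pool) + 1L]] <- m$map$intensity[idx, , drop = FALSE]
      gl <- c(gl, rep(m$group, sum(keep)))
    }
    X <- do.call(rbind, pool)
    set.seed(cfg$seed + 41L)
    sub <- sample.int(nrow(X), min(cfg$embed$n_spectra, nrow(X)))
    X <- X[sub, ]; gl <- gl[sub]
    pca <- pca_embed(X, gl, k = 2L, wavenumber = corpus[[1L]]$map$wavenumber)
    emit(data.frame(spectrum_id = seq_along(gl), group = gl,
                    dim1 = pca$coordinates[, 1L], dim2 = pca$coordinates[, 2L]),
         "pca_embedding.csv")
    emit(loading_interpretation(pca, 20L), "pca_loadings.csv")
    ts <- tsne_embed(X, gl, perplexity = min(cfg$embed$perplexity,
                                             floor((nrow(X) - 1) / 3)),
                     seed = cfg$seed + 42L, n_iter = cfg$embed$n_iter)
    emit(data.frame(spectrum_id = seq_along(gl), group = gl,
                    dim1 = ts$coordinates[, 1L], dim2 = ts$coordinates[, 2L]),
         "tsne_embedding.csv")
  })

  manifest <- list(config = unclass(cfg),
                   artifacts = data.frame(
                     path = artifacts,
                     md5 = unname(tools::md5sum(artifacts))),
                   log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
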