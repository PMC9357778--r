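#' Read and write feature tables
#'
#' CSV round-trip of feature matrices with labels; values are written as
#' decimal text with 17 significant digits so they survive a round trip
#' bit-for-bit.
#'
#' @param path CSV file path.
#' @param features numeric matrix (rows = samples).
#' @param labels optional 0/1 vector stored as a `label` column.
#' @export
write_features <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  df[] <- lapply(df, function(x) formatC(x, digits = 17, format = "g"))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @return `read_features` returns a list `X` (matrix) and `labels`
#'   (vector or NULL).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  X <- as.matrix(df)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN in feature CSV at row %d, column %d", bad[1], bad[2]))
  }
  list(X = X, labels = labels)
}

#' Write a segmentation result
#'
#' Label map as a PGM image (cluster indices spread over the gray range)
#' plus a JSON sidecar with centroids, iteration count, objective trace and
#' a config echo.
#'
#' @param result an `ifrfcm_result`.
#' @param path output path without extension; writes `<path>.pgm` and
#'   `<path>.json`.
#' @export
write_labels <- function(result, path) {
  C <- result$config$clusters
  scale <- if (C > 1) (255 %/% (C - 1)) else 0
  write_pgm(gray_image(result$labels * scale, 256L), paste0(path, ".pgm"))
  cfg <- result$config
  cfg$inertia <- NULL
  jsonlite::write_json(
    list(centroids = result$centroids, n_iter = result$n_iter,
         converged = result$converged, objective_trace = result$objective_trace,
         config = cfg[!vapply(cfg, is.function, logical(1))]),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

derive_seed <- function(master, offset) (master * 97L + offset) %% 2147480000L

#' Run the full tumour-detection pipeline on synthetic phantoms
#'
#' Executes the whole workflow: simulate a labelled phantom set, segment
#' each image with IFRFCM, extract regional GLCM texture features from the
#' denoised (centroid-rendered) segmentation, split train/validation, train
#' a PSO-optimised ELM, predict on the validation split and compute
#' prevalence-based diagnostic metrics. All randomness derives from
#' `seed`.
#'
#' @param n_tumor,n_clean phantom counts.
#' @param size phantom side length.
#' @param noise,level noise settings.
#' @param train_frac fraction of samples used for training.
#' @param clusters IFRFCM cluster count.
#' @param H,n_particles,max_iter PSO-ELM settings.
#' @param seed master seed.
#' @param segment logical; set FALSE to extract features from the raw
#'   images (skips segmentation, much faster).
#' @param out_dir optional directory for artifacts (label maps, features
#'   CSV, model JSON, report JSON).
#' @return list with `report` (diagnostic metrics), `model`, `history`,
#'   `split`, `features`.
#' @export
run_pipeline <- function(n_tumor = 10L, n_clean = 10L, size = 64L,
                         noise = "gaussian", level = 0.05,
                         train_frac = 0.5, clusters = 4L, H = 10L,
                         n_particles = 20L, max_iter = 50L, seed = 1L,
                         segment = TRUE, out_dir = NULL) {
  set <- generate_classification_set(n_tumor, n_clean, size = size,
                                     noise = noise, level = level,
                                     seed = derive_seed(seed, 1L))
  n <- length(set$phantoms)
  imgs <- lapply(seq_len(n), function(i) {
    ph <- set$phantoms[[i]]
    if (!segment) return(ph$image)
    cfg <- cluster_config(clusters = clusters, seed = derive_seed(seed, 100L + i))
    res <- ifrfcm_segment(ph$image, cfg)
    # render each pixel at its cluster centroid: a piecewise-constant
    # denoised image for texture extraction
    denoised <- matrix(pmin(pmax(round(res$centroids[res$labels + 1L]), 0), 255),
                       nrow(res$labels), ncol(res$labels))
    if (!is.null(out_dir)) {
      write_labels(res, file.path(out_dir, sprintf("phantom_%03d_labels", i)))
    }
    gray_image(denoised, 256L)
  })
  X <- do.call(rbind, lapply(imgs, extract_feature_vector))
  y <- set$labels

  idx <- run_seeded(derive_seed(seed, 2L), sample.int(n, round(train_frac * n)))
  fit <- pso_elm_train(X[idx, , drop = FALSE], y[idx],
                       X[-idx, , drop = FALSE], y[-idx],
                       H = H, n_particles = n_particles, max_iter = max_iter,
                       seed = derive_seed(seed, 3L))
  pred <- predict(fit$model, X[-idx, , drop = FALSE])
  report <- evaluate_predictions(pred$class, y[-idx])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(X, file.path(out_dir, "features.csv"), labels = y)
    write_elm(fit$model, file.path(out_dir, "model.json"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE)
    utils::write.csv(data.frame(iteration = seq_along(fit$history) - 1L,
                                best_fitness = fit$history),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  list(report = report, model = fit$model, history = fit$history,
       split = list(train = idx, val = setdiff(seq_len(n), idx)),
       features = X, labels = y)
}
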