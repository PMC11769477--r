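# End-to-end orchestration: ingest (images / feature CSV / synthetic),
# feature extraction, grey-wolf weighting, classification, k-fold
# evaluation, and artifact writing.

#' Pipeline configuration
#'
#' Assembles and validates the nested configuration for [run_pipeline()].
#' Any block can be overridden from a YAML file ([read_pipeline_config()])
#' or from CLI flags; flags win over file keys.
#'
#' @param input `"synthetic"`, `"features"` or `"images"`.
#' @param features_csv Feature CSV path (input = "features"; columns
#'   `f0001`..., plus a `label` column or a separate `labels` CSV).
#' @param image_dir Directory with image files and a `labels.csv`
#'   manifest (`path,label`) as written by [write_image_dataset()].
#' @param labels_csv Optional separate labels CSV.
#' @param synthetic List of [synthetic_features()] or [synthetic_images()]
#'   arguments plus `mode = "features"` (default) or `"images"`.
#' @param model List of [model_spec()] arguments (image mode).
#' @param gwo List of [gwo_config()] arguments (minus `dimension`/`seed`,
#'   filled in at run time); `NULL` disables feature weighting.
#' @param classifier List of [classifier_spec()] arguments.
#' @param k Number of cross-validation folds (default 5).
#' @param seed Global seed.
#' @param out Output directory for artifacts, or `NULL` for none.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = c("synthetic", "features", "images"),
                            features_csv = NULL, image_dir = NULL,
                            labels_csv = NULL,
                            synthetic = list(),
                            model = list(),
                            gwo = list(),
                            classifier = list(),
                            k = 5L, seed = 1L, out = NULL) {
  input <- match.arg(input)
  if (input == "features" && is.null(features_csv)) {
    stop_validation("input = 'features' requires features_csv")
  }
  if (input == "images" && is.null(image_dir)) {
    stop_validation("input = 'images' requires image_dir")
  }
  structure(
    list(input = input, features_csv = features_csv, image_dir = image_dir,
         labels_csv = labels_csv, synthetic = synthetic, model = model,
         gwo = gwo, classifier = classifier, k = as.integer(k),
         seed = as.integer(seed), out = out),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; nested blocks
#' (`synthetic`, `model`, `gwo`, `classifier`) mirror the corresponding
#' module constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

pipeline_features <- function(cfg) {
  if (cfg$input == "features") {
    return(stage("load-features", {
      loaded <- read_feature_csv(cfg$features_csv)
      if (!is.null(cfg$labels_csv)) {
        loaded$labels <- as.integer(utils::read.csv(cfg$labels_csv)$label)
      }
      if (is.null(loaded$labels)) stop_validation("no labels found")
      loaded
    }))
  }
  if (cfg$input == "synthetic" && (cfg$synthetic$mode %||% "features") == "features") {
    return(stage("synthesize-features", {
      args <- cfg$synthetic
      args$mode <- NULL
      args$seed <- args$seed %||% cfg$seed
      do.call(synthetic_features, args)
    }))
  }
  # image path: synthetic images or a directory of files
  if (cfg$input == "synthetic") {
    gen <- stage("synthesize-images", {
      args <- cfg$synthetic
      args$mode <- NULL
      args$seed <- args$seed %||% cfg$seed
      do.call(synthetic_images, args)
    })
    images <- gen$images
    labels <- gen$labels
  } else {
    ingest <- stage("read-images", {
      manifest_path <- cfg$labels_csv %||% file.path(cfg$image_dir, "labels.csv")
      manifest <- utils::read.csv(manifest_path)
      images <- lapply(file.path(cfg$image_dir, manifest$path), read_image)
      list(images = images, labels = as.integer(manifest$label))
    })
    images <- ingest$images
    labels <- ingest$labels
  }
  stage("extract-features", {
    size <- nrow(images[[1]]$pixels)
    margs <- cfg$model
    train <- margs[["train"]] %||% TRUE
    targs <- margs[["training"]] %||% list()
    margs$train <- NULL
    margs$training <- NULL
    margs$input_shape <- margs$input_shape %||% c(size, size, 3L)
    margs$backbone <- margs$backbone %||% "debug"
    spec <- do.call(model_spec, margs)
    model <- build_model(spec, seed = cfg$seed)
    imgs8 <- lapply(images, convert_bit_depth)
    tensor <- normalize_images(imgs8, target_size = spec$input_shape[1])
    if (train) {
      # fit the classification head first, then harvest the FC-layer
      # activations as the per-image descriptor
      model <- train_model(model, tensor, one_hot(labels, spec$n_classes),
                           do.call(training_config, targs), seed = cfg$seed)
    }
    list(features = extract_fc_features(model, tensor), labels = labels)
  })
}

#' Run the end-to-end pipeline
#'
#' Executes ingest -> (optional) feature extraction -> grey-wolf feature
#' weighting + classification under stratified k-fold cross-validation,
#' and optionally writes artifacts: `report.json` (full metrics),
#' `metrics.csv` (fold-averaged accuracy/precision/recall/F1),
#' `best_position.json`, `confusion_fold<i>.csv` and `manifest.json`
#' (config hash, seed, package and R versions). Reruns with the same
#' configuration and seed produce byte-identical reports.
#'
#' @param cfg A [pipeline_config()].
#' @return The `metrics_report`, invisibly, with the resolved feature
#'   matrix attached as attributes.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop_validation("cfg must be a pipeline_config")
  data <- pipeline_features(cfg)
  features <- data$features
  labels <- data$labels

  gwo_cfg <- NULL
  if (!is.null(cfg$gwo)) {
    gwo_cfg <- stage("configure-gwo", {
      args <- cfg$gwo
      args$dimension <- ncol(features)
      args$seed <- args$seed %||% cfg$seed
      if (is.null(args$fitness_spec)) {
        args$fitness_spec <- do.call(classifier_spec, cfg$classifier %||% list())
      }
      do.call(gwo_config, args)
    })
  }
  clf_spec <- stage("configure-classifier", {
    do.call(classifier_spec, cfg$classifier %||% list())
  })
  report <- stage("cross-validate", {
    cross_validate(features, labels, clf_spec, gwo_cfg = gwo_cfg,
                   k = cfg$k, seed = cfg$seed)
  })

  if (!is.null(cfg$out)) {
    stage("write-artifacts", write_pipeline_artifacts(cfg, report))
  }
  invisible(report)
}

write_pipeline_artifacts <- function(cfg, report) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  json_report <- list(
    k = report$k, seed = report$seed,
    mean = as.list(round(report$mean, 10)),
    per_fold = lapply(seq_len(report$k), function(f) {
      as.list(round(unlist(report$per_fold[f, -1]), 10))
    }),
    confusion = lapply(report$confusion, unclass)
  )
  jsonlite::write_json(json_report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(
    data.frame(Method = sprintf("%s%s",
                                toupper((cfg$classifier$family %||% "svm")),
                                if (is.null(cfg$gwo)) "" else "+GWO"),
               Accuracy = report$accuracy, Precision = report$precision,
               Recall = report$recall, `F1 Score` = report$f1,
               check.names = FALSE),
    file.path(cfg$out, "metrics.csv"), row.names = FALSE
  )
  if (!is.null(report$best_positions[[1]])) {
    jsonlite::write_json(report$best_positions,
                         file.path(cfg$out, "best_position.json"),
                         digits = NA)
  }
  for (f in seq_len(report$k)) {
    cc <- report$confusion[[f]]
    utils::write.csv(data.frame(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN),
                     file.path(cfg$out, sprintf("confusion_fold%d.csv", f)),
                     row.names = FALSE)
  }
  cfg_file <- file.path(cfg$out, "config.yaml")
  yaml::write_yaml(unclass(cfg[setdiff(names(cfg), "out")]), cfg_file)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("discwolf")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out)
}
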