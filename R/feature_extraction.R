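# Deep-feature extraction: a pluggable convolutional backbone followed by a
# flatten -> fully-connected(fc_units) -> fully-connected(n_classes) head.
# The per-image descriptor handed to the optimizer/classifier stage is the
# fc_units-wide activation vector of the first dense layer.
#
# Two backbones are available:
#   * "resnet50" — the canonical 50-layer residual network, represented
#     structurally (exact shapes and variable counts; see
#     resnet50_layer_report()). Bundling 23.5M inference weights is out of
#     scope, so image->feature inference for this backbone requires either
#     a precomputed feature CSV or the debug backbone.
#   * "debug" — stride-32 average pooling (no parameters). It preserves
#     coarse spatial intensity structure, which is exactly what the
#     synthetic image generator encodes, so the whole optimizer/classifier
#     stack can be exercised end-to-end in seconds.

#' Model specification
#'
#' @param input_shape Length-3 integer vector `(height, width, channels)`;
#'   height and width must be multiples of 32.
#' @param backbone `"resnet50"` (structural 50-layer residual network) or
#'   `"debug"` (parameter-free stride-32 average pooling).
#' @param fc_units Width of the fully connected feature layer (default 1024).
#' @param n_classes Number of output classes (default 2).
#' @param pretrained Logical; reserved flag for externally supplied backbone
#'   weights. No weights are downloaded — building with
#'   `pretrained = TRUE` fails unless a weight file is supplied.
#' @param features_after_activation Take FC features after the ReLU of the
#'   dense layer (default `TRUE`) or as raw pre-activations.
#' @return A `model_spec` list.
#' @export
model_spec <- function(input_shape = c(320L, 320L, 3L),
                       backbone = c("resnet50", "debug"),
                       fc_units = 1024L, n_classes = 2L,
                       pretrained = FALSE,
                       features_after_activation = TRUE) {
  backbone <- match.arg(backbone)
  if (length(input_shape) != 3) stop_validation("input_shape must have length 3")
  if (fc_units <= 0) stop_validation("fc_units must be positive")
  if (n_classes < 2) stop_validation("n_classes must be at least 2")
  structure(
    list(input_shape = as.integer(input_shape), backbone = backbone,
         fc_units = as.integer(fc_units), n_classes = as.integer(n_classes),
         pretrained = pretrained,
         features_after_activation = features_after_activation),
    class = "model_spec"
  )
}

#' Training configuration for the classification head
#'
#' Defaults follow the study protocol: batch size 4, learning rate 1e-4,
#' 50 epochs, Adam, binary cross-entropy.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the training tensor.
#' @param optimizer Only `"adam"` is implemented.
#' @param loss Only `"binary_crossentropy"` (element-wise over the one-hot
#'   output units) is implemented.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 4L, learning_rate = 1e-4,
                            epochs = 50L, optimizer = "adam",
                            loss = "binary_crossentropy") {
  if (batch_size <= 0 || epochs <= 0 || learning_rate < 0) {
    stop_validation("batch_size and epochs must be positive; learning_rate non-negative")
  }
  if (optimizer != "adam") stop_validation("only the adam optimizer is implemented")
  if (loss != "binary_crossentropy") {
    stop_validation("only binary cross-entropy loss is implemented")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, loss = loss),
            class = "training_config")
}

# Head weights are only materialized when small enough to be useful;
# the full-size residual model is built for structural inspection.
MAX_HEAD_ENTRIES <- 1e7

#' Build the classification model
#'
#' Assembles backbone -> flatten -> fully-connected(`fc_units`) ->
#' fully-connected(`n_classes`) and reports every layer's output shape and
#' variable count. With a 320 x 320 x 3 input the residual backbone emits
#' 10 x 10 x 2048 feature maps, a flatten width of 204,800, an FC-1024
#' layer of 209,716,224 variables and an output layer of 2,050.
#'
#' Head weights (seeded He initialization) are materialized only when the
#' flatten-width x `fc_units` product is small enough to run on a laptop;
#' the structural report is produced either way.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for head weight initialization.
#' @return A `dw_model` with fields `spec`, `layer_report` (model-level
#'   rows: backbone, flatten, fc, output), `backbone_report` (per-layer
#'   detail for the residual backbone), `total_params`,
#'   `total_trainable`, and `head` (dense weights or `NULL`).
#' @export
build_model <- function(spec, seed = 42L) {
  if (!inherits(spec, "model_spec")) stop_validation("spec must be a model_spec")
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  if (h %% 32 != 0 || w %% 32 != 0) {
    stop_validation(
      "input %dx%d is not divisible by the backbone's stride-32 downsampling",
      h, w
    )
  }
  if (isTRUE(spec$pretrained)) {
    stop_validation(paste(
      "no pretrained backbone weights are bundled and none are downloaded;",
      "supply features as CSV or use backbone = 'debug'"
    ))
  }
  if (spec$backbone == "resnet50") {
    backbone_report <- resnet50_layer_report(h, w)
    out_shape <- c(h %/% 32L, w %/% 32L, 2048L)
    backbone_params <- sum(backbone_report$params)
    backbone_trainable <- sum(backbone_report$trainable)
  } else {
    backbone_report <- NULL
    out_shape <- c(h %/% 32L, w %/% 32L, spec$input_shape[3])
    backbone_params <- 0L
    backbone_trainable <- 0L
  }
  flatten_len <- as.integer(prod(out_shape))
  fc_params <- flatten_len * spec$fc_units + spec$fc_units
  out_params <- spec$fc_units * spec$n_classes + spec$n_classes
  layer_report <- data.frame(
    name = c(spec$backbone, "flatten", "fc", "output"),
    output_shape = c(paste(out_shape, collapse = "x"),
                     as.character(flatten_len),
                     as.character(spec$fc_units),
                     as.character(spec$n_classes)),
    params = c(backbone_params, 0, fc_params, out_params),
    trainable = c(backbone_trainable, 0, fc_params, out_params),
    stringsAsFactors = FALSE
  )
  head <- NULL
  if (as.double(flatten_len) * spec$fc_units <= MAX_HEAD_ENTRIES) {
    head <- mlp_init(c(flatten_len, spec$fc_units, spec$n_classes), seed = seed)
  }
  structure(
    list(spec = spec, layer_report = layer_report,
         backbone_report = backbone_report,
         backbone_out_shape = out_shape, flatten_len = flatten_len,
         total_params = sum(layer_report$params),
         total_trainable = sum(layer_report$trainable),
         head = head, seed = seed),
    class = "dw_model"
  )
}

#' @export
print.dw_model <- function(x, ...) {
  cat(sprintf("<dw_model backbone=%s input=%s fc_units=%d classes=%d>\n",
              x$spec$backbone, paste(x$spec$input_shape, collapse = "x"),
              x$spec$fc_units, x$spec$n_classes))
  print(x$layer_report, row.names = FALSE)
  cat(sprintf("total variables: %s (trainable %s)\n",
              format(x$total_params, big.mark = ","),
              format(x$total_trainable, big.mark = ",")))
  invisible(x)
}

# Backbone forward pass on an n x H x W x 3 tensor -> n x flatten matrix.
forward_backbone <- function(model, tensor) {
  d <- dim(tensor)
  if (length(d) != 4) stop_validation("tensor must be n x H x W x C")
  if (d[2] != model$spec$input_shape[1] || d[3] != model$spec$input_shape[2]) {
    stop_validation("tensor is %dx%d but the model expects %dx%d",
                    d[2], d[3], model$spec$input_shape[1], model$spec$input_shape[2])
  }
  if (model$spec$backbone != "debug") {
    stop_validation(paste(
      "inference weights for the residual backbone are not bundled;",
      "use backbone = 'debug' or load a precomputed feature matrix"
    ))
  }
  gh <- model$backbone_out_shape[1]
  gw <- model$backbone_out_shape[2]
  n <- d[1]
  out <- matrix(0, n, model$flatten_len)
  rg <- rep(seq_len(gh), each = d[2] %/% gh)
  cg <- rep(seq_len(gw), each = d[3] %/% gw)
  for (i in seq_len(n)) {
    cell <- vapply(seq_len(d[4]), function(ch) {
      as.numeric(t(rowsum(t(rowsum(tensor[i, , , ch], rg)), cg))) /
        ((d[2] %/% gh) * (d[3] %/% gw))
    }, numeric(gh * gw))
    out[i, ] <- as.numeric(cell)
  }
  out
}

#' Extract fully connected features
#'
#' Runs the backbone and the first dense layer, returning one
#' `fc_units`-wide descriptor per image. A pure function of the model
#' weights and the input: identical images yield identical rows.
#'
#' @param model A built [build_model()] handle with materialized head
#'   weights.
#' @param tensor Normalized image tensor from [normalize_images()].
#' @return Numeric matrix `n x fc_units` with columns `f0001`, `f0002`, ...
#' @export
extract_fc_features <- function(model, tensor) {
  if (!inherits(model, "dw_model")) stop_validation("model must be a dw_model")
  if (is.null(model$head)) {
    stop_validation(paste(
      "this model's dense head is structural only (too large to materialize);",
      "use the debug backbone for in-package inference"
    ))
  }
  flat <- forward_backbone(model, tensor)
  z <- flat %*% model$head$W[[1]] +
    matrix(model$head$b[[1]], nrow(flat), model$spec$fc_units, byrow = TRUE)
  feats <- if (model$spec$features_after_activation) pmax(z, 0) else z
  colnames(feats) <- sprintf("f%04d", seq_len(ncol(feats)))
  feats
}

#' Train the classification head
#'
#' Freezes the (parameter-free or structural) backbone and trains the
#' flatten -> FC -> output head with Adam on element-wise binary
#' cross-entropy against one-hot labels.
#'
#' @param model A [build_model()] handle with materialized head weights.
#' @param tensor Normalized image tensor.
#' @param labels One-hot label matrix from [one_hot()] (or an integer
#'   vector, which is encoded automatically).
#' @param cfg A [training_config()].
#' @param seed Seed controlling mini-batch shuffling.
#' @return The model with updated head weights plus `$trace`, a
#'   `data.frame` with one row per epoch (`epoch`, `loss`, `accuracy`).
#' @export
train_model <- function(model, tensor, labels, cfg = training_config(),
                        seed = 0L) {
  if (!inherits(cfg, "training_config")) stop_validation("cfg must be a training_config")
  if (is.null(model$head)) {
    stop_validation("model head weights are not materialized; use the debug backbone")
  }
  if (!is.matrix(labels)) labels <- one_hot(labels, model$spec$n_classes)
  n <- dim(tensor)[1]
  if (nrow(labels) != n) stop_validation("tensor and labels are misaligned")
  if (n < cfg$batch_size) {
    stop_validation("sample count %d is smaller than batch_size %d", n, cfg$batch_size)
  }
  flat <- forward_backbone(model, tensor)
  fit <- mlp_train(flat, labels, hidden_sizes = model$spec$fc_units,
                   hidden_activation = "relu",
                   learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                   batch_size = cfg$batch_size, seed = seed,
                   init = model$head)
  model$head <- fit$params
  model$trace <- fit$trace
  model
}

#' Write / read a feature matrix as CSV
#'
#' Column headers are `f0001` ... `fNNNN`; an optional `label` column stores
#' integer class labels.
#'
#' @param features Numeric feature matrix.
#' @param path CSV path.
#' @param labels Optional integer label vector.
#' @return `path` (writer) or a list with `features` and `labels` (reader).
#' @export
write_feature_csv <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  names(df) <- sprintf("f%04d", seq_len(ncol(features)))
  if (!is.null(labels)) {
    if (length(labels) != nrow(features)) stop_validation("labels misaligned")
    df$label <- as.integer(labels)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop_validation("feature CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  features <- as.matrix(df)
  if (!is.numeric(features)) stop_validation("non-numeric feature columns in %s", path)
  list(features = features, labels = labels)
}
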