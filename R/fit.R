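#' Hyperparameter set for the three-stage model
#'
#' One complete hyperparameter record: per-omics embedding dimensions,
#' triplet margin, optimiser settings shared by the encoders and the
#' classifier head, and optional fixed per-layer feature counts overriding
#' the elbow rule. Embedding dimensions must satisfy
#' `dim_expression > dim_cna > dim_mutation`, mirroring the relative
#' information content of the three layers.
#'
#' @param dim_expression,dim_cna,dim_mutation embedding dimensions per layer.
#' @param margin triplet margin alpha.
#' @param lr_encoder,lr_classifier Adam learning rates.
#' @param weight_decay L2 penalty for both stages.
#' @param dropout_rate dropout probability for both stages.
#' @param batch_size mini-batch size.
#' @param epochs_encoder,patience_encoder encoder epoch budget and early
#'   stopping patience.
#' @param epochs_classifier,patience_classifier classifier budget/patience.
#' @param top_k optional named vector of fixed feature counts per layer
#'   (e.g. `c(expression = 200)`), overriding the elbow threshold.
#' @param squared_distance use squared Euclidean distance in the triplet
#'   loss.
#' @param include_bias intercept in the classifier head.
#' @return An object of class `tripletdr_hp`.
#' @export
tripletdr_hp <- function(dim_expression = 64, dim_cna = 32, dim_mutation = 16,
                         margin = 1, lr_encoder = 0.01, lr_classifier = 0.01,
                         weight_decay = 1e-4, dropout_rate = 0.1,
                         batch_size = 32, epochs_encoder = 50,
                         patience_encoder = 5, epochs_classifier = 150,
                         patience_classifier = 15, top_k = NULL,
                         squared_distance = FALSE, include_bias = TRUE) {
  if (!(dim_expression > dim_cna && dim_cna > dim_mutation)) {
    stop("embedding dimensions must satisfy ",
         "dim_expression > dim_cna > dim_mutation")
  }
  structure(list(dim_expression = as.integer(dim_expression),
                 dim_cna = as.integer(dim_cna),
                 dim_mutation = as.integer(dim_mutation),
                 margin = margin, lr_encoder = lr_encoder,
                 lr_classifier = lr_classifier, weight_decay = weight_decay,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs_encoder = as.integer(epochs_encoder),
                 patience_encoder = as.integer(patience_encoder),
                 epochs_classifier = as.integer(epochs_classifier),
                 patience_classifier = as.integer(patience_classifier),
                 top_k = top_k, squared_distance = isTRUE(squared_distance),
                 include_bias = isTRUE(include_bias)),
            class = "tripletdr_hp")
}

# per-layer standardisation fitted on training data; binary mutation layers
# are left untouched
scaler_fit <- function(x, kind) {
  if (kind == "mutation") {
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  }
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  sc[sc < 1e-8] <- 1
  list(center = ctr, scale = sc)
}

scaler_apply <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

active_layers <- function(mode) {
  switch(mode,
         all = c("expression", "mutation", "cna"),
         no_encoder = c("expression", "mutation", "cna"),
         expression_only = "expression",
         mut_cna = c("mutation", "cna"))
}

layer_dim <- function(hp, layer) {
  switch(layer, expression = hp$dim_expression, mutation = hp$dim_mutation,
         cna = hp$dim_cna)
}

#' Fit the three-stage multi-omics drug-response model
#'
#' Stage 1 fits a variance-threshold feature mask per active omics layer on
#' the training split (elbow rule, see [fit_mask()]); continuous layers are
#' then standardised with training statistics. Stage 2 trains an independent
#' single-layer ReLU encoder per layer under the batch-all triplet loss
#' ([train_encoder()]). Stage 3 freezes the encoders, concatenates their
#' embeddings (expression, mutation, CNA order), and trains a single-layer
#' sigmoid classifier with binary cross-entropy and minority oversampling
#' ([train_classifier()]). Encoders and classifier are trained
#' independently: classifier training never updates encoder weights.
#'
#' Ablation modes: `"expression_only"` and `"mut_cna"` restrict the active
#' layers; `"no_encoder"` skips stage 2 and feeds the selected, standardised
#' features directly to the classifier.
#'
#' @param data a [multiomics_dataset()] of training samples (both classes
#'   present).
#' @param val optional validation [multiomics_dataset()]; if `NULL`, a
#'   stratified `val_fraction` split is carved from `data`.
#' @param mode omics mode: `"all"`, `"expression_only"`, `"mut_cna"` or
#'   `"no_encoder"`.
#' @param hp a [tripletdr_hp()] hyperparameter set.
#' @param seed master integer seed; per-stage seeds are derived from it, so
#'   the fit is fully reproducible.
#' @param val_fraction fraction used for the internal validation split when
#'   `val` is `NULL`.
#' @return An object of class `tripletdr` with elements `mode`, `layers`
#'   (per-layer mask, scaler and encoder), `classifier`, `hp`, `seed`,
#'   `val_auc` and `drug_name`. Supports [predict()], [print()],
#'   [summary()] and [coef()].
#' @examples
#' \donttest{
#' d <- simulate_dataset(n_samples = 120, seed = 1,
#'   n_features = c(expression = 120, mutation = 60, cna = 80),
#'   n_informative = c(expression = 10, mutation = 5, cna = 8))
#' fit <- tripletdr(d, mode = "expression_only",
#'   hp = tripletdr_hp(dim_expression = 16, dim_cna = 8, dim_mutation = 4,
#'     epochs_encoder = 10, patience_encoder = 10,
#'     epochs_classifier = 30, patience_classifier = 30))
#' fit
#' }
#' @export
tripletdr <- function(data, val = NULL,
                      mode = c("all", "expression_only", "mut_cna",
                               "no_encoder"),
                      hp = tripletdr_hp(), seed = 1, val_fraction = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "multiomics_dataset"),
            inherits(hp, "tripletdr_hp"))
  seed <- as.integer(seed)
  if (is.null(val)) {
    y <- data$labels$labels
    set.seed(derive_seed(seed, 1))
    val_idx <- unlist(lapply(c(0, 1), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(val_fraction * length(idx))))
    }))
    val <- mo_subset(data, sort(val_idx))
    data <- mo_subset(data, setdiff(seq_along(y), val_idx))
  }
  stopifnot(inherits(val, "multiomics_dataset"))
  y_tr <- data$labels$labels
  y_val <- val$labels$labels
  if (length(unique(y_tr)) < 2) stop("training labels contain a single class")
  if (length(unique(y_val)) < 2) {
    stop("validation labels contain a single class")
  }

  layers <- list()
  emb_tr <- list(expression = NULL, mutation = NULL, cna = NULL)
  emb_val <- list(expression = NULL, mutation = NULL, cna = NULL)
  for (layer in active_layers(mode)) {
    li <- match(layer, c("expression", "mutation", "cna"))
    tk <- if (!is.null(hp$top_k) && layer %in% names(hp$top_k)) {
      hp$top_k[[layer]]
    } else {
      NULL
    }
    mask <- fit_mask(data[[layer]], top_k = tk)
    xtr <- apply_mask(data[[layer]], mask)$values
    xva <- apply_mask(val[[layer]], mask)$values
    scaler <- scaler_fit(xtr, layer)
    xtr <- scaler_apply(xtr, scaler)
    xva <- scaler_apply(xva, scaler)
    if (mode == "no_encoder") {
      encoder <- NULL
      emb_tr[[layer]] <- xtr
      emb_val[[layer]] <- xva
    } else {
      cfg <- encoder_config(
        output_dim = layer_dim(hp, layer), margin = hp$margin,
        learning_rate = hp$lr_encoder, weight_decay = hp$weight_decay,
        dropout_rate = hp$dropout_rate, batch_size = hp$batch_size,
        max_epochs = hp$epochs_encoder, patience = hp$patience_encoder,
        seed = derive_seed(seed, 2, li),
        squared_distance = hp$squared_distance)
      encoder <- train_encoder(xtr, y_tr, xva, y_val, cfg, kind = layer)
      emb_tr[[layer]] <- encode(encoder, xtr)
      emb_val[[layer]] <- encode(encoder, xva)
    }
    layers[[layer]] <- list(mask = mask, scaler = scaler, encoder = encoder)
  }

  xhat_tr <- concat_embeddings(emb_tr$expression, emb_tr$mutation,
                               emb_tr$cna)
  xhat_val <- concat_embeddings(emb_val$expression, emb_val$mutation,
                                emb_val$cna)
  clf_cfg <- classifier_config(
    learning_rate = hp$lr_classifier, weight_decay = hp$weight_decay,
    dropout_rate = hp$dropout_rate, batch_size = hp$batch_size,
    max_epochs = hp$epochs_classifier, patience = hp$patience_classifier,
    include_bias = hp$include_bias, seed = derive_seed(seed, 3))
  clf <- train_classifier(xhat_tr, y_tr, xhat_val, y_val, clf_cfg)
  val_auc <- roc_auc(predict_proba(clf, xhat_val), y_val)

  structure(list(mode = mode, layers = layers, classifier = clf, hp = hp,
                 seed = seed, val_auc = val_auc,
                 n_train = length(y_tr), n_val = length(y_val),
                 drug_name = data$drug_name),
            class = "tripletdr")
}

# shared path: masks -> scaling -> encoding -> concatenation
model_embed <- function(object, matrices) {
  emb <- list(expression = NULL, mutation = NULL, cna = NULL)
  for (layer in names(object$layers)) {
    m <- matrices[[layer]]
    if (is.null(m)) stop("missing '", layer, "' matrix required by the model")
    st <- object$layers[[layer]]
    x <- scaler_apply(apply_mask(m, st$mask)$values, st$scaler)
    emb[[layer]] <- if (is.null(st$encoder)) x else encode(st$encoder, x)
  }
  concat_embeddings(emb$expression, emb$mutation, emb$cna)
}

#' Predict drug-response probabilities
#'
#' Applies the fitted masks, scalers and frozen encoders, concatenates the
#' embeddings and returns sigmoid scores. Deterministic: dropout is never
#' applied at prediction time.
#'
#' @param object a fitted `tripletdr` model.
#' @param newdata a [multiomics_dataset()], or `NULL` if the individual
#'   matrices are supplied.
#' @param expression,mutation,cna `omics_matrix` inputs (alternative to
#'   `newdata`); each must contain all mask features of its layer.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   score.
#' @param ... unused.
#' @return Named numeric vector, one score per sample.
#' @export
predict.tripletdr <- function(object, newdata = NULL, expression = NULL,
                              mutation = NULL, cna = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    stopifnot(inherits(newdata, "multiomics_dataset"))
    matrices <- list(expression = newdata$expression,
                     mutation = newdata$mutation, cna = newdata$cna)
  } else {
    matrices <- list(expression = expression, mutation = mutation, cna = cna)
  }
  xhat <- model_embed(object, matrices)
  z <- drop(xhat %*% object$classifier$weights) + object$classifier$bias
  out <- if (type == "response") sigmoid(z) else z
  names(out) <- rownames(xhat)
  out
}

#' @export
print.tripletdr <- function(x, ...) {
  nfeat <- vapply(x$layers, function(l) length(l$mask$features), integer(1))
  cat(sprintf("tripletdr model [mode = %s]\n", x$mode))
  cat(sprintf("  layers: %s\n",
              paste(sprintf("%s (%d features)", names(x$layers), nfeat),
                    collapse = ", ")))
  cat(sprintf("  classifier inputs: %d; validation AUC %.3f\n",
              length(x$classifier$weights), x$val_auc))
  invisible(x)
}

#' @export
summary.tripletdr <- function(object, ...) {
  layers <- lapply(names(object$layers), function(layer) {
    st <- object$layers[[layer]]
    data.frame(layer = layer,
               n_features_in = length(st$mask$variances),
               n_features_kept = length(st$mask$features),
               variance_threshold = st$mask$threshold,
               embedding_dim = if (is.null(st$encoder)) {
                 length(st$mask$features)
               } else {
                 ncol(st$encoder$weights)
               },
               encoder_best_epoch = if (is.null(st$encoder)) NA_integer_
                                    else st$encoder$best_epoch)
  })
  out <- list(mode = object$mode, layers = do.call(rbind, layers),
              n_train = object$n_train, n_val = object$n_val,
              val_auc = object$val_auc,
              classifier_best_epoch = object$classifier$best_epoch)
  class(out) <- "summary.tripletdr"
  out
}

#' @export
print.summary.tripletdr <- function(x, ...) {
  cat(sprintf("Three-stage drug-response model, mode = %s\n", x$mode))
  cat(sprintf("Training samples: %d; validation samples: %d\n",
              x$n_train, x$n_val))
  print(x$layers, row.names = FALSE)
  cat(sprintf("Classifier best epoch: %d; validation AUC: %.3f\n",
              x$classifier_best_epoch, x$val_auc))
  invisible(x)
}

#' @export
coef.tripletdr <- function(object, ...) {
  w <- object$classifier$weights
  names(w) <- object$classifier$feature_names
  if (object$classifier$include_bias) {
    w <- c("(Intercept)" = object$classifier$bias, w)
  }
  w
}

#' Save / load a fitted model archive
#'
#' The archive is a single compressed file holding masks, scalers, encoder
#' and classifier weights, the hyperparameter record and the master seed —
#' everything needed to reproduce predictions.
#'
#' @param model a `tripletdr` model.
#' @param path archive file path.
#' @return `save_tripletdr` returns `path` invisibly; `load_tripletdr`
#'   returns the model.
#' @export
save_tripletdr <- function(model, path) {
  stopifnot(inherits(model, "tripletdr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tripletdr
#' @export
load_tripletdr <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "tripletdr"))
  model
}
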