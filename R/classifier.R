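#' Classifier training configuration
#'
#' Settings for the single-layer sigmoid classifier head: mini-batch Adam on
#' binary cross-entropy over the (oversampled) training set, dropout on the
#' concatenated embedding input, L2 weight decay, and early stopping on
#' validation AUC.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty.
#' @param dropout_rate dropout probability on the input during training.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum epochs; 0 returns the initial weights.
#' @param patience epochs without validation AUC improvement before stopping.
#' @param include_bias fit an intercept term (the pure linear-score variant
#'   is available with `FALSE`).
#' @param seed integer seed.
#' @param oversample balance classes by duplicating minority samples, drawn
#'   once per training run.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(learning_rate = 0.01, weight_decay = 1e-4,
                              dropout_rate = 0.1, batch_size = 32,
                              max_epochs = 200, patience = 20,
                              include_bias = TRUE, seed = 1,
                              oversample = TRUE) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (patience > max_epochs && max_epochs > 0) {
    stop("patience must not exceed max_epochs")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 include_bias = isTRUE(include_bias),
                 seed = as.integer(seed), oversample = isTRUE(oversample)),
            class = "classifier_config")
}

#' Concatenate per-omics embeddings
#'
#' Column-binds embeddings in the fixed order expression, mutation, CNA.
#' `NULL` layers (ablation modes) are skipped; with two layers absent the
#' result equals the remaining one.
#'
#' @param expression,mutation,cna embedding matrices with equal row counts,
#'   or `NULL`.
#' @return The combined samples x total-dimension matrix.
#' @export
concat_embeddings <- function(expression = NULL, mutation = NULL, cna = NULL) {
  parts <- Filter(Negate(is.null),
                  list(expression = expression, mutation = mutation,
                       cna = cna))
  if (length(parts) == 0) stop("at least one embedding is required")
  parts <- lapply(parts, as_values)
  rows <- vapply(parts, nrow, integer(1))
  if (length(unique(rows)) > 1) stop("embeddings have mismatched row counts")
  out <- do.call(cbind, parts)
  colnames(out) <- unlist(lapply(names(parts), function(nm) {
    cn <- colnames(parts[[nm]])
    if (is.null(cn)) cn <- sprintf("%d", seq_len(ncol(parts[[nm]])))
    paste0(substr(nm, 1, 3), "_", cn)
  }))
  out
}

#' Predicted sensitivity probabilities
#'
#' Sigmoid of the linear score `X w (+ b)`; outputs are strictly in (0, 1).
#'
#' @param clf a `sigmoid_classifier`.
#' @param xhat input matrix with width matching the classifier.
#' @return Numeric probability vector.
#' @export
predict_proba <- function(clf, xhat) {
  stopifnot(inherits(clf, "sigmoid_classifier"))
  xhat <- as_values(xhat)
  if (ncol(xhat) != length(clf$weights)) {
    stop(sprintf("input has %d columns but classifier expects %d",
                 ncol(xhat), length(clf$weights)))
  }
  z <- drop(xhat %*% clf$weights) + clf$bias
  sigmoid(z)
}

#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1-y) log(1-p)]` with probabilities clipped to
#' `[eps, 1-eps]`.
#'
#' @param probs probability vector.
#' @param labels binary vector of the same length.
#' @param eps clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  y <- as_binary_labels(labels)
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Minority-oversampled index multiset
#'
#' Returns every original index once, plus minority-class indices drawn with
#' replacement (seeded) until both classes have equal counts. The majority
#' class is never duplicated; an already balanced input is returned
#' unchanged.
#'
#' @param labels binary vector with both classes present.
#' @param seed integer seed for the replacement draws.
#' @return Integer index multiset of length `2 * max(class counts)`.
#' @export
oversample_indices <- function(labels, seed = 1) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("oversampling requires both classes")
  base <- seq_along(y)
  if (n1 == n0) return(base)
  minority <- if (n1 < n0) which(y == 1) else which(y == 0)
  need <- abs(n0 - n1)
  set.seed(as.integer(seed))
  c(base, sample(minority, need, replace = TRUE))
}

#' Train the sigmoid classifier head
#'
#' Minimises binary cross-entropy over the (minority-oversampled) training
#' embeddings with mini-batch Adam, dropout on the input, and L2 weight
#' decay. After each epoch the validation AUC is computed; training stops
#' when it fails to improve for `patience` epochs and the best-validation-AUC
#' weights are returned. The encoder embeddings passed in are treated as
#' frozen inputs: this function never touches encoder state.
#'
#' @param xhat training embedding matrix.
#' @param labels binary training labels.
#' @param xhat_val,labels_val validation split; both classes are required
#'   (AUC is otherwise undefined).
#' @param cfg a [classifier_config()].
#' @return An object of class `sigmoid_classifier`: `weights`, `bias`,
#'   `include_bias`, `history` (per-epoch train loss and validation AUC),
#'   `best_epoch`, `config`.
#' @export
train_classifier <- function(xhat, labels, xhat_val, labels_val,
                             cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  xv <- as_values(xhat)
  y <- as_binary_labels(labels)
  xval <- as_values(xhat_val)
  yval <- as_binary_labels(labels_val)
  if (length(y) != nrow(xv) || length(yval) != nrow(xval)) {
    stop("label length does not match matrix rows")
  }
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (length(unique(yval)) < 2) {
    stop("validation labels contain a single class: AUC undefined")
  }
  m <- ncol(xv)
  set.seed(cfg$seed)
  s <- 1 / sqrt(m)
  w <- stats::runif(m, -s, s)
  b <- 0
  clf <- structure(list(weights = w, bias = b,
                        include_bias = cfg$include_bias,
                        feature_names = colnames(xv),
                        history = NULL, best_epoch = 0L, config = cfg),
                   class = "sigmoid_classifier")
  if (cfg$max_epochs == 0) return(clf)

  pool <- if (cfg$oversample) {
    oversample_indices(y, seed = derive_seed(cfg$seed, 11))
  } else {
    seq_along(y)
  }
  opt_w <- adam_init(m)
  opt_b <- adam_init(1)
  best_auc <- -Inf
  best <- list(w = w, b = b)
  best_epoch <- 0L
  wait <- 0L
  hist <- matrix(NA_real_, cfg$max_epochs, 2,
                 dimnames = list(NULL, c("train_loss", "val_auc")))
  drop_p <- cfg$dropout_rate

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(pool)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_losses <- c()
    for (idx in batches) {
      xb <- xv[idx, , drop = FALSE]
      yb <- y[idx]
      if (drop_p > 0) {
        mask <- matrix(stats::runif(length(xb)) >= drop_p, nrow(xb), ncol(xb))
        xb <- xb * mask / (1 - drop_p)
      }
      z <- drop(xb %*% w) + b
      p <- sigmoid(z)
      epoch_losses <- c(epoch_losses, bce_loss(p, yb))
      dz <- (p - yb) / length(yb)
      gw <- drop(crossprod(xb, dz)) + cfg$weight_decay * w
      opt_w <- adam_step(opt_w, gw, cfg$learning_rate)
      w <- w - opt_w$delta
      if (cfg$include_bias) {
        opt_b <- adam_step(opt_b, sum(dz), cfg$learning_rate)
        b <- b - as.numeric(opt_b$delta)
      }
    }
    val_scores <- sigmoid(drop(xval %*% w) + b)
    val_auc <- roc_auc(val_scores, yval)
    hist[epoch, ] <- c(mean(epoch_losses %||% NA_real_), val_auc)
    if (val_auc > best_auc + 1e-10) {
      best_auc <- val_auc
      best <- list(w = w, b = b)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  clf$weights <- best$w
  clf$bias <- best$b
  clf$history <- as.data.frame(hist[seq_len(epoch), , drop = FALSE])
  clf$best_epoch <- best_epoch
  clf
}

#' @export
print.sigmoid_classifier <- function(x, ...) {
  cat(sprintf(
    "sigmoid_classifier: %d inputs%s, best epoch %d of %d trained\n",
    length(x$weights), if (x$include_bias) " + bias" else "",
    x$best_epoch, if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}
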