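#' Encoder training configuration
#'
#' Settings for one supervised triplet-loss encoder: a single fully connected
#' layer with ReLU activation, trained by mini-batch Adam on the batch-all
#' triplet loss, regularised by dropout on the ReLU output, L2 weight decay,
#' and early stopping on the validation triplet loss.
#'
#' @param output_dim embedding dimension (>= 1).
#' @param margin triplet margin alpha (>= 0) separating positive and negative
#'   pair distances.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient.
#' @param dropout_rate dropout probability on the embedding during training,
#'   in [0, 1).
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs; 0 returns the initial weights.
#' @param patience epochs without validation improvement before stopping
#'   (<= max_epochs).
#' @param seed integer seed; training is fully reproducible given it.
#' @param squared_distance use squared Euclidean distances in the loss.
#' @param oversample balance classes in training batches by duplicating
#'   minority samples (drawn once per run).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(output_dim = 64, margin = 1,
                           learning_rate = 0.01, weight_decay = 1e-4,
                           dropout_rate = 0.1, batch_size = 32,
                           max_epochs = 100, patience = 10, seed = 1,
                           squared_distance = FALSE, oversample = TRUE) {
  if (output_dim < 1) stop("output_dim must be >= 1")
  if (margin < 0) stop("margin must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (patience > max_epochs && max_epochs > 0) {
    stop("patience must not exceed max_epochs")
  }
  structure(list(output_dim = as.integer(output_dim), margin = margin,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 squared_distance = isTRUE(squared_distance),
                 oversample = isTRUE(oversample)),
            class = "encoder_config")
}

#' Enumerate all anchor/positive/negative triplets in a batch
#'
#' Batch-all mining: every ordered (anchor, positive) pair of same-class
#' samples combined with every opposite-class negative, for both classes as
#' anchor class. With class counts `n1`, `n0` this yields
#' `n1(n1-1)n0 + n0(n0-1)n1` triplets.
#'
#' @param labels binary vector for the batch.
#' @return An object of class `triplet_batch` with equal-length index vectors
#'   `anchor`, `positive`, `negative`. A batch with no valid triplet returns
#'   an empty `triplet_batch` with a warning.
#' @export
make_triplets <- function(labels) {
  y <- as_binary_labels(labels)
  pos_cls <- which(y == 1)
  neg_cls <- which(y == 0)
  one_way <- function(same, other) {
    if (length(same) < 2 || length(other) < 1) return(NULL)
    g <- expand.grid(anchor = same, positive = same, negative = other,
                     KEEP.OUT.ATTRS = FALSE)
    g[g$anchor != g$positive, , drop = FALSE]
  }
  g <- rbind(one_way(pos_cls, neg_cls), one_way(neg_cls, pos_cls))
  if (is.null(g) || nrow(g) == 0) {
    warning("no valid triplet in batch (single-class or too small)")
    g <- data.frame(anchor = integer(0), positive = integer(0),
                    negative = integer(0))
  }
  structure(list(anchor = as.integer(g$anchor),
                 positive = as.integer(g$positive),
                 negative = as.integer(g$negative)),
            class = "triplet_batch")
}

#' @export
length.triplet_batch <- function(x) length(x$anchor)

#' Batch-all triplet loss
#'
#' Mean over all triplets of the hinge
#' `max(d(a,p) - d(a,n) + margin, 0)` with `d` the Euclidean distance
#' between embedding rows (squared Euclidean if `squared_distance`). The
#' mean (rather than a sum over pairs) makes the value invariant to batch
#' composition; it rescales gradients uniformly without changing minimisers.
#'
#' @param embeddings numeric matrix, one row per batch sample.
#' @param triplets a `triplet_batch` indexing rows of `embeddings`.
#' @param margin triplet margin alpha.
#' @param squared_distance use squared Euclidean distance.
#' @return Non-negative scalar; an empty triplet batch gives 0 with a
#'   warning.
#' @export
triplet_loss <- function(embeddings, triplets, margin = 1,
                         squared_distance = FALSE) {
  stopifnot(inherits(triplets, "triplet_batch"))
  if (length(triplets) == 0) {
    warning("empty triplet batch: loss defined as 0")
    return(0)
  }
  z <- as_values(embeddings)
  if (max(triplets$anchor, triplets$positive, triplets$negative) > nrow(z)) {
    stop("triplet indices exceed embedding rows")
  }
  d_ap <- rowSums((z[triplets$anchor, , drop = FALSE] -
                     z[triplets$positive, , drop = FALSE])^2)
  d_an <- rowSums((z[triplets$anchor, , drop = FALSE] -
                     z[triplets$negative, , drop = FALSE])^2)
  if (!squared_distance) {
    d_ap <- sqrt(d_ap)
    d_an <- sqrt(d_an)
  }
  mean(pmax(d_ap - d_an + margin, 0))
}

# Gradient of the mean batch-all triplet loss w.r.t. the embedding matrix.
# Returns list(loss, grad). Distances below `eps` contribute zero direction.
triplet_loss_grad <- function(z, triplets, margin, squared_distance = FALSE,
                              eps = 1e-12) {
  K <- length(triplets$anchor)
  nb <- nrow(z)
  a <- triplets$anchor; p <- triplets$positive; n <- triplets$negative
  diff_ap <- z[a, , drop = FALSE] - z[p, , drop = FALSE]
  diff_an <- z[a, , drop = FALSE] - z[n, , drop = FALSE]
  sq_ap <- rowSums(diff_ap^2)
  sq_an <- rowSums(diff_an^2)
  if (squared_distance) {
    hinge <- sq_ap - sq_an + margin
    u_ap <- 2 * diff_ap
    u_an <- 2 * diff_an
  } else {
    d_ap <- sqrt(sq_ap)
    d_an <- sqrt(sq_an)
    hinge <- d_ap - d_an + margin
    u_ap <- diff_ap / pmax(d_ap, eps)
    u_an <- diff_an / pmax(d_an, eps)
  }
  active <- hinge > 0
  loss <- sum(pmax(hinge, 0)) / K
  grad <- matrix(0, nb, ncol(z))
  if (any(active)) {
    acc <- function(idx, m) {
      s <- rowsum(m, group = idx)
      grad[as.integer(rownames(s)), ] <<-
        grad[as.integer(rownames(s)), , drop = FALSE] + s
    }
    ua <- u_ap[active, , drop = FALSE]
    un <- u_an[active, , drop = FALSE]
    acc(a[active], (ua - un) / K)
    acc(p[active], -ua / K)
    acc(n[active], un / K)
  }
  list(loss = loss, grad = grad)
}

#' Encode a reduced omics matrix
#'
#' Applies the single-layer encoder: `relu(X W)`. Dropout is a training-time
#' regulariser only and is never applied here, so encoding is deterministic.
#'
#' @param model a `triplet_encoder`.
#' @param x numeric matrix or `omics_matrix` whose columns match the model's
#'   input features.
#' @return Non-negative embedding matrix, samples x `output_dim`.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "triplet_encoder"))
  xv <- as_values(x)
  if (ncol(xv) != nrow(model$weights)) {
    stop(sprintf("input has %d columns but encoder expects %d",
                 ncol(xv), nrow(model$weights)))
  }
  relu(xv %*% model$weights)
}

#' Train a supervised triplet-loss encoder
#'
#' Trains `relu(X W)` to pull same-class samples together and push
#' opposite-class samples at least `margin` apart, by mini-batch Adam on the
#' mean batch-all triplet loss, with L2 weight decay and dropout on the
#' embedding. After each epoch the batch-all triplet loss over the full
#' validation split is computed; training stops once it fails to improve for
#' `patience` consecutive epochs and the weights of the best validation
#' epoch are returned.
#'
#' @param x training matrix (post feature-selection), samples x features.
#' @param labels binary training labels (both classes required).
#' @param x_val,labels_val validation split (both classes required).
#' @param cfg an [encoder_config()].
#' @param kind omics-layer tag stored on the model.
#' @return An object of class `triplet_encoder`: `weights` (features x
#'   `output_dim`), `feature_ids`, `kind`, `history` (per-epoch train and
#'   validation loss), `best_epoch`, `config`.
#' @export
train_encoder <- function(x, labels, x_val, labels_val, cfg = encoder_config(),
                          kind = NULL) {
  stopifnot(inherits(cfg, "encoder_config"))
  if (inherits(x, "omics_matrix") && is.null(kind)) kind <- x$kind
  feature_ids <- if (inherits(x, "omics_matrix")) x$feature_ids else colnames(x)
  xv <- as_values(x)
  y <- as_binary_labels(labels)
  xval <- as_values(x_val)
  yval <- as_binary_labels(labels_val)
  if (length(y) != nrow(xv) || length(yval) != nrow(xval)) {
    stop("label length does not match matrix rows")
  }
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (length(unique(yval)) < 2) stop("validation labels contain a single class")

  m <- ncol(xv)
  set.seed(cfg$seed)
  s <- 1 / sqrt(m)
  W <- matrix(stats::runif(m * cfg$output_dim, -s, s), m, cfg$output_dim)
  model <- structure(list(weights = W, feature_ids = feature_ids,
                          kind = kind, history = NULL, best_epoch = 0L,
                          config = cfg),
                     class = "triplet_encoder")
  if (cfg$max_epochs == 0) return(model)

  pool <- if (cfg$oversample) {
    oversample_indices(y, seed = derive_seed(cfg$seed, 7))
  } else {
    seq_along(y)
  }
  val_triplets <- suppressWarnings(make_triplets(yval))
  opt <- adam_init(dim(W))
  best_loss <- Inf
  best_W <- W
  best_epoch <- 0L
  wait <- 0L
  hist <- matrix(NA_real_, cfg$max_epochs, 2,
                 dimnames = list(NULL, c("train_loss", "val_loss")))
  drop_p <- cfg$dropout_rate

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(pool)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_losses <- c()
    for (b in batches) {
      yb <- y[b]
      if (length(unique(yb)) < 2) next
      trip <- suppressWarnings(make_triplets(yb))
      if (length(trip) == 0) next
      xb <- xv[b, , drop = FALSE]
      pre <- xb %*% W
      h <- relu(pre)
      if (drop_p > 0) {
        mask <- matrix(stats::runif(length(h)) >= drop_p, nrow(h), ncol(h))
        hd <- h * mask / (1 - drop_p)
      } else {
        hd <- h
      }
      lg <- triplet_loss_grad(hd, trip, cfg$margin, cfg$squared_distance)
      epoch_losses <- c(epoch_losses, lg$loss)
      dh <- lg$grad
      if (drop_p > 0) dh <- dh * mask / (1 - drop_p)
      dpre <- dh * (pre > 0)
      grad <- crossprod(xb, dpre) + cfg$weight_decay * W
      opt <- adam_step(opt, grad, cfg$learning_rate)
      W <- W - opt$delta
    }
    val_emb <- relu(xval %*% W)
    val_loss <- if (length(val_triplets) == 0) 0 else {
      triplet_loss(val_emb, val_triplets, cfg$margin, cfg$squared_distance)
    }
    hist[epoch, ] <- c(mean(epoch_losses %||% NA_real_), val_loss)
    if (val_loss < best_loss - 1e-10) {
      best_loss <- val_loss
      best_W <- W
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$weights <- best_W
  model$history <- as.data.frame(hist[seq_len(epoch), , drop = FALSE])
  model$best_epoch <- best_epoch
  model
}

#' @export
print.triplet_encoder <- function(x, ...) {
  cat(sprintf(
    "triplet_encoder%s: %d -> %d, best epoch %d of %d trained\n",
    if (!is.null(x$kind)) paste0(" [", x$kind, "]") else "",
    nrow(x$weights), ncol(x$weights), x$best_epoch,
    if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}
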