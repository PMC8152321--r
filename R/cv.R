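#' Nested stratified split plan
#'
#' Per repeat, a stratified k-fold partition of the samples; within each
#' training fold, a further stratified validation split. With 5 folds and
#' `val_fraction = 0.2` each cell uses 64% of the samples for training, 16%
#' for validation and 20% for testing. Stratification keeps per-fold class
#' ratios within one sample of the global ratio, which with heavily
#' imbalanced panels is what keeps the AUC defined in every cell.
#'
#' @param n number of samples.
#' @param labels binary vector of length `n`.
#' @param repeats,folds protocol dimensions (default 5 x 5).
#' @param val_fraction fraction of each training fold moved to validation.
#' @param seed integer seed; the plan is fully determined by it.
#' @return An object of class `nested_split_plan`: a list of `repeats`
#'   lists, each of `folds` cells with sorted integer vectors `train`,
#'   `validation`, `test`.
#' @export
nested_split <- function(n, labels, repeats = 5, folds = 5,
                         val_fraction = 0.2, seed = 1) {
  y <- as_binary_labels(labels)
  if (length(y) != n) stop("labels must have length n")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < folds)) {
    stop(sprintf("stratification impossible: a class has %d < %d samples",
                 min(counts), folds))
  }
  plan <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 101, r))
    fold_of <- integer(n)
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    plan[[r]] <- lapply(seq_len(folds), function(f) {
      test <- which(fold_of == f)
      rest <- which(fold_of != f)
      set.seed(derive_seed(seed, 102, r, f))
      val <- unlist(lapply(c(0, 1), function(cls) {
        pool <- rest[y[rest] == cls]
        sample(pool, max(1L, round(val_fraction * length(pool))))
      }))
      list(train = sort(setdiff(rest, val)), validation = sort(val),
           test = sort(test))
    })
  }
  structure(list(repeats = plan, n = n, folds = folds,
                 val_fraction = val_fraction, seed = seed),
            class = "nested_split_plan")
}

#' @export
print.nested_split_plan <- function(x, ...) {
  cell <- x$repeats[[1]][[1]]
  cat(sprintf(
    "nested_split_plan: %d repeats x %d folds over %d samples\n",
    length(x$repeats), x$folds, x$n))
  cat(sprintf("  first cell: %d train / %d validation / %d test\n",
              length(cell$train), length(cell$validation),
              length(cell$test)))
  invisible(x)
}

#' Nested cross-validation with validation-AUC hyperparameter selection
#'
#' Runs the full protocol: for every (repeat, fold) cell and every
#' hyperparameter set, fits the three-stage model on the training split and
#' records validation and test AUC. The reported test AUC per cell is that
#' of the hyperparameter set with the highest validation AUC in that cell
#' (ties to the first set in the list); `selection = "overall"` instead
#' picks one set for all cells by the argmax of the mean validation AUC.
#'
#' @param data a [multiomics_dataset()].
#' @param hp_sets a [tripletdr_hp()] or list of them.
#' @param mode omics mode passed to [tripletdr()].
#' @param repeats,folds,val_fraction protocol dimensions (default 5 x 5
#'   with a 20% validation slice, i.e. 64/16/20).
#' @param seed master seed; per-(repeat, fold, set) seeds are derived from
#'   it so any cell can be re-run in isolation.
#' @param selection `"per_cell"` (default) or `"overall"`.
#' @return An object of class `tripletdr_cv`: `results` (data frame with
#'   columns rep, fold, hp_set, val_auc, test_auc, selected) and
#'   `mean_test_auc`, the mean test AUC over selected cells.
#' @export
cross_validate <- function(data, hp_sets = tripletdr_hp(), mode = "all",
                           repeats = 5, folds = 5, val_fraction = 0.2,
                           seed = 1, selection = c("per_cell", "overall")) {
  selection <- match.arg(selection)
  stopifnot(inherits(data, "multiomics_dataset"))
  if (inherits(hp_sets, "tripletdr_hp")) hp_sets <- list(hp_sets)
  if (length(hp_sets) < 1) stop("at least one hyperparameter set is required")
  y <- data$labels$labels
  plan <- nested_split(length(y), y, repeats, folds, val_fraction,
                       seed = derive_seed(seed, 5))
  rows <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      cell <- plan$repeats[[r]][[f]]
      d_tr <- mo_subset(data, cell$train)
      d_va <- mo_subset(data, cell$validation)
      d_te <- mo_subset(data, cell$test)
      for (h in seq_along(hp_sets)) {
        fit <- tripletdr(d_tr, val = d_va, mode = mode, hp = hp_sets[[h]],
                         seed = derive_seed(seed, r, f, h))
        val_auc <- roc_auc(predict(fit, d_va), d_va$labels$labels)
        test_auc <- roc_auc(predict(fit, d_te), d_te$labels$labels)
        rows[[length(rows) + 1]] <- data.frame(
          rep = r, fold = f, hp_set = h, val_auc = val_auc,
          test_auc = test_auc)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$selected <- FALSE
  if (selection == "per_cell") {
    for (r in seq_len(repeats)) {
      for (f in seq_len(folds)) {
        cell_rows <- which(res$rep == r & res$fold == f)
        best <- cell_rows[which.max(res$val_auc[cell_rows])]
        res$selected[best] <- TRUE
      }
    }
  } else {
    mean_val <- tapply(res$val_auc, res$hp_set, mean)
    best_h <- as.integer(names(mean_val)[which.max(mean_val)])
    res$selected <- res$hp_set == best_h
  }
  structure(list(results = res,
                 mean_test_auc = mean(res$test_auc[res$selected]),
                 mode = mode, selection = selection, seed = seed,
                 n = length(y)),
            class = "tripletdr_cv")
}

#' @export
print.tripletdr_cv <- function(x, ...) {
  cat(sprintf(
    "tripletdr_cv [mode = %s]: %d cells, %d hyperparameter set(s)\n",
    x$mode, length(unique(paste(x$results$rep, x$results$fold))),
    length(unique(x$results$hp_set))))
  cat(sprintf("  mean test AUC over selected cells: %.3f\n",
              x$mean_test_auc))
  invisible(x)
}

#' @export
as.data.frame.tripletdr_cv <- function(x, ...) x$results

#' External validation on an independent dataset
#'
#' Splits the training panel into stratified folds; per (repeat, fold),
#' trains on the remaining folds with the held-out fold as validation, and
#' tests every fitted model on the full external dataset. The reported
#' external AUC is the mean over cells for the hyperparameter set with the
#' best mean validation AUC.
#'
#' @param train training [multiomics_dataset()].
#' @param external external [multiomics_dataset()]; its matrices must
#'   contain every mask feature selected on the training folds.
#' @param hp_sets a [tripletdr_hp()] or list of them.
#' @param repeats,folds protocol dimensions.
#' @param mode omics mode.
#' @param seed master seed.
#' @return A list of class `tripletdr_external`: `results` (per-cell data
#'   frame), `chosen_hp`, `mean_external_auc`, `mean_val_auc`.
#' @export
external_validate <- function(train, external, hp_sets = tripletdr_hp(),
                              repeats = 5, folds = 5, mode = "all",
                              seed = 1) {
  stopifnot(inherits(train, "multiomics_dataset"),
            inherits(external, "multiomics_dataset"))
  if (inherits(hp_sets, "tripletdr_hp")) hp_sets <- list(hp_sets)
  y <- train$labels$labels
  y_ext <- external$labels$labels
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < folds)) stop("a class has fewer samples than folds")
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 201, r))
    fold_of <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      d_tr <- mo_subset(train, which(fold_of != f))
      d_va <- mo_subset(train, which(fold_of == f))
      for (h in seq_along(hp_sets)) {
        fit <- tripletdr(d_tr, val = d_va, mode = mode, hp = hp_sets[[h]],
                         seed = derive_seed(seed, r, f, h))
        rows[[length(rows) + 1]] <- data.frame(
          rep = r, fold = f, hp_set = h,
          val_auc = roc_auc(predict(fit, d_va), d_va$labels$labels),
          external_auc = roc_auc(predict(fit, external), y_ext))
      }
    }
  }
  res <- do.call(rbind, rows)
  mean_val <- tapply(res$val_auc, res$hp_set, mean)
  chosen <- as.integer(names(mean_val)[which.max(mean_val)])
  sel <- res$hp_set == chosen
  structure(list(results = res, chosen_hp = chosen,
                 mean_val_auc = mean(res$val_auc[sel]),
                 mean_external_auc = mean(res$external_auc[sel])),
            class = "tripletdr_external")
}

#' @export
print.tripletdr_external <- function(x, ...) {
  cat(sprintf(
    "tripletdr_external: chosen set %d, mean external AUC %.3f\n",
    x$chosen_hp, x$mean_external_auc))
  invisible(x)
}
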