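#' Construct an omics matrix
#'
#' A samples x features numeric matrix for one omics layer, with unique sample
#' and feature identifiers and a layer tag. Mutation layers must be strictly
#' binary (0 = wild type, 1 = mutated).
#'
#' @param values numeric matrix, rows = samples, columns = features.
#' @param kind one of `"expression"`, `"mutation"`, `"cna"`.
#' @param sample_ids,feature_ids character vectors; default to the dimnames of
#'   `values`.
#' @return An object of class `omics_matrix` with elements `values`,
#'   `sample_ids`, `feature_ids`, `kind`.
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("s1", "s2", "s3"), c("g1", "g2"))), "expression")
#' dim(m)
#' @export
omics_matrix <- function(values, kind = c("expression", "mutation", "cna"),
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  kind <- match.arg(kind)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("number of sample_ids does not match row count")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("number of feature_ids does not match column count")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(feature_ids)) stop("duplicate feature IDs")
  if (anyNA(values)) stop("missing values in omics matrix")
  if (kind == "mutation" && !all(values %in% c(0, 1))) {
    stop("mutation values must be in {0, 1}")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, kind = kind),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# subset an omics_matrix by sample index/ids and/or feature ids
omics_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  omics_matrix(v, x$kind)
}

#' Construct a binary response label vector
#'
#' @param labels binary vector; 1 = sensitive, 0 = resistant. Character labels
#'   `{"S","R"}` or `{"sensitive","resistant"}` (case-insensitive) are mapped.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `label_vector` with `sample_ids` and numeric
#'   0/1 `labels`.
#' @export
label_vector <- function(labels, sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (is.character(labels) || is.factor(labels)) {
    key <- tolower(as.character(labels))
    map <- c(s = 1, sensitive = 1, "1" = 1, r = 0, resistant = 0, "0" = 0)
    if (!all(key %in% names(map))) {
      stop("labels must be in {R,S}, {resistant,sensitive} or {0,1}")
    }
    labels <- unname(map[key])
  }
  labels <- as.numeric(labels)
  if (length(labels) != length(sample_ids)) {
    stop("labels and sample_ids differ in length")
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  structure(list(sample_ids = sample_ids, labels = labels),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label_vector: %d samples (%d sensitive / %d resistant)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Construct an ln(IC50) table
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param ln_ic50 finite numeric vector of natural-log IC50 values.
#' @return An object of class `ic50_table`.
#' @export
ic50_table <- function(sample_ids, ln_ic50) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  ln_ic50 <- as.numeric(ln_ic50)
  if (length(ln_ic50) != length(sample_ids)) {
    stop("ln_ic50 and sample_ids differ in length")
  }
  if (!all(is.finite(ln_ic50))) stop("ln_ic50 values must be finite")
  structure(list(sample_ids = sample_ids, ln_ic50 = ln_ic50),
            class = "ic50_table")
}

#' Bundle co-indexed omics layers and labels for one drug
#'
#' All four components must share an identical ordered sample list; use
#' [align_samples()] to build one from unaligned inputs.
#'
#' @param expression,mutation,cna `omics_matrix` objects of matching kinds.
#' @param labels a `label_vector`.
#' @param drug_name optional drug identifier.
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(expression, mutation, cna, labels,
                               drug_name = "") {
  stopifnot(inherits(expression, "omics_matrix"),
            inherits(mutation, "omics_matrix"),
            inherits(cna, "omics_matrix"),
            inherits(labels, "label_vector"))
  if (expression$kind != "expression" || mutation$kind != "mutation" ||
      cna$kind != "cna") {
    stop("omics layers have mismatched kinds")
  }
  ids <- labels$sample_ids
  if (!identical(expression$sample_ids, ids) ||
      !identical(mutation$sample_ids, ids) ||
      !identical(cna$sample_ids, ids)) {
    stop("all components must share an identical ordered sample_id list")
  }
  structure(list(expression = expression, mutation = mutation, cna = cna,
                 labels = labels, drug_name = drug_name),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "multiomics_dataset%s: %d samples (%d sensitive / %d resistant)\n",
    if (nzchar(x$drug_name)) paste0(" [", x$drug_name, "]") else "",
    length(x$labels$labels), sum(x$labels$labels == 1),
    sum(x$labels$labels == 0)))
  cat(sprintf("  expression: %d features; mutation: %d; cna: %d\n",
              ncol(x$expression$values), ncol(x$mutation$values),
              ncol(x$cna$values)))
  invisible(x)
}

# subset a multiomics_dataset by sample index
mo_subset <- function(data, idx) {
  ids <- data$labels$sample_ids[idx]
  multiomics_dataset(
    omics_subset(data$expression, idx),
    omics_subset(data$mutation, idx),
    omics_subset(data$cna, idx),
    label_vector(data$labels$labels[idx], ids),
    data$drug_name)
}

#' Align omics layers and labels to their common samples
#'
#' Restricts all inputs to the intersection of their sample IDs, reordered to
#' a canonical lexicographic (C-collation) order so downstream fold splits are
#' reproducible regardless of input row order. Dropped IDs per layer are
#' attached as the `"dropped"` attribute.
#'
#' @inheritParams multiomics_dataset
#' @return A `multiomics_dataset` over the common samples.
#' @export
align_samples <- function(expression, mutation, cna, labels, drug_name = "") {
  sets <- list(expression = expression$sample_ids,
               mutation = mutation$sample_ids,
               cna = cna$sample_ids,
               labels = labels$sample_ids)
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("no samples shared across all inputs")
  common <- sort_c(common)
  dropped <- lapply(sets, function(s) setdiff(s, common))
  if (any(lengths(dropped) > 0)) {
    message(sprintf("align_samples: dropped %s samples per layer",
                    paste(lengths(dropped), collapse = "/")))
  }
  out <- multiomics_dataset(
    omics_subset(expression, common),
    omics_subset(mutation, common),
    omics_subset(cna, common),
    label_vector(labels$labels[match(common, labels$sample_ids)], common),
    drug_name)
  attr(out, "dropped") <- dropped
  out
}

# ---- delimited-text I/O ----

#' Read an omics matrix from a delimited table
#'
#' First column holds sample IDs and the header row feature IDs (set
#' `transpose = TRUE` for gene-by-sample files). Missing values are rejected
#' by default; `impute_zero = TRUE` zero-fills missing entries for mutation
#' layers only (absent gene = no mutation).
#'
#' @param path file path.
#' @param kind omics layer tag.
#' @param sep field delimiter; tab by default.
#' @param transpose if `TRUE`, the file is features x samples.
#' @param impute_zero zero-fill NA (mutation layers only).
#' @return An `omics_matrix`.
#' @export
read_omics_matrix <- function(path, kind = c("expression", "mutation", "cna"),
                              sep = "\t", transpose = FALSE,
                              impute_zero = FALSE) {
  kind <- match.arg(kind)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) {
      if (grepl("duplicate 'row.names'", conditionMessage(e))) {
        stop("duplicate sample IDs in ", path, call. = FALSE)
      }
      stop(e)
    })
  if (anyDuplicated(colnames(df))) stop("duplicate feature IDs in ", path)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    col <- bad[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))[1]
    stop(sprintf("non-numeric value in %s at row '%s', column '%s'",
                 path, rownames(df)[row], colnames(df)[col]))
  }
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  if (anyNA(m)) {
    if (impute_zero && kind == "mutation") {
      m[is.na(m)] <- 0
    } else {
      stop("missing values in ", path,
           " (impute_zero applies to mutation layers only)")
    }
  }
  omics_matrix(m, kind)
}

#' Write an omics matrix as a delimited table
#'
#' @param x an `omics_matrix`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_omics_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(sample_id = x$sample_ids, x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column response label table
#'
#' Columns: sample ID and response, the latter in `{R,S}`,
#' `{resistant,sensitive}` or `{0,1}`.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return A `label_vector`.
#' @export
read_labels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("label table must have two columns")
  label_vector(df[[2]], df[[1]])
}

#' Write a response label table
#'
#' @param x a `label_vector`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_labels <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "label_vector"))
  df <- data.frame(sample_id = x$sample_ids,
                   response = ifelse(x$labels == 1, "S", "R"))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ln(IC50) table
#'
#' Two columns: sample ID and ln(IC50). With `log = TRUE` the second column
#' holds raw IC50 values and the natural log is applied on load.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param log apply `log()` to the values.
#' @return An `ic50_table`.
#' @export
read_ic50 <- function(path, sep = "\t", log = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("ln(IC50) table must have two columns")
  v <- as.numeric(df[[2]])
  if (log) v <- base::log(v)
  ic50_table(df[[1]], v)
}

#' Write an ln(IC50) table
#'
#' @param x an `ic50_table`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_ic50 <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "ic50_table"))
  df <- data.frame(sample_id = x$sample_ids, ln_ic50 = x$ln_ic50)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
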