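#' Simulate a label-structured multi-omics dataset
#'
#' Generates co-indexed expression, mutation and CNA matrices plus binary
#' response labels, emulating the structure of a per-drug cell-line panel:
#' a small set of informative features carrying a class-dependent signal, a
#' large majority of low-variance noise features, and heavy class imbalance
#' (resistant samples greatly outnumber sensitive ones).
#'
#' Expression and CNA: informative features are unit-variance Gaussian with
#' the sensitive-class mean shifted by `effect_size` (in noise-sd units);
#' noise features are zero-mean Gaussian with per-feature variance drawn
#' between `noise_variance_floor` and 0.25, well below the informative
#' variance so the variance scree has a detectable knee. Mutation: Bernoulli,
#' with rate `mut_rate_informative_sensitive` on informative features in
#' sensitive samples and `mut_rate_background` elsewhere.
#'
#' Informative features occupy the first `n_informative` columns of each
#' layer and their IDs are recorded in the `"informative"` attribute, so
#' feature-selection recovery is directly assertable.
#'
#' @param n_samples number of samples.
#' @param sensitive_fraction fraction of sensitive samples, in (0,1).
#' @param n_features named counts of features per layer
#'   (expression/mutation/cna).
#' @param n_informative named counts of informative features per layer.
#' @param effect_size sensitive-class mean shift for informative
#'   expression/CNA features, in noise-sd units.
#' @param mut_rate_background background mutation probability.
#' @param mut_rate_informative_sensitive mutation probability for informative
#'   features in sensitive samples.
#' @param noise_variance_floor lower bound of the noise-feature variance.
#' @param seed integer RNG seed; the dataset is fully determined by it.
#' @param drug_name label carried on the returned dataset.
#' @return A [multiomics_dataset()] with attributes `"informative"` (list of
#'   informative feature IDs per layer) and `"config"`.
#' @examples
#' d <- simulate_dataset(n_samples = 60, seed = 7,
#'   n_features = c(expression = 50, mutation = 20, cna = 30),
#'   n_informative = c(expression = 5, mutation = 3, cna = 4))
#' d
#' @export
simulate_dataset <- function(n_samples = 400, sensitive_fraction = 0.15,
                             n_features = c(expression = 1000,
                                            mutation = 300, cna = 500),
                             n_informative = c(expression = 30,
                                               mutation = 10, cna = 20),
                             effect_size = 1.5,
                             mut_rate_background = 0.05,
                             mut_rate_informative_sensitive = 0.4,
                             noise_variance_floor = 0.01,
                             seed = 1, drug_name = "simulated_drug") {
  if (sensitive_fraction <= 0 || sensitive_fraction >= 1) {
    stop("sensitive_fraction must be in (0, 1)")
  }
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  if (length(n_features) != 3 || length(n_informative) != 3) {
    stop("n_features and n_informative must each give three counts")
  }
  if (any(n_informative > n_features)) {
    stop("n_informative cannot exceed n_features for any layer")
  }
  if (noise_variance_floor <= 0 || noise_variance_floor > 0.25) {
    stop("noise_variance_floor must be in (0, 0.25]")
  }
  n_sens <- round(n_samples * sensitive_fraction)
  if (n_sens < 1 || n_sens >= n_samples) {
    stop("configuration yields zero samples of one class")
  }
  set.seed(as.integer(seed))
  ids <- sprintf("S%04d", seq_len(n_samples))
  y <- numeric(n_samples)
  y[sample(n_samples, n_sens)] <- 1

  gauss_layer <- function(m, k, prefix) {
    vals <- matrix(0, n_samples, m)
    if (k > 0) {
      vals[, seq_len(k)] <- stats::rnorm(n_samples * k) +
        effect_size * y
    }
    if (m > k) {
      nn <- m - k
      sds <- sqrt(stats::runif(nn, noise_variance_floor, 0.25))
      vals[, k + seq_len(nn)] <-
        matrix(stats::rnorm(n_samples * nn), n_samples, nn) *
        rep(sds, each = n_samples)
    }
    colnames(vals) <- c(if (k > 0) sprintf("%s_inf_%03d", prefix, seq_len(k)),
                        if (m > k) sprintf("%s_noise_%03d", prefix,
                                           seq_len(m - k)))
    rownames(vals) <- ids
    vals
  }

  expr <- gauss_layer(n_features[1], n_informative[1], "EXP")
  cna <- gauss_layer(n_features[3], n_informative[3], "CNA")

  m_feat <- n_features[2]
  m_inf <- n_informative[2]
  rates <- matrix(mut_rate_background, n_samples, m_feat)
  if (m_inf > 0) rates[y == 1, seq_len(m_inf)] <- mut_rate_informative_sensitive
  mut <- matrix(as.numeric(stats::runif(n_samples * m_feat) < rates),
                n_samples, m_feat)
  colnames(mut) <- c(if (m_inf > 0) sprintf("MUT_inf_%03d", seq_len(m_inf)),
                     if (m_feat > m_inf) sprintf("MUT_noise_%03d",
                                                 seq_len(m_feat - m_inf)))
  rownames(mut) <- ids

  out <- multiomics_dataset(
    omics_matrix(expr, "expression"),
    omics_matrix(mut, "mutation"),
    omics_matrix(cna, "cna"),
    label_vector(y, ids),
    drug_name)
  attr(out, "informative") <- list(
    expression = colnames(expr)[seq_len(n_informative[1])],
    mutation = colnames(mut)[seq_len(n_informative[2])],
    cna = colnames(cna)[seq_len(n_informative[3])])
  attr(out, "config") <- list(
    n_samples = n_samples, sensitive_fraction = sensitive_fraction,
    n_features = n_features, n_informative = n_informative,
    effect_size = effect_size, mut_rate_background = mut_rate_background,
    mut_rate_informative_sensitive = mut_rate_informative_sensitive,
    noise_variance_floor = noise_variance_floor, seed = seed)
  out
}

#' Simulate bimodal ln(IC50) values
#'
#' Draws from a two-component normal mixture, emulating the bimodal ln(IC50)
#' distribution of a drug with distinct sensitive and resistant
#' subpopulations. Component membership is recorded in the `"component"`
#' attribute (1 or 2, by position in `modes`).
#'
#' @param n number of cell lines.
#' @param modes list of two `(mean, sd, weight)` triples; weights must sum
#'   to 1 and sds be positive.
#' @param seed integer RNG seed.
#' @return An [ic50_table()] with attribute `"component"`.
#' @examples
#' tab <- simulate_ic50(100, seed = 3)
#' table(attr(tab, "component"))
#' @export
simulate_ic50 <- function(n,
                          modes = list(c(mean = -3, sd = 0.5, weight = 0.2),
                                       c(mean = 1, sd = 0.5, weight = 0.8)),
                          seed = 1) {
  if (length(modes) != 2) stop("exactly two mixture components are required")
  pars <- do.call(rbind, lapply(modes, function(m) as.numeric(m[1:3])))
  if (any(pars[, 2] <= 0)) stop("component sd must be positive")
  if (abs(sum(pars[, 3]) - 1) > 1e-8) stop("component weights must sum to 1")
  set.seed(as.integer(seed))
  comp <- 1 + as.integer(stats::runif(n) >= pars[1, 3])
  vals <- stats::rnorm(n, mean = pars[comp, 1], sd = pars[comp, 2])
  out <- ic50_table(sprintf("C%04d", seq_len(n)), vals)
  attr(out, "component") <- comp
  out
}
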