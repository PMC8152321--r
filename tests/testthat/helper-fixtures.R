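# shared fixtures and independent oracles, built in code at test time

tiny_matrix <- function(kind = "expression", n = 3, m = 2, seed = 1) {
  set.seed(seed)
  vals <- matrix(round(rnorm(n * m), 3), n, m,
                 dimnames = list(sprintf("s%d", seq_len(n)),
                                 sprintf("g%d", seq_len(m))))
  if (kind == "mutation") vals[] <- rbinom(n * m, 1, 0.3)
  omics_matrix(vals, kind)
}

# small simulated dataset reused across tests (cached per seed)
small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 1, n = 160, effect_size = 1.5) {
  key <- paste(seed, n, effect_size)
  if (is.null(small_sim_cache[[key]])) {
    small_sim_cache[[key]] <- simulate_dataset(
      n_samples = n, sensitive_fraction = 0.2,
      n_features = c(expression = 120, mutation = 60, cna = 80),
      n_informative = c(expression = 10, mutation = 5, cna = 8),
      effect_size = effect_size, seed = seed)
  }
  small_sim_cache[[key]]
}

# hyperparameters scaled down for unit-test speed; ... overrides defaults
fast_hp <- function(...) {
  args <- list(dim_expression = 16, dim_cna = 8, dim_mutation = 4,
               epochs_encoder = 15, patience_encoder = 15,
               epochs_classifier = 40, patience_classifier = 40)
  over <- list(...)
  args[names(over)] <- over
  do.call(tripletdr_hp, args)
}

# O(n^2) Mann-Whitney AUC oracle: explicit pairwise count, ties half credit
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive three-nested-loop triplet loss oracle
triplet_loss_oracle <- function(z, labels, margin) {
  n <- nrow(z)
  d <- function(i, j) sqrt(sum((z[i, ] - z[j, ])^2))
  total <- 0
  count <- 0
  for (a in seq_len(n)) {
    for (p in seq_len(n)) {
      if (p == a || labels[p] != labels[a]) next
      for (ng in seq_len(n)) {
        if (labels[ng] == labels[a]) next
        total <- total + max(d(a, p) - d(a, ng) + margin, 0)
        count <- count + 1
      }
    }
  }
  if (count == 0) return(NA_real_)
  total / count
}

# brute-force elbow oracle: explicit point-to-line geometry on the scaled
# scree, independent of the implementation's closed-form distance
elbow_oracle <- function(variances) {
  v <- sort(variances, decreasing = TRUE)
  n <- length(v)
  pts <- cbind((seq_len(n) - 1) / (n - 1), (v - v[n]) / (v[1] - v[n]))
  a <- pts[1, ]
  b <- pts[n, ]
  ab <- b - a
  dists <- vapply(seq_len(n), function(i) {
    ap <- pts[i, ] - a
    proj <- a + sum(ap * ab) / sum(ab * ab) * ab
    sqrt(sum((pts[i, ] - proj)^2))
  }, numeric(1))
  v[which.max(dists) - 1]
}

# mean inter-class / mean intra-class pairwise embedding distance
class_distance_ratio <- function(z, labels) {
  dm <- as.matrix(dist(z))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(dm[!same & !is.na(same)]) / mean(dm[same & !is.na(same)])
}
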