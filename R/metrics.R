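#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' (sensitive) sample outscores a randomly chosen negative one, with ties
#' given half credit. Exact and threshold-free; invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric score vector (higher = more likely sensitive).
#' @param labels binary vector; 1 = positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes are required")
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
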