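# internal helpers shared across modules

# Deterministic seed derivation: a master seed plus integer tags hashed into
# [0, 2^31 - 2], so any stage of a run can be re-executed in isolation.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (p in parts) {
    h <- (h * 31 + abs(p) + 17) %% 2147483629
  }
  as.integer(h)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

# Adam optimiser state for a single parameter array; weight decay is added to
# the gradient by the caller (L2 regularisation).
adam_init <- function(dim) {
  list(m = array(0, dim), v = array(0, dim), t = 0L)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * m_hat / (sqrt(v_hat) + eps)
  state
}

# Coerce labels to a plain 0/1 numeric vector.
as_binary_labels <- function(labels) {
  if (inherits(labels, "label_vector")) labels <- labels$labels
  labels <- as.numeric(labels)
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary (0 = resistant, 1 = sensitive)")
  }
  labels
}

# Coerce an omics_matrix or plain matrix to a numeric matrix.
as_values <- function(x) {
  if (inherits(x, "omics_matrix")) return(x$values)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  x
}

# Locale-independent lexicographic sort (C collation) so sample orderings are
# reproducible across systems.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
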