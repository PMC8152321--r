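#' Binarization configuration
#'
#' Settings for converting continuous ln(IC50) values into binary
#' sensitive/resistant labels: each cell line's value is resampled from a
#' normal distribution, the pooled draws are smoothed by Gaussian kernel
#' density estimation, and a threshold is read off the density (minimum
#' between the two main modes).
#'
#' @param draws_per_sample normal draws per cell line.
#' @param interval spread of the per-cell-line resampling normal. By default
#'   it is used directly as the standard deviation
#'   (`interval_is_sd = TRUE`); the alternative reading — a 95% confidence
#'   interval of that width, i.e. `sd = interval / 3.92` — is available with
#'   `interval_is_sd = FALSE`.
#' @param kde_bandwidth Gaussian kernel bandwidth (sd) for the density.
#' @param grid_points number of equally spaced density evaluation points.
#' @param interval_is_sd see `interval`.
#' @param seed integer seed for the resampling draws.
#' @return An object of class `binarization_config`.
#' @export
binarization_config <- function(draws_per_sample = 100, interval = 0.5,
                                kde_bandwidth = 0.5, grid_points = 512,
                                interval_is_sd = TRUE, seed = 1) {
  if (draws_per_sample < 1 || interval <= 0 || kde_bandwidth <= 0 ||
      grid_points < 8) {
    stop("all binarization parameters must be positive")
  }
  structure(list(draws_per_sample = as.integer(draws_per_sample),
                 interval = interval, kde_bandwidth = kde_bandwidth,
                 grid_points = as.integer(grid_points),
                 interval_is_sd = isTRUE(interval_is_sd),
                 seed = as.integer(seed)),
            class = "binarization_config")
}

#' Resample ln(IC50) values per cell line
#'
#' Draws `draws_per_sample` values from `Normal(ln_ic50_i, sigma)` for each
#' cell line and pools them, giving `draws_per_sample * n` values whose
#' distribution is then density-estimated.
#'
#' @param ic50 an [ic50_table()].
#' @param cfg a [binarization_config()].
#' @return Numeric vector of pooled draws.
#' @export
resample_ic50 <- function(ic50, cfg = binarization_config()) {
  stopifnot(inherits(ic50, "ic50_table"),
            inherits(cfg, "binarization_config"))
  sigma <- if (cfg$interval_is_sd) cfg$interval else cfg$interval / 3.92
  set.seed(cfg$seed)
  d <- cfg$draws_per_sample
  stats::rnorm(length(ic50$ln_ic50) * d,
               mean = rep(ic50$ln_ic50, each = d), sd = sigma)
}

#' Gaussian kernel density on a fixed grid
#'
#' Fixed-bandwidth Gaussian KDE evaluated on `grid_points` equally spaced
#' points spanning `[min - 3 bw, max + 3 bw]`; the trapezoidal integral over
#' the grid is within 1e-2 of 1.
#'
#' @param pool numeric vector (nonempty).
#' @param cfg a [binarization_config()].
#' @return A data frame with columns `x` and `density`.
#' @export
kde_density <- function(pool, cfg = binarization_config()) {
  stopifnot(inherits(cfg, "binarization_config"))
  if (length(pool) == 0) stop("empty pool")
  bw <- cfg$kde_bandwidth
  dens <- stats::density(pool, bw = bw, kernel = "gaussian",
                         n = cfg$grid_points,
                         from = min(pool) - 3 * bw, to = max(pool) + 3 * bw)
  data.frame(x = dens$x, density = dens$y)
}

#' Threshold between the two main density modes
#'
#' Locates local maxima of the density grid. With two or more modes, the
#' threshold is the grid point of minimum density strictly between the two
#' highest modes. A unimodal density falls back to `mean - sd` of the pooled
#' values (their grid-moment estimate when no pool is supplied), placing the
#' sensitive boundary in the low-IC50 tail.
#'
#' @param grid a data frame from [kde_density()].
#' @param pool optional pooled values the grid was estimated from, used for
#'   the unimodal fallback moments.
#' @return List with `threshold`, `modes` (x positions of local maxima,
#'   highest first) and `unimodal` flag.
#' @export
find_threshold <- function(grid, pool = NULL) {
  x <- grid$x
  f <- grid$density
  n <- length(f)
  if (n < 3) stop("density grid too short")
  if (diff(range(f)) == 0) stop("degenerate density: flat grid")
  interior <- 2:(n - 1)
  is_max <- f[interior] > f[interior - 1] & f[interior] >= f[interior + 1]
  modes_idx <- interior[is_max]
  modes_idx <- modes_idx[order(f[modes_idx], decreasing = TRUE)]
  if (length(modes_idx) >= 2) {
    top2 <- sort(modes_idx[1:2])
    between <- (top2[1] + 1):(top2[2] - 1)
    thr <- x[between[which.min(f[between])]]
    list(threshold = thr, modes = x[modes_idx], unimodal = FALSE)
  } else {
    if (!is.null(pool)) {
      mu <- mean(pool)
      sdv <- stats::sd(pool)
    } else {
      # moments of the estimated density via trapezoidal integration
      dx <- diff(x)
      w <- c(dx / 2, 0) + c(0, dx / 2)
      mu <- sum(w * f * x) / sum(w * f)
      sdv <- sqrt(sum(w * f * (x - mu)^2) / sum(w * f))
    }
    list(threshold = mu - sdv, modes = x[modes_idx], unimodal = TRUE)
  }
}

#' Binarize ln(IC50) values into sensitive/resistant labels
#'
#' Full pipeline: per-cell-line normal resampling ([resample_ic50()]),
#' pooled Gaussian KDE ([kde_density()]), threshold extraction
#' ([find_threshold()]), then labeling — cell lines with ln(IC50) strictly
#' below the threshold are sensitive (respond at low concentration), the
#' rest resistant.
#'
#' @param ic50 an [ic50_table()].
#' @param cfg a [binarization_config()].
#' @return An object of class `ic50_binarization`: `threshold`, `labels`
#'   (a [label_vector()]), `density` (the audit grid), `modes`, `unimodal`,
#'   `config`.
#' @examples
#' tab <- simulate_ic50(200, seed = 5)
#' b <- binarize(tab)
#' b$threshold
#' @export
binarize <- function(ic50, cfg = binarization_config()) {
  stopifnot(inherits(ic50, "ic50_table"))
  if (length(unique(ic50$ln_ic50)) == 1) {
    stop("degenerate density: all ln(IC50) values identical")
  }
  pool <- resample_ic50(ic50, cfg)
  grid <- kde_density(pool, cfg)
  thr <- find_threshold(grid, pool)
  labels <- label_vector(as.numeric(ic50$ln_ic50 < thr$threshold),
                         ic50$sample_ids)
  structure(list(threshold = thr$threshold, labels = labels,
                 density = grid, modes = thr$modes,
                 unimodal = thr$unimodal, config = cfg),
            class = "ic50_binarization")
}

#' @export
print.ic50_binarization <- function(x, ...) {
  cat(sprintf(
    "ic50_binarization: threshold %.3f (%s); %d sensitive / %d resistant\n",
    x$threshold, if (x$unimodal) "unimodal fallback" else "between modes",
    sum(x$labels$labels == 1), sum(x$labels$labels == 0)))
  invisible(x)
}
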