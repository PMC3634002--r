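#' Normal-scale thresholds of an ordinal item
#'
#' Under the latent-response model, the threshold after category j is
#' `qnorm(cumulative proportion through j)`. Categories observed empty at
#' the extremes (so the threshold would sit at +-Inf) are merged into
#' their neighbour with a warning.
#'
#' @param x Integer/factor vector of ordinal responses, or a named table
#'   of category counts.
#' @param levels Optional full category set (so interior empty categories
#'   are kept at zero count).
#' @return Numeric vector of K-1 strictly increasing thresholds; the
#'   observed category proportions are attached as attribute `proportions`.
#' @export
#' @examples
#' estimate_thresholds(rep(1:3, c(50, 30, 20)))  # 0 and qnorm(0.8)
estimate_thresholds <- function(x, levels = NULL) {
  counts <- if (is.table(x) || (is.numeric(x) && !is.null(names(x)))) {
    as.numeric(x)
  } else {
    if (is.null(levels)) {
      levels <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
    }
    as.numeric(table(factor(x, levels = levels)))
  }
  if (length(counts) < 2) {
    abort("Need at least 2 observed categories.",
          class = "drmwell_validation_error")
  }
  while (length(counts) > 2 && counts[1] == 0) {
    warn("Empty lowest category merged into its neighbour.")
    counts <- counts[-1]
  }
  while (length(counts) > 2 && counts[length(counts)] == 0) {
    warn("Empty highest category merged into its neighbour.")
    counts <- counts[-length(counts)]
  }
  p <- counts / sum(counts)
  th <- qnorm(cumsum(p)[-length(p)])
  if (any(!is.finite(th)) || any(diff(th) <= 0)) {
    abort("Degenerate category distribution; thresholds not increasing.",
          class = "drmwell_validation_error")
  }
  attr(th, "proportions") <- p
  th
}

# Bivariate standard-normal CDF P(X <= a, Y <= b) by Gauss-Legendre
# quadrature of phi(x) * Phi((b - rho x)/sqrt(1 - rho^2)) over (-8, a].
# Vectorized over (a, b) pairs; |rho| < 1.
pbvnorm <- function(a, b, rho, n_nodes = 48) {
  stopifnot(length(a) == length(b))
  out <- numeric(length(a))
  s <- sqrt(1 - rho^2)
  fin <- is.finite(a) & is.finite(b)
  out[!fin] <- ifelse(is.infinite(a[!fin]) & a[!fin] > 0, pnorm(b[!fin]),
               ifelse(is.infinite(b[!fin]) & b[!fin] > 0, pnorm(a[!fin]), 0))
  both_inf <- is.infinite(a) & a > 0 & is.infinite(b) & b > 0
  out[both_inf] <- 1
  if (any(fin)) {
    af <- pmin(pmax(a[fin], -8), 8)
    bf <- b[fin]
    gl <- pracma::gaussLegendre(n_nodes, 0, 1)
    out[fin] <- purrr::map2_dbl(af, bf, function(ai, bi) {
      lo <- -8
      x <- lo + (ai - lo) * gl$x
      w <- (ai - lo) * gl$w
      sum(w * dnorm(x) * pnorm((bi - rho * x) / s))
    })
  }
  pmin(pmax(out, 0), 1)
}

# Cell probabilities of the discretized bivariate normal given the two
# threshold vectors; returns a (K1 x K2) matrix.
bvn_cell_probs <- function(tx, ty, rho) {
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  grid <- expand.grid(a = ax, b = ay)
  Fg <- matrix(pbvnorm(grid$a, grid$b, rho), nrow = length(ax))
  k1 <- length(tx) + 1
  k2 <- length(ty) + 1
  P <- Fg[2:(k1 + 1), 2:(k2 + 1), drop = FALSE] -
    Fg[1:k1, 2:(k2 + 1), drop = FALSE] -
    Fg[2:(k1 + 1), 1:k2, drop = FALSE] +
    Fg[1:k1, 1:k2, drop = FALSE]
  pmax(P, 1e-12)
}

#' Polychoric correlation of two ordinal items
#'
#' Two-step estimator: the thresholds are fixed at their univariate
#' estimates ([estimate_thresholds()] on the margins), then the latent
#' bivariate-normal correlation maximizes the multinomial likelihood of
#' the contingency table over `(-0.999, 0.999)` by bounded 1-D
#' optimization. Empty cells contribute nothing to the likelihood (their
#' model probabilities are floored at 1e-12 for numerical safety), so a
#' perfectly concordant table drives the estimate to the bound; estimates
#' pinned there are flagged `saturated`.
#'
#' @param x,y Ordinal vectors, or `x` a 2-way contingency `table` (then
#'   `y` is ignored).
#' @return Single numeric estimate with attributes `thresholds` (list) and
#'   `saturated` (logical).
#' @export
#' @examples
#' x <- rep(1:2, each = 50); y <- rep(1:2, times = 50)
#' polychoric_correlation(table(x, y))
polychoric_correlation <- function(x, y = NULL) {
  tab <- if (is.table(x) || is.matrix(x)) as.matrix(x) else {
    ok <- !is.na(x) & !is.na(y)
    table(x[ok], y[ok])
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("Both items need at least 2 observed categories.",
          class = "drmwell_validation_error")
  }
  tab <- as.matrix(tab)
  tx <- estimate_thresholds(as.table(rowSums(tab)))
  ty <- estimate_thresholds(as.table(colSums(tab)))

  nll <- function(rho) -sum(tab * log(bvn_cell_probs(tx, ty, rho)))
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  est <- opt$minimum
  saturated <- abs(est) > 0.998
  if (saturated) est <- sign(est) * 0.999
  structure(est, thresholds = list(tx, ty), saturated = saturated)
}

#' Polychoric correlation matrix of the seven affect items
#'
#' Pairwise two-step polychoric correlations over complete episodes,
#' with per-item thresholds and the pooled episode count.
#'
#' @param items Data frame / tibble whose columns are the seven affect
#'   items (extra columns ignored), one row per episode.
#' @return A `drm_polychoric`: list with `rho` (7x7 matrix), `thresholds`
#'   (named list), `n` (complete episodes used).
#' @export
polychoric_matrix <- function(items) {
  items <- as_tibble(items)
  cols <- intersect(DRM_ITEMS, names(items))
  if (length(cols) < 2) {
    abort("Need at least two affect item columns.",
          class = "drmwell_schema_error")
  }
  m <- items[cols]
  m <- m[stats::complete.cases(m), ]
  n <- nrow(m)
  p <- length(cols)
  rho <- diag(1, p)
  dimnames(rho) <- list(cols, cols)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- polychoric_correlation(m[[i]], m[[j]])
      rho[i, j] <- rho[j, i] <- as.numeric(r)
    }
  }
  ths <- setNames(lapply(m, estimate_thresholds), cols)
  structure(list(rho = rho, thresholds = ths, n = n),
            class = "drm_polychoric")
}

#' @export
print.drm_polychoric <- function(x, ...) {
  cat(sprintf("<drm_polychoric> %d items, n = %d episodes\n",
              nrow(x$rho), x$n))
  print(round(x$rho, 3))
  invisible(x)
}
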