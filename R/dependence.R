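# Stochastic-dependence analysis between methylation density changes and
# expression changes: Spearman rank correlation, rank pseudo-observations,
# maximum-likelihood fit of the Farlie-Gumbel-Morgenstern copula, and a
# Gaussian product-kernel 2D density estimate.

#' Spearman's rank correlation with a permutation or t-approximation p
#'
#' Rho is the Pearson correlation of average ranks. For n > 30 the p-value
#' uses the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`; for
#' n <= 30 a permutation p is computed -- exhaustive over all n!
#' permutations when n <= 8, Monte Carlo otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param n_perm Monte Carlo permutations for 8 < n <= 30.
#' @param seed Integer seed for the Monte Carlo branch.
#' @return A list with `rho` and `p` (two-sided).
#' @export
spearman_rho <- function(x, y, n_perm = 10000, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector; Spearman rho undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 30) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else if (n <= 8) {
    perms <- permutations_of(n)
    stats_all <- apply(perms, 1, function(pr) stats::cor(rx, ry[pr]))
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
  } else {
    set.seed(seed)
    stats_mc <- vapply(seq_len(n_perm), function(i) {
      stats::cor(rx, sample(ry))
    }, 0)
    p <- (sum(abs(stats_mc) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
  }
  list(rho = rho, p = min(p, 1))
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 only
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Rank pseudo-observations
#'
#' `u_i = rank(x_i) / (n + 1)` with average ranks for ties; values lie
#' strictly inside (0, 1) and are invariant under strictly monotone
#' transforms of `x`.
#'
#' @param x Numeric vector, n >= 1.
#' @return Numeric vector in (0, 1).
#' @export
pseudo_observations <- function(x) {
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Maximum-likelihood fit of the FGM copula
#'
#' Maximizes `sum log(1 + theta (1 - 2u)(1 - 2v))` over theta in \[-1, 1\]
#' (the log-likelihood is concave in theta). The implied Kendall tau is
#' `2 theta / 9` and the implied Spearman rho is `theta / 3`. Solutions on
#' the boundary of the valid range are flagged.
#'
#' @param u,v Paired pseudo-observations in (0, 1).
#' @return A list of class `copula_fit`: `theta`, `loglik`, `tau_implied`,
#'   `rho_s_implied`, `n`, `boundary`.
#' @export
fgm_fit <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 4)
  if (any(u <= 0 | u >= 1 | v <= 0 | v >= 1)) {
    stop("pseudo-observations must lie strictly in (0, 1)")
  }
  a <- (1 - 2 * u) * (1 - 2 * v)
  loglik <- function(theta) sum(log1p(theta * a))
  opt <- stats::optimize(loglik, interval = c(-1, 1), maximum = TRUE,
                         tol = 1e-8)
  theta <- opt$maximum
  ll <- opt$objective
  if (!is.finite(ll)) stop("non-finite FGM log-likelihood")
  # optimize() never returns the exact endpoints; snap if the likelihood
  # keeps increasing there
  for (b in c(-1, 1)) {
    if (is.finite(loglik(b)) && loglik(b) > ll) {
      theta <- b
      ll <- loglik(b)
    }
  }
  structure(list(theta = theta, loglik = ll,
                 tau_implied = 2 * theta / 9,
                 rho_s_implied = theta / 3,
                 n = length(u),
                 boundary = abs(theta) > 0.999),
            class = "copula_fit")
}

#' @export
print.copula_fit <- function(x, ...) {
  cat(sprintf(paste0("<copula_fit> FGM theta %.3f (loglik %.2f, n %d); ",
                     "implied tau %.3f, rho_S %.3f%s\n"),
              x$theta, x$loglik, x$n, x$tau_implied, x$rho_s_implied,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Gaussian product-kernel 2D density estimate (Scott's rule)
#'
#' Evaluates the kernel density on an `n_grid x n_grid` grid extending 3
#' bandwidths beyond the data range, with per-dimension bandwidth
#' `sd * n^(-1/6)` (Scott's rule for d = 2). The returned surface
#' integrates to ~1 over the grid.
#'
#' @param x,y Paired numeric vectors, n >= 10.
#' @param n_grid Grid points per axis (default 50).
#' @return A list with `x`, `y` (grid axes), `z` (density matrix),
#'   `h` (bandwidths), and `total_mass` (grid integral).
#' @export
kde2d_scott <- function(x, y, n_grid = 50) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate (zero-variance) marginal")
  hx <- sx * n^(-1 / 6)
  hy <- sy * n^(-1 / 6)
  gx <- seq(min(x) - 3 * hx, max(x) + 3 * hx, length.out = n_grid)
  gy <- seq(min(y) - 3 * hy, max(y) + 3 * hy, length.out = n_grid)
  kx <- outer(gx, x, function(a, b) stats::dnorm(a - b, sd = hx))
  ky <- outer(gy, y, function(a, b) stats::dnorm(a - b, sd = hy))
  z <- kx %*% t(ky) / n
  mass <- sum(z) * diff(gx[1:2]) * diff(gy[1:2])
  list(x = gx, y = gy, z = z, h = c(hx, hy), total_mass = mass)
}

#' Dependence analysis of methylation density change versus |log2FC|
#'
#' For one density metric, computes Spearman's rho, the FGM copula fit on
#' rank pseudo-observations, and the 2D-KDE surface.
#'
#' @param delta_density Per-gene absolute methylation density change.
#' @param abs_log2fc Per-gene |log2 fold change| (same order).
#' @return A list with `spearman`, `fgm`, `kde`.
#' @export
dependence_analysis <- function(delta_density, abs_log2fc) {
  u <- pseudo_observations(delta_density)
  v <- pseudo_observations(abs_log2fc)
  list(spearman = spearman_rho(delta_density, abs_log2fc),
       fgm = fgm_fit(u, v),
       kde = kde2d_scott(delta_density, abs_log2fc))
}
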