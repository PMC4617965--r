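# Two-replicate irreproducible discovery rate (IDR).
#
# Gaussian copula mixture on rank-transformed replicate scores: a noise
# component (independent standard bivariate normal) and a reproducible
# component (means (mu, mu), common sd sigma, correlation rho), mixing
# proportion pi1 for the reproducible part. Fitting is by pseudo-likelihood
# EM: scores are reduced to ranks, mapped to uniforms u = rank/(n+1), and at
# each iteration converted to pseudo-normal values through the inverse of
# the current mixture marginal CDF, after which one EM step updates
# (pi1, mu, sigma, rho). The local IDR of a feature is the posterior
# probability of the noise component; the global IDR at rank r is the mean
# local IDR of the top r features.

# mixture marginal CDF and a grid-based inverse
.g_cdf <- function(x, pi1, mu, sigma) {
  (1 - pi1) * stats::pnorm(x) + pi1 * stats::pnorm((x - mu) / sigma)
}

.g_inv <- function(u, pi1, mu, sigma) {
  lo <- min(stats::qnorm(min(u)), (mu + sigma * stats::qnorm(min(u)))) - 1
  hi <- max(stats::qnorm(max(u)), (mu + sigma * stats::qnorm(max(u)))) + 1
  grid <- seq(lo, hi, length.out = 8192L)
  gv <- .g_cdf(grid, pi1, mu, sigma)
  # strictly increasing; invert by interpolation
  stats::approx(gv, grid, xout = u, rule = 2)$y
}

# log bivariate normal density, equal means/sds, correlation rho
.dbvn <- function(x, y, mu, sigma, rho) {
  zx <- (x - mu) / sigma; zy <- (y - mu) / sigma
  -log(2 * pi) - 2 * log(sigma) - 0.5 * log(1 - rho^2) -
    (zx^2 - 2 * rho * zx * zy + zy^2) / (2 * (1 - rho^2))
}

#' Fit the two-replicate IDR copula mixture
#'
#' @param p1,p2 per-feature p-values (or any scores after `score_transform`)
#'   from the two biological replicates, same feature order.
#' @param scores if `TRUE` (default `FALSE`), `p1`/`p2` are already
#'   "larger = stronger" scores; otherwise they are p-values and the score
#'   is `-log(p)`.
#' @param init initial parameters `c(pi1, mu, sigma, rho)`,
#'   default `c(0.5, 1, 1, 0.5)`.
#' @param tol convergence threshold on the max absolute parameter change,
#'   default 1e-6.
#' @param max_iter maximum EM iterations, default 500.
#' @return object of class `idr_fit`: `local_idr`, `global_idr` (per input
#'   feature), parameters `pi1`, `mu`, `sigma`, `rho`, `converged`,
#'   `n_iter`.
#' @export
fit_idr <- function(p1, p2, scores = FALSE, init = c(0.5, 1, 1, 0.5),
                    tol = 1e-6, max_iter = 500L) {
  .assert(length(p1) == length(p2), "replicate score vectors differ in length")
  n <- length(p1)
  .assert(n >= 10L, "too few features for IDR fitting")
  x <- if (scores) p1 else -log(pmax(p1, .P_FLOOR))
  y <- if (scores) p2 else -log(pmax(p2, .P_FLOOR))
  .assert(length(unique(x)) > 1L && length(unique(y)) > 1L,
          "degenerate input: all scores tied in a replicate")
  # rank transform, average ties
  u <- rank(x, ties.method = "average") / (n + 1)
  v <- rank(y, ties.method = "average") / (n + 1)

  pi1 <- init[1L]; mu <- init[2L]; sigma <- init[3L]; rho <- init[4L]
  converged <- FALSE; it <- 0L
  gamma <- rep(pi1, n)
  while (it < max_iter) {
    it <- it + 1L
    # pseudo-data refreshed from the current marginal every step
    z1 <- .g_inv(u, pi1, mu, sigma)
    z2 <- .g_inv(v, pi1, mu, sigma)
    # E-step
    l1 <- .dbvn(z1, z2, mu, sigma, rho) + log(pi1)
    l0 <- stats::dnorm(z1, log = TRUE) + stats::dnorm(z2, log = TRUE) +
      log(1 - pi1)
    m <- pmax(l1, l0)
    gamma <- exp(l1 - m) / (exp(l1 - m) + exp(l0 - m))
    # M-step (weighted MLE of the constrained bivariate normal)
    sw <- sum(gamma)
    pi1_new <- sw / n
    mu_new <- sum(gamma * (z1 + z2)) / (2 * sw)
    ss <- sum(gamma * ((z1 - mu_new)^2 + (z2 - mu_new)^2)) / (2 * sw)
    sigma_new <- sqrt(pmax(ss, 1e-6))
    rho_new <- sum(gamma * (z1 - mu_new) * (z2 - mu_new)) /
      (sw * sigma_new^2)
    rho_new <- max(min(rho_new, 0.999), -0.999)
    pi1_new <- max(min(pi1_new, 0.999), 1e-3)
    delta <- max(abs(c(pi1_new - pi1, mu_new - mu, sigma_new - sigma,
                       rho_new - rho)))
    pi1 <- pi1_new; mu <- mu_new; sigma <- sigma_new; rho <- rho_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # the pseudo-likelihood fixed point converges linearly; hitting the strict
  # tol within the iteration budget is not guaranteed, so non-convergence is
  # reported as a flag (and a message), never an error
  if (!converged)
    message(sprintf("fit_idr: EM stopped after %d iterations (last delta %.2g)",
                    it, delta))
  local_idr <- 1 - gamma
  # global IDR: running mean of local IDR down the ranked list
  o <- order(local_idr)
  global_sorted <- cumsum(local_idr[o]) / seq_len(n)
  global_idr <- numeric(n)
  global_idr[o] <- global_sorted
  structure(list(local_idr = local_idr, global_idr = global_idr,
                 pi1 = pi1, mu = mu, sigma = sigma, rho = rho,
                 converged = converged, n_iter = it),
            class = "idr_fit")
}

#' @export
print.idr_fit <- function(x, ...) {
  cat(sprintf(paste0("<idr_fit> n=%d  pi1=%.3f mu=%.3f sigma=%.3f ",
                     "rho=%.3f  (%s, %d iter)\n"),
              length(x$local_idr), x$pi1, x$mu, x$sigma, x$rho,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
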