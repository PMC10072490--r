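#' @keywords internal
"_PACKAGE"

## Deterministic rounding used for fractional molecule counts: round half
## away from zero, so e.g. 50.5 -> 51 and -0.5 -> -1 (counts here are >= 0).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Gauss-Legendre nodes and weights on an interval
#'
#' Computes an n-point Gauss-Legendre quadrature rule via the
#' Golub-Welsch eigenvalue method, rescaled to `[a, b]`.
#'
#' @param n number of nodes (>= 1).
#' @param a,b interval endpoints (default `[0, 1]`).
#' @return list with numeric vectors `nodes` and `weights`.
#' @keywords internal
gauss_legendre <- function(n, a = 0, b = 1) {
  stopifnot(n >= 1)
  if (n == 1) {
    x <- 0
    w <- 2
  } else {
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta
    J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    x <- x[o]
    w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Gauss-Jacobi rule for a Beta-weighted integral on [0, 1]
#'
#' Nodes and weights such that `sum(w_i g(u_i))` equals
#' `E[g(U)]` for `U ~ Beta(alpha, beta)`, exactly for polynomial `g` of
#' degree `<= 2n - 1`. Built by the Golub-Welsch method from the Jacobi
#' recurrence coefficients; handles shape parameters below 1 (integrable
#' endpoint singularities of the density), where an unweighted rule
#' against `dbeta` degrades badly.
#'
#' @param n number of nodes.
#' @param alpha,beta Beta shape parameters (> 0).
#' @return list with `nodes` in (0, 1) and `weights` summing to 1.
#' @keywords internal
gauss_jacobi_beta <- function(n, alpha, beta) {
  stopifnot(n >= 1, alpha > 0, beta > 0)
  ## Jacobi weight (1-x)^a (1+x)^b on [-1, 1] with a = beta-1, b = alpha-1
  a <- beta - 1
  b <- alpha - 1
  ab <- a + b
  k <- seq_len(n - 1)
  diag0 <- c((b - a) / (ab + 2),
             if (n > 1) (b^2 - a^2) / ((2 * k + ab) * (2 * k + ab + 2)) else NULL)
  offd2 <- if (n > 1) {
    v <- 4 * k * (k + a) * (k + b) * (k + ab) /
      ((2 * k + ab)^2 * (2 * k + ab + 1) * (2 * k + ab - 1))
    if (ab == 0) v[1] <- 4 * (1 + a) * (1 + b) / ((2 + ab)^2 * (3 + ab))
    v
  } else numeric(0)
  ## k = 1 must use the dedicated formula (the general one is 0/0-prone)
  if (n > 1)
    offd2[1] <- 4 * (1 + a) * (1 + b) / ((ab + 2)^2 * (ab + 3))
  J <- diag(diag0, n, n)
  if (n > 1) {
    od <- sqrt(offd2)
    J[cbind(k, k + 1)] <- od
    J[cbind(k + 1, k)] <- od
  }
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2
  o <- order(x)
  ## map [-1, 1] -> [0, 1] and normalise to a probability rule
  list(nodes = (x[o] + 1) / 2, weights = w[o] / sum(w))
}

## Quadrature representation of the distribution of the inherited network
## fraction U. Returns nodes u_i and weights summing to 1. A degenerate U
## (V_U = 0 or no beta parameters) collapses to a single atom.
u_quadrature <- function(beta_params, n_nodes) {
  if (is.null(beta_params) || (!is.null(beta_params$v_u) && beta_params$v_u == 0)) {
    e_u <- if (is.null(beta_params)) 0.5 else beta_params$e_u
    return(list(nodes = e_u, weights = 1))
  }
  gauss_jacobi_beta(n_nodes, beta_params$alpha, beta_params$beta)
}

## Stable child-seed derivation for sweep cells: a small multiplicative
## hash of (master_seed, index), kept strictly below 2^31.
child_seed <- function(master_seed, index) {
  s <- (as.double(master_seed) %% 2147483647)
  x <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483629
  as.integer(x %% 2147483647)
}

## Wrap angles into [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)

## Standard error of a sample variance, using the empirical fourth central
## moment (valid for non-normal data): Var(s^2) ~ (m4 - s^4 (n-3)/(n-1)) / n.
var_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  m4 <- mean((x - m)^4)
  s2 <- stats::var(x)
  v <- (m4 - s2^2 * (n - 3) / (n - 1)) / n
  sqrt(max(v, 0))
}
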