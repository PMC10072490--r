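## Exact discrete convolution of two pmfs on 0..(la-1), 0..(lb-1).
conv_pmf <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb - 1)
  for (i in seq_len(la))
    out[i:(i + lb - 1)] <- out[i:(i + lb - 1)] + a[i] * b
  out
}

check_integer_counts <- function(spec) {
  cts <- c(spec$w_n, spec$w_c, spec$m_n, spec$m_c)
  if (any(abs(cts - round(cts)) > 1e-9))
    stop("exact summation requires integer compartment counts ",
         "(build the model_spec with round_counts = TRUE)")
  lapply(spec[c("w_n", "w_c", "m_n", "m_c")], function(x) as.integer(round(x)))
}

## Core accumulator: sums the full state space against the U quadrature.
## Returns raw joint moments S[a+1, b+1] = E(W^a M^b) for a, b = 0..4,
## heteroplasmy moments conditioned on N > 0, the excluded (0,0) mass,
## and the worst per-node normalisation defect.
exact_core <- function(spec, n_nodes) {
  cts <- check_integer_counts(spec)
  w_n <- cts$w_n; w_c <- cts$w_c; m_n <- cts$m_n; m_c <- cts$m_c
  pc <- spec$p_c
  qd <- u_quadrature(spec$u_dist, n_nodes)

  pWc <- stats::dbinom(0:w_c, w_c, pc)
  pMc <- stats::dbinom(0:m_c, m_c, pc)

  S <- matrix(0, 5, 5)
  h1 <- h2 <- p00 <- 0
  norm_defect <- 0

  if (spec$mode != "repulsive") {
    Wsup <- 0:(w_n + w_c)
    Msup <- 0:(m_n + m_c)
    Wpow <- outer(Wsup, 0:4, `^`)
    Mpow <- outer(Msup, 0:4, `^`)
    Tot <- outer(Wsup, Msup, `+`)
    Hmat <- outer(Wsup, Msup, function(w, m) m) / ifelse(Tot == 0, 1, Tot)
    Hmat[1, 1] <- 0
    H2mat <- Hmat^2
    for (i in seq_along(qd$nodes)) {
      u <- qd$nodes[i]; wgt <- qd$weights[i]
      pW <- conv_pmf(stats::dbinom(0:w_n, w_n, u), pWc)
      pM <- conv_pmf(stats::dbinom(0:m_n, m_n, u), pMc)
      norm_defect <- max(norm_defect, abs(1 - sum(pW)), abs(1 - sum(pM)))
      SW <- colSums(pW * Wpow)
      SM <- colSums(pM * Mpow)
      S <- S + wgt * outer(SW, SM)
      P <- outer(pW, pM)
      h1 <- h1 + wgt * sum(P * Hmat)
      h2 <- h2 + wgt * sum(P * H2mat)
      p00 <- p00 + wgt * pW[1] * pM[1]
    }
  } else {
    n_tot <- w_n + m_n
    if (n_tot < 1) stop("repulsive mode with no networked molecules")
    Wc_sup <- 0:w_c
    Mc_sup <- 0:m_c
    for (i in seq_along(qd$nodes)) {
      u <- qd$nodes[i]; wgt <- qd$weights[i]
      d <- min(floor(u * spec$spaces_total), n_tot)
      pWn <- stats::dhyper(0:w_n, w_n, m_n, d)
      norm_defect <- max(norm_defect, abs(1 - sum(pWn)))
      for (k in 0:w_n) {
        pk <- pWn[k + 1]
        if (pk == 0) next
        Wv <- k + Wc_sup
        Mv <- (d - k) + Mc_sup
        SW <- colSums(pWc * outer(Wv, 0:4, `^`))
        SM <- colSums(pMc * outer(Mv, 0:4, `^`))
        S <- S + wgt * pk * outer(SW, SM)
        Tot <- outer(Wv, Mv, `+`)
        Hk <- outer(Wv, Mv, function(w, m) m) / ifelse(Tot == 0, 1, Tot)
        zero <- Tot == 0
        Hk[zero] <- 0
        P <- pk * outer(pWc, pMc)
        h1 <- h1 + wgt * sum(P * Hk)
        h2 <- h2 + wgt * sum(P * Hk^2)
        p00 <- p00 + wgt * sum(P[zero])
      }
    }
  }
  list(S = S, h1 = h1, h2 = h2, p00 = p00, norm_defect = norm_defect)
}

core_to_prediction <- function(core, spec, method, n_nodes) {
  S <- core$S
  E_W <- S[2, 1]; E_M <- S[1, 2]
  E_N <- E_W + E_M
  E_N2 <- S[3, 1] + 2 * S[2, 2] + S[1, 3]
  keep <- 1 - core$p00
  E_h <- core$h1 / keep
  V_h <- core$h2 / keep - E_h^2
  new_prediction(method,
                 E_N = E_N, V_N = E_N2 - E_N^2,
                 E_h = E_h, V_h = V_h,
                 Vp_h = if (spec$h > 0 && spec$h < 1)
                   normalized_vh(V_h, spec$h) else NA_real_,
                 p_zero = core$p00, norm_defect = core$norm_defect,
                 quad_nodes = n_nodes, raw_moments = S)
}

#' Exhaustive moment sum over the inheritance state space
#'
#' Computes moments of the inherited copy number `N` and heteroplasmy `h`
#' exactly (up to `U` quadrature) by summing over the joint distribution
#' of `(W_n, W_c, M_n, M_c)`: for each Gauss-Legendre node of the
#' Beta-distributed inherited network fraction, the conditional laws of
#' `W = W_n + W_c` and `M = M_n + M_c` are formed by discrete convolution
#' (conditional independence given `U` reduces the four-fold sum) and all
#' `f(W, M)` summed on the grid. Heteroplasmy moments exclude the
#' `(W, M) = (0, 0)` atom, whose mass is reported as `p_zero`. In
#' repulsive mode the binomial network kernel is replaced by the
#' hypergeometric one (then `M_n = d(u) - W_n` is determined by `W_n` and
#' the sum runs over `W_n` explicitly).
#'
#' @param spec a [model_spec()] with integer counts.
#' @param quad_nodes number of quadrature nodes (default 200; ignored
#'   when `V(U) = 0`, which needs a single node).
#' @param check_convergence if `TRUE`, recompute with doubled nodes and
#'   warn when the variances move by a relative `> 1e-8`; the doubled
#'   result is returned.
#' @return a `mito_prediction` with method `"exact_sum"`, carrying the
#'   raw joint moments `E(W^a M^b)` (`a, b <= 4`) in `raw_moments`.
#' @examples
#' sp <- model_spec(20, 0.5, p = 1, q = 0, u_dist = fit_beta(0.5, 0.02))
#' exact_moments_sum(sp, quad_nodes = 64)
#' @export
exact_moments_sum <- function(spec, quad_nodes = 200, check_convergence = TRUE) {
  stopifnot(inherits(spec, "model_spec"), quad_nodes >= 1)
  degenerate <- spec$u_dist$v_u == 0
  core <- exact_core(spec, quad_nodes)
  pred <- core_to_prediction(core, spec, "exact_sum", quad_nodes)
  if (check_convergence && !degenerate) {
    core2 <- exact_core(spec, 2 * quad_nodes)
    pred2 <- core_to_prediction(core2, spec, "exact_sum", 2 * quad_nodes)
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
    if (rel(pred$V_N, pred2$V_N) > 1e-8 || rel(pred$V_h, pred2$V_h) > 1e-8)
      warning("quadrature not converged at ", quad_nodes,
              " nodes (relative change > 1e-8 on doubling)")
    pred <- pred2
  }
  pred
}

#' Brute-force enumeration oracle
#'
#' Enumerates every `(W_n, W_c, M_n, M_c)` outcome with its exact
#' probability, conditional on each `U` quadrature node, and accumulates
#' moments of `N` and `h` directly — no convolution shortcuts. Slow by
#' design; restricted to `N0 <= 12` and used to validate
#' [exact_moments_sum()].
#'
#' @inheritParams exact_moments_sum
#' @return a `mito_prediction` with method `"enumeration"`.
#' @export
brute_force_enumeration <- function(spec, quad_nodes = 200) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$N0 > 12) stop("enumeration refused for N0 > 12 (combinatorial blow-up)")
  cts <- check_integer_counts(spec)
  w_n <- cts$w_n; w_c <- cts$w_c; m_n <- cts$m_n; m_c <- cts$m_c
  pc <- spec$p_c
  qd <- u_quadrature(spec$u_dist, quad_nodes)
  E_N <- E_N2 <- h1 <- h2 <- p00 <- 0
  for (i in seq_along(qd$nodes)) {
    u <- qd$nodes[i]; wgt <- qd$weights[i]
    if (spec$mode != "repulsive") {
      g <- expand.grid(Wn = 0:w_n, Wc = 0:w_c, Mn = 0:m_n, Mc = 0:m_c)
      pr <- stats::dbinom(g$Wn, w_n, u) * stats::dbinom(g$Wc, w_c, pc) *
        stats::dbinom(g$Mn, m_n, u) * stats::dbinom(g$Mc, m_c, pc)
    } else {
      d <- min(floor(u * spec$spaces_total), w_n + m_n)
      g <- expand.grid(Wn = 0:w_n, Wc = 0:w_c, Mc = 0:m_c)
      g$Mn <- d - g$Wn
      pr <- stats::dhyper(g$Wn, w_n, m_n, d) * stats::dbinom(g$Wc, w_c, pc) *
        stats::dbinom(g$Mc, m_c, pc)
      ok <- g$Mn >= 0 & g$Mn <= m_n
      g <- g[ok, ]; pr <- pr[ok]
    }
    W <- g$Wn + g$Wc
    M <- g$Mn + g$Mc
    N <- W + M
    E_N <- E_N + wgt * sum(pr * N)
    E_N2 <- E_N2 + wgt * sum(pr * N^2)
    pos <- N > 0
    h <- M[pos] / N[pos]
    h1 <- h1 + wgt * sum(pr[pos] * h)
    h2 <- h2 + wgt * sum(pr[pos] * h^2)
    p00 <- p00 + wgt * sum(pr[!pos])
  }
  keep <- 1 - p00
  E_h <- h1 / keep
  V_h <- h2 / keep - E_h^2
  new_prediction("enumeration",
                 E_N = E_N, V_N = E_N2 - E_N^2, E_h = E_h, V_h = V_h,
                 Vp_h = if (spec$h > 0 && spec$h < 1)
                   normalized_vh(V_h, spec$h) else NA_real_,
                 p_zero = p00)
}

#' Joint central moments of the inherited counts
#'
#' Central moments `E[(W - EW)^j (M - EM)^k]` for `j + k <= 4`, computed
#' exactly from the raw moments of the state-space sum. Input to the
#' second-order delta method.
#'
#' @inheritParams exact_moments_sum
#' @return object of class `joint_moments`: list with `E_W`, `E_M` and a
#'   5x5 matrix `central` (`central[j+1, k+1]` is the `(j, k)` central
#'   moment).
#' @export
joint_moments <- function(spec, quad_nodes = 200) {
  core <- exact_core(spec, quad_nodes)
  S <- core$S
  a <- S[2, 1]; b <- S[1, 2]
  central <- matrix(0, 5, 5)
  for (j in 0:4) for (k in 0:(4 - j)) {
    acc <- 0
    for (r in 0:j) for (s in 0:k)
      acc <- acc + choose(j, r) * choose(k, s) *
        S[r + 1, s + 1] * (-a)^(j - r) * (-b)^(k - s)
    central[j + 1, k + 1] <- acc
  }
  structure(list(E_W = a, E_M = b, central = central, raw = S),
            class = "joint_moments")
}

#' Second-order delta-method heteroplasmy moments
#'
#' Expands `h = M/(W + M)` to second order about the mean counts and
#' takes exact expectations of the quadratic surrogate, which requires
#' joint central moments of `(W, M)` up to order four. This is still an
#' approximation: its residual against [exact_moments_sum()] is a
#' genuine truncation error and is not assumed to vanish (the expansion
#' converges slowly when spatial structure correlates the genotypes).
#' Relative to the first order it contributes a compensatory term along
#' the `p = q` diagonal.
#'
#' @param jm a [joint_moments()] object (missing or wrong-class input is
#'   an error).
#' @param h_mother mother heteroplasmy for normalisation.
#' @return a `mito_prediction` with method `"taylor2"`.
#' @export
taylor_second_order <- function(jm, h_mother) {
  if (missing(jm) || !inherits(jm, "joint_moments"))
    stop("`jm` must be a joint_moments object (central moments to order 4)")
  m <- jm$central
  EW <- jm$E_W; EM <- jm$E_M
  Tt <- EW + EM
  if (Tt <= 0) stop("expected total copy number is zero")
  ## derivatives of h = M / (W + M) at the means
  a1 <- -EM / Tt^2            # f_W
  a2 <- EW / Tt^2             # f_M
  b11 <- 2 * EM / Tt^3        # f_WW
  b22 <- -2 * EW / Tt^3       # f_MM
  b12 <- (EM - EW) / Tt^3     # f_WM
  m20 <- m[3, 1]; m02 <- m[1, 3]; m11 <- m[2, 2]
  m30 <- m[4, 1]; m03 <- m[1, 4]; m21 <- m[3, 2]; m12 <- m[2, 3]
  m40 <- m[5, 1]; m04 <- m[1, 5]; m22 <- m[3, 3]; m31 <- m[4, 2]; m13 <- m[2, 4]

  E_h <- EM / Tt + 0.5 * (b11 * m20 + 2 * b12 * m11 + b22 * m02)

  var_L <- a1^2 * m20 + 2 * a1 * a2 * m11 + a2^2 * m02
  cov_LQ <- 0.5 * (a1 * (b11 * m30 + 2 * b12 * m21 + b22 * m12) +
                   a2 * (b11 * m21 + 2 * b12 * m12 + b22 * m03))
  ES <- b11 * m20 + 2 * b12 * m11 + b22 * m02
  ES2 <- b11^2 * m40 + 4 * b12^2 * m22 + b22^2 * m04 +
    4 * b11 * b12 * m31 + 2 * b11 * b22 * m22 + 4 * b12 * b22 * m13
  var_Q <- 0.25 * (ES2 - ES^2)
  V_h <- var_L + 2 * cov_LQ + var_Q

  new_prediction("taylor2",
                 E_N = Tt, V_N = m20 + m02 + 2 * m11,
                 E_h = E_h, V_h = V_h,
                 Vp_h = if (h_mother > 0 && h_mother < 1)
                   normalized_vh(V_h, h_mother) else NA_real_)
}
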