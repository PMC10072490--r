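#' Fit a beta distribution to the inherited network fraction
#'
#' The proportion `U` of network mass inherited by a daughter is modelled
#' as `Beta(alpha, beta)`. Given a target mean and variance (typically
#' the empirical moments of `u` from simulation), the shape parameters
#' are obtained by moment matching:
#' `alpha + beta = E(1 - E)/V - 1`, `alpha = E (alpha + beta)`.
#'
#' @param e_u target mean, strictly in `(0, 1)`.
#' @param v_u target variance, in `(0, e_u (1 - e_u))`.
#' @return object of class `beta_network_params`: list with `alpha`,
#'   `beta`, `e_u`, `v_u`.
#' @examples
#' fit_beta(0.5, 1 / 12)  # alpha = beta = 1: uniform
#' @export
fit_beta <- function(e_u, v_u) {
  stopifnot(e_u > 0, e_u < 1)
  if (v_u <= 0) stop("`v_u` must be positive (use v_u = 0 via degenerate_u())")
  if (v_u >= e_u * (1 - e_u))
    stop("infeasible variance: v_u must be below e_u * (1 - e_u) = ",
         format(e_u * (1 - e_u)))
  ab <- e_u * (1 - e_u) / v_u - 1
  structure(list(alpha = e_u * ab, beta = (1 - e_u) * ab, e_u = e_u, v_u = v_u),
            class = "beta_network_params")
}

#' @rdname fit_beta
#' @param alpha,beta shape parameters (alternative construction).
#' @export
beta_network_params <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  e_u <- alpha / (alpha + beta)
  v_u <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  structure(list(alpha = alpha, beta = beta, e_u = e_u, v_u = v_u),
            class = "beta_network_params")
}

#' @rdname fit_beta
#' @param at location of the point mass for a degenerate (zero-variance)
#'   inherited fraction.
#' @export
degenerate_u <- function(at) {
  stopifnot(at >= 0, at <= 1)
  structure(list(alpha = NA_real_, beta = NA_real_, e_u = at, v_u = 0),
            class = "beta_network_params")
}

#' Analytic model specification
#'
#' Bundles the genetic parameters, division fraction and
#' inherited-network-fraction distribution for the analytic inheritance
#' models. Three modes: `"null"` (no network; both genotypes binomially
#' partitioned with the cytoplasm), `"random"` (networked molecules
#' binomial with beta-distributed success probability `U`), and
#' `"repulsive"` (networked molecules drawn without replacement into
#' `floor(u * spaces_total)` evenly spaced slots; hypergeometric).
#'
#' Compartment counts default to the simulator's integer rounding
#' ([allocate_counts()]); `round_counts = FALSE` keeps the continuous
#' products `p (1-h) N0` etc., which is what the closed-form expressions
#' assume (the two differ by at most one molecule per compartment).
#'
#' @param N0 mother copy number.
#' @param h mother heteroplasmy.
#' @param p,q network-inclusion proportions for wildtype/mutant.
#' @param p_c inherited cytoplasm fraction (sector angle / 360).
#' @param u_dist a [beta_network_params()]/[fit_beta()]/[degenerate_u()]
#'   object for `U`, or `NULL` (degenerate at `p_c`).
#' @param mode `"random"`, `"null"`, or `"repulsive"`.
#' @param spaces_total total number of exclusion slots along the network
#'   (repulsive mode). See [repulsive_spaces()].
#' @param round_counts round compartment counts to integers (default
#'   `TRUE`; required by the exact-sum and enumeration routes).
#' @return an object of class `model_spec`, with counts `w_n, w_c, m_n,
#'   m_c` and `kappa = p (1-h) + q h`.
#' @export
model_spec <- function(N0, h, p, q, p_c = 0.5, u_dist = NULL,
                       mode = c("random", "null", "repulsive"),
                       spaces_total = NULL, round_counts = TRUE) {
  mode <- match.arg(mode)
  stopifnot(N0 >= 1, h >= 0, h <= 1, p >= 0, p <= 1, q >= 0, q <= 1,
            p_c > 0, p_c <= 1)
  if (mode == "null") { p <- 0; q <- 0 }
  if (is.null(u_dist)) u_dist <- degenerate_u(p_c)
  stopifnot(inherits(u_dist, "beta_network_params"))
  if (mode == "repulsive") {
    if (is.null(spaces_total) || spaces_total < 1)
      stop("repulsive mode requires `spaces_total` >= 1 (see repulsive_spaces())")
    spaces_total <- as.integer(spaces_total)
  }
  if (round_counts) {
    a <- allocate_counts(genetic_params(N0, h, p, q))
    counts <- list(w_n = a$w_n, w_c = a$w_c, m_n = a$m_n, m_c = a$m_c)
  } else {
    counts <- list(w_n = p * (1 - h) * N0, w_c = (1 - p) * (1 - h) * N0,
                   m_n = q * h * N0, m_c = (1 - q) * h * N0)
  }
  structure(c(list(N0 = N0, h = h, p = p, q = q, p_c = p_c,
                   u_dist = u_dist, mode = mode, spaces_total = spaces_total,
                   kappa = p * (1 - h) + q * h),
              counts),
            class = "model_spec")
}

#' Total exclusion slots for the repulsive model
#'
#' The repulsive model places networked molecules into a finite number of
#' spacing-`l` slots; a daughter inheriting a fraction `u` of the network
#' offers `floor(u * spaces_total)` of them. Two presets: `"literal"`
#' takes `floor(1/l)` (the number of slots along a unit length, as the
#' hypergeometric draw count `floor(u/l)` implies), `"geometric"` takes
#' `floor(mass_target / l)` (slots along the whole network length, the
#' default, 500 for `l = 0.1` on a mass-50 network). The model is
#' qualitative either way; the literal preset offers fewer slots than
#' molecules for typical parameters.
#'
#' @param l exclusion radius (cell radii, > 0).
#' @param preset `"geometric"` or `"literal"`.
#' @param mass_target network length for the geometric preset.
#' @return integer number of slots.
#' @export
repulsive_spaces <- function(l, preset = c("geometric", "literal"),
                             mass_target = 50) {
  preset <- match.arg(preset)
  stopifnot(l > 0)
  switch(preset,
         geometric = as.integer(floor(mass_target / l)),
         literal = as.integer(floor(1 / l)))
}

new_prediction <- function(method, E_N, V_N, E_h = NA_real_, V_h = NA_real_,
                           Vp_h = NA_real_, ...) {
  structure(list(method = method, E_N = E_N, V_N = V_N, E_h = E_h,
                 V_h = V_h, Vp_h = Vp_h, ...),
            class = "mito_prediction")
}

#' @export
print.mito_prediction <- function(x, digits = 6, ...) {
  cat(sprintf("Inheritance prediction [%s]\n", x$method))
  cat(sprintf("  E(N) = %s, V(N) = %s\n",
              format(x$E_N, digits = digits), format(x$V_N, digits = digits)))
  if (!is.na(x$E_h))
    cat(sprintf("  E(h) = %s, V(h) = %s, V'(h) = %s\n",
                format(x$E_h, digits = digits), format(x$V_h, digits = digits),
                format(x$Vp_h, digits = digits)))
  invisible(x)
}

#' Binomial null model of mtDNA inheritance
#'
#' With no network, both genotypes are partitioned binomially with the
#' inherited cytoplasm fraction: `M ~ Bin(h N0, p_c)`,
#' `W ~ Bin((1-h) N0, p_c)`. Then `V(N) = p_c (1 - p_c) N0` and the
#' (first-order) normalised heteroplasmy variance is
#' `V'(h) = (1 - p_c) / (p_c N0)`, recovering the familiar `1/N0` at
#' symmetric division.
#'
#' @param N0 mother copy number.
#' @param h mother heteroplasmy, strictly in `(0, 1)`.
#' @param p_c inherited cytoplasm fraction, strictly in `(0, 1)`.
#' @return a `mito_prediction`.
#' @examples
#' binomial_null(100, 0.5, 0.5)
#' @export
binomial_null <- function(N0, h, p_c) {
  stopifnot(N0 >= 1)
  if (!(h > 0 && h < 1)) stop("`h` must be strictly inside (0, 1)")
  if (!(p_c > 0 && p_c < 1)) stop("`p_c` must be strictly inside (0, 1)")
  Vp <- (1 - p_c) / (p_c * N0)
  new_prediction("closed_form", E_N = p_c * N0, V_N = p_c * (1 - p_c) * N0,
                 E_h = h, V_h = Vp * h * (1 - h), Vp_h = Vp)
}

new_component_moments <- function(E_Wn, V_Wn, E_Wc, V_Wc, E_Mn, V_Mn,
                                  E_Mc, V_Mc, cov_WnMn) {
  structure(list(E_Wn = E_Wn, V_Wn = V_Wn, E_Wc = E_Wc, V_Wc = V_Wc,
                 E_Mn = E_Mn, V_Mn = V_Mn, E_Mc = E_Mc, V_Mc = V_Mc,
                 cov_WnMn = cov_WnMn,
                 E_W = E_Wn + E_Wc, V_W = V_Wn + V_Wc,
                 E_M = E_Mn + E_Mc, V_M = V_Mn + V_Mc,
                 cov_WM = cov_WnMn),
            class = "component_moments")
}

#' @export
print.component_moments <- function(x, digits = 6, ...) {
  cat("Component moments of inherited counts\n")
  cat(sprintf("  E(W) = %s, V(W) = %s\n",
              format(x$E_W, digits = digits), format(x$V_W, digits = digits)))
  cat(sprintf("  E(M) = %s, V(M) = %s, Cov(W, M) = %s\n",
              format(x$E_M, digits = digits), format(x$V_M, digits = digits),
              format(x$cov_WM, digits = digits)))
  invisible(x)
}

#' Component moments under random network placement
#'
#' Networked counts are binomial with shared beta-distributed success
#' probability `U` (hence beta-binomial marginally); cytoplasmic counts
#' are independent binomials with `p_c`. By the laws of iterated
#' expectation and total variance: `E(W_n) = w_n E(U)`,
#' `V(W_n) = w_n E(U)(1 - E(U)) + w_n (w_n - 1) V(U)`, and the shared `U`
#' couples the genotypes: `Cov(W_n, M_n) = w_n m_n V(U)`.
#'
#' @param spec a [model_spec()] with mode `"random"` or `"null"`.
#' @return a `component_moments` object.
#' @export
moments_random <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$mode == "repulsive")
    stop("use moments_repulsive() for repulsive mode")
  eu <- spec$u_dist$e_u
  vu <- spec$u_dist$v_u
  pc <- spec$p_c
  bb_var <- function(n) n * eu * (1 - eu) + n * (n - 1) * vu
  new_component_moments(
    E_Wn = spec$w_n * eu, V_Wn = bb_var(spec$w_n),
    E_Wc = spec$w_c * pc, V_Wc = spec$w_c * pc * (1 - pc),
    E_Mn = spec$m_n * eu, V_Mn = bb_var(spec$m_n),
    E_Mc = spec$m_c * pc, V_Mc = spec$m_c * pc * (1 - pc),
    cov_WnMn = spec$w_n * spec$m_n * vu)
}

#' Component moments under repulsive network placement
#'
#' Conditional on an inherited fraction `u`, the daughter's network
#' offers `d(u) = min(floor(u * spaces_total), w_n + m_n)` slots, filled
#' by sampling molecules without replacement:
#' `W_n | u ~ Hypergeometric(w_n + m_n, w_n, d(u))` and
#' `M_n | u = d(u) - W_n` (so `Cov(W_n, M_n | u) = -V(W_n | u)`: the
#' without-replacement filling anti-correlates the genotypes). Marginal
#' moments follow by quadrature of the conditional moments against the
#' Beta density (laws of total variance and covariance); cytoplasmic
#' counts as in [moments_random()].
#'
#' @param spec a [model_spec()] with mode `"repulsive"`.
#' @param quad_nodes Gauss-Legendre nodes for the `U` integral.
#' @return a `component_moments` object.
#' @export
moments_repulsive <- function(spec, quad_nodes = 200) {
  stopifnot(inherits(spec, "model_spec"), spec$mode == "repulsive")
  n_tot <- spec$w_n + spec$m_n
  pc <- spec$p_c
  qd <- u_quadrature(spec$u_dist, quad_nodes)
  d <- pmin(floor(qd$nodes * spec$spaces_total), n_tot)
  fr <- if (n_tot > 0) spec$w_n / n_tot else 0
  E_c <- d * fr
  V_c <- if (n_tot > 1)
    d * fr * (1 - fr) * (n_tot - d) / (n_tot - 1) else rep(0, length(d))
  ## d == n_tot inherits everything deterministically; formula already
  ## gives V = 0 there.
  E_Wn <- sum(qd$weights * E_c)
  V_Wn <- sum(qd$weights * (V_c + E_c^2)) - E_Wn^2
  E_Mn_c <- d - E_c
  E_Mn <- sum(qd$weights * E_Mn_c)
  V_Mn <- sum(qd$weights * (V_c + E_Mn_c^2)) - E_Mn^2
  ## E(Wn * Mn | u) = E(Wn (d - Wn) | u) = d E_c - (V_c + E_c^2)
  E_WnMn <- sum(qd$weights * (d * E_c - V_c - E_c^2))
  new_component_moments(
    E_Wn = E_Wn, V_Wn = V_Wn,
    E_Wc = spec$w_c * pc, V_Wc = spec$w_c * pc * (1 - pc),
    E_Mn = E_Mn, V_Mn = V_Mn,
    E_Mc = spec$m_c * pc, V_Mc = spec$m_c * pc * (1 - pc),
    cov_WnMn = E_WnMn - E_Wn * E_Mn)
}

#' First-order delta-method heteroplasmy variance
#'
#' Treats `h = M / (W + M)` as a function of the inherited counts and
#' expands to first order about their means:
#' `V1(h) = h_M'^2 V(M) + h_W'^2 V(W) + 2 h_M' h_W' Cov(W, M)`, with
#' `h_M' = E(W)/(E(W)+E(M))^2` and `h_W' = -E(M)/(E(W)+E(M))^2`. The
#' covariance enters with a negative coefficient, so negatively
#' correlated genotypes increase heteroplasmy variance.
#'
#' @param cm a `component_moments` object.
#' @param h_mother mother heteroplasmy (for normalisation; `NA` Vp if on
#'   the boundary).
#' @return a `mito_prediction` with method `"taylor1"`.
#' @export
taylor_first_order <- function(cm, h_mother) {
  stopifnot(inherits(cm, "component_moments"))
  tot <- cm$E_W + cm$E_M
  if (tot <= 0) stop("expected total copy number is zero")
  dh_dM <- cm$E_W / tot^2
  dh_dW <- -cm$E_M / tot^2
  V_h <- dh_dM^2 * cm$V_M + dh_dW^2 * cm$V_W + 2 * dh_dM * dh_dW * cm$cov_WM
  new_prediction("taylor1",
                 E_N = tot, V_N = cm$V_W + cm$V_M + 2 * cm$cov_WM,
                 E_h = cm$E_M / tot, V_h = V_h,
                 Vp_h = if (h_mother > 0 && h_mother < 1)
                   normalized_vh(V_h, h_mother) else NA_real_,
                 dh_dW = dh_dW, dh_dM = dh_dM)
}

#' Closed-form copy-number variance, random placement
#'
#' `V(N) = N0 p_c (1 - p_c) + kappa N0 (kappa N0 - 1) V(U)` with
#' `kappa = p (1-h) + q h` the networked fraction of all mtDNA: binomial
#' cytoplasmic noise plus a term quadratic in the networked count driven
#' by the variability of the inherited network fraction.
#'
#' @param spec a [model_spec()] (mode `"random"` or `"null"`).
#' @return the variance `V(N)` (a number).
#' @export
closed_form_copy_number <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$mode == "repulsive")
    stop("closed forms apply to the random-placement model")
  kN <- spec$kappa * spec$N0
  spec$N0 * spec$p_c * (1 - spec$p_c) + kN * (kN - 1) * spec$u_dist$v_u
}

#' Closed-form normalised heteroplasmy variance, random placement
#'
#' First-order result
#' `V1'(h) = (1 - p_c)/(p_c N0) + V(U)/p_c^2 * (h(1-h)(p - q)^2 -
#' (p h + q (1-h))/N0)`. The leading network term is quadratic in
#' `p - q`: genotype-biased network inclusion inflates heteroplasmy
#' variance in proportion to the inherited-network variability. At
#' `p = q` the expression dips slightly below the null — an artefact of
#' the first-order truncation (see [taylor_second_order()]).
#'
#' @param spec a [model_spec()] (mode `"random"` or `"null"`), with
#'   `h` strictly inside `(0, 1)`.
#' @return the normalised variance `V1'(h)` (a number).
#' @export
closed_form_heteroplasmy <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$mode == "repulsive")
    stop("closed forms apply to the random-placement model")
  if (!(spec$h > 0 && spec$h < 1)) stop("`h` must be strictly inside (0, 1)")
  vu <- spec$u_dist$v_u
  with(spec,
       (1 - p_c) / (p_c * N0) +
         (vu / p_c^2) * (h * (1 - h) * (p - q)^2 - (p * h + q * (1 - h)) / N0))
}

#' Assemble V(N) from component moments
#'
#' `V(N) = V(W) + V(M) + 2 Cov(W, M)`.
#'
#' @param cm a `component_moments` object.
#' @return the variance of `N = W + M`.
#' @export
copy_number_variance <- function(cm) {
  stopifnot(inherits(cm, "component_moments"))
  cm$V_W + cm$V_M + 2 * cm$cov_WM
}
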