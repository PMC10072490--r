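test_that("binomial null gives the textbook variances", {
  p <- binomial_null(100, 0.5, 0.5)
  expect_equal(p$V_N, 25)
  expect_equal(p$Vp_h, 1 / 100)
  p <- binomial_null(100, 0.5, 0.1)
  expect_equal(p$V_N, 9)
  expect_equal(p$Vp_h, 0.09)
  # deterministic inheritance limit
  expect_lt(binomial_null(100, 0.5, 1 - 1e-12)$V_N, 1e-9)
  expect_lt(binomial_null(100, 0.5, 1 - 1e-12)$Vp_h, 1e-11)
  expect_error(binomial_null(100, 0, 0.5), "strictly inside")
  expect_error(binomial_null(100, 0.5, 1), "strictly inside")
})

test_that("beta moment matching round-trips and rejects infeasible variances", {
  u <- fit_beta(0.5, 1 / 12)
  expect_equal(c(u$alpha, u$beta), c(1, 1))
  u <- fit_beta(0.5, 0.05)
  expect_equal(c(u$alpha, u$beta), c(2, 2))
  expect_error(fit_beta(0.5, 0.3), "infeasible")
  set.seed(40)
  for (i in 1:20) {
    e <- runif(1, 0.05, 0.95)
    v <- runif(1, 1e-6, 0.99 * e * (1 - e))
    b <- fit_beta(e, v)
    expect_equal(b$alpha / (b$alpha + b$beta), e, tolerance = 1e-12)
    expect_equal(b$alpha * b$beta /
                   ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1)),
                 v, tolerance = 1e-12)
  }
})

test_that("random-placement component moments match their closed forms", {
  # degenerate U with E(U) = p_c reduces to binomial components
  sp <- model_spec(100, 0.5, 1, 1, p_c = 0.5)
  cm <- moments_random(sp)
  expect_equal(cm$V_Wn, sp$w_n * 0.25)
  expect_equal(cm$cov_WnMn, 0)
  # shared-U covariance: w_n m_n V(U) = 50 * 50 * 0.01 = 25
  sp <- model_spec(100, 0.5, 1, 1, p_c = 0.5, u_dist = fit_beta(0.5, 0.01))
  cm <- moments_random(sp)
  expect_equal(cm$cov_WnMn, 25)
  expect_equal(cm$cov_WnMn, sp$w_n * sp$m_n * 0.01)
  # single-trial beta-binomial is Bernoulli(E(U))
  sp1 <- model_spec(2, 0.5, 1, 1, p_c = 0.5, u_dist = fit_beta(0.5, 0.05))
  expect_equal(moments_random(sp1)$V_Wn, 0.25)
})

test_that("repulsive component moments agree with conditional closed forms and MC", {
  # degenerate U with all slots available: deterministic inheritance
  spA <- model_spec(10, 0.5, 1, 1, p_c = 0.5, u_dist = degenerate_u(1),
                    mode = "repulsive", spaces_total = 10)
  cmA <- moments_repulsive(spA)
  expect_equal(cmA$E_Wn, 5)
  expect_equal(cmA$V_Wn, 0, tolerance = 1e-12)
  # degenerate U with d < n: hypergeometric mean d w_n / n
  spB <- model_spec(10, 0.5, 1, 1, p_c = 0.5, u_dist = degenerate_u(0.6),
                    mode = "repulsive", spaces_total = 10)
  expect_equal(moments_repulsive(spB)$E_Wn, 6 * 5 / 10)
  expect_error(model_spec(10, 0.5, 1, 1, mode = "repulsive"), "spaces_total")

  # marginal moments against a large Monte-Carlo oracle
  set.seed(41)
  n <- 2e5
  u <- rbeta(n, 2, 2)
  d <- pmin(floor(u * 10), 10)
  Wn <- rhyper(n, 5, 5, d)
  Mn <- d - Wn
  cm <- moments_repulsive(model_spec(10, 0.5, 1, 1, p_c = 0.5,
                                     u_dist = beta_network_params(2, 2),
                                     mode = "repulsive", spaces_total = 10))
  expect_lt(abs(cm$E_Wn - mean(Wn)), 3 * sd(Wn) / sqrt(n))
  expect_lt(abs(cm$V_Wn - var(Wn)), 3 * var(Wn) * sqrt(2 / n) * 2)
  # covariance against the full-pmf route (independent summation path):
  # with no cytoplasmic molecules, Cov(W, M) = Cov(W_n, M_n)
  ex <- exact_moments_sum(model_spec(10, 0.5, 1, 1, p_c = 0.5,
                                     u_dist = beta_network_params(2, 2),
                                     mode = "repulsive", spaces_total = 10),
                          quad_nodes = 200, check_convergence = FALSE)
  S <- ex$raw_moments
  expect_close(cm$cov_WnMn, S[2, 2] - S[2, 1] * S[1, 2], 1e-9)
  expect_close(cm$E_Wn, S[2, 1], 1e-9)
  expect_close(cm$V_Wn, S[3, 1] - S[2, 1]^2, 1e-9)
})

test_that("first-order delta method reduces to the known closed forms", {
  # binomial null inputs recover (1 - pc) / (pc N0) exactly
  for (pc in c(0.5, 0.1, 0.8)) {
    sp <- model_spec(100, 0.3, 0, 0, p_c = pc, mode = "null",
                     round_counts = FALSE)
    t1 <- taylor_first_order(moments_random(sp), 0.3)
    expect_equal(t1$Vp_h, (1 - pc) / (pc * 100), tolerance = 1e-12)
  }
  # decreasing Cov(W, M) at fixed variances strictly increases V(h)
  sp <- model_spec(100, 0.5, 1, 1, p_c = 0.5, u_dist = fit_beta(0.5, 0.01),
                   round_counts = FALSE)
  cm <- moments_random(sp)
  vh <- sapply(c(25, 0, -25), function(cv) {
    cm2 <- cm
    cm2$cov_WnMn <- cm2$cov_WM <- cv
    taylor_first_order(cm2, 0.5)$V_h
  })
  expect_true(all(diff(vh) > 0))
  cm0 <- cm
  cm0$E_W <- cm0$E_M <- 0
  expect_error(taylor_first_order(cm0, 0.5), "zero")
})

test_that("closed forms match their arithmetic examples and limits", {
  # kappa = 0: pure binomial
  sp0 <- model_spec(100, 0.5, 0, 0, p_c = 0.3, u_dist = fit_beta(0.3, 0.01),
                    round_counts = FALSE)
  expect_equal(closed_form_copy_number(sp0), 100 * 0.3 * 0.7)
  # N0 = 100, kappa = 1, V(U) = 0.01: 25 + 100 * 99 * 0.01 = 124
  sp1 <- model_spec(100, 0.5, 1, 1, p_c = 0.5, u_dist = fit_beta(0.5, 0.01),
                    round_counts = FALSE)
  expect_equal(closed_form_copy_number(sp1), 124)
  # V(U) = 0 recovers the null normalised variance
  expect_equal(closed_form_heteroplasmy(
    model_spec(100, 0.5, 1, 0, p_c = 0.25, round_counts = FALSE)),
    (1 - 0.25) / (0.25 * 100))
  # maximum-bias case p = 1, q = 0: 0.01 + 0.04 * (0.25 - 0.005) = 0.0198
  sp2 <- model_spec(100, 0.5, 1, 0, p_c = 0.5, u_dist = fit_beta(0.5, 0.01),
                    round_counts = FALSE)
  expect_equal(closed_form_heteroplasmy(sp2), 0.0198)
  # p = q at symmetric division: 1/N0 - 4 p V(U) / N0
  for (p in c(0.2, 0.7, 1)) {
    spd <- model_spec(1000, 0.4, p, p, p_c = 0.5,
                      u_dist = fit_beta(0.5, 0.02), round_counts = FALSE)
    expect_equal(closed_form_heteroplasmy(spd),
                 1 / 1000 - 4 * p * 0.02 / 1000, tolerance = 1e-12)
  }
  # V'(h) grows strictly with (p - q)^2 when V(U) > 0
  h <- 0.5
  deltas <- seq(0, 0.5, 0.1)
  vals <- sapply(deltas, function(d)
    closed_form_heteroplasmy(model_spec(1000, h, 0.5 + d, 0.5 - d, p_c = 0.5,
                                        u_dist = fit_beta(0.5, 0.02),
                                        round_counts = FALSE)))
  expect_true(all(diff(vals) > 0))
})

test_that("closed forms are the component-moment assembly, exactly", {
  set.seed(42)
  for (i in 1:30) {
    N0 <- sample(20:2000, 1)
    h <- runif(1, 0.05, 0.95)
    p <- runif(1); q <- runif(1)
    pc <- runif(1, 0.1, 0.9)
    vu <- runif(1, 1e-4, 0.9 * pc * (1 - pc))
    sp <- model_spec(N0, h, p, q, p_c = pc, u_dist = fit_beta(pc, vu),
                     round_counts = FALSE)
    cm <- moments_random(sp)
    expect_close(copy_number_variance(cm), closed_form_copy_number(sp), 1e-10)
    expect_close(taylor_first_order(cm, h)$Vp_h,
                 closed_form_heteroplasmy(sp), 1e-10)
  }
})

test_that("exhaustive sum is exact for degenerate and symmetric cases", {
  # null mode: V(N) equals the binomial value to 1e-9
  sp <- model_spec(150, 0.3, 0, 0, p_c = 0.4, mode = "null")
  ex <- exact_moments_sum(sp, check_convergence = FALSE)
  expect_close(ex$V_N, 150 * 0.4 * 0.6, 1e-9)
  expect_lt(ex$norm_defect, 1e-12)
  # genotype exchange symmetry: h = 0.5, p = q, alpha = beta -> E(h) = 1/2
  sp <- model_spec(40, 0.5, 0.6, 0.6, p_c = 0.5,
                   u_dist = beta_network_params(3, 3))
  ex <- exact_moments_sum(sp, quad_nodes = 64, check_convergence = FALSE)
  expect_equal(ex$E_h, 0.5, tolerance = 1e-9)
  # node doubling flags nothing for smooth beta weights
  expect_silent(exact_moments_sum(sp, quad_nodes = 200))
})

test_that("enumeration oracle matches tiny closed-form cases and the sum", {
  # two molecules, both networked, U fixed at 1/2: each kept w.p. 1/2
  spA <- model_spec(2, 0.5, 1, 1, p_c = 0.5, u_dist = degenerate_u(0.5))
  enA <- brute_force_enumeration(spA)
  expect_equal(enA$E_N, 1)
  expect_equal(enA$V_N, 0.5)
  # two cytoplasmic molecules: two fair coin flips
  spB <- model_spec(2, 0.5, 0, 0, p_c = 0.5, mode = "null")
  enB <- brute_force_enumeration(spB)
  expect_equal(enB$E_N, 1)
  expect_equal(enB$V_N, 0.5)
  expect_equal(enB$p_zero, 0.25)
  expect_error(brute_force_enumeration(
    model_spec(13, 0.5, 1, 1, p_c = 0.5)), "N0 > 12")
  # repulsive kernel agreement at small size
  set.seed(43)
  for (i in 1:5) {
    sp <- random_small_spec(mode = "repulsive")
    ex <- exact_moments_sum(sp, quad_nodes = 48, check_convergence = FALSE)
    en <- brute_force_enumeration(sp, quad_nodes = 48)
    for (f in c("E_N", "V_N", "E_h", "V_h"))
      expect_close(ex[[f]], en[[f]], 1e-9)
  }
})

test_that("second-order delta method behaves as an improvement with known limits", {
  # binomial null: within 5% of the exact sum (first order sits 3% below)
  spn <- model_spec(100, 0.5, 0, 0, p_c = 0.5, mode = "null")
  t2 <- taylor_second_order(joint_moments(spn), 0.5)
  exn <- exact_moments_sum(spn, check_convergence = FALSE)
  expect_lt(abs(t2$Vp_h - exn$Vp_h) / exn$Vp_h, 0.05)
  expect_error(taylor_second_order(list(a = 1), 0.5), "joint_moments")

  # on the p = q diagonal the second-order term opposes the spurious
  # first-order dip below the null
  spd <- model_spec(100, 0.5, 0.8, 0.8, p_c = 0.5,
                    u_dist = fit_beta(0.5, 0.01))
  t1 <- taylor_first_order(moments_random(spd), 0.5)
  t2 <- taylor_second_order(joint_moments(spd, quad_nodes = 64), 0.5)
  expect_lt(t1$Vp_h, 0.01)       # the artefact: below the null
  expect_gt(t2$Vp_h, t1$Vp_h)    # compensatory diagonal correction

  # degenerate U, p = q = 0: first/second order differ at O(1/N0^2)
  dev <- sapply(c(10, 100), function(N0) {
    sp <- model_spec(N0, 0.5, 0, 0, p_c = 0.5, mode = "null")
    tt1 <- taylor_first_order(moments_random(sp), 0.5)
    tt2 <- taylor_second_order(joint_moments(sp), 0.5)
    abs(tt2$Vp_h - tt1$Vp_h)
  })
  expect_lt(dev[2], dev[1] * (10 / 100)^2 * 5)
})

test_that("first order systematically underestimates V(h) for asymmetric division", {
  # V(U) at the scale fitted to simulated networks for a 10% daughter
  bp <- fit_beta(0.1, 0.003)
  for (pq in list(c(1, 0), c(1, 0.5), c(0.5, 0.5))) {
    sp <- model_spec(100, 0.5, pq[1], pq[2], p_c = 0.1, u_dist = bp)
    ex <- exact_moments_sum(sp, quad_nodes = 96, check_convergence = FALSE)
    t1 <- taylor_first_order(moments_random(sp), 0.5)
    expect_gt(ex$V_h, t1$V_h)
  }
})

test_that("analytic component moments match simulation within Monte-Carlo error", {
  set.seed(44)
  pool <- get_network_pool(16, 300)
  gen <- genetic_params(100, 0.3, 0.8, 0.4)
  ens <- run_ensemble(genetics = gen, network_pool = pool, n_reps = 3000)
  s <- ens$summary
  bp <- fit_beta(s$E_U, s$V_U)
  cm <- moments_random(model_spec(100, 0.3, 0.8, 0.4, p_c = 0.5, u_dist = bp))
  out <- ens$outcomes
  n <- nrow(out)
  expect_lt(abs(s$E_W - cm$E_W), 3 * sd(out$W) / sqrt(n))
  expect_lt(abs(s$E_M - cm$E_M), 3 * sd(out$M) / sqrt(n))
  expect_lt(abs(s$V_W - cm$V_W), 3 * var_se_local(out$W))
  expect_lt(abs(s$V_M - cm$V_M), 3 * var_se_local(out$M))
  cw <- out$W - mean(out$W)
  cmm <- out$M - mean(out$M)
  se_cov <- sqrt((mean(cw^2 * cmm^2) - cov(out$W, out$M)^2) / n)
  expect_lt(abs(s$cov_WM - cm$cov_WM), 3 * se_cov)
})
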