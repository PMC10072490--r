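#' Specification of a parameter sweep grid
#'
#' Describes the grid of network-inclusion probabilities `(p, q)` crossed
#' with seed counts, heteroplasmies, copy numbers, placement modes and
#' diffusion scales over which division ensembles are run. Defaults
#' mirror the headline experiment structure: an 11x11 `(p, q)` grid, seed
#' counts 4/16/64, `h` of 0.1 and 0.5, `N0` of 100 and 1000, symmetric
#' division, 2000 replicates per cell.
#'
#' @param p_grid,q_grid inclusion probability grids.
#' @param s_list seed counts.
#' @param h_list mother heteroplasmies.
#' @param N0_list mother copy numbers.
#' @param p_c inherited cytoplasm fraction.
#' @param placement a [placement_params()].
#' @param lambda_list diffusion scales (0 = no diffusion).
#' @param n_reps replicates per grid cell.
#' @param master_seed master RNG seed; every cell derives a stable child
#'   seed from it.
#' @param network_pool_size if positive, pre-grow this many networks per
#'   seed count and cycle through them in every cell (amortises growth
#'   cost; cells still average over network realisations). 0 regrows a
#'   fresh network per replicate.
#' @param exact_max_N0 attach exhaustive-sum predictions only for
#'   `N0` up to this bound (they cost O(N0^2) per quadrature node).
#' @param quad_nodes quadrature nodes for attached analytic predictions.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(p_grid = seq(0, 1, 0.1), q_grid = seq(0, 1, 0.1),
                       s_list = c(4, 16, 64), h_list = c(0.1, 0.5),
                       N0_list = c(100, 1000), p_c = 0.5,
                       placement = placement_params(),
                       lambda_list = 0, n_reps = 2000, master_seed = 1,
                       network_pool_size = 0, exact_max_N0 = 150,
                       quad_nodes = 64) {
  stopifnot(length(p_grid) > 0, length(q_grid) > 0, n_reps >= 2,
            all(p_grid >= 0 & p_grid <= 1), all(q_grid >= 0 & q_grid <= 1),
            p_c > 0, p_c <= 1)
  structure(list(p_grid = p_grid, q_grid = q_grid, s_list = s_list,
                 h_list = h_list, N0_list = N0_list, p_c = p_c,
                 placement = placement, lambda_list = lambda_list,
                 n_reps = n_reps, master_seed = master_seed,
                 network_pool_size = network_pool_size,
                 exact_max_N0 = exact_max_N0, quad_nodes = quad_nodes),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For every grid cell, runs [run_ensemble()] under a deterministic child
#' seed, fits `Beta(alpha, beta)` to the cell's empirical inherited
#' network fraction moments, and attaches the matched analytic
#' predictions: the binomial null baseline (always), and — for
#' undiffused cells — closed forms / first-order delta method (random
#' placement) or hypergeometric component moments (repulsive placement),
#' plus the exhaustive sum when `N0` is small enough. Cells whose
#' empirical `(E(U), V(U))` are beta-infeasible are flagged and carry
#' `NA` analytic columns.
#'
#' @param spec a [sweep_spec()].
#' @param csv_path optional path for the long-format CSV.
#' @param manifest_path optional path for a JSON manifest (parameters +
#'   master seed) sufficient to regenerate the CSV.
#' @param verbose print per-cell progress to stderr.
#' @return a data frame of class `mito_sweep`, one row per cell.
#' @export
run_sweep <- function(spec, csv_path = NULL, manifest_path = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(p = spec$p_grid, q = spec$q_grid, s = spec$s_list,
                      h = spec$h_list, N0 = spec$N0_list,
                      lambda = spec$lambda_list,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))

  pools <- list()
  if (spec$network_pool_size > 0) {
    for (s in unique(grid$s)) {
      set.seed(child_seed(spec$master_seed, 1e6 + s))
      pools[[as.character(s)]] <- replicate(
        spec$network_pool_size, grow_network(growth_params(s = s)),
        simplify = FALSE)
    }
  }

  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- child_seed(spec$master_seed, i)
    set.seed(seed_i)
    gen <- genetic_params(g$N0, g$h, g$p, g$q)
    diff_p <- if (g$lambda > 0) diffusion_params(g$lambda) else NULL
    pool <- if (spec$network_pool_size > 0) pools[[as.character(g$s)]] else NULL
    ens <- run_ensemble(growth = growth_params(s = g$s), genetics = gen,
                        placement = spec$placement, diffusion = diff_p,
                        division = division_params(360 * spec$p_c),
                        n_reps = spec$n_reps, network_pool = pool,
                        keep_outcomes = FALSE)
    sm <- ens$summary
    null_pred <- if (g$h > 0 && g$h < 1)
      binomial_null(g$N0, g$h, spec$p_c) else NULL
    row <- data.frame(
      cell = i, seed = seed_i, p = g$p, q = g$q, s = g$s, h = g$h,
      N0 = g$N0, p_c = spec$p_c, l = spec$placement$l,
      mode = spec$placement$mode, lambda = g$lambda, n_reps = spec$n_reps,
      E_N = sm$E_N, V_N = sm$V_N, se_V_N = sm$se_V_N,
      E_h = sm$E_h, V_h = sm$V_h, se_V_h = sm$se_V_h, Vp_h = sm$Vp_h,
      E_U = sm$E_U, V_U = sm$V_U, n_defined = sm$n_defined,
      relaxations = sm$relaxations,
      null_V_N = if (is.null(null_pred)) NA else null_pred$V_N,
      null_Vp_h = if (is.null(null_pred)) NA else null_pred$Vp_h,
      alpha = NA_real_, beta = NA_real_, beta_ok = FALSE,
      cf_V_N = NA_real_, cf_Vp_h = NA_real_,
      taylor1_V_N = NA_real_, taylor1_Vp_h = NA_real_,
      exact_V_N = NA_real_, exact_Vp_h = NA_real_,
      stringsAsFactors = FALSE)

    feasible <- sm$V_U > 0 && sm$V_U < sm$E_U * (1 - sm$E_U) &&
      sm$E_U > 0 && sm$E_U < 1
    if (feasible) {
      bp <- fit_beta(sm$E_U, sm$V_U)
      row$alpha <- bp$alpha; row$beta <- bp$beta; row$beta_ok <- TRUE
      if (g$lambda == 0 && g$h > 0 && g$h < 1) {
        if (spec$placement$mode == "random") {
          msp <- model_spec(g$N0, g$h, g$p, g$q, p_c = spec$p_c, u_dist = bp,
                            mode = "random", round_counts = FALSE)
          row$cf_V_N <- closed_form_copy_number(msp)
          row$cf_Vp_h <- closed_form_heteroplasmy(msp)
          t1 <- taylor_first_order(moments_random(msp), g$h)
          row$taylor1_V_N <- t1$V_N
          row$taylor1_Vp_h <- t1$Vp_h
          if (g$N0 <= spec$exact_max_N0 && g$p + g$q > 0) {
            ex <- exact_moments_sum(
              model_spec(g$N0, g$h, g$p, g$q, p_c = spec$p_c, u_dist = bp,
                         mode = "random"),
              quad_nodes = spec$quad_nodes, check_convergence = FALSE)
            row$exact_V_N <- ex$V_N
            row$exact_Vp_h <- ex$Vp_h
          }
        } else if (spec$placement$l > 0 && g$p + g$q > 0) {
          st <- repulsive_spaces(spec$placement$l)
          msp <- model_spec(g$N0, g$h, g$p, g$q, p_c = spec$p_c, u_dist = bp,
                            mode = "repulsive", spaces_total = st)
          t1 <- taylor_first_order(
            moments_repulsive(msp, quad_nodes = spec$quad_nodes), g$h)
          row$taylor1_V_N <- t1$V_N
          row$taylor1_Vp_h <- t1$Vp_h
          if (g$N0 <= spec$exact_max_N0) {
            ex <- exact_moments_sum(msp, quad_nodes = spec$quad_nodes,
                                    check_convergence = FALSE)
            row$exact_V_N <- ex$V_N
            row$exact_Vp_h <- ex$Vp_h
          }
        }
      }
    }
    if ((g$p == 0 && g$q == 0) && g$lambda == 0 && g$h > 0 && g$h < 1) {
      ## no networked molecules: the exact route is the plain binomial sum
      ex <- exact_moments_sum(
        model_spec(g$N0, g$h, 0, 0, p_c = spec$p_c, mode = "null"),
        check_convergence = FALSE)
      row$exact_V_N <- ex$V_N
      row$exact_Vp_h <- ex$Vp_h
      row$cf_V_N <- null_pred$V_N
      row$cf_Vp_h <- null_pred$Vp_h
    }
    rows[[i]] <- row
    if (verbose)
      message(sprintf("cell %d/%d (p=%.2f q=%.2f s=%d h=%.2f N0=%d lambda=%g)",
                      i, nrow(grid), g$p, g$q, g$s, g$h, g$N0, g$lambda))
  }
  res <- do.call(rbind, rows)
  class(res) <- c("mito_sweep", "data.frame")
  if (!is.null(csv_path)) utils::write.csv(res, csv_path, row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(
      list(spec = list(p_grid = spec$p_grid, q_grid = spec$q_grid,
                       s_list = spec$s_list, h_list = spec$h_list,
                       N0_list = spec$N0_list, p_c = spec$p_c,
                       placement = unclass(spec$placement),
                       lambda_list = spec$lambda_list, n_reps = spec$n_reps,
                       network_pool_size = spec$network_pool_size),
           master_seed = spec$master_seed,
           n_cells = nrow(res),
           package_version = as.character(utils::packageVersion("mitonetseg"))),
      manifest_path, auto_unbox = TRUE, digits = NA)
  res
}

#' Compare simulated and analytic sweep columns
#'
#' Per cell, z-scores of the simulated `V(N)` and `V'(h)` against the
#' exhaustive-sum predictions, using the Monte-Carlo standard errors of
#' the sample variances; plus the first-order delta-method residual
#' (exact minus first order), which is expected positive for asymmetric
#' division (systematic first-order underestimation of heteroplasmy
#' variance) and non-zero on the `p = q` diagonal.
#'
#' @param result a `mito_sweep` data frame with analytic columns.
#' @return list with the per-cell `table` (cell id, z-scores, residuals)
#'   and a `summary` (counts of `|z| > 3`).
#' @export
compare_sim_vs_theory <- function(result) {
  if (!inherits(result, "mito_sweep") &&
      !all(c("V_N", "exact_V_N", "se_V_N") %in% names(result)))
    stop("`result` must be a mito_sweep with simulated and analytic columns")
  hh <- result$h * (1 - result$h)
  tab <- data.frame(
    cell = result$cell, p = result$p, q = result$q, s = result$s,
    z_V_N = (result$V_N - result$exact_V_N) / result$se_V_N,
    z_Vp_h = (result$Vp_h - result$exact_Vp_h) / (result$se_V_h / hh),
    taylor1_resid_V_h = (result$exact_Vp_h - result$taylor1_Vp_h) * hh)
  ok_n <- !is.na(tab$z_V_N)
  ok_h <- !is.na(tab$z_Vp_h)
  list(table = tab,
       summary = list(
         n_compared_V_N = sum(ok_n),
         n_compared_Vp_h = sum(ok_h),
         n_z3_V_N = sum(abs(tab$z_V_N[ok_n]) > 3),
         n_z3_Vp_h = sum(abs(tab$z_Vp_h[ok_h]) > 3),
         median_taylor1_resid = stats::median(tab$taylor1_resid_V_h,
                                              na.rm = TRUE)))
}

#' @export
print.mito_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %d cells (%d reps each)\n",
              nrow(x), x$n_reps[1]))
  NextMethod()
}
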