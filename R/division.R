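#' Division parameters
#'
#' Cell division is modelled by cutting out a circular sector of angle
#' `phi` (degrees) at a uniformly random orientation; the daughter of
#' interest inherits everything inside the sector. `phi = 180` is
#' symmetric division; the inherited cytoplasm (area) fraction is
#' `p_c = phi / 360`.
#'
#' @param phi sector angle in degrees, in `(0, 360]`.
#' @return an object of class `division_params` with fields `phi` and
#'   `p_c`.
#' @export
division_params <- function(phi = 180) {
  stopifnot(phi > 0, phi <= 360)
  structure(list(phi = phi, p_c = phi / 360), class = "division_params")
}

## Subdivide all network segments to `resolution` and return piece polar
## angles and lengths; used to evaluate sector masses repeatedly.
network_pieces <- function(net, resolution = NULL) {
  if (is.null(resolution))
    resolution <- if (!is.null(net$params)) net$params$e else 0.01
  sg <- net$segments
  n_sub <- pmax(1L, ceiling(sg[, "len"] / resolution))
  seg_id <- rep.int(seq_len(nrow(sg)), n_sub)
  tmid <- (sequence(n_sub) - 0.5) / n_sub[seg_id]
  mx <- sg[seg_id, "x0"] + tmid * (sg[seg_id, "x1"] - sg[seg_id, "x0"])
  my <- sg[seg_id, "y0"] + tmid * (sg[seg_id, "y1"] - sg[seg_id, "y0"])
  list(ang = wrap_angle(atan2(my, mx)), len = sg[seg_id, "len"] / n_sub[seg_id],
       total = net$total_mass)
}

sector_mass_pieces <- function(pieces, sector_start, sector_angle) {
  sum(pieces$len[wrap_angle(pieces$ang - sector_start) < sector_angle])
}

#' Partition a populated cell into a sector daughter
#'
#' Draws a uniform orientation, inherits every molecule whose polar angle
#' lies within the sector (a molecule exactly at the origin is assigned
#' to the sector — a measure-zero tie-break), and records the inherited
#' genotype counts, heteroplasmy and network mass fraction.
#'
#' @param popn a `mito_population`.
#' @param net the `mito_network` the population was placed on (may be
#'   `NULL` when no molecules are networked; then `u` is `NA`).
#' @param dv a [division_params()] object.
#' @param orientation optional fixed sector start angle (radians);
#'   default: drawn uniformly.
#' @param both_daughters if `TRUE`, also record the complement daughter
#'   (diagnostic conservation mode).
#' @return list of class `daughter_outcome` with fields `W`, `M`, `N`,
#'   `h` (`NA` when `N = 0`), `u`, `orientation`, and optionally
#'   `complement`.
#' @export
partition <- function(popn, net = NULL, dv = division_params(),
                      orientation = NULL, both_daughters = FALSE) {
  stopifnot(inherits(popn, "mito_population"), inherits(dv, "division_params"))
  if (is.null(orientation)) orientation <- stats::runif(1, 0, 2 * pi)
  phi_rad <- dv$phi * pi / 180
  m <- popn$molecules
  ang <- wrap_angle(atan2(m$y, m$x))
  inside <- wrap_angle(ang - orientation) < phi_rad
  inside[m$x == 0 & m$y == 0] <- TRUE
  W <- sum(inside & m$genotype == "wildtype")
  M <- sum(inside & m$genotype == "mutant")
  u <- if (!is.null(net) && net$total_mass > 0)
    mass_in_sector(net, orientation, phi_rad) / net$total_mass else NA_real_
  out <- list(W = W, M = M, N = W + M,
              h = if (W + M > 0) M / (W + M) else NA_real_,
              u = u, orientation = orientation)
  if (both_daughters) {
    Wc <- sum(!inside & m$genotype == "wildtype")
    Mc <- sum(!inside & m$genotype == "mutant")
    out$complement <- list(W = Wc, M = Mc, N = Wc + Mc,
                           u = if (is.na(u)) NA_real_ else 1 - u)
  }
  structure(out, class = "daughter_outcome")
}

#' Normalised heteroplasmy variance
#'
#' Divides a heteroplasmy variance by `h (1 - h)` of the mother, removing
#' the leading dependence on the mean; equals `1 / N0` under symmetric
#' binomial inheritance.
#'
#' @param V_h heteroplasmy variance.
#' @param h_mother mother heteroplasmy, strictly inside `(0, 1)`.
#' @return the normalised variance `V_h / (h_mother (1 - h_mother))`.
#' @export
normalized_vh <- function(V_h, h_mother) {
  if (!(h_mother > 0 && h_mother < 1))
    stop("normalisation undefined for h_mother of 0 or 1")
  V_h / (h_mother * (1 - h_mother))
}

#' Simulate an ensemble of divisions
#'
#' Each replicate independently grows a network (unless a fixed `network`
#' or a `network_pool` is supplied), places the mtDNA population,
#' optionally applies pre-division diffusion, partitions once, and
#' records the daughter outcome. Summary statistics use the unbiased
#' (n - 1) variance estimator; heteroplasmy moments are computed over
#' replicates with `N > 0` (the count is reported as `n_defined`).
#'
#' A fixed `network` reuses one structure for all replicates (variance
#' decomposition experiments, or the null model where counts do not
#' depend on the network). A `network_pool` (list of `mito_network`)
#' cycles through pre-grown structures, amortising growth cost across
#' ensembles while still averaging over network realisations.
#'
#' @param growth a [growth_params()] (ignored if `network`/`network_pool`
#'   given).
#' @param genetics a [genetic_params()].
#' @param placement a [placement_params()].
#' @param diffusion a [diffusion_params()] or `NULL` for none.
#' @param division a [division_params()].
#' @param n_reps number of replicates (>= 2).
#' @param network optional fixed `mito_network`.
#' @param network_pool optional list of `mito_network` to cycle through.
#' @param keep_outcomes keep the per-replicate outcome table (default
#'   `TRUE`).
#' @return object of class `mito_ensemble`: list with `outcomes` (data
#'   frame: `W, M, N, h, u, orientation`), `summary` (list with `E_N`,
#'   `V_N`, `E_h`, `V_h`, `Vp_h`, `E_U`, `V_U`, `cov_WM`, `E_W`, `V_W`,
#'   `E_M`, `V_M`, `n_reps`, `n_defined`, `relaxations`), and `params`.
#' @examples
#' set.seed(1)
#' ens <- run_ensemble(growth_params(s = 4),
#'                     genetic_params(100, h = 0.5, p = 1, q = 0),
#'                     n_reps = 100)
#' ens
#' @export
run_ensemble <- function(growth = NULL, genetics,
                         placement = placement_params(),
                         diffusion = NULL,
                         division = division_params(),
                         n_reps,
                         network = NULL, network_pool = NULL,
                         keep_outcomes = TRUE) {
  stopifnot(inherits(genetics, "genetic_params"))
  if (n_reps < 2) stop("`n_reps` must be at least 2")
  alloc <- allocate_counts(genetics)
  needs_net <- alloc$w_n + alloc$m_n > 0
  phi_rad <- division$phi * pi / 180
  do_diffuse <- !is.null(diffusion) && diffusion$lam > 0 && diffusion$n_steps > 0

  W <- M <- integer(n_reps)
  u <- orient <- numeric(n_reps)
  relax <- 0L

  fixed_pieces <- NULL
  if (!is.null(network)) fixed_pieces <- network_pieces(network)
  pool_pieces <- NULL
  if (!is.null(network_pool))
    pool_pieces <- lapply(network_pool, network_pieces)

  for (i in seq_len(n_reps)) {
    if (!is.null(network)) {
      net <- network; pieces <- fixed_pieces
    } else if (!is.null(network_pool)) {
      j <- (i - 1L) %% length(network_pool) + 1L
      net <- network_pool[[j]]; pieces <- pool_pieces[[j]]
    } else if (needs_net || is.null(growth)) {
      if (is.null(growth)) stop("`growth` required when no network is supplied")
      net <- grow_network(growth)
      pieces <- network_pieces(net)
    } else {
      ## null placement: counts do not touch the network, but u is still
      ## recorded, so grow one structure lazily and keep it
      net <- grow_network(growth)
      pieces <- network_pieces(net)
      network <- net
      fixed_pieces <- pieces
    }
    popn <- place_population(net, alloc, placement)
    relax <- relax + popn$relaxations
    if (do_diffuse) popn <- diffuse(popn, diffusion)

    o <- stats::runif(1, 0, 2 * pi)
    m <- popn$molecules
    ang <- wrap_angle(atan2(m$y, m$x))
    inside <- wrap_angle(ang - o) < phi_rad
    inside[m$x == 0 & m$y == 0] <- TRUE
    W[i] <- sum(inside & m$genotype == "wildtype")
    M[i] <- sum(inside & m$genotype == "mutant")
    u[i] <- sector_mass_pieces(pieces, o, phi_rad) / pieces$total
    orient[i] <- o
  }

  N <- W + M
  h <- ifelse(N > 0, M / N, NA_real_)
  n_def <- sum(N > 0)
  V_h <- stats::var(h[N > 0])
  sm <- list(
    n_reps = n_reps, n_defined = n_def,
    E_N = mean(N), V_N = stats::var(N),
    E_W = mean(W), V_W = stats::var(W),
    E_M = mean(M), V_M = stats::var(M),
    cov_WM = stats::cov(W, M),
    E_h = mean(h[N > 0]), V_h = V_h,
    se_V_N = var_se(N), se_V_h = var_se(h[N > 0]),
    Vp_h = if (genetics$h > 0 && genetics$h < 1)
      normalized_vh(V_h, genetics$h) else NA_real_,
    E_U = mean(u), V_U = stats::var(u),
    relaxations = relax)
  structure(list(
    outcomes = if (keep_outcomes)
      data.frame(W = W, M = M, N = N, h = h, u = u, orientation = orient)
    else NULL,
    summary = sm,
    params = list(growth = growth, genetics = genetics, placement = placement,
                  diffusion = diffusion, division = division)),
    class = "mito_ensemble")
}

#' @export
print.mito_ensemble <- function(x, digits = 4, ...) {
  s <- x$summary
  g <- x$params$genetics
  cat(sprintf("Division ensemble: %d replicates (%d with N > 0)\n",
              s$n_reps, s$n_defined))
  cat(sprintf("  mother: N0 = %d, h = %g, p = %g, q = %g\n",
              g$N0, g$h, g$p, g$q))
  cat(sprintf("  E(N) = %s, V(N) = %s\n",
              format(s$E_N, digits = digits), format(s$V_N, digits = digits)))
  if (!is.na(s$Vp_h))
    cat(sprintf("  E(h) = %s, V(h) = %s, V'(h) = %s\n",
                format(s$E_h, digits = digits), format(s$V_h, digits = digits),
                format(s$Vp_h, digits = digits)))
  cat(sprintf("  E(U) = %s, V(U) = %s\n",
              format(s$E_U, digits = digits), format(s$V_U, digits = digits)))
  invisible(x)
}

#' @export
summary.mito_ensemble <- function(object, ...) object$summary

#' Write ensemble outcomes and summary
#'
#' CSV with one row per replicate plus a JSON summary (parameters,
#' replicate count, moment estimates).
#'
#' @param ens a `mito_ensemble`.
#' @param csv_path CSV output path (`NULL` to skip).
#' @param json_path JSON summary path (`NULL` to skip).
#' @param seed the seed used, recorded in the summary.
#' @return `ens`, invisibly.
#' @export
write_ensemble <- function(ens, csv_path = NULL, json_path = NULL, seed = NULL) {
  if (!is.null(csv_path)) {
    if (is.null(ens$outcomes)) stop("ensemble was run with keep_outcomes = FALSE")
    utils::write.csv(cbind(seed = if (is.null(seed)) NA else seed, ens$outcomes),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    pars <- lapply(ens$params, function(p) if (is.null(p)) NULL else unclass(p))
    jsonlite::write_json(list(params = pars, seed = seed, summary = ens$summary),
                         json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(ens)
}
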