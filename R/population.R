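#' Genetic parameters of the mother cell's mtDNA population
#'
#' @param N0 total mother copy number (positive integer).
#' @param h mother heteroplasmy: fraction of molecules carrying the
#'   mutant genotype, in `[0, 1]`.
#' @param p network-inclusion proportion for wildtype molecules.
#' @param q network-inclusion proportion for mutant molecules.
#' @return an object of class `genetic_params`.
#' @export
genetic_params <- function(N0, h, p, q) {
  if (length(N0) != 1 || is.na(N0) || N0 < 1 || N0 != floor(N0))
    stop("`N0` must be a positive integer")
  stopifnot(h >= 0, h <= 1, p >= 0, p <= 1, q >= 0, q <= 1)
  structure(list(N0 = as.integer(N0), h = h, p = p, q = q),
            class = "genetic_params")
}

#' Allocate mtDNA molecules to compartments by genotype
#'
#' Splits the mother's `N0` molecules into wildtype/mutant and
#' network/cytoplasm counts: `w_n = p (1-h) N0` wildtype in the network,
#' `m_n = q h N0` mutant in the network, the remainders in the cytoplasm.
#' Fractional products are resolved deterministically (round half away
#' from zero), with complements taken by subtraction so all totals are
#' conserved.
#'
#' @param gp a [genetic_params()] object.
#' @return list of class `count_allocation` with integer fields
#'   `w_n, w_c, m_n, m_c` and totals `W_total`, `M_total`.
#' @examples
#' allocate_counts(genetic_params(100, h = 0.1, p = 1, q = 0))
#' @export
allocate_counts <- function(gp) {
  stopifnot(inherits(gp, "genetic_params"))
  W_total <- round_half_up((1 - gp$h) * gp$N0)
  M_total <- gp$N0 - W_total
  w_n <- round_half_up(gp$p * W_total)
  m_n <- round_half_up(gp$q * M_total)
  structure(list(w_n = as.integer(w_n), w_c = as.integer(W_total - w_n),
                 m_n = as.integer(m_n), m_c = as.integer(M_total - m_n),
                 W_total = as.integer(W_total), M_total = as.integer(M_total)),
            class = "count_allocation")
}

#' Placement parameters for networked mtDNA
#'
#' In `"random"` mode networked molecules are placed uniformly by arc
#' length. In `"repulsive"` mode each networked molecule carries an
#' exclusion halo of radius `l` (Euclidean distance, units of cell
#' radius): candidates closer than `l` to an already-placed networked
#' molecule are rejected and redrawn, up to `max_attempts` times, after
#' which the attempted candidate with the largest nearest-neighbour
#' distance is accepted and a relaxation event is logged (the hard
#' constraint is relaxed rather than failing, mirroring the numerical
#' limitation of enforcing strict spacing at high occupancy).
#'
#' @param mode `"random"` or `"repulsive"`.
#' @param l exclusion radius (ignored for `"random"`).
#' @param max_attempts rejection cap per molecule (default 1000).
#' @return an object of class `placement_params`.
#' @export
placement_params <- function(mode = c("random", "repulsive"), l = 0,
                             max_attempts = 1000) {
  mode <- match.arg(mode)
  stopifnot(l >= 0, max_attempts >= 1)
  structure(list(mode = mode, l = l, max_attempts = as.integer(max_attempts)),
            class = "placement_params")
}

#' Place a mtDNA population in the cell
#'
#' Networked molecules (in a single uniformly shuffled genotype order, so
#' neither genotype systematically wins contested space under repulsion)
#' are placed on the network; cytoplasmic molecules are placed
#' area-uniformly in the unit disc.
#'
#' @param net a `mito_network` (required whenever networked counts are
#'   positive).
#' @param alloc a [allocate_counts()] result.
#' @param pp a [placement_params()] object.
#' @return object of class `mito_population`: list with `molecules` (a
#'   data frame `x, y, genotype, compartment`) and `relaxations` (number
#'   of repulsion relaxation events).
#' @export
place_population <- function(net, alloc, pp = placement_params()) {
  stopifnot(inherits(alloc, "count_allocation"), inherits(pp, "placement_params"))
  n_net <- alloc$w_n + alloc$m_n
  n_cyt <- alloc$w_c + alloc$m_c
  if (n_net > 0 && (is.null(net) || net$total_mass <= 0))
    stop("networked molecules requested but network is empty")

  relaxations <- 0L
  if (n_net > 0) {
    geno_net <- sample(rep(c("wildtype", "mutant"), c(alloc$w_n, alloc$m_n)))
    if (pp$mode == "random" || pp$l == 0) {
      xy <- sample_network_point(net, n_net)
    } else {
      xy <- matrix(NA_real_, n_net, 2)
      for (i in seq_len(n_net)) {
        if (i == 1) { xy[1, ] <- sample_network_point(net, 1); next }
        placed <- xy[seq_len(i - 1), , drop = FALSE]
        best <- NULL
        best_d <- -Inf
        ok <- FALSE
        for (att in seq_len(pp$max_attempts)) {
          cand <- sample_network_point(net, 1)
          d <- min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2))
          if (d >= pp$l) { xy[i, ] <- cand; ok <- TRUE; break }
          if (d > best_d) { best_d <- d; best <- cand }
        }
        if (!ok) {
          xy[i, ] <- best
          relaxations <- relaxations + 1L
        }
      }
    }
  } else {
    geno_net <- character(0)
    xy <- matrix(numeric(0), 0, 2)
  }

  if (n_cyt > 0) {
    r <- sqrt(stats::runif(n_cyt))
    th <- stats::runif(n_cyt, 0, 2 * pi)
    xy_c <- cbind(r * cos(th), r * sin(th))
    geno_cyt <- c(rep("wildtype", alloc$w_c), rep("mutant", alloc$m_c))
  } else {
    xy_c <- matrix(numeric(0), 0, 2)
    geno_cyt <- character(0)
  }

  mol <- data.frame(
    x = c(xy[, 1], xy_c[, 1]),
    y = c(xy[, 2], xy_c[, 2]),
    genotype = c(geno_net, geno_cyt),
    compartment = rep(c("network", "cytoplasm"), c(n_net, n_cyt)),
    stringsAsFactors = FALSE)
  structure(list(molecules = mol, relaxations = relaxations),
            class = "mito_population")
}

#' Diffusion parameters for pre-division network fragmentation
#'
#' Before division the network fragments, freeing each mtDNA molecule to
#' diffuse in its own organelle. Diffusion is modelled as `n_steps`
#' isotropic Gaussian steps; `lam` is the RMS length of a single step
#' (per-axis standard deviation `lam / sqrt(2)`), so the expected net
#' displacement of an unconfined 100-step walk is `10 * lam`.
#'
#' @param lam step scale (cell radii, >= 0).
#' @param n_steps number of steps (default 100).
#' @param per_axis_sigma if `TRUE`, interpret `lam` as the per-axis
#'   standard deviation instead of the RMS step length.
#' @return an object of class `diffusion_params`.
#' @export
diffusion_params <- function(lam, n_steps = 100, per_axis_sigma = FALSE) {
  stopifnot(lam >= 0, n_steps >= 0)
  structure(list(lam = lam, n_steps = as.integer(n_steps),
                 per_axis_sigma = isTRUE(per_axis_sigma)),
            class = "diffusion_params")
}

#' Apply pre-division diffusion to a population
#'
#' Every molecule (both compartments; the network is fragmented) takes
#' `n_steps` independent Gaussian steps. A step whose endpoint leaves the
#' unit disc is resampled (up to 100 tries, then the molecule stays put
#' for that step). Compartment labels are retained for bookkeeping;
#' positions no longer lie on the network.
#'
#' @param popn a `mito_population`.
#' @param dp a [diffusion_params()] object.
#' @param confine if `FALSE`, the boundary is ignored (used to measure the
#'   unconfined displacement scaling).
#' @return the diffused `mito_population`.
#' @export
diffuse <- function(popn, dp, confine = TRUE) {
  stopifnot(inherits(popn, "mito_population"), inherits(dp, "diffusion_params"))
  if (dp$lam == 0 || dp$n_steps == 0) return(popn)
  sigma <- if (dp$per_axis_sigma) dp$lam else dp$lam / sqrt(2)
  x <- popn$molecules$x
  y <- popn$molecules$y
  n <- length(x)
  for (step in seq_len(dp$n_steps)) {
    nx <- x + stats::rnorm(n, 0, sigma)
    ny <- y + stats::rnorm(n, 0, sigma)
    if (confine) {
      bad <- nx^2 + ny^2 > 1
      tries <- 0L
      while (any(bad) && tries < 100L) {
        k <- sum(bad)
        nx[bad] <- x[bad] + stats::rnorm(k, 0, sigma)
        ny[bad] <- y[bad] + stats::rnorm(k, 0, sigma)
        bad <- nx^2 + ny^2 > 1
        tries <- tries + 1L
      }
      if (any(bad)) {
        nx[bad] <- x[bad]
        ny[bad] <- y[bad]
      }
    }
    x <- nx
    y <- ny
  }
  popn$molecules$x <- x
  popn$molecules$y <- y
  popn
}

#' @export
print.mito_population <- function(x, ...) {
  m <- x$molecules
  cat(sprintf("mtDNA population: %d molecules (%d wildtype, %d mutant; %d networked)\n",
              nrow(m), sum(m$genotype == "wildtype"), sum(m$genotype == "mutant"),
              sum(m$compartment == "network")))
  if (x$relaxations > 0)
    cat(sprintf("  repulsion relaxation events: %d\n", x$relaxations))
  invisible(x)
}

#' @export
plot.mito_population <- function(x, net = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  plot(cos(th), sin(th), type = "l", asp = 1, xlab = "", ylab = "",
       axes = FALSE, ...)
  if (!is.null(net))
    segments(net$segments[, "x0"], net$segments[, "y0"],
             net$segments[, "x1"], net$segments[, "y1"], col = "grey70")
  m <- x$molecules
  points(m$x, m$y, pch = 19, cex = 0.5,
         col = ifelse(m$genotype == "mutant", "blue", "red"))
  invisible(x)
}

#' Write a population to CSV
#'
#' One row per molecule (`x, y, genotype, compartment`), with an optional
#' JSON sidecar of generating parameters.
#'
#' @param popn a `mito_population`.
#' @param path CSV output path.
#' @param sidecar optional JSON sidecar path.
#' @param params optional named list written to the sidecar.
#' @return `path`, invisibly.
#' @export
write_population <- function(popn, path, sidecar = NULL, params = NULL) {
  utils::write.csv(popn$molecules, path, row.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(params, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
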