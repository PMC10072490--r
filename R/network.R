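#' Growth parameters for the mitochondrial network generator
#'
#' The network grows from `s` evenly-spaced seed points on the cell
#' perimeter by an elongation-and-branching process: each active tip
#' elongates deterministically by `e` per unit time step and branches with
#' Poissonian rate `k` per step; tips that reach the cell boundary are
#' clipped to it and die. Growth stops when the total network length
#' reaches `mass_target` (the final increment is trimmed so the mass is
#' exact). If every tip dies first, the perimeter is re-seeded with a
#' fresh set of `s` points and growth continues.
#'
#' @param s number of perimeter seed points (>= 1). Few seeds give
#'   heterogeneous networks, many seeds give homogeneous ones.
#' @param e elongation increment per step, in cell radii (default 0.01).
#' @param k branching rate per tip per step (default 0.02).
#' @param mass_target total network length to generate, in cell radii
#'   (default 50).
#' @param branch_angle_range half-width of the uniform branch deviation
#'   angle, radians (default pi/2).
#' @param max_reseeds maximum number of re-seeding rounds before growth is
#'   declared failed (default 100).
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(s, e = 0.01, k = 0.02, mass_target = 50,
                          branch_angle_range = pi / 2, max_reseeds = 100) {
  if (length(s) != 1 || is.na(s) || s < 1 || s != floor(s))
    stop("`s` must be a positive integer")
  stopifnot(e > 0, k >= 0, mass_target > 0,
            branch_angle_range >= 0, max_reseeds >= 0)
  structure(list(s = as.integer(s), e = e, k = k, mass_target = mass_target,
                 branch_angle_range = branch_angle_range,
                 max_reseeds = as.integer(max_reseeds)),
            class = "growth_params")
}

#' Evenly-spaced seed angles on the cell perimeter
#'
#' Returns `s` perimeter angles `theta0 + 2*pi*i/s`, with the common offset
#' `theta0` drawn uniformly on `[0, 2*pi)` so the seeding is randomly
#' rotated in each realisation.
#'
#' @param s number of seed points (>= 1).
#' @return numeric vector of `s` angles in `[0, 2*pi)`.
#' @export
generate_seed_points <- function(s) {
  if (length(s) != 1 || is.na(s) || s < 1 || s != floor(s))
    stop("`s` must be a positive integer")
  theta0 <- stats::runif(1, 0, 2 * pi)
  wrap_angle(theta0 + 2 * pi * (seq_len(s) - 1) / s)
}

## Internal constructor for the network object. `segments` is a matrix
## with columns x0, y0, x1, y1, len (every segment is a straight chord:
## tips grow in straight lines and branches spawn new tips).
new_network <- function(segments, seed_angles, reseed_count, params = NULL) {
  colnames(segments) <- c("x0", "y0", "x1", "y1", "len")
  structure(list(segments = segments,
                 total_mass = sum(segments[, "len"]),
                 seed_angles = seed_angles,
                 reseed_count = reseed_count,
                 params = params),
            class = "mito_network")
}

#' Grow a random mitochondrial network in the unit disc
#'
#' Implements the elongation-and-branching growth process (see
#' [growth_params()]). Initial tips start on the perimeter heading
#' radially inward; a branch event spawns a new tip at the parent's
#' current position with direction deviated uniformly within
#' `branch_angle_range` of the parent's, while the parent continues
#' unchanged. Since tips never turn, each tip traces one straight segment.
#'
#' @param gp a [growth_params()] object.
#' @param geom a [cell_geometry()] (the simulation always uses the unit
#'   disc; geometry is carried for reporting).
#' @return an object of class `mito_network`: list with `segments` (matrix
#'   of straight segments `x0, y0, x1, y1, len`), `total_mass` (equal to
#'   `gp$mass_target` exactly), `seed_angles`, `reseed_count`.
#' @examples
#' set.seed(1)
#' net <- grow_network(growth_params(s = 4))
#' net$total_mass
#' @export
grow_network <- function(gp, geom = cell_geometry()) {
  stopifnot(inherits(gp, "growth_params"))
  target <- gp$mass_target
  e <- gp$e
  p_branch <- 1 - exp(-gp$k)

  seed_tips <- function() {
    ang <- generate_seed_points(gp$s)
    list(ox = cos(ang), oy = sin(ang), x = cos(ang), y = sin(ang),
         dx = -cos(ang), dy = -sin(ang), angles = ang)
  }

  tp <- seed_tips()
  ox <- tp$ox; oy <- tp$oy; x <- tp$x; y <- tp$y; dx <- tp$dx; dy <- tp$dy
  all_angles <- tp$angles
  ## lengths of finished segments are accumulated as they terminate
  done <- matrix(numeric(0), ncol = 5)
  mass_done <- 0
  reseeds <- 0L

  repeat {
    n_act <- length(x)
    if (n_act == 0) {
      if (reseeds >= gp$max_reseeds)
        stop("network generation failed: re-seed limit (", gp$max_reseeds,
             ") reached before mass target")
      reseeds <- reseeds + 1L
      tp <- seed_tips()
      ox <- tp$ox; oy <- tp$oy
      x <- tp$x; y <- tp$y; dx <- tp$dx; dy <- tp$dy
      all_angles <- c(all_angles, tp$angles)
      next
    }

    ## propose elongation by e for every active tip
    nx <- x + e * dx
    ny <- y + e * dy
    inc <- rep(e, n_act)
    out <- nx^2 + ny^2 > 1
    if (any(out)) {
      ## clip the step to the unit circle: solve |(x,y) + t (dx,dy)| = 1
      xo <- x[out]; yo <- y[out]; dxo <- dx[out]; dyo <- dy[out]
      b <- xo * dxo + yo * dyo
      c0 <- xo^2 + yo^2 - 1
      t_hit <- -b + sqrt(pmax(b^2 - c0, 0))
      t_hit <- pmin(pmax(t_hit, 0), e)
      nx[out] <- xo + t_hit * dxo
      ny[out] <- yo + t_hit * dyo
      inc[out] <- t_hit
    }

    cur_len <- sqrt((nx - ox)^2 + (ny - oy)^2)
    room <- target - mass_done - (sum(cur_len) - sum(inc))
    if (sum(inc) >= room - 1e-12) {
      ## final step: trim increments, in tip order, so total mass is exact
      cum_prev <- cumsum(inc) - inc
      allow <- pmin(inc, pmax(room - cum_prev, 0))
      frac <- ifelse(inc > 0, allow / inc, 0)
      nx <- x + frac * (nx - x)
      ny <- y + frac * (ny - y)
      seg_len <- sqrt((nx - ox)^2 + (ny - oy)^2)
      keep <- seg_len > 0
      done <- rbind(done, cbind(ox, oy, nx, ny, seg_len)[keep, , drop = FALSE])
      return(new_network(done, all_angles, reseeds, gp))
    }

    x <- nx; y <- ny

    ## tips that hit the boundary terminate; bank their segments
    if (any(out)) {
      seg_len <- sqrt((x[out] - ox[out])^2 + (y[out] - oy[out])^2)
      keep <- seg_len > 0
      done <- rbind(done,
                    cbind(ox[out], oy[out], x[out], y[out], seg_len)[keep, , drop = FALSE])
      mass_done <- mass_done + sum(seg_len)
      ox <- ox[!out]; oy <- oy[!out]
      x <- x[!out]; y <- y[!out]; dx <- dx[!out]; dy <- dy[!out]
    }

    ## branching: each surviving tip spawns a new tip with prob 1 - exp(-k)
    n_act <- length(x)
    if (n_act > 0 && p_branch > 0) {
      br <- stats::runif(n_act) < p_branch
      if (any(br)) {
        ang0 <- atan2(dy[br], dx[br])
        dang <- stats::runif(sum(br), -gp$branch_angle_range, gp$branch_angle_range)
        ang1 <- ang0 + dang
        ox <- c(ox, x[br]); oy <- c(oy, y[br])
        x <- c(x, x[br]); y <- c(y, y[br])
        dx <- c(dx, cos(ang1)); dy <- c(dy, sin(ang1))
      }
    }
  }
}

#' Sample points uniformly by arc length on a network
#'
#' Every point of the network is equally likely: a segment is chosen with
#' probability proportional to its length, then a position uniform along
#' it.
#'
#' @param net a `mito_network`.
#' @param n number of points to draw.
#' @return an `n` x 2 matrix of coordinates.
#' @export
sample_network_point <- function(net, n = 1) {
  stopifnot(inherits(net, "mito_network"))
  if (net$total_mass <= 0 || nrow(net$segments) == 0)
    stop("cannot sample from an empty network")
  sg <- net$segments
  idx <- sample.int(nrow(sg), n, replace = TRUE, prob = sg[, "len"])
  t <- stats::runif(n)
  cbind(sg[idx, "x0"] + t * (sg[idx, "x1"] - sg[idx, "x0"]),
        sg[idx, "y0"] + t * (sg[idx, "y1"] - sg[idx, "y0"]))
}

#' Network mass inside an angular sector
#'
#' Total arc length of network falling in the sector
#' `[sector_start, sector_start + sector_angle)` of the unit disc,
#' computed by subdividing each segment to resolution at most the
#' elongation increment `e` and classifying piece midpoints by polar
#' angle. The discretisation error is O(resolution) per sector-boundary
#' crossing.
#'
#' @param net a `mito_network`.
#' @param sector_start start angle (radians).
#' @param sector_angle angular width (radians, in `(0, 2*pi]`).
#' @param resolution subdivision length (default: the generating `e`, or
#'   0.01).
#' @return mass (length in cell radii) in the sector.
#' @export
mass_in_sector <- function(net, sector_start, sector_angle, resolution = NULL) {
  stopifnot(inherits(net, "mito_network"))
  if (!(sector_angle > 0 && sector_angle <= 2 * pi))
    stop("`sector_angle` must be in (0, 2*pi]")
  if (sector_angle == 2 * pi) return(net$total_mass)
  if (is.null(resolution))
    resolution <- if (!is.null(net$params)) net$params$e else 0.01
  sg <- net$segments
  n_sub <- pmax(1L, ceiling(sg[, "len"] / resolution))
  seg_id <- rep.int(seq_len(nrow(sg)), n_sub)
  ## midpoint parameter of each sub-piece along its parent segment
  piece <- sequence(n_sub)
  tmid <- (piece - 0.5) / n_sub[seg_id]
  mx <- sg[seg_id, "x0"] + tmid * (sg[seg_id, "x1"] - sg[seg_id, "x0"])
  my <- sg[seg_id, "y0"] + tmid * (sg[seg_id, "y1"] - sg[seg_id, "y0"])
  plen <- sg[seg_id, "len"] / n_sub[seg_id]
  ang <- wrap_angle(atan2(my, mx))
  inside <- wrap_angle(ang - sector_start) < sector_angle
  sum(plen[inside])
}

#' Deterministic test networks
#'
#' Small closed-form networks used in tests and examples: `"diameter"` is
#' a single chord through the centre (mass 2), `"cross"` two perpendicular
#' diameters (mass 4), `"ring"` a regular polygon inscribed in the circle
#' of radius 1/2 (mass close to pi).
#'
#' @param name one of `"diameter"`, `"cross"`, `"ring"`.
#' @param n_sides number of polygon sides for `"ring"` (default 360).
#' @return a `mito_network`.
#' @export
make_fixture <- function(name = c("diameter", "cross", "ring"), n_sides = 360) {
  name <- match.arg(name)
  seg <- function(x0, y0, x1, y1)
    c(x0, y0, x1, y1, sqrt((x1 - x0)^2 + (y1 - y0)^2))
  m <- switch(name,
    diameter = rbind(seg(-1, 0, 1, 0)),
    cross = rbind(seg(-1, 0, 1, 0), seg(0, -1, 0, 1)),
    ring = {
      th <- 2 * pi * (0:n_sides) / n_sides
      x <- 0.5 * cos(th); y <- 0.5 * sin(th)
      t(vapply(seq_len(n_sides),
               function(i) seg(x[i], y[i], x[i + 1], y[i + 1]),
               numeric(5)))
    })
  new_network(m, seed_angles = numeric(0), reseed_count = 0L)
}

#' @export
print.mito_network <- function(x, ...) {
  cat(sprintf("Mitochondrial network: %d segments, total mass %.4f (cell radii)\n",
              nrow(x$segments), x$total_mass))
  if (!is.null(x$params))
    cat(sprintf("  grown with s = %d seeds, e = %g, k = %g; reseeds: %d\n",
                x$params$s, x$params$e, x$params$k, x$reseed_count))
  invisible(x)
}

#' @export
plot.mito_network <- function(x, ..., col = "forestgreen") {
  th <- seq(0, 2 * pi, length.out = 200)
  plot(cos(th), sin(th), type = "l", asp = 1, xlab = "", ylab = "",
       axes = FALSE, ...)
  segments(x$segments[, "x0"], x$segments[, "y0"],
           x$segments[, "x1"], x$segments[, "y1"], col = col)
  invisible(x)
}

#' Export / import a network as plain text
#'
#' One straight segment per line (`x0 y0 x1 y1`), with a JSON sidecar
#' carrying the generation parameters. Intended for fixtures and
#' debugging, not bulk storage.
#'
#' @param net a `mito_network`.
#' @param path output path for the segment list.
#' @param sidecar optional path for the JSON parameter sidecar.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, sidecar = NULL) {
  stopifnot(inherits(net, "mito_network"))
  utils::write.table(net$segments[, 1:4, drop = FALSE], path,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(mass_target = net$total_mass,
                 reseed_count = net$reseed_count)
    if (!is.null(net$params))
      meta <- c(meta, net$params[c("s", "e", "k")])
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x0", "y0", "x1", "y1")))
  len <- sqrt((m[, "x1"] - m[, "x0"])^2 + (m[, "y1"] - m[, "y0"])^2)
  new_network(cbind(m, len), seed_angles = numeric(0), reseed_count = 0L)
}
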