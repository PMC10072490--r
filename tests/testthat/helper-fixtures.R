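# Shared helpers for building small populations and random model specs.

# A bare population at given coordinates (bypasses placement).
manual_population <- function(x, y, genotype, compartment = "cytoplasm") {
  n <- length(x)
  structure(list(
    molecules = data.frame(x = x, y = y,
                           genotype = rep_len(genotype, n),
                           compartment = rep_len(compartment, n),
                           stringsAsFactors = FALSE),
    relaxations = 0L),
    class = "mito_population")
}

# Random small model spec for oracle cross-validation (integer counts).
random_small_spec <- function(max_N0 = 12, mode = "random") {
  N0 <- sample(4:max_N0, 1)
  h <- runif(1, 0.2, 0.8)
  p <- runif(1)
  q <- runif(1)
  pc <- runif(1, 0.2, 0.8)
  vu <- runif(1, 0.005, 0.8 * pc * (1 - pc))
  if (mode == "repulsive") {
    model_spec(N0, h, p, q, p_c = pc, u_dist = fit_beta(pc, vu),
               mode = "repulsive",
               spaces_total = sample(2:(2 * N0), 1))
  } else {
    model_spec(N0, h, p, q, p_c = pc, u_dist = fit_beta(pc, vu))
  }
}

# Absolute-or-relative closeness used for the 1e-10 / 1e-9 identities.
expect_close <- function(a, b, tol) {
  expect_lt(abs(a - b), tol * max(1, abs(b)))
}

# Standard error of a sample variance from the empirical fourth moment.
var_se_local <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  s2 <- var(x)
  sqrt(max((m4 - s2^2 * (n - 3) / (n - 1)) / n, 0))
}

# Grow a reusable pool of networks once per test run.
network_pool_cache <- new.env(parent = emptyenv())
get_network_pool <- function(s, n, seed = 1000 + s) {
  key <- paste(s, n, seed, sep = "_")
  if (is.null(network_pool_cache[[key]])) {
    network_pool_cache[[key]] <- withr::with_seed(
      seed, replicate(n, grow_network(growth_params(s = s)), simplify = FALSE))
  }
  network_pool_cache[[key]]
}
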