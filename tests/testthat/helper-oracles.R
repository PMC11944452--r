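# Independent brute-force implementations used as oracles for the metric
# suite, plus small fixtures shared across test files. These deliberately
# use naive loops / exhaustive enumeration and never call the package's own
# metric code.

bf_mae <- function(y, z) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - z[i])
  s / length(y)
}

bf_r2 <- function(y, z) {
  ybar <- 0
  for (i in seq_along(y)) ybar <- ybar + y[i]
  ybar <- ybar / length(y)
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - z[i])^2
    ss_tot <- ss_tot + (y[i] - ybar)^2
  }
  1 - ss_res / ss_tot
}

bf_pearson <- function(y, z) {
  n <- length(y)
  my <- sum(y) / n
  mz <- sum(z) / n
  sxy <- sxx <- szz <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - my) * (z[i] - mz)
    sxx <- sxx + (y[i] - my)^2
    szz <- szz + (z[i] - mz)^2
  }
  sxy / sqrt(sxx * szz)
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive optimal transport matching between equal-size samples
bf_w1_exhaustive <- function(p, q) {
  best <- Inf
  for (perm in all_perms(length(p))) {
    cost <- mean(abs(p - q[perm]))
    if (cost < best) best <- cost
  }
  best
}

# unequal sizes: replicate each sample to the least common multiple, which
# makes the empirical distributions equal-weight, then sort and match
bf_w1_lcm <- function(p, q) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  L <- length(p) * length(q) / gcd(length(p), length(q))
  pp <- rep(p, each = L / length(p))
  qq <- rep(q, each = L / length(q))
  mean(abs(sort(pp) - sort(qq)))
}

# A noiseless simulator setup shared by training-oriented tests.
noiseless_params <- function(...) {
  simulator_params(noise_sd_tga = 0, noise_sd_ftir = 0,
                   ftir_replicate_offset_sd = 0, ...)
}

# Oracle-derived training triplets at the given conditions.
oracle_triplets <- function(study, temps) lapply(temps, study$oracle)
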