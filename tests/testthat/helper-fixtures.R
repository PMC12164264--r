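# Shared fixtures and independent oracles used across test files.

# Random work profile on a strictly increasing grid spanning [2.5, 5] A.
random_work_profile <- function(id = "t", n = 40) {
  incr <- runif(n - 1, 0.01, 0.12)
  r <- 2.5 + c(0, cumsum(incr)) * (2.5 / sum(incr))
  work_profile(id, r, cumsum(rnorm(n, sd = 1.5)))
}

# Brute-force Wi oracle: literal double loop over grid indices, the bound
# minimum picked as the smallest-coordinate argmin inside the window.
brute_force_wi <- function(profile, bound_window = c(2.7, 3.3)) {
  r <- profile$coordinate; w <- profile$work
  win <- which(r >= bound_window[1] & r <= bound_window[2])
  i_min <- win[1]
  for (i in win) if (w[i] < w[i_min]) i_min <- i
  best <- -Inf; j_best <- i_min
  for (j in i_min:length(r)) {
    if (w[j] - w[i_min] > best) { best <- w[j] - w[i_min]; j_best <- j }
  }
  list(w_i = best, r_min = r[i_min], r_max = r[j_best])
}

# Direct evaluation of the exponential work average, independent of the
# package's log-sum-exp implementation (safe only for small works).
naive_exponential_average <- function(works, temperature = 300) {
  kT <- 1.9872e-3 * temperature
  -kT * log(mean(exp(-works / kT)))
}

# Minimal ligand table for pairing tests.
toy_records <- function() {
  data.frame(
    ligand_id = c("A", "B", "C"),
    smiles = NA_character_,
    potency_value = c(51.2, 0.494, 5.0),
    potency_units = "nM",
    potency_type = "KD",
    qualifier = "exact",
    stringsAsFactors = FALSE)
}

# Identical fingerprints make every pair pass any similarity cutoff.
uniform_fps <- function(n, nbits = 16) {
  m <- matrix(rep(c(TRUE, FALSE), length.out = nbits), nrow = n,
              ncol = nbits, byrow = TRUE)
  m
}

# Constructed dissociation trajectories with uniform 1-ps sampling.
constructed_trajectory <- function(type = c("one_step", "plateau", "bound"),
                                   plateau_ps = 500) {
  type <- match.arg(type)
  if (type == "one_step") {
    t <- 0:100
    hb <- c(rep(2.9, 50), seq(3, 13, length.out = 51))
    com <- c(rep(0.5, 50), seq(1, 31, length.out = 51))
  } else if (type == "plateau") {
    t <- 0:(100 + plateau_ps)
    hb <- c(rep(2.9, 50), rep(6, plateau_ps), seq(6, 13, length.out = 51))
    com <- c(rep(0.5, 50), rep(3, plateau_ps), seq(8, 31, length.out = 51))
  } else {
    t <- 0:100
    hb <- rep(2.9, 101)
    com <- rep(0.3, 101)
  }
  dissociation_trajectory(t, com, hb, ligand_id = type)
}
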