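test_that("analytic landscape gradients match finite differences", {
  ls1 <- single_barrier_landscape(height = 12)
  h <- 1e-6
  r <- seq(2.5, 5.5, by = 0.17)
  fd <- (landscape_energy(ls1, r + h) - landscape_energy(ls1, r - h)) / (2 * h)
  expect_equal(landscape_gradient(ls1, r), fd, tolerance = 1e-6)

  ls2 <- multistep_landscape()
  com <- seq(0, 8, by = 0.43); hb <- seq(2, 10, by = 0.43)[seq_along(com)]
  g <- landscape_gradient(ls2, com, hb)
  fd_com <- (landscape_energy(ls2, com + h, hb) -
               landscape_energy(ls2, com - h, hb)) / (2 * h)
  fd_hb <- (landscape_energy(ls2, com, hb + h) -
              landscape_energy(ls2, com, hb - h)) / (2 * h)
  expect_equal(unname(g[, "com"]), fd_com, tolerance = 1e-6)
  expect_equal(unname(g[, "hb"]), fd_hb, tolerance = 1e-6)
})

test_that("pulling on a flat landscape accumulates almost no quasi-bound work", {
  flat <- landscape_spec(data.frame(center = 4, height = 0, width = 0.5))
  profs <- brownian_smd(flat, smd_protocol(speed = 0.5),
                        n_trajectories = 120, seed = 3)
  dg <- jarzynski_free_energy(extract_quasi_bound_works(profs)$w_i)
  expect_lte(abs(dg), 0.5)
})

test_that("pulling is bit-reproducible per seed and trajectory index", {
  ls1 <- single_barrier_landscape()
  a <- brownian_smd(ls1, n_trajectories = 3, seed = 5)
  b <- brownian_smd(ls1, n_trajectories = 3, seed = 5)
  for (i in 1:3) expect_identical(a[[i]]$work, b[[i]]$work)
  # trajectory i depends only on seed + i - 1, not on the batch
  c4 <- brownian_smd(ls1, n_trajectories = 1, seed = 7)
  d4 <- brownian_smd(ls1, n_trajectories = 3, seed = 5)
  expect_identical(c4[[1]]$work, d4[[3]]$work)
})

test_that("an unstable time step is refused with advice", {
  steep <- landscape_spec(data.frame(center = 4, height = 40, width = 0.2))
  expect_error(brownian_smd(steep, n_trajectories = 1, seed = 1, dt = 0.5),
               "reduce dt")
})

test_that("a fixed restraint accumulates exactly zero work and samples Boltzmann", {
  ls1 <- single_barrier_landscape()
  eq <- equilibrium_sample(ls1, r_center = 2.5, duration_ps = 2000,
                           record_stride = 100, seed = 2)
  expect_true(all(eq$work == 0))

  # binned positions vs the analytic Boltzmann weight of G + spring
  kT <- KB_KCAL * 300
  ok <- 0
  for (s in 1:3) {
    eq <- equilibrium_sample(ls1, r_center = 2.5, duration_ps = 2000,
                             record_stride = 100, seed = s)
    breaks <- quantile(eq$position, probs = seq(0, 1, 0.1))
    breaks[1] <- -Inf; breaks[11] <- Inf
    obs <- table(cut(eq$position, breaks))
    grid <- seq(1.5, 3.5, length.out = 4000)
    dens <- exp(-(landscape_energy(ls1, grid) +
                    25 * (grid - 2.5)^2) / kT)
    cdf <- cumsum(dens) / sum(dens)
    pr <- diff(c(0, approx(grid, cdf, xout = breaks[2:10],
                           yleft = 0, yright = 1)$y, 1))
    p <- suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value)
    if (p > 0.001) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("the Jarzynski estimate respects the second-law bound on the landscape", {
  # exact restrained free-energy profile via numerical integration
  ls1 <- single_barrier_landscape(height = 10)
  kT <- KB_KCAL * 300
  grid <- seq(1.5, 6, length.out = 3000)
  fr <- function(rc) {
    u <- landscape_energy(ls1, grid) + 25 * (grid - rc)^2
    -kT * log(sum(exp(-(u - min(u)) / kT))) + min(u)
  }
  rc <- seq(2.5, 5, length.out = 120)
  prof_f <- vapply(rc, fr, numeric(1))
  in_win <- rc >= 2.7 & rc <= 3.3
  df_exact <- max(prof_f[which(in_win)[which.min(prof_f[in_win])]:length(rc)]) -
    min(prof_f[in_win])

  profs <- brownian_smd(ls1, smd_protocol(speed = 0.5),
                        n_trajectories = 120, seed = 21)
  wi <- extract_quasi_bound_works(profs)$w_i
  dg <- jarzynski_free_energy(wi)
  s <- bootstrap_uncertainty(wi, jarzynski_config(seed = 21))
  expect_gte(dg, df_exact - 3 * s)
})

test_that("RAMD-like runs terminate at the stop distance or flag truncation", {
  tr <- simulate_ramd_like(one_step_landscape(), seed = 2)
  expect_false(attr(tr, "truncated"))
  expect_gte(max(tr$com_displacement_A), 30)
  expect_true(all(diff(tr$time_ps) > 0))

  # a vanishing force on a deep well cannot reach the stop distance
  deep <- one_step_landscape(depth = 30)
  weak <- ramd_protocol(force_magnitude = 1e-6, max_steps = 20000L)
  tr2 <- simulate_ramd_like(deep, weak, seed = 3)
  expect_true(attr(tr2, "truncated"))
  expect_lt(max(tr2$com_displacement_A), 30)
})

test_that("mechanism classes are recovered from their generating landscapes", {
  # a reduced-seed version of the 50-replicate recovery check
  one <- vapply(1:12, function(s) detect_metastable_intermediate(
    simulate_ramd_like(one_step_landscape(), seed = s))$intermediate,
    logical(1))
  multi <- vapply(1:12, function(s) detect_metastable_intermediate(
    simulate_ramd_like(multistep_landscape(), seed = s))$intermediate,
    logical(1))
  expect_lte(mean(one), 0.1)
  expect_gte(mean(multi), 0.9)
})

test_that("synthetic series reproduce their kinetics model exactly where degenerate", {
  # constant on-rates make potency a monotone function of the barrier
  sp <- series_spec(n_ligands = 25, kon_log10_sd = 0, seed = 4)
  series <- generate_congeneric_series(sp)
  pkd <- -log10(potency_to_molar(series$records$potency_value,
                                 series$records$potency_units))
  expect_equal(cor(series$barriers, pkd, method = "spearman"), 1)

  # identical barriers admit no cliffs at all
  sp0 <- series_spec(n_ligands = 10, barrier_sd = 0, seed = 5)
  s0 <- generate_congeneric_series(sp0)
  pairs <- build_pairs(s0$records, cliff_criteria(similarity_cutoff = 0),
                       fingerprints = s0$fingerprints)
  expect_false(any(pairs$is_cliff))

  expect_error(series_spec(prefactor = -1))
})

test_that("series generation recovers its on-rate dispersion and is seeded", {
  sp <- series_spec(n_ligands = 10000, kon_log10_sd = 0.2, seed = 6)
  series <- generate_congeneric_series(sp)
  expect_equal(sd(log10(series$records$k_on)), 0.2, tolerance = 0.05)

  a <- generate_congeneric_series(series_spec(n_ligands = 6, seed = 7))
  b <- generate_congeneric_series(series_spec(n_ligands = 6, seed = 7))
  expect_identical(a$records, b$records)
  expect_identical(a$fingerprints, b$fingerprints)

  # the attached landscape barrier equals the ground-truth barrier
  expect_equal(max(landscape_energy(a$landscapes[[1]],
                                    seq(2.5, 6, by = 0.001))),
               unname(a$barriers[1]), tolerance = 1e-3)
})
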