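#' Constant-velocity pulling protocol
#'
#' The steered-pulling protocol: the H-bond coordinate's restraint centre is
#' moved from `r_start` to `r_end` at constant `speed` with spring constant
#' `spring_k`. Defaults mirror the standard dynamic-undocking run: 2.5 to
#' 5 Angstrom at 5 Angstrom/ns (500 ps) with 50 kcal mol-1 A-2.
#'
#' @param r_start,r_end Angstrom.
#' @param speed Angstrom per ns.
#' @param spring_k kcal mol-1 A-2.
#' @param temperature kelvin.
#' @return list of class `smd_protocol`; `duration_ps` is derived.
#' @export
smd_protocol <- function(r_start = 2.5, r_end = 5, speed = 5, spring_k = 50,
                         temperature = 300) {
  stopifnot(r_end > r_start, speed > 0, spring_k > 0, temperature > 0)
  structure(list(r_start = r_start, r_end = r_end, speed = speed,
                 spring_k = spring_k, temperature = temperature,
                 duration_ps = (r_end - r_start) / speed * 1000),
            class = "smd_protocol")
}

#' Random-acceleration dissociation protocol
#'
#' A constant-magnitude, randomly oriented force is applied to the ligand
#' centroid; whenever the centroid moves less than `min_displacement` over
#' one `check_interval`, the force direction is re-drawn. The run stops when
#' the centroid displacement reaches `stop_distance` or at `max_steps`.
#' Defaults: 16 kcal mol-1 A-1, checks every 100 fs against 0.025 Angstrom,
#' stop at 30 Angstrom.
#'
#' @param force_magnitude kcal mol-1 A-1.
#' @param check_interval_fs fs.
#' @param min_displacement Angstrom.
#' @param stop_distance Angstrom.
#' @param max_steps integer cap on integration steps (default 300000, i.e.
#'   3 ns at the default 10-fs step).
#' @param temperature kelvin.
#' @return list of class `ramd_protocol`.
#' @export
ramd_protocol <- function(force_magnitude = 16, check_interval_fs = 100,
                          min_displacement = 0.025, stop_distance = 30,
                          max_steps = 300000L, temperature = 300) {
  stopifnot(force_magnitude > 0, check_interval_fs > 0, min_displacement > 0,
            stop_distance > 0, max_steps > 0)
  structure(list(force_magnitude = force_magnitude,
                 check_interval_fs = check_interval_fs,
                 min_displacement = min_displacement,
                 stop_distance = stop_distance,
                 max_steps = as.integer(max_steps),
                 temperature = temperature),
            class = "ramd_protocol")
}

#' Analytic Gaussian free-energy landscape
#'
#' A sum of Gaussian wells (negative height) and barriers (positive height).
#' One-dimensional terms need columns `center`, `height`, `width`;
#' two-dimensional terms (over centroid displacement and H-bond distance)
#' need `center_com`, `center_hb`, `height`, `width_com`, `width_hb`.
#'
#' @param terms data.frame of Gaussian terms as above.
#' @param diffusion diffusion coefficient, A^2/ps.
#' @param start optional named start point for simulations (`c(com=, hb=)`
#'   for 2-D, a scalar for 1-D).
#' @return list of class `landscape_spec` with `dimensionality` inferred.
#' @export
landscape_spec <- function(terms, diffusion = 0.1, start = NULL) {
  stopifnot(is.data.frame(terms), nrow(terms) >= 1L, diffusion > 0)
  if (all(c("center", "height", "width") %in% names(terms))) {
    dim <- 1L
    stopifnot(all(terms$width > 0))
  } else if (all(c("center_com", "center_hb", "height", "width_com",
                   "width_hb") %in% names(terms))) {
    dim <- 2L
    stopifnot(all(terms$width_com > 0), all(terms$width_hb > 0))
  } else {
    stop("terms must have 1-D (center, height, width) or 2-D ",
         "(center_com, center_hb, height, width_com, width_hb) columns")
  }
  structure(list(terms = terms, dimensionality = dim, diffusion = diffusion,
                 start = start),
            class = "landscape_spec")
}

#' Evaluate a landscape's free energy
#'
#' @param landscape a [landscape_spec()].
#' @param r coordinate (1-D) or centroid displacement (2-D), vectorized.
#' @param hb H-bond distance for 2-D landscapes.
#' @return G in kcal/mol.
#' @export
landscape_energy <- function(landscape, r, hb = NULL) {
  tm <- landscape$terms
  g <- numeric(length(r))
  if (landscape$dimensionality == 1L) {
    for (k in seq_len(nrow(tm)))
      g <- g + tm$height[k] * exp(-0.5 * ((r - tm$center[k]) / tm$width[k])^2)
  } else {
    stopifnot(!is.null(hb), length(hb) == length(r))
    for (k in seq_len(nrow(tm)))
      g <- g + tm$height[k] *
        exp(-0.5 * (((r - tm$center_com[k]) / tm$width_com[k])^2 +
                      ((hb - tm$center_hb[k]) / tm$width_hb[k])^2))
  }
  g
}

#' Analytic gradient of a landscape
#'
#' @inheritParams landscape_energy
#' @return for 1-D, dG/dr; for 2-D, a matrix with columns `com`, `hb`.
#' @export
landscape_gradient <- function(landscape, r, hb = NULL) {
  tm <- landscape$terms
  if (landscape$dimensionality == 1L) {
    g <- numeric(length(r))
    for (k in seq_len(nrow(tm))) {
      z <- (r - tm$center[k]) / tm$width[k]
      g <- g - tm$height[k] * z / tm$width[k] * exp(-0.5 * z^2)
    }
    g
  } else {
    stopifnot(!is.null(hb), length(hb) == length(r))
    gx <- numeric(length(r)); gy <- numeric(length(r))
    for (k in seq_len(nrow(tm))) {
      zx <- (r - tm$center_com[k]) / tm$width_com[k]
      zy <- (hb - tm$center_hb[k]) / tm$width_hb[k]
      e <- tm$height[k] * exp(-0.5 * (zx^2 + zy^2))
      gx <- gx - e * zx / tm$width_com[k]
      gy <- gy - e * zy / tm$width_hb[k]
    }
    cbind(com = gx, hb = gy)
  }
}

#' Single-barrier 1-D landscape
#'
#' One Gaussian barrier between the bound basin and the quasi-bound plateau;
#' the notional transition-state barrier height is the ground truth that the
#' pulling + Jarzynski pipeline should recover. The default geometry keeps
#' the barrier's peak curvature (`height / width^2`) below the pulling
#' protocol's 50 kcal mol-1 A-2 spring constant — a harmonic restraint cannot
#' resolve features sharper than its own curvature — while leaving the bound
#' window around 3 Angstrom essentially flat.
#'
#' @param height kcal/mol (default 10).
#' @param center Angstrom (default 4.5).
#' @param width Angstrom (default 0.55).
#' @param diffusion A^2/ps.
#' @return a [landscape_spec()].
#' @export
single_barrier_landscape <- function(height = 10, center = 4.5, width = 0.55,
                                     diffusion = 0.1) {
  landscape_spec(data.frame(center = center, height = height, width = width),
                 diffusion = diffusion, start = 2.5)
}

# 2-D dissociation landscapes share a bound well at (com 0, hb 2.9 A, an
# optimal H-bond). With diffusion 0.1 A^2/ps the drift of a freely pulled
# ligand over one 100-fs check (~0.27 A) clearly exceeds the 0.025-A
# displacement heuristic while a trapped ligand's net movement falls below
# it every few ps, so the direction re-randomization behaves as intended.

#' One-step dissociation landscape (2-D)
#'
#' A single bound well coupling the centroid and the H-bond: once the H-bond
#' breaks, nothing holds the ligand and pocket exit is immediate (rupture and
#' departure are concerted).
#'
#' @param depth well depth, kcal/mol (positive number; stored negative).
#'   The default 10 gives a peak restoring gradient just below the 16
#'   kcal mol-1 A-1 dissociation force, so rupture is quick once the force
#'   points outward.
#' @param diffusion A^2/ps.
#' @return a [landscape_spec()] with a `start` at the bound well.
#' @export
one_step_landscape <- function(depth = 10, diffusion = 0.1) {
  landscape_spec(
    data.frame(center_com = 0, center_hb = 2.9, height = -depth,
               width_com = 0.7, width_hb = 0.4),
    diffusion = diffusion, start = c(com = 0, hb = 2.9))
}

#' Multistep dissociation landscape (2-D)
#'
#' The bound well plus a metastable intermediate in which the H-bond is
#' already broken (hb around 5.5 Angstrom) while the centroid is still in
#' the pocket (com around 2.5 Angstrom), flanked by two steep ridges that
#' close the exit channels with an intact (low hb) or fully extended (high
#' hb) H-bond coordinate. Against a constant pulling force a barrier only
#' blocks where its gradient exceeds the force, so the ridges are tall and
#' narrow (peak gradient about 19 kcal mol-1 A-1 versus the 16 kcal mol-1
#' A-1 dissociation force); dissociation must pass through, and dwell in,
#' the intermediate valley before the ligand leaves.
#'
#' @param depth bound-well depth, kcal/mol.
#' @param intermediate_depth depth of the metastable well, kcal/mol; the
#'   default holds the ligand for hundreds of ps to nanoseconds against the
#'   dissociation force.
#' @param ridge_height height of the channel-blocking ridges, kcal/mol.
#' @param diffusion A^2/ps.
#' @return a [landscape_spec()] with a `start` at the bound well.
#' @export
multistep_landscape <- function(depth = 10, intermediate_depth = 52,
                                ridge_height = 32, diffusion = 0.1) {
  landscape_spec(
    data.frame(center_com = c(0, 2.5, 3.5, 4.0),
               center_hb = c(2.9, 5.5, 2.9, 9),
               height = c(-depth, -intermediate_depth, ridge_height,
                          ridge_height),
               width_com = c(0.7, 1.5, 1.0, 1.0),
               width_hb = c(0.4, 1.3, 1.8, 2.5)),
    diffusion = diffusion, start = c(com = 0, hb = 2.9))
}

#' Brownian-dynamics constant-velocity pulling
#'
#' Simulates overdamped (Brownian) dynamics on
#' `G(r) + (k/2) (r - r_c(t))^2` with the restraint centre moved at constant
#' speed, `r_c(t) = r_start + speed * t`, accumulating the external work
#' `dW = k (r_c - r) dr_c`. Each trajectory first equilibrates in the
#' restrained bound basin (`equil_ps`, restraint fixed at `r_start`), so
#' starting configurations are drawn from the bound-state distribution. Work
#' profiles are sampled on a fixed grid of restraint-centre positions and are
#' bit-identical for a fixed seed (trajectory i uses seed `seed + i - 1`).
#'
#' @param landscape a 1-D [landscape_spec()].
#' @param protocol an [smd_protocol()].
#' @param n_trajectories number of pulling cycles (default 120).
#' @param dt integration step, ps (default 0.01, i.e. 10 fs); too large a
#'   step (deterministic drift above 0.1 Angstrom per step) raises an error.
#' @param seed integer.
#' @param n_points approximate number of recorded grid points per profile.
#' @param equil_ps equilibration time before pulling starts.
#' @return list of [work_profile()] objects.
#' @export
brownian_smd <- function(landscape, protocol = smd_protocol(),
                         n_trajectories = 120, dt = 0.01, seed = 1,
                         n_points = 250, equil_ps = 20) {
  stopifnot(inherits(landscape, "landscape_spec"),
            landscape$dimensionality == 1L,
            inherits(protocol, "smd_protocol"))
  n_steps <- as.integer(round(protocol$duration_ps / dt))
  n_equil <- as.integer(round(equil_ps / dt))
  stride <- max(1L, n_steps %/% as.integer(n_points))
  speed_ps <- protocol$speed / 1000
  tm <- landscape$terms
  lapply(seq_len(n_trajectories), function(i) {
    set.seed(seed + i - 1L)
    sim <- cpp_brownian_pull(tm$center, tm$height, tm$width,
                             protocol$r_start, speed_ps, protocol$spring_k,
                             protocol$temperature, landscape$diffusion,
                             dt, n_steps, n_equil, stride, KB_KCAL)
    work_profile(sprintf("traj%04d", i), sim$coordinate, sim$work,
                 required_span = NULL)
  })
}

#' Equilibrium sampling under a fixed restraint
#'
#' Runs the same Brownian integrator with the restraint centre held fixed
#' (zero pulling speed): positions sample the Boltzmann distribution of
#' `G(r) + (k/2)(r - r_center)^2` and the accumulated pulling work is exactly
#' zero by construction.
#'
#' @param landscape a 1-D [landscape_spec()].
#' @param r_center restraint centre, Angstrom.
#' @param spring_k kcal mol-1 A-2 (0 = unrestrained).
#' @param temperature kelvin.
#' @param duration_ps sampled time after `equil_ps` of equilibration.
#' @param dt ps.
#' @param seed integer.
#' @param record_stride record every this many steps.
#' @param equil_ps equilibration time.
#' @return list with `position` (numeric vector) and `work` (numeric vector,
#'   identically zero).
#' @export
equilibrium_sample <- function(landscape, r_center, spring_k = 50,
                               temperature = 300, duration_ps = 1000,
                               dt = 0.01, seed = 1, record_stride = 10,
                               equil_ps = 50) {
  stopifnot(landscape$dimensionality == 1L)
  tm <- landscape$terms
  set.seed(seed)
  sim <- cpp_brownian_pull(tm$center, tm$height, tm$width, r_center, 0,
                           spring_k, temperature, landscape$diffusion, dt,
                           as.integer(round(duration_ps / dt)),
                           as.integer(round(equil_ps / dt)),
                           as.integer(record_stride), KB_KCAL)
  list(position = sim$position, work = sim$work)
}

#' RAMD-like forced-dissociation simulation
#'
#' Overdamped dynamics on a 2-D landscape over (centroid displacement,
#' H-bond distance) plus a constant-magnitude external force of random
#' orientation, re-drawn whenever the displacement over one check interval
#' falls below the protocol's heuristic. The centroid displacement reflects
#' at zero and the H-bond distance at `hb_min` (van der Waals contact).
#' Terminates when the centroid reaches `stop_distance` or at `max_steps`
#' (then flagged truncated).
#'
#' @param landscape a 2-D [landscape_spec()].
#' @param protocol a [ramd_protocol()].
#' @param seed integer.
#' @param start named numeric `c(com=, hb=)`; default the landscape's own
#'   start point.
#' @param dt ps.
#' @param record_stride record every this many steps.
#' @param hb_min lower reflecting bound for the donor-acceptor distance,
#'   Angstrom (default 2, about van der Waals contact).
#' @return a [dissociation_trajectory()] (attribute `truncated` set when the
#'   step cap was hit).
#' @export
simulate_ramd_like <- function(landscape, protocol = ramd_protocol(),
                               seed = 1, start = landscape$start, dt = 0.01,
                               record_stride = 10L, hb_min = 2) {
  stopifnot(inherits(landscape, "landscape_spec"),
            landscape$dimensionality == 2L,
            inherits(protocol, "ramd_protocol"))
  if (is.null(start)) stop("no start point: supply start = c(com=, hb=)")
  tm <- landscape$terms
  set.seed(seed)
  sim <- cpp_ramd_2d(tm$center_com, tm$center_hb, tm$height, tm$width_com,
                     tm$width_hb, start[["com"]], start[["hb"]],
                     protocol$force_magnitude,
                     protocol$check_interval_fs / 1000,
                     protocol$min_displacement, protocol$stop_distance, dt,
                     protocol$max_steps, protocol$temperature,
                     landscape$diffusion, as.integer(record_stride), KB_KCAL,
                     hb_min)
  # recorded times can repeat the terminal point on the stride boundary
  keep <- !duplicated(sim$time)
  dissociation_trajectory(sim$time[keep], sim$com[keep], sim$hb[keep],
                          ligand_id = sprintf("ramd_seed%d", seed),
                          truncated = sim$truncated)
}

#' Specification of a synthetic congeneric ligand series
#'
#' Emulates a congeneric series with barrier-controlled off-rates and roughly
#' constant on-rates: per ligand, a dissociation barrier
#' `dG' ~ Normal(barrier_mean, barrier_sd)` sets
#' `k_off = prefactor * exp(-dG'/(kB*T))`; `log10 k_on ~ Normal(kon_log10_mean,
#' kon_log10_sd)`; `K_D = k_off / k_on`. Structural similarity is emulated by
#' a shared scaffold bit template with a few per-ligand bit flips.
#'
#' @param n_ligands at least 2 (default 50).
#' @param barrier_mean,barrier_sd kcal/mol (defaults 20 and 2, putting
#'   off-rates in the 1e-3..1 s-1 range typical of drug-like binders).
#' @param kon_log10_mean,kon_log10_sd log10 of M-1 s-1 (defaults 6 and 0.2:
#'   "relatively constant" on-rates around 1e6).
#' @param prefactor Arrhenius prefactor, s-1 (default 6.2e12, about kT/h at
#'   300 K).
#' @param temperature kelvin.
#' @param n_bits fingerprint length (default 166).
#' @param template_density fraction of template bits set (default 0.35).
#' @param n_flips per-ligand bit flips from the template (default 6).
#' @param seed integer.
#' @return list of class `series_spec`.
#' @export
series_spec <- function(n_ligands = 50, barrier_mean = 20, barrier_sd = 2,
                        kon_log10_mean = 6, kon_log10_sd = 0.2,
                        prefactor = 6.2e12, temperature = 300,
                        n_bits = 166, template_density = 0.35, n_flips = 6,
                        seed = 1) {
  stopifnot(n_ligands >= 2, barrier_sd >= 0, kon_log10_sd >= 0,
            prefactor > 0, n_flips < n_bits)
  structure(as.list(environment()), class = "series_spec")
}

#' Generate a synthetic congeneric series with known ground truth
#'
#' Draws per-ligand barriers and on-rates per [series_spec()], converts them
#' to `k_off`, `k_on` and `K_D`, builds template-derived fingerprints, and
#' attaches a 1-D pulling landscape per ligand whose Gaussian barrier equals
#' the ligand's true dissociation barrier, so that [brownian_smd()] plus
#' [jarzynski_free_energy()] can recover it end to end.
#'
#' @param spec a [series_spec()].
#' @return list with `records` (ligand table: ligand_id, smiles = NA,
#'   potency_value/units/type (K_D in nM), qualifier, k_on, k_off,
#'   series_id), `fingerprints` (logical matrix, rows named by ligand),
#'   `barriers` (named numeric, the ground-truth dG'), `landscapes` (named
#'   list of 1-D [landscape_spec()]).
#' @export
generate_congeneric_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed)
  n <- spec$n_ligands
  ids <- sprintf("SYN%03d", seq_len(n))
  barrier <- rnorm(n, spec$barrier_mean, spec$barrier_sd)
  barrier <- pmax(barrier, 1)               # a barrier below 1 kcal/mol is unphysical here
  kT <- KB_KCAL * spec$temperature
  k_off <- spec$prefactor * exp(-barrier / kT)
  k_on <- 10^rnorm(n, spec$kon_log10_mean, spec$kon_log10_sd)
  kd_M <- k_off / k_on

  template <- runif(spec$n_bits) < spec$template_density
  fps <- t(vapply(seq_len(n), function(i) {
    f <- template
    flip <- sample.int(spec$n_bits, spec$n_flips)
    f[flip] <- !f[flip]
    f
  }, logical(spec$n_bits)))
  rownames(fps) <- ids

  records <- data.frame(
    ligand_id = ids, smiles = NA_character_,
    potency_value = kd_M * 1e9, potency_units = "nM", potency_type = "KD",
    qualifier = "exact", k_on = k_on, k_off = k_off,
    series_id = "synthetic", stringsAsFactors = FALSE)
  # wider barrier than the 10-kcal default so that the 50 kcal/mol/A^2
  # pulling spring resolves the 14-26 kcal/mol series barriers equally well
  landscapes <- setNames(lapply(barrier, function(b)
    single_barrier_landscape(height = b, center = 4.6, width = 0.75)), ids)
  list(records = records, fingerprints = fps,
       barriers = setNames(barrier, ids), landscapes = landscapes)
}
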