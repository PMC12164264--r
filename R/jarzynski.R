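#' Configuration for the Jarzynski estimator
#'
#' @param temperature simulation temperature in kelvin (default 300, matching
#'   the pulling protocol).
#' @param n_resamples number of bootstrap subsamples (default 100).
#' @param subsample_size trajectories per subsample (default 40).
#' @param seed integer seed for the bootstrap; `NULL` uses the current RNG
#'   state.
#' @param replace draw subsamples with replacement? The protocol draws 40
#'   distinct trajectories out of 120, so the default is `FALSE`.
#' @param kB Boltzmann constant, kcal mol-1 K-1.
#' @return list of class `jarzynski_config`.
#' @export
jarzynski_config <- function(temperature = 300, n_resamples = 100,
                             subsample_size = 40, seed = NULL,
                             replace = FALSE, kB = KB_KCAL) {
  stopifnot(temperature > 0, n_resamples >= 1, subsample_size >= 1)
  structure(list(temperature = temperature, n_resamples = n_resamples,
                 subsample_size = subsample_size, seed = seed,
                 replace = replace, kB = kB),
            class = "jarzynski_config")
}

#' Jarzynski free energy from a nonequilibrium work sample
#'
#' Evaluates the exponential work average
#' `dG = -kB*T * log( (1/N) * sum_i exp(-W_i / (kB*T)) )`,
#' shifted by `min(works)` before exponentiating (log-sum-exp) so that large
#' work values (25 kcal/mol and beyond at 300 K) do not underflow.
#'
#' The estimate always lies between `min(works)` and `mean(works)` (Jensen's
#' inequality); it tends to the mean as T grows and to the minimum as T
#' approaches zero.
#'
#' @param works numeric vector of per-trajectory work values, kcal/mol.
#' @param temperature kelvin.
#' @param kB Boltzmann constant, kcal mol-1 K-1.
#' @return free energy in kcal/mol.
#' @export
jarzynski_free_energy <- function(works, temperature = 300, kB = KB_KCAL) {
  works <- as.numeric(works)
  if (length(works) == 0L) stop("empty work sample")
  if (!all(is.finite(works))) stop("work sample contains non-finite values")
  kT <- kB * temperature
  w0 <- min(works)
  w0 - kT * log(mean(exp(-(works - w0) / kT)))
}

#' Bootstrap standard deviation of the Jarzynski estimate
#'
#' Resamples the work set in `n_resamples` random subsamples of
#' `subsample_size` trajectories (the protocol uses 100 subsamples of 40 out
#' of 120), recomputes the free energy on each, and returns the population
#' (ddof 0) standard deviation of the resampled estimates. Reproducible for a
#' fixed `config$seed`.
#'
#' @param works numeric vector of work values, kcal/mol.
#' @param config a [jarzynski_config()].
#' @return standard deviation in kcal/mol.
#' @export
bootstrap_uncertainty <- function(works, config = jarzynski_config()) {
  works <- as.numeric(works)
  if (!all(is.finite(works))) stop("work sample contains non-finite values")
  m <- config$subsample_size
  if (!config$replace && length(works) < m)
    stop("sample of ", length(works), " works is smaller than subsample_size = ",
         m, "; lower subsample_size")
  if (!is.null(config$seed)) set.seed(config$seed)
  est <- vapply(seq_len(config$n_resamples), function(i) {
    jarzynski_free_energy(sample(works, m, replace = config$replace),
                          config$temperature, config$kB)
  }, numeric(1L))
  sqrt(mean((est - mean(est))^2))
}

#' Running free-energy estimate vs. number of trajectories
#'
#' Computes the Jarzynski estimate on the first n works for n = 1..N, as a
#' convergence diagnostic for the number of pulling cycles. The curve is
#' flagged converged when the running estimates over the last quarter of the
#' sample vary (max - min) by less than `tol`.
#'
#' @param works numeric vector, in acquisition order.
#' @param temperature kelvin.
#' @param tol convergence tolerance, kcal/mol (default 0.5).
#' @param kB Boltzmann constant.
#' @return data.frame with columns `n`, `dg_qb` and attribute `converged`.
#' @export
convergence_curve <- function(works, temperature = 300, tol = 0.5,
                              kB = KB_KCAL) {
  works <- as.numeric(works)
  if (length(works) < 2L) stop("need at least two works for a convergence curve")
  ns <- seq_along(works)
  dg <- vapply(ns, function(n)
    jarzynski_free_energy(works[seq_len(n)], temperature, kB), numeric(1L))
  out <- data.frame(n = ns, dg_qb = dg)
  last_q <- dg[ns >= ceiling(3 * length(works) / 4)]
  attr(out, "converged") <- (max(last_q) - min(last_q)) < tol
  out
}

#' Quasi-bound free-energy estimate for one ligand
#'
#' Bundles the Jarzynski free energy, its bootstrap standard deviation and
#' the underlying Wi sample.
#'
#' @param ligand_id character scalar.
#' @param works numeric vector of quasi-bound works Wi, kcal/mol.
#' @param config a [jarzynski_config()].
#' @return object of class `quasi_bound_estimate`: list with `ligand_id`,
#'   `dg_qb`, `sd`, `n_trajectories`, `works`.
#' @export
quasi_bound_estimate <- function(ligand_id, works,
                                 config = jarzynski_config()) {
  dg <- jarzynski_free_energy(works, config$temperature, config$kB)
  s <- if (length(works) >= config$subsample_size || config$replace)
    bootstrap_uncertainty(works, config) else NA_real_
  structure(list(ligand_id = ligand_id, dg_qb = dg, sd = s,
                 n_trajectories = length(works), works = as.numeric(works)),
            class = "quasi_bound_estimate")
}

#' @export
print.quasi_bound_estimate <- function(x, ...) {
  cat("<quasi_bound_estimate> ", x$ligand_id, ": dG_QB = ",
      signif(x$dg_qb, 4), " +/- ", signif(x$sd, 3), " kcal/mol (N = ",
      x$n_trajectories, ")\n", sep = "")
  invisible(x)
}

#' Tabulate quasi-bound estimates
#'
#' @param estimates list of [quasi_bound_estimate()] objects.
#' @return data.frame with columns `ligand_id`, `dg_qb`, `sd`,
#'   `n_trajectories`.
#' @export
estimates_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(ligand_id = e$ligand_id, dg_qb = e$dg_qb, sd = e$sd,
               n_trajectories = e$n_trajectories, stringsAsFactors = FALSE)))
}
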