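#' Construct a dissociation trajectory
#'
#' A reduced 2-D view of one forced-unbinding trajectory: the ligand
#' centroid's displacement from its starting position and the key H-bond
#' donor-acceptor distance, both in Angstrom, as functions of time in ps.
#'
#' @param time_ps increasing numeric vector.
#' @param com_displacement_A,hbond_distance_A non-negative numeric vectors,
#'   same length as `time_ps`.
#' @param ligand_id character scalar.
#' @param truncated logical: did the simulation hit its step cap before the
#'   ligand left?
#' @return data.frame of class `dissociation_trajectory`.
#' @export
dissociation_trajectory <- function(time_ps, com_displacement_A,
                                    hbond_distance_A, ligand_id = "ligand",
                                    truncated = FALSE) {
  n <- length(time_ps)
  if (n == 0L) stop("empty trajectory")
  if (length(com_displacement_A) != n || length(hbond_distance_A) != n)
    stop("time, centroid and H-bond series must have equal lengths")
  if (any(diff(time_ps) <= 0)) stop("time must be strictly increasing")
  if (any(com_displacement_A < 0) || any(hbond_distance_A < 0))
    stop("distances must be non-negative")
  out <- data.frame(time_ps = time_ps,
                    com_displacement_A = com_displacement_A,
                    hbond_distance_A = hbond_distance_A)
  attr(out, "ligand_id") <- ligand_id
  attr(out, "truncated") <- truncated
  class(out) <- c("dissociation_trajectory", "data.frame")
  out
}

#' Read a dissociation trajectory from CSV
#'
#' Expects columns `time_ps`, `com_displacement_A`, `hbond_distance_A`.
#'
#' @param path CSV file.
#' @param ligand_id defaults to the file name.
#' @return a [dissociation_trajectory()].
#' @export
read_dissociation_trajectory <- function(path,
                                         ligand_id = sub("\\.[^.]*$", "",
                                                         basename(path))) {
  df <- read.csv(path)
  need <- c("time_ps", "com_displacement_A", "hbond_distance_A")
  if (!all(need %in% names(df)))
    stop("file '", path, "' must have columns ", paste(need, collapse = ", "))
  dissociation_trajectory(df$time_ps, df$com_displacement_A,
                          df$hbond_distance_A, ligand_id)
}

#' Detect a metastable intermediate along a dissociation trajectory
#'
#' A multistep dissociation shows a delay between rupture of the main H-bond
#' and the ligand actually leaving the pocket. The detector accumulates the
#' time spent with the H-bond broken (`hbond_distance > hb_broken`) while the
#' centroid is still near its bound position (`com_displacement < com_bound`)
#' and calls an intermediate when that dwell exceeds `dwell_min`. The three
#' cutoffs are heuristic interpretations of a qualitative picture and are
#' deliberately configurable.
#'
#' @param traj a [dissociation_trajectory()].
#' @param hb_broken Angstrom; H-bond considered broken beyond this distance
#'   (default 5).
#' @param com_bound Angstrom; ligand considered still in the pocket below
#'   this displacement (default 7.5).
#' @param dwell_min ps; minimal dwell to call an intermediate (default 100).
#' @return list with `intermediate` (logical) and `dwell_ps`.
#' @export
detect_metastable_intermediate <- function(traj, hb_broken = 5,
                                           com_bound = 7.5, dwell_min = 100) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  cond <- traj$hbond_distance_A > hb_broken &
    traj$com_displacement_A < com_bound
  if (nrow(traj) == 1L) {
    dwell <- 0
  } else {
    dt <- diff(traj$time_ps)
    dt <- c(dt, dt[length(dt)])       # attribute the last sample one step
    dwell <- sum(dt[cond])
  }
  list(intermediate = dwell > dwell_min, dwell_ps = dwell)
}

#' Classify a ligand's dissociation mechanism from a trajectory set
#'
#' Runs the intermediate detector on every trajectory and calls the
#' mechanism `multistep` when the fraction of trajectories showing an
#' intermediate reaches `majority_fraction` (boundary counted as multistep:
#' the conservative call, since multistep means the quasi-bound analysis does
#' not apply).
#'
#' @param trajectories list of [dissociation_trajectory()] objects.
#' @param majority_fraction fraction in (0, 1\]; default 0.5.
#' @param ... passed to [detect_metastable_intermediate()].
#' @return list of class `mechanism_call`: `label` ("one_step" or
#'   "multistep"), `fraction_with_intermediate`, `dwell_ps` (per trajectory),
#'   `n_trajectories`.
#' @export
classify_series_mechanism <- function(trajectories, majority_fraction = 0.5,
                                      ...) {
  if (length(trajectories) == 0L) stop("need at least one trajectory")
  calls <- lapply(trajectories, detect_metastable_intermediate, ...)
  frac <- mean(vapply(calls, `[[`, logical(1L), "intermediate"))
  structure(list(
    label = if (frac >= majority_fraction) "multistep" else "one_step",
    fraction_with_intermediate = frac,
    dwell_ps = vapply(calls, `[[`, numeric(1L), "dwell_ps"),
    n_trajectories = length(trajectories)),
    class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> ", x$label, " (", round(100 * x$fraction_with_intermediate),
      "% of ", x$n_trajectories, " trajectories show an intermediate)\n",
      sep = "")
  invisible(x)
}

#' 2-D occupancy histogram over (centroid displacement, H-bond distance)
#'
#' Pools all trajectory samples into a gridded count table; the total count
#' equals the number of pooled samples (mass conservation).
#'
#' @param trajectories list of [dissociation_trajectory()] objects.
#' @param bins integer length-2: number of bins per axis (default c(50, 50)).
#' @param limits optional list with `com` and `hb` length-2 ranges; default
#'   the pooled data range.
#' @return list with `counts` (matrix, com x hb), `com_breaks`, `hb_breaks`.
#' @export
density_map <- function(trajectories, bins = c(50, 50), limits = NULL) {
  if (length(trajectories) == 0L) stop("need at least one trajectory")
  com <- unlist(lapply(trajectories, `[[`, "com_displacement_A"))
  hb <- unlist(lapply(trajectories, `[[`, "hbond_distance_A"))
  if (is.null(limits))
    limits <- list(com = range(com), hb = range(hb))
  cb <- seq(limits$com[1L], limits$com[2L], length.out = bins[1L] + 1L)
  hbb <- seq(limits$hb[1L], limits$hb[2L], length.out = bins[2L] + 1L)
  ci <- findInterval(com, cb, rightmost.closed = TRUE, all.inside = TRUE)
  hi <- findInterval(hb, hbb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1L], bins[2L])
  for (k in seq_along(ci))
    counts[ci[k], hi[k]] <- counts[ci[k], hi[k]] + 1L
  list(counts = counts, com_breaks = cb, hb_breaks = hbb)
}

#' Applicability of the quasi-bound analysis to a ligand series
#'
#' Two-step heuristic: the analysis is trusted only when (a) a representative
#' ligand shows a robust main interaction, dG_QB above `dgqb_min` (default
#' 15 kcal/mol), and (b) its dissociation is one-step (no metastable
#' intermediate between H-bond rupture and pocket exit).
#'
#' @param reference_estimate a [quasi_bound_estimate()] (or any list with a
#'   `dg_qb` field) for a representative ligand.
#' @param mechanism a `mechanism_call` from [classify_series_mechanism()].
#' @param dgqb_min kcal/mol; default 15.
#' @return list with `verdict` ("applicable"/"not_applicable") and `reasons`
#'   (character vector of failed conditions, empty when applicable).
#' @export
applicability_check <- function(reference_estimate, mechanism,
                                dgqb_min = 15) {
  reasons <- character()
  if (!(reference_estimate$dg_qb > dgqb_min))
    reasons <- c(reasons, sprintf(
      "reference dG_QB = %.2f kcal/mol does not exceed %.2f (labile main interaction)",
      reference_estimate$dg_qb, dgqb_min))
  if (mechanism$label != "one_step")
    reasons <- c(reasons,
                 "dissociation is multistep (metastable intermediate present)")
  list(verdict = if (length(reasons)) "not_applicable" else "applicable",
       reasons = reasons)
}
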