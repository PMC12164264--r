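#' Construct a pulling work profile
#'
#' A work profile is one steered-pulling trajectory's cumulative external
#' work as a function of the pulled reaction coordinate (the key
#' donor-acceptor hydrogen-bond distance). It is the raw object from which
#' the per-trajectory quasi-bound work Wi is extracted.
#'
#' @param trajectory_id character scalar naming the trajectory.
#' @param coordinate numeric vector of reaction-coordinate values (Angstrom),
#'   strictly increasing.
#' @param work numeric vector of cumulative work values (kcal/mol), same
#'   length as `coordinate`, all finite.
#' @param required_span numeric length-2: the coordinate interval the profile
#'   must cover. The pulling protocol runs 2.5 to 5 Angstrom; the default
#'   requires coverage of \[2.6, 4.8\] so slightly clipped profiles are still
#'   accepted. Use `NULL` to skip the span check.
#'
#' @return an object of class `work_profile`.
#' @export
work_profile <- function(trajectory_id, coordinate, work,
                         required_span = c(2.6, 4.8)) {
  stopifnot(is.character(trajectory_id), length(trajectory_id) == 1L)
  coordinate <- as.numeric(coordinate)
  work <- as.numeric(work)
  if (length(coordinate) != length(work))
    stop("coordinate and work must have the same length")
  if (length(coordinate) < 2L)
    stop("a work profile needs at least two points")
  if (!all(is.finite(coordinate)) || !all(is.finite(work)))
    stop("work profile '", trajectory_id, "' contains non-finite values")
  if (any(diff(coordinate) <= 0))
    stop("work profile '", trajectory_id,
         "': reaction coordinate must be strictly increasing")
  if (!is.null(required_span)) {
    if (coordinate[1L] > required_span[1L] ||
        coordinate[length(coordinate)] < required_span[2L])
      stop("work profile '", trajectory_id, "' spans [",
           signif(coordinate[1L], 4), ", ",
           signif(coordinate[length(coordinate)], 4),
           "] A but must cover [", required_span[1L], ", ",
           required_span[2L], "] A")
  }
  structure(list(trajectory_id = trajectory_id, coordinate = coordinate,
                 work = work),
            class = "work_profile")
}

#' @export
print.work_profile <- function(x, ...) {
  cat("<work_profile> ", x$trajectory_id, ": ", length(x$coordinate),
      " points, r in [", signif(min(x$coordinate), 4), ", ",
      signif(max(x$coordinate), 4), "] A, W in [",
      signif(min(x$work), 4), ", ", signif(max(x$work), 4),
      "] kcal/mol\n", sep = "")
  invisible(x)
}

parse_profile_block <- function(lines, id, file, first_line, required_span) {
  rows <- strsplit(trimws(lines), "[,[:space:]]+")
  n_col <- lengths(rows)
  if (any(n_col != 2L))
    stop("file '", file, "', line ", first_line + which(n_col != 2L)[1L] - 1L,
         ": expected two columns")
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(vapply(rows, function(r) anyNA(suppressWarnings(as.numeric(r))),
                        logical(1L)))[1L]
    stop("file '", file, "', line ", first_line + bad - 1L,
         ": non-numeric value '", paste(rows[[bad]], collapse = " "), "'")
  }
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  work_profile(id, m[, 1L], m[, 2L], required_span = required_span)
}

#' Read pulling work profiles from plain-text tables
#'
#' Each trajectory is a two-column numeric table (reaction coordinate in
#' Angstrom, cumulative work in kcal/mol), whitespace- or comma-delimited,
#' with `#` comment lines allowed. A file may hold one trajectory or several
#' separated by blank lines. `source` may be a directory (all regular files
#' in it are read, sorted by name) or a character vector of file paths.
#' Trajectory ids are taken from the file name (extension stripped), with a
#' `_<block>` suffix when a file holds several blocks.
#'
#' @param source directory or file path(s).
#' @param required_span passed to [work_profile()]; `NULL` disables the
#'   span check.
#' @return list of [work_profile()] objects, input order preserved.
#' @export
read_work_profiles <- function(source, required_span = c(2.6, 4.8)) {
  if (length(source) == 1L && dir.exists(source)) {
    files <- sort(list.files(source, full.names = TRUE))
    files <- files[!dir.exists(files)]
  } else {
    files <- source
  }
  if (length(files) == 0L) stop("no work-profile files found in source")
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("work-profile file(s) not found: ", paste(missing, collapse = ", "))

  profiles <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    keep <- !grepl("^[[:space:]]*#", lines)
    blank <- grepl("^[[:space:]]*$", lines)
    block_id <- cumsum(blank)
    idx <- which(keep & !blank)
    if (length(idx) == 0L) stop("file '", f, "' holds no data rows")
    base_id <- sub("\\.[^.]*$", "", basename(f))
    blocks <- split(idx, block_id[idx])
    multi <- length(blocks) > 1L
    for (b in seq_along(blocks)) {
      rows <- blocks[[b]]
      id <- if (multi) paste0(base_id, "_", b) else base_id
      profiles[[length(profiles) + 1L]] <-
        parse_profile_block(lines[rows], id, f, rows[1L], required_span)
    }
  }
  profiles
}

#' Write work profiles as two-column text files
#'
#' Lossless counterpart of [read_work_profiles()]: one file per profile,
#' named `<trajectory_id>.dat`, full double precision.
#'
#' @param profiles list of [work_profile()] objects.
#' @param destination directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_work_profiles <- function(profiles, destination) {
  if (length(profiles) == 0L) {
    warning("no work profiles to write")
    return(invisible(character()))
  }
  bad <- vapply(profiles, function(p) !all(is.finite(p$work)), logical(1L))
  if (any(bad))
    stop("refusing to write profiles with non-finite work: ",
         paste(vapply(profiles[bad], `[[`, "", "trajectory_id"),
               collapse = ", "))
  if (!dir.exists(destination))
    dir.create(destination, recursive = TRUE)
  paths <- vapply(profiles, function(p) {
    path <- file.path(destination, paste0(p$trajectory_id, ".dat"))
    writeLines(paste(format(p$coordinate, digits = 17, trim = TRUE),
                     format(p$work, digits = 17, trim = TRUE)),
               path)
    path
  }, character(1L))
  invisible(paths)
}

#' Extract the quasi-bound work Wi from one profile
#'
#' The per-trajectory quasi-bound work is the maximum along the work profile
#' (the quasi-bound state, where the key H-bond is broken), referenced to the
#' work minimum in the bound window around 3 Angstrom (the bound state, with
#' an optimal H-bond): `w_i = max_{r >= r_min} W(r) - W(r_min)` with `r_min`
#' the argmin of W restricted to `bound_window`. Ties in both the minimum
#' and the maximum are broken toward the smaller coordinate, so the result is
#' deterministic. The raw coordinate grid is used as-is (no interpolation).
#'
#' @param profile a [work_profile()].
#' @param bound_window numeric length-2 window (Angstrom) in which the bound
#'   minimum is sought; default `c(2.7, 3.3)`.
#' @return a one-row data.frame with columns `trajectory_id`, `w_i`, `r_min`,
#'   `r_max`.
#' @export
extract_quasi_bound_work <- function(profile, bound_window = c(2.7, 3.3)) {
  stopifnot(inherits(profile, "work_profile"), length(bound_window) == 2L,
            bound_window[1L] < bound_window[2L])
  r <- profile$coordinate
  w <- profile$work
  in_win <- which(r >= bound_window[1L] & r <= bound_window[2L])
  if (length(in_win) == 0L)
    stop("bound window [", bound_window[1L], ", ", bound_window[2L],
         "] A holds no grid points of profile '", profile$trajectory_id, "'")
  i_min <- in_win[which.min(w[in_win])]   # first = smallest coordinate on ties
  after <- i_min:length(r)
  i_max <- after[which.max(w[after])]
  data.frame(trajectory_id = profile$trajectory_id,
             w_i = w[i_max] - w[i_min],
             r_min = r[i_min],
             r_max = r[i_max],
             stringsAsFactors = FALSE)
}

#' Extract Wi for a list of profiles
#'
#' @param profiles list of [work_profile()] objects.
#' @inheritParams extract_quasi_bound_work
#' @return data.frame with one row per profile.
#' @export
extract_quasi_bound_works <- function(profiles, bound_window = c(2.7, 3.3)) {
  do.call(rbind, lapply(profiles, extract_quasi_bound_work,
                        bound_window = bound_window))
}
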