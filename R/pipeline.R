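#' Published HSP90alpha Vernalis benchmark table
#'
#' Nine congeneric resorcinol HSP90alpha inhibitors with experimentally
#' measured on-rates (M-1 s-1), off-rates (s-1) and K_D (nM), plus the
#' quasi-bound free energies computed under two ligand force fields (PFROSST
#' and GAFF) with their bootstrap standard deviations. K_D values for
#' VER45862 and VER45861 are single measurements; VER45862 additionally lacks
#' the R1 halogen and is the known outlier excluded from the headline
#' correlations.
#'
#' @return data.frame with columns `ligand_id`, `k_on`, `k_off`, `kd_nM`,
#'   `dgqb_pfrosst`, `sd_pfrosst`, `dgqb_gaff`, `sd_gaff`,
#'   `single_measurement`.
#' @export
table1_vernalis <- function() {
  path <- system.file("extdata", "table1_vernalis.csv", package = "quasibound")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Published HSP90alpha pair-set confusion counts
#'
#' The K_D-based activity-cliff classification of the 207 similarity-matched
#' HSP90alpha pairs at the -5 kcal/mol ddG_QB threshold: 18 actual cliffs, 29
#' predicted, 13 of them correct, 5 cliffs missed. The remaining cells follow
#' by conservation: FP = 29 - 13 = 16, TN = 207 - 18 - 16 = 173.
#'
#' @return a [confusion_matrix()].
#' @export
hsp90_pairset_confusion <- function() {
  pairs_total <- 207L; cliffs <- 18L; predicted <- 29L
  tp <- 13L; fn <- 5L
  stopifnot(cliffs == tp + fn)
  fp <- predicted - tp
  tn <- pairs_total - cliffs - fp
  confusion_matrix(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Rank-correlation benchmark on the Vernalis table
#'
#' Recomputes the four headline correlations from the shipped benchmark
#' table: dG_QB(PFROSST) against pK_D and dG_QB(GAFF) against pk_off, with
#' the VER45862 outlier excluded (n = 8), plus the all-nine variants for
#' transparency.
#'
#' @param exclude ligand ids dropped from the headline rows (default
#'   `"VER45862"`).
#' @return data.frame with columns `force_field`, `against`, `excluded`,
#'   `pearson_r`, `spearman_rho`, `n`.
#' @export
benchmark_table1 <- function(exclude = "VER45862") {
  tb <- table1_vernalis()
  records <- data.frame(ligand_id = tb$ligand_id, potency_value = tb$kd_nM,
                        potency_units = "nM", k_off = tb$k_off,
                        stringsAsFactors = FALSE)
  combos <- expand.grid(force_field = c("PFROSST", "GAFF"),
                        against = c("pkd", "pkoff"),
                        excluded = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ff <- combos$force_field[i]
    est <- data.frame(
      ligand_id = tb$ligand_id,
      dg_qb = if (ff == "PFROSST") tb$dgqb_pfrosst else tb$dgqb_gaff,
      stringsAsFactors = FALSE)
    ex <- if (combos$excluded[i]) exclude else character()
    cc <- rank_correlations(est, records, against = combos$against[i],
                            exclude = ex)
    data.frame(force_field = ff, against = combos$against[i],
               excluded = combos$excluded[i], pearson_r = cc$pearson_r,
               spearman_rho = cc$spearman_rho, n = cc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates the full analysis on a synthetic congeneric series with
#' known ground truth: generate the series, pull every ligand's landscape
#' with Brownian-dynamics cycles, reduce the work profiles to quasi-bound
#' works, estimate dG_QB with bootstrap errors, build similarity-matched
#' cliff-labelled pairs from the ground-truth potencies, classify the pairs
#' from ddG_QB, and summarise confusion counts, MCC and rank correlations.
#' Deterministic for a fixed `seed`.
#'
#' @param spec a [series_spec()] (its own seed is overridden by `seed`).
#' @param n_trajectories pulling cycles per ligand (default 120).
#' @param protocol an [smd_protocol()].
#' @param criteria a [cliff_criteria()]; the default similarity cutoff keeps
#'   all template-derived synthetic pairs.
#' @param threshold ddG_QB decision threshold, kcal/mol. The default -2.73
#'   mirrors the cliff definition itself: with near-constant on-rates, a true
#'   100-fold potency cliff corresponds to a barrier difference of the same
#'   magnitude.
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, writes dgqb.csv, pairs.csv,
#'   eval.csv and summary.json there.
#' @param jarzynski a [jarzynski_config()] template for the bootstrap.
#' @return list with `estimates` (data.frame), `pairs`, `evaluations`,
#'   `confusion`, `mcc`, `correlations` (vs pkd and pkoff), `series`,
#'   `summary` (flat list, what summary.json holds).
#' @export
run_pipeline <- function(spec = series_spec(), n_trajectories = 120,
                         protocol = smd_protocol(),
                         criteria = cliff_criteria(similarity_cutoff = 0.7),
                         threshold = -2.73, seed = 1, out_dir = NULL,
                         jarzynski = jarzynski_config()) {
  spec$seed <- seed
  series <- generate_congeneric_series(spec)
  ids <- series$records$ligand_id

  estimates <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    profiles <- brownian_smd(series$landscapes[[ids[i]]], protocol,
                             n_trajectories = n_trajectories,
                             seed = seed + i * 10000L)
    wi <- extract_quasi_bound_works(profiles)
    cfg <- jarzynski
    cfg$seed <- seed + i
    estimates[[i]] <- quasi_bound_estimate(ids[i], wi$w_i, cfg)
  }
  est_tab <- estimates_table(estimates)

  pairs <- build_pairs(series$records, criteria,
                       fingerprints = series$fingerprints)
  ev <- evaluate_pairs(pairs, est_tab, threshold = threshold)
  cors <- list(
    pkd = rank_correlations(est_tab, series$records, against = "pkd"),
    pkoff = rank_correlations(est_tab, series$records, against = "pkoff"))

  summary <- list(
    seed = seed, n_ligands = length(ids), n_trajectories = n_trajectories,
    n_pairs = nrow(pairs), n_cliffs = sum(pairs$is_cliff),
    threshold = threshold,
    similarity_cutoff = criteria$similarity_cutoff,
    ddg_threshold = criteria$ddg_threshold,
    bound_window = c(2.7, 3.3),
    confusion = unclass(ev$confusion), mcc = mcc(ev$confusion),
    pearson_r_pkd = cors$pkd$pearson_r,
    spearman_rho_pkd = cors$pkd$spearman_rho,
    pearson_r_pkoff = cors$pkoff$pearson_r,
    spearman_rho_pkoff = cors$pkoff$spearman_rho)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(est_tab, file.path(out_dir, "dgqb.csv"), row.names = FALSE)
    write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
    write.csv(ev$evaluations, file.path(out_dir, "eval.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(estimates = est_tab, pairs = pairs, evaluations = ev$evaluations,
       confusion = ev$confusion, mcc = mcc(ev$confusion),
       correlations = cors, series = series, summary = summary)
}
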