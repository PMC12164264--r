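POTENCY_UNIT_SCALE <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Convert a potency value to molar
#'
#' @param value positive numeric potency value(s).
#' @param units character unit(s): one of M, mM, uM (or the micro sign
#'   variant), nM, pM.
#' @return numeric, molar.
#' @export
potency_to_molar <- function(value, units) {
  units <- sub("µ", "u", units)
  scale <- POTENCY_UNIT_SCALE[units]
  if (anyNA(scale))
    stop("unrecognized potency units: ",
         paste(unique(units[is.na(scale)]), collapse = ", "))
  if (any(!is.finite(value) | value <= 0))
    stop("potency values must be positive and finite")
  unname(value * scale)
}

#' Keep only ligands with exact potency values
#'
#' Records whose potency carries a qualifier ("<", ">", "~") are censored or
#' approximate and are dropped before building matched pairs; the counts
#' removed per qualifier are reported as a message.
#'
#' @param records data.frame of ligand records with a `qualifier` column
#'   (one of "exact", "<", ">", "~").
#' @return the filtered data.frame.
#' @export
filter_exact_activities <- function(records) {
  if (nrow(records) == 0L) return(records)
  stopifnot("qualifier" %in% names(records))
  drop <- records$qualifier != "exact"
  if (any(drop)) {
    counts <- table(records$qualifier[drop])
    message("removed ", sum(drop), " record(s) without exact potency: ",
            paste(names(counts), counts, sep = " x ", collapse = ", "))
  }
  records[!drop, , drop = FALSE]
}

#' Free-energy difference of a ligand pair from its potency ratio
#'
#' Converts the potency ratio of the weaker over the stronger binder into a
#' binding free-energy difference, `ddG = kB*T * log(weak / strong)`, in
#' kcal/mol. A 100-fold ratio at 298.15 K gives the conventional
#' activity-cliff threshold 2.73 kcal/mol.
#'
#' @param potency_weak,potency_strong potencies in a common molar unit;
#'   `potency_weak >= potency_strong` after canonical ordering (a higher
#'   dissociation constant means weaker binding).
#' @param temperature kelvin (default 298.15).
#' @param kB Boltzmann constant, kcal mol-1 K-1.
#' @return ddG in kcal/mol, non-negative when the arguments are ordered.
#' @export
pair_free_energy_difference <- function(potency_weak, potency_strong,
                                        temperature = 298.15, kB = KB_KCAL) {
  if (any(!is.finite(potency_weak) | potency_weak <= 0) ||
      any(!is.finite(potency_strong) | potency_strong <= 0))
    stop("potencies must be positive and finite")
  kB * temperature * log(potency_weak / potency_strong)
}

#' Tanimoto coefficient between two fingerprint bit vectors
#'
#' `|A & B| / |A | B|` over bit sets; 1 when both vectors have no bit set
#' (identical empty sets).
#'
#' @param a,b logical or 0/1 numeric vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' MACCS key fingerprints from SMILES
#'
#' Computes 166-key MACCS structural fingerprints with the OpenBabel backend
#' (ChemmineOB). The backend pads the keys into a 256-bit block; the padding
#' bits are never set and do not affect Tanimoto values.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical matrix, one row per molecule, rownames = `names(smiles)`
#'   when present.
#' @export
maccs_fingerprint <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                           identity),
    error = function(e) stop("failed to parse SMILES input: ",
                             conditionMessage(e), call. = FALSE))
  if (length(mols) != length(smiles))
    stop("SMILES failed to parse (", length(smiles) - length(mols),
         " of ", length(smiles), " records rejected)")
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  fp <- matrix(fp != 0, nrow = length(smiles))
  rownames(fp) <- names(smiles)
  fp
}

#' MACCS/Tanimoto similarity of two molecules
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return Tanimoto coefficient over MACCS keys, in \[0, 1\]; symmetric.
#' @export
maccs_tanimoto <- function(smiles_a, smiles_b) {
  fp <- maccs_fingerprint(c(smiles_a, smiles_b))
  tanimoto(fp[1L, ], fp[2L, ])
}

#' Activity-cliff pairing criteria
#'
#' An activity cliff is a pair of structurally similar ligands whose
#' potencies differ by more than `fold_threshold` (default 100-fold,
#' equivalently a binding free-energy difference above
#' `kB*T*log(fold_threshold)`, 2.73 kcal/mol at 298.15 K).
#'
#' @param fold_threshold potency ratio defining a cliff (> 1; default 100).
#' @param similarity_cutoff minimal MACCS/Tanimoto similarity for a matched
#'   pair (default 0.7).
#' @param temperature kelvin for the ratio-to-energy conversion (default
#'   298.15).
#' @param ddg_threshold kcal/mol; default derived from `fold_threshold` and
#'   `temperature`.
#' @param kB Boltzmann constant.
#' @return list of class `cliff_criteria`.
#' @export
cliff_criteria <- function(fold_threshold = 100, similarity_cutoff = 0.7,
                           temperature = 298.15,
                           ddg_threshold = kB * temperature *
                             log(fold_threshold),
                           kB = KB_KCAL) {
  stopifnot(fold_threshold > 1, similarity_cutoff >= 0, similarity_cutoff <= 1,
            temperature > 0)
  structure(list(fold_threshold = fold_threshold,
                 ddg_threshold = ddg_threshold,
                 similarity_cutoff = similarity_cutoff,
                 temperature = temperature, kB = kB),
            class = "cliff_criteria")
}

#' Build similarity-matched, cliff-labelled ligand pairs
#'
#' Forms all unordered pairs of records whose fingerprint similarity reaches
#' `criteria$similarity_cutoff`, orders each pair so `id_strong` is the more
#' potent ligand (lower molar potency), computes
#' `ddg_bind = kB*T*log(potency_weak/potency_strong)` and labels the pair a
#' cliff when `ddg_bind > criteria$ddg_threshold`. Potencies are normalized
#' to molar first; pairs are only formed within a potency type, and IC50
#' values are additionally only compared within the same `series_id` (IC50 is
#' not comparable across assays). When a `series_id` column is present,
#' pairing is restricted to within-series for all types.
#'
#' @param records data.frame with columns `ligand_id`, `potency_value`,
#'   `potency_units`, `potency_type` and optionally `smiles`, `series_id`.
#'   Records should already be passed through [filter_exact_activities()].
#' @param criteria a [cliff_criteria()].
#' @param fingerprints optional logical matrix of fingerprints, one row per
#'   record (rownames matching `ligand_id` or in record order); when `NULL`,
#'   MACCS fingerprints are computed from the `smiles` column.
#' @return data.frame with columns `id_weak`, `id_strong`, `similarity`,
#'   `ddg_bind`, `is_cliff`, sorted by (`id_weak`, `id_strong`).
#' @export
build_pairs <- function(records, criteria = cliff_criteria(),
                        fingerprints = NULL) {
  if (nrow(records) < 2L) {
    warning("fewer than two ligand records; no pairs to build")
    return(data.frame(id_weak = character(), id_strong = character(),
                      similarity = numeric(), ddg_bind = numeric(),
                      is_cliff = logical(), stringsAsFactors = FALSE))
  }
  if (anyDuplicated(records$ligand_id))
    stop("duplicated ligand_id in records")
  if (is.null(fingerprints)) {
    if (is.null(records$smiles))
      stop("records lack a smiles column and no fingerprints were supplied")
    fingerprints <- maccs_fingerprint(setNames(records$smiles,
                                               records$ligand_id))
  }
  if (nrow(fingerprints) != nrow(records))
    stop("fingerprints must have one row per record")
  molar <- potency_to_molar(records$potency_value, records$potency_units)
  series <- if (!is.null(records$series_id)) records$series_id
            else rep(NA_character_, nrow(records))

  out <- list()
  n <- nrow(records)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (records$potency_type[i] != records$potency_type[j]) next
      same_series <- !is.na(series[i]) && !is.na(series[j]) &&
        series[i] == series[j]
      if (records$potency_type[i] == "IC50" && !same_series) next
      if (!is.na(series[i]) && !is.na(series[j]) && !same_series) next
      sim <- tanimoto(fingerprints[i, ], fingerprints[j, ])
      if (sim < criteria$similarity_cutoff) next
      weak <- if (molar[i] >= molar[j]) i else j
      strong <- if (weak == i) j else i
      ddg <- pair_free_energy_difference(molar[weak], molar[strong],
                                         criteria$temperature, criteria$kB)
      out[[length(out) + 1L]] <- data.frame(
        id_weak = records$ligand_id[weak],
        id_strong = records$ligand_id[strong],
        similarity = sim, ddg_bind = ddg,
        is_cliff = ddg > criteria$ddg_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(id_weak = character(), id_strong = character(),
                      similarity = numeric(), ddg_bind = numeric(),
                      is_cliff = logical(), stringsAsFactors = FALSE))
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$id_weak, pairs$id_strong), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
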