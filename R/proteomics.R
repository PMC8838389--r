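#' Normalized spectral abundance factors
#'
#' Per sample, `nsaf = (SpC / L) / sum_j (SpC_j / L_j)` with L the protein
#' length in amino acids; columns sum to 1 exactly (zero-count proteins get
#' NSAF 0). Spectral counts should already be averaged across technical
#' replicates; biological replicates stay separate columns.
#'
#' @param spectral_counts matrix proteins x samples (nonnegative; technical-
#'   replicate averages may be fractional).
#' @param protein_length_aa positive lengths in amino acids; named vectors
#'   are matched to rownames.
#' @param percent return NSAF100 (= 100 x NSAF, the reporting scale of the
#'   printed protein tables) instead of NSAF.
#' @return Matrix of NSAF (or NSAF100) values.
#' @export
nsaf <- function(spectral_counts, protein_length_aa, percent = FALSE) {
  m <- as.matrix(spectral_counts)
  if (any(m < 0)) stop("spectral counts must be nonnegative")
  if (!is.null(names(protein_length_aa)) && !is.null(rownames(m))) {
    protein_length_aa <- protein_length_aa[rownames(m)]
  }
  if (any(protein_length_aa <= 0)) stop("protein lengths must be positive")
  saf <- m / protein_length_aa
  tot <- colSums(saf)
  if (any(tot == 0)) {
    stop("sample(s) with all-zero spectral counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  }
  out <- sweep(saf, 2L, tot, "/")
  if (percent) 100 * out else out
}

#' Peptide-evidence filter for protein identification
#'
#' A peptide is significant iff its identification p-value is below `max_p`
#' and it was seen in at least `min_spectra` spectra; a protein is retained
#' iff it has at least `min_sig_peptides` significant peptides.
#'
#' @param evidence data.frame with columns protein_id, peptide,
#'   spectra_count, p_value.
#' @param min_spectra spectra floor per peptide (default 5).
#' @param max_p peptide confidence cut-off (default 0.05, exclusive).
#' @param min_sig_peptides significant peptides required per protein
#'   (default 2).
#' @return Character vector of retained protein ids.
#' @export
evidence_filter <- function(evidence, min_spectra = 5L, max_p = 0.05,
                            min_sig_peptides = 2L) {
  needed <- c("protein_id", "peptide", "spectra_count", "p_value")
  if (!all(needed %in% names(evidence))) {
    stop("evidence needs columns: ", paste(needed, collapse = ", "))
  }
  sig <- evidence$p_value < max_p & evidence$spectra_count >= min_spectra
  counts <- table(evidence$protein_id[sig])
  sort(names(counts)[counts >= min_sig_peptides])
}

#' Differential NSAF flags between genotypes across the time course
#'
#' Per protein and timepoint: when both genotypes were detected, the log2
#' NSAF ratio (russet/waxy by default) is flagged when its magnitude
#' exceeds `fc_log2_min` (default 0.58, a 50% increase or decrease);
#' one-sided detection is reported as a presence/absence call rather than
#' an infinite fold change; detection in neither genotype is recorded as
#' undetected.
#'
#' @param profiles matrix proteins x conditions of per-condition mean NSAF
#'   (see [condition_means()]).
#' @param numerator,denominator genotypes of the ratio.
#' @param fc_log2_min log2 cut-off (default 0.58, exclusive).
#' @return data.frame: protein_id, timepoint, log2_ratio (NA unless both
#'   sides detected), direction (sign of numerator - denominator), status
#'   in {flagged, not_flagged, presence_absence, undetected}.
#' @export
differential_nsaf <- function(profiles, numerator = "russet",
                              denominator = "waxy", fc_log2_min = 0.58) {
  conds <- profile_conditions(profiles)
  tps <- sort(unique(conds$timepoint_dafb))
  rows <- lapply(tps, function(tp) {
    num <- profiles[, condition_key(numerator, tp)]
    den <- profiles[, condition_key(denominator, tp)]
    lr <- ifelse(num > 0 & den > 0, log2(num / den), NA_real_)
    status <- ifelse(num == 0 & den == 0, "undetected",
              ifelse(xor(num > 0, den > 0), "presence_absence",
              ifelse(abs(lr) > fc_log2_min, "flagged", "not_flagged")))
    data.frame(protein_id = rownames(profiles), timepoint = tp,
               log2_ratio = lr, direction = sign(num - den), status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Count proteins per functional bin
#'
#' Exhaustive partition of a protein set over a (possibly partial)
#' protein-to-bin map; unmapped proteins fall into `"unassigned"`. Counts
#' always sum to the input size.
#'
#' @param proteins character vector.
#' @param bin_map named character vector protein -> bin.
#' @return Named integer vector of counts (zero-count bins of the map are
#'   kept).
#' @export
bin_summary <- function(proteins, bin_map) {
  bins <- ifelse(proteins %in% names(bin_map), bin_map[proteins], "unassigned")
  levels <- unique(c(sort(unique(bin_map)), "unassigned"))
  out <- table(factor(bins, levels = levels))
  setNames(as.integer(out), names(out))
}
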