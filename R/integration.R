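#' Pearson correlation between two condition profiles
#'
#' Computes r over the shared non-missing conditions and a two-sided p via
#' the t transform `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. Profiles are compared on per-condition means (10 points in the
#' reference design), the grid on which the published correlation heatmaps
#' operate.
#'
#' @param x,y numeric profiles of equal length (>= 3 shared non-missing
#'   conditions; nonconstant).
#' @return list with `r`, `p`, `n_points`; a constant vector gives
#'   `r = NA` with a `reason`.
#' @export
profile_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n_points = n,
                          reason = "fewer than 3 shared conditions"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_points = n,
                reason = "constant profile"))
  }
  r <- stats::cor(x, y)
  p <- cor_t_pvalue(r, n)
  list(r = r, p = p, n_points = n)
}

cor_t_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  2 * stats::pt(-abs(t), n - 2)
}

#' Nominate gene-metabolite candidate pairs by profile correlation
#'
#' Evaluates every gene x metabolite pair on identical condition grids and
#' flags pairs whose Pearson r exceeds `r_min` with p below `p_max`. The
#' defaults (r > 0.78, p < 0.01) are the published nomination rule, which
#' is internally consistent at 10 condition points (r = 0.78 gives p
#' 0.008). No multiple-testing correction is applied by default, matching
#' the raw-p reporting of the published analysis; pass the result through
#' [bh_fdr()] if a corrected screen is wanted.
#'
#' @param gene_profiles,metabolite_profiles matrices (features x
#'   conditions) with identical condition columns.
#' @param r_min correlation cut-off (default 0.78, exclusive).
#' @param p_max p-value cut-off (default 0.01, exclusive).
#' @param mode `"positive"` flags r > r_min (published rule); `"absolute"`
#'   also nominates strong negative correlates.
#' @return data.frame of all pairs sorted by r descending: gene_id,
#'   metabolite_id, r, p, n_points, passes.
#' @export
nominate_candidates <- function(gene_profiles, metabolite_profiles,
                                r_min = 0.78, p_max = 0.01,
                                mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  if (!nrow(gene_profiles) || !nrow(metabolite_profiles)) {
    return(data.frame(gene_id = character(), metabolite_id = character(),
                      r = numeric(), p = numeric(), n_points = integer(),
                      passes = logical(), stringsAsFactors = FALSE))
  }
  if (!identical(colnames(gene_profiles), colnames(metabolite_profiles))) {
    stop("gene and metabolite profiles must share an identical condition grid")
  }
  n <- ncol(gene_profiles)
  r <- stats::cor(t(gene_profiles), t(metabolite_profiles))
  p <- cor_t_pvalue(r, n)
  out <- data.frame(
    gene_id = rep(rownames(gene_profiles), times = nrow(metabolite_profiles)),
    metabolite_id = rep(rownames(metabolite_profiles),
                        each = nrow(gene_profiles)),
    r = as.vector(r), p = as.vector(p), n_points = n,
    stringsAsFactors = FALSE, row.names = NULL)
  stat <- if (mode == "absolute") abs(out$r) else out$r
  out$passes <- !is.na(stat) & stat > r_min & out$p < p_max
  out[order(-out$r), , drop = FALSE]
}

#' Sign concordance of transcript and protein genotype ratios
#'
#' For each mapped gene/protein pair and each timepoint where both layers
#' are evaluable, records whether the transcript log2 ratio and the protein
#' call agree in direction. Protein presence/absence calls are compared by
#' their direction; timepoints where the protein was undetected (or either
#' ratio is zero/missing) are skipped.
#'
#' @param gene_log2fc matrix genes x timepoints of transcript log2 ratios
#'   (russet/waxy orientation, as from [differential_expression()]).
#' @param protein_table output of [differential_nsaf()] with the same ratio
#'   orientation.
#' @param id_map data.frame with columns gene_id, protein_id; defaults to
#'   identity on the shared ids.
#' @return data.frame: gene_id, protein_id, n_evaluable, n_agree,
#'   fraction; unmapped ids are listed in the `unmapped` attribute, not
#'   fatal.
#' @export
rna_protein_concordance <- function(gene_log2fc, protein_table,
                                    id_map = NULL) {
  prot_ids <- unique(protein_table$protein_id)
  if (is.null(id_map)) {
    shared <- intersect(rownames(gene_log2fc), prot_ids)
    id_map <- data.frame(gene_id = shared, protein_id = shared,
                         stringsAsFactors = FALSE)
  }
  unmapped <- setdiff(prot_ids, id_map$protein_id)
  tps <- colnames(gene_log2fc)
  rows <- lapply(seq_len(nrow(id_map)), function(i) {
    g <- id_map$gene_id[i]; pr <- id_map$protein_id[i]
    if (!g %in% rownames(gene_log2fc)) return(NULL)
    pt <- protein_table[protein_table$protein_id == pr, ]
    n_eval <- 0L; n_agree <- 0L
    for (tp in tps) {
      grow <- gene_log2fc[g, tp]
      prow <- pt[pt$timepoint == as.numeric(tp), ]
      if (!nrow(prow) || prow$status == "undetected") next
      psign <- if (prow$status == "presence_absence") prow$direction
               else sign(prow$log2_ratio)
      gsign <- sign(grow)
      if (!is.finite(gsign) || gsign == 0 || psign == 0) next
      n_eval <- n_eval + 1L
      if (gsign == psign) n_agree <- n_agree + 1L
    }
    data.frame(gene_id = g, protein_id = pr, n_evaluable = n_eval,
               n_agree = n_agree,
               fraction = if (n_eval > 0) n_agree / n_eval else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), protein_id = character(),
                      n_evaluable = integer(), n_agree = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "unmapped") <- unmapped
  out
}
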