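welch_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group variance at all
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p_value = p, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Per-timepoint two-group Welch test on metabolite features
#'
#' Compares the two genotypes at a single timepoint with a two-sided Welch
#' t-test on the values as given (the caller chooses the scale; see
#' [differential_metabolites()] for the log10 wrapper). The log2 fold change
#' is always computed from the raw group means.
#'
#' @param matrix abundance matrix (features x samples).
#' @param design a [study_design()].
#' @param timepoint DAFB timepoint to test.
#' @param group_a,group_b genotypes compared (fold change is a over b).
#' @param transform optional function applied to the values before the test
#'   (e.g. `function(x) log10(x + 1)`); the fold change stays raw-scale.
#' @return data.frame: feature_id, timepoint, log2fc, statistic, p_value,
#'   degenerate.
#' @export
welch_test <- function(matrix, design, timepoint, group_a = "russet",
                       group_b = "waxy", transform = NULL) {
  matrix <- validate_abundance(matrix)
  design <- study_design(design)
  ids_a <- design$sample_id[design$genotype == group_a &
                            design$timepoint_dafb == timepoint]
  ids_b <- design$sample_id[design$genotype == group_b &
                            design$timepoint_dafb == timepoint]
  ids_a <- intersect(ids_a, colnames(matrix))
  ids_b <- intersect(ids_b, colnames(matrix))
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("need >= 2 replicates per group at timepoint ", timepoint)
  }
  A <- matrix[, ids_a, drop = FALSE]
  B <- matrix[, ids_b, drop = FALSE]
  TA <- if (is.null(transform)) A else transform(A)
  TB <- if (is.null(transform)) B else transform(B)
  res <- lapply(seq_len(nrow(matrix)), function(i) welch_stat(TA[i, ], TB[i, ]))
  data.frame(
    feature_id = rownames(matrix),
    timepoint = timepoint,
    log2fc = log2(rowMeans(A) / rowMeans(B)),
    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
    degenerate = vapply(res, `[[`, logical(1L), "degenerate"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-timepoint differential metabolite table across the time course
#'
#' Runs [welch_test()] at every timepoint of the design on log10(x+1)
#' transformed EIC areas (LC-MS areas are positive and right-skewed; the
#' log stabilizes the replicate variance) and appends a Benjamini-Hochberg
#' q-value within each timepoint.
#'
#' @param matrix abundance matrix.
#' @param design a [study_design()].
#' @param group_a,group_b genotypes compared.
#' @param log_transform apply the log10(x+1) transform before testing.
#' @return data.frame with one row per feature x timepoint: feature_id,
#'   timepoint, log2fc, statistic, p_value, q_value, degenerate.
#' @export
differential_metabolites <- function(matrix, design, group_a = "russet",
                                     group_b = "waxy", log_transform = TRUE) {
  design <- study_design(design)
  tf <- if (log_transform) function(x) log10(x + 1) else NULL
  tabs <- lapply(sort(unique(design$timepoint_dafb)), function(tp) {
    tab <- welch_test(matrix, design, tp, group_a, group_b, transform = tf)
    tab$q_value <- bh_fdr(tab$p_value)
    tab
  })
  do.call(rbind, tabs)
}

#' Multigroup pattern filter: genotype- and development-associated features
#'
#' Classifies each feature by two ratio rules on its condition-mean
#' profile: genotype-associated if |log2(russet/waxy)| >= `fc_genotype_log2`
#' at one or more timepoints; development-associated if the max/min ratio
#' across timepoints within either genotype is >= `fc_development`. Features
#' can satisfy both, either, or neither rule. (Features whose abundance is
#' unchanged between the genotypes are retained only through the
#' development rule: the filter keeps features *outside* the +-1 log2 band,
#' i.e. those actually associated with one of the two patterns.)
#'
#' @param profiles output of [condition_means()], strictly positive after
#'   `pseudocount`.
#' @param fc_genotype_log2 log2 threshold of the genotype rule (default 1).
#' @param fc_development raw fold threshold of the development rule
#'   (default 2).
#' @param pseudocount added before forming ratios.
#' @return data.frame: feature_id, genotype_associated,
#'   development_associated, class in {genotype_associated,
#'   development_associated, both, none}.
#' @export
multigroup_pattern_filter <- function(profiles, fc_genotype_log2 = 1,
                                      fc_development = 2, pseudocount = 0) {
  p <- profiles + pseudocount
  if (any(p <= 0)) {
    stop("profiles must be strictly positive after pseudocount; ",
         "supply a pseudocount for zero abundances")
  }
  conds <- profile_conditions(profiles)
  tps <- sort(unique(conds$timepoint_dafb))
  gr <- abs(log2(p[, condition_key("russet", tps), drop = FALSE] /
                 p[, condition_key("waxy", tps), drop = FALSE]))
  genotype_assoc <- apply(gr, 1L, max) >= fc_genotype_log2
  dev_assoc <- rep(FALSE, nrow(p))
  for (g in intersect(GENOTYPES, conds$genotype)) {
    block <- p[, condition_key(g, tps), drop = FALSE]
    dev_assoc <- dev_assoc |
      (apply(block, 1L, max) / apply(block, 1L, min) >= fc_development)
  }
  cls <- ifelse(genotype_assoc & dev_assoc, "both",
         ifelse(genotype_assoc, "genotype_associated",
         ifelse(dev_assoc, "development_associated", "none")))
  data.frame(feature_id = rownames(p), genotype_associated = genotype_assoc,
             development_associated = dev_assoc, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Venn-style meta-analysis of the per-timepoint comparisons
#'
#' From the combined differential table, forms the per-timepoint set of
#' features with `p < p_max` and raw |fold change| > `fc_min`, and the
#' center of the Venn diagram: features in every set with (by default) a
#' consistent sign of log2 fold change across all timepoints.
#'
#' @param diff_table output of [differential_metabolites()] (feature_id,
#'   timepoint, log2fc, p_value), covering the same feature universe at
#'   every timepoint.
#' @param p_max p-value cut-off (default 0.01).
#' @param fc_min raw fold-change cut-off (default 1.5; applied as
#'   |log2fc| > log2(fc_min)).
#' @param signed require direction consistency for the center (default
#'   TRUE; set FALSE for a pure significance intersection).
#' @return list with `sets` (named list of per-timepoint feature vectors),
#'   `center`, `p_max`, `fc_min`.
#' @export
venn_meta_analysis <- function(diff_table, p_max = 0.01, fc_min = 1.5,
                               signed = TRUE) {
  tps <- sort(unique(diff_table$timepoint))
  if (length(tps) < 2L) stop("need at least two timepoint tables")
  universe <- NULL
  sets <- list()
  per_tp <- split(diff_table, diff_table$timepoint)
  for (tp in as.character(tps)) {
    tab <- per_tp[[tp]]
    if (is.null(universe)) universe <- sort(tab$feature_id)
    if (!identical(sort(tab$feature_id), universe)) {
      stop("timepoint ", tp, " covers a different feature universe")
    }
    sets[[tp]] <- tab$feature_id[tab$p_value < p_max &
                                 abs(tab$log2fc) > log2(fc_min)]
  }
  center <- Reduce(intersect, sets)
  if (signed && length(center)) {
    sgn <- sapply(per_tp, function(tab) {
      sign(tab$log2fc[match(center, tab$feature_id)])
    })
    if (is.null(dim(sgn))) sgn <- base::matrix(sgn, nrow = 1L)
    consistent <- apply(sgn, 1L, function(s) all(s == s[1L]))
    center <- center[consistent]
  }
  list(sets = sets, center = center, p_max = p_max, fc_min = fc_min)
}

#' Top positive and negative PCA loadings per component
#'
#' PCA of the samples on log10(x+1)-transformed, mean-centered (not
#' unit-scaled) feature values; for each requested component, returns the
#' most discriminating features: the `n_per_sign` largest positive and
#' largest negative loadings, each ordered by |loading|. In the reference
#' design PC1 tracks fruit development and PC2 separates the genotypes, so
#' PC2 loadings nominate russeting markers.
#'
#' @param matrix abundance matrix (features x samples), >= 2 features and
#'   >= 2 samples.
#' @param components integer vector of components to report (default 1:2).
#' @param n_per_sign features per sign (default 20; truncated with a
#'   warning if the matrix has fewer).
#' @param log_transform apply log10(x+1) first (default TRUE).
#' @return list of per-component records: component, explained_variance,
#'   top_positive, top_negative, loadings (full named vector). The
#'   `explained_variance` entries over all components are nonincreasing and
#'   sum to <= 1.
#' @export
pca_top_loadings <- function(matrix, components = 1:2, n_per_sign = 20L,
                             log_transform = TRUE) {
  matrix <- validate_abundance(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("PCA needs >= 2 features and >= 2 samples")
  }
  x <- t(if (log_transform) log10(matrix + 1) else matrix)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  if (n_per_sign > nrow(matrix)) {
    warning("n_per_sign exceeds feature count; truncating to ", nrow(matrix))
    n_per_sign <- nrow(matrix)
  }
  lapply(components, function(k) {
    if (k > ncol(pc$rotation)) stop("component ", k, " not available")
    load <- pc$rotation[, k]
    pos <- load[load > 0]; neg <- load[load < 0]
    top_pos <- names(sort(abs(pos), decreasing = TRUE))[seq_len(min(n_per_sign, length(pos)))]
    top_neg <- names(sort(abs(neg), decreasing = TRUE))[seq_len(min(n_per_sign, length(neg)))]
    list(component = k, explained_variance = ev[k],
         top_positive = top_pos, top_negative = top_neg, loadings = load)
  })
}
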