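#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = count / (gene length in kb x library size in millions)`.
#'
#' @param counts integer matrix genes x samples.
#' @param gene_length_bp positive gene lengths (bp), recycled over rows;
#'   named vectors are matched to rownames.
#' @param library_size positive total mapped reads per sample; named
#'   vectors are matched to colnames.
#' @return RPKM matrix of the same shape.
#' @export
rpkm <- function(counts, gene_length_bp, library_size) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(names(gene_length_bp)) && !is.null(rownames(counts))) {
    gene_length_bp <- gene_length_bp[rownames(counts)]
  }
  if (!is.null(names(library_size)) && !is.null(colnames(counts))) {
    library_size <- library_size[colnames(counts)]
  }
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  sweep(counts / (gene_length_bp / 1000), 2L, library_size / 1e6, "/")
}

#' Expression filter on read counts and RPKM
#'
#' Removes genes too weakly measured to test. Permissive reading (default):
#' a gene is removed if its maximum per-library read count is below
#' `min_reads` or its replicate-mean RPKM is below `min_mean_rpkm` in
#' *every* condition — this keeps stage-specific genes expressed in only
#' part of the time course. Strict mode removes a gene whose total reads
#' fall below `min_reads` or whose mean RPKM is below the floor in *any*
#' condition. Thresholds are exclusive: a gene exactly at `min_reads` /
#' `min_mean_rpkm` is retained.
#'
#' @param counts integer matrix genes x samples.
#' @param rpkm_matrix matching RPKM matrix (see [rpkm()]).
#' @param design a [study_design()].
#' @param min_reads read floor (default 10).
#' @param min_mean_rpkm replicate-mean RPKM floor (default 0.1).
#' @param strict use the strict reading.
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(counts, rpkm_matrix, design, min_reads = 10,
                              min_mean_rpkm = 0.1, strict = FALSE) {
  design <- study_design(design)
  mean_rpkm <- condition_means(rpkm_matrix, design)
  stopifnot(identical(rownames(counts), rownames(rpkm_matrix)))
  if (strict) {
    keep <- rowSums(counts) >= min_reads &
      apply(mean_rpkm, 1L, min) >= min_mean_rpkm
  } else {
    keep <- apply(counts, 1L, max) >= min_reads &
      apply(mean_rpkm, 1L, max) >= min_mean_rpkm
  }
  rownames(counts)[keep]
}

#' Baggerley's weighted proportion test on count replicates
#'
#' Compares the per-gene read proportion between two groups of replicate
#' libraries. Within each group, replicate proportions `p_i = y_i / N_i`
#' are combined with library-size weights `w_i = N_i / sum(N_i)` into
#' `p_hat = sum(w_i p_i)`; its variance is the between-replicate weighted
#' variance `sum(w_i (p_i - p_hat)^2) * sum(w_i^2) / (1 - sum(w_i^2))`,
#' floored at the binomial variance `p_hat (1 - p_hat) / sum(N_i)`. The
#' statistic `t = (p_hat_A - p_hat_B) / sqrt(V_A + V_B)` is referred to a
#' t distribution with `n_A + n_B - 2` degrees of freedom (two-sided).
#'
#' @param counts_a,counts_b count matrices (genes x replicates), >= 2
#'   replicates per group.
#' @param lib_a,lib_b library sizes (total mapped reads) per replicate.
#' @return data.frame: gene_id, statistic, df, p_value. Genes with zero
#'   counts in both groups get p = 1 by convention.
#' @export
baggerley_test <- function(counts_a, counts_b, lib_a, lib_b) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) < 2L || ncol(counts_b) < 2L) {
    stop("need >= 2 replicates per group")
  }
  stopifnot(length(lib_a) == ncol(counts_a), length(lib_b) == ncol(counts_b))
  group <- function(y, N) {
    w <- N / sum(N)
    p <- sweep(y, 2L, N, "/")
    phat <- rowSums(sweep(p, 2L, w, "*"))  # equals rowSums(y)/sum(N)
    vw <- rowSums(sweep((p - phat)^2, 2L, w, "*")) * sum(w^2) / (1 - sum(w^2))
    vfloor <- phat * (1 - phat) / sum(N)
    list(phat = phat, v = pmax(vw, vfloor))
  }
  A <- group(counts_a, lib_a)
  B <- group(counts_b, lib_b)
  t <- (A$phat - B$phat) / sqrt(A$v + B$v)
  df <- ncol(counts_a) + ncol(counts_b) - 2L
  p <- 2 * stats::pt(-abs(t), df)
  zero <- rowSums(counts_a) == 0 & rowSums(counts_b) == 0
  t[zero | !is.finite(t)] <- 0
  p[zero | is.na(p)] <- 1
  data.frame(gene_id = rownames(counts_a) %||% seq_len(nrow(counts_a)),
             statistic = t, df = df, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values with monotonicity enforcement (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values, same length; always `q >= p`.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes across the time course
#'
#' A gene is selected iff at some timepoint |log2 ratio| > `fc_log2_min`
#' and q < `q_max` (strict inequalities, following the printed rule
#' "-2 > log2 ratio > 2, FDR p < 0.05 in at least one time-point").
#'
#' @param log2fc matrix genes x timepoints of log2 genotype ratios.
#' @param q matrix of matching BH q-values.
#' @param fc_log2_min log2 fold cut-off (default 2).
#' @param q_max FDR cut-off (default 0.05).
#' @return Character vector of selected gene ids.
#' @export
select_de <- function(log2fc, q, fc_log2_min = 2, q_max = 0.05) {
  stopifnot(identical(dim(log2fc), dim(q)))
  hit <- abs(log2fc) > fc_log2_min & q < q_max
  hit[is.na(hit)] <- FALSE
  rownames(log2fc)[rowSums(hit) > 0L]
}

#' Per-timepoint differential expression pipeline
#'
#' Runs [baggerley_test()] (russet vs waxy) at every timepoint, applies
#' [bh_fdr()] across genes within each timepoint, computes log2 ratios of
#' per-condition mean RPKM, and selects genes with [select_de()].
#'
#' @param counts integer matrix genes x samples.
#' @param gene_length_bp,library_size see [rpkm()].
#' @param design a [study_design()].
#' @param fc_log2_min,q_max selection thresholds (defaults 2 and 0.05).
#' @param pseudocount added to mean RPKM before the ratio (default 0).
#' @return list with matrices `log2fc`, `p`, `q` (genes x timepoints) and
#'   `selected` gene ids.
#' @export
differential_expression <- function(counts, gene_length_bp, library_size,
                                    design, fc_log2_min = 2, q_max = 0.05,
                                    pseudocount = 0) {
  design <- study_design(design)
  if (!is.null(names(library_size))) library_size <- library_size[colnames(counts)]
  tps <- sort(unique(design$timepoint_dafb))
  p <- q <- base::matrix(NA_real_, nrow(counts), length(tps),
                         dimnames = list(rownames(counts), as.character(tps)))
  for (k in seq_along(tps)) {
    ids_r <- design$sample_id[design$genotype == "russet" &
                              design$timepoint_dafb == tps[k]]
    ids_w <- design$sample_id[design$genotype == "waxy" &
                              design$timepoint_dafb == tps[k]]
    bt <- baggerley_test(counts[, ids_r, drop = FALSE],
                         counts[, ids_w, drop = FALSE],
                         library_size[ids_r], library_size[ids_w])
    p[, k] <- bt$p_value
    q[, k] <- bh_fdr(bt$p_value)
  }
  rp <- rpkm(counts, gene_length_bp, library_size)
  lfc <- suppressWarnings(
    log2_ratio_profile(condition_means(rp, design), pseudocount = pseudocount))
  list(log2fc = lfc, p = p, q = q,
       selected = select_de(lfc, q, fc_log2_min, q_max))
}

#' Cluster expression profiles by Pearson correlation, complete linkage
#'
#' Distance = 1 - Pearson correlation between per-condition mean profiles;
#' agglomeration by complete linkage; the tree is cut into `k` clusters.
#' Constant profiles (undefined correlation) are excluded with a warning
#' and reported separately. Cluster ids are relabeled by decreasing size.
#'
#' @param profiles matrix genes x conditions (see [condition_means()]).
#' @param k number of clusters (default 9, the reference analysis).
#' @return list with `clusters` (named integer vector), `hclust` (the
#'   dendrogram; merge heights are nondecreasing), `excluded` (constant
#'   profiles).
#' @export
cluster_expression <- function(profiles, k = 9L) {
  sds <- apply(profiles, 1L, stats::sd)
  excluded <- rownames(profiles)[sds == 0 | !is.finite(sds)]
  if (length(excluded)) {
    warning(length(excluded), " constant profile(s) excluded from clustering")
  }
  keep <- setdiff(rownames(profiles), excluded)
  if (length(keep) < k) stop("fewer than k nonconstant profiles")
  d <- stats::as.dist(1 - stats::cor(t(profiles[keep, , drop = FALSE])))
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  clusters <- relabel[as.character(raw)]
  names(clusters) <- names(raw)
  list(clusters = clusters, hclust = hc, excluded = excluded)
}

#' Hypergeometric over-representation of annotation terms in a cluster
#'
#' Upper-tail hypergeometric p per term (probability of observing at least
#' the seen overlap between the cluster and the term's gene set within the
#' universe), followed by BH correction across terms.
#'
#' @param cluster_genes character vector, subset of `universe`.
#' @param annotation named list term -> gene ids (subset of `universe`).
#' @param universe character vector of all testable genes.
#' @return data.frame: term, hits, cluster_size, term_size, universe_size,
#'   p_value, q_value; empty for an empty cluster.
#' @export
hypergeometric_enrichment <- function(cluster_genes, annotation, universe) {
  if (!all(cluster_genes %in% universe)) stop("cluster must be within universe")
  if (!length(cluster_genes)) {
    return(data.frame(term = character(), hits = integer(),
                      cluster_size = integer(), term_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(universe); n <- length(cluster_genes)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(annotation[[term]], universe)
    K <- length(genes)
    k <- length(intersect(cluster_genes, genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, hits = k, cluster_size = n, term_size = K,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
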