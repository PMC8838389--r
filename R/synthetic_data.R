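#' Simulation configuration for the synthetic tri-omics generator
#'
#' Bundles the knobs of the generators with the defaults that emulate the
#' reference experiment: 2 genotypes x 5 timepoints x 3 replicates, a
#' planted genotype effect of 3 log2 units, 20% replicate coefficient of
#' variation on LC-MS areas, and negative-binomial counts with dispersion
#' 0.05 for RNA-seq replicates.
#'
#' @param seed integer master seed; each generator derives its own
#'   substream (`seed + fixed offset`) so layers can be regenerated
#'   independently.
#' @param n_features number of metabolite features (>= 10).
#' @param n_genes,n_proteins,n_varieties,n_loci sizes of the other layers.
#' @param class_proportions named proportions over the metabolite classes
#'   `null`, `russet_up`, `russet_down`, `dev_up`, `dev_down`,
#'   `crossover_conjugate`; must sum to 1.
#' @param effect_log2fc planted log2 effect size for differential classes.
#' @param replicate_cv replicate coefficient of variation of the
#'   multiplicative log-normal noise on metabolite areas.
#' @param nb_dispersion negative-binomial dispersion of RNA-seq counts.
#' @param library_size_mean mean total mapped reads per library.
#' @param prop_de,prop_clustered fractions of genes carrying a planted
#'   genotype effect / a planted expression archetype (the rest are null).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_features = 200L,
                       n_genes = 500L,
                       n_proteins = 100L,
                       n_varieties = 27L,
                       n_loci = 16L,
                       class_proportions = c(null = 0.70, russet_up = 0.08,
                                             russet_down = 0.08, dev_up = 0.05,
                                             dev_down = 0.05,
                                             crossover_conjugate = 0.04),
                       effect_log2fc = 3,
                       replicate_cv = 0.2,
                       nb_dispersion = 0.05,
                       library_size_mean = 2e7,
                       prop_de = 0.1,
                       prop_clustered = 0.2) {
  classes <- c("null", "russet_up", "russet_down", "dev_up", "dev_down",
               "crossover_conjugate")
  if (!setequal(names(class_proportions), classes)) {
    stop("class_proportions must be named over: ", paste(classes, collapse = ", "))
  }
  class_proportions <- class_proportions[classes]
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stop("class_proportions must be nonnegative and sum to 1")
  }
  if (n_features < 10L) stop("n_features must be >= 10")
  if (n_varieties < 2L) stop("n_varieties must be >= 2")
  if (prop_de < 0 || prop_clustered < 0 || prop_de + prop_clustered > 1) {
    stop("prop_de and prop_clustered must be nonnegative with sum <= 1")
  }
  stopifnot(replicate_cv >= 0, nb_dispersion >= 0, library_size_mean > 0)
  structure(list(seed = as.integer(seed), n_features = as.integer(n_features),
                 n_genes = as.integer(n_genes), n_proteins = as.integer(n_proteins),
                 n_varieties = as.integer(n_varieties), n_loci = as.integer(n_loci),
                 class_proportions = class_proportions,
                 effect_log2fc = effect_log2fc, replicate_cv = replicate_cv,
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 prop_de = prop_de, prop_clustered = prop_clustered),
            class = "sim_config")
}

# mean-one multiplicative log-normal noise at a given CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

assign_classes <- function(n, proportions) {
  counts <- floor(proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) { # give remainder to the largest classes, deterministic
    ord <- order(proportions * n - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  rep(names(proportions), counts)
}

#' Generate a synthetic metabolome with planted differential classes
#'
#' Features are log-normal around a per-feature base area with replicate
#' CV `replicate_cv`. Planted classes: `russet_up`/`russet_down` multiply the
#' russet genotype by `2^(+-effect_log2fc)` at every timepoint; `dev_up`/
#' `dev_down` apply a monotone multiplier across timepoints in both
#' genotypes; `crossover_conjugate` is higher in russet at the first two
#' timepoints and higher in waxy afterwards, mimicking the conjugated
#' triterpenes whose trend reverses mid-development.
#'
#' @param config a [sim_config()].
#' @param design a [study_design()].
#' @return list with `matrix` (features x samples EIC areas) and
#'   `ground_truth` (`metabolite_class` named character vector).
#' @export
generate_metabolome <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  design <- study_design(design)
  set.seed(config$seed + 101L)
  n <- config$n_features
  ids <- sprintf("feat%04d", seq_len(n))
  cls <- assign_classes(n, config$class_proportions)
  names(cls) <- ids
  base <- stats::rlnorm(n, meanlog = log(5000), sdlog = 1)
  tps <- sort(unique(design$timepoint_dafb))
  ti <- match(design$timepoint_dafb, tps)          # 1..n_timepoints
  nt <- length(tps)
  e <- config$effect_log2fc
  m <- base::matrix(0, nrow = n, ncol = nrow(design),
                    dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    russet <- design$genotype[j] == "russet"
    dev_frac <- if (nt > 1) (ti[j] - 1) / (nt - 1) else 0
    log2_mult <- numeric(n)
    log2_mult[cls == "russet_up"] <- if (russet) e else 0
    log2_mult[cls == "russet_down"] <- if (russet) -e else 0
    log2_mult[cls == "dev_up"] <- e * dev_frac
    log2_mult[cls == "dev_down"] <- -e * dev_frac
    log2_mult[cls == "crossover_conjugate"] <-
      if (russet) (if (ti[j] <= 2) e else -e) else 0
    m[, j] <- base * 2^log2_mult * lnorm_noise(n, config$replicate_cv)
  }
  list(matrix = validate_abundance(m),
       ground_truth = list(metabolite_class = cls))
}

# archetype log2 expression offsets over one genotype's timepoints
archetype_profiles <- function(n_timepoints, effect) {
  dev <- seq(0, 1, length.out = n_timepoints)
  mid <- exp(-((seq_len(n_timepoints) - (n_timepoints + 1) / 2)^2) / 2)
  mid <- (mid - min(mid)) / (max(mid) - min(mid))
  list(
    # strong increasing expression in waxy, fading in russet (clusters C1-C3)
    waxy_up = list(waxy = effect * dev, russet = -1 * dev),
    # enhanced expression in russet at mid-development (clusters C4-C7)
    russet_mid = list(waxy = rep(0, n_timepoints), russet = effect * mid)
  )
}

#' Generate synthetic RNA-seq counts with planted effects and archetypes
#'
#' Counts are negative-binomial with mean = expected RPKM x gene length (kb)
#' x library size (millions) and dispersion `nb_dispersion`; gene lengths
#' are uniform on 500-5000 bp. A fraction `prop_de` of genes carries a flat
#' genotype effect of `+-effect_log2fc` log2 units (sign alternating); a
#' fraction `prop_clustered` follows one of two expression archetypes
#' (waxy-high-increasing, russet-high-mid-development); the rest are null.
#'
#' @param config a [sim_config()].
#' @param design a [study_design()].
#' @return list with `counts` (integer matrix genes x samples),
#'   `gene_length_bp`, `library_size`, and `ground_truth`
#'   (`de_gene_set` named signed log2 effects, `cluster_label` named
#'   archetype ids).
#' @export
generate_transcriptome <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  design <- study_design(design)
  set.seed(config$seed + 202L)
  n <- config$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  lens <- round(stats::runif(n, 500, 5000))
  lib <- round(config$library_size_mean *
                 pmax(0.5, stats::rnorm(nrow(design), 1, 0.1)))
  names(lib) <- design$sample_id
  tps <- sort(unique(design$timepoint_dafb))
  ti <- match(design$timepoint_dafb, tps)
  n_de <- round(config$prop_de * n)
  n_cl <- round(config$prop_clustered * n)
  kind <- rep("null", n)
  kind[seq_len(n_de)] <- "de"
  if (n_cl > 0) kind[n_de + seq_len(n_cl)] <- "archetype"
  de_sign <- rep_len(c(1, -1), n_de)
  de_set <- setNames(de_sign * config$effect_log2fc, ids[kind == "de"])
  arch <- archetype_profiles(length(tps), config$effect_log2fc)
  arch_id <- rep_len(names(arch), n_cl)
  cluster_label <- setNames(arch_id, ids[kind == "archetype"])
  arch_full <- rep(NA_character_, n)
  arch_full[kind == "archetype"] <- arch_id
  base_rpkm <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)
  counts <- base::matrix(0L, nrow = n, ncol = nrow(design),
                         dimnames = list(ids, design$sample_id))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  for (j in seq_len(nrow(design))) {
    g <- design$genotype[j]
    log2_off <- numeric(n)
    if (n_de > 0 && g == "russet") log2_off[kind == "de"] <- de_set
    for (a in names(arch)) {
      sel <- !is.na(arch_full) & arch_full == a
      log2_off[sel] <- arch[[a]][[g]][ti[j]]
    }
    mu <- base_rpkm * 2^log2_off * (lens / 1000) * (lib[j] / 1e6)
    counts[, j] <- if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
                   else stats::rpois(n, mu)
  }
  list(counts = counts,
       gene_length_bp = setNames(lens, ids),
       library_size = lib,
       ground_truth = list(de_gene_set = de_set, cluster_label = cluster_label))
}

#' Generate a synthetic spectral-count proteome tied to a transcriptome
#'
#' Proteins are a subset of the simulated genes; spectral counts are Poisson
#' with rate proportional to the gene's realized transcript abundance and
#' the protein length. A peptide-evidence table carries per-peptide spectra
#' counts and p-values spanning both sides of the evidence filters (p <
#' 0.05, >= 5 spectra, >= 2 significant peptides).
#'
#' @param config a [sim_config()].
#' @param transcriptome output of [generate_transcriptome()].
#' @return list with `spectral_counts` (proteins x samples),
#'   `protein_length_aa`, `evidence` (protein_id, peptide, spectra_count,
#'   p_value), and `ground_truth` (`protein_genes`: the gene each protein
#'   reports on).
#' @export
generate_proteome <- function(config, transcriptome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  genes <- rownames(transcriptome$counts)
  if (config$n_proteins > length(genes)) {
    stop("protein subset larger than gene set (", config$n_proteins, " > ",
         length(genes), ")")
  }
  pick <- genes[seq_len(config$n_proteins)]
  ids <- sub("^gene", "prot", pick)
  len_aa <- pmax(50L, round(transcriptome$gene_length_bp[pick] / 3))
  names(len_aa) <- ids
  # realized RPKM of the parent gene drives the spectral-count rate
  rp <- rpkm(transcriptome$counts[pick, , drop = FALSE],
             transcriptome$gene_length_bp[pick], transcriptome$library_size)
  lambda <- sweep(rp / 10, 1, len_aa / 500, "*")
  spc <- base::matrix(stats::rpois(length(lambda), lambda),
                      nrow = nrow(lambda), dimnames = list(ids, colnames(rp)))
  n_pep <- pmax(1L, stats::rpois(length(ids), 3))
  evidence <- data.frame(
    protein_id = rep(ids, n_pep), stringsAsFactors = FALSE)
  evidence$peptide <- paste0("PEP", seq_len(nrow(evidence)))
  evidence$spectra_count <- stats::rpois(nrow(evidence), 6)
  evidence$p_value <- stats::rbeta(nrow(evidence), 0.4, 3)
  list(spectral_counts = spc, protein_length_aa = len_aa, evidence = evidence,
       ground_truth = list(protein_genes = setNames(pick, ids)))
}

#' Generate a synthetic SSR allele-call panel with one clone pair
#'
#' Each locus has an allele pool of 8-14 labels (fragment sizes); varieties
#' draw 2 (diploid) or 3 (triploid) distinct alleles per locus. The first
#' two varieties are an exact clone pair, duplicated allele-for-allele,
#' mirroring the perfect allelic identity of the two studied sports.
#'
#' @param config a [sim_config()].
#' @return list with `calls` (variety, locus, allele1..allele3; NA for the
#'   absent triploid slot) and `ground_truth` (`clone_pair`, `allele_pools`).
#' @export
generate_ssr_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_varieties < 2L) stop("n_varieties must be >= 2")
  set.seed(config$seed + 404L)
  loci <- sprintf("SSR%02d", seq_len(config$n_loci))
  pools <- lapply(loci, function(l) {
    k <- sample(8:14, 1L)
    as.character(seq(100L, by = 2L, length.out = k))
  })
  names(pools) <- loci
  vars <- sprintf("V%02d", seq_len(config$n_varieties))
  ploidy <- sample(c(2L, 3L), config$n_varieties, replace = TRUE,
                   prob = c(0.9, 0.1))
  rows <- list()
  for (i in seq_along(vars)) {
    for (l in loci) {
      al <- sort(sample(pools[[l]], ploidy[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        variety = vars[i], locus = l,
        allele1 = al[1L], allele2 = al[2L],
        allele3 = if (ploidy[i] == 3L) al[3L] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  # variety 2 becomes a perfect clone of variety 1
  clone_of <- calls[calls$variety == vars[1L], ]
  clone_of$variety <- vars[2L]
  calls[calls$variety == vars[2L], ] <- clone_of
  list(calls = calls,
       ground_truth = list(clone_pair = vars[1:2], allele_pools = pools))
}

#' Generate condition-level profiles with planted gene-metabolite links
#'
#' Builds gene and metabolite condition profiles (log-scale, one value per
#' genotype x timepoint condition) where the first `n_linked` gene/metabolite
#' pairs share a planted Pearson correlation `rho`; all remaining profiles
#' are independent noise. Used to validate the cross-omics nomination rule.
#'
#' @param n_genes,n_metabolites numbers of profiles.
#' @param n_linked number of planted pairs (gene i with metabolite i).
#' @param rho planted correlation of linked pairs.
#' @param n_conditions profile length (10 in the reference design).
#' @param seed integer seed.
#' @return list with `gene_profiles`, `metabolite_profiles` (matrices with
#'   rows as features) and `linked_pairs` (data.frame gene_id,
#'   metabolite_id, rho).
#' @export
generate_linked_profiles <- function(n_genes = 50L, n_metabolites = 20L,
                                     n_linked = min(n_genes, n_metabolites),
                                     rho = 0.95, n_conditions = 10L,
                                     seed = 1L) {
  stopifnot(n_linked <= min(n_genes, n_metabolites), abs(rho) <= 1)
  set.seed(seed)
  g <- base::matrix(stats::rnorm(n_genes * n_conditions), nrow = n_genes,
                    dimnames = list(sprintf("gene%05d", seq_len(n_genes)), NULL))
  m <- base::matrix(stats::rnorm(n_metabolites * n_conditions),
                    nrow = n_metabolites,
                    dimnames = list(sprintf("feat%04d", seq_len(n_metabolites)), NULL))
  if (n_linked > 0L) for (i in seq_len(n_linked)) {
    m[i, ] <- rho * scale(g[i, ])[, 1L] + sqrt(1 - rho^2) * stats::rnorm(n_conditions)
  }
  cond <- condition_key(rep(GENOTYPES, each = ceiling(n_conditions / 2)),
                        seq_len(n_conditions))[seq_len(n_conditions)]
  colnames(g) <- colnames(m) <- cond
  list(gene_profiles = g, metabolite_profiles = m,
       linked_pairs = data.frame(
         gene_id = rownames(g)[seq_len(n_linked)],
         metabolite_id = rownames(m)[seq_len(n_linked)],
         rho = rep_len(rho, n_linked), stringsAsFactors = FALSE))
}
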