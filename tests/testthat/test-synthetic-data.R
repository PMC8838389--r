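test_that("simulation config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_features = 5), ">= 10")
  expect_error(sim_config(n_varieties = 1), ">= 2")
  expect_error(sim_config(class_proportions = c(null = 0.5, russet_up = 0.6,
                                                russet_down = 0, dev_up = 0,
                                                dev_down = 0,
                                                crossover_conjugate = 0)),
               "sum to 1")
  expect_error(sim_config(class_proportions = c(bad = 1)), "named over")
  expect_error(sim_config(prop_de = 0.8, prop_clustered = 0.5), "sum <= 1")
})

test_that("all generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_features = 40, n_genes = 50, n_proteins = 20,
                    n_varieties = 6)
  a <- generate_metabolome(cfg, ref_design)
  b <- generate_metabolome(cfg, ref_design)
  expect_identical(a, b)
  ta <- generate_transcriptome(cfg, ref_design)
  tb <- generate_transcriptome(cfg, ref_design)
  expect_identical(ta, tb)
  expect_identical(generate_proteome(cfg, ta), generate_proteome(cfg, ta))
  expect_identical(generate_ssr_panel(cfg), generate_ssr_panel(cfg))
})

test_that("metabolome abundances are nonnegative with planted effect sizes", {
  cfg <- sim_config(seed = 3, n_features = 400)
  met <- generate_metabolome(cfg, ref_design)
  expect_true(all(met$matrix >= 0))
  cls <- met$ground_truth$metabolite_class
  expect_setequal(names(cls), rownames(met$matrix))
  lr <- log2_ratio_profile(condition_means(met$matrix, ref_design))
  up <- names(cls)[cls == "russet_up"]
  # mean empirical log2 ratio of the planted class within 3 +- 0.5 per timepoint
  expect_true(all(abs(colMeans(lr[up, ]) - 3) < 0.5))
  down <- names(cls)[cls == "russet_down"]
  expect_true(all(abs(colMeans(lr[down, ]) + 3) < 0.5))
  # crossover class switches direction between timepoints 2 and 3
  xo <- names(cls)[cls == "crossover_conjugate"]
  expect_true(all(colMeans(lr[xo, c("57", "78")]) > 1))
  expect_true(all(colMeans(lr[xo, c("99", "120", "150")]) < -1))
})

test_that("transcriptome counts are integral with sane lengths and archetypes", {
  cfg <- sim_config(seed = 8, n_genes = 300, prop_clustered = 0.4)
  tx <- generate_transcriptome(cfg, ref_design)
  expect_true(all(tx$counts >= 0))
  expect_true(all(tx$counts == round(tx$counts)))
  expect_true(all(tx$gene_length_bp >= 500 & tx$gene_length_bp <= 5000))
  # same-archetype genes correlate strongly on condition profiles
  rp <- rpkm(tx$counts, tx$gene_length_bp, tx$library_size)
  prof <- condition_means(rp, ref_design)
  lab <- tx$ground_truth$cluster_label
  for (a in unique(lab)) {
    genes <- names(lab)[lab == a][1:10]
    cors <- stats::cor(t(prof[genes, ]))
    expect_gt(mean(cors[upper.tri(cors)]), 0.8)
  }
  # planted DE genes show the planted sign
  lr <- log2_ratio_profile(prof)
  de <- tx$ground_truth$de_gene_set
  expect_true(all(sign(rowMeans(lr[names(de), ])) == sign(de)))
})

test_that("near-zero dispersion approaches Poisson count variance", {
  run_fano <- function(dispersion, seed) {
    cfg <- sim_config(seed = seed, n_genes = 2000, nb_dispersion = dispersion,
                      prop_de = 0, prop_clustered = 0)
    tx <- generate_transcriptome(cfg, ref_design)
    ids <- ref_design$sample_id[ref_design$timepoint_dafb == 57 &
                                ref_design$genotype == "waxy"]
    # rescale replicates to a common library so means are shared
    lib <- tx$library_size[ids]
    sc <- sweep(tx$counts[, ids], 2, mean(lib) / lib, "*")
    mean(apply(sc, 1, var) / rowMeans(sc), na.rm = TRUE)
  }
  expect_equal(run_fano(1e-6, 12), 1, tolerance = 0.2)     # Poisson limit
  expect_gt(run_fano(0.5, 12), 5)                          # overdispersed
})

test_that("proteome generation respects the gene subset and zero counts", {
  cfg <- sim_config(seed = 14, n_genes = 60, n_proteins = 30)
  tx <- generate_transcriptome(cfg, ref_design)
  pr <- generate_proteome(cfg, tx)
  expect_true(all(pr$ground_truth$protein_genes %in% rownames(tx$counts)))
  expect_error(generate_proteome(sim_config(n_genes = 60, n_proteins = 200),
                                 tx), "subset larger")
  # zero-count proteins produce NSAF 0 without errors
  out <- nsaf(pr$spectral_counts + ifelse(rowSums(pr$spectral_counts) == 0, 1, 0),
              pr$protein_length_aa)
  expect_true(all(is.finite(out)))
  expect_true(all(c("protein_id", "peptide", "spectra_count", "p_value") %in%
                  names(pr$evidence)))
  # evidence spans both sides of the identification filters
  kept <- evidence_filter(pr$evidence)
  expect_gt(length(kept), 0)
  expect_lt(length(kept), length(unique(pr$evidence$protein_id)))
})

test_that("concordant gene-protein pairs mostly share ratio signs", {
  cfg <- sim_config(seed = 26, n_genes = 100, n_proteins = 40, prop_de = 0.5,
                    prop_clustered = 0)
  tx <- generate_transcriptome(cfg, ref_design)
  pr <- generate_proteome(cfg, tx)
  lfc <- log2_ratio_profile(condition_means(
    rpkm(tx$counts, tx$gene_length_bp, tx$library_size), ref_design))
  keep <- rowSums(pr$spectral_counts) > 0
  np <- nsaf(pr$spectral_counts[keep, ], pr$protein_length_aa[keep])
  pt <- differential_nsaf(condition_means(np, ref_design))
  map <- data.frame(gene_id = unname(pr$ground_truth$protein_genes[keep]),
                    protein_id = names(pr$ground_truth$protein_genes)[keep])
  cc <- rna_protein_concordance(lfc, pt, map)
  de_genes <- names(tx$ground_truth$de_gene_set)
  frac <- cc$fraction[cc$gene_id %in% de_genes & cc$n_evaluable >= 3]
  expect_gt(mean(frac, na.rm = TRUE), 0.8)
})

test_that("SSR panel has 8-14 allele pools and an exact clone pair", {
  pan <- generate_ssr_panel(sim_config(seed = 7))
  pools <- pan$ground_truth$allele_pools
  expect_true(all(lengths(pools) >= 8 & lengths(pools) <= 14))
  calls <- pan$calls
  # every observed allele belongs to its locus pool
  for (l in names(pools)) {
    obs <- unlist(calls[calls$locus == l, c("allele1", "allele2", "allele3")])
    expect_true(all(stats::na.omit(obs) %in% pools[[l]]))
  }
  pair <- pan$ground_truth$clone_pair
  a <- calls[calls$variety == pair[1], -1]
  b <- calls[calls$variety == pair[2], -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_error(generate_ssr_panel(sim_config(seed = 1, n_varieties = 1)),
               ">= 2")
})
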