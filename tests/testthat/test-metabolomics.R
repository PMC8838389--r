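test_that("welch test matches closed-form statistics and handles degeneracy", {
  d <- study_design(data.frame(
    sample_id = c(paste0("r", 1:3), paste0("w", 1:3)),
    genotype = rep(c("russet", "waxy"), each = 3),
    timepoint_dafb = 57L, replicate = rep(1:3, 2)))
  m <- rbind(f1 = c(1, 2, 3, 4, 5, 6),   # russet (1,2,3) vs waxy (4,5,6)
             f2 = c(2, 2, 2, 2, 2, 2))   # identical groups
  colnames(m) <- d$sample_id
  res <- welch_test(m, d, 57)
  expect_equal(res$statistic[1], -3.674, tolerance = 1e-3)
  expect_equal(res$p_value[1], 0.0213, tolerance = 1e-2)
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$p_value[2], 1)  # zero variance, equal means
  expect_true(res$degenerate[2])
  # zero variance, unequal means -> p = 0 flagged
  m2 <- rbind(f = c(1, 1, 1, 3, 3, 3)); colnames(m2) <- d$sample_id
  res2 <- welch_test(m2, d, 57)
  expect_equal(res2$p_value, 0)
  expect_true(res2$degenerate)
})

test_that("planted genotype effects are detected with high power", {
  # russet_up features (effect 3, CV 0.2, n = 3) rejected at p < 0.01
  cfg <- sim_config(seed = 61, n_features = 300,
                    class_proportions = c(null = 0.5, russet_up = 0.5,
                                          russet_down = 0, dev_up = 0,
                                          dev_down = 0, crossover_conjugate = 0))
  met <- generate_metabolome(cfg, ref_design)
  dm <- differential_metabolites(met$matrix, ref_design)
  up <- names(met$ground_truth$metabolite_class)[
    met$ground_truth$metabolite_class == "russet_up"]
  hit <- dm[dm$feature_id %in% up, ]
  expect_gt(mean(hit$p_value < 0.01), 0.8)
  expect_equal(mean(hit$log2fc), 3, tolerance = 0.2)
})

test_that("null data reject near the nominal rate", {
  cfg <- sim_config(seed = 62, n_features = 2000, effect_log2fc = 0)
  met <- generate_metabolome(cfg, ref_design)
  dm <- differential_metabolites(met$matrix, ref_design)
  expect_lt(abs(mean(dm$p_value < 0.05) - 0.05), 0.025)
})

test_that("multigroup pattern filter classifies by the two ratio rules", {
  flat <- profile_from_rows(list(
    flat = rep(7, 10),
    small = c(rep(1, 5), rep(2^0.5, 5))))     # log2fc 0.5, flat in time
  colnames(flat) <- colnames(phloretin())
  cls <- multigroup_pattern_filter(flat)
  expect_identical(cls$class, c("none", "none"))
  # phloretin: genotype ratios all > 2x and development span > 10x
  expect_identical(multigroup_pattern_filter(phloretin())$class, "both")
  expect_error(multigroup_pattern_filter(flat - 1), "positive")
})

test_that("multigroup filter is invariant to a global scale factor", {
  p <- phloretin()
  expect_identical(multigroup_pattern_filter(p),
                   multigroup_pattern_filter(p * 137))
})

test_that("venn meta-analysis center is the direction-consistent intersection", {
  tps <- c(57, 78, 99, 120, 150)
  mk <- function(feature, lfc, p) {
    data.frame(feature_id = feature, timepoint = tps, log2fc = lfc, p_value = p)
  }
  tab <- rbind(
    mk("always_up", rep(2, 5), rep(0.001, 5)),        # center
    mk("four_of_five", rep(2, 5), c(0.001, 0.001, 0.5, 0.001, 0.001)),
    mk("flip", c(2, 2, -2, 2, 2), rep(0.001, 5)))     # significant, sign flips
  v <- venn_meta_analysis(tab)
  expect_identical(v$center, "always_up")
  expect_true("four_of_five" %in% v$sets[["57"]])
  expect_false("four_of_five" %in% v$sets[["99"]])
  unsigned <- venn_meta_analysis(tab, signed = FALSE)
  expect_setequal(unsigned$center, c("always_up", "flip"))
})

test_that("venn center equals a brute-force set intersection", {
  set.seed(71)
  tps <- c(57, 78, 99, 120, 150)
  feats <- sprintf("f%03d", 1:200)
  tab <- do.call(rbind, lapply(tps, function(tp) {
    data.frame(feature_id = feats, timepoint = tp,
               log2fc = rnorm(200, 0, 2), p_value = runif(200))
  }))
  v <- venn_meta_analysis(tab, signed = FALSE)
  oracle <- Reduce(intersect, lapply(split(tab, tab$timepoint), function(x) {
    x$feature_id[x$p_value < 0.01 & abs(x$log2fc) > log2(1.5)]
  }))
  expect_setequal(v$center, oracle)
  # invariance under permuted timepoint order
  perm <- tab[order(rev(tab$timepoint), tab$feature_id), ]
  expect_setequal(venn_meta_analysis(perm, signed = FALSE)$center, v$center)
})

test_that("PCA loadings agree with a direct eigendecomposition", {
  set.seed(81)
  m <- matrix(rlnorm(5 * 12, 5, 1), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:12)))
  sel <- pca_top_loadings(m, components = 1, n_per_sign = 5)[[1]]
  x <- scale(t(log10(m + 1)), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  v1 <- ev$vectors[, 1]
  if (sign(v1[1]) != sign(sel$loadings[1])) v1 <- -v1
  expect_equal(unname(sel$loadings), unname(v1), tolerance = 1e-8)
  expect_equal(sel$explained_variance, ev$values[1] / sum(ev$values),
               tolerance = 1e-8)
})

test_that("PCA explained variances are nonincreasing and rank-1 data saturate PC1", {
  s <- matrix(outer(c(1, 2, 4), c(1, 3, 5, 7)), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  sel <- pca_top_loadings(s, components = 1, n_per_sign = 3,
                          log_transform = FALSE)[[1]]
  expect_equal(sel$explained_variance, 1, tolerance = 1e-12)
  set.seed(82)
  m <- matrix(rlnorm(40 * 10), nrow = 40,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:10)))
  comps <- pca_top_loadings(m, components = 1:5, n_per_sign = 3)
  evs <- vapply(comps, `[[`, numeric(1), "explained_variance")
  expect_true(all(diff(evs) <= 1e-12))
  expect_lte(sum(evs), 1 + 1e-12)
  expect_warning(pca_top_loadings(m[1:3, ], components = 1, n_per_sign = 20),
                 "truncating")
})

test_that("PC axes recover the planted design structure", {
  # development-dominant metabolome (the published regime: most features
  # track maturity): the planted trend loads PC1, the genotype split PC2
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 90 + s, n_features = 120,
                      class_proportions = c(null = 0.1, russet_up = 0.1,
                                            russet_down = 0.1, dev_up = 0.35,
                                            dev_down = 0.35,
                                            crossover_conjugate = 0))
    met <- generate_metabolome(cfg, ref_design)
    sel <- pca_top_loadings(met$matrix, components = 1:2)
    cls <- met$ground_truth$metabolite_class
    dev_feats <- names(cls)[cls %in% c("dev_up", "dev_down")]
    gen_feats <- names(cls)[cls %in% c("russet_up", "russet_down")]
    pc1 <- c(sel[[1]]$top_positive, sel[[1]]$top_negative)
    pc2 <- c(sel[[2]]$top_positive, sel[[2]]$top_negative)
    dev_on_1 <- mean(pc1 %in% dev_feats)
    gen_on_2 <- mean(pc2 %in% gen_feats)
    if (dev_on_1 > mean(pc1 %in% gen_feats) &&
        gen_on_2 > mean(pc2 %in% dev_feats)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
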