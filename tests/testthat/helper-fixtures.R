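# Shared fixtures, all built in code.

ref_design <- make_design()  # 2 genotypes x {57,78,99,120,150} DAFB x 3 reps

# tiny abundance matrix with known per-condition means
toy_matrix <- function(design = ref_design, features = c("f1", "f2"),
                       base = c(10, 100)) {
  m <- matrix(rep(base, ncol = nrow(design), times = nrow(design)),
              nrow = length(features), ncol = nrow(design),
              dimnames = list(features, design$sample_id))
  m
}

# profile matrix (condition columns) from a named list genotype_tp -> values
profile_from_rows <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

extdata <- function(f) system.file("extdata", f, package = "russetomics")

ltp3_rpkm <- function() read_abundance(extdata("ltp3_rpkm.tsv"))
phloretin <- function() read_abundance(extdata("phloretin_eic.tsv"))
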