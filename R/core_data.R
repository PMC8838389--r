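#' @keywords internal
"_PACKAGE"

GENOTYPES <- c("waxy", "russet")

#' Build and validate a study design table
#'
#' A study design maps each sample to a genotype (waxy or russet skin),
#' a sampling timepoint in days after full bloom (DAFB) and a biological
#' replicate index. Every statistic in the package is computed against such
#' a design; the reference experiment is 2 genotypes x 5 timepoints
#' (57, 78, 99, 120, 150 DAFB) x 3 replicates.
#'
#' @param x data.frame with columns `sample_id`, `genotype`
#'   (`"waxy"`/`"russet"`), `timepoint_dafb` (integer days), `replicate`
#'   (positive integer).
#' @return A validated `study_design` data.frame.
#' @export
study_design <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "timepoint_dafb", "replicate")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$sample_id <- as.character(x$sample_id)
  x$genotype <- as.character(x$genotype)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicated sample_id in design: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$genotype), GENOTYPES)
  if (length(bad)) stop("unknown genotype level(s): ", paste(bad, collapse = ", "))
  x$timepoint_dafb <- as.integer(x$timepoint_dafb)
  x$replicate <- as.integer(x$replicate)
  if (any(x$replicate < 1L)) stop("replicate indices must be positive")
  if (any(is.na(x$timepoint_dafb))) stop("timepoint_dafb must be integer days")
  class(x) <- c("study_design", "data.frame")
  x
}

#' Construct the standard two-genotype time-course design
#'
#' @param timepoints integer vector of DAFB timepoints (strictly increasing).
#' @param replicates number of biological replicates per (genotype, timepoint).
#' @return A `study_design` with sample ids `<genotype>_<dafb>_<rep>`.
#' @export
make_design <- function(timepoints = c(57L, 78L, 99L, 120L, 150L),
                        replicates = 3L) {
  timepoints <- as.integer(timepoints)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must form a strictly increasing set")
  }
  grid <- expand.grid(replicate = seq_len(replicates), timepoint_dafb = timepoints,
                      genotype = GENOTYPES, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "timepoint_dafb", "replicate")]
  grid$sample_id <- sprintf("%s_%d_%d", grid$genotype, grid$timepoint_dafb,
                            grid$replicate)
  study_design(grid[, c("sample_id", "genotype", "timepoint_dafb", "replicate")])
}

#' Read a study design from TSV
#'
#' Expects a header `sample_id  genotype  timepoint_dafb  replicate`.
#' @param path file path.
#' @return A `study_design`.
#' @export
read_design <- function(path) {
  study_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read an abundance matrix from TSV
#'
#' First column is the feature id, remaining columns are samples. Values may
#' be EIC peak areas, RPKM, spectral counts or NSAF depending on the layer;
#' all must be nonnegative.
#'
#' @param path file path.
#' @return Numeric matrix, features in rows (rownames), samples in columns.
#' @export
read_abundance <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_abundance(m)
}

#' Validate an abundance matrix
#'
#' @param m numeric matrix with unique feature rownames and sample colnames.
#' @return `m`, invisibly checked: nonnegative, unique feature ids.
#' @export
validate_abundance <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("abundance must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("abundance matrix needs unique feature rownames")
  }
  if (any(m < 0, na.rm = TRUE)) stop("abundance values must be nonnegative")
  m
}

condition_key <- function(genotype, timepoint) sprintf("%s_%d", genotype, timepoint)

#' Per-condition replicate means
#'
#' Averages biological replicates within each (genotype, timepoint) cell,
#' producing the 10-condition profile (in the reference design) that
#' downstream correlation, clustering and ratio computations operate on.
#' Column order is fixed: all waxy timepoints in increasing DAFB order, then
#' all russet timepoints, so serialization is stable across runs.
#'
#' @param matrix abundance matrix (features x samples).
#' @param design a [study_design()] covering every sample in `matrix`.
#' @param na_rm drop missing replicates from the mean (a fully missing cell
#'   is an error); never imputes.
#' @return Matrix features x conditions with columns `<genotype>_<dafb>` and
#'   attribute `conditions` (data.frame genotype, timepoint_dafb).
#' @export
condition_means <- function(matrix, design, na_rm = TRUE) {
  matrix <- validate_abundance(matrix)
  design <- study_design(design)
  unknown <- setdiff(colnames(matrix), design$sample_id)
  if (length(unknown)) {
    stop("sample(s) present in matrix but absent from design: ",
         paste(unknown, collapse = ", "))
  }
  tps <- sort(unique(design$timepoint_dafb))
  gts <- intersect(GENOTYPES, unique(design$genotype))
  conds <- expand.grid(timepoint_dafb = tps, genotype = gts,
                       stringsAsFactors = FALSE)[, c("genotype", "timepoint_dafb")]
  out <- base::matrix(NA_real_, nrow = nrow(matrix), ncol = nrow(conds),
                      dimnames = list(rownames(matrix),
                                      condition_key(conds$genotype, conds$timepoint_dafb)))
  for (j in seq_len(nrow(conds))) {
    ids <- design$sample_id[design$genotype == conds$genotype[j] &
                            design$timepoint_dafb == conds$timepoint_dafb[j]]
    ids <- intersect(ids, colnames(matrix))
    if (!length(ids)) {
      stop("no sample for condition ", colnames(out)[j], " in matrix")
    }
    cell <- matrix[, ids, drop = FALSE]
    mu <- rowMeans(cell, na.rm = na_rm)
    if (any(!is.finite(mu))) {
      stop("condition ", colnames(out)[j], " has only missing replicates for ",
           "feature(s): ",
           paste(utils::head(rownames(matrix)[!is.finite(mu)], 5L), collapse = ", "))
    }
    out[, j] <- mu
  }
  attr(out, "conditions") <- conds
  out
}

#' Condition annotation of a profile matrix
#'
#' @param profiles output of [condition_means()].
#' @return data.frame with columns genotype and timepoint_dafb, one row per
#'   profile column.
#' @export
profile_conditions <- function(profiles) {
  conds <- attr(profiles, "conditions")
  if (is.null(conds)) {
    parts <- strsplit(colnames(profiles), "_", fixed = TRUE)
    conds <- data.frame(genotype = vapply(parts, `[`, "", 1L),
                        timepoint_dafb = as.integer(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  conds
}

#' Per-timepoint log2 genotype ratio of condition profiles
#'
#' Computes `log2((numerator + pseudocount) / (denominator + pseudocount))`
#' at every timepoint, the quantity the differential selection rules of all
#' three omics layers threshold. With strictly positive profiles and
#' pseudocount 0 the ratio is exact; a zero denominator with pseudocount 0
#' yields +/-Inf, which is kept and flagged with a warning rather than
#' silently dropped.
#'
#' @param profiles output of [condition_means()].
#' @param numerator,denominator genotype whose profile goes on top / bottom
#'   (defaults russet / waxy, the convention of the printed ratios).
#' @param pseudocount nonnegative value added to both sides.
#' @return Matrix features x timepoints of log2 ratios; column names are the
#'   DAFB timepoints.
#' @export
log2_ratio_profile <- function(profiles, numerator = "russet",
                               denominator = "waxy", pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  conds <- profile_conditions(profiles)
  for (g in c(numerator, denominator)) {
    if (!g %in% conds$genotype) stop("genotype not present in profiles: ", g)
  }
  tps <- sort(unique(conds$timepoint_dafb))
  num <- profiles[, match(condition_key(numerator, tps), colnames(profiles)),
                  drop = FALSE]
  den <- profiles[, match(condition_key(denominator, tps), colnames(profiles)),
                  drop = FALSE]
  ratio <- log2((num + pseudocount) / (den + pseudocount))
  colnames(ratio) <- as.character(tps)
  n_bad <- sum(!is.finite(ratio))
  if (n_bad > 0L) {
    warning(n_bad, " non-finite log2 ratio(s) (zero or missing abundance); ",
            "kept as +/-Inf or NaN")
  }
  ratio
}
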