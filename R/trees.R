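#' Binary allele coding of SSR calls
#'
#' Expands allele calls into a varieties x (locus, allele) presence/absence
#' matrix, the ploidy-independent coding that lets diploid and triploid
#' varieties share one distance space. A column is created for every allele
#' observed in at least one variety.
#'
#' @param calls data.frame with columns variety, locus and either a single
#'   `allele` column (long format, one row per allele) or `allele1`,
#'   `allele2`, `allele3` (wide; NA for the unused triploid slot).
#' @return Binary matrix, rownames = varieties, colnames = `locus.allele`,
#'   with attribute `locus` mapping columns to loci.
#' @export
binarize_ssr <- function(calls) {
  if (!nrow(calls)) stop("empty allele-call table")
  if ("allele" %in% names(calls)) {
    long <- calls[, c("variety", "locus", "allele")]
  } else {
    acols <- grep("^allele[0-9]+$", names(calls), value = TRUE)
    if (!length(acols)) stop("calls need an allele column or allele1..allele3")
    long <- do.call(rbind, lapply(acols, function(a) {
      data.frame(variety = calls$variety, locus = calls$locus,
                 allele = calls[[a]], stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$allele), ]
  }
  long$variety <- as.character(long$variety)
  long$col <- paste(long$locus, long$allele, sep = ".")
  vars <- unique(long$variety)
  cols <- sort(unique(long$col))
  m <- base::matrix(0L, nrow = length(vars), ncol = length(cols),
                    dimnames = list(vars, cols))
  m[cbind(match(long$variety, vars), match(long$col, cols))] <- 1L
  attr(m, "locus") <- sub("\\.[^.]*$", "", cols)
  m
}

#' Pearson correlation distance between observation rows
#'
#' `d(i, j) = 1 - r(row_i, row_j)`, in `[0, 2]`. Constant rows have an
#' undefined correlation; their distances are returned as NA with a
#' warning.
#'
#' @param m numeric matrix, observations in rows (>= 2 columns).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pearson_distance <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 columns to correlate")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("constant row(s) have undefined Pearson distance: ",
            paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- 1 - suppressWarnings(stats::cor(t(m)))
  # snap floating-point dust to zero so exact clones merge at height 0
  d[abs(d) < 1e-12] <- 0
  diag(d) <- 0
  d
}

#' UPGMA phenogram from a distance matrix
#'
#' Iteratively merges the closest pair, averaging distances with cluster-
#' size weights; node heights are half the merge distance, so the tree is
#' ultrametric (all leaves equidistant from the root). Ties are resolved
#' deterministically by sorting leaves lexicographically before
#' agglomeration.
#'
#' @param d symmetric distance matrix (or `dist`) with labels.
#' @return A rooted ultrametric `phylo` tree (ape).
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (any(is.na(m))) stop("distance matrix contains NA (degenerate input?)")
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  # as.phylo.hclust halves the merge heights, giving leaf depth = h/2
  phy
}

#' Bootstrap supports for an SSR UPGMA phenogram
#'
#' Resamples loci (keeping all allele columns of a marker together — the
#' alleles of one SSR are not independent) with replacement `B` times,
#' rebuilds the Pearson-distance UPGMA tree on each replicate, and scores
#' each internal node of the original tree by the percentage of replicate
#' trees containing the same bipartition.
#'
#' @param binary output of [binarize_ssr()] (or any matrix with a `locus`
#'   attribute / `locus` argument mapping columns to resample units).
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed for reproducible resampling.
#' @param locus optional character vector overriding the column-to-locus
#'   map.
#' @return The original `phylo` tree with `node.label` set to integer
#'   percent supports (root included).
#' @export
bootstrap_support <- function(binary, B = 100L, seed = NULL, locus = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(locus)) locus <- attr(binary, "locus")
  if (is.null(locus)) stop("no locus map: pass `locus` or use binarize_ssr()")
  units <- unique(locus)
  if (length(units) < 2L) stop("need >= 2 resample units (loci)")
  if (!is.null(seed)) set.seed(seed)
  ref <- upgma(pearson_distance(binary))
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    take <- sample(units, length(units), replace = TRUE)
    cols <- unlist(lapply(take, function(u) which(locus == u)), use.names = FALSE)
    rep_m <- binary[, cols, drop = FALSE]
    boots[[b]] <- tryCatch(upgma(suppressWarnings(pearson_distance(rep_m))),
                           error = function(e) NULL)
  }
  ok <- !vapply(boots, is.null, logical(1L))
  if (!all(ok)) {
    warning(sum(!ok), " degenerate replicate(s) contributed no support")
  }
  counts <- ape::prop.clades(ref, boots[ok], rooted = TRUE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / B))
  ref
}

#' Jukes-Cantor corrected distances between aligned protein sequences
#'
#' Pairwise mismatch fractions p are computed with pairwise deletion of
#' gap positions, then corrected for multiple substitutions with the
#' 20-state Jukes-Cantor formula `d = -(19/20) ln(1 - (20/19) p)`.
#' Saturated pairs (p >= 19/20) have no finite corrected distance and are
#' returned as NA with a warning.
#'
#' @param sequences named character vector of equal-length aligned amino
#'   acid sequences, a character matrix (sequences in rows), or an ape
#'   `AAbin` alignment.
#' @param gap_chars characters treated as gaps/unknowns (pairwise deleted).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jc_protein_distance <- function(sequences, gap_chars = c("-", ".", "?", "X", "x")) {
  if (inherits(sequences, "AAbin")) {
    sequences <- toupper(vapply(as.character(as.list(sequences)),
                                paste, character(1L), collapse = ""))
  }
  if (is.character(sequences) && is.null(dim(sequences))) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) stop("sequences must be aligned (equal length)")
    chars <- t(vapply(sequences, function(s) strsplit(s, "")[[1L]],
                      character(lens[1L])))
  } else {
    chars <- as.matrix(sequences)
  }
  chars <- toupper(chars)
  n <- nrow(chars)
  labs <- rownames(chars) %||% paste0("seq", seq_len(n))
  d <- base::matrix(0, n, n, dimnames = list(labs, labs))
  valid <- !(chars %in% gap_chars)
  dim(valid) <- dim(chars)
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- valid[i, ] & valid[j, ]
      if (!any(use)) { d[i, j] <- d[j, i] <- NA_real_; next }
      p <- mean(chars[i, use] != chars[j, use])
      if (p >= 19 / 20) {
        d[i, j] <- d[j, i] <- NA_real_
        saturated <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -(19 / 20) * log(1 - (20 / 19) * p)
      }
    }
  }
  if (saturated) warning("saturated pair(s) (p >= 19/20): distance undefined, NA")
  d
}

#' Protein-family tree from an aligned FASTA
#'
#' Builds the acyltransferase-family phenogram: Jukes-Cantor distances on
#' the alignment, then UPGMA (the operative method of the source analysis;
#' pass `method = "nj"` for a neighbor-joining alternative) with bootstrap
#' supports from resampled alignment columns.
#'
#' @param alignment path to an aligned protein FASTA, or anything
#'   [jc_protein_distance()] accepts.
#' @param B bootstrap replicates (default 100; 0 skips supports).
#' @param seed optional integer seed.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return A `phylo` tree, with `node.label` percent supports if `B > 0`.
#' @export
protein_tree <- function(alignment, B = 100L, seed = NULL,
                         method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- ape::read.FASTA(alignment, type = "AA")
  }
  if (inherits(alignment, "AAbin")) {
    alignment <- toupper(vapply(as.character(as.list(alignment)),
                                paste, character(1L), collapse = ""))
  }
  build <- function(seqs) {
    d <- jc_protein_distance(seqs)
    if (method == "upgma") upgma(d) else ape::nj(stats::as.dist(d))
  }
  ref <- build(alignment)
  if (B > 0L) {
    if (!is.null(seed)) set.seed(seed)
    L <- nchar(alignment[1L])
    boots <- vector("list", B)
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- vapply(alignment, function(s) {
        paste(strsplit(s, "")[[1L]][cols], collapse = "")
      }, character(1L))
      boots[[b]] <- tryCatch(build(res), error = function(e) NULL)
    }
    ok <- !vapply(boots, is.null, logical(1L))
    counts <- ape::prop.clades(ref, boots[ok], rooted = (method == "upgma"))
    counts[is.na(counts)] <- 0L
    ref$node.label <- as.character(round(100 * counts / B))
  }
  ref
}

#' Serialize a phenogram to Newick
#'
#' Branch lengths are kept; integer bootstrap supports (if present) become
#' internal node labels. The output round-trips through
#' [ape::read.tree()].
#'
#' @param tree a `phylo`.
#' @param file optional path; when NULL the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read an SSR allele-call table from TSV
#'
#' Expects columns `variety`, `locus`, `allele1`..`allele3` (empty cells
#' for the unused ploidy slot) or long format with a single `allele`
#' column.
#' @param path file path.
#' @return data.frame of calls.
#' @export
read_ssr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("variety", "locus") %in% names(tab))) {
    stop("SSR table needs variety and locus columns")
  }
  tab
}
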