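# Monoisotopic masses of the most abundant isotopes (IUPAC/CODATA, >= 9 s.f.).
# The compound set of the study needs only C, H, N, O, Na; P and S are
# included because they cost nothing and broaden applicability.
ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740049,
  O  = 15.9949146196,
  Na = 22.9897692809,
  P  = 30.97376163,
  S  = 31.97207100
)

PROTON_MASS <- 1.00727646
ELECTRON_MASS <- 0.000548579909

# Singly charged adducts; mass_delta is added to the neutral monoisotopic
# mass. Proton transfer carries the charge, so the electron mass is already
# folded into the proton mass; the sodium adduct subtracts one electron.
ADDUCTS <- list(
  "[M+H]+"  = list(mass_delta = PROTON_MASS, charge = 1L),
  "[M-H]-"  = list(mass_delta = -PROTON_MASS, charge = -1L),
  "[M+Na]+" = list(mass_delta = ELEMENT_MASSES[["Na"]] - ELECTRON_MASS, charge = 1L)
)

#' Parse a molecular formula string
#'
#' Accepts canonical Hill-style formulas such as `"C39H54O6"`; an omitted
#' count means 1. Supported elements: C, H, N, O, Na, P, S.
#'
#' @param text nonempty formula string.
#' @return A `molecular_formula`: named integer vector of element counts.
#' @export
parse_formula <- function(text) {
  if (inherits(text, "molecular_formula")) return(text)
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("formula must be a single nonempty string")
  }
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text)[[1L]]
  tokens <- regmatches(text, gregexpr(pat, text))[[1L]]
  if (paste(tokens, collapse = "") != text) {
    # locate the first character not consumed by a valid token
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    }
    pos <- which(!covered)[1L]
    stop("cannot parse formula '", text, "' at position ", pos)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  bad <- !sym %in% names(ELEMENT_MASSES)
  if (any(bad)) {
    pos <- m[which(bad)[1L]]
    stop("unknown element symbol '", sym[bad][1L], "' in '", text,
         "' at position ", pos)
  }
  counts <- tapply(cnt, factor(sym, levels = names(ELEMENT_MASSES)), sum)
  counts <- counts[!is.na(counts) & counts > 0L]
  if (!length(counts)) stop("formula '", text, "' contains no atoms")
  out <- as.integer(counts)
  names(out) <- names(counts)
  class(out) <- "molecular_formula"
  out
}

#' @export
format.molecular_formula <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(unclass(x)[ord] == 1L, "", unclass(x)[ord]), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add two molecular formulas
#' @param a,b formulas (strings or `molecular_formula`).
#' @return The combined `molecular_formula`.
#' @export
formula_add <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  class(out) <- "molecular_formula"
  out
}

#' Subtract a molecular formula from another
#'
#' Errors (naming the element) if any count would go negative, so a neutral
#' loss can never remove atoms the precursor does not carry.
#' @param a,b formulas; computes `a - b`.
#' @return The difference `molecular_formula`.
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0L)) {
    stop("negative count for element ", names(out)[out < 0L][1L],
         " after subtracting ", format(b))
  }
  out <- out[out > 0L]
  class(out) <- "molecular_formula"
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses (C exactly 12 by definition).
#' @param f formula (string or `molecular_formula`).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  sum(ELEMENT_MASSES[names(f)] * unclass(f))
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' @param f neutral formula.
#' @param adduct one of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`.
#' @return m/z in Th.
#' @export
ion_mz <- function(f, adduct = "[M-H]-") {
  if (!adduct %in% names(ADDUCTS)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(ADDUCTS), collapse = ", "))
  }
  monoisotopic_mass(f) + ADDUCTS[[adduct]]$mass_delta
}

#' Signed parts-per-million mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`, the accuracy measure of
#' the annotation tables. Always recomputed from formula + observed m/z;
#' printed errors are never trusted.
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' m/z of a fragment ion after neutral losses
#'
#' The precursor is given as the ion composition (e.g. `C39H55O6` for the
#' protonated ester); each neutral loss is subtracted, and the remaining
#' composition's m/z is returned at unit charge with electron-mass
#' correction (minus one electron for positive ions, plus one for negative).
#'
#' @param precursor_ion ion composition formula.
#' @param losses list (or vector) of neutral-loss formulas; may be empty.
#' @param polarity `"positive"` or `"negative"`.
#' @return Fragment m/z.
#' @export
fragment_mz <- function(precursor_ion, losses = list(),
                        polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  frag <- parse_formula(precursor_ion)
  if (length(losses)) {
    if (!is.list(losses)) losses <- as.list(losses)
    for (loss in losses) frag <- formula_subtract(frag, loss)
  }
  m <- monoisotopic_mass(frag)
  if (polarity == "positive") m - ELECTRON_MASS else m + ELECTRON_MASS
}

#' Candidate triterpene-hydroxycinnamate ester series
#'
#' Enumerates esters of pentacyclic triterpenic-acid cores with coumaroyl or
#' caffeoyl moieties. Esterification is modeled as condensation
#' (core + hydroxycinnamic acid - H2O), i.e. core + acyl moiety, where
#' coumaroyl = C9H6O2 and caffeoyl = C9H6O3. The default cores are the
#' triterpenic acid and its mono- and di-hydroxylated forms
#' (C30H48O3/O4/O5), whose deprotonated esters reproduce the diagnostic
#' nominal ion set {601, 617, 633, 649} observed in russeted apple skin.
#'
#' @param cores character vector of core formulas.
#' @param acyl named character vector of acyl-moiety formulas.
#' @param mode adduct used for the reported m/z (negative mode by default;
#'   these esters ionize best as deprotonated ions).
#' @return data.frame with one row per distinct ester formula: `formula`,
#'   `exact_mz`, `nominal_mz` and the contributing `combinations`.
#' @export
conjugate_series <- function(cores = c("C30H48O3", "C30H48O4", "C30H48O5"),
                             acyl = c(coumaroyl = "C9H6O2", caffeoyl = "C9H6O3"),
                             mode = "[M-H]-") {
  combos <- expand.grid(core = cores, acyl_name = names(acyl),
                        stringsAsFactors = FALSE)
  combos$formula <- vapply(seq_len(nrow(combos)), function(i) {
    format(formula_add(combos$core[i], acyl[[combos$acyl_name[i]]]))
  }, character(1L))
  combos$label <- paste0(combos$core, "+", combos$acyl_name)
  uf <- unique(combos$formula)
  out <- data.frame(
    formula = uf,
    exact_mz = vapply(uf, function(f) ion_mz(f, mode), numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$nominal_mz <- as.integer(round(out$exact_mz))
  out$combinations <- vapply(uf, function(f) {
    paste(combos$label[combos$formula == f], collapse = "; ")
  }, character(1L))
  out[order(out$exact_mz), , drop = FALSE]
}

#' Annotate an observed m/z against candidate formulas
#'
#' @param observed observed m/z.
#' @param mode adduct assumed for all candidates.
#' @param candidates data.frame with columns `name` and `formula`, or a
#'   named character vector of formulas.
#' @param tol_ppm tolerance; only candidates with |ppm| <= `tol_ppm` are
#'   returned (default 5 ppm, the usual high-resolution TOF window).
#' @return data.frame of matches sorted by |ppm| (best first); zero rows if
#'   nothing matches.
#' @export
annotate_mass <- function(observed, mode = "[M-H]-", candidates,
                          tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  if (!is.data.frame(candidates)) {
    candidates <- data.frame(
      name = if (is.null(names(candidates))) as.character(candidates)
             else names(candidates),
      formula = as.character(candidates), stringsAsFactors = FALSE)
  }
  theo <- vapply(candidates$formula, function(f) ion_mz(f, mode), numeric(1L))
  ppm <- ppm_error(observed, theo)
  out <- data.frame(name = candidates$name, formula = candidates$formula,
                    observed_mz = observed, theoretical_mz = theo,
                    ppm_error = ppm, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[abs(out$ppm_error) <= tol_ppm, , drop = FALSE]
  out[order(abs(out$ppm_error)), , drop = FALSE]
}
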