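# Variant effect scoring: isoform log odds ratios, disruptive-variant
# classification, aQTL effect-size scaling, delta-usage, in silico saturation
# mutagenesis and the linear CSE hexamer baseline.

#' Wildtype/variant sequence pair
#'
#' @slot wt,var equal-length DNA sequences.
#' @slot offsets 0-based positions at which the sequences differ (usually
#'   one; multi-nucleotide variants are carried by the same machinery).
#' @slot id optional variant identifier.
#' @export
setClass("VariantPair",
  representation(wt = "character", var = "character", offsets = "integer",
                 id = "character")
)

setValidity("VariantPair", function(object) {
  if (nchar(object@wt) != nchar(object@var))
    return("wt and var must have equal length")
  a <- strsplit(object@wt, "")[[1]]
  b <- strsplit(object@var, "")[[1]]
  diffs <- which(a != b) - 1L
  if (!identical(sort(diffs), sort(object@offsets)))
    return("sequences must differ exactly at the stated offsets")
  TRUE
})

#' @rdname VariantPair-class
#' @param wt,var wildtype and variant sequences.
#' @param id optional identifier.
#' @return a \linkS4class{VariantPair}; mismatch offsets are derived from the
#'   sequences.
#' @export
variantPair <- function(wt, var, id = NA_character_) {
  a <- strsplit(wt, "")[[1]]
  b <- strsplit(var, "")[[1]]
  if (length(a) != length(b)) stop("input error: sequences differ in length")
  offsets <- which(a != b) - 1L
  if (length(offsets) == 0L) stop("input error: sequences are identical")
  new("VariantPair", wt = wt, var = var, offsets = as.integer(offsets),
      id = as.character(id))
}

setMethod("show", "VariantPair", function(object) {
  cat("VariantPair", if (!is.na(object@id)) object@id else "",
      "- mismatch at 0-based offset(s):",
      paste(object@offsets, collapse = ","), "\n")
})

#' Isoform log odds ratio between variant and wildtype proportions
#'
#' `LOR = log[(y_var/(1-y_var)) / (y_wt/(1-y_wt))]` in natural log (the
#' convention used consistently across the package; use `base2 = TRUE` for
#' log2 reporting). Proportions are clamped by [safeLogit()]'s epsilon
#' before the logit.
#'
#' @param y_wt,y_var proximal isoform proportions in [0, 1].
#' @param base2 report in log2 instead of natural log.
#' @return log odds ratio (scalar or vector).
#' @export
lor <- function(y_wt, y_var, base2 = FALSE) {
  if (any(y_wt < 0 | y_wt > 1 | y_var < 0 | y_var > 1))
    stop("input error: proportions must lie in [0, 1]")
  out <- safeLogit(y_var) - safeLogit(y_wt)
  if (base2) out / log(2) else out
}

#' Predicted variant effect (log odds ratio) under a model
#'
#' Runs the network on both sequences and returns the LOR of the proximal
#' isoform proportions. `mode = "windowed"` follows the isoform-MPRA
#' convention (sum over the 0-based 76-126 window); `"any_not_distal"`
#' follows the expression-MPRA / population convention (sum over all 205
#' positional bins).
#'
#' @param model a \linkS4class{PASNet}.
#' @param pair a \linkS4class{VariantPair} (205-nt sequences).
#' @param mode proximal isoform definition.
#' @param library sub-library intercept index (default 11).
#' @return predicted LOR (natural log).
#' @export
variantEffect <- function(model, pair, mode = c("windowed", "any_not_distal"),
                          library = 11L) {
  mode <- match.arg(mode)
  validObject(pair)
  if (nchar(pair@wt) != PAS_LEN)
    stop("input error: sequences must be 205 nt")
  preds <- pasForward(model, c(pair@wt, pair@var), library)
  y <- proximalIsoform(preds, mode)
  unname(lor(y[1L], y[2L]))
}

#' Classify a variant as disruptive
#'
#' A variant is disruptive when the absolute isoform odds ratio with respect
#' to the wildtype exceeds 2, i.e. |LOR| > ln 2.
#'
#' @param lor_value log odds ratio(s), natural log.
#' @return logical.
#' @export
classifyDisruptive <- function(lor_value) {
  stopifnot(all(is.finite(lor_value)))
  abs(lor_value) > log(2)
}

#' Orientation sign for aQTL effect scaling
#'
#' Variants near the distal PAS act on the distal isoform directly
#' (lambda = +1); variants far from the transcript end are assumed to act
#' through a competing PAS and have their effect inverted (lambda = -1). The
#' heuristic: +1 within 150 bp of the annotated transcript end. The extended
#' rule used with newer aQTL atlases additionally assigns +1 within 500 bp
#' when the variant creates a canonical CSE hexamer (AATAAA/ATTAAA) de novo.
#'
#' @param distance_to_end distance (nt) from SNP to annotated transcript end.
#' @param creates_denovo_cse does the variant create a canonical CSE absent
#'   from the wildtype?
#' @param use_v8_rule enable the 500-bp de novo CSE extension.
#' @return +1 or -1.
#' @export
assignLambda <- function(distance_to_end, creates_denovo_cse = FALSE,
                         use_v8_rule = FALSE) {
  if (is.na(distance_to_end)) stop("missing annotation: distance to end")
  if (distance_to_end <= 150) return(1)
  if (use_v8_rule && creates_denovo_cse && distance_to_end <= 500) return(1)
  -1
}

#' Does a variant create a canonical CSE hexamer de novo?
#'
#' @param wt,var equal-length sequences.
#' @return TRUE if AATAAA or ATTAAA occurs in `var` at a position where it
#'   does not occur in `wt`.
#' @export
createsDeNovoCSE <- function(wt, var) {
  for (hex in c("AATAAA", "ATTAAA")) {
    if (length(setdiff(motifHits(var, hex), motifHits(wt, hex))) > 0)
      return(TRUE)
  }
  FALSE
}

#' aQTL effect size: change in distal usage index
#'
#' Scales the measured mean distal usage (PDUI) by the predicted variant
#' odds ratio: `1 / (1 + e^{-lambda*LOR} * (1-y)/y) - y`.
#'
#' @param lor_value predicted LOR (natural log).
#' @param y_pdui_base mean distal usage index in (0, 1); boundary values are
#'   epsilon-clamped.
#' @param lambda orientation sign from [assignLambda()].
#' @return predicted change in PDUI.
#' @export
aqtlEffect <- function(lor_value, y_pdui_base, lambda = 1) {
  stopifnot(lambda %in% c(-1, 1))
  y <- clamp(y_pdui_base, 1e-6, 1 - 1e-6)
  1 / (1 + exp(-lambda * lor_value) * (1 - y) / y) - y
}

#' Change in isoform proportion induced by a variant
#'
#' Shifts the baseline usage's odds by the predicted LOR:
#' `sigmoid(logit(baseline) + LOR) - baseline`. Bounded in
#' (-baseline, 1 - baseline) and monotone in LOR.
#'
#' @param lor_value predicted LOR (natural log).
#' @param baseline_usage baseline isoform proportion in (0, 1).
#' @return delta usage.
#' @export
deltaUsage <- function(lor_value, baseline_usage) {
  sigmoid(safeLogit(baseline_usage) + lor_value) - baseline_usage
}

#' In silico saturation mutagenesis of one PAS
#'
#' Substitutes every alternate base at every position and scores each
#' variant's LOR against the reference; reference-base entries are exactly 0.
#'
#' @param model a \linkS4class{PASNet}.
#' @param sequence 205-nt reference sequence.
#' @param mode proximal isoform definition (see [variantEffect()]).
#' @param library sub-library intercept index.
#' @param chunk forward-pass batch size.
#' @return 205 x 4 matrix of LORs (columns A, C, G, T).
#' @export
ism <- function(model, sequence, mode = c("windowed", "any_not_distal"),
                library = 11L, chunk = 128L) {
  mode <- match.arg(mode)
  ref_chars <- strsplit(sequence, "")[[1]]
  variants <- character(0)
  coords <- list()
  for (i in seq_len(PAS_LEN)) {
    for (b in setdiff(DNA_BASES, ref_chars[i])) {
      variants <- c(variants, substituteBase(sequence, i - 1L, b))
      coords[[length(coords) + 1L]] <- c(i, match(b, DNA_BASES))
    }
  }
  y_all <- numeric(length(variants))
  for (s in seq(1L, length(variants), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(variants))
    preds <- pasForward(model, variants[idx], library)
    y_all[idx] <- proximalIsoform(preds, mode)
  }
  y_ref <- proximalIsoform(pasForward(model, sequence, library), mode)
  out <- matrix(0, PAS_LEN, 4L, dimnames = list(NULL, DNA_BASES))
  for (j in seq_along(coords)) {
    out[coords[[j]][1L], coords[[j]][2L]] <- lor(y_ref, y_all[j])
  }
  out
}

# ---- Linear CSE hexamer baseline --------------------------------------------

# One-hot features for a hexamer with reference coding against AATAAA: an
# indicator per (position, non-reference base).
hexamer_features <- function(hexamers, reference = "AATAAA") {
  ref <- strsplit(reference, "")[[1]]
  feats <- matrix(0, length(hexamers), 18L)
  nms <- character(18L)
  k <- 1L
  for (i in 1:6) {
    for (b in setdiff(DNA_BASES, ref[i])) {
      nms[k] <- paste0("pos", i, "_", b)
      feats[, k] <- vapply(hexamers, function(h) {
        as.numeric(substr(h, i, i) == b)
      }, numeric(1), USE.NAMES = FALSE)
      k <- k + 1L
    }
  }
  colnames(feats) <- nms
  feats
}

#' Fit a linear CSE hexamer effect model
#'
#' Least-squares regression of measured LORs on one-hot hexamer features
#' (reference coding against the consensus AATAAA, so the fitted intercept is
#' the prediction for the consensus itself). Rank-deficient designs are
#' reported and fitted with the pseudoinverse.
#'
#' @param hexamers character vector of 6-mers.
#' @param lors measured log odds ratios (same length).
#' @return list with `coefficients` (intercept + 18 position/base weights),
#'   `rank_deficient` flag, and `predict(hexamers)` function.
#' @export
fitHexamerModel <- function(hexamers, lors) {
  stopifnot(length(hexamers) == length(lors))
  if (length(unique(hexamers)) < 24L)
    stop("need at least 24 distinct hexamer observations")
  X <- cbind(intercept = 1, hexamer_features(hexamers))
  qx <- qr(X)
  rank_def <- qx$rank < ncol(X)
  if (rank_def) {
    warning("rank-deficient hexamer design; using pseudoinverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% lors) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- drop(qr.coef(qx, lors))
  }
  names(beta) <- colnames(X)
  list(
    coefficients = beta,
    rank_deficient = rank_def,
    predict = function(hex) {
      Xn <- cbind(1, hexamer_features(hex))
      drop(Xn %*% beta)
    }
  )
}
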