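#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' Ground-truth cleavage law for synthetic data
#'
#' Encodes the generative law used by every synthetic-data generator in the
#' package: PAS strength is additive in logit space over a 6-position core
#' hexamer (CSE) weight matrix and a set of positional motif effects; cleavage
#' mass is laid out over a fixed positional kernel spanning offsets +7..+57 nt
#' downstream of the CSE start, in competition with a distal signal of fixed
#' logit strength.
#'
#' @slot cse_pwm 4 x 6 numeric matrix (rows A,C,G,T): additive logit
#'   contribution of each base at each CSE position. Hexamers are also drawn
#'   from the position-wise softmax of these weights.
#' @slot motif_effects list of `list(motif=, window=, effect=)` entries; a hit
#'   of `motif` whose 0-based start falls inside `window` (inclusive pair)
#'   adds `effect` to the strength logit.
#' @slot cleavage_kernel numeric vector of length 51, the positional cleavage
#'   profile over offsets +7..+57 from the CSE start; must sum to 1.
#' @slot distal_baseline_logit scalar logit strength of the distal competitor.
#' @slot noise_dispersion scalar >= 0; 0 gives multinomial counts, larger
#'   values add Dirichlet-multinomial overdispersion (Dirichlet concentration
#'   1/dispersion).
#' @export
setClass("GroundTruthLaw",
  representation(
    cse_pwm = "matrix",
    motif_effects = "list",
    cleavage_kernel = "numeric",
    distal_baseline_logit = "numeric",
    noise_dispersion = "numeric"
  )
)

setValidity("GroundTruthLaw", function(object) {
  msg <- character(0)
  if (!all(dim(object@cse_pwm) == c(4L, 6L)))
    msg <- c(msg, "cse_pwm must be a 4 x 6 matrix")
  if (!all(is.finite(object@cse_pwm)))
    msg <- c(msg, "cse_pwm must be finite")
  k <- object@cleavage_kernel
  if (length(k) != 51L || any(k < 0) || !all(is.finite(k)))
    msg <- c(msg, "cleavage_kernel must be 51 non-negative finite values")
  else if (abs(sum(k) - 1) > 1e-9)
    msg <- c(msg, "cleavage_kernel must sum to 1")
  for (me in object@motif_effects) {
    if (!all(c("motif", "window", "effect") %in% names(me)) ||
        !is.finite(me$effect) || length(me$window) != 2L)
      msg <- c(msg, "each motif effect needs motif, window (length 2), finite effect")
  }
  if (!is.finite(object@distal_baseline_logit))
    msg <- c(msg, "distal_baseline_logit must be finite")
  if (length(object@noise_dispersion) != 1L || object@noise_dispersion < 0)
    msg <- c(msg, "noise_dispersion must be a scalar >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic MPRA bundle
#'
#' A \linkS4class{SummarizedExperiment} holding a library of synthetic PAS
#' records: assays `counts` (206 x n integer cleavage counts) and `target`
#' (206 x n true cleavage proportions; row 206 is the distal isoform mass),
#' with per-record sequence, sub-library label, CSE offset and read depth in
#' `colData`, and the generating \linkS4class{GroundTruthLaw} plus seed in
#' `metadata`.
#'
#' @export
setClass("PASBundle", contains = "SummarizedExperiment")

setValidity("PASBundle", function(object) {
  msg <- character(0)
  need <- c("sequence", "library", "cse_offset", "depth")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!all(c("counts", "target") %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'counts' and 'target'")
  else {
    tg <- assay(object, "target")
    if (nrow(tg) != 206L) msg <- c(msg, "target assay must have 206 rows")
    else if (ncol(tg) > 0 && max(abs(colSums(tg) - 1)) > 1e-9)
      msg <- c(msg, "target columns must sum to 1")
    if (any(assay(object, "counts") < 0)) msg <- c(msg, "counts must be >= 0")
  }
  if ("depth" %in% colnames(colData(object)) &&
      ncol(object) > 0 && any(colData(object)$depth < 1))
    msg <- c(msg, "read depth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Residual network architecture configuration
#'
#' @slot n_groups number of residual groups (default 7).
#' @slot blocks_per_group residual blocks per group (default 4).
#' @slot dilation_schedule per-group dilation rates (default 1,2,4,8,4,2,1).
#' @slot channels convolution channels (default 32).
#' @slot filter_width convolution filter width (default 3).
#' @slot library_count number of sub-library intercepts (default 13).
#' @slot input_len input sequence length (205).
#' @slot output_len output distribution length (206; last bin = distal mass).
#' @export
setClass("ArchitectureConfig",
  representation(
    n_groups = "integer", blocks_per_group = "integer",
    dilation_schedule = "integer", channels = "integer",
    filter_width = "integer", library_count = "integer",
    input_len = "integer", output_len = "integer"
  )
)

setValidity("ArchitectureConfig", function(object) {
  msg <- character(0)
  if (length(object@dilation_schedule) != object@n_groups)
    msg <- c(msg, "dilation_schedule must have n_groups entries")
  cnt <- c(object@n_groups, object@blocks_per_group, object@channels,
           object@filter_width, object@library_count)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Residual cleavage-prediction network
#'
#' Handle for the dilated residual convolutional network. Parameters live in
#' a nested list of numeric arrays (see [buildModel()]); `history` records the
#' per-epoch training loss of the most recent [trainPASNet()] call.
#'
#' @slot config an \linkS4class{ArchitectureConfig}.
#' @slot params nested list of weights.
#' @slot history numeric vector of per-epoch mean training losses.
#' @export
setClass("PASNet",
  representation(config = "ArchitectureConfig", params = "list",
                 history = "numeric")
)

#' Per-position saliency mask for variant interpretation
#'
#' @slot w unconstrained per-position parameters (length N).
#' @slot s per-position retention scores, softplus(instance-norm(w)); the
#'   mutated position is pinned at a large finite cap standing in for
#'   +infinity.
#' @slot mutated_pos 0-based mutated position(s) (frozen in optimization).
#' @slot background Laplace-smoothed wildtype PSSM (N x 4, rows sum to 1).
#' @slot diagnostics list: loss / reconstruction trajectories.
#' @export
setClass("MaskState",
  representation(w = "numeric", s = "numeric", mutated_pos = "integer",
                 background = "matrix", diagnostics = "list")
)

setValidity("MaskState", function(object) {
  msg <- character(0)
  if (any(object@s <= 0)) msg <- c(msg, "scores s must be > 0")
  if (nrow(object@background) != length(object@w))
    msg <- c(msg, "background rows must match mask length")
  if (ncol(object@background) == 4L &&
      max(abs(rowSums(object@background) - 1)) > 1e-9)
    msg <- c(msg, "background rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Condition-specific residual APA model
#'
#' A small convolutional scorer (2 layers, 16 filters, width 8, global
#' average pooling, 2 output channels) shared across PAS slots, plus per-slot
#' regression weights combining baseline logit, condition residual and log
#' distance under a masked softmax.
#'
#' @slot cnn nested list of CNN weights.
#' @slot w 10 x 3 regression weight matrix (score, distance, bias per slot).
#' @slot config list of training hyper-parameters.
#' @slot phase integer: 0 = untrained, 1 = regression fitted, 2 = CNN fitted.
#' @export
setClass("TissueModel",
  representation(cnn = "list", w = "matrix", config = "list",
                 phase = "integer")
)

setMethod("show", "GroundTruthLaw", function(object) {
  cat("GroundTruthLaw\n")
  cat("  CSE consensus:",
      paste(DNA_BASES[apply(object@cse_pwm, 2L, which.max)], collapse = ""),
      "\n")
  cat("  motif effects:", length(object@motif_effects), "\n")
  cat("  kernel support: CSE +7..+57 nt; distal baseline logit:",
      format(object@distal_baseline_logit), "\n")
  cat("  noise dispersion:", object@noise_dispersion, "\n")
})

setMethod("show", "ArchitectureConfig", function(object) {
  cat("ArchitectureConfig:", object@n_groups, "groups x",
      object@blocks_per_group, "blocks,", object@channels, "channels, width",
      object@filter_width, "\n")
  cat("  dilations:", paste(object@dilation_schedule, collapse = ","),
      "| input", object@input_len, "nt -> output", object@output_len,
      "bins\n")
})

setMethod("show", "PASNet", function(object) {
  show(object@config)
  cat("  residual blocks:", nResidualBlocks(object), "| trained epochs:",
      length(object@history), "\n")
})

setMethod("show", "MaskState", function(object) {
  cat("MaskState over", length(object@w), "positions; mutated position(s):",
      paste(object@mutated_pos, collapse = ","), "(0-based)\n")
  top <- order(object@s, decreasing = TRUE)[1:5]
  cat("  top retention scores at 0-based positions:",
      paste(top - 1L, collapse = ","), "\n")
})

setMethod("show", "TissueModel", function(object) {
  cat("TissueModel (2-layer CNN, 16 filters, width 8, GAP), phase",
      object@phase, "\n")
})

#' @rdname PASBundle-class
#' @param object,x a PASBundle.
#' @export
setGeneric("cleavageTargets", function(x) standardGeneric("cleavageTargets"))

#' @rdname PASBundle-class
#' @export
setMethod("cleavageTargets", "PASBundle", function(x) assay(x, "target"))

#' @rdname PASBundle-class
#' @export
setGeneric("pasSequences", function(x) standardGeneric("pasSequences"))

#' @rdname PASBundle-class
#' @export
setMethod("pasSequences", "PASBundle", function(x) colData(x)$sequence)

#' @rdname PASBundle-class
#' @export
setGeneric("groundTruthLaw", function(x) standardGeneric("groundTruthLaw"))

#' @rdname PASBundle-class
#' @export
setMethod("groundTruthLaw", "PASBundle", function(x) metadata(x)$law)

#' Number of residual blocks of a PASNet
#' @param model a \linkS4class{PASNet}.
#' @return integer count of residual blocks.
#' @export
nResidualBlocks <- function(model) {
  cfg <- model@config
  cfg@n_groups * cfg@blocks_per_group
}

#' Retention scores of a MaskState
#' @param mask a \linkS4class{MaskState}.
#' @return numeric vector of per-position retention scores.
#' @export
maskScores <- function(mask) mask@s
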