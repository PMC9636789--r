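#' @useDynLib polyacode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats optim rnorm runif rbinom rmultinom sd prcomp isoreg
#'   fisher.test wilcox.test cor rgamma quantile median setNames
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
PAS_LEN <- 205L
OUT_LEN <- 206L

#' Derive a reproducible sub-seed for a named operation
#'
#' All generators in the package draw from per-operation random streams derived
#' from one root seed, so that adding a call to one generator never perturbs
#' the stream of another. The derivation is a stable integer hash of the
#' operation name folded into the root seed, kept strictly below 2^31.
#'
#' @param seed Integer root seed.
#' @param op Character scalar naming the operation (stream label).
#' @return An integer seed in [0, 2^31).
#' @export
deriveSeed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  h <- 0
  for (code in utf8ToInt(op)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h * 2654435.0) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' One-hot encode a DNA sequence
#'
#' Encodes an ACGT string as an L x 4 indicator matrix (column order A, C, G,
#' T). The base `N` encodes as an all-zero row, preserving shape without
#' asserting a base identity.
#'
#' @param seq A single DNA string.
#' @return An L x 4 numeric matrix.
#' @export
oneHot <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !(chars %in% c(DNA_BASES, "N"))
  if (any(bad)) {
    stop("sequence contains characters outside ACGTN: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  x <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  idx <- match(chars, DNA_BASES)
  keep <- !is.na(idx)
  x[cbind(which(keep), idx[keep])] <- 1
  x
}

# Decode an L x 4 one-hot matrix back to a string.
oneHotToSeq <- function(x) {
  paste(DNA_BASES[max.col(x)], collapse = "")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Logit and inverse-logit with epsilon clamping
#'
#' Proportions are clamped into [eps, 1 - eps] before taking the log-odds so
#' that saturated measurements (0 or 1) stay finite.
#'
#' @param p Proportions.
#' @param eps Clamp half-width (default 1e-6).
#' @return Log-odds (natural log).
#' @export
safeLogit <- function(p, eps = 1e-6) {
  p <- clamp(p, eps, 1 - eps)
  log(p / (1 - p))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  z <- z - max(z[is.finite(z)])
  e <- exp(z)
  e[!is.finite(z) & z < 0] <- 0
  e / sum(e)
}

# Row-wise softmax of a matrix.
rowSoftmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Length of the longest run of base `base` in a sequence string.
maxBaseRun <- function(seq, base = "A") {
  r <- rle(strsplit(toupper(seq), "")[[1]] == base)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else max(runs)
}

# TRUE if any window of length win_min..win_max has strictly more than
# `frac` of base `base` (the internal-priming criterion).
hasRichWindow <- function(seq, base = "A", win_min = 12L, win_max = 20L,
                          frac = 0.75) {
  isb <- as.integer(strsplit(toupper(seq), "")[[1]] == base)
  n <- length(isb)
  cs <- c(0L, cumsum(isb))
  for (w in seq.int(win_min, win_max)) {
    if (w > n) break
    counts <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
    if (any(counts / w > frac)) return(TRUE)
  }
  FALSE
}

# All start offsets (0-based) where `motif` occurs in `seq`.
motifHits <- function(seq, motif) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Substitute a single base
#'
#' @param seq DNA string.
#' @param pos 0-based position to substitute.
#' @param base replacement base.
#' @return the edited sequence.
#' @export
substituteBase <- function(seq, pos, base) {
  substr(seq, pos + 1L, pos + 1L) <- base
  seq
}
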