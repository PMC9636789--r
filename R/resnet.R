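# Dilated residual convolutional network for base-resolution 3' cleavage
# prediction. The trunk transforms a one-hot 205 x 4 sequence through
# n_groups x blocks_per_group pre-activation residual blocks (two
# batch-normalized, ReLU-activated dilated convolutions plus an unweighted
# elementwise-add skip per block); after each group an extra skip connection
# feeds the accumulated feature map to the output head. The head emits one
# logit per sequence position plus a distal logit from global average
# pooling, a learned positional bias, and a per-sub-library additive
# intercept on all 206 logits; a softmax yields the cleavage distribution.

#' Construct an architecture configuration
#'
#' Defaults reproduce the full-scale architecture: 7 residual groups of 4
#' blocks with dilation schedule 1,2,4,8,4,2,1, 32 channels and width-3
#' filters, 13 sub-library intercepts, a 205-nt input window and a 206-way
#' output (bin 206 = distal isoform mass).
#'
#' @param n_groups,blocks_per_group,dilation_schedule,channels,filter_width
#'   architecture dimensions (see slots of
#'   \linkS4class{ArchitectureConfig}).
#' @param library_count number of sub-library intercepts.
#' @return an \linkS4class{ArchitectureConfig}.
#' @export
archConfig <- function(n_groups = 7L, blocks_per_group = 4L,
                       dilation_schedule = c(1L, 2L, 4L, 8L, 4L, 2L, 1L),
                       channels = 32L, filter_width = 3L,
                       library_count = 13L) {
  if (length(dilation_schedule) != n_groups)
    stop("configuration error: dilation_schedule must have n_groups entries")
  new("ArchitectureConfig",
      n_groups = as.integer(n_groups),
      blocks_per_group = as.integer(blocks_per_group),
      dilation_schedule = as.integer(dilation_schedule),
      channels = as.integer(channels),
      filter_width = as.integer(filter_width),
      library_count = as.integer(library_count),
      input_len = PAS_LEN, output_len = OUT_LEN)
}

#' Build a cleavage-prediction network
#'
#' Trunk weights use He initialization; the output head (per-position
#' projection, distal pooling weights, positional bias and library
#' intercepts) is zero-initialized, so an untrained model predicts the
#' uniform 206-way distribution.
#'
#' @param cfg an \linkS4class{ArchitectureConfig}.
#' @param seed integer seed for weight initialization.
#' @return a \linkS4class{PASNet}.
#' @export
buildModel <- function(cfg = archConfig(), seed = 1L) {
  validObject(cfg)
  C <- cfg@channels
  with_seed(deriveSeed(seed, "model_init"), {
    groups <- lapply(seq_len(cfg@n_groups), function(g) {
      lapply(seq_len(cfg@blocks_per_group), function(k) {
        list(bn1 = bn_init(C), conv1 = conv_init(C, C, cfg@filter_width),
             bn2 = bn_init(C), conv2 = conv_init(C, C, cfg@filter_width))
      })
    })
    params <- list(
      stem = conv_init(4L, C, 1L, scale = sqrt(2 / 4)),
      groups = groups,
      head = list(
        pos = list(W = list(matrix(0, C, 1L)), b = 0),
        dist_w = numeric(C), dist_b = 0,
        pos_bias = numeric(OUT_LEN),
        Wlib = matrix(0, OUT_LEN, cfg@library_count)
      )
    )
    new("PASNet", config = cfg, params = params, history = numeric(0))
  })
}

# Full forward pass over a batch. X: (B*L) x 4 one-hot; lib: integer vector
# of sub-library indices (length B). Returns logits (B x 206) and, when
# `keep_cache`, all intermediates needed for the backward pass.
net_forward <- function(params, cfg, X, lib, training = FALSE,
                        keep_cache = FALSE) {
  L <- cfg@input_len
  B <- length(lib)
  cache <- if (keep_cache) list(groups = vector("list", cfg@n_groups))
           else NULL
  h <- conv_fwd(X, params$stem, 1L, B, L)
  if (keep_cache) cache$stem_in <- X
  skip_sum <- matrix(0, nrow(h), ncol(h))
  run_updates <- list()
  for (g in seq_len(cfg@n_groups)) {
    dil <- cfg@dilation_schedule[g]
    blocks_cache <- if (keep_cache)
      vector("list", cfg@blocks_per_group) else NULL
    for (k in seq_len(cfg@blocks_per_group)) {
      bp <- params$groups[[g]][[k]]
      h0 <- h
      b1 <- bnrelu_fwd(h0, bp$bn1, training)
      c1 <- conv_fwd(b1$Y, bp$conv1, dil, B, L)
      b2 <- bnrelu_fwd(c1, bp$bn2, training)
      c2 <- conv_fwd(b2$Y, bp$conv2, dil, B, L)
      h <- h0 + c2
      if (training) {
        run_updates[[length(run_updates) + 1L]] <-
          list(g = g, k = k, bn1 = b1$run, bn2 = b2$run)
      }
      if (keep_cache) {
        blocks_cache[[k]] <- list(h0 = h0, r1 = b1$Y, c1 = c1, r2 = b2$Y,
                                  bn1 = b1$cache, bn2 = b2$cache)
      }
    }
    skip_sum <- skip_sum + h
    if (keep_cache) cache$groups[[g]] <- blocks_cache
  }
  pos <- conv_fwd(skip_sum, params$head$pos, 1L, B, L)   # (B*L) x 1
  pos_mat <- t(matrix(pos, nrow = L, ncol = B))          # B x L
  grp <- rep(seq_len(B), each = L)
  gap <- rowsum(skip_sum, grp) / L                       # B x C
  dist <- drop(gap %*% params$head$dist_w) + params$head$dist_b
  logits <- cbind(pos_mat, dist)
  logits <- sweep(logits, 2L, params$head$pos_bias, "+")
  logits <- logits + t(params$head$Wlib[, lib, drop = FALSE])
  if (keep_cache) {
    cache$skip_sum <- skip_sum
    cache$gap <- gap
    cache$lib <- lib
  }
  list(logits = logits, cache = cache, run_updates = run_updates)
}

# Backward pass: dlogits (B x 206) -> gradients congruent with params.
net_backward <- function(params, cfg, cache, dlogits) {
  L <- cfg@input_len
  B <- nrow(dlogits)
  C <- cfg@channels
  head <- params$head
  gpar <- list(stem = NULL, groups = vector("list", cfg@n_groups),
               head = list())

  dWlib <- matrix(0, OUT_LEN, cfg@library_count)
  agg <- rowsum(dlogits, cache$lib)
  dWlib[, as.integer(rownames(agg))] <- t(agg)
  gpar$head$pos_bias <- colSums(dlogits)
  gpar$head$Wlib <- dWlib

  dpos_mat <- dlogits[, seq_len(L), drop = FALSE]
  ddist <- dlogits[, OUT_LEN]
  dpos <- matrix(as.vector(t(dpos_mat)), ncol = 1L)      # (B*L) x 1
  cb <- conv_bwd(dpos, cache$skip_sum, head$pos, 1L, B, L)
  gpar$head$pos <- cb$dW
  dskip <- cb$dX
  gpar$head$dist_w <- drop(crossprod(cache$gap, ddist))
  gpar$head$dist_b <- sum(ddist)
  dgap_rows <- (matrix(ddist, ncol = 1L) %*% head$dist_w) / L   # B x C
  dskip <- dskip + dgap_rows[rep(seq_len(B), each = L), , drop = FALSE]

  dh <- dskip  # gradient flowing into the output of the last group
  for (g in rev(seq_len(cfg@n_groups))) {
    dil <- cfg@dilation_schedule[g]
    gblocks <- vector("list", cfg@blocks_per_group)
    for (k in rev(seq_len(cfg@blocks_per_group))) {
      bp <- params$groups[[g]][[k]]
      bc <- cache$groups[[g]][[k]]
      dout <- dh
      cb2 <- conv_bwd(dout, bc$r2, bp$conv2, dil, B, L)
      bb2 <- bnrelu_bwd(cb2$dX, bp$bn2, bc$bn2)
      cb1 <- conv_bwd(bb2$dX, bc$r1, bp$conv1, dil, B, L)
      bb1 <- bnrelu_bwd(cb1$dX, bp$bn1, bc$bn1)
      dh <- dout + bb1$dX
      gblocks[[k]] <- list(
        bn1 = list(gamma = bb1$dpar$gamma, beta = bb1$dpar$beta,
                   run_mean = bp$bn1$run_mean * 0,
                   run_var = bp$bn1$run_var * 0),
        conv1 = cb1$dW,
        bn2 = list(gamma = bb2$dpar$gamma, beta = bb2$dpar$beta,
                   run_mean = bp$bn2$run_mean * 0,
                   run_var = bp$bn2$run_var * 0),
        conv2 = cb2$dW
      )
    }
    gpar$groups[[g]] <- gblocks
    if (g > 1L) dh <- dh + dskip  # extra skip feeds every group output
  }
  sb <- conv_bwd(dh, cache$stem_in, params$stem, 1L, B, L)
  gpar$stem <- sb$dW
  gpar$dX <- sb$dX
  gpar
}

# One-hot encode a character vector of sequences into a stacked (n*L) x 4
# matrix (sample-major rows).
encodeBatch <- function(seqs) {
  do.call(rbind, lapply(seqs, oneHot))
}

#' Forward pass: predicted cleavage distribution(s)
#'
#' Applies the network in evaluation mode (batch-norm running statistics) and
#' returns softmax-normalized 206-way cleavage distributions; bin 206 is the
#' distal isoform mass.
#'
#' @param model a \linkS4class{PASNet}.
#' @param sequences character vector of 205-nt ACGT(N) sequences.
#' @param library sub-library index (scalar or per-sequence); default 11, the
#'   human intronic sub-library convention used for variant prediction.
#' @return an n x 206 matrix of cleavage probabilities (rows sum to 1).
#' @export
pasForward <- function(model, sequences, library = 11L) {
  cfg <- model@config
  bad <- nchar(sequences) != cfg@input_len
  if (any(bad))
    stop("input error: sequences must be ", cfg@input_len, " nt")
  lib <- rep_len(as.integer(library), length(sequences))
  if (any(lib < 1L | lib > cfg@library_count))
    stop("input error: library index out of range")
  X <- encodeBatch(sequences)
  out <- net_forward(model@params, cfg, X, lib, training = FALSE)
  rowSoftmax(out$logits)
}

#' Predicted cleavage for a single record
#' @inheritParams pasForward
#' @param sequence one 205-nt sequence.
#' @return numeric cleavage vector of length 206 summing to 1.
#' @export
cleavageVector <- function(model, sequence, library = 11L) {
  drop(pasForward(model, sequence, library))
}

# ---- Loss --------------------------------------------------------------------

#' Loss and reporting windows
#'
#' All conventional 1-based positions are converted to 0-based indices here
#' and nowhere else: the isoform-consistency loss window 80-110 becomes
#' [79, 109], the proximal reporting window 77-127 becomes [76, 126], and the
#' distal bin is index 205.
#'
#' @param iso_loss_window inclusive 0-based index pair for the consistency
#'   loss term.
#' @param proximal_report_window inclusive 0-based index pair for proximal
#'   isoform reporting.
#' @return list with iso_loss_window, proximal_report_window, distal_index.
#' @export
lossWindows <- function(iso_loss_window = c(79L, 109L),
                        proximal_report_window = c(76L, 126L)) {
  stopifnot(all(iso_loss_window >= 0L), all(iso_loss_window <= 205L),
            all(proximal_report_window >= 0L),
            all(proximal_report_window <= 205L))
  list(iso_loss_window = as.integer(iso_loss_window),
       proximal_report_window = as.integer(proximal_report_window),
       distal_index = 205L)
}

# 1-based index range of a 0-based inclusive window pair.
window_idx <- function(w) (w[1L] + 1L):(w[2L] + 1L)

#' Hybrid cleavage/isoform training loss
#'
#' KL(target || prediction) over all 206 bins plus a binary KL consistency
#' term between the summed isoform masses over the isoform-loss window.
#' Predictions are clamped to >= 1e-12 inside logarithms; `0 * log(0/q)` is
#' treated as 0.
#'
#' @param pred,target cleavage vectors of length 206 (both sum to 1; target
#'   may contain zeros).
#' @param w windows from [lossWindows()].
#' @return non-negative scalar loss.
#' @export
hybridLoss <- function(pred, target, w = lossWindows()) {
  stopifnot(length(pred) == OUT_LEN, length(target) == OUT_LEN)
  p <- pmax(pred, 1e-12)
  nz <- target > 0
  full <- sum(target[nz] * log(target[nz] / p[nz]))
  idx <- window_idx(w$iso_loss_window)
  y_iso <- sum(target[idx])
  p_iso <- clamp(sum(pred[idx]), 1e-12, 1 - 1e-12)
  bin <- 0
  if (y_iso > 0) bin <- bin + y_iso * log(y_iso / p_iso)
  if (y_iso < 1) bin <- bin + (1 - y_iso) * log((1 - y_iso) / (1 - p_iso))
  full + bin
}

# Loss and gradient w.r.t. logits for a batch. preds: B x 206 softmax rows,
# targets: B x 206. Returns mean loss and (1/B)-scaled gradient.
hybrid_loss_grad <- function(preds, targets, w = lossWindows()) {
  B <- nrow(preds)
  p <- pmax(preds, 1e-12)
  nz <- targets > 0
  full <- sum(targets[nz] * log(targets[nz] / p[nz]))
  idx <- window_idx(w$iso_loss_window)
  y_iso <- rowSums(targets[, idx, drop = FALSE])
  p_iso <- clamp(rowSums(preds[, idx, drop = FALSE]), 1e-12, 1 - 1e-12)
  bin <- ifelse(y_iso > 0, y_iso * log(y_iso / p_iso), 0) +
    ifelse(y_iso < 1, (1 - y_iso) * log((1 - y_iso) / (1 - p_iso)), 0)
  loss <- (full + sum(bin)) / B
  # d/dlogits of KL(y||softmax) = p - y;  consistency term: g * p_j *
  # (1[j in window] - p_iso) with g = -y/p_iso + (1-y)/(1-p_iso)
  g <- -y_iso / p_iso + (1 - y_iso) / (1 - p_iso)
  inA <- matrix(0, B, OUT_LEN)
  inA[, idx] <- 1
  dlogits <- (preds - targets) +
    (g * preds) * (inA - matrix(p_iso, B, OUT_LEN))
  list(loss = loss, dlogits = dlogits / B)
}

#' Proximal isoform proportion of a cleavage distribution
#'
#' @param pred cleavage vector (length 206) or n x 206 matrix.
#' @param mode "windowed" sums over the proximal reporting window (0-based
#'   76-126); "any_not_distal" sums bins 0-204.
#' @param w windows from [lossWindows()].
#' @return proportion(s) in [0, 1].
#' @export
proximalIsoform <- function(pred, mode = c("windowed", "any_not_distal"),
                            w = lossWindows()) {
  mode <- match.arg(mode)
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  idx <- if (mode == "windowed") window_idx(w$proximal_report_window)
         else seq_len(PAS_LEN)
  drop(rowSums(pred[, idx, drop = FALSE]))
}

# ---- Shift augmentation ------------------------------------------------------

#' Shift a record and its cleavage target jointly
#'
#' Shifts the sequence and the 205 positional target bins by the same offset
#' (drawn uniformly in [-max_shift, max_shift] when `shift` is NULL). Vacated
#' sequence positions are filled with random bases; positional target mass
#' shifted out of range is accumulated on the nearest retained edge bin; the
#' distal bin is unchanged.
#'
#' @param sequence 205-nt sequence.
#' @param target length-206 cleavage vector.
#' @param max_shift maximum shift magnitude (default 15; must be < 205).
#' @param shift optional fixed shift (overrides the random draw).
#' @return list(sequence, target, shift).
#' @export
shiftAugment <- function(sequence, target, max_shift = 15L, shift = NULL) {
  if (max_shift >= PAS_LEN)
    stop("configuration error: max_shift must be < 205")
  s <- if (is.null(shift)) sample(seq.int(-max_shift, max_shift), 1L)
       else as.integer(shift)
  stopifnot(abs(s) <= max_shift)
  if (s == 0L) return(list(sequence = sequence, target = target, shift = 0L))
  ch <- strsplit(sequence, "")[[1]]
  pos <- target[seq_len(PAS_LEN)]
  new_ch <- character(PAS_LEN)
  new_pos <- numeric(PAS_LEN)
  src <- seq_len(PAS_LEN) - s
  valid <- src >= 1L & src <= PAS_LEN
  new_ch[valid] <- ch[src[valid]]
  new_ch[!valid] <- sample(DNA_BASES, sum(!valid), replace = TRUE)
  new_pos[valid] <- pos[src[valid]]
  lost <- sum(pos) - sum(new_pos)
  if (lost > 0) {
    edge <- if (s > 0L) PAS_LEN else 1L
    new_pos[edge] <- new_pos[edge] + lost
  }
  list(sequence = paste(new_ch, collapse = ""),
       target = c(new_pos, target[OUT_LEN]), shift = s)
}

# ---- Training ----------------------------------------------------------------

#' Train a cleavage-prediction network
#'
#' Mini-batch training with the Adam optimizer on the hybrid
#' cleavage/isoform loss. Targets default to the count-derived empirical
#' cleavage proportions of the bundle (`use_counts = TRUE`); set it to FALSE
#' to train on the noise-free law targets. Optional joint shift augmentation
#' of sequence and target is applied per record per epoch.
#'
#' @param model a \linkS4class{PASNet}.
#' @param bundle a \linkS4class{PASBundle}.
#' @param epochs training epochs (default 5).
#' @param batch mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param augment_shift maximum joint shift in nt (default 0 = off).
#' @param use_counts train on empirical count proportions (default) rather
#'   than true targets.
#' @param seed integer seed for batch order, augmentation and padding.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{PASNet} with per-epoch mean losses in
#'   `@history`.
#' @export
trainPASNet <- function(model, bundle, epochs = 5L, batch = 64L, lr = 1e-3,
                        augment_shift = 0L, use_counts = TRUE, seed = 1L,
                        verbose = FALSE) {
  n <- ncol(bundle)
  if (n == 0L) stop("bundle is empty")
  cfg <- model@config
  w <- lossWindows()
  targets <- if (use_counts) {
    cnt <- assay(bundle, "counts")
    sweep(cnt, 2L, pmax(colSums(cnt), 1L), "/")
  } else cleavageTargets(bundle)
  seqs <- pasSequences(bundle)
  lib <- colData(bundle)$library
  params <- model@params
  opt <- adam_init(params)
  history <- numeric(0)
  with_seed(deriveSeed(seed, "train"), {
    enc <- lapply(seqs, oneHot)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        B <- length(idx)
        if (augment_shift > 0L) {
          sh <- lapply(idx, function(i) {
            shiftAugment(seqs[i], targets[, i], max_shift = augment_shift)
          })
          X <- encodeBatch(vapply(sh, `[[`, character(1), "sequence"))
          Y <- t(vapply(sh, `[[`, numeric(OUT_LEN), "target"))
        } else {
          X <- do.call(rbind, enc[idx])
          Y <- t(targets[, idx, drop = FALSE])
        }
        fw <- net_forward(params, cfg, X, lib[idx], training = TRUE,
                          keep_cache = TRUE)
        preds <- rowSoftmax(fw$logits)
        lg <- hybrid_loss_grad(preds, Y, w)
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        grads <- net_backward(params, cfg, fw$cache, lg$dlogits)
        grads$dX <- NULL
        st <- adam_step(params, grads, opt, lr = lr)
        params <- st$params
        opt <- st$state
        for (u in fw$run_updates) {
          params$groups[[u$g]][[u$k]]$bn1$run_mean <- u$bn1$run_mean
          params$groups[[u$g]][[u$k]]$bn1$run_var <- u$bn1$run_var
          params$groups[[u$g]][[u$k]]$bn2$run_mean <- u$bn2$run_mean
          params$groups[[u$g]][[u$k]]$bn2$run_var <- u$bn2$run_var
        }
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
      if (verbose)
        message(sprintf("epoch %d: mean loss %.4f", ep, ep_loss / nb))
    }
  })
  new("PASNet", config = cfg, params = params, history = history)
}

# Gradient of a scalar function of the logits with respect to the one-hot
# input, in evaluation mode (batch-norm running statistics, so the network is
# a fixed differentiable function of its input). Used by the mask-based
# interpreter. dlogits: B x 206.
net_input_grad <- function(params, cfg, cache, dlogits) {
  L <- cfg@input_len
  B <- nrow(dlogits)
  head <- params$head
  dpos <- matrix(as.vector(t(dlogits[, seq_len(L), drop = FALSE])),
                 ncol = 1L)
  dskip <- dpos %*% t(head$pos$W[[1L]])
  ddist <- dlogits[, OUT_LEN]
  dskip <- dskip +
    ((matrix(ddist, ncol = 1L) %*% head$dist_w) / L)[rep(seq_len(B),
                                                         each = L), ,
                                                     drop = FALSE]
  # eval-mode BN+ReLU backward: affine per channel, masked by the stored
  # activation output
  bnrelu_bwd_eval <- function(dY, par, Yout, eps = 1e-3) {
    giv <- par$gamma / sqrt(par$run_var + eps)
    cpp_relu_bwd(dY, Yout) * rep(giv, each = nrow(dY))
  }
  dh <- dskip
  for (g in rev(seq_len(cfg@n_groups))) {
    dil <- cfg@dilation_schedule[g]
    for (k in rev(seq_len(cfg@blocks_per_group))) {
      bp <- params$groups[[g]][[k]]
      bc <- cache$groups[[g]][[k]]
      dout <- dh
      cb2 <- conv_bwd(dout, bc$r2, bp$conv2, dil, B, L)
      db2 <- bnrelu_bwd_eval(cb2$dX, bp$bn2, bc$r2)
      cb1 <- conv_bwd(db2, bc$r1, bp$conv1, dil, B, L)
      db1 <- bnrelu_bwd_eval(cb1$dX, bp$bn1, bc$r1)
      dh <- dout + db1
    }
    if (g > 1L) dh <- dh + dskip
  }
  sb <- conv_bwd(dh, cache$stem_in, params$stem, 1L, B, L)
  sb$dX
}

# Flatten a nested parameter list into {path, dim, values} records (and back)
# so a model round-trips through plain JSON.
flatten_params <- function(p, prefix = character(0)) {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p))
      out <- c(out, flatten_params(p[[nm]], c(prefix, nm)))
    for (i in seq_along(p))
      if (is.null(names(p)) || names(p)[i] == "")
        out <- c(out, flatten_params(p[[i]], c(prefix, as.character(i))))
    out
  } else {
    list(list(path = paste(prefix, collapse = "/"),
              dim = if (is.null(dim(p))) length(p) else dim(p),
              values = as.numeric(p)))
  }
}

unflatten_params <- function(entries) {
  assign_path <- function(node, keys, v) {
    k <- keys[1L]
    idx <- suppressWarnings(as.integer(k))
    key <- if (!is.na(idx) && as.character(idx) == k) idx else k
    if (length(keys) == 1L) {
      node[[key]] <- v
    } else {
      child <- if (is.numeric(key) && length(node) >= key) node[[key]]
               else if (is.character(key)) node[[key]] else NULL
      if (is.null(child)) child <- list()
      node[[key]] <- assign_path(child, keys[-1L], v)
    }
    node
  }
  params <- list()
  for (e in entries) {
    keys <- strsplit(e$path, "/", fixed = TRUE)[[1]]
    v <- if (length(e$dim) > 1L) array(e$values, dim = e$dim)
         else as.numeric(e$values)
    params <- assign_path(params, keys, v)
  }
  params
}

#' Save / load a model as a self-describing JSON archive
#'
#' The archive carries the architecture configuration, all weight arrays
#' (flattened with their dimensions) and the training history, so a model
#' restored with `loadPASNet` reproduces predictions exactly.
#'
#' @param model a \linkS4class{PASNet}.
#' @param path output file.
#' @return `loadPASNet` returns the restored model.
#' @export
savePASNet <- function(model, path) {
  cfg <- model@config
  arch <- list(n_groups = cfg@n_groups, blocks_per_group = cfg@blocks_per_group,
               dilation_schedule = cfg@dilation_schedule,
               channels = cfg@channels, filter_width = cfg@filter_width,
               library_count = cfg@library_count)
  jsonlite::write_json(
    list(config = arch, params = flatten_params(model@params),
         history = model@history),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname savePASNet
#' @export
loadPASNet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cf <- x$config
  cfg <- archConfig(n_groups = cf$n_groups,
                    blocks_per_group = cf$blocks_per_group,
                    dilation_schedule = unlist(cf$dilation_schedule),
                    channels = cf$channels, filter_width = cf$filter_width,
                    library_count = cf$library_count)
  entries <- lapply(x$params, function(e) {
    list(path = e$path, dim = unlist(e$dim), values = unlist(e$values))
  })
  new("PASNet", config = cfg, params = unflatten_params(entries),
      history = as.numeric(unlist(x$history)))
}
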