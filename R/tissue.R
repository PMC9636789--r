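# Condition-specific residual APA models: a small shared CNN predicts
# per-PAS condition residuals which are layered on top of baseline logit
# scores under a masked softmax (trained in two phases), and variant effects
# are scaled by the condition residual difference.

#' Construct an untrained condition-residual model
#'
#' The scorer CNN has 2 convolutional layers (16 filters, 8 positions wide),
#' global average pooling and a dense layer to 2 output channels (channel 1:
#' reference condition residual, channel 2: target condition residual),
#' shared across all PAS slots. Per-slot regression weights (score,
#' distance, bias) combine the baseline logit plus residual with the log
#' distance. Training is two-phase: first the regression weights alone with
#' residuals forced to 0 (KL objective), then the CNN jointly under a margin
#' loss that only sees PASs whose measured between-condition usage difference
#' exceeds `margin`.
#'
#' @param seed integer seed for CNN initialization.
#' @param filters,width CNN size (defaults 16 and 8).
#' @param phase1_maxit L-BFGS iteration cap for phase 1 (default 200).
#' @param phase2_epochs Adam epochs for phase 2 (default 25).
#' @param margin measured |delta| threshold gating the phase-2 loss
#'   (default 0.2).
#' @param lr phase-2 Adam learning rate (default 0.01).
#' @return a \linkS4class{TissueModel}.
#' @export
tissueModel <- function(seed = 1L, filters = 16L, width = 8L,
                        phase1_maxit = 200L, phase2_epochs = 25L,
                        margin = 0.2, lr = 0.01) {
  with_seed(deriveSeed(seed, "tissue_model"), {
    cnn <- list(
      conv1 = conv_init(4L, filters, width, scale = sqrt(2 / (4 * width))),
      conv2 = conv_init(filters, filters, width,
                        scale = sqrt(2 / (filters * width))),
      dense = list(W = matrix(rnorm(filters * 2L, sd = 0.1), filters, 2L),
                   b = numeric(2L))
    )
    w <- cbind(score = rep(1, 10), distance = rep(0, 10), bias = rep(0, 10))
    new("TissueModel", cnn = cnn, w = w,
        config = list(filters = filters, width = width,
                      phase1_maxit = phase1_maxit,
                      phase2_epochs = phase2_epochs, margin = margin,
                      lr = lr),
        phase = 0L)
  })
}

# CNN forward over a stack of sequences (already one-hot, (B*L) x 4).
# Returns s (B x 2) and a cache for the backward pass.
tissue_cnn_fwd <- function(cnn, X, B) {
  L <- PAS_LEN
  c1 <- conv_fwd(X, cnn$conv1, 1L, B, L)
  r1 <- relu_fwd(c1)
  c2 <- conv_fwd(r1, cnn$conv2, 1L, B, L)
  r2 <- relu_fwd(c2)
  gap <- rowsum(r2, rep(seq_len(B), each = L)) / L
  s <- sweep(gap %*% cnn$dense$W, 2L, cnn$dense$b, "+")
  list(s = s, cache = list(X = X, c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                           gap = gap))
}

tissue_cnn_bwd <- function(cnn, cache, dS) {
  B <- nrow(dS)
  L <- PAS_LEN
  ddense <- list(W = crossprod(cache$gap, dS), b = colSums(dS))
  dgap <- dS %*% t(cnn$dense$W)
  dr2 <- dgap[rep(seq_len(B), each = L), , drop = FALSE] / L
  dc2 <- relu_bwd(dr2, cache$c2)
  cb2 <- conv_bwd(dc2, cache$r1, cnn$conv2, 1L, B, L)
  dc1 <- relu_bwd(cb2$dX, cache$c1)
  cb1 <- conv_bwd(dc1, cache$X, cnn$conv1, 1L, B, L)
  list(conv1 = cb1$dW, conv2 = cb2$dW, dense = ddense)
}

#' Condition residual scores for a set of PAS sequences
#'
#' @param model a \linkS4class{TissueModel} or a list of them (an ensemble,
#'   in which case the arithmetic mean of the per-model scores is returned).
#' @param sequences character vector of 205-nt sequences.
#' @return n x 2 matrix of residual scores (columns: reference condition,
#'   target condition).
#' @export
tissueScore <- function(model, sequences) {
  if (is.list(model)) {
    stopifnot(length(model) >= 1L)
    mats <- lapply(model, tissueScore, sequences = sequences)
    return(Reduce(`+`, mats) / length(mats))
  }
  X <- encodeBatch(sequences)
  out <- tissue_cnn_fwd(model@cnn, X, length(sequences))$s
  colnames(out) <- c("ref", "tissue")
  out
}

# Masked-softmax proportions for one gene's PASs under regression weights w
# (per-slot rows), baseline logits, residual s and log distances.
tissue_softmax <- function(w, logit_base, s, d) {
  k <- length(logit_base)
  slots <- seq_len(k)
  f <- w[slots, 1L] * (logit_base + s) + w[slots, 2L] * d + w[slots, 3L]
  softmax(f)
}

#' Predicted per-PAS condition proportions
#'
#' Masked softmax of `w_score * (logit_base + s) + w_distance * d + w_bias`
#' over a gene's existing PASs. For the reference condition the residual `s`
#' is the CNN's reference channel; for the target condition its target
#' channel; `use_residual = FALSE` forces s = 0 (the phase-1 regime).
#'
#' @param model a \linkS4class{TissueModel}.
#' @param gene_df rows of one gene (columns sequence, logit_base, distance).
#' @param condition "ref" or "tissue".
#' @param use_residual include the CNN residual (default TRUE when phase 2
#'   has run).
#' @return proportions over the gene's PASs (sums to 1).
#' @export
tissueForward <- function(model, gene_df, condition = c("ref", "tissue"),
                          use_residual = model@phase >= 2L) {
  condition <- match.arg(condition)
  k <- nrow(gene_df)
  stopifnot(k <= 10L)
  s <- if (use_residual) {
    tissueScore(model, gene_df$sequence)[, condition]
  } else {
    numeric(k)
  }
  tissue_softmax(model@w, gene_df$logit_base, s, gene_df$distance)
}

# Split a paired-condition table into per-gene pieces with proportions.
tissue_split <- function(df) {
  lapply(split(df, df$gene), function(g) {
    g$y_ref <- g$count_ref / max(sum(g$count_ref), 1)
    g$y_tis <- g$count_tissue / max(sum(g$count_tissue), 1)
    g
  })
}

#' Phase 1: fit the regression weights with residuals forced to zero
#'
#' Minimizes the mean masked KL divergence between predicted and observed
#' isoform proportions summed over both conditions (L-BFGS on the per-slot
#' regression weights; the CNN is frozen and its residual contribution is
#' exactly zero, so the result is invariant to CNN initialization).
#'
#' @param model a \linkS4class{TissueModel}.
#' @param df paired-condition table from [generateTissueDataset()].
#' @return the fitted model (phase = 1) with `attr(, "loss")` start/end.
#' @export
phase1Train <- function(model, df) {
  genes <- tissue_split(df)
  obj <- function(theta) {
    w <- matrix(theta, 10L, 3L)
    tot <- 0
    for (g in genes) {
      yhat <- pmax(tissue_softmax(w, g$logit_base, 0, g$distance), 1e-12)
      nz_r <- g$y_ref > 0
      nz_t <- g$y_tis > 0
      tot <- tot + sum(g$y_tis[nz_t] * log(g$y_tis[nz_t] / yhat[nz_t])) +
        sum(g$y_ref[nz_r] * log(g$y_ref[nz_r] / yhat[nz_r]))
    }
    tot / length(genes)
  }
  start <- as.numeric(model@w)
  loss0 <- obj(start)
  fit <- optim(start, obj, method = "L-BFGS-B",
               control = list(maxit = model@config$phase1_maxit))
  model@w <- matrix(fit$par, 10L, 3L,
                    dimnames = list(NULL, c("score", "distance", "bias")))
  model@phase <- max(model@phase, 1L)
  attr(model, "loss") <- c(start = loss0, end = fit$value)
  model
}

# Margin loss and gradients for one batch of genes. `genes` is a list of
# per-gene tables (from tissue_split), `X` the stacked one-hot encodings of
# their sequences. Returns the batch loss and gradients for cnn and w.
phase2_batch_grad <- function(params, genes, X, margin) {
  nseq <- sum(vapply(genes, nrow, integer(1)))
  fw <- tissue_cnn_fwd(params$cnn, X, nseq)
  dS <- matrix(0, nseq, 2L)
  gw_w <- params$w * 0
  loss <- 0
  row0 <- 0L
  for (g in genes) {
    k <- nrow(g)
    rows <- row0 + seq_len(k)
    row0 <- row0 + k
    s_ref <- fw$s[rows, 1L]
    s_tis <- fw$s[rows, 2L]
    slots <- seq_len(k)
    base <- g$logit_base
    d <- g$distance
    p_ref <- tissue_softmax(params$w, base, s_ref, d)
    p_tis <- tissue_softmax(params$w, base, s_tis, d)
    D <- g$y_tis - g$y_ref
    Dhat <- p_tis - p_ref
    gate <- abs(D) > margin
    hin <- sign(D) * (D - Dhat)
    act <- gate & (hin > 0)
    loss <- loss + sum(pmax(hin[gate], 0))
    if (!any(act)) next
    dDhat <- ifelse(act, -sign(D), 0)
    for (cond in 1:2) {
      p <- if (cond == 1L) p_ref else p_tis
      sgn <- if (cond == 1L) -1 else 1
      dy <- sgn * dDhat
      dfv <- p * (dy - sum(dy * p))
      sc <- if (cond == 1L) s_ref else s_tis
      gw_w[slots, 1L] <- gw_w[slots, 1L] + dfv * (base + sc)
      gw_w[slots, 2L] <- gw_w[slots, 2L] + dfv * d
      gw_w[slots, 3L] <- gw_w[slots, 3L] + dfv
      dS[rows, cond] <- dS[rows, cond] + dfv * params$w[slots, 1L]
    }
  }
  K <- length(genes)
  list(loss = loss / K,
       grads = list(cnn = tissue_cnn_bwd(params$cnn, fw$cache, dS / K),
                    w = gw_w / K))
}

#' Phase 2: fit the residual CNN under the margin loss
#'
#' Unfreezes the CNN and jointly optimizes it with the regression weights by
#' Adam, penalizing only PASs whose measured between-condition proportion
#' difference exceeds the margin: `max(sign(D) * (D - D_hat), 0)` for
#' `|D| > margin`, where `D = y_tissue - y_ref` and `D_hat` the predicted
#' difference (target-channel residual for the tissue condition,
#' reference-channel residual for the reference condition).
#'
#' @param model a phase-1 \linkS4class{TissueModel}.
#' @param df paired-condition table.
#' @param batch genes per Adam step (default 16).
#' @param seed shuffling seed.
#' @return the fitted model (phase = 2) with `attr(, "loss_history")`.
#' @export
phase2Train <- function(model, df, batch = 16L, seed = 1L) {
  if (model@phase < 1L) stop("run phase1Train first")
  margin <- model@config$margin
  genes <- tissue_split(df)
  active <- vapply(genes, function(g) any(abs(g$y_tis - g$y_ref) > margin),
                   logical(1))
  if (!any(active)) {
    warning("no PAS exceeds the margin threshold; phase 2 is a no-op")
    model@phase <- 2L
    return(model)
  }
  params <- list(cnn = model@cnn, w = model@w)
  opt <- adam_init(params)
  history <- numeric(0)
  with_seed(deriveSeed(seed, "phase2"), {
    enc <- lapply(genes, function(g) encodeBatch(g$sequence))
    for (ep in seq_len(model@config$phase2_epochs)) {
      ord <- sample(which(active))
      ep_loss <- 0
      for (start_i in seq(1L, length(ord), by = batch)) {
        gidx <- ord[start_i:min(start_i + batch - 1L, length(ord))]
        bg <- phase2_batch_grad(params, genes[gidx],
                                do.call(rbind, enc[gidx]), margin)
        st <- adam_step(params, bg$grads, opt, lr = model@config$lr)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + bg$loss
      }
      history <- c(history, ep_loss)
    }
  })
  model@cnn <- params$cnn
  model@w <- params$w
  model@phase <- 2L
  attr(model, "loss_history") <- history
  model
}

#' Train an ensemble of condition-residual models
#'
#' Independently initialized and phase-2-trained models; predictions average
#' the per-model residual scores (see [tissueScore()]).
#'
#' @param df paired-condition table.
#' @param n_models ensemble size (default 10).
#' @param seed root seed.
#' @param ... passed to [tissueModel()].
#' @return list of \linkS4class{TissueModel}s.
#' @export
trainTissueEnsemble <- function(df, n_models = 10L, seed = 1L, ...) {
  lapply(seq_len(n_models), function(i) {
    m <- tissueModel(seed = deriveSeed(seed, paste0("ens", i)), ...)
    m <- phase1Train(m, df)
    phase2Train(m, df, seed = deriveSeed(seed, paste0("ens_ph2_", i)))
  })
}

#' Condition-scaled variant effect size
#'
#' Scales the variant odds ratio by a condition-specific odds ratio derived
#' from the residual-score difference of the variant sequence:
#' `1 / (1 + e^{-gamma*(s_tissue - s_ref)} * e^{-lambda*LOR} * (1-y)/y) - y`.
#' With a zero residual difference (or gamma = 0) this reduces exactly to
#' [aqtlEffect()].
#'
#' @param lor_value baseline predicted LOR.
#' @param y_pdui_base mean distal usage in (0, 1).
#' @param lambda orientation sign (see [assignLambda()]).
#' @param gamma residual scaling hyper-parameter.
#' @param s_var_tissue,s_var_ref residual scores of the variant sequence in
#'   the target and reference condition.
#' @return predicted condition-specific change in PDUI.
#' @export
tissueScaledEffect <- function(lor_value, y_pdui_base, lambda = 1, gamma = 1,
                               s_var_tissue = 0, s_var_ref = 0) {
  stopifnot(lambda %in% c(-1, 1))
  y <- clamp(y_pdui_base, 1e-6, 1 - 1e-6)
  1 / (1 + exp(-gamma * (s_var_tissue - s_var_ref)) *
         exp(-lambda * lor_value) * (1 - y) / y) - y
}

#' Tune the residual scaling factor gamma
#'
#' Evaluates each candidate on scored variant sets (one per condition) and
#' returns the gamma maximizing the median Spearman correlation between
#' predicted and measured effects across conditions; one shared gamma for
#' all conditions. Ties resolve to the smallest candidate.
#'
#' @param gammas numeric candidate grid (>= 1 value).
#' @param sets list of data.frames with columns lor, y_pdui_base, lambda,
#'   s_var_tissue, s_var_ref, measured.
#' @return list(gamma, objective = median Spearman per candidate).
#' @export
tuneGamma <- function(gammas, sets) {
  stopifnot(length(gammas) >= 1L, length(sets) >= 1L)
  gammas <- sort(gammas)
  objective <- vapply(gammas, function(g) {
    rs <- vapply(sets, function(df) {
      pred <- tissueScaledEffect(df$lor, df$y_pdui_base, df$lambda, g,
                                 df$s_var_tissue, df$s_var_ref)
      suppressWarnings(cor(pred, df$measured, method = "spearman"))
    }, numeric(1))
    median(rs, na.rm = TRUE)
  }, numeric(1))
  objective[is.na(objective)] <- -Inf
  best <- which(objective >= max(objective))[1L]  # smallest gamma on ties
  list(gamma = gammas[best], objective = setNames(objective,
                                                  as.character(gammas)))
}
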