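# Mask-based variant interpretation ("scrambling"): optimize per-position
# retention scores so that sequence pairs randomized everywhere except the
# retained features still reconstruct the model's predicted wildtype/variant
# log odds ratio. The scores interpolate, per position, between the wildtype
# base (large s) and a Laplace-smoothed background (s -> 0); discrete
# sequences are drawn with the Gumbel trick and gradients flow through a
# straight-through estimator.

MASK_CAP <- 1e4  # finite stand-in for the pinned s = +Inf at the mutation

#' Laplace-smoothed background of a one-hot pattern
#'
#' `b(x)_ij = (x_ij + 1) / 5`: the wildtype base keeps probability 0.4 and
#' each alternative 0.2.
#'
#' @param x N x 4 one-hot matrix.
#' @return N x 4 PSSM whose rows sum to 1.
#' @export
smoothedBackground <- function(x) {
  if (!all(rowSums(x) == 1) || !all(x %in% c(0, 1)))
    stop("input must be a one-hot pattern")
  (x + 1) / 5
}

#' Softmax-relaxed PSSM under a retention mask
#'
#' Position-wise `softmax(log b(x) + x * s)`: s = 0 recovers the smoothed
#' background exactly, s -> Inf recovers the one-hot wildtype.
#'
#' @param x N x 4 one-hot wildtype pattern.
#' @param s per-position retention scores (> 0).
#' @return N x 4 relaxed PSSM.
#' @export
relaxPssm <- function(x, s) {
  rowSoftmax(log(smoothedBackground(x)) + x * s)
}

#' Draw a one-hot sample from a PSSM via the Gumbel trick
#'
#' @param pssm N x 4 position-wise probabilities.
#' @return N x 4 one-hot sample.
#' @export
gumbelSample <- function(pssm) {
  g <- -log(-log(matrix(runif(length(pssm)), nrow(pssm), ncol(pssm))))
  pick <- max.col(log(pmax(pssm, 1e-12)) + g)
  out <- matrix(0, nrow(pssm), ncol(pssm))
  out[cbind(seq_len(nrow(pssm)), pick)] <- 1
  out
}

#' Construct the variant sample from a wildtype sample
#'
#' `x_s_var = x_s_wt + (x_var - x_wt)`: identical randomized background,
#' only the mutated position(s) changed. Requires the wildtype sample to
#' carry the wildtype base at the mutated position(s) (guaranteed when its
#' retention score is pinned).
#'
#' @param x_s_wt sampled one-hot wildtype pattern.
#' @param x_wt,x_var one-hot wildtype and variant patterns.
#' @return one-hot variant sample.
#' @export
variantSample <- function(x_s_wt, x_wt, x_var) {
  out <- x_s_wt + (x_var - x_wt)
  if (any(out < 0) || any(out > 1) || !all(rowSums(out) == 1))
    stop("wildtype sample does not carry the reference base at the mutation")
  out
}

#' Scrambler optimization settings
#'
#' @param target_lor the LOR to reconstruct (filled in by
#'   [interpretVariant()] when NULL).
#' @param entropy_weight weight of the entropy (KL-to-background) term.
#' @param t_bits target mean per-position KL during warmup.
#' @param iters gradient-descent iterations (default 300).
#' @param warmup_iters iterations under the targeted-KL objective before
#'   switching to unbounded entropy maximization (default 30).
#' @param lr Adam learning rate (default 0.01).
#' @param samples_per_step Gumbel samples per iteration (default 32).
#' @return settings list.
#' @export
scrambleObjective <- function(target_lor = NULL, entropy_weight = 0.5,
                              t_bits = 0.25, iters = 300L, warmup_iters = 30L,
                              lr = 0.01, samples_per_step = 32L) {
  stopifnot(entropy_weight >= 0, t_bits >= 0)
  list(target_lor = target_lor, entropy_weight = entropy_weight,
       t_bits = t_bits, iters = as.integer(iters),
       warmup_iters = as.integer(warmup_iters), lr = lr,
       samples_per_step = as.integer(samples_per_step))
}

# ---- Scoring-model interface -------------------------------------------------

#' Linear (optionally pairwise-interacting) surrogate scoring model
#'
#' A differentiable stand-in scorer for testing and for fast interpretation
#' experiments: `score(x) = intercept + sum(W * x) + sum_k coeff_k *
#' x[i_k, bi_k] * x[j_k, bj_k]` on the logit scale.
#'
#' @param weights N x 4 additive weight matrix.
#' @param interactions list of `list(i=, bi=, j=, bj=, coeff=)` with 1-based
#'   positions and base indices (A=1..T=4).
#' @param intercept scalar.
#' @return list(score, grad) closures operating on one-hot matrices.
#' @export
linearSurrogate <- function(weights, interactions = list(), intercept = 0) {
  score1 <- function(x) {
    s <- intercept + sum(weights * x)
    for (it in interactions)
      s <- s + it$coeff * x[it$i, it$bi] * x[it$j, it$bj]
    s
  }
  grad1 <- function(x) {
    g <- weights
    for (it in interactions) {
      g[it$i, it$bi] <- g[it$i, it$bi] + it$coeff * x[it$j, it$bj]
      g[it$j, it$bj] <- g[it$j, it$bj] + it$coeff * x[it$i, it$bi]
    }
    g
  }
  list(
    score = function(x) {
      if (is.list(x)) vapply(x, score1, numeric(1)) else score1(x)
    },
    grad = function(x) {
      if (is.list(x)) lapply(x, grad1) else grad1(x)
    }
  )
}

#' Logit-scale scorer backed by a trained cleavage network
#'
#' Wraps a \linkS4class{PASNet} as a differentiable scorer: the score is the
#' logit of the proximal isoform proportion and the gradient is obtained by
#' back-propagation to the one-hot input (evaluation mode). Batched: both
#' closures also accept a list of one-hot matrices.
#'
#' @param model a \linkS4class{PASNet}.
#' @param mode proximal isoform definition (see [proximalIsoform()]).
#' @param library sub-library index.
#' @return list(score, grad) closures.
#' @export
pasNetScorer <- function(model, mode = c("windowed", "any_not_distal"),
                         library = 11L) {
  mode <- match.arg(mode)
  cfg <- model@config
  w <- lossWindows()
  idx <- if (mode == "windowed") window_idx(w$proximal_report_window)
         else seq_len(PAS_LEN)
  run <- function(xs) {
    X <- do.call(rbind, xs)
    lib <- rep(as.integer(library), length(xs))
    fw <- net_forward(model@params, cfg, X, lib, training = FALSE,
                      keep_cache = TRUE)
    preds <- rowSoftmax(fw$logits)
    P <- rowSums(preds[, idx, drop = FALSE])
    list(fw = fw, preds = preds, P = clamp(P, 1e-9, 1 - 1e-9))
  }
  list(
    score = function(x) {
      xs <- if (is.list(x)) x else list(x)
      safeLogit(run(xs)$P, eps = 1e-9)
    },
    grad = function(x) {
      xs <- if (is.list(x)) x else list(x)
      r <- run(xs)
      B <- length(xs)
      # d logit(P)/d logits_j = (p_j (1[j in A] - P)) / (P (1 - P))
      inA <- matrix(0, B, OUT_LEN)
      inA[, idx] <- 1
      dlogits <- (r$preds * (inA - r$P)) / (r$P * (1 - r$P))
      dX <- net_input_grad(model@params, cfg, r$fw$cache, dlogits)
      out <- lapply(seq_len(B), function(b) {
        dX[(b - 1L) * PAS_LEN + seq_len(PAS_LEN), , drop = FALSE]
      })
      if (is.list(x)) out else out[[1L]]
    }
  )
}

# Instance norm (mean/sd over the free positions) followed by softplus.
mask_transform <- function(w, free, eps = 1e-3) {
  mu <- mean(w[free])
  sdv <- sqrt(mean((w[free] - mu)^2) + eps)
  z <- (w - mu) / sdv
  s <- log1p(exp(pmin(z, 30)))
  s[pmax(z, 0) >= 30] <- z[pmax(z, 0) >= 30]
  list(z = z, s = s, mu = mu, sd = sdv)
}

#' Optimize a retention mask explaining a variant's predicted effect
#'
#' Gradient-based search for per-position scores s (softplus of
#' instance-normalized free parameters, the mutated position pinned at a
#' large cap) such that wildtype/variant sample pairs drawn from the relaxed
#' PSSM reconstruct the model's original LOR while the rest of the sequence
#' is maximally randomized. The first `warmup_iters` iterations target a
#' small mean KL to the background before entropy is maximized unbounded.
#' With multiple restarts the per-restart masks are averaged and the
#' best-reconstructing restart's diagnostics are returned.
#'
#' @param scorer scoring model (list with `score` and `grad`; see
#'   [pasNetScorer()] and [linearSurrogate()]).
#' @param pair a \linkS4class{VariantPair}.
#' @param obj settings from [scrambleObjective()].
#' @param n_restarts independent optimization attempts (default 1).
#' @param seed integer seed.
#' @return a \linkS4class{MaskState}; diagnostics hold the loss trajectory,
#'   the scrambled-LOR trajectory, the target LOR and the final
#'   reconstruction error.
#' @export
interpretVariant <- function(scorer, pair, obj = scrambleObjective(),
                             n_restarts = 1L, seed = 1L) {
  validObject(pair)
  x_wt <- oneHot(pair@wt)
  x_var <- oneHot(pair@var)
  N <- nrow(x_wt)
  u <- pair@offsets + 1L
  free <- setdiff(seq_len(N), u)
  btil <- smoothedBackground(x_wt)
  delta <- if (is.null(obj$target_lor)) {
    drop(scorer$score(x_var) - scorer$score(x_wt))
  } else obj$target_lor
  wt_base_col <- max.col(x_wt)

  run_restart <- function(rs) {
    with_seed(deriveSeed(seed, paste0("scramble", rs)), {
      w <- rnorm(N, 0, 0.5)
      opt <- adam_init(list(w = w))
      loss_traj <- numeric(obj$iters)
      lor_traj <- numeric(obj$iters)
      for (it in seq_len(obj$iters)) {
        mt <- mask_transform(w, free)
        s <- mt$s
        s[u] <- MASK_CAP
        xhat <- relaxPssm(x_wt, s)
        xhat_wt <- xhat[cbind(seq_len(N), wt_base_col)]
        # sampled reconstruction term (straight-through gradient)
        S <- obj$samples_per_step
        wt_samples <- lapply(seq_len(S), function(i) gumbelSample(xhat))
        var_samples <- lapply(wt_samples, variantSample, x_wt = x_wt,
                              x_var = x_var)
        sc_wt <- scorer$score(wt_samples)
        sc_var <- scorer$score(var_samples)
        d_s <- sc_var - sc_wt
        g_wt <- scorer$grad(wt_samples)
        g_var <- scorer$grad(var_samples)
        ds <- numeric(N)
        dxhat <- matrix(0, N, 4L)
        for (i in seq_len(S)) {
          dxhat <- dxhat + (2 * (d_s[i] - delta) / S) *
            (g_var[[i]] - g_wt[[i]])
        }
        ds <- rowSums(dxhat * xhat * (x_wt - xhat_wt))
        # entropy (KL to background) term
        kl_pos <- rowSums(btil * log(btil / pmax(xhat, 1e-12)))
        kl_mean <- mean(kl_pos[free])
        dkl_ds <- (xhat_wt - 0.4) / length(free)
        if (it <= obj$warmup_iters) {
          ent_loss <- obj$entropy_weight * (kl_mean - obj$t_bits)^2
          ds <- ds + obj$entropy_weight * 2 * (kl_mean - obj$t_bits) * dkl_ds
        } else {
          ent_loss <- obj$entropy_weight * kl_mean
          ds <- ds + obj$entropy_weight * dkl_ds
        }
        loss_traj[it] <- mean((d_s - delta)^2) + ent_loss
        lor_traj[it] <- mean(d_s)
        if (!all(is.finite(ds))) stop("non-finite scrambler gradient")
        # softplus + instance-norm backward over the free positions
        dz <- ds * sigmoid(mt$z)
        dz[u] <- 0
        dzf <- dz[free]
        zf <- mt$z[free]
        dw <- numeric(N)
        dw[free] <- (dzf - mean(dzf) - zf * mean(dzf * zf)) / mt$sd
        st <- adam_step(list(w = w), list(w = dw), opt, lr = obj$lr)
        w <- st$params$w
        opt <- st$state
      }
      mt <- mask_transform(w, free)
      s <- mt$s
      s[u] <- MASK_CAP
      list(w = w, s = s, loss = loss_traj, lor = lor_traj,
           recon = abs(mean(tail(lor_traj, 20)) - delta))
    })
  }

  runs <- lapply(seq_len(n_restarts), run_restart)
  s_mean <- Reduce(`+`, lapply(runs, `[[`, "s")) / length(runs)
  best <- which.min(vapply(runs, `[[`, numeric(1), "recon"))
  new("MaskState",
      w = runs[[best]]$w, s = s_mean, mutated_pos = pair@offsets,
      background = btil,
      diagnostics = list(loss = runs[[best]]$loss,
                         scrambled_lor = runs[[best]]$lor,
                         target_lor = delta,
                         reconstruction_error = runs[[best]]$recon,
                         restarts = length(runs)))
}
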