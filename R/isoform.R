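# Pairwise and multi-PAS isoform-usage regression on top of per-PAS logit
# scores, with the endogenous-data filters, stability-embedding PCA and
# isotonic effect-size calibration.

#' Filter endogenous isoform tables
#'
#' Applies the standard 3'-seq quality filters. For the pairwise task (one
#' row per adjacent PAS pair with columns `count_p`, `count_d`,
#' `distance_bp`, and sequences `seq_p`, `seq_d`): total read count >= 500,
#' sites 100-4000 bp apart, and no more than 7 consecutive adenines in either
#' sequence. For the multi-PAS task (one row per gene x PAS with columns
#' `gene`, `count`, `distance_bp` [gap to previous PAS; NA for the first] and
#' `sequence`): at most 10 PASs per gene, at least 10 total counts, adjacent
#' PASs separated by 50-40,000 bp, and no more than 13 consecutive adenines.
#'
#' @param tables data.frame as described above.
#' @param task "pairwise" or "multipas".
#' @return list(tables = surviving rows, report = named removal counts per
#'   rule).
#' @export
applyEndogenousFilters <- function(tables, task = c("pairwise", "multipas")) {
  task <- match.arg(task)
  if (task == "pairwise") {
    report <- c(low_count = 0L, distance = 0L, polyA = 0L)
    if (nrow(tables) == 0L) return(list(tables = tables, report = report))
    bad_count <- (tables$count_p + tables$count_d) < 500
    bad_dist <- tables$distance_bp < 100 | tables$distance_bp > 4000
    bad_pa <- vapply(seq_len(nrow(tables)), function(i) {
      maxBaseRun(tables$seq_p[i]) > 7 || maxBaseRun(tables$seq_d[i]) > 7
    }, logical(1))
    report <- c(low_count = sum(bad_count), distance = sum(bad_dist),
                polyA = sum(bad_pa))
    keep <- !(bad_count | bad_dist | bad_pa)
    list(tables = tables[keep, , drop = FALSE], report = report)
  } else {
    report <- c(too_many_pas = 0L, low_count = 0L, distance = 0L, polyA = 0L)
    if (nrow(tables) == 0L) return(list(tables = tables, report = report))
    genes <- split(seq_len(nrow(tables)), tables$gene)
    drop_gene <- logical(length(genes))
    reason <- character(length(genes))
    for (gi in seq_along(genes)) {
      rows <- tables[genes[[gi]], , drop = FALSE]
      gaps <- rows$distance_bp[-1L]
      if (nrow(rows) > 10L) {
        drop_gene[gi] <- TRUE; reason[gi] <- "too_many_pas"
      } else if (sum(rows$count) < 10) {
        drop_gene[gi] <- TRUE; reason[gi] <- "low_count"
      } else if (length(gaps) && (any(gaps < 50) || any(gaps > 40000))) {
        drop_gene[gi] <- TRUE; reason[gi] <- "distance"
      } else if (any(vapply(rows$sequence, maxBaseRun, numeric(1)) > 13)) {
        drop_gene[gi] <- TRUE; reason[gi] <- "polyA"
      }
    }
    for (r in names(report)) report[r] <- sum(reason == r)
    keep_rows <- unlist(genes[!drop_gene], use.names = FALSE)
    list(tables = tables[sort(keep_rows), , drop = FALSE], report = report)
  }
}

#' Pseudo-counted isoform logit
#'
#' `logit((c_p + pseudo) / (c_p + c_d + pseudo))` with a 0.5 pseudo-count.
#' The zero-count corner (c_p = c_d = 0) evaluates to logit(1); proportions
#' are clamped to [1e-4, 1 - 1e-4] before the logit so every non-negative
#' count pair yields a finite value.
#'
#' @param c_p,c_d proximal and distal counts (>= 0).
#' @param pseudo pseudo-count (default 0.5).
#' @return finite logit(s).
#' @export
estimateLogit <- function(c_p, c_d, pseudo = 0.5) {
  stopifnot(all(c_p >= 0), all(c_d >= 0))
  p <- (c_p + pseudo) / (c_p + c_d + pseudo)
  safeLogit(p, eps = 1e-4)
}

#' Fit the pairwise isoform regression
#'
#' Least squares for
#' `logit_endogenous ~ w_p * logit_p + w_d * logit_d + w_dist * d + bias`,
#' with leave-fold-out cross-validated Spearman correlation.
#'
#' @param df data.frame with columns `logit_endog`, `logit_p`, `logit_d`,
#'   `distance` (log distance between the sites).
#' @param folds cross-validation folds (default 5).
#' @return list(weights = named vector, cv_spearman, fitted).
#' @export
fitPairwise <- function(df, folds = 5L) {
  if (nrow(df) < 10L) stop("need at least 10 pairs")
  X <- cbind(logit_p = df$logit_p, logit_d = df$logit_d,
             distance = df$distance, bias = 1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) warning("degenerate pairwise design; pseudoinverse")
  beta <- qr.coef(qx, df$logit_endog)
  beta[is.na(beta)] <- 0
  fold_id <- rep_len(seq_len(folds), nrow(df))[sample.int(nrow(df))]
  cv_pred <- numeric(nrow(df))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    b <- qr.coef(qr(X[tr, , drop = FALSE]), df$logit_endog[tr])
    b[is.na(b)] <- 0
    cv_pred[!tr] <- X[!tr, , drop = FALSE] %*% b
  }
  list(weights = setNames(drop(beta), colnames(X)),
       cv_spearman = suppressWarnings(
         cor(cv_pred, df$logit_endog, method = "spearman")),
       fitted = drop(X %*% beta))
}

# ---- Masked softmax multi-PAS model -----------------------------------------

# Feature matrix (score, 4 PCs, log distance) for gene-table rows.
mp_features <- function(df) {
  cbind(score = df$logit, saluki1 = df$saluki1, saluki2 = df$saluki2,
        saluki3 = df$saluki3, saluki4 = df$saluki4, distance = df$distance)
}

# Unpack the 13 free parameters (proximal bias pinned at 0: a shared bias
# shift cancels in the softmax).
mp_unpack <- function(theta) {
  nm <- c("score", paste0("saluki", 1:4), "distance", "bias")
  list(distal = setNames(theta[1:7], nm),
       proximal = setNames(c(theta[8:13], 0), nm))
}

mp_pack <- function(weights) {
  unname(c(weights$distal, weights$proximal[1:6]))
}

# Predicted distal proportion per gene: masked softmax over the gene's
# existing PASs, distal-most PAS scored with the distal role.
mp_predict_yd <- function(theta, df) {
  w <- mp_unpack(theta)
  F <- mp_features(df)
  f_p <- drop(F %*% w$proximal[1:6]) + w$proximal[7]
  f_d <- drop(F %*% w$distal[1:6]) + w$distal[7]
  f <- ifelse(df$is_distal, f_d, f_p)
  gmax <- tapply(f, df$gene, max)  # per-gene shift; cancels in the ratio
  e <- exp(f - gmax[as.character(df$gene)])
  denom <- tapply(e, df$gene, sum)
  num <- tapply(e * df$is_distal, df$gene, sum)
  drop(num / denom)
}

#' Fit the masked softmax multi-PAS regression
#'
#' Maximizes the fit of the predicted distal isoform proportion
#' `y_hat_d = exp(f_d) / sum_i 1{exists} exp(f_i)` to the observed
#' `y_d = c_d / sum c_i` by quasi-Newton (L-BFGS) minimization of the mean
#' per-gene binary KL divergence (a squared-error objective on the
#' proportions is selectable). Role scores `f` combine the per-PAS logit
#' score, 4 stability-embedding PCs and the cumulative log distance; the
#' proximal bias is pinned at 0 for identifiability.
#'
#' @param df gene table as from [generateMultiPASGenes()] (columns gene,
#'   is_distal, logit, saluki1..4, distance, count).
#' @param objective "kl" (default) or "squared".
#' @param maxit optimizer iteration cap.
#' @return list(weights = list(distal, proximal), value, convergence,
#'   message).
#' @export
fitMultiPAS <- function(df, objective = c("kl", "squared"), maxit = 500L) {
  objective <- match.arg(objective)
  npas <- table(df$gene)
  if (any(npas > 10L)) stop("genes must have at most 10 PASs")
  tot <- tapply(df$count, df$gene, sum)
  y_d <- tapply(df$count * df$is_distal, df$gene, sum) / pmax(tot, 1)
  y_d <- clamp(drop(y_d), 1e-6, 1 - 1e-6)
  objfun <- function(theta) {
    yhat <- clamp(mp_predict_yd(theta, df), 1e-9, 1 - 1e-9)
    if (objective == "kl") {
      mean(y_d * log(y_d / yhat) + (1 - y_d) * log((1 - y_d) / (1 - yhat)))
    } else {
      mean((y_d - yhat)^2)
    }
  }
  fit <- optim(numeric(13L), objfun, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  if (fit$convergence != 0)
    warning("multi-PAS fit did not converge: ", fit$message,
            " (returning last iterate)")
  list(weights = mp_unpack(fit$par), value = fit$value,
       convergence = fit$convergence, message = fit$message)
}

#' Predict per-isoform proportions under the masked softmax model
#'
#' @param weights list(distal, proximal) weight vectors (as returned by
#'   [fitMultiPAS()] or [defaultMultiPASWeights()]), or a list of such weight
#'   sets (an ensemble, e.g. one per stability-model fold), in which case the
#'   arithmetic mean of the predicted proportions is returned.
#' @param gene_df rows of one gene (columns is_distal, logit, saluki1..4,
#'   distance).
#' @return numeric vector of proportions over the gene's PASs (sums to 1).
#' @export
predictMultiPAS <- function(weights, gene_df) {
  one <- function(w) {
    F <- mp_features(gene_df)
    f_p <- drop(F %*% w$proximal[1:6]) + w$proximal[7]
    f_d <- drop(F %*% w$distal[1:6]) + w$distal[7]
    softmax(ifelse(gene_df$is_distal, f_d, f_p))
  }
  if (!is.null(weights$distal)) return(one(weights))
  rowMeans(vapply(weights, one, numeric(nrow(gene_df))))
}

#' Principal components of a stability-embedding matrix
#'
#' Standard centered PCA projection onto the first k components,
#' variance-ordered, with explained-variance fractions.
#'
#' @param embedding isoforms x hidden-units numeric matrix.
#' @param k number of components (default 4).
#' @return list(scores = isoforms x k, explained = variance fractions,
#'   rotation).
#' @export
embedPCs <- function(embedding, k = 4L) {
  if (ncol(embedding) < k) stop("k exceeds the number of embedding columns")
  pc <- prcomp(embedding, center = TRUE, scale. = FALSE)
  if (k > length(pc$sdev) || sum(pc$sdev[seq_len(k)] > 0) < k)
    stop("k exceeds the rank of the centered embedding")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Monotone (isotonic) calibration of predicted effect sizes
#'
#' Pool-adjacent-violators fit of held-out measured absolute effects against
#' predicted absolute effects; the returned map is a non-decreasing step
#' interpolation (constant extrapolation outside the training range).
#'
#' @param pred_effects predicted effect sizes (absolute values are used).
#' @param measured held-out measured effect sizes (absolute values used).
#' @return list(map = function(x), knots, values).
#' @export
isotonicCalibrate <- function(pred_effects, measured) {
  stopifnot(length(pred_effects) == length(measured),
            length(pred_effects) >= 2L)
  x <- abs(pred_effects)
  y <- abs(measured)
  ord <- order(x)
  ir <- isoreg(x[ord], y[ord])
  knots <- ir$x
  vals <- ir$yf
  map <- function(z) {
    z <- abs(z)
    idx <- findInterval(z, knots, all.inside = FALSE)
    out <- numeric(length(z))
    inside <- idx >= 1L
    out[inside] <- vals[pmin(idx[inside], length(vals))]
    out[!inside] <- vals[1L]
    out
  }
  list(map = map, knots = knots, values = vals)
}
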