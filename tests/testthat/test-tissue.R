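# Condition-residual models: masked softmax forward, two-phase training,
# ensembling, condition-scaled effects and gamma tuning.

test_that("the masked softmax forward follows the regression form", {
  tm <- tissueModel(seed = 50)
  gene <- data.frame(sequence = random_seq(3, seed = 50),
                     logit_base = c(0.5, -1, 1.2), distance = c(0, 2.5, 3.1))
  # identity score weights with zero residual: softmax of baseline logits
  tm@w[, 1] <- 1
  tm@w[, 2] <- 0
  tm@w[, 3] <- 0
  p <- tissueForward(tm, gene, "tissue", use_residual = FALSE)
  expect_equal(unname(p), unname(polyacode:::softmax(gene$logit_base)),
               tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # with residuals the proportions still normalize
  p2 <- tissueForward(tm, gene, "tissue", use_residual = TRUE)
  expect_equal(sum(p2), 1, tolerance = 1e-12)
})

test_that("phase 1 is invariant to CNN initialization and reduces the loss", {
  td <- generateTissueDataset(40, seed = 51)
  m1 <- phase1Train(tissueModel(seed = 1), td)
  m2 <- phase1Train(tissueModel(seed = 999), td)
  expect_equal(m1@w, m2@w, tolerance = 1e-8)
  l <- attr(m1, "loss")
  expect_lt(l["end"], l["start"])
  expect_equal(m1@phase, 1L)
})

test_that("a single-PAS gene contributes zero phase-1 loss", {
  g1 <- data.frame(gene = 1, pas = 1, n_pas = 1,
                   sequence = random_seq(seed = 52), cse_offset = 69,
                   logit_base = 0.3, distance = 0,
                   has_motif = FALSE, count_ref = 50, count_tissue = 60)
  m <- phase1Train(tissueModel(seed = 1), g1)
  expect_equal(unname(attr(m, "loss")["end"]), 0, tolerance = 1e-9)
})

test_that("the phase-2 margin loss gates on measured differences", {
  # no PAS exceeding the margin: warning and no-op
  td <- generateTissueDataset(15, effect = 0.05, seed = 53)
  m <- phase1Train(tissueModel(seed = 1), td)
  genes <- polyacode:::tissue_split(td)
  D <- unlist(lapply(genes, function(g) g$y_tis - g$y_ref))
  expect_false(any(abs(D) > 0.2))  # fixed-seed fixture stays under the margin
  expect_warning(m2 <- phase2Train(m, td), "no-op")
  expect_equal(m2@cnn, m@cnn)
  # perfect predictions: loss identically zero
  g <- genes[[1]]
  g$y_ref <- g$count_ref / sum(g$count_ref)
  g$y_tis <- g$y_ref + c(0.5, rep(-0.5 / (nrow(g) - 1), nrow(g) - 1))
  params <- list(cnn = m@cnn, w = m@w)
  bg <- polyacode:::phase2_batch_grad(params, list(g),
                                      polyacode:::encodeBatch(g$sequence),
                                      margin = 2)  # nothing passes the gate
  expect_equal(bg$loss, 0)
})

test_that("phase-2 gradients match finite differences", {
  td <- generateTissueDataset(10, seed = 54)
  m <- phase1Train(tissueModel(seed = 2), td)
  genes <- polyacode:::tissue_split(td)
  X <- do.call(rbind, lapply(genes, function(g)
    polyacode:::encodeBatch(g$sequence)))
  params <- list(cnn = m@cnn, w = m@w)
  set.seed(55)
  params$cnn$dense$W[] <- rnorm(32, sd = 0.2)
  bg <- polyacode:::phase2_batch_grad(params, genes, X, 0.2)
  expect_gt(bg$loss, 0)  # fixed-seed fixture has active hinges
  lossf <- function(p) polyacode:::phase2_batch_grad(p, genes, X, 0.2)$loss
  eps <- 1e-6
  for (spec in list(
    list(g = function(p) p$w, s = function(p, v) { p$w[] <- v; p },
         a = bg$grads$w),
    list(g = function(p) p$cnn$dense$W,
         s = function(p, v) { p$cnn$dense$W[] <- v; p },
         a = bg$grads$cnn$dense$W),
    list(g = function(p) p$cnn$conv1$W[[4]],
         s = function(p, v) { p$cnn$conv1$W[[4]][] <- v; p },
         a = bg$grads$cnn$conv1$W[[4]]))) {
    v <- spec$g(params)
    for (i in sample(length(v), 3)) {
      num <- (lossf(spec$s(params, replace(v, i, v[i] + eps))) -
                lossf(spec$s(params, replace(v, i, v[i] - eps)))) / (2 * eps)
      expect_equal(spec$a[i], num, tolerance = 1e-4)
    }
  }
})

test_that("ensemble scores average per-model scores, order-invariantly", {
  seqs <- random_seq(4, seed = 56)
  m1 <- tissueModel(seed = 1)
  m2 <- tissueModel(seed = 2)
  s1 <- tissueScore(m1, seqs)
  s2 <- tissueScore(m2, seqs)
  expect_equal(tissueScore(list(m1), seqs), s1)
  expect_equal(tissueScore(list(m1, m2), seqs), (s1 + s2) / 2,
               tolerance = 1e-12)
  expect_equal(tissueScore(list(m2, m1), seqs),
               tissueScore(list(m1, m2), seqs), tolerance = 1e-12)
})

test_that("the condition-scaled effect reduces to the baseline scaling", {
  set.seed(57)
  for (i in 1:20) {
    l <- rnorm(1)
    y <- runif(1, 0.05, 0.95)
    lam <- sample(c(-1, 1), 1)
    s <- rnorm(1)
    # zero residual difference: exact reduction for any gamma
    expect_equal(tissueScaledEffect(l, y, lam, gamma = rnorm(1),
                                    s_var_tissue = s, s_var_ref = s),
                 aqtlEffect(l, y, lam), tolerance = 1e-12)
    # gamma = 0: reduction regardless of the residuals
    expect_equal(tissueScaledEffect(l, y, lam, gamma = 0,
                                    s_var_tissue = rnorm(1),
                                    s_var_ref = rnorm(1)),
                 aqtlEffect(l, y, lam), tolerance = 1e-12)
  }
  expect_equal(tissueScaledEffect(log(2), 0.5, 1, gamma = 1,
                                  s_var_tissue = log(2), s_var_ref = 0),
               0.3, tolerance = 1e-12)
})

test_that("gamma tuning maximizes the median rank correlation", {
  set.seed(58)
  gamma0 <- 1.5
  sets <- lapply(1:4, function(i) {
    n <- 60
    df <- data.frame(lor = rnorm(n), y_pdui_base = runif(n, 0.2, 0.8),
                     lambda = sample(c(-1, 1), n, replace = TRUE),
                     s_var_tissue = rnorm(n), s_var_ref = rnorm(n))
    df$measured <- tissueScaledEffect(df$lor, df$y_pdui_base, df$lambda,
                                      gamma0, df$s_var_tissue,
                                      df$s_var_ref) + rnorm(n, sd = 0.01)
    df
  })
  grid <- seq(0, 3, by = 0.25)
  tg <- tuneGamma(grid, sets)
  expect_lt(abs(tg$gamma - gamma0), 0.5)
  # single-candidate grid returns that candidate
  expect_equal(tuneGamma(0.7, sets)$gamma, 0.7)
  # uninformative residuals: flat objective, smallest gamma by the tie rule
  sets0 <- lapply(sets, function(df) {
    df$s_var_tissue <- 0
    df$s_var_ref <- 0
    df
  })
  expect_equal(tuneGamma(c(0.5, 1, 2), sets0)$gamma, 0.5)
})

test_that("the ensemble recovers a planted condition-specific motif effect", {
  td <- generateTissueDataset(300, seed = 5)
  te <- generateTissueDataset(80, seed = 99)
  mods <- trainTissueEnsemble(td, n_models = 2L, seed = 1)
  sc <- tissueScore(mods, te$sequence)
  dsc <- sc[, "tissue"] - sc[, "ref"]
  rho <- cor(dsc, as.numeric(te$has_motif), method = "spearman")
  expect_gte(rho, 0.5)
  # sign agreement on held-out PASs: motif-bearing PASs sit above the median
  expect_gt(mean((dsc > median(dsc)) == te$has_motif), 0.7)
})
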