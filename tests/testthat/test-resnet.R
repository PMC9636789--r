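# The residual network: architecture contracts, forward normalization,
# hand-derived backward passes, hybrid loss, shift augmentation, training.

test_that("architecture configuration enforces its invariants", {
  cfg <- archConfig()
  expect_equal(cfg@n_groups * cfg@blocks_per_group, 28L)
  expect_equal(cfg@output_len, 206L)
  expect_equal(cfg@input_len, 205L)
  expect_equal(max(cfg@dilation_schedule), 8L)
  expect_error(archConfig(n_groups = 3L), "dilation_schedule")
  # a minimal single-block network still produces a valid distribution
  m1 <- buildModel(archConfig(n_groups = 1L, blocks_per_group = 1L,
                              dilation_schedule = 1L, channels = 4L))
  p <- cleavageVector(m1, random_seq(seed = 1))
  expect_length(p, 206L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("an untrained model with zero-initialized head is uniform", {
  m <- buildModel(tiny_cfg(), seed = 2)
  p <- cleavageVector(m, random_seq(seed = 2))
  expect_equal(unname(p), rep(1 / 206, 206), tolerance = 1e-12)
})

test_that("forward outputs normalize and reject malformed input", {
  m <- tiny_model()
  seqs <- random_seq(5, seed = 3)
  preds <- pasForward(m, seqs)
  expect_equal(dim(preds), c(5L, 206L))
  expect_equal(unname(rowSums(preds)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(preds >= 0))
  expect_error(pasForward(m, substr(seqs[1], 1, 100)), "205")
  expect_error(pasForward(m, gsub("A", "X", seqs[1])), "ACGTN")
  # N encodes to all-zeros and still yields a valid distribution
  pn <- cleavageVector(m, paste0("N", substr(seqs[1], 2, 205)))
  expect_equal(sum(pn), 1, tolerance = 1e-6)
})

test_that("the sub-library enters only as an additive intercept", {
  m <- tiny_model(seed = 4)
  seqs <- random_seq(2, seed = 4)
  lg <- function(s, l) {
    X <- polyacode:::encodeBatch(s)
    polyacode:::net_forward(m@params, m@config, X, l)$logits
  }
  d1 <- lg(seqs[1], 3L) - lg(seqs[1], 9L)
  d2 <- lg(seqs[2], 3L) - lg(seqs[2], 9L)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(unname(drop(d1)),
               m@params$head$Wlib[, 3] - m@params$head$Wlib[, 9],
               tolerance = 1e-12)
})

test_that("backward pass matches finite differences", {
  cfg <- tiny_cfg(channels = 3L)
  m <- tiny_model(seed = 5, channels = 3L)
  seqs <- random_seq(3, seed = 5)
  X <- polyacode:::encodeBatch(seqs)
  lib <- c(1L, 5L, 13L)
  law <- defaultLaw()
  Y <- t(vapply(seqs, function(s) polyacode:::lawTarget(law, s),
                numeric(206)))
  loss_fn <- function(params) {
    fw <- polyacode:::net_forward(params, cfg, X, lib, training = TRUE)
    polyacode:::hybrid_loss_grad(polyacode:::rowSoftmax(fw$logits), Y)$loss
  }
  fw <- polyacode:::net_forward(m@params, cfg, X, lib, training = TRUE,
                                keep_cache = TRUE)
  lg <- polyacode:::hybrid_loss_grad(polyacode:::rowSoftmax(fw$logits), Y)
  gr <- polyacode:::net_backward(m@params, cfg, fw$cache, lg$dlogits)
  eps <- 1e-5
  set.seed(6)
  check <- function(get, set, ana) {
    v <- get(m@params)
    for (i in sample(length(v), min(3L, length(v)))) {
      p1 <- set(m@params, replace(v, i, v[i] + eps))
      p2 <- set(m@params, replace(v, i, v[i] - eps))
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_equal(ana[i], num, tolerance = 1e-4)
    }
  }
  check(function(p) p$stem$W[[1]],
        function(p, v) { p$stem$W[[1]][] <- v; p }, gr$stem$W[[1]])
  check(function(p) p$groups[[1]][[1]]$conv1$W[[2]],
        function(p, v) { p$groups[[1]][[1]]$conv1$W[[2]][] <- v; p },
        gr$groups[[1]][[1]]$conv1$W[[2]])
  check(function(p) p$groups[[2]][[1]]$bn1$gamma,
        function(p, v) { p$groups[[2]][[1]]$bn1$gamma <- v; p },
        gr$groups[[2]][[1]]$bn1$gamma)
  check(function(p) p$head$dist_w,
        function(p, v) { p$head$dist_w <- v; p }, gr$head$dist_w)
})

test_that("hybrid loss satisfies its identities and closed forms", {
  w <- lossWindows()
  p <- polyacode:::softmax(rnorm(206))
  expect_equal(hybridLoss(p, p, w), 0, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    a <- polyacode:::softmax(rnorm(206, sd = 2))
    b <- polyacode:::softmax(rnorm(206, sd = 2))
    expect_gte(hybridLoss(a, b, w), -1e-12)
  }
  # two-point target (one inside the isoform window) vs uniform prediction:
  # full KL is log(103); the window term follows the binary KL formula
  target <- numeric(206)
  target[c(90, 150)] <- 0.5
  unif <- rep(1 / 206, 206)
  y_iso <- 0.5
  p_iso <- 31 / 206
  expected <- log(103) +
    y_iso * log(y_iso / p_iso) + (1 - y_iso) * log((1 - y_iso) / (1 - p_iso))
  expect_equal(hybridLoss(unif, target, w), expected, tolerance = 1e-12)
  # zero-prediction bins where the target is positive stay finite
  pz <- c(0, polyacode:::softmax(rnorm(204)), 0)
  expect_true(is.finite(hybridLoss(pz, target, w)))
  # gradient vanishes at pred == target
  Y <- matrix(target, 1)
  g0 <- polyacode:::hybrid_loss_grad(Y + 1e-15, Y, w)
  expect_lt(max(abs(g0$dlogits)), 1e-8)
})

test_that("proximal isoform windows follow the stated conventions", {
  unif <- rep(1 / 206, 206)
  expect_equal(proximalIsoform(unif, "windowed"), 51 / 206)
  expect_equal(proximalIsoform(unif, "any_not_distal"), 205 / 206)
  distal_only <- c(numeric(205), 1)
  expect_equal(proximalIsoform(distal_only, "windowed"), 0)
  expect_equal(proximalIsoform(distal_only, "any_not_distal"), 0)
})

test_that("shift augmentation moves sequence and target jointly", {
  set.seed(8)
  seq <- random_seq()
  target <- polyacode:::lawTarget(defaultLaw(), seq)
  expect_identical(shiftAugment(seq, target, shift = 0)$sequence, seq)
  sh <- shiftAugment(seq, target, shift = 5)
  expect_equal(sum(sh$target), 1, tolerance = 1e-12)
  expect_equal(sh$target[206], target[206])
  expect_equal(sh$target[6:205], target[1:200])
  expect_identical(substr(sh$sequence, 6, 205), substr(seq, 1, 200))
  # interior-supported target: +5 then -5 restores it
  back <- shiftAugment(sh$sequence, sh$target, shift = -5)
  expect_equal(back$target, target, tolerance = 1e-12)
  expect_identical(substr(back$sequence, 1, 200), substr(seq, 1, 200))
  # mass shifted off the edge accumulates on the retained edge bin
  shr <- shiftAugment(seq, target, max_shift = 120, shift = 110)
  expect_equal(sum(shr$target), 1, tolerance = 1e-12)
  expect_error(shiftAugment(seq, target, max_shift = 205), "configuration")
})

test_that("training reduces the loss and is reproducible; 0 epochs is a no-op", {
  b <- tiny_bundle(n = 120, seed = 9)
  m <- buildModel(tiny_cfg(), seed = 1)
  m0 <- trainPASNet(m, b, epochs = 0L, seed = 1)
  expect_identical(m0@params, m@params)
  m2 <- trainPASNet(m, b, epochs = 2L, batch = 32L, seed = 1)
  expect_length(m2@history, 2L)
  expect_lt(m2@history[2], m2@history[1])
  m2b <- trainPASNet(m, b, epochs = 2L, batch = 32L, seed = 1)
  expect_identical(m2@params, m2b@params)
})

test_that("a model round-trips through its JSON archive", {
  m <- tiny_model(seed = 10)
  s <- random_seq(seed = 10)
  path <- tempfile(fileext = ".json")
  savePASNet(m, path)
  m2 <- loadPASNet(path)
  expect_equal(cleavageVector(m2, s), cleavageVector(m, s),
               tolerance = 1e-12)
})
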