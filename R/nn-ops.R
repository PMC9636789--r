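# Minimal batched 1-D convolution engine.
#
# A batch of B sequences of length L with C channels is stored as a single
# (B*L) x C matrix, rows ordered sample-major (row (b-1)*L + l = position l of
# sample b). A dilated convolution of width W is a sum of W shifted matrix
# products; the shifts never cross sample boundaries. The hot paths (shifted
# products, batch norm, ReLU) are compiled (src/nn_kernels.cpp); backward
# passes are hand-derived and validated against finite differences in the
# test suite.

# Tap offsets for a width-W convolution with dilation d ('same' padding;
# even widths pad one extra position on the right).
conv_offsets <- function(width, dilation) {
  (seq_len(width) - 1L - (width - 1L) %/% 2L) * dilation
}

conv_init <- function(c_in, c_out, width, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (width * c_in))
  list(
    W = lapply(seq_len(width), function(t) {
      matrix(rnorm(c_in * c_out, sd = scale), c_in, c_out)
    }),
    b = numeric(c_out)
  )
}

conv_fwd <- function(X, par, dilation, B, L) {
  cpp_conv_fwd(X, par$W, par$b, conv_offsets(length(par$W), dilation), B, L)
}

conv_bwd <- function(dY, X, par, dilation, B, L) {
  r <- cpp_conv_bwd(dY, X, par$W, conv_offsets(length(par$W), dilation), B, L)
  list(dW = list(W = r$dW, b = drop(r$db)), dX = r$dX)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

# Fused batch-norm + ReLU over batch and positions (per channel). In
# training mode returns a cache and updated running statistics
# (momentum 0.9).
bnrelu_fwd <- function(X, par, training, momentum = 0.9, eps = 1e-3) {
  if (training) {
    r <- cpp_bnrelu_fwd_train(X, par$gamma, par$beta, eps)
    list(Y = r$Y, cache = list(xhat = r$xhat, inv = drop(r$inv)),
         run = list(
           run_mean = momentum * par$run_mean + (1 - momentum) * drop(r$mu),
           run_var = momentum * par$run_var + (1 - momentum) * drop(r$var)))
  } else {
    list(Y = cpp_bnrelu_fwd_eval(X, par$gamma, par$beta, par$run_mean,
                                 par$run_var, eps),
         cache = NULL, run = NULL)
  }
}

bnrelu_bwd <- function(dY, par, cache) {
  r <- cpp_bnrelu_bwd(dY, par$gamma, par$beta, cache$xhat, cache$inv)
  list(dpar = list(gamma = drop(r$dgamma), beta = drop(r$dbeta)), dX = r$dX)
}

relu_fwd <- function(X) cpp_relu(X)

relu_bwd <- function(dY, Xpre) cpp_relu_bwd(dY, Xpre)

# ---- Adam optimizer over a nested named list of numeric arrays --------------

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

# One Adam update. `params` and `grads` are congruent nested lists.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      for (nm in keys) {
        if (is.character(nm) && is.null(g[[nm]]))
          stop("missing gradient for parameter '", nm, "'")
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# Elementwise sum of two congruent nested lists of arrays.
grad_accumulate <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in seq_along(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) grad_accumulate(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

grad_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")
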