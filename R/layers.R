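# Layer objects: environments holding parameters (value/grad/trainable) and
# a fwd(x, training) method returning list(y, back). back(gy) accumulates
# parameter gradients in place and returns the input gradient.

new_param <- function(value, trainable = TRUE, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = if (is.null(dim(value))) length(value) else dim(value))
  p$trainable <- trainable
  p$name <- name
  class(p) <- "dsfbr_param"
  p
}

#' Collect all parameters of a model or layer
#'
#' Recursively walks lists/environments and returns every parameter object.
#'
#' @param obj a layer, module list, or model handle.
#' @return list of parameter environments (class dsfbr_param).
#' @export
collect_params <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "dsfbr_param")) {
      out[[length(out) + 1L]] <<- o
    } else if (is.environment(o) && !is.null(o$.params)) {
      for (p in o$.params) walk(p)
      if (!is.null(o$.children)) for (ch in o$.children) walk(ch)
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(obj)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

he_init <- function(dims, fan_in, rng_sd_scale = 1) {
  array(stats::rnorm(prod(dims), sd = rng_sd_scale * sqrt(2 / fan_in)), dims)
}

new_layer <- function(params = list(), children = list()) {
  ly <- new.env(parent = emptyenv())
  ly$.params <- params
  ly$.children <- children
  ly
}

#' Convolution layer constructor
#'
#' @param k kernel size; @param cin,cout channel widths.
#' @param stride,pad,pad_mode geometry; @param bias include a bias term.
#' @return layer object with $fwd(x, training).
#' @export
layer_conv2d <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                         pad_mode = "zero", bias = TRUE) {
  w <- new_param(he_init(c(k, k, cin, cout), k * k * cin), name = "conv.w")
  b <- if (bias) new_param(numeric(cout), name = "conv.b") else NULL
  ly <- new_layer(params = if (bias) list(w = w, b = b) else list(w = w))
  ly$k <- k; ly$stride <- stride; ly$pad <- pad; ly$pad_mode <- pad_mode
  ly$fwd <- function(x, training = TRUE) {
    op <- conv2d(x, w$value, if (is.null(b)) NULL else b$value,
                 stride = stride, pad = pad, pad_mode = pad_mode)
    list(y = op$y, back = function(gy) {
      g <- op$back(gy)
      w$grad <- w$grad + g$gw
      if (!is.null(b)) b$grad <- b$grad + g$gb
      g$gx
    })
  }
  ly
}

#' Batch-normalization layer (per-channel over space and batch)
#' @param c channel width; @param eps stability constant; @param momentum
#'   running-statistics update rate.
#' @return layer object.
#' @export
layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  gamma <- new_param(rep(1, c), name = "bn.gamma")
  beta <- new_param(numeric(c), name = "bn.beta")
  ly <- new_layer(params = list(gamma = gamma, beta = beta))
  ly$running_mean <- numeric(c)
  ly$running_var <- rep(1, c)
  ly$eps <- eps
  ly$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    n <- d[1] * d[2] * d[4]
    xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])  # n x C
    if (training) {
      mu <- colMeans(xm)
      va <- colMeans(xm^2) - mu^2
      va <- pmax(va, 0)
      ly$running_mean <- (1 - momentum) * ly$running_mean + momentum * mu
      ly$running_var <- (1 - momentum) * ly$running_var + momentum * va * n / max(n - 1L, 1L)
    } else {
      mu <- ly$running_mean
      va <- ly$running_var
    }
    istd <- 1 / sqrt(va + eps)
    xhat <- (xm - rep(mu, each = n)) * rep(istd, each = n)
    ym <- xhat * rep(gamma$value, each = n) + rep(beta$value, each = n)
    y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    back <- function(gy) {
      gym <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), ncol = d[3])
      gamma$grad <- gamma$grad + colSums(gym * xhat)
      beta$grad <- beta$grad + colSums(gym)
      if (training) {
        s1 <- colSums(gym)
        s2 <- colSums(gym * xhat)
        gxm <- (rep(gamma$value * istd, each = n) / n) *
          (n * gym - rep(s1, each = n) - xhat * rep(s2, each = n))
      } else {
        gxm <- gym * rep(gamma$value * istd, each = n)
      }
      aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    }
    list(y = y, back = back)
  }
  ly
}

#' Convolution + BatchNorm + ReLU block (the basic CBR unit)
#'
#' The convolution carries no bias: the normalization shift subsumes it.
#'
#' @param k kernel size; @param cin,cout widths; @param stride,pad geometry.
#' @return layer object.
#' @export
layer_cbr <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                      pad_mode = "zero") {
  conv <- layer_conv2d(k, cin, cout, stride = stride, pad = pad,
                       pad_mode = pad_mode, bias = FALSE)
  bn <- layer_bn(cout)
  ly <- new_layer(children = list(conv = conv, bn = bn))
  ly$conv <- conv; ly$bn <- bn
  ly$fwd <- function(x, training = TRUE) {
    o1 <- conv$fwd(x, training)
    o2 <- bn$fwd(o1$y, training)
    o3 <- relu_op(o2$y)
    list(y = o3$y, back = function(gy) o1$back(o2$back(o3$back(gy))))
  }
  ly
}

# 1-D channel convolution layer (ECA gate), replicate padding, no bias
layer_conv1d_channel <- function(k = 3L) {
  w <- new_param(stats::rnorm(k, sd = sqrt(1 / k)), name = "eca.w")
  ly <- new_layer(params = list(w = w))
  ly$k <- k
  ly$fwd <- function(d, training = TRUE) {
    op <- conv1d_channel(d, w$value)
    list(y = op$y, back = function(gy) {
      g <- op$back(gy)
      w$grad <- w$grad + g$gw
      g$gd
    })
  }
  ly
}

# scalar trainable parameter (HBR alpha)
layer_scalar <- function(init = 1.0, name = "alpha") {
  new_param(init, name = name)
}

# ---- inference-only primitives for the transformer backbone ----

layer_linear <- function(cin, cout, bias = TRUE) {
  w <- new_param(array(stats::rnorm(cin * cout, sd = 0.02), c(cin, cout)), name = "lin.w")
  b <- if (bias) new_param(numeric(cout), name = "lin.b") else NULL
  ly <- new_layer(params = if (bias) list(w = w, b = b) else list(w = w))
  ly$apply <- function(x) {
    # x: (tokens, cin) matrix
    y <- x %*% w$value
    if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
    y
  }
  ly
}

layer_layernorm <- function(c, eps = 1e-6) {
  gamma <- new_param(rep(1, c), name = "ln.gamma")
  beta <- new_param(numeric(c), name = "ln.beta")
  ly <- new_layer(params = list(gamma = gamma, beta = beta))
  ly$apply <- function(x) {
    # x: (tokens, c)
    mu <- rowMeans(x)
    xc <- x - mu
    va <- rowMeans(xc^2)
    xh <- xc / sqrt(va + eps)
    sweep(sweep(xh, 2L, gamma$value, "*"), 2L, beta$value, "+")
  }
  ly
}

gelu <- function(x) x * stats::pnorm(x)
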