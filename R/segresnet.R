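#' Segmentation network configuration
#'
#' An encoder-decoder residual network: initial 3x3 convolution with spatial
#' dropout, then per spatial level pre-activation residual blocks (two 3x3
#' convolutions, each preceded by group normalization and ReLU, with an
#' additive identity skip). Strided 3x3 convolutions halve the spatial size
#' and double the features between encoder levels. The decoder has a single
#' block per level: a 1x1 convolution halves the features, bilinear x2
#' upsampling restores the spatial size, and the matching encoder output is
#' added. A 1x1 convolution and sigmoid produce the pixel-wise probability
#' map. No variational auto-encoder branch.
#'
#' @param init_filters filters after the initial convolution (default 16).
#' @param n_levels spatial levels (default 4; the input is downsampled
#'   `n_levels - 1` times).
#' @param blocks_per_level encoder residual blocks per level; default
#'   `c(1, 2, 2, 4)` truncated/extended to `n_levels`.
#' @param conv_kernel convolution kernel size (3).
#' @param dropout_rate spatial dropout after the initial convolution.
#' @param norm_groups group-normalization groups (reduced automatically
#'   when a level has fewer channels).
#' @param threshold probability threshold for binarizing predictions.
#' @return object of class `seg_model_config`.
#' @export
seg_model_config <- function(init_filters = 16L, n_levels = 4L,
                             blocks_per_level = NULL, conv_kernel = 3L,
                             dropout_rate = 0.2, norm_groups = 8L,
                             threshold = 0.5) {
  if (is.null(blocks_per_level)) {
    base <- c(1L, 2L, 2L, 4L)
    blocks_per_level <- if (n_levels <= 4L) base[seq_len(n_levels)] else
      c(base, rep(4L, n_levels - 4L))
  }
  if (length(blocks_per_level) != n_levels)
    stop("model config error: blocks_per_level must have n_levels entries",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("model config error: dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(init_filters = as.integer(init_filters),
                 n_levels = as.integer(n_levels),
                 blocks_per_level = as.integer(blocks_per_level),
                 conv_kernel = as.integer(conv_kernel),
                 dropout_rate = dropout_rate,
                 norm_groups = as.integer(norm_groups),
                 threshold = threshold),
            class = "seg_model_config")
}

level_filters <- function(cfg, l) cfg$init_filters * 2L^(l - 1L)

init_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

block_param_names <- function(prefix) {
  paste0(prefix, ".", c("g1", "be1", "W1", "b1", "g2", "be2", "W2", "b2"))
}

init_block_params <- function(k, C) {
  list(g1 = rep(1, C), be1 = rep(0, C), W1 = init_conv(k, C, C),
       b1 = rep(0, C), g2 = rep(1, C), be2 = rep(0, C),
       W2 = init_conv(k, C, C), b2 = rep(0, C))
}

#' Build a segmentation model
#'
#' @param config a [seg_model_config()].
#' @param input_size expected `(r, theta)` input size; predictions on other
#'   shapes are rejected. Sizes not divisible by `2^(n_levels - 1)` are
#'   padded symmetrically inside the network and cropped back at the head.
#' @param seed weight-initialization seed (He-normal convolutions, unit
#'   gain / zero offset group norm).
#' @return object of class `seg_model`.
#' @export
build_model <- function(config = seg_model_config(),
                        input_size = c(200L, 448L), seed = 1L) {
  stopifnot(inherits(config, "seg_model_config"))
  m <- 2L^(config$n_levels - 1L)
  if (any(input_size < m))
    stop("model config error: input smaller than the downsampling factor ",
         m, call. = FALSE)
  k <- config$conv_kernel
  with_seed(seed, {
    p <- list()
    f1 <- config$init_filters
    p[["stem.W"]] <- init_conv(k, 1L, f1)
    p[["stem.b"]] <- rep(0, f1)
    for (l in seq_len(config$n_levels)) {
      fl <- level_filters(config, l)
      if (l > 1L) {
        p[[paste0("enc", l, ".down.W")]] <- init_conv(k, fl %/% 2L, fl)
        p[[paste0("enc", l, ".down.b")]] <- rep(0, fl)
      }
      for (i in seq_len(config$blocks_per_level[l])) {
        bp <- init_block_params(k, fl)
        for (nm in names(bp))
          p[[paste0("enc", l, ".blk", i, ".", nm)]] <- bp[[nm]]
      }
    }
    for (l in rev(seq_len(config$n_levels - 1L))) {
      fl <- level_filters(config, l)
      p[[paste0("dec", l, ".up.W")]] <- init_conv(1L, 2L * fl, fl)
      p[[paste0("dec", l, ".up.b")]] <- rep(0, fl)
      bp <- init_block_params(k, fl)
      for (nm in names(bp))
        p[[paste0("dec", l, ".blk.", nm)]] <- bp[[nm]]
    }
    p[["head.W"]] <- init_conv(1L, f1, 1L)
    p[["head.b"]] <- 0
    structure(list(config = config,
                   input_size = as.integer(input_size), params = p),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("seg_model: %d levels, %d initial filters, ",
                     "%d parameters, input %d x %d\n"),
              x$config$n_levels, x$config$init_filters, np,
              x$input_size[1], x$input_size[2]))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `seg_model`.
#' @return integer parameter count.
#' @export
n_model_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

block_fwd <- function(p, prefix, x, groups) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  n1 <- gn_fwd(x, g("g1"), g("be1"), groups)
  r1 <- relu_fwd(n1$y)
  c1 <- nn_conv_fwd(r1$y, g("W1"), g("b1"), 1L, 1L)
  n2 <- gn_fwd(c1, g("g2"), g("be2"), groups)
  r2 <- relu_fwd(n2$y)
  c2 <- nn_conv_fwd(r2$y, g("W2"), g("b2"), 1L, 1L)
  list(y = x + c2, n1 = n1, m1 = r1$mask, r1 = r1$y,
       n2 = n2, m2 = r2$mask, r2 = r2$y)
}

block_bwd <- function(p, prefix, dy, cache, groups, acc) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  b2 <- nn_conv_bwd(cache$r2, g("W2"), dy, 1L, 1L)
  acc(paste0(prefix, ".W2"), b2$dW); acc(paste0(prefix, ".b2"), b2$db)
  dn2 <- b2$dx * cache$m2
  g2 <- gn_bwd(dn2, g("g2"), cache$n2)
  acc(paste0(prefix, ".g2"), g2$dgamma); acc(paste0(prefix, ".be2"), g2$dbeta)
  b1 <- nn_conv_bwd(cache$r1, g("W1"), g2$dx, 1L, 1L)
  acc(paste0(prefix, ".W1"), b1$dW); acc(paste0(prefix, ".b1"), b1$db)
  dn1 <- b1$dx * cache$m1
  g1 <- gn_bwd(dn1, g("g1"), cache$n1)
  acc(paste0(prefix, ".g1"), g1$dgamma); acc(paste0(prefix, ".be1"), g1$dbeta)
  dy + g1$dx
}

pad_amounts <- function(n, m) {
  r <- (m - n %% m) %% m
  c(r %/% 2L, r - r %/% 2L)
}

# Forward pass. Returns the probability map (input-sized matrix) and, when
# keep_cache, the intermediate tensors required by seg_backward().
seg_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  L <- cfg$n_levels; G <- cfg$norm_groups
  m <- 2L^(L - 1L)
  H0 <- nrow(x); W0 <- ncol(x)
  pr <- pad_amounts(H0, m); pc <- pad_amounts(W0, m)
  xp <- matrix(0, H0 + sum(pr), W0 + sum(pc))
  xp[pr[1] + seq_len(H0), pc[1] + seq_len(W0)] <- x
  cube <- array(xp, c(dim(xp), 1L))
  p <- model$params
  cc <- list(pr = pr, pc = pc, H0 = H0, W0 = W0, x = cube)
  cur <- nn_conv_fwd(cube, p[["stem.W"]], p[["stem.b"]], 1L, 1L)
  if (training && cfg$dropout_rate > 0) {
    dm <- spatial_dropout_mask(dim(cur)[3], cfg$dropout_rate)
    cur <- cur * rep(dm, each = prod(dim(cur)[1:2]))
    cc$dropmask <- dm
  }
  skips <- vector("list", L)
  cc$enc <- vector("list", L)
  for (l in seq_len(L)) {
    ec <- list()
    if (l > 1L) {
      ec$down_in <- cur
      cur <- nn_conv_fwd(cur, p[[paste0("enc", l, ".down.W")]],
                         p[[paste0("enc", l, ".down.b")]], 2L, 1L)
    }
    ec$blocks <- vector("list", cfg$blocks_per_level[l])
    for (i in seq_len(cfg$blocks_per_level[l])) {
      bf <- block_fwd(p, paste0("enc", l, ".blk", i), cur, G)
      cur <- bf$y
      ec$blocks[[i]] <- bf
    }
    skips[[l]] <- cur
    cc$enc[[l]] <- ec
  }
  cc$dec <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    dc <- list(cur_in = cur, z_dims = NULL)
    z <- nn_conv_fwd(cur, p[[paste0("dec", l, ".up.W")]],
                     p[[paste0("dec", l, ".up.b")]], 1L, 0L)
    dc$z_dims <- dim(z)
    cur <- up2_fwd(z) + skips[[l]]
    bf <- block_fwd(p, paste0("dec", l, ".blk"), cur, G)
    cur <- bf$y
    dc$block <- bf
    cc$dec[[l]] <- dc
  }
  cc$head_in <- cur
  logits <- nn_conv_fwd(cur, p[["head.W"]], p[["head.b"]], 1L, 0L)
  prob_pad <- sigmoid(logits[, , 1])
  cc$prob_pad <- prob_pad
  prob <- prob_pad[pr[1] + seq_len(H0), pc[1] + seq_len(W0), drop = FALSE]
  if (keep_cache) list(prob = prob, cache = cc) else list(prob = prob)
}

# Backward pass from dL/dprob (input-sized). Returns the flat gradient list
# aligned with model$params.
seg_backward <- function(model, cache, dprob) {
  cfg <- model$config
  L <- cfg$n_levels; G <- cfg$norm_groups
  p <- model$params
  gacc <- new.env(parent = emptyenv())
  acc <- function(nm, v)
    assign(nm, get0(nm, envir = gacc, ifnotfound = 0) + v, envir = gacc)
  pr <- cache$pr; pc <- cache$pc
  dpp <- matrix(0, nrow(cache$prob_pad), ncol(cache$prob_pad))
  dpp[pr[1] + seq_len(cache$H0), pc[1] + seq_len(cache$W0)] <- dprob
  dlogits <- dpp * cache$prob_pad * (1 - cache$prob_pad)
  hb <- nn_conv_bwd(cache$head_in, p[["head.W"]],
                    array(dlogits, c(dim(dlogits), 1L)), 1L, 0L)
  acc("head.W", hb$dW); acc("head.b", hb$db)
  dcur <- hb$dx
  dskip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    ds <- block_bwd(p, paste0("dec", l, ".blk"), dcur, dc$block, G, acc)
    dskip[[l]] <- if (is.null(dskip[[l]])) ds else dskip[[l]] + ds
    dz <- up2_bwd(ds, dc$z_dims)
    ub <- nn_conv_bwd(dc$cur_in, p[[paste0("dec", l, ".up.W")]], dz, 1L, 0L)
    acc(paste0("dec", l, ".up.W"), ub$dW)
    acc(paste0("dec", l, ".up.b"), ub$db)
    if (l == L - 1L) {
      dskip[[L]] <- if (is.null(dskip[[L]])) ub$dx else dskip[[L]] + ub$dx
    } else {
      dcur <- ub$dx
    }
  }
  dchain <- NULL
  for (l in rev(seq_len(L))) {
    d <- dskip[[l]]
    if (is.null(d)) d <- dchain else if (!is.null(dchain)) d <- d + dchain
    ec <- cache$enc[[l]]
    for (i in rev(seq_len(cfg$blocks_per_level[l])))
      d <- block_bwd(p, paste0("enc", l, ".blk", i), d, ec$blocks[[i]], G,
                     acc)
    if (l > 1L) {
      db <- nn_conv_bwd(ec$down_in, p[[paste0("enc", l, ".down.W")]], d,
                        2L, 1L)
      acc(paste0("enc", l, ".down.W"), db$dW)
      acc(paste0("enc", l, ".down.b"), db$db)
      dchain <- db$dx
    } else {
      dstem <- d
    }
  }
  if (!is.null(cache$dropmask))
    dstem <- dstem * rep(cache$dropmask, each = prod(dim(dstem)[1:2]))
  sb <- nn_conv_bwd(cache$x, p[["stem.W"]], dstem, 1L, 1L)
  acc("stem.W", sb$dW); acc("stem.b", sb$db)
  grads <- mget(names(p), envir = gacc,
                ifnotfound = list(0))
  grads
}
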