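#' Network configuration
#'
#' A slice-wise (2D) encoder-decoder U-Net with skip connections and an
#' optional non-local self-attention block at the bottleneck, the lowest
#' resolution of the network. The full-scale configuration is depth 4 with 64
#' base filters on 256 x 256 sections; `base_filters` and `depth` scale down
#' so the same architecture trains on a CPU in minutes.
#'
#' @param in_channels Input channels; 1 for single-sequence T1CE.
#' @param out_mode Output head; `"sigmoid_1ch"` (single-channel foreground
#'   probability) is the only implemented mode.
#' @param depth Number of down/up-sampling stages; `input_size` must be
#'   divisible by `2^depth`.
#' @param base_filters Filters at the first encoder level (>= 4); doubled at
#'   each deeper level.
#' @param nonlocal_enabled Insert one non-local block at the bottleneck.
#' @param nonlocal_variant `"embedded_gaussian"` (softmax attention) or
#'   `"dot_product"`.
#' @param nonlocal_channel_reduction Channel reduction inside the block; the
#'   bottleneck channel count must be divisible by it.
#' @param input_size In-plane input size `(H, W)`.
#' @return A list of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, out_mode = "sigmoid_1ch",
                           depth = 4L, base_filters = 64L,
                           nonlocal_enabled = TRUE,
                           nonlocal_variant = "embedded_gaussian",
                           nonlocal_channel_reduction = 2L,
                           input_size = c(256, 256)) {
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  input_size <- as.integer(input_size)
  if (out_mode != "sigmoid_1ch") stop("only the sigmoid_1ch head is implemented")
  if (base_filters < 4L) stop("base_filters must be >= 4")
  if (any(input_size %% 2L^depth != 0L))
    stop(sprintf("input_size must be divisible by 2^depth = %d", 2L^depth))
  if (!nonlocal_variant %in% c("embedded_gaussian", "dot_product"))
    stop("nonlocal_variant must be embedded_gaussian or dot_product")
  bottleneck_ch <- base_filters * 2L^depth
  if (bottleneck_ch %% as.integer(nonlocal_channel_reduction) != 0L)
    stop("bottleneck channels not divisible by nonlocal_channel_reduction")
  structure(list(in_channels = as.integer(in_channels), out_mode = out_mode,
                 depth = depth, base_filters = base_filters,
                 nonlocal_enabled = isTRUE(nonlocal_enabled),
                 nonlocal_variant = nonlocal_variant,
                 nonlocal_channel_reduction = as.integer(nonlocal_channel_reduction),
                 input_size = input_size),
            class = "network_config")
}

# Uniform(-1/sqrt(fan_in), +1/sqrt(fan_in)) for weights and biases, the
# conventional convolution default. Normalized layers also carry the
# instance-norm affine pair (gain 1, shift 0 at init); their conv bias is
# kept for uniformity but is a no-op under normalization.
conv_init <- function(k, cin, cout, zero = FALSE, norm = FALSE) {
  n <- k * k * cin * cout
  bound <- 1 / sqrt(k * k * cin)
  w <- if (zero) rep(0, n) else stats::runif(n, -bound, bound)
  w <- if (k == 1) array(w, c(cin, cout)) else array(w, c(k, k, cin, cout))
  out <- list(w = w, b = if (zero) rep(0, cout) else stats::runif(cout, -bound, bound))
  if (norm) { out$g <- rep(1, cout); out$be <- rep(0, cout) }
  out
}

#' Initialize the weights of a non-local attention block
#'
#' Embedded-Gaussian self-attention: for each spatial position i the output is
#' a residual update `z_i = W_z y_i + x_i` with
#' `y_i = sum_j softmax_j(theta(x_i)' phi(x_j)) g(x_j)`; theta, phi and g are
#' 1x1 convolutions to `channels / reduction` channels. The output projection
#' `W_z` is zero-initialized, so a freshly inserted block is exactly the
#' identity.
#'
#' @param channels Input channel count.
#' @param reduction Channel reduction factor; must divide `channels`.
#' @return A named list of 1x1-convolution weights.
#' @export
nonlocal_init <- function(channels, reduction = 2L) {
  if (channels %% reduction != 0L)
    stop("channels must be divisible by the reduction factor")
  cr <- channels %/% reduction
  list(theta = conv_init(1, channels, cr), phi = conv_init(1, channels, cr),
       g = conv_init(1, channels, cr), wz = conv_init(1, cr, channels, zero = TRUE))
}

#' Analytic parameter count of the non-local block
#'
#' Three projections `channels -> channels/reduction` plus the output
#' projection back, each a 1x1 convolution with bias.
#'
#' @inheritParams nonlocal_init
#' @return Integer parameter count.
#' @export
nonlocal_param_count <- function(channels, reduction = 2L) {
  cr <- channels %/% reduction
  3L * (channels * cr + cr) + (cr * channels + channels)
}

#' Apply a non-local attention block to a feature map
#'
#' @param x 4D feature map `(H, W, C, N)`.
#' @param weights Output of [nonlocal_init()] for `C` channels.
#' @param variant `"embedded_gaussian"` (softmax-normalized attention, rows
#'   sum to 1) or `"dot_product"` (scaled by the number of positions).
#' @param return_attention Also return the `(HW, HW)` attention matrix of each
#'   sample (for inspection/testing).
#' @return The transformed feature map, same shape; with
#'   `return_attention = TRUE`, `list(y = , attention = list)`.
#' @export
nonlocal_forward <- function(x, weights, variant = "embedded_gaussian",
                             return_attention = FALSE) {
  d <- dim(x)
  if (length(d) != 4L) stop("x must be a 4D (H, W, C, N) array")
  out <- nonlocal_fwd_cache(x, weights, variant)
  if (return_attention) list(y = out$y, attention = out$cache$A) else out$y
}

nonlocal_fwd_cache <- function(x, p, variant) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  y <- array(0, d)
  cache <- list(X = vector("list", N), theta = vector("list", N),
                phi = vector("list", N), g = vector("list", N),
                A = vector("list", N), Y = vector("list", N), variant = variant)
  for (n in seq_len(N)) {
    X <- matrix(x[, , , n], hw, C)
    th <- X %*% p$theta$w; th <- sweep(th, 2, p$theta$b, "+")
    ph <- X %*% p$phi$w; ph <- sweep(ph, 2, p$phi$b, "+")
    g <- X %*% p$g$w; g <- sweep(g, 2, p$g$b, "+")
    S <- th %*% t(ph)
    if (variant == "embedded_gaussian") {
      E <- exp(sweep(S, 1, apply(S, 1, max), "-"))  # row-wise stabilization
      A <- E / rowSums(E)
    } else {
      A <- S / hw
    }
    Y <- A %*% g
    Z <- Y %*% p$wz$w
    Z <- sweep(Z, 2, p$wz$b, "+")
    y[, , , n] <- array(X + Z, c(d[1], d[2], C))
    cache$X[[n]] <- X; cache$theta[[n]] <- th; cache$phi[[n]] <- ph
    cache$g[[n]] <- g; cache$A[[n]] <- A; cache$Y[[n]] <- Y
  }
  list(y = y, cache = cache)
}

nonlocal_bwd <- function(dy, p, cache) {
  d <- dim(dy); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dx <- array(0, d)
  gr <- list(theta = list(w = 0 * p$theta$w, b = 0 * p$theta$b),
             phi = list(w = 0 * p$phi$w, b = 0 * p$phi$b),
             g = list(w = 0 * p$g$w, b = 0 * p$g$b),
             wz = list(w = 0 * p$wz$w, b = 0 * p$wz$b))
  for (n in seq_len(N)) {
    dZ <- matrix(dy[, , , n], hw, C)
    X <- cache$X[[n]]; A <- cache$A[[n]]; Y <- cache$Y[[n]]
    th <- cache$theta[[n]]; ph <- cache$phi[[n]]; g <- cache$g[[n]]
    gr$wz$w <- gr$wz$w + t(Y) %*% dZ
    gr$wz$b <- gr$wz$b + colSums(dZ)
    dY <- dZ %*% t(p$wz$w)
    dA <- dY %*% t(g)
    dg <- t(A) %*% dY
    if (cache$variant == "embedded_gaussian") {
      dS <- A * (dA - rowSums(dA * A))
    } else {
      dS <- dA / hw
    }
    dth <- dS %*% ph
    dph <- t(dS) %*% th
    gr$theta$w <- gr$theta$w + t(X) %*% dth
    gr$theta$b <- gr$theta$b + colSums(dth)
    gr$phi$w <- gr$phi$w + t(X) %*% dph
    gr$phi$b <- gr$phi$b + colSums(dph)
    gr$g$w <- gr$g$w + t(X) %*% dg
    gr$g$b <- gr$g$b + colSums(dg)
    dX <- dZ + dth %*% t(p$theta$w) + dph %*% t(p$phi$w) + dg %*% t(p$g$w)
    dx[, , , n] <- array(dX, c(d[1], d[2], C))
  }
  list(dx = dx, grads = gr)
}

#' Build a U-Net
#'
#' Two 3x3 convolution / instance-norm / ReLU layers per resolution level,
#' 2x2 max pooling on the way down, a 2x2 up-convolution (with the same
#' norm + ReLU) on the way up, channel concatenation with the matching
#' encoder level, and a 1x1 sigmoid head. With `nonlocal_enabled`, exactly
#' one non-local block sits at the bottleneck.
#'
#' @param cfg A [network_config()].
#' @param seed Seed for He-normal weight initialization.
#' @return A list of class `unet` with fields `cfg` and `params`.
#' @export
build_unet <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(seed, {
    f <- cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)
    fb <- cfg$base_filters * 2L^cfg$depth
    params <- list()
    cin <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      params[[paste0("enc", i, "a")]] <- conv_init(3, cin, f[i], norm = TRUE)
      params[[paste0("enc", i, "b")]] <- conv_init(3, f[i], f[i], norm = TRUE)
      cin <- f[i]
    }
    params$bot_a <- conv_init(3, f[cfg$depth], fb, norm = TRUE)
    params$bot_b <- conv_init(3, fb, fb, norm = TRUE)
    if (cfg$nonlocal_enabled)
      params$nonlocal <- nonlocal_init(fb, cfg$nonlocal_channel_reduction)
    cin <- fb
    for (i in rev(seq_len(cfg$depth))) {
      params[[paste0("up", i)]] <- conv_init(2, cin, f[i], norm = TRUE)  # 2x2 up-conv
      params[[paste0("dec", i, "a")]] <- conv_init(3, 2L * f[i], f[i], norm = TRUE)
      params[[paste0("dec", i, "b")]] <- conv_init(3, f[i], f[i], norm = TRUE)
      cin <- f[i]
    }
    params$head <- conv_init(1, f[1], 1L)
    structure(list(cfg = cfg, params = params), class = "unet")
  })
}

#' Total trainable parameter count of a network
#'
#' @param net A `unet` (or its `params` list).
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(net) {
  params <- if (inherits(net, "unet")) net$params else net
  sum(vapply(rapply(params, length, how = "unlist"), identity, numeric(1)))
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass over a batch of sections x: (H, W, in_channels, N).
# All 3x3 convolutions run with a fused ReLU; the 1x1 head is linear
# followed by a sigmoid. Returns probabilities and, when need_cache,
# everything backward needs.
unet_forward <- function(net, x, need_cache = FALSE) {
  p <- net$params; cfg <- net$cfg
  cache <- list(pre = list(), skips = list(), pool = list())
  conv <- function(name, x) {
    z <- .cpp_conv3_forward(x, p[[name]]$w, p[[name]]$b, FALSE)
    nr <- .cpp_in_forward(z, p[[name]]$g, p[[name]]$be)
    if (need_cache)
      cache$pre[[name]] <<- list(x = x, z = z, y = nr$y, mu = nr$mu, istd = nr$istd)
    nr$y
  }
  h <- x
  for (i in seq_len(cfg$depth)) {
    h <- conv(paste0("enc", i, "a"), h)
    h <- conv(paste0("enc", i, "b"), h)
    cache$skips[[i]] <- h
    pl <- .cpp_maxpool_forward(h)
    if (need_cache) cache$pool[[i]] <- pl$idx
    h <- pl$y
  }
  h <- conv("bot_a", h)
  h <- conv("bot_b", h)
  if (cfg$nonlocal_enabled) {
    nl <- nonlocal_fwd_cache(h, p$nonlocal, cfg$nonlocal_variant)
    if (need_cache) cache$nl <- nl$cache
    h <- nl$y
  }
  upconv <- function(name, x) {
    z <- .cpp_upconv2_forward(x, p[[name]]$w, p[[name]]$b, FALSE)
    nr <- .cpp_in_forward(z, p[[name]]$g, p[[name]]$be)
    if (need_cache)
      cache$pre[[name]] <<- list(x = x, z = z, y = nr$y, mu = nr$mu, istd = nr$istd)
    nr$y
  }
  for (i in rev(seq_len(cfg$depth))) {
    h <- upconv(paste0("up", i), h)
    h <- cat_ch(h, cache$skips[[i]])
    h <- conv(paste0("dec", i, "a"), h)
    h <- conv(paste0("dec", i, "b"), h)
  }
  if (need_cache) cache$head_in <- h
  logits <- .cpp_conv1_forward(h, p$head$w, p$head$b)
  prob <- 1 / (1 + exp(-logits))
  if (need_cache) { cache$prob <- prob; list(prob = prob, cache = cache) }
  else prob
}

# Backward pass; dlogits is dLoss/dlogits at the sigmoid head (loss gradient
# fused with the sigmoid). Returns gradients shaped like params.
unet_backward <- function(net, cache, dlogits) {
  p <- net$params; cfg <- net$cfg
  grads <- list()
  conv_bwd <- function(name, dy) {
    cc <- cache$pre[[name]]
    nb <- .cpp_in_backward(cc$z, p[[name]]$g, cc$mu, cc$istd, cc$y, dy)
    res <- .cpp_conv3_backward(cc$x, p[[name]]$w, cc$z, nb$dx, FALSE)
    grads[[name]] <<- list(w = res$dw, b = res$db, g = nb$dgamma, be = nb$dbeta)
    res$dx
  }
  res <- .cpp_conv1_backward(cache$head_in, p$head$w, dlogits)
  grads$head <- list(w = res$dw, b = res$db)
  dh <- res$dx
  dskip <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dh <- conv_bwd(paste0("dec", i, "b"), dh)
    dh <- conv_bwd(paste0("dec", i, "a"), dh)
    nch <- dim(dh)[3] / 2
    dskip[[i]] <- dh[, , nch + seq_len(nch), , drop = FALSE]
    dh <- dh[, , seq_len(nch), , drop = FALSE]
    nm <- paste0("up", i)
    cc <- cache$pre[[nm]]
    nb <- .cpp_in_backward(cc$z, p[[nm]]$g, cc$mu, cc$istd, cc$y, dh)
    res <- .cpp_upconv2_backward(cc$x, p[[nm]]$w, cc$z, nb$dx, FALSE)
    grads[[nm]] <- list(w = res$dw, b = res$db, g = nb$dgamma, be = nb$dbeta)
    dh <- res$dx
  }
  if (cfg$nonlocal_enabled) {
    nl <- nonlocal_bwd(dh, p$nonlocal, cache$nl)
    grads$nonlocal <- nl$grads
    dh <- nl$dx
  }
  dh <- conv_bwd("bot_b", dh)
  dh <- conv_bwd("bot_a", dh)
  for (i in rev(seq_len(cfg$depth))) {
    sk <- cache$skips[[i]]
    dh <- .cpp_maxpool_backward(dh, cache$pool[[i]], dim(sk)[1], dim(sk)[2])
    dh <- dh + dskip[[i]]
    dh <- conv_bwd(paste0("enc", i, "b"), dh)
    dh <- conv_bwd(paste0("enc", i, "a"), dh)
  }
  grads
}

#' Predict a 3D mask for a preprocessed volume
#'
#' Runs the network over the coronal slice stack in batches, binarizes the
#' per-pixel foreground probability at `threshold`, and reassembles a 3D mask
#' with the volume's spacing. Note the boundary convention: a pixel is
#' foreground when its probability is strictly above the threshold, so
#' `threshold = 0` marks every strictly positive probability.
#'
#' @param net A trained `unet`.
#' @param vol An [image_volume()] whose slices match the network input size.
#' @param threshold Binarization threshold in \[0,1\); default 0.5.
#' @param batch_size Slices per forward pass.
#' @return A [seg_mask()].
#' @export
predict_mask <- function(net, vol, threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(net, "unet"), inherits(vol, "image_volume"))
  d <- dim(vol$data)
  if (!all(d[1:2] == net$cfg$input_size))
    stop(sprintf("slice size %dx%d does not match network input %dx%d",
                 d[1], d[2], net$cfg$input_size[1], net$cfg$input_size[2]))
  out <- array(0, d)
  starts <- seq(1L, d[3], by = batch_size)
  for (s in starts) {
    ks <- s:min(s + batch_size - 1L, d[3])
    x <- array(vol$data[, , ks], c(d[1], d[2], 1L, length(ks)))
    prob <- unet_forward(net, x)
    out[, , ks] <- ifelse(prob[, , 1L, ] > threshold, 1, 0)
  }
  seg_mask(out, spacing = vol$spacing)
}

#' Per-slice foreground probabilities
#'
#' Like [predict_mask()] but returns the raw probability volume.
#'
#' @inheritParams predict_mask
#' @return An [image_volume()] of probabilities in \[0,1\].
#' @export
predict_probabilities <- function(net, vol, batch_size = 8L) {
  d <- dim(vol$data)
  out <- array(0, d)
  for (s in seq(1L, d[3], by = batch_size)) {
    ks <- s:min(s + batch_size - 1L, d[3])
    x <- array(vol$data[, , ks], c(d[1], d[2], 1L, length(ks)))
    out[, , ks] <- unet_forward(net, x)[, , 1L, ]
  }
  image_volume(out, spacing = vol$spacing, orientation = vol$orientation)
}
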