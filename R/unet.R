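# From-scratch 2-D U-Net: conv3x3 (im2col), batch norm, dropout, 2x2 max
# pooling, 2x2 stride-2 transposed-conv upsampling, softmax + soft-Dice loss,
# Adam training. Feature maps are arrays dim c(H, W, C, N).

#' U-Net architecture specification
#'
#' A symmetric encoder/decoder with `depth` resolution levels. Each block
#' applies conv3x3 -> batch norm -> ReLU twice, then dropout; encoder blocks
#' end in 2x2 stride-2 max pooling, decoder blocks start from a 2x2 stride-2
#' transposed convolution and the concatenated skip connection. Channels
#' double per level from `base_channels` up to `max_channels`
#' (`min(base * 2^level, max)`), and mirror back down on the expanding path.
#' Convolution kernels are He-Normal initialized. Same-padding keeps the
#' spatial shape; [conv_output_size()] documents the valid-padding
#' arithmetic for reference.
#'
#' @param depth Number of levels (default 5).
#' @param base_channels Channels at the top level (default 8).
#' @param max_channels Channel cap (default 128).
#' @param n_classes Output classes (default 3: background, cavity,
#'   myocardium).
#' @param in_channels Input image channels (default 1, grayscale).
#' @param dropout Dropout rate per block (default 0.1).
#' @param batch_norm Use batch normalization (default `TRUE`).
#' @return A `unet_spec`.
#' @export
unet_spec <- function(depth = 5L, base_channels = 8L, max_channels = 128L,
                      n_classes = 3L, in_channels = 1L, dropout = 0.1,
                      batch_norm = TRUE) {
  stopifnot(depth >= 2L, base_channels >= 1L, n_classes >= 2L,
            dropout >= 0, dropout < 1)
  channels <- pmin(base_channels * 2^(seq_len(depth) - 1L), max_channels)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 dropout = dropout, batch_norm = isTRUE(batch_norm)),
            class = "unet_spec")
}

#' Spatial size after an unpadded convolution
#'
#' An unpadded k x k convolution shrinks each dimension by k - 1 (for
#' instance 256 -> 254 with a 3x3 kernel); the network itself uses same
#' padding so shapes are preserved.
#'
#' @param size Input side length.
#' @param kernel Kernel size (default 3).
#' @param padding `"same"` or `"valid"`.
#' @return Output side length.
#' @export
conv_output_size <- function(size, kernel = 3L, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  if (padding == "same") size else size - kernel + 1L
}

he_init <- function(dim_, fan_in) {
  array(stats::rnorm(prod(dim_), 0, sqrt(2 / fan_in)), dim_)
}

#' Build (initialize) a U-Net model
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for He-Normal initialization.
#' @return A `unet_model`: `spec`, named parameter list `params`, and
#'   running batch-norm moments for inference.
#' @export
build_unet <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  ch <- spec$channels; D <- spec$depth
  params <- list()
  add_conv <- function(name, cin, cout, k = 3L) {
    params[[paste0(name, ".W")]] <<- he_init(c(k, k, cin, cout),
                                             k * k * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c_) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c_)
    params[[paste0(name, ".beta")]] <<- numeric(c_)
  }
  cin <- spec$in_channels
  for (l in seq_len(D)) {
    add_conv(sprintf("enc%d.conv1", l), cin, ch[l])
    add_bn(sprintf("enc%d.bn1", l), ch[l])
    add_conv(sprintf("enc%d.conv2", l), ch[l], ch[l])
    add_bn(sprintf("enc%d.bn2", l), ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(D - 1L))) {
    # transposed conv halves channels, then skip concat doubles them back
    params[[sprintf("dec%d.up.W", l)]] <- he_init(c(2L, 2L, ch[l + 1L], ch[l]),
                                                  4L * ch[l + 1L])
    params[[sprintf("dec%d.up.b", l)]] <- numeric(ch[l])
    add_conv(sprintf("dec%d.conv1", l), 2L * ch[l], ch[l])
    add_bn(sprintf("dec%d.bn1", l), ch[l])
    add_conv(sprintf("dec%d.conv2", l), ch[l], ch[l])
    add_bn(sprintf("dec%d.bn2", l), ch[l])
  }
  add_conv("out.conv", ch[1L], spec$n_classes, k = 1L)
  running <- list()
  for (nm in names(params)) {
    if (endsWith(nm, ".gamma")) {
      base <- sub("\\.gamma$", "", nm)
      running[[paste0(base, ".mean")]] <- numeric(length(params[[nm]]))
      running[[paste0(base, ".var")]] <- rep(1, length(params[[nm]]))
    }
  }
  structure(list(spec = spec, params = params, bn_running = running,
                 seed = as.integer(seed)),
            class = "unet_model")
}

#' Parameter count of a U-Net model
#' @param model A `unet_model`.
#' @return Integer total number of parameters.
#' @export
unet_n_params <- function(model) sum(vapply(model$params, length, integer(1)))

## ---- array <-> matrix helpers --------------------------------------------

fm_as_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

fm_from_mat <- function(m, H, W, C, N) {
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1, 2, 4, 3))
}

## ---- conv 3x3, same padding, stride 1 ------------------------------------

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  P <- array(0, c(H + 2L, W + 2L, C, N))
  P[2:(H + 1L), 2:(W + 1L), , ] <- x
  M <- matrix(0, H * W * N, 9L * C)
  k <- 0L
  for (kw in 0:2) for (kh in 0:2) {
    k <- k + 1L
    slab <- P[(1:H) + kh, (1:W) + kw, , , drop = FALSE]
    M[, ((k - 1L) * C + 1L):(k * C)] <- fm_as_mat(slab)
  }
  M
}

conv3_wmat <- function(W) {
  # (3,3,Cin,Cout) -> (9*Cin, Cout) with cin fastest, then kh, then kw,
  # matching the im2col block order (kh fastest within kw).
  d <- dim(W)
  m <- aperm(W, c(3, 1, 2, 4))
  dim(m) <- c(9L * d[3], d[4])
  m
}

conv3_fwd <- function(x, W, b, keep_cache = TRUE) {
  d <- dim(x)
  M <- im2col3(x)
  out <- row_shift(M %*% conv3_wmat(W), b)
  y <- fm_from_mat(out, d[1], d[2], dim(W)[4], d[4])
  if (keep_cache) list(y = y, M = M, dim_in = d) else list(y = y)
}

conv3_bwd <- function(dy, W, cache) {
  d_in <- cache$dim_in
  dY <- fm_as_mat(dy)
  dWmat <- crossprod(cache$M, dY)
  dW <- array(0, dim(W))
  m <- dWmat
  dim(m) <- c(dim(W)[3], 3L, 3L, dim(W)[4])
  dW[] <- aperm(m, c(2, 3, 1, 4))
  db <- colSums(dY)
  # dx = same-padding conv of dy with spatially flipped, channel-swapped W
  Wf <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dx <- conv3_fwd(dy, Wf, numeric(dim(W)[3]), keep_cache = FALSE)$y
  list(dx = dx, dW = dW, db = db)
}

## ---- conv 1x1 ------------------------------------------------------------

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  Wm <- matrix(W, d[3], dim(W)[4])
  out <- row_shift(fm_as_mat(x) %*% Wm, b)
  fm_from_mat(out, d[1], d[2], dim(W)[4], d[4])
}

conv1_bwd <- function(dy, x, W) {
  d <- dim(x)
  Wm <- matrix(W, d[3], dim(W)[4])
  dY <- fm_as_mat(dy)
  Xm <- fm_as_mat(x)
  dW <- array(crossprod(Xm, dY), dim(W))
  db <- colSums(dY)
  dx <- fm_from_mat(dY %*% t(Wm), d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

## ---- batch norm ----------------------------------------------------------

bn_fwd <- function(x, gamma, beta, training, run_mean, run_var,
                   momentum = 0.9) {
  d <- dim(x)
  Xm <- fm_as_mat(x)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm * Xm) - mu^2
    v[v < 0] <- 0
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  sd_ <- sqrt(v + BN_EPS)
  Zn <- row_scale(row_shift(Xm, -mu), 1 / sd_)
  Y <- row_shift(row_scale(Zn, gamma), beta)
  list(y = fm_from_mat(Y, d[1], d[2], d[3], d[4]),
       Zn = Zn, sd = sd_, dim = d,
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$dim
  dY <- fm_as_mat(dy)
  dgamma <- colSums(dY * cache$Zn)
  dbeta <- colSums(dY)
  dZn <- row_scale(dY, gamma)
  dX <- row_scale(row_shift(dZn, -colMeans(dZn)) -
                    row_scale(cache$Zn, colMeans(dZn * cache$Zn)),
                  1 / cache$sd)
  list(dx = fm_from_mat(dX, d[1], d[2], d[3], d[4]),
       dgamma = dgamma, dbeta = dbeta)
}

## ---- 2x2 max pooling, stride 2 -------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  s00 <- x[seq(1, H, 2), seq(1, W, 2), , , drop = FALSE]
  s10 <- x[seq(2, H, 2), seq(1, W, 2), , , drop = FALSE]
  s01 <- x[seq(1, H, 2), seq(2, W, 2), , , drop = FALSE]
  s11 <- x[seq(2, H, 2), seq(2, W, 2), , , drop = FALSE]
  y <- pmax(s00, s10, s01, s11)
  list(y = y, s = list(s00, s10, s01, s11), dim_in = d)
}

pool_bwd <- function(dy, cache) {
  d <- cache$dim_in; H <- d[1]; W <- d[2]
  g <- array(0, d)
  assigned <- array(FALSE, dim(dy))
  offs <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  y <- pmax(cache$s[[1]], cache$s[[2]], cache$s[[3]], cache$s[[4]])
  for (k in 1:4) {
    hit <- (cache$s[[k]] == y) & !assigned
    assigned <- assigned | hit
    o <- offs[[k]]
    g[seq(o[1], H, 2), seq(o[2], W, 2), , ] <- dy * hit
  }
  g
}

## ---- transposed conv 2x2, stride 2 ---------------------------------------

tconv_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(W)[4]
  Xm <- fm_as_mat(x)
  y <- array(0, c(2L * H, 2L * Wd, Cout, N))
  for (a in 1:2) for (b_ in 1:2) {
    O <- row_shift(Xm %*% W[a, b_, , ], b)
    y[seq(a, 2L * H, 2), seq(b_, 2L * Wd, 2), , ] <-
      fm_from_mat(O, H, Wd, Cout, N)
  }
  list(y = y, Xm = Xm, dim_in = d)
}

tconv_bwd <- function(dy, W, cache) {
  d <- cache$dim_in; H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(W)[4]
  dW <- array(0, dim(W))
  db <- numeric(Cout)
  dXm <- matrix(0, nrow(cache$Xm), Cin)
  for (a in 1:2) for (b_ in 1:2) {
    dyo <- dy[seq(a, 2L * H, 2), seq(b_, 2L * Wd, 2), , , drop = FALSE]
    dYm <- fm_as_mat(dyo)
    dW[a, b_, , ] <- crossprod(cache$Xm, dYm)
    db <- db + colSums(dYm)
    dXm <- dXm + dYm %*% t(W[a, b_, , ])
  }
  list(dx = fm_from_mat(dXm, H, Wd, Cin, N), dW = dW, db = db)
}

## ---- activations / dropout -----------------------------------------------

relu_fwd <- function(x) (x > 0) * x

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x))
  list(y = x * mask / (1 - rate), mask = mask)
}

softmax_channels <- function(scores) {
  d <- dim(scores)
  S <- fm_as_mat(scores)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  fm_from_mat(P, d[1], d[2], d[3], d[4])
}

## ---- forward / backward over the whole network ---------------------------

unet_forward <- function(model, x, training = FALSE) {
  spec <- model$spec; D <- spec$depth; p <- model$params
  run <- model$bn_running
  cache <- list(blocks = list())
  a <- x
  skips <- list()
  block_fwd <- function(prefix, a, cache_blocks) {
    cb <- list(a_in = a)
    c1 <- conv3_fwd(a, p[[paste0(prefix, ".conv1.W")]],
                    p[[paste0(prefix, ".conv1.b")]], keep_cache = training)
    h <- c1$y
    if (spec$batch_norm) {
      bn1 <- bn_fwd(h, p[[paste0(prefix, ".bn1.gamma")]],
                    p[[paste0(prefix, ".bn1.beta")]], training,
                    run[[paste0(prefix, ".bn1.mean")]],
                    run[[paste0(prefix, ".bn1.var")]])
      run[[paste0(prefix, ".bn1.mean")]] <<- bn1$run_mean
      run[[paste0(prefix, ".bn1.var")]] <<- bn1$run_var
      h <- bn1$y
    } else bn1 <- NULL
    r1 <- relu_fwd(h)
    c2 <- conv3_fwd(r1, p[[paste0(prefix, ".conv2.W")]],
                    p[[paste0(prefix, ".conv2.b")]], keep_cache = training)
    h2 <- c2$y
    if (spec$batch_norm) {
      bn2 <- bn_fwd(h2, p[[paste0(prefix, ".bn2.gamma")]],
                    p[[paste0(prefix, ".bn2.beta")]], training,
                    run[[paste0(prefix, ".bn2.mean")]],
                    run[[paste0(prefix, ".bn2.var")]])
      run[[paste0(prefix, ".bn2.mean")]] <<- bn2$run_mean
      run[[paste0(prefix, ".bn2.var")]] <<- bn2$run_var
      h2 <- bn2$y
    } else bn2 <- NULL
    r2 <- relu_fwd(h2)
    dr <- dropout_fwd(r2, spec$dropout, training)
    cb$c1 <- c1; cb$bn1 <- bn1; cb$relu1_in <- if (spec$batch_norm) bn1$y else c1$y
    cb$r1 <- r1
    cb$c2 <- c2; cb$bn2 <- bn2; cb$relu2_in <- if (spec$batch_norm) bn2$y else c2$y
    cb$drop_mask <- dr$mask
    list(y = dr$y, cb = cb)
  }

  for (l in seq_len(D)) {
    bf <- block_fwd(sprintf("enc%d", l), a, cache$blocks)
    cache$blocks[[sprintf("enc%d", l)]] <- bf$cb
    if (l < D) {
      skips[[l]] <- bf$y
      pf <- pool_fwd(bf$y)
      cache$blocks[[sprintf("pool%d", l)]] <- pf
      a <- pf$y
    } else a <- bf$y
  }
  for (l in rev(seq_len(D - 1L))) {
    tf <- tconv_fwd(a, p[[sprintf("dec%d.up.W", l)]],
                    p[[sprintf("dec%d.up.b", l)]])
    cache$blocks[[sprintf("up%d", l)]] <- tf
    up <- tf$y
    d_up <- dim(up)
    merged <- array(0, c(d_up[1], d_up[2], 2L * d_up[3], d_up[4]))
    merged[, , seq_len(d_up[3]), ] <- skips[[l]]
    merged[, , d_up[3] + seq_len(d_up[3]), ] <- up
    bf <- block_fwd(sprintf("dec%d", l), merged, cache$blocks)
    cache$blocks[[sprintf("dec%d", l)]] <- bf$cb
    a <- bf$y
  }
  scores <- conv1_fwd(a, p[["out.conv.W"]], p[["out.conv.b"]])
  cache$out_in <- a
  probs <- softmax_channels(scores)
  model$bn_running <- run
  list(probs = probs, scores = scores, cache = cache, model = model,
       skip_dims = lapply(skips, dim))
}

# Soft Dice loss over foreground classes (labels 1..K-1), plus the gradient
# with respect to the class probabilities.
dice_loss_grad <- function(probs, onehot) {
  K <- dim(probs)[3]
  fg <- 2:K
  loss <- 0
  dprobs <- array(0, dim(probs))
  for (k in fg) {
    pk <- probs[, , k, , drop = FALSE]
    gk <- onehot[, , k, , drop = FALSE]
    I <- sum(pk * gk)
    S <- sum(pk) + sum(gk)
    dice_k <- if (S == 0) 1 else 2 * I / S
    loss <- loss + (1 - dice_k)
    if (S > 0)
      dprobs[, , k, ] <- -(2 * gk * S - 2 * I) / S^2
  }
  nf <- length(fg)
  list(loss = loss / nf, dprobs = dprobs / nf)
}

#' Soft Dice loss of class probabilities against an integer mask
#'
#' `1 - mean over foreground classes of (2 sum(p g) / (sum p + sum g))`;
#' a class absent from both prediction and reference contributes Dice 1.
#'
#' @param probs Array `(H, W, n_classes, N)` of class probabilities.
#' @param true_mask Integer mask array `(H, W, N)` or matrix with labels
#'   `0 .. n_classes-1`.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, true_mask) {
  if (length(dim(true_mask)) == 2L)
    dim(true_mask) <- c(dim(true_mask), 1L)
  if (!all(dim(probs)[c(1, 2, 4)] == dim(true_mask))) stop("shape mismatch")
  onehot <- masks_to_onehot(true_mask, dim(probs)[3])
  dice_loss_grad(probs, onehot)$loss
}

masks_to_onehot <- function(masks, K) {
  d <- dim(masks)
  oh <- array(0, c(d[1], d[2], K, d[3]))
  for (k in seq_len(K)) oh[, , k, ] <- (masks == (k - 1L)) * 1
  oh
}

unet_backward <- function(fwd, onehot) {
  model <- fwd$model; spec <- model$spec; D <- spec$depth
  p <- model$params
  lg <- dice_loss_grad(fwd$probs, onehot)
  # softmax backward
  dP <- fm_as_mat(lg$dprobs)
  P <- fm_as_mat(fwd$probs)
  dS <- P * (dP - rowSums(dP * P))
  d_sc <- dim(fwd$scores)
  dscores <- fm_from_mat(dS, d_sc[1], d_sc[2], d_sc[3], d_sc[4])

  grads <- list()
  ob <- conv1_bwd(dscores, fwd$cache$out_in, p[["out.conv.W"]])
  grads[["out.conv.W"]] <- ob$dW
  grads[["out.conv.b"]] <- ob$db
  da <- ob$dx

  block_bwd <- function(prefix, da) {
    cb <- fwd$cache$blocks[[prefix]]
    if (!is.null(cb$drop_mask))
      da <- da * cb$drop_mask / (1 - spec$dropout)
    da <- da * (cb$relu2_in > 0)
    if (spec$batch_norm) {
      bb <- bn_bwd(da, p[[paste0(prefix, ".bn2.gamma")]], cb$bn2)
      grads[[paste0(prefix, ".bn2.gamma")]] <<- bb$dgamma
      grads[[paste0(prefix, ".bn2.beta")]] <<- bb$dbeta
      da <- bb$dx
    }
    c2b <- conv3_bwd(da, p[[paste0(prefix, ".conv2.W")]], cb$c2)
    grads[[paste0(prefix, ".conv2.W")]] <<- c2b$dW
    grads[[paste0(prefix, ".conv2.b")]] <<- c2b$db
    da <- c2b$dx
    da <- da * (cb$relu1_in > 0)
    if (spec$batch_norm) {
      bb <- bn_bwd(da, p[[paste0(prefix, ".bn1.gamma")]], cb$bn1)
      grads[[paste0(prefix, ".bn1.gamma")]] <<- bb$dgamma
      grads[[paste0(prefix, ".bn1.beta")]] <<- bb$dbeta
      da <- bb$dx
    }
    c1b <- conv3_bwd(da, p[[paste0(prefix, ".conv1.W")]], cb$c1)
    grads[[paste0(prefix, ".conv1.W")]] <<- c1b$dW
    grads[[paste0(prefix, ".conv1.b")]] <<- c1b$db
    c1b$dx
  }

  dskips <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {
    da <- block_bwd(sprintf("dec%d", l), da)
    # split concat gradient: first half -> skip, second half -> upsample
    C <- dim(da)[3] / 2L
    dskips[[l]] <- da[, , seq_len(C), , drop = FALSE]
    dup <- da[, , C + seq_len(C), , drop = FALSE]
    tb <- tconv_bwd(dup, p[[sprintf("dec%d.up.W", l)]],
                    fwd$cache$blocks[[sprintf("up%d", l)]])
    grads[[sprintf("dec%d.up.W", l)]] <- tb$dW
    grads[[sprintf("dec%d.up.b", l)]] <- tb$db
    da <- tb$dx
  }
  for (l in rev(seq_len(D))) {
    if (l < D) {
      da <- pool_bwd(da, fwd$cache$blocks[[sprintf("pool%d", l)]])
      da <- da + dskips[[l]]
    }
    da <- block_bwd(sprintf("enc%d", l), da)
  }
  list(loss = lg$loss, grads = grads)
}

## ---- training ------------------------------------------------------------

pairs_to_batch <- function(pairs, idx = seq_along(pairs)) {
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  x <- array(0, c(H, W, 1L, length(idx)))
  m <- array(0L, c(H, W, length(idx)))
  for (i in seq_along(idx)) {
    x[, , 1L, i] <- pairs[[idx[i]]]$image
    m[, , i] <- pairs[[idx[i]]]$mask
  }
  list(x = x, mask = m)
}

#' Train a U-Net on image/mask pairs with Dice loss and Adam
#'
#' @param spec A [unet_spec()] (or an already built `unet_model` to resume).
#' @param pairs List of at least 8 image/mask pairs (`phantom_pair`s or
#'   equivalent); image sides must be divisible by `2^(depth-1)`.
#' @param epochs Training epochs (default 20).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 8).
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param augment Apply random flips/rotations each epoch (default `FALSE`).
#' @return A trained `unet_model` with `loss_history` (mean Dice loss per
#'   epoch).
#' @export
train_unet <- function(spec, pairs, epochs = 20L, lr = 1e-3, batch_size = 8L,
                       seed = 1L, augment = FALSE) {
  if (length(pairs) < 8L) stop("need at least 8 training pairs")
  side <- dim(pairs[[1]]$image)
  div <- 2L^(spec$depth - 1L)
  if (any(side %% div != 0))
    stop("image size must be divisible by ", div)
  model <- if (inherits(spec, "unet_model")) spec else build_unet(spec, seed)
  spec <- model$spec
  set.seed(as.integer(seed))
  adam_m <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  adam_v <- adam_m
  t <- 0
  n <- length(pairs)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    use <- if (augment) augment_images(pairs, seed = seed * 1000L + ep)
           else pairs
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      batch <- pairs_to_batch(use, idx)
      fwd <- unet_forward(model, batch$x, training = TRUE)
      model$bn_running <- fwd$model$bn_running
      onehot <- masks_to_onehot(batch$mask, spec$n_classes)
      bw <- unet_backward(fwd, onehot)
      if (!is.finite(bw$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      losses <- c(losses, bw$loss)
      t <- t + 1
      for (nm in names(model$params)) {
        g <- bw$grads[[nm]]
        adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * g
        adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * g^2
        model$params[[nm]] <- model$params[[nm]] -
          lr * (adam_m[[nm]] / (1 - 0.9^t)) /
            (sqrt(adam_v[[nm]] / (1 - 0.999^t)) + 1e-8)
      }
    }
    history[ep] <- mean(losses)
  }
  model$loss_history <- history
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a segmentation mask
#'
#' Runs the network in inference mode (dropout off, running batch-norm
#' moments) and takes the per-pixel argmax over class scores.
#'
#' @param model A trained `unet_model`.
#' @param image 2-D matrix, or array `(H, W, N)` of images.
#' @return Integer mask with labels `0 .. n_classes-1`, same spatial shape.
#' @export
predict_mask <- function(model, image) {
  single <- is.matrix(image)
  if (single) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  x <- array(image, c(d[1], d[2], 1L, d[3]))
  fwd <- unet_forward(model, x, training = FALSE)
  P <- fwd$probs
  out <- array(0L, c(d[1], d[2], d[3]))
  for (i in seq_len(d[3]))
    out[, , i] <- apply(P[, , , i, drop = FALSE][, , , 1], c(1, 2),
                        which.max) - 1L
  if (single) out[, , 1] else out
}

#' Mean Dice over foreground classes of predicted vs reference masks
#'
#' @param model A trained `unet_model`.
#' @param pairs List of image/mask pairs.
#' @return Data frame with per-pair, per-class Dice and IoU plus the mean
#'   foreground Dice as attribute `mean_dice`.
#' @export
evaluate_unet <- function(model, pairs) {
  K <- model$spec$n_classes
  rows <- list()
  for (i in seq_along(pairs)) {
    pred <- predict_mask(model, pairs[[i]]$image)
    for (k in seq_len(K - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = i, class = k,
        dice = dice_score(pred, pairs[[i]]$mask, k),
        iou = iou(pred, pairs[[i]]$mask, k))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_dice") <- mean(out$dice)
  out
}

## ---- ROI cropping --------------------------------------------------------

#' Crop an image to the region of interest of a reference mask
#'
#' Takes the tight bounding box of the mask foreground, expands it by
#' `margin` pixels, clips it to the image, then grows it (inside the image
#' where possible, by zero padding otherwise) until both sides are divisible
#' by `divisor`. The returned box supports lossless paste-back of
#' predictions via [roi_paste()].
#'
#' @param image 2-D matrix.
#' @param reference_mask Integer mask; foreground is every nonzero pixel.
#' @param margin Margin in pixels (default 8).
#' @param divisor Required side divisibility (default 1 = none; use
#'   `2^(depth-1)` for a U-Net input).
#' @return List with `image` (cropped, possibly zero-padded) and `box` (a
#'   `roi_box`: inclusive row/col bounds in the original image plus padding
#'   amounts).
#' @export
roi_crop <- function(image, reference_mask, margin = 8L, divisor = 1L) {
  fg <- which(reference_mask != 0, arr.ind = TRUE)
  if (!nrow(fg)) stop("reference mask is empty")
  r <- range(fg[, 1]); c_ <- range(fg[, 2])
  r0 <- max(1L, r[1] - margin); r1 <- min(nrow(image), r[2] + margin)
  c0 <- max(1L, c_[1] - margin); c1 <- min(ncol(image), c_[2] + margin)
  grow <- function(lo, hi, size, limit) {
    # grow the interval inside [1, limit] until its length is a multiple of
    # `size`; report leftover padding if the image is too small
    len <- hi - lo + 1L
    need <- (size - len %% size) %% size
    while (need > 0L && (lo > 1L || hi < limit)) {
      if (lo > 1L) { lo <- lo - 1L; need <- need - 1L }
      else { hi <- hi + 1L; need <- need - 1L }
    }
    c(lo, hi, need)
  }
  gr <- grow(r0, r1, divisor, nrow(image))
  gc_ <- grow(c0, c1, divisor, ncol(image))
  crop <- image[gr[1]:gr[2], gc_[1]:gc_[2], drop = FALSE]
  if (gr[3] > 0L || gc_[3] > 0L) {
    padded <- matrix(0, nrow(crop) + gr[3], ncol(crop) + gc_[3])
    padded[seq_len(nrow(crop)), seq_len(ncol(crop))] <- crop
    crop <- padded
  }
  box <- structure(list(rows = as.integer(gr[1:2]),
                        cols = as.integer(gc_[1:2]),
                        pad = as.integer(c(gr[3], gc_[3])), margin = margin,
                        full_dim = dim(image)),
                   class = "roi_box")
  list(image = crop, box = box)
}

#' Paste a cropped prediction back into full-image coordinates
#'
#' @param crop Matrix in crop coordinates (e.g. a predicted mask).
#' @param box The `roi_box` from [roi_crop()].
#' @param fill Background value outside the box (default 0).
#' @return Matrix with the original image dimensions.
#' @export
roi_paste <- function(crop, box, fill = 0L) {
  out <- matrix(fill, box$full_dim[1], box$full_dim[2])
  nr <- box$rows[2] - box$rows[1] + 1L
  nc <- box$cols[2] - box$cols[1] + 1L
  out[box$rows[1]:box$rows[2], box$cols[1]:box$cols[2]] <-
    crop[seq_len(nr), seq_len(nc)]
  out
}
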