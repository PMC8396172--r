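#' Specification of the volumetric V-Net detector
#'
#' Describes the encoder/decoder network: `n_stages` resolution stages of
#' cubic 5x5x5 convolutions with a residual connection around each stage's
#' convolution block, 2x2x2 stride-2 down-convolutions between encoder
#' stages, 2x2x2 stride-2 transposed convolutions in the decoder, skip
#' connections that concatenate each encoder stage's features into the
#' matching decoder stage, batch normalization and PReLU after every
#' convolution, dropout after every activation, and a final 1x1x1
#' convolution to a single sigmoid channel.
#'
#' The full-scale configuration (5 stages, channels 8-128, 96^3 patches)
#' mirrors the full-scale V-Net design; compact configurations (2-3 stages,
#' small channel counts) train on a desk CPU.
#'
#' @param n_stages number of resolution stages (>= 1).
#' @param channels integer vector of feature channels per stage (length
#'   `n_stages`).
#' @param convs_per_stage convolutions in each stage's block (recycled).
#' @param kernel cubic convolution kernel size (default 5).
#' @param down_kernel down/up-sampling kernel (applied with stride =
#'   `down_kernel`).
#' @param dropout_rate dropout probability after each activation.
#' @return an object of class `vnet_spec`.
#' @export
vnet_spec <- function(n_stages = 5, channels = c(8, 16, 32, 64, 128),
                      convs_per_stage = c(1, 2, 3, 3, 3), kernel = 5,
                      down_kernel = 2, dropout_rate = 0.01) {
  stopifnot(n_stages >= 1, length(channels) >= n_stages)
  channels <- as.integer(channels[seq_len(n_stages)])
  convs_per_stage <- as.integer(rep_len(convs_per_stage, n_stages))
  structure(list(n_stages = n_stages, channels = channels,
                 convs_per_stage = convs_per_stage, kernel = as.integer(kernel),
                 down_kernel = as.integer(down_kernel),
                 dropout_rate = dropout_rate),
            class = "vnet_spec")
}

#' Check that a patch size is admissible for a network spec
#' @param spec a `vnet_spec`.
#' @param patch cubic patch edge length.
#' @return `TRUE` invisibly, or an error.
#' @export
check_patch_size <- function(spec, patch) {
  div <- spec$down_kernel^(spec$n_stages - 1)
  if (patch %% div != 0)
    stop("patch size ", patch, " not divisible by ", div,
         " (down-sampling across ", spec$n_stages, " stages)")
  invisible(TRUE)
}

# ---- parameter construction -------------------------------------------------

init_conv_unit <- function(params, buffers, nm, cin, cout, k) {
  fan_in <- k^3 * cin
  params[[paste0(nm, ".w")]] <- array(rnorm(k^3 * cin * cout, 0,
                                            sqrt(2 / fan_in)),
                                      c(k, k, k, cin, cout))
  params[[paste0(nm, ".b")]] <- numeric(cout)
  params[[paste0(nm, ".bn_g")]] <- rep(1, cout)
  params[[paste0(nm, ".bn_b")]] <- numeric(cout)
  params[[paste0(nm, ".alpha")]] <- rep(0.25, cout)
  buffers[[paste0(nm, ".bn_m")]] <- numeric(cout)
  buffers[[paste0(nm, ".bn_v")]] <- rep(1, cout)
  list(params = params, buffers = buffers)
}

# transposed conv weights are (k,k,k,cout,cin)
init_convt_unit <- function(params, buffers, nm, cin, cout, k) {
  fan_in <- k^3 * cin
  params[[paste0(nm, ".w")]] <- array(rnorm(k^3 * cout * cin, 0,
                                            sqrt(2 / fan_in)),
                                      c(k, k, k, cout, cin))
  params[[paste0(nm, ".b")]] <- numeric(cout)
  params[[paste0(nm, ".bn_g")]] <- rep(1, cout)
  params[[paste0(nm, ".bn_b")]] <- numeric(cout)
  params[[paste0(nm, ".alpha")]] <- rep(0.25, cout)
  buffers[[paste0(nm, ".bn_m")]] <- numeric(cout)
  buffers[[paste0(nm, ".bn_v")]] <- rep(1, cout)
  list(params = params, buffers = buffers)
}

#' Build a V-Net model
#'
#' Instantiates the network of a [vnet_spec()] with randomly initialized
#' weights (He initialization; PReLU slopes at 0.25) and reports the exact
#' trainable parameter count.
#'
#' @param spec a `vnet_spec`.
#' @param seed optional RNG seed for the initialization.
#' @return an object of class `vnet`: list with `spec`, `params` (flat named
#'   list of trainable arrays), `buffers` (batch-norm running statistics)
#'   and `n_parameters`.
#' @export
build_vnet <- function(spec = vnet_spec(), seed = NULL) {
  with_seed(seed, {
    S <- spec$n_stages
    C <- spec$channels
    k <- spec$kernel
    dk <- spec$down_kernel
    params <- list()
    buffers <- list()
    upd <- function(res) { params <<- res$params; buffers <<- res$buffers }
    upd(init_conv_unit(params, buffers, "in", 1, C[1], k))
    for (s in seq_len(S)) {
      for (j in seq_len(spec$convs_per_stage[s]))
        upd(init_conv_unit(params, buffers, sprintf("enc%d.conv%d", s, j),
                           C[s], C[s], k))
      if (s < S)
        upd(init_conv_unit(params, buffers, sprintf("down%d", s),
                           C[s], C[s + 1], dk))
    }
    for (s in rev(seq_len(S - 1))) {
      upd(init_convt_unit(params, buffers, sprintf("up%d", s),
                          C[s + 1], C[s], dk))
      upd(init_conv_unit(params, buffers, sprintf("dec%d.conv1", s),
                         2 * C[s], C[s], k))
      if (spec$convs_per_stage[s] > 1)
        for (j in 2:spec$convs_per_stage[s])
          upd(init_conv_unit(params, buffers, sprintf("dec%d.conv%d", s, j),
                             C[s], C[s], k))
    }
    params[["out.w"]] <- array(rnorm(C[1], 0, sqrt(2 / C[1])),
                               c(1, 1, 1, C[1], 1))
    params[["out.b"]] <- 0
    n_par <- sum(vapply(params, length, numeric(1)))
    structure(list(spec = spec, params = params, buffers = buffers,
                   n_parameters = n_par),
              class = "vnet")
  })
}

#' @export
print.vnet <- function(x, ...) {
  cat(sprintf("<vnet> %d stages, channels %s, %s trainable parameters\n",
              x$spec$n_stages, paste(x$spec$channels, collapse = "-"),
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# ---- elementary layers ------------------------------------------------------

# broadcast a per-channel vector over an (x,y,z,c,n) array
bc_channel <- function(v, d) {
  sp <- prod(d[1:3])
  rep(rep(v, each = sp), d[5])
}

bn_fwd <- function(x, g, b, m_run, v_run, training, momentum = 0.9,
                   eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  if (training) {
    sp <- prod(d[1:3])
    n_per <- sp * d[5]
    mm <- matrix(x, nrow = sp)
    cs <- colSums(mm)
    mu <- rowSums(matrix(cs, nrow = C)) / n_per
    cs2 <- colSums(mm^2)
    ex2 <- rowSums(matrix(cs2, nrow = C)) / n_per
    va <- pmax(ex2 - mu^2, 0)
    m_new <- momentum * m_run + (1 - momentum) * mu
    v_new <- momentum * v_run + (1 - momentum) * va
  } else {
    mu <- m_run; va <- v_run; m_new <- m_run; v_new <- v_run
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (x - bc_channel(mu, d)) * bc_channel(inv_sd, d)
  y <- xhat * bc_channel(g, d) + bc_channel(b, d)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, g = g, d = d),
       m_run = m_new, v_run = v_new)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[4]
  sp <- prod(d[1:3])
  n_per <- sp * d[5]
  xhat <- cache$xhat
  sum_c <- function(a) rowSums(matrix(colSums(matrix(a, nrow = sp)), nrow = C))
  dg <- sum_c(dy * xhat)
  db <- sum_c(dy)
  gi <- cache$g * cache$inv_sd
  dx <- (dy - bc_channel(db / n_per, d) - xhat * bc_channel(dg / n_per, d)) *
    bc_channel(gi, d)
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

prelu_fwd <- function(x, alpha) {
  d <- dim(x)
  a <- bc_channel(alpha, d)
  neg <- x < 0
  y <- ifelse(neg, a * x, x)
  dim(y) <- d
  list(y = y, cache = list(x = x, neg = neg, d = d))
}

prelu_bwd <- function(dy, cache, alpha) {
  d <- cache$d
  C <- d[4]
  sp <- prod(d[1:3])
  a <- bc_channel(alpha, d)
  dx <- dy * ifelse(cache$neg, a, 1)
  dim(dx) <- d
  grad_a_full <- dy * ifelse(cache$neg, cache$x, 0)
  dalpha <- rowSums(matrix(colSums(matrix(grad_a_full, nrow = sp)), nrow = C))
  list(dx = dx, dalpha = dalpha)
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  y <- x * keep
  dim(y) <- dim(x)
  list(y = y, mask = keep)
}

# ---- composite conv -> BN -> PReLU -> dropout units -------------------------

cbp_fwd <- function(net, nm, x, stride, pad, training, transposed = FALSE,
                    update_buffers = NULL) {
  p <- net$params
  b <- net$buffers
  if (transposed) {
    z <- cpp_convt3d_fwd(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                         stride)
  } else {
    z <- cpp_conv3d_fwd(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                        stride, pad)
  }
  bn <- bn_fwd(z, p[[paste0(nm, ".bn_g")]], p[[paste0(nm, ".bn_b")]],
               b[[paste0(nm, ".bn_m")]], b[[paste0(nm, ".bn_v")]], training)
  if (training && !is.null(update_buffers)) {
    update_buffers[[paste0(nm, ".bn_m")]] <- bn$m_run
    update_buffers[[paste0(nm, ".bn_v")]] <- bn$v_run
  }
  act <- prelu_fwd(bn$y, p[[paste0(nm, ".alpha")]])
  dr <- dropout_fwd(act$y, net$spec$dropout_rate, training)
  list(y = dr$y,
       cache = list(x = x, in_dim = dim(x), bn = bn$cache, act = act$cache,
                    drop_mask = dr$mask, stride = stride, pad = pad,
                    transposed = transposed, nm = nm))
}

cbp_bwd <- function(net, cache, dy, grads) {
  nm <- cache$nm
  p <- net$params
  if (!is.null(cache$drop_mask)) {
    dy <- dy * cache$drop_mask
    dim(dy) <- dim(cache$act$x)
  }
  pa <- prelu_bwd(dy, cache$act, p[[paste0(nm, ".alpha")]])
  grads[[paste0(nm, ".alpha")]] <- grads[[paste0(nm, ".alpha")]] %||% 0 +
    pa$dalpha
  bb <- bn_bwd(pa$dx, cache$bn)
  grads[[paste0(nm, ".bn_g")]] <- (grads[[paste0(nm, ".bn_g")]] %||% 0) + bb$dg
  grads[[paste0(nm, ".bn_b")]] <- (grads[[paste0(nm, ".bn_b")]] %||% 0) + bb$db
  if (cache$transposed) {
    res <- cpp_convt3d_bwd(cache$x, bb$dx, p[[paste0(nm, ".w")]], cache$stride)
    dx <- res$dx
    grads[[paste0(nm, ".w")]] <- (grads[[paste0(nm, ".w")]] %||% 0) + res$dw
    grads[[paste0(nm, ".b")]] <- (grads[[paste0(nm, ".b")]] %||% 0) + res$db
  } else {
    k <- dim(p[[paste0(nm, ".w")]])[1]
    dx <- cpp_conv3d_bwd_data(bb$dx, p[[paste0(nm, ".w")]], cache$stride,
                              cache$pad, cache$in_dim)
    res <- cpp_conv3d_bwd_w(cache$x, bb$dx, k, cache$stride, cache$pad)
    grads[[paste0(nm, ".w")]] <- (grads[[paste0(nm, ".w")]] %||% 0) + res$dw
    grads[[paste0(nm, ".b")]] <- (grads[[paste0(nm, ".b")]] %||% 0) + res$db
  }
  list(dx = dx, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# ---- full network forward / backward ---------------------------------------

#' Forward pass of a V-Net
#'
#' @param net a `vnet`.
#' @param x input array `(x, y, z, 1, batch)` of normalized intensities.
#' @param training use batch statistics, dropout and cache activations.
#' @return list with `prob` (sigmoid output, same spatial shape as input,
#'   one channel) and, when `training`, a `cache` for [vnet_backward()] and
#'   updated `buffers`.
#' @export
vnet_forward <- function(net, x, training = FALSE) {
  spec <- net$spec
  S <- spec$n_stages
  k <- spec$kernel
  pad <- (k - 1) %/% 2
  dk <- spec$down_kernel
  upd_buf <- if (training) new.env() else NULL
  caches <- list()
  fwd <- function(nm, x, stride = 1, p = pad, transposed = FALSE) {
    r <- cbp_fwd(net, nm, x, stride, p, training, transposed, upd_buf)
    caches[[nm]] <<- r$cache
    r$y
  }
  h <- fwd("in", x)
  enc <- vector("list", S)
  for (s in seq_len(S)) {
    r <- h
    for (j in seq_len(spec$convs_per_stage[s]))
      h <- fwd(sprintf("enc%d.conv%d", s, j), h)
    h <- h + r
    enc[[s]] <- h
    if (s < S) h <- fwd(sprintf("down%d", s), h, stride = dk, p = 0)
  }
  g <- h
  for (s in rev(seq_len(S - 1))) {
    u <- fwd(sprintf("up%d", s), g, stride = dk, p = 0, transposed = TRUE)
    h <- concat_channels(u, enc[[s]])
    h <- fwd(sprintf("dec%d.conv1", s), h)
    if (spec$convs_per_stage[s] > 1)
      for (j in 2:spec$convs_per_stage[s])
        h <- fwd(sprintf("dec%d.conv%d", s, j), h)
    g <- h + u
  }
  logits <- cpp_conv3d_fwd(g, net$params[["out.w"]], net$params[["out.b"]],
                           1L, 0L)
  prob <- 1 / (1 + exp(-logits))
  dim(prob) <- dim(logits)
  out <- list(prob = prob)
  if (training) {
    out$cache <- list(caches = caches, enc = enc, final_in = g, logits = logits,
                      x_dim = dim(x))
    out$buffers <- as.list(upd_buf)
  }
  out
}

#' Backward pass of a V-Net
#'
#' @param net a `vnet`.
#' @param fwd result of `vnet_forward(..., training = TRUE)`.
#' @param dprob gradient of the loss w.r.t. the probability output.
#' @return flat named list of parameter gradients.
#' @export
vnet_backward <- function(net, fwd, dprob) {
  spec <- net$spec
  S <- spec$n_stages
  dk <- spec$down_kernel
  caches <- fwd$cache$caches
  grads <- list()
  prob <- fwd$prob
  dlogits <- dprob * prob * (1 - prob)
  dim(dlogits) <- dim(prob)
  # final 1x1x1 conv
  k1 <- 1L
  dg <- cpp_conv3d_bwd_data(dlogits, net$params[["out.w"]], 1L, 0L,
                            dim(fwd$cache$final_in))
  rw <- cpp_conv3d_bwd_w(fwd$cache$final_in, dlogits, k1, 1L, 0L)
  grads[["out.w"]] <- rw$dw
  grads[["out.b"]] <- rw$db
  bwd <- function(nm, dy) {
    r <- cbp_bwd(net, caches[[nm]], dy, grads)
    grads <<- r$grads
    r$dx
  }
  denc <- vector("list", S)  # accumulated gradient w.r.t. enc[[s]]
  for (s in seq_len(S)) denc[[s]] <- 0
  dgout <- dg
  for (s in seq_len(S - 1)) {
    # decoder stage s (processed in reverse order of the forward loop:
    # forward went S-1 .. 1, so backward visits 1 .. S-1)
    du_res <- dgout               # residual branch into u
    dh <- dgout                   # block output branch
    if (spec$convs_per_stage[s] > 1)
      for (j in rev(2:spec$convs_per_stage[s]))
        dh <- bwd(sprintf("dec%d.conv%d", s, j), dh)
    dcat <- bwd(sprintf("dec%d.conv1", s), dh)
    Cs <- spec$channels[s]
    du <- dcat[, , , seq_len(Cs), , drop = FALSE] + du_res
    dskip <- dcat[, , , Cs + seq_len(Cs), , drop = FALSE]
    denc[[s]] <- denc[[s]] + dskip
    dgout <- bwd(sprintf("up%d", s), du)
  }
  # dgout now carries the gradient w.r.t. the bottom stage output e_S
  dh <- dgout + denc[[S]]
  for (s in rev(seq_len(S))) {
    if (s < S) dh <- dh + denc[[s]]
    dres <- dh
    for (j in rev(seq_len(spec$convs_per_stage[s])))
      dh <- bwd(sprintf("enc%d.conv%d", s, j), dh)
    dh <- dh + dres
    if (s > 1) dh <- bwd(sprintf("down%d", s - 1), dh)
  }
  dx_in <- bwd("in", dh)
  grads$.dx <- dx_in
  grads
}
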