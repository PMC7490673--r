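# Bidirectional GRU sequence-to-sequence reconstruction model.
# The encoder runs a forward and a backward GRU over a 24-hour window of
# standardized hourly vectors; the concatenated final states emit a
# next-step prediction and the decoder's initial hidden state. A
# unidirectional GRU decoder, fed the next-step prediction as its first
# input and then its own outputs autoregressively, reconstructs the
# window in reverse order. Training applies input dropout (fresh mask
# per timestep) and recurrent dropout (one mask per sequence per layer),
# both rate 0.2; inference is deterministic.
#
# Gradients are computed by full backpropagation through time, verified
# against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

slice_t <- function(arr, t) {
  matrix(arr[, t, ], nrow = dim(arr)[1])
}

gru_param_names <- c("Uz", "Ur", "Uh", "Wz", "Wr", "Wh", "bz", "br", "bh")

gru_init_layer <- function(m_in, H) {
  list(Uz = glorot(m_in, H), Ur = glorot(m_in, H), Uh = glorot(m_in, H),
       Wz = glorot(H, H), Wr = glorot(H, H), Wh = glorot(H, H),
       bz = rep(0, H), br = rep(0, H), bh = rep(0, H))
}

gru_init_params <- function(m, H) {
  p <- list()
  for (pref in c("ef", "eb", "d")) {
    lay <- gru_init_layer(m, H)
    names(lay) <- paste0(pref, "_", names(lay))
    p <- c(p, lay)
  }
  p$Wp <- glorot(2 * H, m)
  p$bp <- rep(0, m)
  p$Ws <- glorot(2 * H, H)
  p$bs <- rep(0, H)
  p$Wo <- glorot(H, m)
  p$bo <- rep(0, m)
  p
}

layer_params <- function(params, pref) {
  out <- params[paste0(pref, "_", gru_param_names)]
  names(out) <- gru_param_names
  out
}

# One GRU cell step. `rmask` is the recurrent-dropout mask applied to
# the previous state as seen by the gates (the carried state itself is
# not masked).
gru_step <- function(p, x, h, rmask = NULL) {
  hm <- if (is.null(rmask)) h else h * rmask
  z <- sigmoid(sweep(x %*% p$Uz + hm %*% p$Wz, 2, p$bz, "+"))
  r <- sigmoid(sweep(x %*% p$Ur + hm %*% p$Wr, 2, p$br, "+"))
  hh <- tanh(sweep(x %*% p$Uh + (r * hm) %*% p$Wh, 2, p$bh, "+"))
  h2 <- z * h + (1 - z) * hh
  list(h = h2, cache = list(x = x, h_prev = h, hm = hm, z = z, r = r,
                            hh = hh, rmask = rmask))
}

# Backward through one GRU step. Returns gradient wrt the (masked)
# input, wrt the previous state, and accumulates parameter gradients.
gru_step_backward <- function(p, g, cache, dh2) {
  dz <- dh2 * (cache$h_prev - cache$hh)
  dhh <- dh2 * (1 - cache$z)
  dh <- dh2 * cache$z
  dhh_pre <- dhh * (1 - cache$hh^2)
  dx <- dhh_pre %*% t(p$Uh)
  d_rhm <- dhh_pre %*% t(p$Wh)
  dr <- d_rhm * cache$hm
  dhm <- d_rhm * cache$r
  dz_pre <- dz * cache$z * (1 - cache$z)
  dr_pre <- dr * cache$r * (1 - cache$r)
  dx <- dx + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
  dhm <- dhm + dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr)
  dh <- dh + if (is.null(cache$rmask)) dhm else dhm * cache$rmask
  g$Uz <- g$Uz + t(cache$x) %*% dz_pre
  g$Ur <- g$Ur + t(cache$x) %*% dr_pre
  g$Uh <- g$Uh + t(cache$x) %*% dhh_pre
  g$Wz <- g$Wz + t(cache$hm) %*% dz_pre
  g$Wr <- g$Wr + t(cache$hm) %*% dr_pre
  g$Wh <- g$Wh + t(cache$r * cache$hm) %*% dhh_pre
  g$bz <- g$bz + colSums(dz_pre)
  g$br <- g$br + colSums(dr_pre)
  g$bh <- g$bh + colSums(dhh_pre)
  list(dx = dx, dh = dh, g = g)
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(rbinom(nr * nc, 1, 1 - rate) / (1 - rate), nr, nc)
}

mask_mult <- function(x, m) if (is.null(m)) x else x * m

# Full forward pass over a batch of windows (B x l x m). Returns the
# reconstruction array Y (B x l x m, in decoder order: position j
# reconstructs input position l - j + 1), the next-step prediction, and
# all caches needed for backprop when `keep_cache`.
gru_forward_batch <- function(params, Xw, H, training = FALSE,
                              dropout = 0.2, rec_dropout = 0.2,
                              keep_cache = FALSE) {
  B <- dim(Xw)[1]
  l <- dim(Xw)[2]
  m <- dim(Xw)[3]
  pf <- layer_params(params, "ef")
  pb <- layer_params(params, "eb")
  pd <- layer_params(params, "d")
  use_drop <- training && (dropout > 0 || rec_dropout > 0)
  rm_f <- if (use_drop) drop_mask(B, H, rec_dropout) else NULL
  rm_b <- if (use_drop) drop_mask(B, H, rec_dropout) else NULL
  rm_d <- if (use_drop) drop_mask(B, H, rec_dropout) else NULL
  mk_in <- function() if (use_drop) drop_mask(B, m, dropout) else NULL

  cf <- vector("list", l)
  mx_f <- vector("list", l)
  h <- matrix(0, B, H)
  for (t in seq_len(l)) {
    mx_f[t] <- list(mk_in())
    st <- gru_step(pf, mask_mult(slice_t(Xw, t), mx_f[[t]]), h, rm_f)
    h <- st$h
    cf[[t]] <- st$cache
  }
  hf_last <- h
  cb <- vector("list", l)
  mx_b <- vector("list", l)
  h <- matrix(0, B, H)
  for (s in seq_len(l)) {          # processes t = l, l-1, ..., 1
    t <- l - s + 1L
    mx_b[s] <- list(mk_in())
    st <- gru_step(pb, mask_mult(slice_t(Xw, t), mx_b[[s]]), h, rm_b)
    h <- st$h
    cb[[s]] <- st$cache
  }
  hb_last <- h
  henc <- cbind(hf_last, hb_last)
  xnext <- sweep(henc %*% params$Wp, 2, params$bp, "+")
  s_pre <- sweep(henc %*% params$Ws, 2, params$bs, "+")
  d0 <- tanh(s_pre)

  cd <- vector("list", l)
  mx_d <- vector("list", l)
  Y <- array(0, c(B, l, m))
  h <- d0
  u <- xnext
  for (j in seq_len(l)) {
    mx_d[j] <- list(mk_in())
    st <- gru_step(pd, mask_mult(u, mx_d[[j]]), h, rm_d)
    h <- st$h
    cd[[j]] <- st$cache
    y <- sweep(h %*% params$Wo, 2, params$bo, "+")
    Y[, j, ] <- y
    u <- y
  }
  out <- list(Y = Y, xnext = xnext, henc = henc, d0 = d0)
  if (keep_cache) {
    out$cache <- list(cf = cf, cb = cb, cd = cd, mx_f = mx_f, mx_b = mx_b,
                      mx_d = mx_d, s_pre = s_pre, B = B, l = l, m = m, H = H)
  }
  out
}

# Backward pass: dY is the gradient of the loss wrt Y. Returns the full
# parameter gradient list (same shapes as params).
gru_backward_batch <- function(params, fw, dY) {
  ch <- fw$cache
  B <- ch$B; l <- ch$l; m <- ch$m; H <- ch$H
  pf <- layer_params(params, "ef")
  pb <- layer_params(params, "eb")
  pd <- layer_params(params, "d")
  zero_like <- function(p) lapply(p, function(x) x * 0)
  gf <- zero_like(pf); gb <- zero_like(pb); gd <- zero_like(pd)
  gWo <- params$Wo * 0; gbo <- params$bo * 0
  dd_next <- matrix(0, B, H)   # dh flowing into step j from step j+1
  du_next <- matrix(0, B, m)   # gradient wrt u_{j+1} (= y_j)
  for (j in rev(seq_len(l))) {
    dy <- matrix(dY[, j, ], nrow = B) + du_next
    dh_j <- dy %*% t(params$Wo) + dd_next
    gWo <- gWo + t(get_dec_h(fw, j)) %*% dy
    gbo <- gbo + colSums(dy)
    bk <- gru_step_backward(pd, gd, ch$cd[[j]], dh_j)
    gd <- bk$g
    du_next <- mask_mult(bk$dx, ch$mx_d[[j]])
    dd_next <- bk$dh
  }
  dxnext <- du_next
  dd0 <- dd_next
  ds <- dd0 * (1 - tanh(ch$s_pre)^2)
  gWs <- t(fw$henc) %*% ds
  gbs <- colSums(ds)
  gWp <- t(fw$henc) %*% dxnext
  gbp <- colSums(dxnext)
  dhenc <- ds %*% t(params$Ws) + dxnext %*% t(params$Wp)
  dhf <- dhenc[, seq_len(H), drop = FALSE]
  dhb <- dhenc[, H + seq_len(H), drop = FALSE]
  for (t in rev(seq_len(l))) {
    bk <- gru_step_backward(pf, gf, ch$cf[[t]], dhf)
    gf <- bk$g
    dhf <- bk$dh
  }
  for (s in rev(seq_len(l))) {
    bk <- gru_step_backward(pb, gb, ch$cb[[s]], dhb)
    gb <- bk$g
    dhb <- bk$dh
  }
  g <- list()
  names(gf) <- paste0("ef_", gru_param_names)
  names(gb) <- paste0("eb_", gru_param_names)
  names(gd) <- paste0("d_", gru_param_names)
  g <- c(gf, gb, gd)
  g$Wp <- gWp; g$bp <- gbp; g$Ws <- gWs; g$bs <- gbs
  g$Wo <- gWo; g$bo <- gbo
  g[names(params)]
}

# Decoder hidden state at step j, recovered from the cached next step or
# recomputed from the cell cache.
get_dec_h <- function(fw, j) {
  ch <- fw$cache
  cc <- ch$cd[[j]]
  cc$z * cc$h_prev + (1 - cc$z) * cc$hh
}

# Reversed-reconstruction loss: decoder position j is compared with
# input position l - j + 1.
gru_loss_and_grad <- function(params, Xw, H, training = FALSE, ...) {
  fw <- gru_forward_batch(params, Xw, H, training = training,
                          keep_cache = TRUE, ...)
  B <- dim(Xw)[1]; l <- dim(Xw)[2]; m <- dim(Xw)[3]
  Tgt <- Xw[, rev(seq_len(l)), , drop = FALSE]
  diff <- fw$Y - Tgt
  loss <- mean(diff^2)
  dY <- 2 * diff / length(diff)
  list(loss = loss, grads = gru_backward_batch(params, fw, dY))
}

gru_cv_loss <- function(params, Xw, H) {
  fw <- gru_forward_batch(params, Xw, H, training = FALSE)
  l <- dim(Xw)[2]
  Tgt <- Xw[, rev(seq_len(l)), , drop = FALSE]
  mean((fw$Y - Tgt)^2)
}

#' Train the bidirectional GRU sequence-to-sequence model
#'
#' Windows of `l = 24` standardized hourly vectors are reconstructed in
#' reverse order (see the reversal contract in [score_reconstructions()]
#' consolidation). Windows never straddle contiguous-segment boundaries.
#' Trained with Adam on mean squared error, input dropout 0.2 and
#' recurrent dropout 0.2, early stopping on the healthy-validation loss
#' with best-epoch restore.
#'
#' @param H_R,H_CV Raw hourly feature matrices (rows in time order).
#' @param hidden_units Hidden state size per direction.
#' @param seed Integer seed.
#' @param l Window length (default 24 hours).
#' @param segment_r,segment_cv Contiguous-segment markers for the two
#'   sets (e.g. block ids); windows are built within segments only.
#' @param epochs,batch_size,lr,patience Optimizer settings.
#' @param dropout,rec_dropout Dropout rates used during training only.
#' @return `sw_model` with `arch = "gru_seq2seq"`.
#' @export
train_gru_seq2seq <- function(H_R, H_CV, hidden_units = 20, seed = 1L,
                              l = 24, segment_r = NULL, segment_cv = NULL,
                              epochs = 30, batch_size = 32, lr = 2e-3,
                              patience = 5, dropout = 0.2,
                              rec_dropout = 0.2) {
  H_R <- as.matrix(H_R)
  H_CV <- as.matrix(H_CV)
  m <- ncol(H_R)
  scaler <- fit_scaler(H_R)
  Xtr <- apply_scaler(H_R, scaler)
  Xcv <- apply_scaler(H_CV, scaler)
  wtr <- make_windows(Xtr, l, segment_r)
  wcv <- make_windows(Xcv, l, segment_cv)
  assert_that(length(wtr$start) > 0, "no training windows of length l")
  assert_that(length(wcv$start) > 0, "no validation windows of length l")
  log_dt <- data.table(epoch = integer(0), train_loss = numeric(0),
                       cv_loss = numeric(0))
  with_seed(seed, {
    params <- gru_init_params(m, hidden_units)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    nw <- dim(wtr$windows)[1]
    for (ep in seq_len(epochs)) {
      idx <- sample.int(nw)
      tr_loss <- 0
      nb <- 0L
      for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
        Xb <- wtr$windows[b, , , drop = FALSE]
        lg <- gru_loss_and_grad(params, Xb, hidden_units, training = TRUE,
                                dropout = dropout, rec_dropout = rec_dropout)
        up <- adam_step(params, lg$grads, opt, lr = lr)
        params <- up$params
        opt <- up$state
        tr_loss <- tr_loss + lg$loss
        nb <- nb + 1L
      }
      cv_loss <- gru_cv_loss(params, wcv$windows, hidden_units)
      log_dt <- rbind(log_dt, data.table(epoch = ep, train_loss = tr_loss / nb,
                                         cv_loss = cv_loss))
      if (cv_loss < best$loss - 1e-9) {
        best <- list(loss = cv_loss, params = params, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  structure(list(arch = "gru_seq2seq", params = best$params, scaler = scaler,
                 hidden_units = hidden_units, l = l, log = log_dt,
                 best_epoch = best$epoch, cv_loss = best$loss, seed = seed),
            class = "sw_model")
}
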