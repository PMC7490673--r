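# Reconstruction models: shared standardization/window infrastructure,
# the fully connected autoencoder (window length 1) and the per-
# participant local-outlier-factor baseline. The recurrent
# sequence-to-sequence model lives in gru.R.

# --- standardization -------------------------------------------------

# z-score statistics from the healthy training set only; reused
# unchanged for every other set (H_CV, N_CV, N_T).
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(mean = mu, sd = sdev)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

# --- windowing -------------------------------------------------------

#' Build stride-1 subsequence windows within contiguous segments
#'
#' Windows of length `l` starting at every position, never straddling a
#' segment boundary (segments are contiguous same-split hour runs, so no
#' window mixes data across splits or across gaps).
#'
#' @param X Numeric matrix, rows = hours in time order.
#' @param l Window length.
#' @param segment Vector marking contiguous segments (same value =
#'   same segment); defaults to one segment.
#' @return List: `windows` array (n_windows x l x m), `start` row index
#'   of each window, `segment` id per window, `seg_len` named lengths.
#' @export
make_windows <- function(X, l, segment = NULL) {
  X <- as.matrix(X)
  if (is.null(segment)) segment <- rep(1L, nrow(X))
  runs <- rle(as.character(segment))
  ends <- cumsum(runs$lengths)
  starts_seg <- ends - runs$lengths + 1L
  w_start <- integer(0)
  w_seg <- character(0)
  for (s in seq_along(runs$values)) {
    if (runs$lengths[s] < l) next  # shorter than one window: excluded
    st <- starts_seg[s]:(ends[s] - l + 1L)
    w_start <- c(w_start, st)
    w_seg <- c(w_seg, rep(runs$values[s], length(st)))
  }
  m <- ncol(X)
  arr <- array(NA_real_, c(length(w_start), l, m))
  for (j in seq_len(l)) arr[, j, ] <- X[w_start + j - 1L, , drop = FALSE]
  list(windows = arr, start = w_start, segment = w_seg,
       seg_len = setNames(runs$lengths, runs$values))
}

# --- Adam optimizer over a list of parameter matrices ----------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# --- FNN autoencoder -------------------------------------------------

fnn_forward <- function(params, X, activation) {
  A <- sweep(X %*% params$W1, 2, params$b1, "+")
  Z <- switch(activation,
              relu = pmax(A, 0),
              tanh = tanh(A),
              linear = A)
  Y <- sweep(Z %*% params$W2, 2, params$b2, "+")
  list(A = A, Z = Z, Y = Y)
}

fnn_loss <- function(params, X, activation) {
  Y <- fnn_forward(params, X, activation)$Y
  mean((Y - X)^2)
}

#' Train the fully connected autoencoder (window length 1)
#'
#' A single fully connected encoder layer compresses each standardized
#' hourly feature vector to `hidden_units` dimensions; a single fully
#' connected decoder layer reconstructs it. Trained with Adam on mean
#' squared reconstruction error over the healthy training set, with
#' early stopping on the healthy validation loss (best-epoch checkpoint
#' restored). Standardization statistics come from `H_R` only and are
#' stored in the model.
#'
#' @param H_R,H_CV Numeric matrices of raw (unstandardized) hourly
#'   feature vectors, training and validation.
#' @param hidden_units Bottleneck width (grid 10-50 in the sweep).
#' @param seed Integer seed (reproducible final loss).
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience, epochs.
#' @param activation Encoder activation: "relu", "tanh" or "linear".
#' @return Object of class `sw_model` with `arch = "fnn_ad"`, trained
#'   parameters, scaler and the per-epoch training log.
#' @export
train_fnn_ad <- function(H_R, H_CV, hidden_units = 20, seed = 1L,
                         epochs = 200, batch_size = 256, lr = 1e-3,
                         patience = 5, activation = "relu") {
  H_R <- as.matrix(H_R)
  H_CV <- as.matrix(H_CV)
  m <- ncol(H_R)
  if (hidden_units >= m) {
    warning("hidden_units >= feature dimension: no compression")
  }
  scaler <- fit_scaler(H_R)
  Xtr <- apply_scaler(H_R, scaler)
  Xcv <- apply_scaler(H_CV, scaler)
  log_dt <- data.table(epoch = integer(0), train_loss = numeric(0),
                       cv_loss = numeric(0))
  with_seed(seed, {
    params <- list(W1 = glorot(m, hidden_units), b1 = rep(0, hidden_units),
                   W2 = glorot(hidden_units, m), b2 = rep(0, m))
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    n <- nrow(Xtr)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      tr_loss <- 0
      nb <- 0L
      for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
        Xb <- Xtr[b, , drop = FALSE]
        fw <- fnn_forward(params, Xb, activation)
        dY <- 2 * (fw$Y - Xb) / length(Xb)
        dZ <- dY %*% t(params$W2)
        dA <- switch(activation,
                     relu = dZ * (fw$A > 0),
                     tanh = dZ * (1 - fw$Z^2),
                     linear = dZ)
        grads <- list(W1 = t(Xb) %*% dA, b1 = colSums(dA),
                      W2 = t(fw$Z) %*% dY, b2 = colSums(dY))
        up <- adam_step(params, grads, opt, lr = lr)
        params <- up$params
        opt <- up$state
        tr_loss <- tr_loss + mean((fw$Y - Xb)^2)
        nb <- nb + 1L
      }
      cv_loss <- fnn_loss(params, Xcv, activation)
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
  structure(list(arch = "fnn_ad", params = best$params, scaler = scaler,
                 hidden_units = hidden_units, activation = activation,
                 l = 1L, log = log_dt, best_epoch = best$epoch,
                 cv_loss = best$loss, seed = seed),
            class = "sw_model")
}

# --- local outlier factor baseline -----------------------------------

pairwise_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# LOF novelty scores for query points against a reference set, given the
# reference's k-distances and local reachability densities.
lof_query_scores <- function(dq, ord_q, kdist_ref, lrd_ref, k) {
  n_q <- nrow(dq)
  s <- numeric(n_q)
  for (i in seq_len(n_q)) {
    nb <- ord_q[i, seq_len(k)]
    reach <- pmax(kdist_ref[nb], dq[i, nb])
    lrd_q <- 1 / mean(reach)
    s[i] <- mean(lrd_ref[nb]) / lrd_q
  }
  s
}

lof_reference <- function(dtr, ord_tr, k) {
  n <- nrow(dtr)
  kdist <- dtr[cbind(seq_len(n), ord_tr[, k])]
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- ord_tr[i, seq_len(k)]
    reach <- pmax(kdist[nb], dtr[i, nb])
    lrd[i] <- 1 / mean(reach)
  }
  list(kdist = kdist, lrd = lrd)
}

#' Fit the per-participant local outlier factor baseline
#'
#' Fits LOF on a participant's healthy training hours and picks the
#' neighbor count by the convergence loop: starting at 10 neighbors and
#' incrementing by 1 until the mean and SD of the healthy-validation
#' scores both change by less than `tol` (relative), capped at
#' `k_cap` with a warning.
#'
#' @param H_R,H_CV Raw feature matrices for one participant.
#' @param k_start Initial neighbor count (default 10).
#' @param tol Relative convergence tolerance on mean and SD.
#' @param k_cap Neighbor cap.
#' @param seed Unused (LOF is deterministic); kept for interface parity.
#' @return `sw_model` with `arch = "lof"`; `reconstruct()` returns LOF
#'   scores (treated as 1-dimensional errors downstream).
#' @export
fit_lof <- function(H_R, H_CV, k_start = 10, tol = 1e-3, k_cap = 100,
                    seed = NULL) {
  H_R <- as.matrix(H_R)
  H_CV <- as.matrix(H_CV)
  assert_that(nrow(H_R) >= k_start + 1,
              "need at least k_start + 1 training hours for LOF")
  scaler <- fit_scaler(H_R)
  Xtr <- apply_scaler(H_R, scaler)
  Xcv <- apply_scaler(H_CV, scaler)
  dtr <- pairwise_dist(Xtr, Xtr)
  diag(dtr) <- Inf
  ord_tr <- t(apply(dtr, 1, order))
  dq <- pairwise_dist(Xcv, Xtr)
  ord_q <- t(apply(dq, 1, order))
  k_max <- min(k_cap, nrow(Xtr) - 1L)
  scores_at <- function(k) {
    ref <- lof_reference(dtr, ord_tr, k)
    lof_query_scores(dq, ord_q, ref$kdist, ref$lrd, k)
  }
  k <- min(k_start, k_max)
  s_prev <- scores_at(k)
  trace <- data.table(k = k, mean = mean(s_prev), sd = sd(s_prev))
  converged <- FALSE
  while (k < k_max) {
    k <- k + 1L
    s_cur <- scores_at(k)
    trace <- rbind(trace, data.table(k = k, mean = mean(s_cur), sd = sd(s_cur)))
    dm <- abs(mean(s_cur) - mean(s_prev)) / max(abs(mean(s_prev)), 1e-12)
    ds <- abs(sd(s_cur) - sd(s_prev)) / max(abs(sd(s_prev)), 1e-12)
    if (dm < tol && ds < tol) {
      converged <- TRUE
      break
    }
    s_prev <- s_cur
  }
  if (!converged && k >= min(k_cap, k_max)) {
    warning("LOF neighbor-convergence not reached by cap; using k = ", k)
  }
  ref <- lof_reference(dtr, ord_tr, k)
  structure(list(arch = "lof", X = Xtr, scaler = scaler, k = k,
                 kdist = ref$kdist, lrd = ref$lrd, trace = trace,
                 converged = converged),
            class = "sw_model")
}

# --- inference -------------------------------------------------------

#' Reconstruct data with a trained model
#'
#' Deterministic inference (dropout off). Inputs are standardized with
#' the model's stored statistics; outputs stay on the standardized
#' scale, which is also the scale on which reconstruction errors are
#' scored.
#'
#' @param model An `sw_model`.
#' @param newdata Raw feature matrix (rows = hours in time order) for
#'   `fnn_ad`/`lof`; for `gru_seq2seq`, pass the matrix plus `segment`
#'   to window it internally.
#' @param segment Optional contiguous-segment marker (GRU only).
#' @return For `fnn_ad`: list(x, xhat) standardized matrices. For
#'   `gru_seq2seq`: list(x, xhat) window arrays plus window starts. For
#'   `lof`: numeric score vector.
#' @export
reconstruct <- function(model, newdata, segment = NULL) {
  assert_that(inherits(model, "sw_model"), "need an sw_model")
  newdata <- as.matrix(newdata)
  if (model$arch == "lof") {
    X <- apply_scaler(newdata, model$scaler)
    dq <- pairwise_dist(X, model$X)
    ord_q <- t(apply(dq, 1, order))
    return(lof_query_scores(dq, ord_q, model$kdist, model$lrd, model$k))
  }
  if (ncol(newdata) != length(model$scaler$mean)) {
    stop("feature dimension mismatch: model expects ",
         length(model$scaler$mean), " features", call. = FALSE)
  }
  X <- apply_scaler(newdata, model$scaler)
  if (model$arch == "fnn_ad") {
    Y <- fnn_forward(model$params, X, model$activation)$Y
    return(list(x = X, xhat = Y))
  }
  if (model$arch == "gru_seq2seq") {
    wl <- make_windows(X, model$l, segment)
    if (!length(wl$start)) {
      return(list(x = wl$windows, xhat = wl$windows, start = wl$start))
    }
    xhat <- gru_forward_batch(model$params, wl$windows, model$hidden_units,
                              training = FALSE)$Y
    return(list(x = wl$windows, xhat = xhat, start = wl$start))
  }
  stop("unknown architecture: ", model$arch, call. = FALSE)
}

#' @export
print.sw_model <- function(x, ...) {
  cat("sw_model:", x$arch,
      if (!is.null(x$hidden_units)) paste0("(hidden = ", x$hidden_units, ")"),
      if (!is.null(x$k)) paste0("(k = ", x$k, ")"), "\n")
  invisible(x)
}
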