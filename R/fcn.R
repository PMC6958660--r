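# Fully convolutional network for time series: three conv blocks
# (128/256/128 filters, kernels 8/5/3, "same" padding, stride 1), each
# followed by batch normalization and ReLU, then global average pooling and
# the softmax head. Convolutions carry no bias (the BN shift beta plays that
# role). Implemented as im2col matrix products; activations are stored as
# (B*L) x channels matrices with row index (t-1)*B + b, so a time shift is a
# contiguous row-block shift.
#
# BN uses batch statistics during training (running estimates updated with
# momentum 0.9, epsilon 1e-5) and the running estimates at prediction time.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# im2col: returns (B*L) x (K*C) matrix; column block k holds the input
# shifted by (k - 1 - pad_left) timesteps, zero-padded at the edges.
fcn_im2col <- function(Xm, B, L, K) {
  C <- ncol(Xm)
  pad_l <- (K - 1L) %/% 2L
  M <- matrix(0, B * L, K * C)
  for (k in seq_len(K)) {
    o <- k - 1L - pad_l
    t_lo <- max(1L, 1L - o); t_hi <- min(L, L - o)
    if (t_lo > t_hi) next
    dst <- ((t_lo - 1L) * B + 1L):(t_hi * B)
    src <- ((t_lo + o - 1L) * B + 1L):((t_hi + o) * B)
    M[dst, (k - 1L) * C + seq_len(C)] <- Xm[src, , drop = FALSE]
  }
  M
}

fcn_col2im <- function(dM, B, L, K, C) {
  pad_l <- (K - 1L) %/% 2L
  dX <- matrix(0, B * L, C)
  for (k in seq_len(K)) {
    o <- k - 1L - pad_l
    t_lo <- max(1L, 1L - o); t_hi <- min(L, L - o)
    if (t_lo > t_hi) next
    dst <- ((t_lo - 1L) * B + 1L):(t_hi * B)
    src <- ((t_lo + o - 1L) * B + 1L):((t_hi + o) * B)
    dX[src, ] <- dX[src, ] + dM[dst, (k - 1L) * C + seq_len(C), drop = FALSE]
  }
  dX
}

fcn_loss_grad <- function(model, xb, yb, want_grads = TRUE) {
  B <- nrow(xb); L <- ncol(xb)
  lambda <- model$config$l2_lambda
  # to time-major (B*L) x 1 layout: row (t-1)*B + b = xb[b, t]
  A <- matrix(xb[cbind(rep(seq_len(B), L), rep(seq_len(L), each = B))], B * L, 1)
  caches <- list()
  for (i in seq_along(model$params$blocks)) {
    blk <- model$params$blocks[[i]]
    K <- blk$kernel
    M <- fcn_im2col(A, B, L, K)
    Zc <- M %*% blk$W
    if (want_grads) {                # training mode: batch statistics
      mu <- colMeans(Zc)
      va <- colMeans(Zc^2) - mu^2
      model$params$blocks[[i]]$run_mean <-
        BN_MOMENTUM * blk$run_mean + (1 - BN_MOMENTUM) * mu
      model$params$blocks[[i]]$run_var <-
        BN_MOMENTUM * blk$run_var + (1 - BN_MOMENTUM) * va
    } else {
      mu <- blk$run_mean; va <- blk$run_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    Xhat <- sweep(sweep(Zc, 2, mu), 2, inv_sd, `*`)
    Zbn <- sweep(sweep(Xhat, 2, blk$gamma, `*`), 2, blk$beta, `+`)
    Aout <- pmax(Zbn, 0)
    caches[[i]] <- list(A_in = A, M = M, Xhat = Xhat, inv_sd = inv_sd,
                        Zbn = Zbn)
    A <- Aout
  }
  Fo <- ncol(A)
  grp <- rep(seq_len(B), L)
  g <- rowsum(A, grp) / L                     # B x F  global average pool
  logits <- g %*% t(model$params$V) + matrix(model$params$c, B,
                                             model$n_class, byrow = TRUE)
  probs <- softmax(logits)
  ce <- -mean(log(pmax(probs[cbind(seq_len(B), yb)], 1e-300)))
  l2 <- sum(model$params$V^2)
  for (blk in model$params$blocks) l2 <- l2 + sum(blk$W^2)
  out <- list(loss = ce + lambda * l2, probs = probs)
  if (!want_grads) return(out)

  dlogits <- probs
  dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
  dlogits <- dlogits / B
  gV <- t(dlogits) %*% g + 2 * lambda * model$params$V
  gc_ <- colSums(dlogits)
  dg <- dlogits %*% model$params$V            # B x F
  dA <- dg[grp, , drop = FALSE] / L           # (B*L) x F
  grads_blocks <- vector("list", length(model$params$blocks))
  for (i in rev(seq_along(model$params$blocks))) {
    blk <- model$params$blocks[[i]]
    ch <- caches[[i]]
    dZbn <- dA * (ch$Zbn > 0)
    dgamma <- colSums(dZbn * ch$Xhat)
    dbeta <- colSums(dZbn)
    N <- nrow(dZbn)
    dXhat <- sweep(dZbn, 2, blk$gamma, `*`)
    dZc <- sweep(dXhat - matrix(colMeans(dXhat), N, ncol(dXhat), byrow = TRUE) -
                   ch$Xhat * matrix(colMeans(dXhat * ch$Xhat), N,
                                    ncol(dXhat), byrow = TRUE),
                 2, ch$inv_sd, `*`)
    gW <- t(ch$M) %*% dZc + 2 * lambda * blk$W
    dM <- dZc %*% t(blk$W)
    dA <- fcn_col2im(dM, B, L, blk$kernel, ncol(ch$A_in))
    grads_blocks[[i]] <- list(W = gW, gamma = dgamma, beta = dbeta,
                              run_mean = blk$run_mean * 0,
                              run_var = blk$run_var * 0, kernel = 0)
  }
  out$grads <- list(blocks = grads_blocks, V = gV, c = gc_)
  # BN running stats were updated in-place above; surface them to the trainer
  out$updated_blocks <- model$params$blocks
  out
}
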