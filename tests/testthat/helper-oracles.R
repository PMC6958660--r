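# Straight-from-the-equations reference recurrent cells, kept deliberately
# naive and independent of the package's compiled implementation.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))
ref_gru_step <- function(x, h, p) {
  z <- ref_sigmoid(p$bz + p$Uz %*% x + p$Wz %*% h)
  r <- ref_sigmoid(p$br + p$Ur %*% x + p$Wr %*% h)
  hc <- tanh(p$bh + p$Uh %*% x + p$Wh %*% (r * h))
  as.numeric(z * h + (1 - z) * hc)
}
ref_lstm_step <- function(x, h, s, p, cand = ref_sigmoid) {
  g <- ref_sigmoid(p$bg + p$Ug %*% x + p$Wg %*% h)
  f <- ref_sigmoid(p$bf + p$Uf %*% x + p$Wf %*% h)
  o <- ref_sigmoid(p$bo + p$Uo %*% x + p$Wo %*% h)
  s_new <- f * s + g * cand(p$bc + p$Uc %*% x + p$Wc %*% h)
  list(h = as.numeric(tanh(s_new) * o), s = as.numeric(s_new))
}
rand_params <- function(type, in_dim, H) {
  gates <- if (type == "gru") c("z", "r", "h") else c("g", "f", "o", "c")
  p <- list()
  for (g in gates) {
    p[[paste0("U", g)]] <- matrix(stats::rnorm(H * in_dim), H, in_dim)
    p[[paste0("W", g)]] <- matrix(stats::rnorm(H * H), H, H)
    p[[paste0("b", g)]] <- stats::rnorm(H)
  }
  p
}

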