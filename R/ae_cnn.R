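# 1-D convolution primitives over arrays [batch, length, channels],
# kernel k (odd), stride 2, zero padding (k-1)/2, so each conv halves the
# length and each transposed conv doubles it. Implemented by im2col so the
# inner loop is one BLAS matrix product.

# im2col matrix [B*Lo, k*C] from padded input; column blocks are kernel taps.
conv_im2col <- function(X, k) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  pad <- (k - 1L) %/% 2L
  Lo <- L %/% 2L
  Xp <- array(0, c(B, L + 2L * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  cols <- matrix(0, B * Lo, k * C)
  for (kk in seq_len(k)) {
    pos <- 2L * (seq_len(Lo) - 1L) + kk      # index into padded axis
    blk <- Xp[, pos, , drop = FALSE]
    dim(blk) <- c(B * Lo, C)
    cols[, (kk - 1L) * C + seq_len(C)] <- blk
  }
  cols
}

conv_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1L]; L <- d[2L]
  k <- nrow(W) / d[3L]
  cols <- conv_im2col(X, k)
  Y <- sweep(cols %*% W, 2L, b, "+")
  dim(Y) <- c(B, L %/% 2L, ncol(W))
  list(Y = Y, cols = cols)
}

# Scatter-add of dXcol back onto the (padded) input grid; adjoint of im2col.
conv_col2im <- function(dcols, B, L, C, k) {
  pad <- (k - 1L) %/% 2L
  Lo <- L %/% 2L
  dXp <- array(0, c(B, L + 2L * pad, C))
  for (kk in seq_len(k)) {
    pos <- 2L * (seq_len(Lo) - 1L) + kk
    blk <- dcols[, (kk - 1L) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(B, Lo, C)
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] + blk
  }
  dXp[, pad + seq_len(L), , drop = FALSE]
}

conv_bwd <- function(cols, W, dY, B, L, C) {
  Lo <- L %/% 2L
  dYm <- dY; dim(dYm) <- c(B * Lo, ncol(W))
  dW <- crossprod(cols, dYm)
  db <- colSums(dYm)
  dX <- conv_col2im(dYm %*% t(W), B, L, C, nrow(W) / C)
  list(dX = dX, dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }

dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

#' Build an untrained convolutional autoencoder
#'
#' Encoder: dense layer resampling the window onto an internal grid of
#' `cp2` samples, three strided 1-D convolutions (channel widths from the
#' config, kernel 3, stride 2, each halving the length), then a dense layer
#' flattening to the latent vector. Decoder: the mirror image with three
#' transposed convolutions and a final dense layer back to the input
#' length. ReLU activations sit between layers; the latent and the output
#' layers are linear.
#'
#' @param cfg A [ae_config()] with `arch = "cnn"`.
#' @return Untrained model of class `pp_ae` (weights initialized from the
#'   config seed).
#' @export
build_cnn_ae <- function(cfg) {
  stopifnot(inherits(cfg, "pp_ae_config"))
  set.seed(cfg$seed)
  P <- cfg$cp2
  ch <- cfg$cnn_channels
  k <- cfg$kernel
  flat <- (P %/% 8L) * ch[3L]
  conv_init <- function(cin, cout) {
    list(W = matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                    k * cin, cout),
         b = numeric(cout))
  }
  # transposed conv reuses the paired conv weight shape [k*cout, cin] but
  # its bias runs over its own output channels (cout)
  tconv_init <- function(cout, cin) {
    list(W = matrix(stats::rnorm(k * cout * cin, sd = sqrt(2 / (k * cin))),
                    k * cout, cin),
         b = numeric(cout))
  }
  params <- list(
    L1 = dense_init(cfg$input_len, P),
    C1 = conv_init(1L, ch[1L]),
    C2 = conv_init(ch[1L], ch[2L]),
    C3 = conv_init(ch[2L], ch[3L]),
    L2 = dense_init(flat, cfg$latent_dim),
    DL = dense_init(cfg$latent_dim, flat),
    D1 = tconv_init(ch[2L], ch[3L]),  # ch3 -> ch2
    D2 = tconv_init(ch[1L], ch[2L]),  # ch2 -> ch1
    D3 = tconv_init(1L, ch[1L]),      # ch1 -> 1
    L3 = dense_init(P, cfg$input_len)
  )
  structure(list(cfg = cfg, params = params), class = c("pp_ae_cnn", "pp_ae"))
}

cnn_forward <- function(model, X) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(X); P <- cfg$cp2; ch <- cfg$cnn_channels
  a1 <- relu(sweep(X %*% p$L1$W, 2L, p$L1$b, "+"))          # [B, P]
  x1 <- a1; dim(x1) <- c(B, P, 1L)
  c1 <- conv_fwd(x1, p$C1$W, p$C1$b); h1 <- relu(c1$Y)      # [B, P/2, ch1]
  c2 <- conv_fwd(h1, p$C2$W, p$C2$b); h2 <- relu(c2$Y)      # [B, P/4, ch2]
  c3 <- conv_fwd(h2, p$C3$W, p$C3$b); h3 <- relu(c3$Y)      # [B, P/8, ch3]
  flat <- h3; dim(flat) <- c(B, (P %/% 8L) * ch[3L])
  z <- sweep(flat %*% p$L2$W, 2L, p$L2$b, "+")              # latent [B, d]
  g0 <- relu(sweep(z %*% p$DL$W, 2L, p$DL$b, "+"))
  g0a <- g0; dim(g0a) <- c(B, P %/% 8L, ch[3L])
  d1 <- tconv_apply(g0a, p$D1$W, p$D1$b); u1 <- relu(d1)    # [B, P/4, ch2]
  d2 <- tconv_apply(u1, p$D2$W, p$D2$b); u2 <- relu(d2)     # [B, P/2, ch1]
  d3 <- tconv_apply(u2, p$D3$W, p$D3$b); u3 <- relu(d3)     # [B, P, 1]
  u3m <- u3; dim(u3m) <- c(B, P)
  recon <- sweep(u3m %*% p$L3$W, 2L, p$L3$b, "+")           # [B, input_len]
  list(latent = z, recon = recon,
       cache = list(X = X, a1 = a1, c1 = c1, h1 = h1, c2 = c2, h2 = h2,
                    c3 = c3, h3 = h3, flat = flat, z = z, g0 = g0,
                    d1 = d1, u1 = u1, d2 = d2, u2 = u2, d3 = d3, u3m = u3m))
}

# Transposed conv as adjoint of conv with weights [k*Cout_here, Cin_here]:
# W maps (output channels as the paired conv's input). U: [B, Li, Cin].
tconv_apply <- function(U, W, b) {
  d <- dim(U); B <- d[1L]; Li <- d[2L]; Cin <- d[3L]
  k <- 3L
  Cout <- nrow(W) %/% k
  Um <- U; dim(Um) <- c(B * Li, Cin)
  dcols <- Um %*% t(W)                         # [B*Li, k*Cout]
  V <- conv_col2im(dcols, B, 2L * Li, Cout, k) # [B, 2Li, Cout]
  sweep(V, 3L, b, "+")
}

tconv_grads <- function(U, W, dV) {
  d <- dim(U); B <- d[1L]; Li <- d[2L]; Cin <- d[3L]
  k <- 3L
  Cout <- nrow(W) %/% k
  dcols_out <- conv_im2col(dV, k)              # [B*Li, k*Cout]
  Um <- U; dim(Um) <- c(B * Li, Cin)
  dW <- crossprod(dcols_out, Um)               # [k*Cout, Cin]
  db <- apply(dV, 3L, sum)
  dU <- dcols_out %*% W                        # [B*Li, Cin]
  dim(dU) <- c(B, Li, Cin)
  list(dU = dU, dW = dW, db = db)
}

cnn_backward <- function(model, cache, dRecon) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(dRecon); P <- cfg$cp2; ch <- cfg$cnn_channels
  g <- list()
  # L3
  g$L3 <- list(W = crossprod(cache$u3m, dRecon), b = colSums(dRecon))
  du3m <- dRecon %*% t(p$L3$W)
  du3 <- du3m * (cache$u3m > 0)
  dim(du3) <- c(B, P, 1L)
  # D3 (tconv ch1 -> 1)
  t3 <- tconv_grads(cache$u2, p$D3$W, du3)
  g$D3 <- list(W = t3$dW, b = t3$db)
  du2 <- t3$dU * (cache$d2 > 0)
  # D2 (tconv ch2 -> ch1)
  t2 <- tconv_grads(cache$u1, p$D2$W, du2)
  g$D2 <- list(W = t2$dW, b = t2$db)
  du1 <- t2$dU * (cache$d1 > 0)
  # D1 (tconv ch3 -> ch2)
  g0a <- cache$g0; dim(g0a) <- c(B, P %/% 8L, ch[3L])
  t1 <- tconv_grads(g0a, p$D1$W, du1)
  g$D1 <- list(W = t1$dW, b = t1$db)
  dg0 <- t1$dU; dim(dg0) <- c(B, (P %/% 8L) * ch[3L])
  dg0 <- dg0 * (cache$g0 > 0)
  # DL
  g$DL <- list(W = crossprod(cache$z, dg0), b = colSums(dg0))
  dz <- dg0 %*% t(p$DL$W)
  # L2
  g$L2 <- list(W = crossprod(cache$flat, dz), b = colSums(dz))
  dflat <- dz %*% t(p$L2$W)
  dh3 <- dflat; dim(dh3) <- c(B, P %/% 8L, ch[3L])
  dh3 <- dh3 * (cache$c3$Y > 0)
  b3 <- conv_bwd(cache$c3$cols, p$C3$W, dh3, B, P %/% 4L, ch[2L])
  g$C3 <- list(W = b3$dW, b = b3$db)
  dh2 <- b3$dX * (cache$c2$Y > 0)
  b2 <- conv_bwd(cache$c2$cols, p$C2$W, dh2, B, P %/% 2L, ch[1L])
  g$C2 <- list(W = b2$dW, b = b2$db)
  dh1 <- b2$dX * (cache$c1$Y > 0)
  b1 <- conv_bwd(cache$c1$cols, p$C1$W, dh1, B, P, 1L)
  g$C1 <- list(W = b1$dW, b = b1$db)
  da1 <- b1$dX; dim(da1) <- c(B, P)
  da1 <- da1 * (cache$a1 > 0)
  g$L1 <- list(W = crossprod(cache$X, da1), b = colSums(da1))
  g
}
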