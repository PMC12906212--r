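## Minimal convolutional-network engine (forward + backprop + Adam), sized
## for the 16x32 task screens. Layout: valid 4x4 convolutions (stride 1, no
## padding) and 3x3 non-overlapping max pooling in ceil mode (edge windows
## may be partial), which takes 16x32 -> 13x29x8 -> 5x10x8 -> 2x7x16 ->
## 1x3x16 -> dense 16 -> 4 logits. Activations are stored as (H, W, C, N)
## arrays; convolutions run through precomputed im2col index tables.

.conv_idx <- function(H, W, C, kh, kw) {
  oh <- H - kh + 1L; ow <- W - kw + 1L
  P <- oh * ow; K <- kh * kw * C
  idx <- matrix(0L, P, K)
  k <- 0L
  for (c in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    i <- rep(seq_len(oh) + di - 1L, times = ow)
    j <- rep(seq_len(ow) + dj - 1L, each = oh)
    idx[, k] <- i + (j - 1L) * H + (c - 1L) * H * W
  }
  list(idx = idx, oh = oh, ow = ow, P = P, K = K)
}

.conv_fwd <- function(A, Wk, b, ci) {
  d <- dim(A); N <- d[4]
  Am <- matrix(A, d[1] * d[2] * d[3], N)
  big <- matrix(0, ci$P * N, ci$K)
  for (k in seq_len(ci$K)) big[, k] <- Am[ci$idx[, k], ]
  out <- big %*% Wk + rep(b, each = ci$P * N)
  Cout <- ncol(Wk)
  out <- aperm(array(out, c(ci$P, N, Cout)), c(1, 3, 2))
  list(Z = array(out, c(ci$oh, ci$ow, Cout, N)), big = big)
}

.conv_bwd <- function(dZ, big, Wk, ci, in_dim, N) {
  Cout <- ncol(Wk)
  dZm <- matrix(aperm(array(dZ, c(ci$P, Cout, N)), c(1, 3, 2)),
                ci$P * N, Cout)
  dW <- crossprod(big, dZm)
  db <- colSums(dZm)
  dPatch <- dZm %*% t(Wk)
  dAm <- matrix(0, prod(in_dim), N)
  for (k in seq_len(ci$K))
    dAm[ci$idx[, k], ] <- dAm[ci$idx[, k], ] + matrix(dPatch[, k], ci$P, N)
  list(dA = array(dAm, c(in_dim, N)), dW = dW, db = db)
}

.pool_windows <- function(H, W, size = 3L) {
  rs <- seq(1L, H, size); cs <- seq(1L, W, size)
  win <- list()
  for (b in cs) for (a in rs)
    win[[length(win) + 1L]] <- list(r = a:min(a + size - 1L, H),
                                    c = b:min(b + size - 1L, W))
  list(win = win, oh = length(rs), ow = length(cs))
}

.pool_fwd <- function(A, pw) {
  d <- dim(A); C <- d[3]; N <- d[4]
  nw <- length(pw$win)
  out <- array(0, c(pw$oh, pw$ow, C, N))
  arg <- vector("list", nw)
  for (w in seq_len(nw)) {
    bl <- A[pw$win[[w]]$r, pw$win[[w]]$c, , , drop = FALSE]
    m <- matrix(bl, length(pw$win[[w]]$r) * length(pw$win[[w]]$c), C * N)
    mi <- max.col(t(m), ties.method = "first")
    out[((w - 1L) %% pw$oh) + 1L, ((w - 1L) %/% pw$oh) + 1L, , ] <-
      m[cbind(mi, seq_len(C * N))]
    arg[[w]] <- mi
  }
  list(Z = out, arg = arg)
}

.pool_bwd <- function(dZ, A_dim, pw, arg) {
  C <- A_dim[3]; N <- A_dim[4]
  dA <- array(0, c(A_dim[1], A_dim[2], C, N))
  for (w in seq_along(pw$win)) {
    r <- pw$win[[w]]$r; cc <- pw$win[[w]]$c
    len <- length(r) * length(cc)
    dm <- matrix(0, len, C * N)
    g <- dZ[((w - 1L) %% pw$oh) + 1L, ((w - 1L) %/% pw$oh) + 1L, , ]
    dm[cbind(arg[[w]], seq_len(C * N))] <- as.vector(g)
    dA[r, cc, , ] <- dA[r, cc, , , drop = FALSE] +
      array(dm, c(length(r), length(cc), C, N))
  }
  dA
}

.cnn_geometry <- function() {
  ci1 <- .conv_idx(16L, 32L, 1L, 4L, 4L)
  pw1 <- .pool_windows(ci1$oh, ci1$ow)
  ci2 <- .conv_idx(pw1$oh, pw1$ow, 8L, 4L, 4L)
  pw2 <- .pool_windows(ci2$oh, ci2$ow)
  list(ci1 = ci1, pw1 = pw1, ci2 = ci2, pw2 = pw2,
       flat = pw2$oh * pw2$ow * 16L)
}

.cnn_init <- function(seed, geom) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = he(geom$ci1$K, 8L), b1 = rep(0, 8),
       W2 = he(geom$ci2$K, 16L), b2 = rep(0, 16),
       W3 = he(geom$flat, 16L), b3 = rep(0, 16),
       W4 = he(16L, 4L), b4 = rep(0, 4))
}

.cnn_forward <- function(par, geom, A, keep = FALSE) {
  c1 <- .conv_fwd(A, par$W1, par$b1, geom$ci1)
  a1 <- pmax(c1$Z, 0)
  p1 <- .pool_fwd(a1, geom$pw1)
  c2 <- .conv_fwd(p1$Z, par$W2, par$b2, geom$ci2)
  a2 <- pmax(c2$Z, 0)
  p2 <- .pool_fwd(a2, geom$pw2)
  N <- dim(A)[4]
  flat <- matrix(p2$Z, geom$flat, N)
  h <- pmax(crossprod(par$W3, flat) + par$b3, 0)   # 16 x N
  logits <- crossprod(par$W4, h) + par$b4          # 4 x N
  if (!keep) return(logits)
  list(logits = logits, h = h, flat = flat, p2 = p2, a2 = a2, c2 = c2,
       p1 = p1, a1 = a1, c1 = c1, A = A)
}

.cnn_backward <- function(par, geom, fw, dlogits) {
  N <- ncol(dlogits)
  g <- list()
  g$W4 <- fw$h %*% t(dlogits); g$b4 <- rowSums(dlogits)
  dh <- (par$W4 %*% dlogits) * (fw$h > 0)
  g$W3 <- fw$flat %*% t(dh); g$b3 <- rowSums(dh)
  dflat <- par$W3 %*% dh
  dP2 <- array(dflat, dim(fw$p2$Z))
  dA2 <- .pool_bwd(dP2, dim(fw$a2), geom$pw2, fw$p2$arg) * (fw$c2$Z > 0)
  bw2 <- .conv_bwd(dA2, fw$c2$big, par$W2, geom$ci2,
                   dim(fw$p1$Z)[1:3], N)
  g$W2 <- bw2$dW; g$b2 <- bw2$db
  dA1 <- .pool_bwd(bw2$dA, dim(fw$a1), geom$pw1, fw$p1$arg) * (fw$c1$Z > 0)
  bw1 <- .conv_bwd(dA1, fw$c1$big, par$W1, geom$ci1, dim(fw$A)[1:3], N)
  g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

## Weighted softmax cross-entropy; y is an integer class vector (1..4),
## w per-sample weights. Returns loss and dlogits.
.xent <- function(logits, y, w) {
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  iy <- cbind(y, seq_len(N))
  loss <- -sum(w * log(pmax(p[cbind(y, seq_len(N))], 1e-12))) / sum(w)
  d <- p
  d[iy] <- d[iy] - 1
  d <- sweep(d, 2, w / sum(w), "*")
  list(loss = loss, dlogits = d, p = p)
}

.adam_new <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0), t = 0)
}

.adam_step <- function(par, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8,
                       wd = 0) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps) -
      lr * wd * par[[nm]]
  }
  list(par = par, st = st)
}
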