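# Brute-force texture oracle: literal double loops over pixel pairs and
# direct evaluation of the textbook formulas. Kept deliberately naive and
# independent of the package's vectorized implementation.

bf_quantize <- function(img, mask, levels) {
  vals <- img[mask]
  mn <- min(vals); mx <- max(vals)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (!mask[r, c]) next
    q[r, c] <- if (mx == mn) 1L
               else min(levels, floor((img[r, c] - mn) / (mx - mn) * levels) + 1L)
  }
  q
}

bf_glcm <- function(img, mask, levels, distance) {
  q <- bf_quantize(img, mask, levels)
  M <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img) - distance)) {
      if (!mask[r, c] || !mask[r, c + distance]) next
      i <- q[r, c]; j <- q[r, c + distance]
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
    }
  }
  M / sum(M)
}

bf_haralick <- function(P) {
  L <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- 0; sdy <- 0
  for (i in 1:L) { sdx <- sdx + (i - mux)^2 * px[i]
                   sdy <- sdy + (i - muy)^2 * py[i] }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  psum <- numeric(2 * L); pdiff <- numeric(L)  # psum[k]=p(i+j=k), pdiff[k+1]=p(|i-j|=k)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  asm <- 0; contrast <- 0; corr_num <- 0; varce <- 0; idm <- 0
  entropy <- 0
  for (i in 1:L) for (j in 1:L) {
    asm <- asm + P[i, j]^2
    corr_num <- corr_num + i * j * P[i, j]
    varce <- varce + (i - mux)^2 * P[i, j]
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    entropy <- entropy - P[i, j] * lg(P[i, j])
  }
  for (k in 0:(L - 1)) contrast <- contrast + k^2 * pdiff[k + 1]
  correlation <- if (sdx == 0 || sdy == 0) 0 else
    (corr_num - mux * muy) / (sdx * sdy)
  sum_avg <- 0
  for (k in 2:(2 * L)) sum_avg <- sum_avg + k * psum[k]
  sum_var <- 0; sum_ent <- 0
  for (k in 2:(2 * L)) {
    sum_var <- sum_var + (k - sum_avg)^2 * psum[k]
    sum_ent <- sum_ent - psum[k] * lg(psum[k])
  }
  mud <- 0
  for (k in 0:(L - 1)) mud <- mud + k * pdiff[k + 1]
  diff_var <- 0; diff_ent <- 0
  for (k in 0:(L - 1)) {
    diff_var <- diff_var + (k - mud)^2 * pdiff[k + 1]
    diff_ent <- diff_ent - pdiff[k + 1] * lg(pdiff[k + 1])
  }
  hx <- 0; hy <- 0
  for (i in 1:L) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = varce, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, diff_var = diff_var,
    diff_ent = diff_ent, imc1 = imc1, imc2 = imc2)
}

# Gaussian random field with isotropic power spectral density ~ f^alpha,
# built by shaping complex white noise in the frequency domain.
make_power_field <- function(n, alpha, seed) {
  set.seed(seed)
  fidx <- function(m) ifelse(seq_len(m) - 1 > m / 2,
                             seq_len(m) - 1 - m, seq_len(m) - 1) / m
  f <- fidx(n)
  R <- sqrt(outer(f^2, f^2, "+"))
  A <- R^(alpha / 2)
  A[1, 1] <- 0
  Z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  Re(stats::fft(Z * A, inverse = TRUE)) / n
}

# Draw a filled disk (dx^2 + dy^2 <= r^2) of intensity 1 on black.
draw_disk <- function(n, cx, cy, r) {
  img <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- 1
  img
}
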