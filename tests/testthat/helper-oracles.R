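# Independent brute-force oracles used to freeze expected values.

# chi-square statistic from explicit expected counts, sum (O-E)^2/E
oracle_chi2 <- function(pos1, neg1, pos2, neg2) {
  obs <- matrix(c(pos1, neg1, pos2, neg2), 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# all-pairs nearest-background distance (image border counts as background)
oracle_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j]) {
        out[i, j] <- sqrt(min((bg[, 1] - (i + 1))^2 + (bg[, 2] - (j + 1))^2))
      }
    }
  }
  out
}

# eccentricity via direct pixel enumeration (independent of the package's
# vectorised moments code)
oracle_eccentricity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
  m20 <- 0; m02 <- 0; m11 <- 0
  for (k in seq_len(nrow(pts))) {
    dy <- pts[k, 1] - cy; dx <- pts[k, 2] - cx
    m20 <- m20 + dx^2; m02 <- m02 + dy^2; m11 <- m11 + dx * dy
  }
  m20 <- m20 / nrow(pts); m02 <- m02 / nrow(pts); m11 <- m11 / nrow(pts)
  lam <- eigen(matrix(c(m20, m11, m11, m02), 2))$values
  sqrt(max(1 - lam[2] / lam[1], 0))
}

# --- shape fixtures ---------------------------------------------------------

make_disk <- function(r, n = 2 * r + 9) {
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

make_square <- function(a, pad = 4) {
  n <- a + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + a), (pad + 1):(pad + a)] <- TRUE
  m
}

make_ellipse <- function(a, b, angle_deg = 0, n = 2 * ceiling(a) + 9) {
  cx <- (n + 1) / 2
  th <- angle_deg * pi / 180
  outer(seq_len(n), seq_len(n), function(i, j) {
    dy <- i - cx; dx <- j - cx
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

upscale_mask <- function(mask, s) {
  mask[rep(seq_len(nrow(mask)), each = s), rep(seq_len(ncol(mask)), each = s)]
}
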