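# Maximal-overlap discrete wavelet transform (MODWT), Daubechies-6 basis.
# Circular filtering via the standard pyramid recursion; shift-invariant
# and defined for any signal length, which suits arbitrary ECG records.

# Daubechies-6 (12-tap) scaling filter, synthesis ordering.
.db6_g <- c(
   1.1154074335010947e-01,  4.9462389039845306e-01,  7.5113390802109536e-01,
   3.1525035170919763e-01, -2.2626469396543983e-01, -1.2976686756726194e-01,
   9.7501605587323043e-02,  2.7522865530305727e-02, -3.1582039317486030e-02,
   5.5384220116149613e-04,  4.7772575109455108e-03, -1.0773010853084796e-03
)
# quadrature-mirror wavelet filter: h_l = (-1)^l g_{L-1-l}
.db6_h <- rev(.db6_g) * (-1)^(seq_along(.db6_g) - 1)

.circ_shift <- function(x, s) {
  # y[t] = x[(t - s) mod N], 0-based
  n <- length(x)
  s <- s %% n
  if (s == 0) x else c(x[(n - s + 1):n], x[1:(n - s)])
}

.modwt_filter <- function(v, filt, j) {
  # one filtering pass at level j with upsampled filter (stride 2^(j-1))
  out <- numeric(length(v))
  stride <- 2^(j - 1)
  for (l in seq_along(filt)) {
    out <- out + filt[l] * .circ_shift(v, (l - 1) * stride)
  }
  out
}

.imodwt_filter <- function(w, filt, j) {
  out <- numeric(length(w))
  stride <- 2^(j - 1)
  for (l in seq_along(filt)) {
    out <- out + filt[l] * .circ_shift(w, -(l - 1) * stride)
  }
  out
}

# forward MODWT to `levels`; returns list(W = N x J matrix of wavelet
# coefficients, V = level-J scaling coefficients)
modwt_db6 <- function(x, levels) {
  n <- length(x)
  ht <- .db6_h / sqrt(2)
  gt <- .db6_g / sqrt(2)
  W <- matrix(0, n, levels)
  v <- x
  for (j in seq_len(levels)) {
    W[, j] <- .modwt_filter(v, ht, j)
    v <- .modwt_filter(v, gt, j)
  }
  list(W = W, V = v)
}

imodwt_db6 <- function(dec) {
  ht <- .db6_h / sqrt(2)
  gt <- .db6_g / sqrt(2)
  levels <- ncol(dec$W)
  v <- dec$V
  for (j in rev(seq_len(levels))) {
    v <- .imodwt_filter(dec$W[, j], ht, j) + .imodwt_filter(v, gt, j)
  }
  v
}
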