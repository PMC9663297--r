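# shared fixtures and independent oracle implementations

# a minimal hand-written 3-residue PDB text with known B-factors
write_tiny_pdb <- function(path, b = c(90.0, 45.2, 70.0)) {
  fmt <- function(i, resno, x, bb) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
            i, resno, x, 0, 0, bb)
  }
  writeLines(c(fmt(1, 1, 0, b[1]), fmt(2, 2, 3.8, b[2]), fmt(3, 3, 7.6, b[3]),
               "END"), path)
  path
}

# default two-block synthetic model used across tests: ordered helix +
# disordered coil, the study condition for disorder benchmarking
ordered_disordered_model <- function(seed = 1, n_ord = 300, n_dis = 250,
                                     rho = 0.5) {
  synth_model(list(
    segment_spec("helix", n_ord, 90, 5, disordered = FALSE),
    segment_spec("coil", n_dis, 40, 8, disordered = TRUE)
  ), seed = seed, ar1_rho = rho)
}

# O(n k) direct-summation Gaussian convolution with edge-repeated reflection
oracle_gaussian <- function(v, sigma) {
  n <- length(v)
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in -r:r) {
      jj <- i + j
      while (jj < 1 || jj > n) {
        if (jj < 1) jj <- 1 - jj
        if (jj > n) jj <- 2 * n + 1 - jj
      }
      acc <- acc + w[j + r + 1] * v[jj]
    }
    out[i] <- acc
  }
  out
}

# brute-force centered moving average with symmetric shrink
oracle_window_mean <- function(v, window) {
  n <- length(v)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(v[(i - h):(i + h)])
  }
  out
}

# O(n^2) pairwise-comparison AUC with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# independent end-to-end shape-mer counting: plain loops from coordinates to
# binned ids, no calls into the package's fragment/count machinery
oracle_shapemer_counts <- function(xyz, k = 16, r = 10,
                                   res_kmer = 4, res_radius = 6) {
  n <- nrow(xyz)
  moments <- function(pts) {
    ctr <- sweep(pts, 2, colMeans(pts))
    m <- function(p, q, s) sum(ctr[, 1]^p * ctr[, 2]^q * ctr[, 3]^s)
    o3 <- m(2,0,0) + m(0,2,0) + m(0,0,2)
    o4 <- m(2,0,0)*m(0,2,0) + m(2,0,0)*m(0,0,2) + m(0,2,0)*m(0,0,2) -
      m(1,1,0)^2 - m(1,0,1)^2 - m(0,1,1)^2
    S <- matrix(c(m(2,0,0), m(1,1,0), m(1,0,1),
                  m(1,1,0), m(0,2,0), m(0,1,1),
                  m(1,0,1), m(0,1,1), m(0,0,2)), 3, 3)
    o5 <- det(S)
    f <- m(3,0,0)^2 + m(0,3,0)^2 + m(0,0,3)^2 +
      3 * (m(2,1,0)^2 + m(2,0,1)^2 + m(1,2,0)^2 + m(0,2,1)^2 +
             m(1,0,2)^2 + m(0,1,2)^2) + 6 * m(1,1,1)^2
    c(o3, o4, o5, f)
  }
  bin <- function(mm, res, kind) {
    paste0(kind, ":", paste(as.integer(round(res * sign(mm) * log(1 + abs(mm)))),
                            collapse = "_"))
  }
  ids <- character(0)
  if (n >= k) {
    for (s in 1:(n - k + 1)) {
      ids <- c(ids, bin(moments(xyz[s:(s + k - 1), , drop = FALSE]),
                        res_kmer, "kmer"))
    }
  }
  for (i in 1:n) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    ids <- c(ids, bin(moments(xyz[d <= r, , drop = FALSE]),
                      res_radius, "radius"))
  }
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = rnorm(3, sd = 20))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% tr$rot, 2, tr$shift, "+")
}
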