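test_that("fragmentation yields sliding k-mers and radius neighborhoods", {
  m <- synth_model(segment_spec("helix", 20, 90, 0), seed = 1)$model
  fk <- fragment_model(m, "kmer", k = 16)
  expect_length(fk, 5)   # 20 - 16 + 1
  expect_true(all(vapply(fk, function(f) length(f$members), integer(1)) == 16))

  # chain shorter than k: no k-mer fragments, not an error
  m5 <- synth_model(segment_spec("helix", 5, 90, 0), seed = 1)$model
  expect_length(fragment_model(m5, "kmer", k = 16), 0)

  # radius memberships equal the all-pairs distance oracle
  mm <- synth_model(list(segment_spec("helix", 15, 90, 0),
                         segment_spec("coil", 15, 50, 5, TRUE)), seed = 2)$model
  fr <- fragment_model(mm, "radius", r = 10)
  xyz <- as.matrix(mm$residues[, c("x", "y", "z")])
  for (f in fr) {
    d <- sqrt(colSums((t(xyz) - xyz[f$center + 1, ])^2))
    expect_equal(sort(f$members), sort(which(d <= 10) - 1L))
  }
  # an isolated residue's radius fragment is itself
  lone <- af2_model(data.frame(chain = "A", resno = 1, aa = "G",
                               x = 0, y = 0, z = 0, plddt = 90))
  fl <- fragment_model(lone, "radius")
  expect_equal(fl[[1]]$members, 0L)
})

test_that("moment invariants are rigid-motion invariant and match the oracle", {
  set.seed(51)
  for (rep_i in 1:10) {
    pts <- matrix(rnorm(48, sd = 5), 16, 3)
    inv <- moment_invariants(pts)
    tr <- random_rigid_transform()
    inv2 <- moment_invariants(apply_rigid(pts, tr))
    expect_lt(max(abs(inv - inv2) / pmax(abs(inv), 1e-12)), 1e-8)
  }
  # degenerate collinear points: rank-1 covariance
  line <- cbind(1:16, 0, 0)
  invl <- moment_invariants(line)
  expect_equal(unname(invl["O4"]), 0)
  expect_equal(unname(invl["O5"]), 0)
  expect_gt(invl["O3"], 0)

  # direct-summation check of every term on a fresh cloud
  pts <- matrix(rnorm(48), 16, 3)
  ctr <- sweep(pts, 2, colMeans(pts))
  mu <- function(p, q, r) sum(ctr[, 1]^p * ctr[, 2]^q * ctr[, 3]^r)
  expect_equal(unname(moment_invariants(pts)["O3"]),
               mu(2, 0, 0) + mu(0, 2, 0) + mu(0, 0, 2), tolerance = 1e-9)
  expect_equal(unname(moment_invariants(pts)["F"]),
               mu(3,0,0)^2 + mu(0,3,0)^2 + mu(0,0,3)^2 +
                 3 * (mu(2,1,0)^2 + mu(2,0,1)^2 + mu(1,2,0)^2 +
                        mu(0,2,1)^2 + mu(1,0,2)^2 + mu(0,1,2)^2) +
                 6 * mu(1,1,1)^2, tolerance = 1e-9)
})

test_that("shape-mer discretization is the declared log-binning", {
  expect_equal(discretize_shapemer(c(0, 0, 0, 0)), "kmer:0_0_0_0")
  expect_equal(discretize_shapemer(c(10, 0, 0, 0), resolution = 4),
               paste0("kmer:", round(4 * log(11)), "_0_0_0"))
  inv <- c(3.2, -1.5, 0.7, 12)
  expect_identical(discretize_shapemer(inv), discretize_shapemer(inv))
  expect_error(discretize_shapemer(inv, resolution = 0), "resolution")
  # monotone in each component
  a <- discretize_shapemer(c(5, 0, 0, 0), resolution = 4)
  b <- discretize_shapemer(c(500, 0, 0, 0), resolution = 4)
  get1 <- function(id) as.integer(strsplit(sub("kmer:", "", id), "_")[[1]][1])
  expect_gt(get1(b), get1(a))
})

test_that("shape-mer counts are additive and rigid-motion invariant", {
  m <- synth_model(segment_spec("helix", 20, 90, 0), seed = 3)$model
  counts <- shapemer_counts(m)
  # rotation invariance of the full pipeline, many transforms
  set.seed(52)
  xyz <- as.matrix(m$residues[, c("x", "y", "z")])
  for (rep_i in 1:10) {
    tr <- random_rigid_transform()
    m2 <- m
    m2$residues[, c("x", "y", "z")] <- apply_rigid(xyz, tr)
    expect_identical(unclass(shapemer_counts(m2)), unclass(counts))
  }
  # counting two identical copies doubles every count: emulate by doubling
  tm <- tfidf_matrix(list(a = counts, b = counts))
  expect_equal(tm$matrix[1, ], tm$matrix[2, ])
})

test_that("shape-mer counts equal the end-to-end brute-force oracle", {
  m <- synth_model(segment_spec("helix", 20, 90, 0), seed = 4)$model
  xyz <- as.matrix(m$residues[, c("x", "y", "z")])
  expect_identical(unclass(shapemer_counts(m)), oracle_shapemer_counts(xyz))

  mixed <- synth_model(list(segment_spec("helix", 18, 90, 0),
                            segment_spec("coil", 12, 45, 4, TRUE)),
                       seed = 5)$model
  expect_identical(unclass(shapemer_counts(mixed)),
                   oracle_shapemer_counts(as.matrix(
                     mixed$residues[, c("x", "y", "z")])))
})

test_that("segment-restricted counting never spans a split boundary", {
  m <- synth_model(list(segment_spec("helix", 60, 95, 1),
                        segment_spec("coil", 30, 30, 3, TRUE),
                        segment_spec("helix", 60, 95, 1)), seed = 6)$model
  seg <- split_high_confidence(m, min_len = 20)
  expect_gte(nrow(seg), 2)
  counts <- shapemer_counts(m, segments = seg)
  # equals the sum of per-segment brute-force counts
  xyz <- as.matrix(m$residues[, c("x", "y", "z")])
  per_seg <- lapply(seq_len(nrow(seg)), function(j) {
    oracle_shapemer_counts(xyz[(seg$start[j] + 1):seg$end[j], , drop = FALSE])
  })
  all_ids <- sort(unique(unlist(lapply(per_seg, names))))
  merged <- setNames(numeric(length(all_ids)), all_ids)
  for (ps in per_seg) merged[names(ps)] <- merged[names(ps)] + ps
  expect_identical(unclass(counts),
                   setNames(as.integer(merged), names(merged)))
})

test_that("TFIDF uses the smoothed idf with a floor of one", {
  docs <- list(
    a = structure(c(`s1` = 2L, `s2` = 1L), class = "shapemer_counts"),
    b = structure(c(`s1` = 1L, `s3` = 4L), class = "shapemer_counts"),
    c = structure(c(`s1` = 3L), class = "shapemer_counts"))
  tm <- tfidf_matrix(docs)
  n <- 3
  idf <- function(df) log((1 + n) / (1 + df)) + 1
  # hand-computed values
  expect_equal(tm$matrix["a", "s1"], 2 * idf(3))
  expect_equal(tm$matrix["a", "s2"], 1 * idf(1))
  expect_equal(tm$matrix["b", "s3"], 4 * idf(1))
  expect_equal(tm$matrix["c", "s2"], 0)
  # term present everywhere gets idf exactly 1
  expect_equal(idf(3), 1)
})

test_that("NMF is monotone, deterministic and exact on low-rank input", {
  set.seed(61)
  w1 <- runif(12); h1 <- runif(9)
  x1 <- outer(w1, h1)
  fit1 <- nmf_topics(x1, 1)
  expect_lt(sqrt(sum((x1 - fit1$W %*% fit1$H)^2)) / sqrt(sum(x1^2)), 1e-6)

  x <- matrix(runif(15 * 12), 15, 12)
  fit <- nmf_topics(x, 4)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  fit2 <- nmf_topics(x, 4)
  expect_identical(fit$W, fit2$W)

  # full-rank limit reconstructs closely
  xs <- matrix(runif(6 * 8), 6, 8)
  fits <- nmf_topics(xs, 6, max_iter = 5000, tol = 1e-14)
  expect_lt(sqrt(sum((xs - fits$W %*% fits$H)^2)) / sqrt(sum(xs^2)), 1e-3)

  expect_error(nmf_topics(matrix(c(-1, 1, 1, 1), 2, 2), 1), "nonnegative")
})

test_that("NMF recovers planted topics from a noisy count corpus", {
  set.seed(62)
  p_true <- 3
  w_true <- matrix(rexp(40 * p_true), 40, p_true)
  h_true <- matrix(0, p_true, 30)
  for (t in 1:p_true) h_true[t, ((t - 1) * 10 + 1):(t * 10)] <- runif(10, 1, 3)
  x <- matrix(rpois(40 * 30, w_true %*% h_true * 2), 40, 30)
  fit <- nmf_topics(x, p_true, max_iter = 2000)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- max(vapply(perms, function(pm) {
    mean(vapply(1:p_true, function(t) cos(fit$H[pm[t], ], h_true[t, ]),
                numeric(1)))
  }, numeric(1)))
  expect_gte(best, 0.9)
})

test_that("knee assignment keeps the high-weight head and ignores flat topics", {
  w <- matrix(c(10, 9, 8, 0.1, 0.1, 0.1), ncol = 1)
  expect_equal(assign_topics_knee(w)[[1]], 1:3)
  expect_equal(assign_topics_knee(matrix(0, 6, 1))[[1]], integer(0))
  expect_equal(assign_topics_knee(matrix(5, 6, 1))[[1]], integer(0))
  # chord-distance oracle on a random profile
  set.seed(63)
  col <- sort(c(runif(5, 8, 10), runif(20, 0, 0.5)), decreasing = TRUE)
  y <- col; n <- length(y)
  d <- abs((y[n] - y[1]) * (seq_len(n) - 1) - (n - 1) * (y - y[1])) /
    sqrt((n - 1)^2 + (y[n] - y[1])^2)
  knee <- which.max(d)
  expect_equal(assign_topics_knee(matrix(col, ncol = 1))[[1]],
               which(col > col[knee]))
})

test_that("residue topic scores follow the RBF-weighted sum contract", {
  m <- synth_model(segment_spec("helix", 20, 90, 0), seed = 7)$model
  counts <- shapemer_counts(m)
  tm <- tfidf_matrix(list(a = counts, b = counts))
  fit <- nmf_topics(tm$matrix, 1, vocabulary = tm$vocabulary)
  frags <- c(fragment_model(m, "kmer"), fragment_model(m, "radius"))
  sc <- residue_topic_scores(m, frags, fit, 1)
  expect_true(all(sc >= 0))

  # zero topic row gives zero scores
  fit0 <- fit; fit0$H[1, ] <- 0
  expect_equal(residue_topic_scores(m, frags, fit0, 1), rep(0, 20))

  # hand-evaluated two-fragment oracle on a toy model
  toy <- af2_model(data.frame(chain = "A", resno = 1:4, aa = "A",
                              x = c(0, 3.8, 7.6, 11.4), y = 0, z = 0,
                              plddt = 90))
  tfr <- list(list(center = 0L, kind = "radius", members = c(0L, 1L)),
              list(center = 2L, kind = "radius", members = c(1L, 2L, 3L)))
  xyz <- as.matrix(toy$residues[, c("x", "y", "z")])
  ids <- vapply(tfr, function(f) {
    discretize_shapemer(moment_invariants(xyz[f$members + 1, , drop = FALSE]),
                        kind = "radius", resolution = 6)
  }, character(1))
  h <- matrix(c(0.7, 0.3), 1, 2)
  fit2 <- structure(list(W = matrix(1), H = h, p = 1,
                         vocabulary = ids, objective = 0),
                    class = "topic_model")
  # if the two fragments bin to the same shape-mer only the first column is used
  hh <- setNames(as.numeric(h), ids)
  sc2 <- residue_topic_scores(toy, tfr, fit2, 1)
  rbf <- function(i, cen) exp(-sum((xyz[i, ] - xyz[cen, ])^2) / (2 * 25))
  exp_sc <- c(hh[ids[1]] * rbf(1, 1),
              hh[ids[1]] * rbf(2, 1) + hh[ids[2]] * rbf(2, 3),
              hh[ids[2]] * rbf(3, 3),
              hh[ids[2]] * rbf(4, 3))
  expect_equal(sc2, unname(exp_sc), tolerance = 1e-12)
  # a residue at a fragment center receives that fragment's full weight
  expect_equal(unname(sc2[3] - hh[[ids[2]]] * rbf(3, 3)), 0)
})

test_that("cosine matching is scale-invariant and finds rotated copies", {
  a <- structure(c(s1 = 1L, s2 = 2L), class = "shapemer_counts")
  b <- structure(c(s1 = 2L, s2 = 4L), class = "shapemer_counts")
  d <- structure(c(s3 = 5L), class = "shapemer_counts")
  res <- cosine_match(a, list(same = b, disjoint = d))
  expect_equal(res$similarity[res$id == "same"], 1)
  expect_equal(res$similarity[res$id == "disjoint"], 0)
  expect_error(cosine_match(structure(integer(0), class = "shapemer_counts"),
                            list(a)), "empty")

  m <- synth_model(list(segment_spec("helix", 25, 92, 1),
                        segment_spec("strand", 15, 88, 1)), seed = 8)$model
  set.seed(64)
  tr <- random_rigid_transform()
  m2 <- m
  m2$residues[, c("x", "y", "z")] <-
    apply_rigid(as.matrix(m$residues[, c("x", "y", "z")]), tr)
  other <- synth_model(segment_spec("coil", 40, 50, 5, TRUE), seed = 9)$model
  corpus <- list(rotated = shapemer_counts(m2),
                 unrelated = shapemer_counts(other))
  hit <- cosine_match(shapemer_counts(m), corpus)
  expect_equal(hit$id[1], "rotated")
  expect_gte(hit$similarity[1], 0.999)
})
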