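#' Fragment a model into local Calpha neighborhoods
#'
#' Two fragmentation schemes feed the shape-mer pipeline: `kmer` slides a
#' window of `k` consecutive residues along each chain (center = window
#' midpoint), and `radius` takes, for every residue, all Calpha atoms within
#' `r` Angstrom of its Calpha (center included). Chains shorter than `k`
#' simply contribute no k-mer fragments.
#'
#' @param model an [af2_model()].
#' @param kind `"kmer"` or `"radius"`.
#' @param k k-mer length (default 16).
#' @param r neighborhood radius in A (default 10).
#' @return List of fragments, each a list with `center` (0-based residue
#'   index), `kind` and `members` (0-based residue indices).
#' @export
fragment_model <- function(model, kind = c("kmer", "radius"), k = 16, r = 10) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "af2_model"))
  frags <- list()
  if (kind == "kmer") {
    for (ch in model$chains) {
      idx <- model$residues$index[model$residues$chain == ch]
      n <- length(idx)
      if (n < k) next
      for (s in seq_len(n - k + 1)) {
        members <- idx[s:(s + k - 1)]
        frags[[length(frags) + 1]] <- list(
          center = members[ceiling(k / 2)], kind = "kmer", members = members)
      }
    }
  } else {
    xyz <- ca_xyz(model)
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nrow(xyz))) {
      members <- model$residues$index[d[i, ] <= r]
      frags[[length(frags) + 1]] <- list(
        center = model$residues$index[i], kind = "radius", members = members)
    }
  }
  frags
}

#' Rotation-invariant moment descriptors of a point cloud
#'
#' Second- and third-order central-moment invariants of a set of Calpha
#' coordinates: with mu_pqr = sum over points of
#' (x - xbar)^p (y - ybar)^q (z - zbar)^r,
#' \itemize{
#'   \item O3 = mu200 + mu020 + mu002 (trace of the second-moment tensor),
#'   \item O4 = mu200 mu020 + mu200 mu002 + mu020 mu002 - mu110^2 - mu101^2
#'     - mu011^2 (sum of principal 2x2 minors),
#'   \item O5 = det of the second-moment tensor,
#'   \item F = mu300^2 + mu030^2 + mu003^2 + 3(mu210^2 + mu201^2 + mu120^2 +
#'     mu021^2 + mu102^2 + mu012^2) + 6 mu111^2 (third-order tensor norm).
#' }
#' All four are invariant under rigid motion; degenerate point sets yield
#' zeros rather than errors.
#'
#' @param coords m x 3 coordinate matrix (>= 1 point).
#' @param normalize_by_count divide moments by the point count for
#'   size-robust descriptors (default `FALSE`; raw sums weight larger
#'   neighborhoods more).
#' @return Named numeric vector `c(O3, O4, O5, F)`.
#' @export
moment_invariants <- function(coords, normalize_by_count = FALSE) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) >= 1)
  c0 <- sweep(coords, 2, colMeans(coords))
  x <- c0[, 1]; y <- c0[, 2]; z <- c0[, 3]
  denom <- if (normalize_by_count) nrow(c0) else 1
  mu <- function(p, q, r) sum(x^p * y^q * z^r) / denom
  S <- matrix(c(mu(2, 0, 0), mu(1, 1, 0), mu(1, 0, 1),
                mu(1, 1, 0), mu(0, 2, 0), mu(0, 1, 1),
                mu(1, 0, 1), mu(0, 1, 1), mu(0, 0, 2)), 3, 3)
  o3 <- S[1, 1] + S[2, 2] + S[3, 3]
  o4 <- S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
    S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2
  o5 <- det(S)
  f <- mu(3, 0, 0)^2 + mu(0, 3, 0)^2 + mu(0, 0, 3)^2 +
    3 * (mu(2, 1, 0)^2 + mu(2, 0, 1)^2 + mu(1, 2, 0)^2 +
           mu(0, 2, 1)^2 + mu(1, 0, 2)^2 + mu(0, 1, 2)^2) +
    6 * mu(1, 1, 1)^2
  c(O3 = o3, O4 = o4, O5 = o5, F = f)
}

#' Discretize moment invariants into a shape-mer identifier
#'
#' Each invariant m is mapped to the integer
#' `round(resolution * sign(m) * log(1 + |m|))`; the shape-mer id is the
#' fragment kind plus the four integers. The mapping is deterministic and
#' monotone in each invariant; coarser resolutions merge more fragments into
#' the same shape-mer.
#'
#' @param invariants numeric vector `c(O3, O4, O5, F)`.
#' @param kind fragment kind tag (`"kmer"` or `"radius"`).
#' @param resolution bin resolution (> 0); the pipeline defaults are 4 for
#'   k-mer and 6 for radius fragments.
#' @return A single shape-mer id string, e.g. `"kmer:12_8_3_21"`.
#' @export
discretize_shapemer <- function(invariants, kind = "kmer", resolution = 4) {
  if (resolution <= 0) stop("resolution must be > 0")
  comp <- round(resolution * sign(invariants) * log1p(abs(invariants)))
  paste0(kind, ":", paste(as.integer(comp), collapse = "_"))
}

#' Shape-mer count vector of a model
#'
#' Runs both fragmentation schemes, computes moment invariants per fragment
#' and discretizes them into shape-mers; the result is the sparse count
#' vector over the union of both schemes' shape-mers. When `segments` are
#' supplied (the high-confidence splits of a predicted model), fragments are
#' computed per segment and never span a segment boundary.
#'
#' @param model an [af2_model()].
#' @param segments optional segment data frame from
#'   [split_high_confidence()]; counts are then accumulated across splits.
#' @param k,r fragment parameters (defaults 16 and 10 A).
#' @param res_kmer,res_radius discretization resolutions (defaults 4 and 6).
#' @param normalize_by_count see [moment_invariants()].
#' @return Named integer vector of shape-mer counts (class `shapemer_counts`).
#' @export
shapemer_counts <- function(model, segments = NULL, k = 16, r = 10,
                            res_kmer = 4, res_radius = 6,
                            normalize_by_count = FALSE) {
  stopifnot(inherits(model, "af2_model"))
  pieces <- if (is.null(segments) || nrow(segments) == 0) {
    list(model)
  } else {
    lapply(seq_len(nrow(segments)), function(j) {
      model_subset(model, segments$start[j]:(segments$end[j] - 1))
    })
  }
  ids <- character(0)
  for (piece in pieces) {
    xyz <- ca_xyz(piece)
    for (kind in c("kmer", "radius")) {
      frags <- fragment_model(piece, kind, k = k, r = r)
      res <- if (kind == "kmer") res_kmer else res_radius
      for (f in frags) {
        inv <- moment_invariants(xyz[f$members + 1L, , drop = FALSE],
                                 normalize_by_count = normalize_by_count)
        ids <- c(ids, discretize_shapemer(inv, kind = kind, resolution = res))
      }
    }
  }
  counts <- table(ids)
  out <- setNames(as.integer(counts), names(counts))
  class(out) <- "shapemer_counts"
  out
}

#' @export
print.shapemer_counts <- function(x, ...) {
  cat(sprintf("<shapemer_counts> %d distinct shape-mers, %d fragments\n",
              length(x), sum(unclass(x))))
  invisible(x)
}

counts_to_matrix <- function(counts_list, vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(counts_list, names))))
  }
  m <- matrix(0, length(counts_list), length(vocabulary),
              dimnames = list(names(counts_list), vocabulary))
  for (i in seq_along(counts_list)) {
    ci <- counts_list[[i]]
    hit <- intersect(names(ci), vocabulary)
    m[i, hit] <- as.numeric(unclass(ci)[hit])
  }
  m
}

#' TFIDF matrix over shape-mer count vectors
#'
#' Proteins are documents, shape-mers are terms:
#' `tfidf(d, t) = count(d, t) * (ln((1 + n) / (1 + df(t))) + 1)` with the
#' smoothed inverse document frequency, so a term present in every document
#' keeps a factor of exactly 1.
#'
#' @param counts_list list of [shapemer_counts()] vectors (documents, in row
#'   order).
#' @return List with `matrix` (n x m, nonnegative) and `vocabulary`.
#' @export
tfidf_matrix <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  m <- counts_to_matrix(counts_list)
  if (ncol(m) == 0) stop("empty shape-mer vocabulary")
  n <- nrow(m)
  df <- colSums(m > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  list(matrix = sweep(m, 2, idf, "*"), vocabulary = colnames(m))
}

# deterministic nonnegative initialization in the NNDSVDa style: the leading
# SVD factors with negative parts zeroed, zeros backfilled with the matrix mean
nndsvd_init <- function(x, p) {
  s <- svd(x, nu = p, nv = p)
  w <- matrix(0, nrow(x), p)
  h <- matrix(0, p, ncol(x))
  w[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  h[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (p > 1) {
    for (j in 2:p) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg) {
        if (npos > 0) {
          w[, j] <- sqrt(s$d[j] * npos) * up / sqrt(sum(up^2))
          h[j, ] <- sqrt(s$d[j] * npos) * vp / sqrt(sum(vp^2))
        }
      } else {
        w[, j] <- sqrt(s$d[j] * nneg) * un / sqrt(sum(un^2))
        h[j, ] <- sqrt(s$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(x)
  w[w <= 0] <- eps * 1e-2
  h[h <= 0] <- eps * 1e-2
  list(w = w, h = h)
}

#' Nonnegative matrix factorization topic model
#'
#' Factorizes a nonnegative n x m matrix into W (n x p, protein-to-topic) and
#' H (p x m, topic-to-shape-mer) by multiplicative updates minimizing the
#' Frobenius norm, from a deterministic SVD-based nonnegative initialization,
#' so results are reproducible without a seed. The objective is
#' non-increasing across iterations.
#'
#' @param x nonnegative numeric matrix (e.g. the TFIDF matrix).
#' @param p number of topics (<= min(n, m)); the full structural-space map
#'   uses 250, small corpora should use far fewer.
#' @param max_iter maximum update iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-9).
#' @param vocabulary optional shape-mer names for H's columns.
#' @return A `topic_model` list: `W`, `H`, `p`, `objective` (per-iteration
#'   Frobenius losses), `vocabulary`.
#' @export
nmf_topics <- function(x, p, max_iter = 500, tol = 1e-9, vocabulary = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("NMF input must be nonnegative")
  stopifnot(p >= 1, p <= min(dim(x)))
  init <- nndsvd_init(x, p)
  w <- init$w; h <- init$h
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (t(w) %*% x) / (t(w) %*% w %*% h + eps)
    w <- w * (x %*% t(h)) / (w %*% h %*% t(h) + eps)
    err <- sqrt(sum((x - w %*% h)^2))
    obj <- c(obj, err)
    if (is.finite(prev) && prev - err <= tol * max(prev, 1)) break
    prev <- err
  }
  structure(list(W = w, H = h, p = p, objective = obj,
                 vocabulary = vocabulary %||% colnames(x)),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> %d proteins x %d topics x %d shape-mers, final loss %.4g\n",
              nrow(x$W), x$p, ncol(x$H), tail(x$objective, 1)))
  invisible(x)
}

#' Assign proteins to topics by knee detection on the weight profile
#'
#' For each topic, the column of W is sorted in descending order and the knee
#' is the point of maximum perpendicular distance to the chord from the first
#' to the last point; proteins with weight strictly above the knee weight are
#' assigned. Topics whose profile is flat (maximum chord distance below
#' `1e-9 * max(weight)`) assign no proteins.
#'
#' @param w nonnegative n x p weight matrix (W of the topic model).
#' @return List of length p; each element an integer vector of assigned
#'   protein row indices.
#' @export
assign_topics_knee <- function(w) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("W must be nonnegative")
  lapply(seq_len(ncol(w)), function(t) {
    col <- w[, t]
    if (max(col) <= 0) return(integer(0))
    o <- order(col, decreasing = TRUE)
    y <- col[o]
    n <- length(y)
    if (n < 3) return(integer(0))
    # perpendicular distance of (i, y_i) to the chord (1, y_1) -- (n, y_n)
    dx <- n - 1
    dy <- y[n] - y[1]
    dist <- abs(dy * (seq_len(n) - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
    if (max(dist) < 1e-9 * max(y)) return(integer(0))
    knee <- which.max(dist)
    sort(o[y > y[knee]])
  })
}

#' Per-residue topic scores
#'
#' Aggregates, over every fragment containing a residue, the topic's weight
#' for the fragment's shape-mer times an RBF kernel of the distance between
#' the residue's Calpha and the fragment center's Calpha:
#' `score(i) = sum_f H[t, s(f)] * exp(-||x_i - x_center(f)||^2 / (2 sigma^2))`.
#' Shape-mers absent from the model's vocabulary contribute zero.
#'
#' @param model an [af2_model()].
#' @param fragments fragments from [fragment_model()] (computed on `model`).
#' @param topics a `topic_model` from [nmf_topics()] (with vocabulary).
#' @param topic 1-based topic index.
#' @param sigma_rbf RBF bandwidth in A (default 5).
#' @param res_kmer,res_radius discretization resolutions matching the counts.
#' @param normalize_by_count see [moment_invariants()].
#' @return Numeric vector of nonnegative per-residue scores.
#' @export
residue_topic_scores <- function(model, fragments, topics, topic,
                                 sigma_rbf = 5, res_kmer = 4, res_radius = 6,
                                 normalize_by_count = FALSE) {
  stopifnot(inherits(model, "af2_model"), inherits(topics, "topic_model"),
            topic >= 1, topic <= topics$p)
  xyz <- ca_xyz(model)
  h <- topics$H[topic, ]
  names(h) <- topics$vocabulary
  scores <- numeric(length(model))
  for (f in fragments) {
    inv <- moment_invariants(xyz[f$members + 1L, , drop = FALSE],
                             normalize_by_count = normalize_by_count)
    res <- if (f$kind == "kmer") res_kmer else res_radius
    id <- discretize_shapemer(inv, kind = f$kind, resolution = res)
    wt <- h[id]
    if (is.na(wt) || wt == 0) next
    cen <- xyz[f$center + 1L, ]
    for (i in f$members) {
      d2 <- sum((xyz[i + 1L, ] - cen)^2)
      scores[i + 1L] <- scores[i + 1L] + wt * exp(-d2 / (2 * sigma_rbf^2))
    }
  }
  scores
}

#' Rank a corpus by cosine similarity to a query shape-mer vector
#'
#' @param query a [shapemer_counts()] vector (nonzero).
#' @param corpus list of [shapemer_counts()] vectors.
#' @return Data frame `index`, `id` (names of `corpus`, if any), `similarity`
#'   sorted by decreasing similarity; similarities lie in \[0, 1\].
#' @export
cosine_match <- function(query, corpus) {
  stopifnot(length(corpus) >= 1)
  if (sum(unclass(query)) == 0) stop("query shape-mer vector is empty")
  vocab <- sort(unique(c(names(query), unlist(lapply(corpus, names)))))
  qm <- counts_to_matrix(list(q = query), vocab)[1, ]
  cm <- counts_to_matrix(corpus, vocab)
  qn <- sqrt(sum(qm^2))
  sims <- vapply(seq_len(nrow(cm)), function(i) {
    nrm <- sqrt(sum(cm[i, ]^2))
    if (nrm == 0) 0 else sum(qm * cm[i, ]) / (qn * nrm)
  }, numeric(1))
  o <- order(sims, decreasing = TRUE)
  data.frame(index = o,
             id = if (!is.null(names(corpus))) names(corpus)[o] else NA,
             similarity = sims[o], stringsAsFactors = FALSE)
}
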