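#' Specify a synthetic model segment
#'
#' @param kind `"helix"`, `"strand"` or `"coil"`.
#' @param length number of residues (>= 1).
#' @param plddt_mean mean pLDDT of the segment (0-100).
#' @param plddt_sd standard deviation of the per-residue pLDDT noise (>= 0).
#' @param disordered logical ground-truth disorder label for the segment.
#' @return A `model_segment_spec` list.
#' @export
segment_spec <- function(kind = c("helix", "strand", "coil"), length,
                         plddt_mean, plddt_sd = 0, disordered = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length >= 1, plddt_mean >= 0, plddt_mean <= 100, plddt_sd >= 0)
  structure(list(kind = kind, length = as.integer(length),
                 plddt_mean = plddt_mean, plddt_sd = plddt_sd,
                 disordered = isTRUE(disordered)),
            class = "model_segment_spec")
}

# ideal alpha-helix Calpha trace: rise 1.5 A/residue, radius 2.3 A,
# 100 degrees/residue turn
helix_trace <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

# near-extended strand: 3.8 A Calpha-Calpha step with alternating pleat
strand_trace <- function(n) {
  i <- seq_len(n) - 1
  dy <- 1.0
  dx <- sqrt(3.8^2 - dy^2)
  cbind(dx * i, 0.5 * dy * (-1)^i, rep(0, n))
}

runif_sphere <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# self-avoiding random walk with 3.8 A steps and a clash radius, grown from
# `start`; `existing` are coordinates the walk must also avoid. The 3.8 A
# step already exceeds the 2.5 A clash radius, so the immediate predecessor
# never triggers a rejection.
coil_trace <- function(n, start, existing, clash = 2.5, max_retry = 1000) {
  out <- matrix(NA_real_, n, 3)
  out[1, ] <- start
  pts <- rbind(existing, matrix(start, 1))
  for (i in seq_len(n - 1)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cand <- out[i, ] + 3.8 * runif_sphere()
      if (min(rowSums(sweep(pts, 2, cand)^2)) >= clash^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("self-avoiding walk failed after ", max_retry,
           " retries; try fewer/shorter coil segments")
    }
    out[i + 1, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# place a rigid segment trace so its first residue continues the chain at a
# 3.8 A step, retrying orientations until no clash with existing points
place_segment <- function(trace, prev_end, existing, clash = 2.5,
                          max_retry = 200) {
  if (is.null(prev_end)) return(trace)
  for (try in seq_len(max_retry)) {
    rot <- random_rotation()
    tr <- trace %*% t(rot)
    anchor <- prev_end + 3.8 * runif_sphere()
    tr <- sweep(tr, 2, tr[1, ] - anchor, "-")
    if (is.null(existing) || nrow(existing) == 0) return(tr)
    # cross-distances between the chain so far and the candidate placement;
    # the junction pair itself sits at 3.8 A by construction and is exempt
    cross <- as.matrix(stats::dist(rbind(existing, tr)))[
      seq_len(nrow(existing)), nrow(existing) + seq_len(nrow(tr)), drop = FALSE]
    cross[nrow(existing), 1] <- Inf
    if (min(cross) >= clash) return(tr)
  }
  stop("could not place segment without clashes after ", max_retry, " retries")
}

#' Generate a synthetic AlphaFold-like model with known disorder labels
#'
#' Builds a Calpha trace from ordered segments: helices use ideal alpha-helix
#' geometry (1.5 A rise, 2.3 A radius, 100 degrees/residue), strands are
#' near-extended 3.8 A steps with an alternating pleat, and coils are 3.8 A
#' self-avoiding random walks (2.5 A clash radius). Consecutive Calpha-Calpha
#' distances always fall in \[3.5, 4.1\] A. Per-residue pLDDT is drawn
#' Normal(mean, sd) clipped to \[0, 100\]; with `ar1_rho > 0` the noise is an
#' AR(1) process so that smoothing-based operations see realistic
#' autocorrelation. The disorder annotation is the segment's `disordered`
#' flag. Fixed seed gives bit-identical output.
#'
#' What this emulates -- and does not: segment-level geometry and a pLDDT
#' profile correlated with order/disorder, not real side chains, packing or
#' the pLDDT-structure coupling of a real network.
#'
#' @param segments list of [segment_spec()]s.
#' @param seed integer seed.
#' @param ar1_rho AR(1) autocorrelation of the pLDDT noise in \[0, 1); default
#'   0 (i.i.d.).
#' @param chain chain identifier.
#' @return A list with elements `model` ([af2_model()]) and `annotation`
#'   ([disorder_annotation()]).
#' @export
synth_model <- function(segments, seed = 1, ar1_rho = 0, chain = "A") {
  if (inherits(segments, "model_segment_spec")) segments <- list(segments)
  stopifnot(length(segments) >= 1, ar1_rho >= 0, ar1_rho < 1)
  with_seed(seed, {
    coords <- NULL
    labels <- integer(0)
    plddt_mean <- numeric(0)
    plddt_sd <- numeric(0)
    for (sg in segments) {
      stopifnot(inherits(sg, "model_segment_spec"))
      prev_end <- if (is.null(coords)) NULL else coords[nrow(coords), ]
      tr <- switch(sg$kind,
        helix = place_segment(helix_trace(sg$length), prev_end, coords),
        strand = place_segment(strand_trace(sg$length), prev_end, coords),
        coil = {
          start <- if (is.null(prev_end)) c(0, 0, 0)
                   else prev_end + 3.8 * runif_sphere()
          coil_trace(sg$length, start,
                     if (is.null(coords)) matrix(numeric(0), 0, 3) else coords)
        })
      coords <- rbind(coords, tr)
      labels <- c(labels, rep(as.integer(sg$disordered), sg$length))
      plddt_mean <- c(plddt_mean, rep(sg$plddt_mean, sg$length))
      plddt_sd <- c(plddt_sd, rep(sg$plddt_sd, sg$length))
    }
    n <- nrow(coords)
    z <- rnorm(n)
    if (ar1_rho > 0) {
      for (i in 2:n) z[i] <- ar1_rho * z[i - 1] + sqrt(1 - ar1_rho^2) * z[i]
    }
    plddt <- pmin(pmax(plddt_mean + plddt_sd * z, 0), 100)
    aa <- sample(names(GGXGG_AA_VOLUMES), n, replace = TRUE)
    model <- af2_model(data.frame(
      chain = chain, resno = seq_len(n), aa = aa,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      plddt = plddt, stringsAsFactors = FALSE
    ), id = "synthetic")
    list(model = model, annotation = disorder_annotation(labels))
  })
}

#' Generate a block-structured synthetic PAE matrix
#'
#' Within-block entries are drawn Normal(`intra_mean`, `noise_sd`) and
#' between-block entries Normal(`inter_mean`, `noise_sd`), clipped at 0; the
#' diagonal is set to `intra_mean / 2`. This plants a known rigid-domain
#' partition for testing PAE community clustering.
#'
#' @param block_sizes integer vector of residue counts per block.
#' @param intra_mean within-block mean error (A); must be < `inter_mean`.
#' @param inter_mean between-block mean error (A).
#' @param noise_sd Gaussian noise SD (A).
#' @param seed integer seed.
#' @return A [pae_matrix()] with attribute `blocks` (the planted membership).
#' @export
synth_pae <- function(block_sizes, intra_mean = 2, inter_mean = 25,
                      noise_sd = 0.5, seed = 1) {
  stopifnot(all(block_sizes >= 1), intra_mean >= 0, inter_mean >= 0,
            noise_sd >= 0, intra_mean < inter_mean)
  with_seed(seed, {
    L <- sum(block_sizes)
    member <- rep(seq_along(block_sizes), block_sizes)
    same <- outer(member, member, "==")
    mu <- ifelse(same, intra_mean, inter_mean)
    vals <- matrix(pmax(rnorm(L * L, mu, noise_sd), 0), L, L)
    diag(vals) <- intra_mean / 2
    p <- pae_matrix(vals)
    attr(p, "blocks") <- member
    p
  })
}

#' Generate a synthetic homo-oligomer state scan with a planted true state
#'
#' Per state s, `n_models` pTM-like scores are drawn
#' Normal(base - gap * |s - true_state|, noise_sd) and clipped to \[0, 1\], so
#' the annotated state has the highest expected score and neighboring states
#' fall off by `gap` per step.
#'
#' @param true_state annotated oligomeric state (1..n_states).
#' @param n_states number of states scanned (default 4).
#' @param n_models models (score replicates) per state (default 5, matching
#'   the five AlphaFold2 pTM parameter sets).
#' @param gap score drop per state away from the truth (> 0).
#' @param noise_sd score noise SD.
#' @param base expected score at the true state (default 0.85).
#' @param seed integer seed.
#' @return An `oligomer_scan` object (see [oligomer_scan()]).
#' @export
synth_oligomer_scan <- function(true_state, n_states = 4, n_models = 5,
                                gap = 0.2, noise_sd = 0.05, base = 0.85,
                                seed = 1) {
  stopifnot(true_state >= 1, true_state <= n_states, gap > 0, noise_sd >= 0)
  with_seed(seed, {
    scores <- lapply(seq_len(n_states), function(s) {
      pmin(pmax(rnorm(n_models, base - gap * abs(s - true_state), noise_sd),
                0), 1)
    })
    oligomer_scan(states = seq_len(n_states), scores = scores,
                  annotated_state = true_state)
  })
}

#' Generate a toy MSA of mutated query copies
#'
#' The query (row 1) is a uniform random amino-acid sequence; each further row
#' is a copy in which every column is substituted (to a different residue)
#' independently with probability `mutation_rate`.
#'
#' @param n_rows total rows including the query (>= 1).
#' @param length alignment width.
#' @param mutation_rate per-column substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @return An [msa()].
#' @export
synth_msa <- function(n_rows, length, mutation_rate = 0.1, seed = 1) {
  stopifnot(n_rows >= 1, length >= 1, mutation_rate >= 0, mutation_rate <= 1)
  aas <- names(GGXGG_AA_VOLUMES)
  with_seed(seed, {
    query <- sample(aas, length, replace = TRUE)
    seqs <- character(n_rows)
    seqs[1] <- paste(query, collapse = "")
    if (n_rows > 1) {
      for (r in 2:n_rows) {
        row <- query
        hit <- runif(length) < mutation_rate
        if (any(hit)) {
          row[hit] <- vapply(row[hit], function(a) sample(setdiff(aas, a), 1),
                             character(1))
        }
        seqs[r] <- paste(row, collapse = "")
      }
    }
    msa(c("query", if (n_rows > 1) paste0("seq", 2:n_rows)), seqs)
  })
}

#' Plant a binding site and decoy pockets on a model
#'
#' The site is grown from a random seed residue by 3D Calpha proximity
#' (`n_site` nearest residues). The "true" pocket is a point cloud at those
#' residues' Calpha positions plus uniform jitter; the returned known site is
#' the closure of that cloud under the [pocket_residues()] contact mapping, so
#' the true pocket reproduces its own site exactly (overlap F-score 1). Decoy
#' pockets are jittered clouds centered at residues >= `decoy_min_dist` A from
#' every site residue, so they share no residues with the site (F-score 0).
#'
#' @param model an [af2_model()].
#' @param n_site number of core site residues (<= model length).
#' @param n_decoys number of decoy pockets.
#' @param seed integer seed.
#' @param jitter half-width (A) of the uniform point jitter.
#' @param decoy_min_dist minimum decoy-to-site distance (A), default 15.
#' @return List with `site` (0-based residue indices), `true_pocket` and
#'   `decoys` (list) as `pocket_prediction` objects.
#' @export
synth_binding_site <- function(model, n_site, n_decoys = 2, seed = 1,
                               jitter = 0.4, decoy_min_dist = 15) {
  stopifnot(inherits(model, "af2_model"), n_site >= 1,
            n_site <= length(model), n_decoys >= 0)
  with_seed(seed, {
    xyz <- ca_xyz(model)
    seed_res <- sample(nrow(xyz), 1)
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[seed_res, ])^2))
    core <- order(d)[seq_len(n_site)]
    pts <- xyz[core, , drop = FALSE] +
      matrix(runif(3 * n_site, -jitter, jitter), ncol = 3)
    true_pocket <- pocket_prediction("true", pts, score = 1)
    site <- pocket_residues(true_pocket, model)
    site_xyz <- xyz[site + 1L, , drop = FALSE]
    dmin_site <- apply(xyz, 1, function(p) {
      min(sqrt(rowSums(sweep(site_xyz, 2, p)^2)))
    })
    far <- which(dmin_site >= decoy_min_dist + 2 * jitter)
    if (length(far) < n_decoys) {
      stop("model too small/compact to place ", n_decoys,
           " decoys >= ", decoy_min_dist, " A from the site")
    }
    centers <- sample(far, n_decoys)
    decoys <- lapply(seq_len(n_decoys), function(k) {
      p <- sweep(matrix(runif(15, -jitter, jitter), ncol = 3), 2,
                 xyz[centers[k], ], "+")
      pocket_prediction(paste0("decoy", k), p, score = runif(1, 0, 0.5))
    })
    list(site = site, true_pocket = true_pocket, decoys = decoys)
  })
}

#' Build an ideal all-atom helical backbone
#'
#' Constructs N, CA, C (and O) backbone atoms for an n-residue polyalanine
#' chain from internal coordinates (bond lengths N-CA 1.458 A, CA-C 1.525 A,
#' C-N 1.329 A; standard angles; omega fixed at 180 degrees), placed by the
#' natural-extension reference frame. Useful as a geometry fixture for
#' torsion-restraint generation, where a Calpha-only trace is not enough.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees (defaults: ideal alpha helix).
#' @param plddt constant pLDDT assigned to every residue.
#' @return An [af2_model()] with a full backbone atom table.
#' @export
synth_backbone_helix <- function(n, phi = -57, psi = -47, plddt = 90) {
  stopifnot(n >= 2)
  # internal coordinates per backbone atom, cycled N -> CA -> C
  place <- function(a, b, c, bond, angle, torsion) {
    # NeRF: place the next atom at distance `bond` from c, angle at c, and
    # the given torsion about b-c
    ang <- angle * pi / 180
    tor <- torsion * pi / 180
    d2 <- c(bond * cos(pi - ang),
            bond * sin(pi - ang) * cos(tor),
            bond * sin(pi - ang) * sin(tor))
    bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
    ab <- (b - a)
    nv <- pracma_cross(ab, bc); nv <- nv / sqrt(sum(nv^2))
    m <- cbind(bc, pracma_cross(nv, bc), nv)
    c(m %*% d2) + c
  }
  atoms <- list(
    c(0, 0, 0),            # N1
    c(1.458, 0, 0),        # CA1
    NULL                   # C1 placed below
  )
  # C1 via a dummy atom to define the first frame
  dummy <- c(-0.5, 1, 0)
  atoms[[3]] <- place(dummy, atoms[[1]], atoms[[2]], 1.525, 111.2, phi)
  names_seq <- c("N", "CA", "C")
  coords <- do.call(rbind, atoms)
  atom_names <- names_seq
  resno <- c(1L, 1L, 1L)
  for (i in 2:n) {
    k <- nrow(coords)
    Ni <- place(coords[k - 2, ], coords[k - 1, ], coords[k, ],
                1.329, 116.2, psi)
    CAi <- place(coords[k - 1, ], coords[k, ], Ni, 1.458, 121.7, 180)
    Ci <- place(coords[k, ], Ni, CAi, 1.525, 111.2, phi)
    coords <- rbind(coords, Ni, CAi, Ci)
    atom_names <- c(atom_names, names_seq)
    resno <- c(resno, rep(i, 3L))
  }
  ca <- atom_names == "CA"
  res <- data.frame(chain = "A", resno = unique(resno), aa = "A",
                    x = coords[ca, 1], y = coords[ca, 2], z = coords[ca, 3],
                    plddt = plddt, stringsAsFactors = FALSE)
  at <- data.frame(chain = "A", resno = resno, atom = atom_names,
                   element = substr(atom_names, 1, 1),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   o = 1, b = plddt, stringsAsFactors = FALSE)
  af2_model(res, atoms = at, id = "ideal_helix")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
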