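# Mean residue volumes (A^3) used to derive effective Calpha-sphere radii for
# the coarse SASA fallback (one sphere per residue, r = (3V / 4 pi)^(1/3)).
GGXGG_AA_VOLUMES <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

# Theoretical maximum accessible surface area (A^2) of residue X in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013), used to normalize
# all-atom absolute SASA to relative SASA.
MAX_ASA_THEORETICAL <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0
)

# van der Waals radii by element for the all-atom path
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90)

aa_sphere_radius <- function(aa) {
  v <- GGXGG_AA_VOLUMES[aa]
  v[is.na(v)] <- mean(GGXGG_AA_VOLUMES)
  unname((3 * v / (4 * pi))^(1 / 3))
}

# deterministic near-uniform sphere points (golden-spiral / Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Counts, for each sphere, the fraction of `n_points` deterministic
#' golden-spiral test points on its probe-expanded surface that fall inside no
#' other probe-expanded sphere.
#'
#' @param xyz n x 3 coordinate matrix (sphere centers).
#' @param radii vector of n sphere radii (A).
#' @param probe probe radius (A), default 1.4 (water).
#' @param n_points test points per sphere, default 960.
#' @return Numeric vector of per-sphere accessible areas (A^2).
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, n >= 1)
  er <- radii + probe
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  # neighbor search radius: two largest expanded spheres touching
  cut2 <- (2 * max(er))^2
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (er[i] + er)^2 & seq_len(n) != i)
    surf <- sweep(pts * er[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, xyz[j, ])^2)
      acc <- acc & dj2 >= er[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * er[i]^2 * mean(acc)
  }
  out
}

#' Relative solvent-accessible surface area per residue
#'
#' For full-atom models, absolute SASA is computed per atom by Shrake-Rupley
#' (1.4 A probe, element van der Waals radii), summed per residue and divided
#' by the residue's maximum exposure in an extended Gly-X-Gly reference
#' conformation, so values may slightly exceed 1. For Calpha-only models a
#' coarse fallback is used (flagged in the `coarse` attribute): one sphere per
#' residue with a volume-derived radius, normalized by the free-sphere maximum
#' of the same estimator so that an isolated residue scores 1 by construction.
#'
#' @param model an [af2_model()].
#' @param probe probe radius (A), default 1.4.
#' @param n_points Shrake-Rupley test points, default 960.
#' @return Numeric vector of per-residue relative SASA (>= 0), with attribute
#'   `coarse = TRUE` when the Calpha fallback was used.
#' @export
relative_sasa <- function(model, probe = 1.4, n_points = 960) {
  stopifnot(inherits(model, "af2_model"))
  aa <- model$residues$aa
  unknown <- !aa %in% names(GGXGG_AA_VOLUMES)
  if (any(unknown)) {
    warning(sum(unknown), " residue(s) of unknown type; using average ",
            "reference surface")
  }
  has_atoms <- !is.null(model$atoms) &&
    any(!model$atoms$atom %in% "CA")
  if (has_atoms) {
    at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
    radii <- VDW_RADII[toupper(at$element)]
    radii[is.na(radii)] <- 1.70
    area <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]), radii,
                          probe = probe, n_points = n_points)
    key <- paste(at$chain, at$resno)
    per_res <- tapply(area, key, sum)
    rk <- paste(model$residues$chain, model$residues$resno)
    abs_sasa <- as.numeric(per_res[rk])
    abs_sasa[is.na(abs_sasa)] <- 0
    maxasa <- MAX_ASA_THEORETICAL[aa]
    maxasa[is.na(maxasa)] <- mean(MAX_ASA_THEORETICAL)
    out <- abs_sasa / unname(maxasa)
    attr(out, "coarse") <- FALSE
  } else {
    radii <- aa_sphere_radius(aa)
    area <- shrake_rupley(ca_xyz(model), radii, probe = probe,
                          n_points = n_points)
    out <- area / (4 * pi * (radii + probe)^2)
    attr(out, "coarse") <- TRUE
  }
  out
}

#' Centered moving-average smoothing
#'
#' Windowed mean with the window shrinking symmetrically at the termini, so
#' the output has the same length and stays within the input's range.
#'
#' @param values numeric vector.
#' @param window nominal window size in residues (>= 1), default 20.
#' @return Numeric vector of the same length.
#' @export
window_smooth <- function(values, window = 20) {
  if (window < 1) stop("window must be >= 1")
  n <- length(values)
  half <- floor(window / 2)
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  # symmetric shrink: use min(half, i-1, n-i) on both sides
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

#' Per-residue disorder score
#'
#' Higher scores mean more likely disordered. `plddt` maps confidence to
#' 1 - pLDDT/100; `rsa` is the relative solvent accessibility; the `_20`
#' variants apply a 20-residue centered moving average ([window_smooth()])
#' per chain before orientation.
#'
#' @param model an [af2_model()].
#' @param metric one of `"plddt"`, `"plddt_20"`, `"rsa"`, `"rsa_20"`.
#' @param window smoothing window for the `_20` variants (default 20).
#' @return Numeric vector of per-residue scores.
#' @export
disorder_score <- function(model, metric = c("plddt", "plddt_20", "rsa",
                                             "rsa_20"), window = 20) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "af2_model"))
  base <- switch(sub("_20$", "", metric),
    plddt = model$residues$plddt,
    rsa = as.numeric(relative_sasa(model))
  )
  if (grepl("_20$", metric)) {
    base <- unlist(lapply(model$chains, function(ch) {
      window_smooth(base[model$residues$chain == ch], window = window)
    }), use.names = FALSE)
  }
  if (grepl("^plddt", metric)) 1 - base / 100 else base
}

#' ROC curve and AUC for per-residue disorder prediction
#'
#' The AUC is computed by the rank statistic (Mann-Whitney U divided by
#' n1 * n0), with ties contributing 1/2; the curve is the standard step curve
#' over score thresholds.
#'
#' @param scores numeric vector, higher = more disordered.
#' @param labels a [disorder_annotation()] or a 0/1 vector of the same length.
#' @return List with `fpr`, `tpr` (step-curve coordinates) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (inherits(labels, "disorder_annotation")) labels <- labels$labels
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("ROC needs at least one positive and one negative label")
  }
  r <- rank(scores)   # midranks handle ties with weight 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1L)
  fp <- cumsum(labels[o] == 0L)
  # collapse tied thresholds to the last index of each tie group
  keep <- c(diff(scores[o]) != 0, TRUE)
  list(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1), auc = auc)
}
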