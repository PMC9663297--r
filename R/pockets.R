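#' Construct a pocket prediction
#'
#' A pocket as produced by a grid-based detector: a cloud of fill points with
#' the detector's ranking score.
#'
#' @param id pocket identifier.
#' @param points m x 3 matrix of fill-point coordinates (A), m >= 1.
#' @param score detector ranking score.
#' @return A `pocket_prediction` object.
#' @export
pocket_prediction <- function(id, points, score = NA_real_) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1) stop("a pocket needs at least one point")
  structure(list(id = id, points = points, score = score),
            class = "pocket_prediction")
}

#' @export
print.pocket_prediction <- function(x, ...) {
  cat(sprintf("<pocket_prediction> %s: %d points, score %.3g\n",
              x$id, nrow(x$points), x$score))
  invisible(x)
}

#' Read pocket predictions from a detector output file
#'
#' Accepts either a PDB-style fill-point file (each pseudo-atom record is one
#' pocket point; pockets distinguished by residue number) or a plain TSV with
#' columns `pocket_id`, `x`, `y`, `z`, `score`.
#'
#' @param path input file.
#' @return List of [pocket_prediction()] objects.
#' @export
read_pockets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50)
  if (any(grepl("^(ATOM|HETATM)", first))) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    out <- lapply(split(seq_len(nrow(at)), at$resno), function(i) {
      pocket_prediction(paste0("pocket", at$resno[i[1]]),
                        as.matrix(at[i, c("x", "y", "z")]),
                        score = mean(at$b[i]))
    })
    return(unname(out))
  }
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("pocket_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("pocket TSV needs columns: ", paste(need, collapse = ", "))
  }
  unname(lapply(split(tab, tab$pocket_id), function(d) {
    pocket_prediction(d$pocket_id[1], as.matrix(d[, c("x", "y", "z")]),
                      score = if ("score" %in% names(d)) d$score[1] else NA)
  }))
}

#' Map a pocket point cloud to its associated residues
#'
#' A residue is pocket-associated if any of its atoms lies within
#' `contact_cutoff` of any pocket point. For Calpha-only models the cutoff is
#' enlarged to `ca_fallback_cutoff` (flagged via the `coarse` attribute),
#' since side-chain atoms reach several Angstrom beyond the Calpha.
#'
#' @param pocket a [pocket_prediction()].
#' @param model an [af2_model()].
#' @param contact_cutoff heavy-atom contact cutoff (A), default 4.5.
#' @param ca_fallback_cutoff Calpha-only cutoff (A), default 8.
#' @return Sorted integer vector of 0-based residue indices, with attribute
#'   `coarse`.
#' @export
pocket_residues <- function(pocket, model, contact_cutoff = 4.5,
                            ca_fallback_cutoff = 8) {
  stopifnot(inherits(pocket, "pocket_prediction"),
            inherits(model, "af2_model"))
  has_atoms <- !is.null(model$atoms) && any(!model$atoms$atom %in% "CA")
  if (has_atoms) {
    at <- model$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    cut <- contact_cutoff
    key <- paste(at$chain, at$resno)
  } else {
    xyz <- ca_xyz(model)
    cut <- ca_fallback_cutoff
    key <- paste(model$residues$chain, model$residues$resno)
  }
  hit <- rep(FALSE, nrow(xyz))
  for (p in seq_len(nrow(pocket$points))) {
    d2 <- rowSums(sweep(xyz, 2, pocket$points[p, ])^2)
    hit <- hit | d2 <= cut^2
  }
  rk <- paste(model$residues$chain, model$residues$resno)
  out <- sort(model$residues$index[rk %in% unique(key[hit])])
  attr(out, "coarse") <- !has_atoms
  out
}

#' Confidence of a pocket from its associated residues
#'
#' @param pocket a [pocket_prediction()].
#' @param model an [af2_model()].
#' @param residues optional precomputed [pocket_residues()] result.
#' @param ... passed to [pocket_residues()].
#' @return List with `mean_plddt` and `quality` (`"high"` if mean pLDDT is
#'   strictly above 90, else `"low"`).
#' @export
pocket_confidence <- function(pocket, model, residues = NULL, ...) {
  if (is.null(residues)) residues <- pocket_residues(pocket, model, ...)
  if (!length(residues)) stop("pocket has no associated residues")
  m <- mean(model$residues$plddt[model$residues$index %in% residues])
  list(mean_plddt = m, quality = if (m > 90) "high" else "low")
}

#' Residue-level overlap metrics between predicted and known sites
#'
#' Confusion counts over `n_total` residues: TP = |P intersect K|,
#' FP = |P \\ K|, FN = |K \\ P|, TN = n_total - |P union K|. F-score is
#' `2 TP / (2 TP + FP + FN)`; MCC is the usual product-moment formula. A zero
#' denominator yields 0 for that metric.
#'
#' @param predicted,known integer vectors of residue indices (subsets of
#'   `0:(n_total - 1)`).
#' @param n_total total residue count.
#' @return List with `f_score`, `mcc` and the confusion counts.
#' @export
overlap_metrics <- function(predicted, known, n_total) {
  predicted <- unique(as.integer(predicted))
  known <- unique(as.integer(known))
  if (n_total < length(union(predicted, known))) {
    stop("n_total is smaller than |predicted union known|")
  }
  tp <- length(intersect(predicted, known))
  fp <- length(setdiff(predicted, known))
  fn <- length(setdiff(known, predicted))
  tn <- n_total - tp - fp - fn
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(f_score = f, mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Filter and rank enzyme candidates by pocket score
#'
#' Keeps models with mean pLDDT >= 70 (inclusive) and 100-500 residues, then
#' ranks them by the score of their top pocket, optionally discarding
#' candidates whose top pocket has low mean pLDDT.
#'
#' @param models list of [af2_model()]s.
#' @param pocket_scores numeric vector: top pocket score per model.
#' @param pocket_mean_plddt optional numeric vector of the top pocket's mean
#'   pLDDT per model, used with `min_pocket_plddt`.
#' @param min_pocket_plddt optional secondary filter: drop candidates whose
#'   top pocket mean pLDDT is below this value.
#' @param min_plddt,min_len,max_len the candidate filter (defaults 70,
#'   100, 500).
#' @return Data frame `index`, `n_residues`, `mean_plddt`, `pocket_score`,
#'   ranked by decreasing pocket score.
#' @export
enzyme_candidate_filter <- function(models, pocket_scores,
                                    pocket_mean_plddt = NULL,
                                    min_pocket_plddt = NULL,
                                    min_plddt = 70, min_len = 100,
                                    max_len = 500) {
  stopifnot(length(models) == length(pocket_scores))
  n_res <- vapply(models, length, integer(1))
  mp <- vapply(models, function(m) mean(m$residues$plddt), numeric(1))
  keep <- mp >= min_plddt & n_res >= min_len & n_res <= max_len
  if (!is.null(min_pocket_plddt)) {
    stopifnot(length(pocket_mean_plddt) == length(models))
    keep <- keep & pocket_mean_plddt >= min_pocket_plddt
  }
  out <- data.frame(index = which(keep), n_residues = n_res[keep],
                    mean_plddt = mp[keep], pocket_score = pocket_scores[keep])
  out[order(-out$pocket_score), , drop = FALSE]
}
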