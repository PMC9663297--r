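#' Gaussian smoothing of a per-residue profile
#'
#' Discrete Gaussian convolution with the kernel truncated at 4 sigma and a
#' reflective boundary (the edge value is repeated into the pad, as in the
#' usual 1-D image-filter convention). Output length equals input length.
#' This is the filter applied to the pLDDT profile before splitting a model
#' into high-confidence segments.
#'
#' @param values numeric vector (one value per residue).
#' @param sigma kernel standard deviation in residues (> 0), default 5.
#' @return Numeric vector of the same length.
#' @export
smooth_gaussian <- function(values, sigma = 5) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  n <- length(values)
  if (n == 0) stop("empty input")
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  # reflective boundary with the edge value repeated:
  # ... c b a | a b c ... | ... c b a (applied repeatedly for short inputs)
  reflect <- function(j) {
    while (any(bad <- j < 1L | j > n)) {
      j[j < 1L] <- 1L - j[j < 1L]
      j[j > n] <- 2L * n + 1L - j[j > n]
    }
    j
  }
  padded <- values[reflect((1L - r):(n + r))]
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

segment_record <- function(chain, start, end, plddt) {
  data.frame(chain = chain, start = start, end = end, length = end - start,
             median_plddt = median(plddt), mean_plddt = mean(plddt),
             stringsAsFactors = FALSE)
}

# maximal runs of TRUE in a logical vector, as 0-based half-open [start, end)
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Split a model into high-confidence segments by smoothed pLDDT
#'
#' The pLDDT profile of each chain is Gaussian-smoothed (`sigma`) and the
#' chain is cut into maximal runs where the smoothed score is strictly above
#' `threshold`; runs shorter than `min_len` residues are discarded. This is
#' the trimming step that isolates well-predicted structural units before
#' shape-mer analysis.
#'
#' @param model an [af2_model()].
#' @param sigma Gaussian filter SD in residues (default 5).
#' @param threshold smoothed-pLDDT cutoff (strict `>`, default 70).
#' @param min_len minimum segment length in residues (default 50).
#' @return Data frame of segments: `chain`, `start`, `end` (0-based,
#'   half-open, model-wide indices), `length`, `median_plddt`, `mean_plddt`
#'   (raw pLDDT over the segment), sorted and non-overlapping.
#' @export
split_high_confidence <- function(model, sigma = 5, threshold = 70,
                                  min_len = 50) {
  stopifnot(inherits(model, "af2_model"),
            threshold >= 0, threshold <= 100, min_len >= 1)
  out <- list()
  for (ch in model$chains) {
    i <- which(model$residues$chain == ch)
    sm <- smooth_gaussian(model$residues$plddt[i], sigma = sigma)
    rr <- runs_of(sm > threshold)
    rr <- rr[rr$end - rr$start >= min_len, , drop = FALSE]
    off <- i[1] - 1L   # chain offset into model-wide 0-based indexing
    for (j in seq_len(nrow(rr))) {
      sel <- i[(rr$start[j] + 1):rr$end[j]]
      out[[length(out) + 1]] <- segment_record(
        ch, off + rr$start[j], off + rr$end[j], model$residues$plddt[sel])
    }
  }
  if (!length(out)) {
    return(segment_record("", 0L, 1L, 0)[0, ])
  }
  do.call(rbind, out)
}

#' Find uncovered domain-like regions
#'
#' Scans maximal contiguous runs of residues flagged `TRUE` in
#' `uncovered_mask` (e.g. residues with no experimental or homology model)
#' and reports those of domain-like length (`min_len` to `max_len` residues)
#' whose median raw pLDDT is strictly above `plddt_threshold` -- candidate
#' novel folded domains rather than termini or linkers.
#'
#' @param model an [af2_model()].
#' @param uncovered_mask logical vector, one entry per residue.
#' @param min_len,max_len length bounds in residues (defaults 100 and 500).
#' @param plddt_threshold median-pLDDT cutoff (strict `>`, default 70).
#' @param use_smoothed use the sigma = 5 smoothed profile for the median
#'   instead of raw scores (default `FALSE`).
#' @return Data frame of regions in the [split_high_confidence()] layout.
#' @export
find_domain_like_regions <- function(model, uncovered_mask, min_len = 100,
                                     max_len = 500, plddt_threshold = 70,
                                     use_smoothed = FALSE) {
  stopifnot(inherits(model, "af2_model"))
  if (length(uncovered_mask) != length(model)) {
    stop("uncovered_mask length (", length(uncovered_mask),
         ") does not match model length (", length(model), ")")
  }
  scores <- if (use_smoothed) {
    unlist(lapply(model$chains, function(ch) {
      smooth_gaussian(model$residues$plddt[model$residues$chain == ch])
    }))
  } else model$residues$plddt
  rr <- runs_of(as.logical(uncovered_mask))
  out <- list()
  for (j in seq_len(nrow(rr))) {
    len <- rr$end[j] - rr$start[j]
    if (len < min_len || len > max_len) next
    sel <- (rr$start[j] + 1):rr$end[j]
    if (median(scores[sel]) > plddt_threshold) {
      out[[length(out) + 1]] <- segment_record(
        model$residues$chain[sel[1]], rr$start[j], rr$end[j],
        scores[sel])
    }
  }
  if (!length(out)) return(segment_record("", 0L, 1L, 0)[0, ])
  do.call(rbind, out)
}

#' Per-model pLDDT summary
#'
#' @param model an [af2_model()].
#' @return A one-row data frame with `mean`, `median`, `frac_confident`
#'   (fraction of residues with pLDDT strictly > 70) and `frac_very_high`
#'   (strictly > 90).
#' @export
plddt_summary <- function(model) {
  stopifnot(inherits(model, "af2_model"), length(model) >= 1)
  p <- model$residues$plddt
  data.frame(mean = mean(p), median = median(p),
             frac_confident = mean(p > 70),
             frac_very_high = mean(p > 90))
}
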