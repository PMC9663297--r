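#' Construct a homo-oligomer state scan
#'
#' Bookkeeping container for a copy-number scan: for each candidate
#' oligomeric state, the pTM-like scores of the models predicted for that
#' state (typically the five pTM parameter sets), with an optional annotated
#' true state.
#'
#' @param states integer vector of copy numbers scanned (e.g. 1:4).
#' @param scores list (same length as `states`) of numeric score vectors in
#'   \[0, 1\], each non-empty.
#' @param annotated_state optional annotated true state (must be in `states`).
#' @return An `oligomer_scan` object.
#' @export
oligomer_scan <- function(states, scores, annotated_state = NULL) {
  states <- as.integer(states)
  stopifnot(length(states) >= 1, length(scores) == length(states))
  for (s in seq_along(scores)) {
    if (!length(scores[[s]])) stop("state ", states[s], " has no scores")
    if (any(scores[[s]] < 0 | scores[[s]] > 1)) {
      stop("pTM scores must lie in [0, 1]")
    }
  }
  if (!is.null(annotated_state) && !annotated_state %in% states) {
    stop("annotated_state must be one of the scanned states")
  }
  structure(list(states = states, scores = scores,
                 annotated_state = annotated_state),
            class = "oligomer_scan")
}

#' @export
print.oligomer_scan <- function(x, ...) {
  agg <- vapply(x$scores, min, numeric(1))
  cat(sprintf("<oligomer_scan> states %s; worst-of-models %s%s\n",
              paste(x$states, collapse = ","),
              paste(sprintf("%.2f", agg), collapse = ","),
              if (is.null(x$annotated_state)) ""
              else sprintf("; annotated %d", x$annotated_state)))
  invisible(x)
}

#' Expand an MSA for an N-copy homo-oligomer prediction
#'
#' The alignment is copied once per subunit, each copy padded with gaps to
#' the full `copies * width` and placed in its own column block, then
#' concatenated row-wise; a query row consisting of the query sequence
#' repeated in every block is prepended so the target sequence covers all
#' copies. Every non-query row therefore has non-gap characters in at most
#' one block.
#'
#' @param x an [msa()] (query first; the query row is assumed gap-free).
#' @param copies number of subunits (>= 1).
#' @return An [msa()] of width `copies * width` with
#'   `copies * n + 1` rows.
#' @export
expand_msa_homooligomer <- function(x, copies) {
  stopifnot(inherits(x, "msa"))
  if (copies < 1) stop("copies must be >= 1")
  copies <- as.integer(copies)
  L <- x$width
  gap_block <- strrep("-", L)
  ids <- paste0("query_x", copies)
  seqs <- strrep(x$seqs[1], copies)
  for (j in seq_len(copies)) {
    pre <- strrep("-", (j - 1) * L)
    post <- strrep("-", (copies - j) * L)
    ids <- c(ids, paste0(x$ids, "_copy", j))
    seqs <- c(seqs, paste0(pre, x$seqs, post))
  }
  msa(ids, seqs)
}

#' Residue renumbering for a merged heterodimer chain
#'
#' To let a single-chain predictor fold and dock two chains at once, both are
#' treated as one long chain with an artificial `gap`-residue numbering break
#' between them: chain A keeps 1..len_a and chain B becomes
#' `len_a + gap + 1 .. len_a + gap + len_b`. The mapping is invertible.
#'
#' @param len_a,len_b chain lengths (>= 1).
#' @param gap size of the numbering gap in residues (>= 1), default 200.
#' @return Data frame `chain` (`"A"`/`"B"`), `original`, `merged`.
#' @export
renumber_heterodimer <- function(len_a, len_b, gap = 200) {
  stopifnot(len_a >= 1, len_b >= 1)
  if (gap < 1) stop("gap must be >= 1")
  data.frame(
    chain = rep(c("A", "B"), c(len_a, len_b)),
    original = c(seq_len(len_a), seq_len(len_b)),
    merged = c(seq_len(len_a), len_a + gap + seq_len(len_b)),
    stringsAsFactors = FALSE)
}

#' Predict the oligomeric state from a scan
#'
#' Each state is aggregated to the worst (minimum) of its per-model scores --
#' a state only counts as supported if all parameter sets agree -- and the
#' predicted state is the aggregate argmax, ties broken toward the smaller
#' (more parsimonious) state.
#'
#' @param scan an [oligomer_scan()].
#' @param aggregate aggregation over a state's model scores: `"min"`
#'   (default) or `"mean"`.
#' @return List with `state` (predicted copy number) and `table` (data frame
#'   `state`, `aggregate`).
#' @export
predict_state <- function(scan, aggregate = c("min", "mean")) {
  stopifnot(inherits(scan, "oligomer_scan"))
  aggregate <- match.arg(aggregate)
  fn <- if (aggregate == "min") min else mean
  agg <- vapply(scan$scores, fn, numeric(1))
  o <- order(scan$states)
  best <- o[which.max(agg[o])]   # which.max takes the first (= smallest state)
  list(state = scan$states[best],
       table = data.frame(state = scan$states, aggregate = agg))
}

#' Was a state scan successful?
#'
#' Success means the scan peak matches the annotated state, or the state
#' right after the annotated one scores substantially lower -- at least
#' `margin` below the annotated state's aggregate -- so the scan still flags
#' the annotated state as the last well-supported one.
#'
#' @param scan an [oligomer_scan()] with `annotated_state` set.
#' @param margin required score drop, default 0.1.
#' @param aggregate see [predict_state()].
#' @return Logical.
#' @export
scan_success <- function(scan, margin = 0.1, aggregate = "min") {
  stopifnot(inherits(scan, "oligomer_scan"))
  if (is.null(scan$annotated_state)) {
    stop("scan has no annotated state")
  }
  pred <- predict_state(scan, aggregate = aggregate)
  if (pred$state == scan$annotated_state) return(TRUE)
  tab <- pred$table
  a <- tab$aggregate[tab$state == scan$annotated_state]
  nxt <- tab$aggregate[tab$state == scan$annotated_state + 1L]
  length(nxt) == 1 && (a - nxt) >= margin
}
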