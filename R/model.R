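#' Construct an AlphaFold-style model object
#'
#' `af2_model` is the package's central container: one record per residue with
#' chain id, author residue number, one-letter amino acid, Calpha coordinates
#' and the per-residue pLDDT confidence (0-100) that AlphaFold2 stores in the
#' B-factor column. Residues are indexed 0-based internally (`$index`); author
#' residue numbers are preserved as labels only.
#'
#' @param residues data frame with columns `chain`, `resno` (integer),
#'   `aa` (one-letter code), `x`, `y`, `z` (Angstrom), `plddt` (0-100).
#' @param atoms optional data frame of full-atom records with columns
#'   `chain`, `resno`, `atom`, `element`, `x`, `y`, `z`, `o`, `b`.
#' @param id optional model identifier.
#' @return An object of class `af2_model`.
#' @export
af2_model <- function(residues, atoms = NULL, id = NULL) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1)
  need <- c("chain", "resno", "aa", "x", "y", "z", "plddt")
  miss <- setdiff(need, names(residues))
  if (length(miss)) stop("residues is missing columns: ", paste(miss, collapse = ", "))
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  if (any(!is.finite(residues$plddt)) ||
      any(residues$plddt < 0 | residues$plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]")
  }
  if (any(!is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop("every residue needs a finite Calpha coordinate")
  }
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0)) {
      stop("residue numbers must be strictly increasing within chain ", ch)
    }
  }
  residues$index <- seq_len(nrow(residues)) - 1L
  rownames(residues) <- NULL
  m <- list(
    id = id,
    chains = unique(residues$chain),
    residues = residues,
    atoms = atoms
  )
  class(m) <- "af2_model"
  m
}

#' @export
print.af2_model <- function(x, ...) {
  cat(sprintf(
    "<af2_model%s> %d residues, %d chain(s) [%s], mean pLDDT %.2f%s\n",
    if (is.null(x$id)) "" else paste0(" ", x$id),
    nrow(x$residues), length(x$chains), paste(x$chains, collapse = ","),
    mean(x$residues$plddt),
    if (is.null(x$atoms)) ", Calpha-only" else sprintf(", %d atoms", nrow(x$atoms))
  ))
  invisible(x)
}

#' @export
length.af2_model <- function(x) nrow(x$residues)

# Calpha coordinate matrix (n x 3)
ca_xyz <- function(model) {
  as.matrix(model$residues[, c("x", "y", "z")])
}

#' Subset a model to a set of residues
#'
#' @param model an [af2_model()].
#' @param index 0-based residue indices to keep (in model order).
#' @return An `af2_model` containing only the selected residues (atoms, if
#'   present, are subset to the same residues). Internal indices are recomputed.
#' @export
model_subset <- function(model, index) {
  stopifnot(inherits(model, "af2_model"))
  keep <- model$residues$index %in% index
  if (!any(keep)) stop("subset selects no residues")
  res <- model$residues[keep, , drop = FALSE]
  atoms <- model$atoms
  if (!is.null(atoms)) {
    key <- paste(res$chain, res$resno)
    atoms <- atoms[paste(atoms$chain, atoms$resno) %in% key, , drop = FALSE]
  }
  af2_model(res[, setdiff(names(res), "index")], atoms = atoms, id = model$id)
}

#' Construct a predicted-aligned-error matrix object
#'
#' The PAE matrix gives the expected positional error (Angstrom) of residue i
#' when the predicted and true structures are superposed on residue j. It is
#' allowed to be asymmetric.
#'
#' @param values numeric LxL matrix, entries >= 0 Angstrom.
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("PAE matrix must be square")
  if (any(!is.finite(values))) stop("PAE matrix contains non-finite entries")
  if (any(values < 0)) stop("PAE entries must be >= 0")
  structure(list(values = values, n = nrow(values)), class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  asym <- max(abs(x$values - t(x$values)))
  cat(sprintf("<pae_matrix> %d x %d, mean %.2f A, %s\n", x$n, x$n,
              mean(x$values),
              if (asym > 1e-9) sprintf("asymmetric (max |PAE(i,j)-PAE(j,i)| = %.2f A)", asym)
              else "symmetric"))
  invisible(x)
}

#' Is a PAE matrix asymmetric?
#'
#' @param pae a [pae_matrix()].
#' @param tol numeric tolerance.
#' @return Logical.
#' @export
pae_is_asymmetric <- function(pae, tol = 1e-9) {
  max(abs(pae$values - t(pae$values))) > tol
}

#' Construct a multiple sequence alignment object
#'
#' @param ids character vector of row identifiers; the first row is the query.
#' @param seqs character vector of aligned sequences (amino acids plus `-`),
#'   all the same width.
#' @return An object of class `msa`.
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(seqs) >= 1)
  w <- unique(nchar(seqs))
  if (length(w) != 1) {
    bad <- ids[nchar(seqs) != nchar(seqs)[1]][1]
    stop("alignment rows have unequal width (first offending row: ", bad, ")")
  }
  structure(list(ids = as.character(ids), seqs = toupper(seqs), width = w,
                 n = length(seqs)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns, query: %s\n", x$n, x$width, x$ids[1]))
  invisible(x)
}

#' Construct a per-residue order/disorder annotation
#'
#' @param labels integer vector of 0 (ordered) / 1 (disordered), one per residue.
#' @param protein_id optional identifier.
#' @param resno optional author residue numbers (defaults to 1..n).
#' @return An object of class `disorder_annotation`.
#' @export
disorder_annotation <- function(labels, protein_id = NULL, resno = NULL) {
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop("disorder labels must be 0 or 1")
  structure(list(labels = labels,
                 protein_id = protein_id,
                 resno = resno %||% seq_along(labels)),
            class = "disorder_annotation")
}
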