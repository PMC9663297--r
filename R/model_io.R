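#' Read an AlphaFold-style model from PDB or mmCIF
#'
#' Builds an [af2_model()] with one record per residue that has a Calpha atom.
#' The per-residue confidence (pLDDT) is taken from the Calpha B-factor field,
#' where AlphaFold2 stores it; B-factors of other atoms are ignored for
#' confidence. Chains are kept in file order. Multi-model files are reduced to
#' the first model with a warning. Residues without a Calpha atom are skipped
#' with a warning. B-factors outside \[0, 100\] are accepted (the file may be a
#' real experimental structure) but flagged with a warning and recorded in the
#' `plddt_is_bfactor` attribute.
#'
#' @param path path to a coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param keep_atoms keep the full-atom table (needed for all-atom SASA and
#'   torsion restraints)? Default `TRUE`.
#' @return An [af2_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif"),
                       keep_atoms = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE, multi = FALSE),
    error = function(e) stop("could not parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- "A"

  ca <- at[at$elety == "CA", , drop = FALSE]
  # residues present but lacking a Calpha are skipped
  key_all <- unique(paste(at$chain, at$resno, at$resid))
  key_ca <- paste(ca$chain, ca$resno, ca$resid)
  dropped <- setdiff(key_all, key_ca)
  if (length(dropped)) {
    warning(length(dropped), " residue(s) without a Calpha atom skipped: ",
            paste(head(dropped, 3), collapse = ", "),
            if (length(dropped) > 3) ", ...")
  }
  if (nrow(ca) == 0) stop("no Calpha atoms found in ", path)

  flagged <- any(ca$b < 0 | ca$b > 100)
  if (flagged) {
    warning("B-factors outside [0, 100]: treating them as plain B-factors, ",
            "not pLDDT (experimental structure?)")
  }
  res <- data.frame(
    chain = ca$chain,
    resno = ca$resno,
    aa = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z,
    plddt = if (flagged) pmin(pmax(ca$b, 0), 100) else ca$b,
    stringsAsFactors = FALSE
  )
  # insertion codes / non-monotonic author numbering: keep file order,
  # renumber sequentially so downstream matrix alignment stays unambiguous
  for (ch in unique(res$chain)) {
    i <- which(res$chain == ch)
    if (any(diff(res$resno[i]) <= 0)) {
      warning("non-increasing residue numbers in chain ", ch,
              " (insertion codes?); renumbering sequentially")
      res$resno[i] <- seq_along(i)
    }
  }
  atoms <- NULL
  if (keep_atoms) {
    atoms <- data.frame(
      chain = at$chain, resno = at$resno, atom = at$elety,
      element = if ("elesy" %in% names(at)) at$elesy else substr(at$elety, 1, 1),
      x = at$x, y = at$y, z = at$z,
      o = if (all(is.na(at$o))) 1 else at$o,
      b = at$b, stringsAsFactors = FALSE
    )
  }
  m <- af2_model(res, atoms = atoms,
                 id = sub("\\.(pdb|cif|mmcif|ent)$", "", basename(path),
                          ignore.case = TRUE))
  attr(m, "plddt_is_bfactor") <- flagged
  m
}

#' Write a model to PDB format
#'
#' Standard ATOM records at PDB precision (3 decimals on coordinates, 2 on
#' B-factors). The B-factor column carries the per-residue pLDDT unless
#' `b_override` is given, in which case every atom gets that constant value --
#' the convention used when preparing predicted models as molecular-replacement
#' search models.
#'
#' @param model an [af2_model()].
#' @param path output file path.
#' @param b_override optional constant B-factor applied to every atom.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, b_override = NULL) {
  stopifnot(inherits(model, "af2_model"))
  if (any(model$residues$resno > 9999)) {
    stop("residue numbers > 9999 cannot be written to PDB; renumber first")
  }
  if (!is.null(model$atoms) && nrow(model$atoms) > 0) {
    a <- model$atoms
    b <- if (is.null(b_override)) a$b else rep(b_override, nrow(a))
    res3 <- vapply(seq_len(nrow(a)), function(i) {
      j <- which(model$residues$chain == a$chain[i] &
                   model$residues$resno == a$resno[i])
      if (length(j)) bio3d::aa123(model$residues$aa[j[1]]) else "UNK"
    }, character(1))
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = res3, chain = a$chain,
                     elety = a$atom, o = a$o, b = b)
  } else {
    r <- model$residues
    b <- if (is.null(b_override)) r$plddt else rep(b_override, nrow(r))
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(ca_xyz(model))),
                     resno = r$resno, resid = bio3d::aa123(r$aa),
                     chain = r$chain, elety = rep("CA", nrow(r)),
                     o = rep(1, nrow(r)), b = b)
  }
  invisible(path)
}

#' Read an AlphaFold-DB-style PAE JSON file
#'
#' Accepts both public dialects and normalizes them to the same matrix: the
#' nested dialect (`predicted_aligned_error` as a list of rows, possibly
#' wrapped in a one-element array) and the flat dialect (parallel vectors
#' `residue1`, `residue2`, `distance` with 1-based indices).
#'
#' @param path path to the JSON file.
#' @return A [pae_matrix()].
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  # AFDB serves a one-element array around the object
  if (is.list(x) && is.null(names(x)) && length(x) == 1) x <- x[[1]]
  as_square <- function(v) {
    if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else as.matrix(v)
  }
  vals <- NULL
  if (!is.null(x$predicted_aligned_error)) {
    vals <- as_square(x$predicted_aligned_error)
  } else if (!is.null(x$pae)) {
    vals <- as_square(x$pae)
  } else if (!is.null(x$distance)) {
    r1 <- unlist(x$residue1); r2 <- unlist(x$residue2)
    d <- as.numeric(unlist(x$distance))
    if (length(r1) != length(d) || length(r2) != length(d)) {
      stop("flat PAE dialect has unequal residue1/residue2/distance lengths")
    }
    L <- max(r1, r2)
    vals <- matrix(NA_real_, L, L)
    vals[cbind(r1, r2)] <- d
    if (anyNA(vals)) {
      miss <- which(is.na(vals), arr.ind = TRUE)
      stop("flat PAE dialect missing ", nrow(miss), " index pair(s), e.g. (",
           paste(miss[1, ], collapse = ","), ")")
    }
  } else {
    stop("unrecognized PAE JSON: expected 'predicted_aligned_error' or ",
         "'residue1'/'residue2'/'distance' fields")
  }
  if (nrow(vals) != ncol(vals)) stop("PAE matrix is not square: ",
                                     nrow(vals), " x ", ncol(vals))
  if (any(vals < 0)) stop("PAE contains negative entries")
  pae_matrix(vals)
}

#' Read a multiple sequence alignment from FASTA or A3M
#'
#' A3M lowercase insertion states are removed (the standard a3m-to-aligned
#' convention), yielding a rectangular alignment with the query first.
#'
#' @param path input file.
#' @param format `"a3m"`, `"fasta"` or `"auto"` (by extension).
#' @return An [msa()].
#' @export
read_msa <- function(path, format = c("auto", "a3m", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty alignment file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE, forceDNAtolower = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("no sequences in ", path)
  ids <- names(seqs)
  s <- unlist(seqs, use.names = FALSE)
  if (format == "a3m") s <- gsub("[a-z.]", "", s)
  w <- nchar(s)
  if (length(unique(w)) != 1) {
    bad <- ids[w != w[1]][1]
    stop("ragged alignment after ", format, " normalization (row '", bad,
         "' has width ", w[w != w[1]][1], ", expected ", w[1], ")")
  }
  msa(ids, s)
}

#' Write an alignment to A3M/FASTA
#'
#' @param x an [msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  seqinr::write.fasta(as.list(x$seqs), names = x$ids, file.out = path)
  invisible(path)
}
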