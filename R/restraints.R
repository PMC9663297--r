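# Default adaptive-restraint coefficients. All distance-dependent parameters
# scale linearly with the reference distance d0 relative to d_ref_scale, so
# longer reference distances get wider wells, wider flat bottoms and faster
# top-out.
RESTRAINT_DEFAULTS <- list(
  kappa0 = 10,       # base strength, energy units
  d_ref_scale = 3,   # A; distance at which base widths apply
  w0 = 0.3,          # base wellHalfWidth at d0 = d_ref_scale (A)
  t0 = 0.075,        # base tolerance at d0 = d_ref_scale (A)
  f0 = 2             # base fallOff at d0 = d_ref_scale
)

#' Generate pLDDT-weighted adaptive distance restraints
#'
#' One restraint per Calpha pair of the reference model with reference
#' distance `d0 <= distance_cutoff` and sequence separation >= 3 (within a
#' chain), mapped onto the working model by chain id and residue number.
#' Base parameters grow linearly with d0: `wellHalfWidth = w0 * d0 / s`,
#' `tolerance = t0 * d0 / s`, `fallOff = f0 * d0 / s` (s = `d_ref_scale`).
#' With pLDDT weighting on, the lowest confidence p of the pair modulates
#' them: kappa is multiplied by `clip((p - 50) / 50, 0, 1)` (zero strength at
#' p = 50, full at p = 100) while tolerance and fallOff are multiplied by
#' `1 + (100 - p) / 50` (uncertain pairs get wider flat bottoms and faster
#' top-out). Pairs with p < 50 are disabled outright.
#'
#' @param working an [af2_model()] to be restrained.
#' @param reference the [af2_model()] providing target distances and pLDDT.
#' @param distance_cutoff maximum reference Calpha distance (A), default 8.
#' @param plddt_weighting apply the confidence modulation? Default `TRUE`.
#' @param min_seq_sep minimum within-chain sequence separation, default 3.
#' @param params coefficient list overriding `RESTRAINT_DEFAULTS` entries.
#' @return Data frame of restraints: `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `atom`, `target`, `kappa`, `wellHalfWidth`, `tolerance`,
#'   `fallOff`, `min_plddt`, `enabled`.
#' @export
make_distance_restraints <- function(working, reference, distance_cutoff = 8,
                                     plddt_weighting = TRUE, min_seq_sep = 3,
                                     params = list()) {
  stopifnot(inherits(working, "af2_model"), inherits(reference, "af2_model"),
            distance_cutoff > 0)
  p <- utils::modifyList(RESTRAINT_DEFAULTS, params)
  wk <- paste(working$residues$chain, working$residues$resno)
  rk <- paste(reference$residues$chain, reference$residues$resno)
  shared <- intersect(rk, wk)
  if (!length(shared)) stop("working and reference share no residues")
  ref <- reference$residues[match(shared, rk), , drop = FALSE]
  xyz <- as.matrix(ref[, c("x", "y", "z")])
  n <- nrow(ref)
  d <- as.matrix(stats::dist(xyz))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_chain <- ref$chain[i] == ref$chain[j]
      if (same_chain && abs(ref$resno[j] - ref$resno[i]) < min_seq_sep) next
      d0 <- d[i, j]
      if (d0 > distance_cutoff) next
      scale <- d0 / p$d_ref_scale
      kappa <- p$kappa0
      tol <- p$t0 * scale
      falloff <- p$f0 * scale
      whw <- p$w0 * scale
      minp <- min(ref$plddt[i], ref$plddt[j])
      enabled <- TRUE
      if (plddt_weighting) {
        if (minp < 50) {
          enabled <- FALSE
          kappa <- 0
        } else {
          kappa <- kappa * min(max((minp - 50) / 50, 0), 1)
        }
        tol <- tol * (1 + (100 - minp) / 50)
        falloff <- falloff * (1 + (100 - minp) / 50)
      }
      out[[length(out) + 1]] <- data.frame(
        chain_a = ref$chain[i], resno_a = ref$resno[i],
        chain_b = ref$chain[j], resno_b = ref$resno[j],
        atom = "CA", target = d0, kappa = kappa, wellHalfWidth = whw,
        tolerance = tol, fallOff = falloff, min_plddt = minp,
        enabled = enabled, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no restrainable pairs within the cutoff")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Energy and force of an adaptive (top-out) distance restraint
#'
#' With deviation `x = max(0, |r - target| - tolerance)` and
#' `c = wellHalfWidth`, the energy is
#' `E = kappa * (1 - exp(-x^2 / (2 c^2 (1 + fallOff * x / c))))`:
#' zero (and zero force) throughout the flat bottom, quadratic in x near the
#' bottom, with a restoring force that peaks around x ~ c and tapers toward
#' zero at large deviations for fallOff > 0 -- so a restraint that clearly
#' disagrees with the data stops pulling. Disabled restraints return (0, 0).
#'
#' @param restraint one row of [make_distance_restraints()] output (or any
#'   list with `target`, `kappa`, `wellHalfWidth`, `tolerance`, `fallOff`,
#'   `enabled`).
#' @param r current interatomic distance(s), A (> 0).
#' @return List with vectors `energy` and `force` (dE/dx magnitude).
#' @export
adaptive_energy <- function(restraint, r) {
  stopifnot(all(r > 0))
  if (!isTRUE(restraint$enabled) || restraint$kappa == 0) {
    return(list(energy = rep(0, length(r)), force = rep(0, length(r))))
  }
  kappa <- restraint$kappa
  cc <- restraint$wellHalfWidth
  f <- restraint$fallOff
  x <- pmax(0, abs(r - restraint$target) - restraint$tolerance)
  x[x < 1e-12] <- 0   # keep the flat bottom exactly flat at its boundary
  g <- x^2 / (2 * cc^2 * (1 + f * x / cc))
  e <- kappa * (1 - exp(-g))
  # dE/dx = kappa * exp(-g) * g'(x)
  gp <- (2 * x + f * x^2 / cc) / (2 * cc^2 * (1 + f * x / cc)^2)
  list(energy = e, force = kappa * exp(-g) * gp)
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 formulation of the angle between the two planes spanned by
#' (a, b, c) and (b, c, d), in degrees in (-180, 180\].
#'
#' @param a,b,c,d 3-vectors.
#' @return Angle in degrees, or `NA` for degenerate (collinear) geometry.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Generate torsion restraints against a reference model
#'
#' Restrains the working model's backbone phi/psi (and, where side-chain
#' atoms are present, chi1) torsions to the reference model's values.
#' Torsions on residues with pLDDT < 50 are disabled, consistent with the
#' distance-restraint scheme; degenerate (collinear) or incomplete torsions
#' are skipped with a warning.
#'
#' @param working an [af2_model()] (atom table required).
#' @param reference the reference [af2_model()] (atom table required).
#' @param strength restraint strength passed through to the output.
#' @return Data frame: `chain`, `resno`, `torsion` (`phi`/`psi`/`chi1`),
#'   `target` (degrees), `strength`, `enabled`.
#' @export
make_torsion_restraints <- function(working, reference, strength = 1) {
  stopifnot(inherits(working, "af2_model"), inherits(reference, "af2_model"))
  if (is.null(reference$atoms)) stop("reference model has no atom records")
  at <- reference$atoms
  getxyz <- function(ch, rn, name) {
    i <- which(at$chain == ch & at$resno == rn & at$atom == name)
    if (!length(i)) return(NULL)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  out <- list()
  skipped <- 0L
  for (ch in reference$chains) {
    rns <- reference$residues$resno[reference$residues$chain == ch]
    for (k in seq_along(rns)) {
      rn <- rns[k]
      plddt <- reference$residues$plddt[reference$residues$chain == ch &
                                          reference$residues$resno == rn]
      defs <- list()
      if (k > 1) {
        defs$phi <- list(getxyz(ch, rns[k - 1], "C"), getxyz(ch, rn, "N"),
                         getxyz(ch, rn, "CA"), getxyz(ch, rn, "C"))
      }
      if (k < length(rns)) {
        defs$psi <- list(getxyz(ch, rn, "N"), getxyz(ch, rn, "CA"),
                         getxyz(ch, rn, "C"), getxyz(ch, rns[k + 1], "N"))
      }
      cb <- getxyz(ch, rn, "CB"); cg <- getxyz(ch, rn, "CG")
      if (!is.null(cb) && !is.null(cg)) {
        defs$chi1 <- list(getxyz(ch, rn, "N"), getxyz(ch, rn, "CA"), cb, cg)
      }
      for (nm in names(defs)) {
        pts <- defs[[nm]]
        if (any(vapply(pts, is.null, logical(1)))) {
          skipped <- skipped + 1L
          next
        }
        ang <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        if (is.na(ang)) {
          skipped <- skipped + 1L
          next
        }
        out[[length(out) + 1]] <- data.frame(
          chain = ch, resno = rn, torsion = nm, target = ang,
          strength = strength, enabled = plddt >= 50,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0) {
    warning(skipped, " torsion(s) skipped (missing atoms or degenerate geometry)")
  }
  if (!length(out)) stop("no torsions could be restrained")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write distance restraints as TSV
#'
#' Plain flat-bottom-harmonic export consumable by refinement programs that
#' accept tabulated distance restraints.
#'
#' @param restraints output of [make_distance_restraints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  write.table(restraints, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
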