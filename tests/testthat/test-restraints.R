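helix_ref <- function(n = 40, plddt = 90, seed = 1) {
  m <- synth_model(segment_spec("helix", n, plddt, 0), seed = seed)$model
  m
}

test_that("restraint generation honors cutoff, separation and pLDDT gating", {
  ref <- helix_ref()
  rs <- make_distance_restraints(ref, ref, distance_cutoff = 8)
  expect_true(all(rs$target <= 8))
  expect_true(all(abs(rs$resno_b - rs$resno_a) >= 3))
  expect_true(all(rs$enabled))
  expect_true(all(rs$kappa > 0))

  # pair with min pLDDT 49 is disabled with zero strength
  ref2 <- ref
  ref2$residues$plddt[5] <- 49
  rs2 <- make_distance_restraints(ref2, ref2)
  touching <- rs2$resno_a == 5 | rs2$resno_b == 5
  expect_true(all(!rs2$enabled[touching]))
  expect_true(all(rs2$kappa[touching] == 0))
  expect_true(all(rs2$enabled == (rs2$min_plddt >= 50)))

  # p = 100 gives multiplier exactly 1 on kappa and tolerance
  ref3 <- ref
  ref3$residues$plddt[] <- 100
  rs3 <- make_distance_restraints(ref3, ref3)
  rs3_off <- make_distance_restraints(ref3, ref3, plddt_weighting = FALSE)
  expect_equal(rs3$kappa, rs3_off$kappa)
  expect_equal(rs3$tolerance, rs3_off$tolerance)
})

test_that("well width, tolerance and fallOff grow with reference distance", {
  ref <- helix_ref()
  rs <- make_distance_restraints(ref, ref, plddt_weighting = FALSE)
  short <- rs[which.min(rs$target), ]
  long <- rs[which.max(rs$target), ]
  expect_gt(long$target, short$target)
  expect_gt(long$wellHalfWidth, short$wellHalfWidth)
  expect_gt(long$tolerance, short$tolerance)
  expect_gt(long$fallOff, short$fallOff)
})

test_that("confidence multipliers are monotone with exact endpoints", {
  ref <- helix_ref()
  kappa_mult <- c(); tol_mult <- c()
  ps <- c(50, 60, 75, 90, 100)
  for (p in ps) {
    r <- ref
    r$residues$plddt[] <- p
    rs <- make_distance_restraints(r, r)
    rs0 <- make_distance_restraints(r, r, plddt_weighting = FALSE)
    kappa_mult <- c(kappa_mult, rs$kappa[1] / rs0$kappa[1])
    tol_mult <- c(tol_mult, rs$tolerance[1] / rs0$tolerance[1])
  }
  expect_true(all(diff(kappa_mult) > 0))
  expect_true(all(diff(tol_mult) < 0))
  expect_equal(kappa_mult[1], 0)
  expect_equal(kappa_mult[length(ps)], 1)
  expect_equal(tol_mult[length(ps)], 1)
})

test_that("pair selection is symmetric in working/reference roles", {
  ref <- helix_ref(seed = 2)
  work <- helix_ref(seed = 3)
  a <- make_distance_restraints(work, ref)
  b <- make_distance_restraints(ref, work)
  key <- function(d) paste(d$resno_a, d$resno_b)
  expect_setequal(key(a), key(b))
})

test_that("adaptive energy has a flat bottom, a single force peak and a tapering tail", {
  r <- list(target = 5, kappa = 10, wellHalfWidth = 0.5, tolerance = 0.2,
            fallOff = 1, enabled = TRUE)
  # inside the tolerance: exactly zero energy and force
  inside <- adaptive_energy(r, c(5, 5.1, 4.85, 5.2))
  expect_equal(inside$energy, rep(0, 4))
  expect_equal(inside$force, rep(0, 4))

  # disabled restraint contributes nothing
  rd <- r; rd$enabled <- FALSE
  expect_equal(adaptive_energy(rd, 12)$energy, 0)
  expect_equal(adaptive_energy(rd, 12)$force, 0)

  # dense sampling: energy continuous non-decreasing, force has one interior max
  x <- seq(0, 15 * r$wellHalfWidth, length.out = 4000)
  ef <- adaptive_energy(r, r$target + r$tolerance + x)
  expect_true(all(diff(ef$energy) >= -1e-12))
  peak <- which.max(ef$force)
  expect_gt(peak, 1)
  expect_lt(peak, length(x))
  expect_true(all(diff(ef$force[1:peak]) >= -1e-9))
  expect_true(all(diff(ef$force[peak:length(x)]) <= 1e-9))

  # analytic force equals the numerical derivative of the energy
  h <- 1e-6
  num <- (adaptive_energy(r, r$target + r$tolerance + x + h)$energy -
            adaptive_energy(r, r$target + r$tolerance + x - h)$energy) / (2 * h)
  expect_equal(ef$force, num, tolerance = 1e-6)

  # top-out: at 10x wellHalfWidth the force is below 20% of the peak
  f10 <- ef$force[which.min(abs(x - 10 * r$wellHalfWidth))]
  expect_lt(f10 / max(ef$force), 0.20)
})

test_that("torsion restraints reproduce ideal helix dihedrals", {
  hb <- synth_backbone_helix(12)
  tr <- make_torsion_restraints(hb, hb)
  interior <- tr[tr$resno %in% 3:10, ]
  expect_equal(mean(interior$target[interior$torsion == "phi"]), -57,
               tolerance = 2 / 57)
  expect_equal(mean(interior$target[interior$torsion == "psi"]), -47,
               tolerance = 2 / 47)
  expect_true(all(tr$enabled))

  # low-confidence residues are disabled
  hb2 <- hb
  hb2$residues$plddt[5] <- 40
  hb2$atoms$b[hb2$atoms$resno == 5] <- 40
  tr2 <- make_torsion_restraints(hb2, hb2)
  expect_true(all(!tr2$enabled[tr2$resno == 5]))

  # collinear atoms give a degenerate torsion: skipped with a warning
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))))
})

test_that("identical working and reference means zero torsion deviation", {
  hb <- synth_backbone_helix(8)
  tr <- make_torsion_restraints(hb, hb)
  # targets come from the reference; the working model's own dihedrals match
  at <- hb$atoms
  get <- function(rn, nm) as.numeric(at[at$resno == rn & at$atom == nm,
                                        c("x", "y", "z")])
  for (k in 2:7) {
    phi_t <- tr$target[tr$resno == k & tr$torsion == "phi"]
    phi_w <- dihedral(get(k - 1, "C"), get(k, "N"), get(k, "CA"), get(k, "C"))
    expect_equal(phi_w, phi_t, tolerance = 1e-9)
  }
})

test_that("dihedral sign convention matches an established implementation", {
  set.seed(71)
  for (rep_i in 1:5) {
    pts <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(pts)))),
                 tolerance = 1e-6)
  }
})
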