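test_that("template construction validates labels and exposes two terminal sulfurs", {
  tpl <- linker_template("trans", "RR")
  expect_s3_class(tpl, "linker_template")
  expect_identical(sum(tpl$atoms$element == "S"), 2L)
  expect_setequal(tpl$atoms$name[tpl$end_atoms], c("AS", "BS"))
  # sulfurs are termini of the kinematic graph: they appear in exactly one bond
  for (e in tpl$end_atoms)
    expect_identical(sum(tpl$bonds == e), 1L)
  expect_error(linker_template("zigzag", "RR"))
  expect_error(linker_template("trans", "RQ"))
})

test_that("reference conformer matches an independent forward-kinematics oracle", {
  tpl <- linker_template("trans", "RR")
  cf <- build_conformer(tpl)
  Xo <- oracle_build(tpl, cf$torsion_values)
  expect_lt(max(abs(cf$coordinates - Xo)), 1e-8)
  # S-S distance agrees with the oracle recomputation
  d_o <- sqrt(sum((Xo["AS", ] - Xo["BS", ])^2))
  expect_equal(end_to_end(cf), d_o, tolerance = 1e-10)
})

test_that("built conformers honour the template's ideal internal coordinates", {
  tpl <- linker_template("cis", "RS")
  cf <- build_conformer(tpl)
  X <- cf$coordinates
  zm <- tpl$zmat
  for (i in 2:nrow(zm)) {
    d <- sqrt(sum((X[i, ] - X[zm[i, "p"], ])^2))
    expect_equal(d, unname(zm[i, "r"]), tolerance = 1e-9)
  }
  # azo dihedral at its fixed cis value
  azo <- measure_dihedral(X["A1", ], X["N1", ], X["N2", ], X["B1", ])
  expect_equal(azo, 10, tolerance = 1e-6)
  # ring closures: benzene and succinimide closing bonds near ideal lengths
  expect_equal(sqrt(sum((X["A5", ] - X["A6", ])^2)), 1.39, tolerance = 1e-3)
  expect_equal(sqrt(sum((X["AC4r", ] - X["AC5r", ])^2)), 1.52, tolerance = 1e-2)
})

test_that("R/R and S/S templates are exact mirror images", {
  # the mirror image of R/R at torsions tau is S/S at -tau; for trans the
  # fixed torsions (azo 180, amides 180) are mirror-neutral, so the identity
  # is exact
  tplR <- linker_template("trans", "RR")
  tplS <- linker_template("trans", "SS")
  tau <- photoruler:::.reference_torsions(tplR)
  tau2 <- -tau
  # the succinimide attachment torsion carries a fixed +90 phase offset for
  # the slaved ring atom, which reflects to -90: shift by -180
  ring <- grepl("ch2_nring", names(tau))
  tau2[ring] <- -tau[ring] - 180
  c1 <- build_conformer(tplR, tau)
  c2 <- build_conformer(tplS, tau2)
  expect_equal(end_to_end(c1), end_to_end(c2), tolerance = 1e-9)
  expect_lt(max(abs(dist(c1$coordinates) - dist(c2$coordinates))), 1e-8)
})

test_that("cis R/R and S/S ensembles are statistically equivalent", {
  # the cis azo reference (+10 deg) makes the fixed frame weakly chiral, so
  # the R/R vs S/S identity holds only in distribution (twist signs are
  # sampled symmetrically)
  e1 <- sample_conformers(linker_template("cis", "RR"), 4000, seed = 17)
  e2 <- sample_conformers(linker_template("cis", "SS"), 4000, seed = 18)
  expect_lt(abs(mean(e1$ss) - mean(e2$ss)), 0.25)
  expect_lt(abs(sd(e1$ss) - sd(e2$ss)), 0.25)
})

test_that("stereo labels map to opposite signed-volume handedness", {
  # independent oracle: determinant of the three substituent vectors
  oracle_sign <- function(X, centre, subs) {
    m <- rbind(X[subs[1], ] - X[centre, ], X[subs[2], ] - X[centre, ],
               X[subs[3], ] - X[centre, ])
    sign(m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
           m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
           m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1]))
  }
  X <- build_conformer(linker_template("trans", "RS"))$coordinates
  sA <- oracle_sign(X, "AC3r", c("AS", "AC2r", "AC4r"))
  sB <- oracle_sign(X, "BC3r", c("BS", "BC2r", "BC4r"))
  expect_identical(sA, -sB)
  expect_identical(sA, chirality_sign(X, "AC3r", "AS", "AC2r", "AC4r"))
  # package convention: R is the positive sign
  expect_identical(sA, 1)
})

test_that("sampling is deterministic and respects fixed torsions and clashes", {
  tpl <- linker_template("trans", "SS")
  e1 <- sample_conformers(tpl, 100, seed = 11)
  e2 <- sample_conformers(tpl, 100, seed = 11)
  expect_identical(e1$torsions, e2$torsions)
  expect_identical(e1$n_accepted, 100L)

  e3 <- sample_conformers(tpl, 25, seed = 3, keep_coords = TRUE)
  cp <- photoruler:::.clash_pairs(tpl, 0.8)
  for (k in seq_len(25)) {
    X <- e3$coords[[k]]
    # azo dihedral fixed at 180 for every conformer
    azo <- abs(measure_dihedral(X[3, ], X[1, ], X[2, ], X[4, ]))
    expect_equal(azo, 180, tolerance = 1e-6)
    d2 <- (X[cp[, 1], 1] - X[cp[, 2], 1])^2 + (X[cp[, 1], 2] - X[cp[, 2], 2])^2 +
      (X[cp[, 1], 3] - X[cp[, 2], 3])^2
    expect_true(all(d2 >= cp[, 3]^2))
    # both stereocentres keep S-handedness across all conformers
    rownames(X) <- tpl$atoms$name
    expect_identical(chirality_sign(X, "AC3r", "AS", "AC2r", "AC4r"), -1)
    expect_identical(chirality_sign(X, "BC3r", "BS", "BC2r", "BC4r"), -1)
  }
})

test_that("an impossible clash cutoff raises the sampling diagnostic", {
  tpl <- linker_template("cis", "RR")
  expect_error(
    sample_conformers(tpl, 10, seed = 1, clash_cutoff = 2.5,
                      max_proposal_factor = 50),
    "torsion ranges")
})

test_that("end-to-end distance is a rigid-motion-invariant Euclidean distance", {
  cf <- build_conformer(linker_template("trans", "RR"))
  # direct two-point case
  cf2 <- cf
  cf2$coordinates[cf$end_atoms[1], ] <- c(0, 0, 0)
  cf2$coordinates[cf$end_atoms[2], ] <- c(5, 0, 0)
  expect_equal(end_to_end(cf2), 5)
  set.seed(42)
  for (i in 1:5) {
    rm_ <- random_rigid_motion()
    cfr <- cf
    cfr$coordinates <- apply_rigid(cf$coordinates, rm_)
    expect_equal(end_to_end(cfr), end_to_end(cf), tolerance = 1e-9)
  }
})

test_that("cis ensembles are shorter on average and broader than trans", {
  et <- sample_conformers(linker_template("trans", "RR"), 2000, seed = 5)
  ec <- sample_conformers(linker_template("cis", "RR"), 2000, seed = 5)
  expect_lt(mean(ec$ss), mean(et$ss))
  expect_lt(sd(et$ss), sd(ec$ss))
  # ordering holds for a looser clash cutoff too (0.9 and above reject every
  # conformer: the planar-anilide O...ring contact sits at 0.79 x vdW sum)
  et2 <- sample_conformers(linker_template("trans", "RR"), 800, seed = 6,
                           clash_cutoff = 0.7)
  ec2 <- sample_conformers(linker_template("cis", "RR"), 800, seed = 6,
                           clash_cutoff = 0.7)
  expect_lt(mean(ec2$ss), mean(et2$ss))
})

test_that("sampler converges to the exhaustive torsion-grid distribution", {
  # reduced 3-torsion chain: 6 sp3-like atoms, last-to-first distance under
  # three free torsions; compare MC sampling against full grid enumeration
  zm <- cbind(p = c(0, 1, 2, 3, 4, 5), g = c(0, 0, 1, 2, 3, 4),
              gg = c(0, 0, 0, 1, 2, 3), r = c(0, 1.5, 1.5, 1.5, 1.5, 1.5),
              theta = c(0, 0, 109.5, 109.5, 109.5, 109.5),
              phi = c(0, 0, 0, 0, 0, 0), tid = c(0, 0, 0, 1, 2, 3))
  tpl <- list(
    atoms = data.frame(name = paste0("C", 1:6), element = "C",
                       vdw = rep(0.1, 6)),
    bonds = cbind(2:6, 1:5), zmat = zm,
    rotatable_torsions = list(spec = matrix(
      c(1, 0, NA, 180, 0), 3, 5, byrow = TRUE,
      dimnames = list(paste0("t", 1:3),
                      c("mode", "c1", "c2", "hw", "sign_random")))),
    azo_state = "trans", stereo = "R/R", end_atoms = c(1L, 6L))
  class(tpl) <- "linker_template"
  ens <- sample_conformers(tpl, 20000, seed = 9)
  # exhaustive 10-degree grid oracle
  grid <- seq(-175, 175, by = 10)
  dd <- numeric(length(grid)^3)
  i <- 0
  for (t1 in grid) for (t2 in grid) for (t3 in grid) {
    i <- i + 1
    X <- photoruler:::.pr_build_coords(zm, c(t1, t2, t3))
    dd[i] <- sqrt(sum((X[6, ] - X[1, ])^2))
  }
  brks <- seq(0, 8, by = 0.5)
  h_mc <- hist(ens$ss, breaks = brks, plot = FALSE)$counts / length(ens$ss)
  h_gr <- hist(dd, breaks = brks, plot = FALSE)$counts / length(dd)
  expect_lt(sum(abs(h_mc - h_gr)) / 2, 0.05)  # total variation
})
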