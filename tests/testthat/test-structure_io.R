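test_that("PDB parsing is bit-exact, resolves altlocs and skips HETATM", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(c(
    atom_line(1, "CA", "ALA", "A", 10, 12.345, 67.890, -1.000),
    atom_line(2, "CB", "ALA", "A", 10, 1, 1, 1, occ = 0.6, altloc = "A"),
    atom_line(3, "CB", "ALA", "A", 10, 2, 2, 2, occ = 0.4, altloc = "B"),
    "HETATM    4  O   HOH A 501      0.000   0.000   0.000  1.00  0.00           O",
    atom_line(5, "CA", "GLY", "B", 10, 5, 5, 5),
    atom_line(6, "CA", "GLY", "C", 10, 9, 9, 9))), f)
  s <- read_channel_pdb(f)
  ca <- s$atoms[s$atoms$chain == "A" & s$atoms$atom == "CA", ]
  expect_identical(c(ca$x, ca$y, ca$z), c(12.345, 67.890, -1.000))
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_identical(nrow(cb), 1L)
  expect_identical(c(cb$x, cb$y, cb$z), c(1, 1, 1))  # occupancy 0.6 wins
  expect_false(any(s$atoms$resid == "HOH"))
  expect_identical(s$chains, c("A", "B", "C"))
})

test_that("equal-occupancy altlocs resolve alphabetically", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(c(
    atom_line(1, "CB", "ALA", "A", 1, 7, 7, 7, occ = 0.5, altloc = "B"),
    atom_line(2, "CB", "ALA", "A", 1, 3, 3, 3, occ = 0.5, altloc = "A"),
    atom_line(3, "CA", "ALA", "B", 1, 0, 0, 0),
    atom_line(4, "CA", "ALA", "C", 1, 1, 1, 1))), f)
  s <- read_channel_pdb(f)
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_identical(cb$x, 3)
})

test_that("malformed coordinates and empty files are rejected informatively", {
  f <- tempfile(fileext = ".pdb")
  bad <- atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  substr(bad, 31, 38) <- "  xx.yyy"
  writeLines(pdb_lines(c(bad,
    atom_line(2, "CA", "ALA", "B", 1, 0, 0, 0),
    atom_line(3, "CA", "ALA", "C", 1, 0, 0, 0))), f)
  expect_error(read_channel_pdb(f), "line 1")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f2)
  expect_error(read_channel_pdb(f2), "no ATOM")
})

test_that("structures round-trip through write and load to 3 decimals", {
  tri <- make_toy_trimer(toy_trimer_params("closed"))
  f <- tempfile(fileext = ".pdb")
  write_channel_pdb(tri, f)
  tri2 <- read_channel_pdb(f)
  expect_identical(nrow(tri2$atoms), nrow(tri$atoms))
  for (col in c("x", "y", "z"))
    expect_lt(max(abs(tri2$atoms[[col]] - round(tri$atoms[[col]], 3))), 5e-4)
  expect_identical(tri2$atoms$atom, tri$atoms$atom)
})

test_that("horizontal distances on a perfect C3 trimer are three equal values", {
  tri <- make_toy_trimer(toy_trimer_params("closed"))
  d <- interchain_distances(tri, residue_pair_spec("horizontal", 328))
  expect_identical(nrow(d), 3L)
  expect_lt(diff(range(d$distance)), 1e-6)
  expect_equal(attr(d, "mean"), mean(d$distance))
  expect_equal(attr(d, "sd"), sd(d$distance))
})

test_that("hand-placed anchors give the expected Pythagorean distance", {
  s <- point_trimer(list(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0)))
  d <- interchain_distances(s, residue_pair_spec("horizontal", 328))
  expect_equal(d$distance[d$pair == "A-B"], 5)
})

test_that("missing anchors are reported with guidance", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(c(
    atom_line(1, "CA", "GLY", "A", 50, 0, 0, 0),
    atom_line(2, "CA", "GLY", "B", 50, 5, 0, 0),
    atom_line(3, "CA", "GLY", "C", 50, 0, 5, 0))), f)
  s <- read_channel_pdb(f)
  expect_error(interchain_distances(s, residue_pair_spec("horizontal", 50)),
               "reconstruct_cb")
  expect_error(interchain_distances(s, residue_pair_spec("horizontal", 99)),
               "residue 99")
})

test_that("vertical distances follow the orientation convention", {
  tri <- make_toy_trimer(toy_trimer_params("open"))
  cw <- interchain_distances(tri, residue_pair_spec("vertical", 328, 345,
                                                    orientation = "clockwise"))
  ccw <- interchain_distances(tri, residue_pair_spec(
    "vertical", 328, 345, orientation = "counterclockwise"))
  # flipping orientation permutes the same pairing pattern cyclically:
  # on a C3 structure the three distances coincide within each orientation
  expect_lt(diff(range(cw$distance)), 1e-6)
  expect_lt(diff(range(ccw$distance)), 1e-6)
  expect_gt(abs(cw$distance[1] - ccw$distance[1]), 0.5)
  expect_error(residue_pair_spec("vertical", 328, 345), "orientation")
})

test_that("distances are invariant under rigid motions", {
  tri <- make_toy_trimer(toy_trimer_params("closed"))
  spec <- residue_pair_spec("vertical", 328, 345, orientation = "clockwise")
  d0 <- interchain_distances(tri, spec)$distance
  set.seed(7)
  for (i in 1:3) {
    trir <- transform_structure(tri, random_rigid_motion())
    expect_equal(interchain_distances(trir, spec)$distance, d0,
                 tolerance = 1e-9)
  }
})

test_that("CB reconstruction matches built CBs and transforms equivariantly", {
  tri <- make_toy_trimer(toy_trimer_params("closed"))
  a <- tri$atoms
  res <- a[a$chain == "A" & a$resno == 340, ]
  get <- function(at) as.numeric(res[res$atom == at, c("x", "y", "z")])
  cb <- reconstruct_cb(get("N"), get("CA"), get("C"))
  expect_lt(sqrt(sum((cb - get("CB"))^2)), 0.3)
  # equivariance
  set.seed(12)
  rm_ <- random_rigid_motion()
  cb2 <- reconstruct_cb(as.numeric(apply_rigid(rbind(get("N")), rm_)),
                        as.numeric(apply_rigid(rbind(get("CA")), rm_)),
                        as.numeric(apply_rigid(rbind(get("C")), rm_)))
  expect_equal(cb2, as.numeric(apply_rigid(rbind(cb), rm_)), tolerance = 1e-9)
  # degenerate collinear backbone
  expect_error(reconstruct_cb(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("coordination feasibility classifies by distance bands", {
  mk <- function(r) point_trimer(list(c(r / sqrt(3), 0, 0),
                                      c(-r / (2 * sqrt(3)), r / 2, 0),
                                      c(-r / (2 * sqrt(3)), -r / 2, 0)),
                                 resno = 343, atom = "CG")
  expect_identical(coordination_feasible(mk(5.5), 343)$call, "full")
  expect_identical(coordination_feasible(mk(9.0), 343)$call, "proximal")
  expect_identical(coordination_feasible(mk(20), 343)$call, "infeasible")
  # CB fallback when the named atom is absent
  s <- point_trimer(list(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0)), atom = "CB")
  r <- coordination_feasible(s, 328, atom = "CG")
  expect_identical(r$atom, "CB")
  expect_identical(r$call, "full")
})

test_that("the species residue map is bijective on its entries", {
  zf <- c(336, 353, 350, 351, 347, 343, 356, 358, 344)
  rat <- residue_map(zf, from = "zf")
  expect_false(any(is.na(rat)))
  expect_identical(residue_map(rat, from = "rat"), zf)
  expect_identical(residue_map(336, "zf"), 328)
  expect_identical(residue_map(345, "rat"), 353)
  expect_true(is.na(residue_map(999, "zf")))
})
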