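# Shared oracle helpers: independent implementations used only to check the
# package's results. They deliberately use different formulations (Rodrigues
# rotations, direct vector algebra) from the package internals.

# dihedral a-b-c-d in degrees, standard atan2 formulation (IUPAC sign)
measure_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  x <- sum(pracma_cross(b1, b2) * pracma_cross(b2, b3))
  y <- sqrt(sum(b2^2)) * sum(b1 * pracma_cross(b2, b3))
  atan2(y, x) * 180 / pi
}

measure_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# independent forward kinematics (matrix-chain oracle): build an explicit
# orthonormal frame from the a-side reference; at phi = 0 the new atom
# eclipses a, matching the IUPAC dihedral convention
oracle_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  e1 <- (c - b); e1 <- e1 / sqrt(sum(e1^2))
  w <- (a - b) - sum((a - b) * e1) * e1
  p_hat <- w / sqrt(sum(w^2))
  q_hat <- pracma_cross(e1, p_hat)
  u <- -cos(th) * e1 + sin(th) * (cos(ph) * p_hat + sin(ph) * q_hat)
  c + r * u
}

# rebuild a conformer's coordinates atom by atom with oracle_place
oracle_build <- function(template, torsions) {
  zm <- template$zmat
  n <- nrow(zm)
  X <- matrix(0, n, 3)
  X[2, ] <- c(zm[2, "r"], 0, 0)
  th <- zm[3, "theta"] * pi / 180
  X[3, ] <- c(zm[3, "r"] * cos(th), zm[3, "r"] * sin(th), 0)
  for (i in 4:n) {
    phi <- zm[i, "phi"] + if (zm[i, "tid"] > 0) torsions[zm[i, "tid"]] else 0
    X[i, ] <- oracle_place(X[zm[i, "gg"], ], X[zm[i, "g"], ], X[zm[i, "p"], ],
                           zm[i, "r"], zm[i, "theta"], phi)
  }
  rownames(X) <- template$atoms$name
  X
}

# random rigid motion (rotation + translation), seeded by caller
random_rigid_motion <- function() {
  ang <- stats::runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(R = rx %*% ry %*% rz, t = stats::runif(3, -20, 20))
}

apply_rigid <- function(X, rm) sweep(X %*% t(rm$R), 2, rm$t, "+")

# apply a rigid motion to a channel_structure
transform_structure <- function(struct, rm) {
  Xn <- apply_rigid(as.matrix(struct$atoms[, c("x", "y", "z")]), rm)
  struct$atoms$x <- Xn[, 1]; struct$atoms$y <- Xn[, 2]; struct$atoms$z <- Xn[, 3]
  struct
}

# minimal PDB text fixture builder
pdb_lines <- function(records) c(records, "END")

atom_line <- function(serial, name, res, chain, resno, x, y, z, occ = 1,
                      altloc = " ", element = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, res, chain, resno, x, y, z, occ, 0, element)
}

# three-chain point structure: one CB per chain at the given positions
point_trimer <- function(positions, resno = 328, atom = "CB") {
  lines <- character(0)
  chains <- c("A", "B", "C")
  for (i in seq_along(positions))
    lines <- c(lines, atom_line(i, atom, "ALA", chains[i], resno,
                                positions[[i]][1], positions[[i]][2],
                                positions[[i]][3], element = "C"))
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines(lines), f)
  read_channel_pdb(f)
}
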