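#' @useDynLib photoruler, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
NULL

# Bondi van der Waals radii (Angstrom) used for clash rejection.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Ideal small-molecule bond lengths (Angstrom); aromatic C-C 1.39, N=N 1.25,
# amide C-N 1.33, sp3 C-C 1.52, C-S 1.81, plus standard auxiliary values.
.bond <- c(ar_cc = 1.39, azo_nn = 1.25, azo_cn = 1.41, amide_cn = 1.33,
           aryl_n = 1.40, co = 1.23, sp3_cc = 1.52, ch2_n = 1.45,
           imide_cn = 1.39, ring_cc2 = 1.52, ring_cc3 = 1.53,
           ring_co = 1.21, cs = 1.81)

# Planar cyclic ring: given side lengths (cyclic order), interior angles (deg)
# of the circumscribed polygon. Used for the rigid succinimide 5-ring.
.ring_interior_angles <- function(sides) {
  f <- function(R) sum(2 * asin(sides / (2 * R))) - 2 * pi
  R <- stats::uniroot(f, c(max(sides) / 2 + 1e-9, 100))$root
  th <- cumsum(c(0, 2 * asin(sides / (2 * R))))[seq_along(sides)]
  pts <- cbind(R * cos(th), R * sin(th))
  k <- length(sides)
  vapply(seq_len(k), function(i) {
    p <- pts[i, ]
    v1 <- pts[if (i == 1) k else i - 1, ] - p
    v2 <- pts[if (i == k) 1 else i + 1, ] - p
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }, numeric(1))
}

#' Kinematic template of the reacted bifunctional azobenzene cross-linker
#'
#' Builds an internal-coordinate model of the bis(maleimido-glycine)azobenzene
#' cross-linker after maleimide--thiol addition at both ends: the chain
#' S--C(succinimide)--N(ring)--CH2--C(=O)--NH--phenyl--N=N--phenyl--NH--
#' C(=O)--CH2--N(ring)--C(succinimide)--S, heavy atoms only. The azo dihedral
#' is fixed per isomer (180 deg for \code{trans}; 10 deg for \code{cis}, with
#' the C-N=N angle opened to 122 deg and the phenyl rings twisted 53 deg out
#' of plane as in crystalline cis-azobenzene). Amide omega torsions are fixed
#' trans; benzene and succinimide rings are rigid and planar; succinimide
#' puckering is ignored. The two thioether-bearing ring carbons are
#' stereocentres whose handedness is set by \code{stereo}.
#'
#' @param isomer \code{"trans"} or \code{"cis"} azo configuration.
#' @param stereo stereoisomer label: \code{"RR"}, \code{"SS"}, \code{"RS"} or
#'   \code{"SR"} for the two stereocentres (first letter = arm attached at the
#'   first azo nitrogen).
#' @return An object of class \code{linker_template}: atom table (name,
#'   element, vdW radius), bond list, internal-coordinate table, rotatable
#'   torsion definitions with sampling ranges, azo state, stereo labels and
#'   the indices of the two terminal sulfur atoms.
#' @examples
#' tpl <- linker_template("trans", "RR")
#' nrow(tpl$atoms)
#' @export
linker_template <- function(isomer = c("trans", "cis"),
                            stereo = c("RR", "SS", "RS", "SR")) {
  isomer <- match.arg(isomer)
  stereo <- match.arg(stereo)
  hands <- strsplit(stereo, "")[[1]]

  azo_phi <- if (isomer == "trans") 180 else 10
  cnn <- if (isomer == "trans") 114 else 122
  twist_ref <- if (isomer == "trans") 0 else 53
  twist_hw <- if (isomer == "trans") 10 else 30

  sa <- .ring_interior_angles(c(.bond["imide_cn"], .bond["ring_cc2"],
                                .bond["ring_cc3"], .bond["ring_cc2"],
                                .bond["imide_cn"]))
  names(sa) <- c("N", "C2", "C3", "C4", "C5")
  exoN <- (360 - sa["N"]) / 2

  rows <- list()
  add <- function(name, elem, p, g, gg, r, th, ph, tid = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, elem = elem, p = p, g = g, gg = gg,
      r = r, theta = th, phi = ph, tid = tid, stringsAsFactors = FALSE)
    length(rows)
  }
  add("N1", "N", 0, 0, 0, 0, 0, 0)
  add("N2", "N", 1, 0, 0, .bond["azo_nn"], 0, 0)
  add("A1", "C", 1, 2, 0, .bond["azo_cn"], cnn, 0)
  add("B1", "C", 2, 1, 3, .bond["azo_cn"], cnn, azo_phi)

  # one arm: phenyl ring, glycinamide, succinimide ring, terminal S
  arm <- function(pref, ipso, nazo, nazo2, tw, am, ps1, ps2, hand) {
    i2 <- add(paste0(pref, "2"), "C", ipso, nazo, nazo2, .bond["ar_cc"], 120, 0, tw)
    add(paste0(pref, "6"), "C", ipso, nazo, nazo2, .bond["ar_cc"], 120, 180, tw)
    i3 <- add(paste0(pref, "3"), "C", i2, ipso, nazo, .bond["ar_cc"], 120, 180)
    i4 <- add(paste0(pref, "4"), "C", i3, i2, ipso, .bond["ar_cc"], 120, 0)
    add(paste0(pref, "5"), "C", i4, i3, i2, .bond["ar_cc"], 120, 0)
    iNam <- add(paste0(pref, "Nam"), "N", i4, i3, i2, .bond["aryl_n"], 120, 180)
    iC <- add(paste0(pref, "Cco"), "C", iNam, i4, i3, .bond["amide_cn"], 123, 0, am)
    add(paste0(pref, "Oco"), "O", iC, iNam, i4, .bond["co"], 123, 0)
    iCm <- add(paste0(pref, "Cm"), "C", iC, iNam, i4, .bond["sp3_cc"], 114, 180)
    iNr <- add(paste0(pref, "Nr"), "N", iCm, iC, iNam, .bond["ch2_n"], 109.5, 0, ps1)
    iC2 <- add(paste0(pref, "C2r"), "C", iNr, iCm, iC, .bond["imide_cn"], exoN, 90, ps2)
    iC5 <- add(paste0(pref, "C5r"), "C", iNr, iCm, iC, .bond["imide_cn"], exoN, 270, ps2)
    add(paste0(pref, "O2r"), "O", iC2, iNr, iCm, .bond["ring_co"], 125, 0)
    iC3 <- add(paste0(pref, "C3r"), "C", iC2, iNr, iCm, .bond["ring_cc2"], sa["C2"], 180)
    add(paste0(pref, "O5r"), "O", iC5, iNr, iCm, .bond["ring_co"], 125, 0)
    add(paste0(pref, "C4r"), "C", iC3, iC2, iNr, .bond["ring_cc3"], sa["C3"], 0)
    add(paste0(pref, "S"), "S", iC3, iC2, iNr, .bond["cs"], 110,
        if (hand == "R") -115 else 115)
  }
  endA <- arm("A", 3, 1, 2, 1L, 3L, 5L, 7L, hands[1])
  endB <- arm("B", 4, 2, 1, 2L, 4L, 6L, 8L, hands[2])

  zdf <- do.call(rbind, rows)
  zmat <- as.matrix(zdf[, c("p", "g", "gg", "r", "theta", "phi", "tid")])

  # bonds: parent links plus ring closures
  bonds <- cbind(2:nrow(zdf), zdf$p[-1])
  closures <- rbind(c("A5", "A6"), c("B5", "B6"),
                    c("AC4r", "AC5r"), c("BC4r", "BC5r"))
  for (k in seq_len(nrow(closures)))
    bonds <- rbind(bonds, match(closures[k, ], zdf$name))

  # rotatable torsion catalogue (azo dihedral and amide omegas excluded: fixed)
  # modes: 1 = uniform around one centre, 2 = two-lobe; sign_random flips the
  # whole twist value so both azo-twist enantiomers are visited.
  torspec <- rbind(
    phenyl_twist_A = c(1, twist_ref, NA, twist_hw, 1),
    phenyl_twist_B = c(1, twist_ref, NA, twist_hw, 1),
    aryl_amide_A   = c(2, 0, 180, 30, 0),
    aryl_amide_B   = c(2, 0, 180, 30, 0),
    gly_co_ch2_A   = c(2, 0, 180, 30, 0),
    gly_co_ch2_B   = c(2, 0, 180, 30, 0),
    gly_ch2_nring_A = c(2, 0, 180, 30, 0),
    gly_ch2_nring_B = c(2, 0, 180, 30, 0))
  colnames(torspec) <- c("mode", "c1", "c2", "hw", "sign_random")

  torsion_atoms <- list(
    phenyl_twist_A = c("A2", "A1", "N1", "N2"),
    phenyl_twist_B = c("B2", "B1", "N2", "N1"),
    aryl_amide_A = c("ACco", "ANam", "A4", "A3"),
    aryl_amide_B = c("BCco", "BNam", "B4", "B3"),
    gly_co_ch2_A = c("ANr", "ACm", "ACco", "ANam"),
    gly_co_ch2_B = c("BNr", "BCm", "BCco", "BNam"),
    gly_ch2_nring_A = c("AC2r", "ANr", "ACm", "ACco"),
    gly_ch2_nring_B = c("BC2r", "BNr", "BCm", "BCco"))

  out <- list(
    atoms = data.frame(name = zdf$name, element = zdf$elem,
                       vdw = unname(.vdw_radii[zdf$elem]),
                       stringsAsFactors = FALSE),
    bonds = unname(bonds),
    zmat = zmat,
    rotatable_torsions = list(spec = torspec, atoms = torsion_atoms),
    azo_state = isomer,
    azo_dihedral = azo_phi,
    stereo = paste(hands, collapse = "/"),
    end_atoms = c(endA, endB))
  class(out) <- "linker_template"
  out
}

#' @export
print.linker_template <- function(x, ...) {
  cat(sprintf("linker_template: %s azo (C-N=N-C %g deg), stereo %s, %d atoms, %d rotatable torsions\n",
              x$azo_state, x$azo_dihedral, x$stereo, nrow(x$atoms),
              nrow(x$rotatable_torsions$spec)))
  invisible(x)
}

# all-pairs bond-graph distances (BFS) on the template
.bond_graph_distances <- function(template) {
  n <- nrow(template$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(template$bonds))) {
    i <- template$bonds[k, 1]; j <- template$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][D[s, adj[[v]]] > D[s, v] + 1]
      D[s, nb] <- D[s, v] + 1
      queue <- c(queue, nb)
    }
  }
  D
}

# pairs separated by > 3 bonds, with clash cutoffs
.clash_pairs <- function(template, clash_cutoff) {
  D <- .bond_graph_distances(template)
  rv <- template$atoms$vdw
  idx <- which(upper.tri(D) & D > 3, arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2],
        clash_cutoff * (rv[idx[, 1]] + rv[idx[, 2]]))
}

# reference torsion values: phenyl twists at their reference, arm torsions anti
.reference_torsions <- function(template) {
  spec <- template$rotatable_torsions$spec
  ref <- spec[, "c1"]
  ref[c("gly_co_ch2_A", "gly_co_ch2_B")] <- 180
  ref
}

#' Cartesian coordinates of one conformer
#'
#' Forward kinematics: builds per-atom 3-D coordinates from the template's
#' internal-coordinate table and a vector of rotatable torsion values.
#'
#' @param template a [linker_template()].
#' @param torsions named or positional numeric vector of torsion values (deg),
#'   one per rotatable torsion; defaults to the reference (extended) values.
#' @return An object of class \code{conformer}: \code{coordinates} (n x 3
#'   matrix, Angstrom), \code{torsion_values}, and \code{clash_free}.
#' @export
build_conformer <- function(template, torsions = .reference_torsions(template)) {
  stopifnot(inherits(template, "linker_template"))
  spec <- template$rotatable_torsions$spec
  if (length(torsions) != nrow(spec))
    stop("expected ", nrow(spec), " torsion values")
  X <- .pr_build_coords(template$zmat, as.numeric(torsions))
  rownames(X) <- template$atoms$name
  cp <- .clash_pairs(template, 0.8)
  d2 <- (X[cp[, 1], 1] - X[cp[, 2], 1])^2 + (X[cp[, 1], 2] - X[cp[, 2], 2])^2 +
    (X[cp[, 1], 3] - X[cp[, 2], 3])^2
  out <- list(coordinates = X,
              torsion_values = setNames(as.numeric(torsions), rownames(spec)),
              clash_free = all(d2 >= cp[, 3]^2),
              end_atoms = template$end_atoms)
  class(out) <- "conformer"
  out
}

#' Sample clash-free conformers of the cross-linker
#'
#' Rejection sampling: rotatable torsions are drawn independently from their
#' allowed ranges (phenyl twists uniformly about the isomer reference with a
#' random enantiomeric sign; the conjugation-restrained amide and glycine-arm
#' torsions from two lobes at 0/180 +/- 30 deg), the conformer is built by
#' forward kinematics, and any conformer with a non-bonded pair (separated by
#' more than 3 bonds) closer than \code{clash_cutoff} times the sum of the two
#' Bondi vdW radii is rejected. The azo dihedral never varies. Deterministic
#' for a fixed seed.
#'
#' @param template a [linker_template()].
#' @param n number of accepted conformers required (>= 1).
#' @param seed integer seed.
#' @param clash_cutoff fraction of the vdW-radius sum below which two
#'   non-bonded atoms clash (default 0.8).
#' @param max_proposal_factor proposal budget, as a multiple of \code{n}.
#' @param keep_coords if TRUE, per-conformer coordinate matrices are retained
#'   (memory scales with \code{n}).
#' @return An object of class \code{conformer_ensemble}: the template, the
#'   accepted torsion matrix, S--S end-to-end distances, seed and acceptance
#'   counts.
#' @examples
#' ens <- sample_conformers(linker_template("trans", "RR"), n = 50, seed = 1)
#' mean(end_to_end(ens))
#' @export
sample_conformers <- function(template, n, seed, clash_cutoff = 0.8,
                              max_proposal_factor = 2000, keep_coords = FALSE) {
  stopifnot(inherits(template, "linker_template"), n >= 1)
  spec <- template$rotatable_torsions$spec
  spec[is.na(spec)] <- 0
  cp <- .clash_pairs(template, clash_cutoff)
  set.seed(seed)
  res <- .pr_sample_conformers(template$zmat, spec, cp,
                               as.integer(template$end_atoms), as.integer(n),
                               max_proposal_factor * n, keep_coords)
  if (res$n_accepted < n) {
    rate <- res$n_accepted / res$n_proposed
    ranges <- apply(template$rotatable_torsions$spec, 1, function(r)
      if (r["mode"] == 2) sprintf("{%g,%g}+/-%g", r["c1"], r["c2"], r["hw"])
      else sprintf("%g+/-%g%s", r["c1"], r["hw"],
                   if (r["sign_random"] == 1) " (sign-random)" else ""))
    stop(sprintf(paste0(
      "acceptance rate %.2e below budget (%d/%g proposals accepted); ",
      "offending torsion ranges: %s"),
      rate, res$n_accepted, res$n_proposed,
      paste(rownames(template$rotatable_torsions$spec), ranges,
            sep = "=", collapse = ", ")))
  }
  colnames(res$torsions) <- rownames(spec)
  out <- list(template = template, torsions = res$torsions, ss = res$ss,
              seed = seed, n_accepted = res$n_accepted,
              n_proposed = res$n_proposed, clash_cutoff = clash_cutoff,
              coords = if (keep_coords) res$coords else NULL)
  class(out) <- "conformer_ensemble"
  out
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(paste0("conformer_ensemble: %s/%s, n = %d (acceptance %.1f%%), ",
                     "S-S %.2f +/- %.2f A\n"),
              x$template$azo_state, x$template$stereo, x$n_accepted,
              100 * x$n_accepted / x$n_proposed, mean(x$ss), stats::sd(x$ss)))
  invisible(x)
}

#' S--S end-to-end distance
#'
#' Euclidean distance between the two terminal sulfur atoms of a conformer,
#' or the vector of distances stored in an ensemble.
#'
#' @param x a \code{conformer} or \code{conformer_ensemble}.
#' @return numeric vector of distances in Angstrom.
#' @export
end_to_end <- function(x) {
  if (inherits(x, "conformer_ensemble")) return(x$ss)
  stopifnot(inherits(x, "conformer"))
  p <- x$coordinates[x$end_atoms, ]
  sqrt(sum((p[1, ] - p[2, ])^2))
}

#' Signed-volume handedness of a stereocentre
#'
#' Sign of the determinant of the three substituent vectors (in the priority
#' order S, ring carbonyl-side carbon, ring methylene-side carbon) from the
#' stereocentre. Positive is labelled R, negative S, by the package's fixed
#' convention.
#'
#' @param coords n x 3 coordinate matrix with named rows.
#' @param centre,s,c_prev,c_next atom names: stereocentre, sulfur, the ring
#'   carbon on the carbonyl side and on the methylene side.
#' @return +1 or -1.
#' @export
chirality_sign <- function(coords, centre, s, c_prev, c_next) {
  v <- rbind(coords[s, ] - coords[centre, ],
             coords[c_prev, ] - coords[centre, ],
             coords[c_next, ] - coords[centre, ])
  sign(det(v))
}
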