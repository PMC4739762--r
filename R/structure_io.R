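#' Read a trimeric channel structure from a PDB file
#'
#' Minimal fixed-column PDB reader for protein coordinates: ATOM records are
#' parsed, HETATM records skipped, alternate locations resolved by highest
#' occupancy then alphabetical altloc identifier, and insertion codes kept.
#' Author residue numbering is preserved as deposited.
#'
#' @param path path to a PDB-format text file.
#' @param symmetry_order expected oligomer count (default 3 for a trimer).
#' @return An object of class \code{channel_structure}: an atom table
#'   (chain, resno, ins, resid, atom, element, x, y, z, occ) plus the ordered
#'   chain identifiers and \code{symmetry_order}.
#' @export
read_channel_pdb <- function(path, symmetry_order = 3) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  ")
  if (!length(sel)) stop("no ATOM records (no protein chains) in ", path)
  al <- lines[sel]
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d", what, sel[bad[1]]))
    v
  }
  atoms <- data.frame(
    atom = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resid = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = as.integer(num(al, 23, 26, "residue number")),
    ins = trimws(substr(al, 27, 27)),
    x = num(al, 31, 38, "x coordinate"),
    y = num(al, 39, 46, "y coordinate"),
    z = num(al, 47, 54, "z coordinate"),
    occ = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1.0
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- substr(gsub("[0-9]", "", atoms$atom[noel]), 1, 1)

  # altloc resolution: highest occupancy wins, ties broken alphabetically
  # (blank altloc sorts first); deposition order is preserved otherwise
  atoms$.idx <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins,
                                   atoms$atom, sep = "\r")), ]
  atoms <- atoms[order(atoms$.idx), ]
  atoms$.idx <- NULL
  rownames(atoms) <- NULL
  chains <- unique(atoms$chain)
  if (length(chains) < symmetry_order)
    stop(sprintf("found %d chain(s); expected at least %d",
                 length(chains), symmetry_order))
  structure(list(atoms = atoms, chains = chains,
                 symmetry_order = symmetry_order),
            class = "channel_structure")
}

#' @export
print.channel_structure <- function(x, ...) {
  cat(sprintf("channel_structure: %d atoms, chains %s (symmetry order %d)\n",
              nrow(x$atoms), paste(x$chains, collapse = ""), x$symmetry_order))
  invisible(x)
}

#' Write a structure to PDB format
#'
#' @param struct a \code{channel_structure}.
#' @param path output file path; if NULL the lines are returned invisibly.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_channel_pdb <- function(struct, path = NULL) {
  a <- struct$atoms
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                  sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, name4, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$ins), a$ins, " "), a$x, a$y, a$z, a$occ, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# coordinates of one named atom in one residue of one chain; NULL if absent
.atom_xyz <- function(struct, chain, resno, atom) {
  a <- struct$atoms
  i <- which(a$chain == chain & a$resno == resno & a$atom == atom)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Residue-pair specification for cross-linking distance measurement
#'
#' @param mode \code{"horizontal"} (same residue on two adjacent subunits) or
#'   \code{"vertical"} (outer residue of one subunit to inner residue of the
#'   adjacent subunit).
#' @param residue_a,residue_b author residue numbers; horizontal mode forces
#'   \code{residue_b = residue_a}.
#' @param atom anchor atom name (default \code{"CB"}).
#' @param orientation \code{"clockwise"} or \code{"counterclockwise"};
#'   required for vertical mode. Clockwise means residue_a in chain i pairs
#'   with residue_b in chain i+1 (file order, cyclic).
#' @return An object of class \code{residue_pair_spec}.
#' @export
residue_pair_spec <- function(mode = c("horizontal", "vertical"),
                              residue_a, residue_b = residue_a, atom = "CB",
                              orientation = NULL) {
  mode <- match.arg(mode)
  if (mode == "horizontal") residue_b <- residue_a
  if (mode == "vertical") {
    if (is.null(orientation))
      stop("vertical mode requires an orientation")
    orientation <- match.arg(orientation, c("clockwise", "counterclockwise"))
  }
  structure(list(mode = mode, residue_a = residue_a, residue_b = residue_b,
                 atom = atom, orientation = orientation),
            class = "residue_pair_spec")
}

#' Inter-subunit anchor distances on a trimer
#'
#' Horizontal mode measures the three unordered adjacent-pair distances
#' (A,B), (B,C), (C,A) between \code{residue_a}'s anchor atom on each chain.
#' Vertical mode measures the three ordered pairs residue_a(chain i) ->
#' residue_b(next chain under the orientation). Chain cyclic order is file
#' order.
#'
#' @param struct a \code{channel_structure}.
#' @param spec a [residue_pair_spec()].
#' @return A data.frame with columns \code{pair} and \code{distance}, plus
#'   attributes \code{mean} and \code{sd}.
#' @export
interchain_distances <- function(struct, spec) {
  stopifnot(inherits(struct, "channel_structure"),
            inherits(spec, "residue_pair_spec"))
  ch <- struct$chains[seq_len(struct$symmetry_order)]
  k <- length(ch)
  get <- function(chain, resno) {
    p <- .atom_xyz(struct, chain, resno, spec$atom)
    if (is.null(p)) {
      a <- struct$atoms
      has_res <- any(a$chain == chain & a$resno == resno)
      if (!has_res)
        stop(sprintf("residue %d not found in chain %s", resno, chain))
      if (spec$atom == "CB")
        stop(sprintf(paste0("no CB in chain %s residue %d (glycine?); ",
                            "use reconstruct_cb()"), chain, resno))
      stop(sprintf("atom %s not found in chain %s residue %d",
                   spec$atom, chain, resno))
    }
    p
  }
  if (spec$mode == "horizontal") {
    pairs <- cbind(seq_len(k), c(seq_len(k)[-1], 1))
    d <- apply(pairs, 1, function(ij)
      sqrt(sum((get(ch[ij[1]], spec$residue_a) -
                  get(ch[ij[2]], spec$residue_a))^2)))
    lab <- paste0(ch[pairs[, 1]], "-", ch[pairs[, 2]])
  } else {
    step <- if (spec$orientation == "clockwise") 1 else -1
    nxt <- ((seq_len(k) - 1 + step) %% k) + 1
    d <- vapply(seq_len(k), function(i)
      sqrt(sum((get(ch[i], spec$residue_a) -
                  get(ch[nxt[i]], spec$residue_b))^2)), numeric(1))
    lab <- paste0(ch, seq_len(k) * 0 + spec$residue_a, "->",
                  ch[nxt], spec$residue_b)
  }
  out <- data.frame(pair = lab, distance = d, stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(d)
  attr(out, "sd") <- stats::sd(d)
  out
}

#' Reconstruct an ideal C-beta position from backbone atoms
#'
#' Places a virtual C-beta 1.52 A from C-alpha by the standard local-frame
#' construction from N, CA and C (tetrahedral geometry, L-amino-acid
#' handedness). Needed for glycine anchor sites.
#'
#' @param n,ca,c numeric xyz coordinates of the backbone N, CA and C atoms.
#' @return numeric xyz of the virtual CB.
#' @export
reconstruct_cb <- function(n, ca, c) {
  if (any(is.na(c(n, ca, c)))) stop("missing backbone atom")
  b1 <- n - ca; b2 <- c - ca
  n1 <- b1 / sqrt(sum(b1^2)); n2 <- b2 / sqrt(sum(b2^2))
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  scr <- sqrt(sum(cr^2))
  if (scr < 1e-6) stop("degenerate (collinear) N-CA-C backbone")
  bis <- -(n1 + n2); bis <- bis / sqrt(sum(bis^2))
  perp <- cr / scr
  # 1.52 A at the tetrahedral offset from the N-CA-C bisector plane
  dirv <- bis * cos(0.9128) + perp * sin(0.9128)
  ca + 1.52 * dirv
}

#' Metal-coordination feasibility between subunits
#'
#' Classifies the minimum inter-subunit distance between the selected atoms:
#' \code{"full"} coordination when it is at or below \code{full_cutoff}
#' (about 6 A for Cd2+ bridging of cysteine pairs), \code{"proximal"} up to
#' 1.6 x the cutoff (about 9 A, side-chain rearrangement required), otherwise
#' \code{"infeasible"}.
#'
#' @param struct a \code{channel_structure}.
#' @param resno author residue number of the site (same on every chain).
#' @param atom atom name to measure (falls back to CB when absent).
#' @param full_cutoff full-coordination distance (default 6.0 A).
#' @return list with \code{call} (the class label), \code{distance} (minimum
#'   inter-subunit distance), and the atom actually used.
#' @export
coordination_feasible <- function(struct, resno, atom = "CG",
                                  full_cutoff = 6.0) {
  ch <- struct$chains[seq_len(struct$symmetry_order)]
  used <- atom
  pts <- lapply(ch, function(cc) .atom_xyz(struct, cc, resno, atom))
  if (any(vapply(pts, is.null, logical(1)))) {
    used <- "CB"
    pts <- lapply(ch, function(cc) .atom_xyz(struct, cc, resno, "CB"))
    if (any(vapply(pts, is.null, logical(1))))
      stop(sprintf("residue %d: neither %s nor CB resolvable on all chains",
                   resno, atom))
  }
  k <- length(pts)
  dmin <- min(apply(cbind(seq_len(k), c(seq_len(k)[-1], 1)), 1, function(ij)
    sqrt(sum((pts[[ij[1]]] - pts[[ij[2]]])^2))))
  call <- if (dmin <= full_cutoff) "full"
          else if (dmin <= 1.6 * full_cutoff) "proximal"
          else "infeasible"
  list(call = call, distance = dmin, atom = used)
}

#' Equivalent-residue map between the zebrafish P2X4 and rat P2X2 numbering
#'
#' Bijective lookup between the author numbering of the crystallized
#' zebrafish P2X4 construct and the rat P2X2 positions used in the
#' light-gating experiments (e.g. zfP2X4 I336 <-> rP2X2 I328).
#'
#' @param residue integer residue number(s).
#' @param from \code{"zf"} (zebrafish P2X4) or \code{"rat"} (rat P2X2).
#' @return the mapped residue number(s); NA where unmapped.
#' @export
residue_map <- function(residue, from = c("zf", "rat")) {
  from <- match.arg(from)
  zf <- c(336, 353, 350, 351, 347, 343, 356, 358, 344)
  rat <- c(328, 345, 342, 343, 339, 335, 348, 350, 336)
  if (from == "zf") rat[match(residue, zf)] else zf[match(residue, rat)]
}
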