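# Bondi vdW radii for pore profiling; unknown elements fall back to carbon.
.pore_vdw <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- .vdw_radii["C"]
  unname(r)
}

.backbone_atoms <- c("N", "CA", "C", "O")

# rigid transform moving `axis` onto +z with `origin` at 0
.axis_frame <- function(origin, axis) {
  w <- axis / sqrt(sum(axis^2))
  u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(R = rbind(u, v, w), origin = origin)
}

# largest-sphere radius at in-plane centre (cx, cy) for height z:
# min over atoms of (3-D distance to atom centre - vdW radius)
# single-point sphere radius (used by tests as a slow reference)
.sphere_radius <- function(cx, cy, zval, coords, radii) {
  min(sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2 +
             (coords[, 3] - zval)^2) - radii)
}

#' Pore radius profile along the channel axis
#'
#' HOLE-style profile: at each axial position z, the radius of the largest
#' sphere whose centre lies in the z-plane (centre refined by a deterministic
#' grid local search starting from the axis point) and whose surface touches
#' but does not overlap any selected atom's van der Waals sphere. The
#' \code{"backbone"} subset restricts the atom set to N, CA, C, O to
#' emphasize global helix displacements over side-chain detail.
#'
#' @param struct a \code{channel_structure}.
#' @param atom_subset \code{"backbone"} or \code{"all"}.
#' @param axis \code{"auto"} (principal axis of the selected atoms) or a
#'   numeric length-3 direction vector.
#' @param z_range numeric length-2 axial range (A, in the axis frame centred
#'   on the selection centroid); NULL spans the selection.
#' @param step axial step (default 0.25 A).
#' @param coarse,fine coarse grid spacing and final refinement step (A) of
#'   the in-plane centre search.
#' @param max_center_offset maximum in-plane distance (A) the sphere centre
#'   may wander from the axis (keeps the search inside the pore).
#' @return An object of class \code{pore_profile}: \code{z}, \code{r},
#'   \code{atom_subset} and the axis definition.
#' @export
compute_profile <- function(struct, atom_subset = c("backbone", "all"),
                            axis = "auto", z_range = NULL, step = 0.25,
                            coarse = 0.5, fine = 0.1,
                            max_center_offset = 3) {
  stopifnot(inherits(struct, "channel_structure"))
  atom_subset <- match.arg(atom_subset)
  a <- struct$atoms
  if (atom_subset == "backbone") a <- a[a$atom %in% .backbone_atoms, ]
  if (!nrow(a)) stop("empty atom selection")
  X <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(X)
  if (identical(axis, "auto")) {
    # for a symmetric bundle the two in-plane eigenvalues are (nearly)
    # degenerate; the channel axis is the eigenvector with the isolated one
    pc <- prcomp(X, center = TRUE)
    ev <- pc$sdev^2
    gap12 <- abs(ev[1] - ev[2]); gap23 <- abs(ev[2] - ev[3])
    ax <- if (gap12 >= gap23) pc$rotation[, 1] else pc$rotation[, 3]
  } else ax <- as.numeric(axis)
  fr <- .axis_frame(ctr, ax)
  Xl <- sweep(X, 2, fr$origin) %*% t(fr$R)
  if (is.null(z_range)) z_range <- range(Xl[, 3])
  z <- seq(z_range[1], z_range[2], by = step)
  if (!length(z)) stop("empty z range")
  rv <- .pore_vdw(a$element)
  prof <- .pr_pore_profile(Xl, rv, z, coarse, fine, max_center_offset)
  out <- list(z = z, r = pmax(prof[, 1], 0), center_x = prof[, 2],
              center_y = prof[, 3], atom_subset = atom_subset,
              axis = ax, origin = ctr, step = step, clipped = prof[, 1] < 0)
  class(out) <- "pore_profile"
  out
}

#' @export
print.pore_profile <- function(x, ...) {
  m <- min_radius(x)
  cat(sprintf("pore_profile (%s atoms): z in [%.1f, %.1f] A (step %.2f), min radius %.2f A at z = %.2f\n",
              x$atom_subset, min(x$z), max(x$z), x$step, m["r"], m["z"]))
  invisible(x)
}

#' Constriction point of a pore profile
#'
#' Location and value of the minimum radius inside a z window. Ties are
#' broken toward the smallest z.
#'
#' @param profile a [compute_profile()] result.
#' @param z_window numeric length-2 window; NULL uses the full profile.
#' @return named numeric c(z, r).
#' @export
min_radius <- function(profile, z_window = NULL) {
  stopifnot(inherits(profile, "pore_profile"))
  sel <- if (is.null(z_window)) seq_along(profile$z)
         else which(profile$z >= z_window[1] & profile$z <= z_window[2])
  if (!length(sel)) stop("empty z window")
  i <- sel[which.min(profile$r[sel])]   # which.min takes the first (lowest z)
  c(z = profile$z[i], r = profile$r[i])
}

#' Open/closed call from the constriction radius
#'
#' The pore is called open when the minimum radius inside the window admits
#' an ion of radius \code{ion_radius} (default 0.95 A, Na+).
#'
#' @inheritParams min_radius
#' @param ion_radius probe ion radius in Angstrom.
#' @return logical.
#' @export
classify_open <- function(profile, ion_radius = 0.95, z_window = NULL) {
  unname(min_radius(profile, z_window)["r"] >= ion_radius)
}
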