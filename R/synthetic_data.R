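# --------------------------------------------------------------------------
# Synthetic fixtures: all generators are pure functions of (params, seed).
# Structures produced here are SYNTHETIC stand-ins for real channel
# coordinates: poly-alanine helix bundles with the gating geometry of a
# trimeric P2X-like TM domain, not real protein models.

# Ideal poly-alanine alpha-helix backbone (N, CA, C, O, CB) built by forward
# kinematics with phi = -57, psi = -47, omega = 180. Canonicalized so the
# helix axis is +z, residue 1 at the top (z decreasing with residue number).
.ideal_helix <- function(n_res, phi = -57, psi = -47) {
  rows <- list()
  add <- function(name, p, g, gg, r, th, ph) {
    rows[[length(rows) + 1L]] <<- c(p = p, g = g, gg = gg, r = r, th = th,
                                    ph = ph, tid = 0)
    length(rows)
  }
  idx <- matrix(0L, n_res, 5,
                dimnames = list(NULL, c("N", "CA", "C", "O", "CB")))
  for (i in seq_len(n_res)) {
    if (i == 1) {
      iN <- add("N", 0, 0, 0, 0, 0, 0)
      iCA <- add("CA", iN, 0, 0, 1.458, 0, 0)
      iC <- add("C", iCA, iN, 0, 1.525, 111.2, 0)
    } else {
      pC <- idx[i - 1, "C"]; pCA <- idx[i - 1, "CA"]; pN <- idx[i - 1, "N"]
      iN <- add("N", pC, pCA, pN, 1.329, 116.2, psi)
      iCA <- add("CA", iN, pC, pCA, 1.458, 121.7, 180)      # omega trans
      iC <- add("C", iCA, iN, pC, 1.525, 111.2, phi)
    }
    if (i > 1) {
      # carbonyl O of the previous residue, anti to the new N
      iO <- add("O", idx[i - 1, "C"], idx[i - 1, "CA"], idx[i - 1, "N"],
                1.231, 120.5, psi + 180)
      idx[i - 1, "O"] <- iO
    }
    if (i > 1) {
      iCB <- add("CB", iCA, iN, idx[i - 1, "C"], 1.521, 110.4, phi + 122.6)
      idx[i, "CB"] <- iCB
    } else {
      iCB <- add("CB", iCA, iN, iC, 1.521, 110.4, 122.6)
      idx[i, "CB"] <- iCB
    }
    idx[i, c("N", "CA", "C")] <- c(iN, iCA, iC)
  }
  # terminal O
  i <- n_res
  iO <- add("O", idx[i, "C"], idx[i, "CA"], idx[i, "N"], 1.231, 120.5, psi + 180)
  idx[i, "O"] <- iO
  zm <- do.call(rbind, rows)
  X <- .pr_build_coords(zm, numeric(0))
  atn <- character(nrow(X)); resno <- integer(nrow(X))
  for (i in seq_len(n_res)) for (a in colnames(idx)) {
    atn[idx[i, a]] <- a; resno[idx[i, a]] <- i
  }
  ca <- X[idx[, "CA"], , drop = FALSE]
  ctr <- colMeans(ca)
  pc <- prcomp(ca, center = TRUE)
  ax <- pc$rotation[, 1]
  if (sum((ca[1, ] - ctr) * ax) < 0) ax <- -ax   # residue 1 on the +axis side
  fr <- .axis_frame(ctr, ax)
  Xl <- sweep(X, 2, fr$origin) %*% t(fr$R)
  o <- order(resno, match(atn, c("N", "CA", "C", "O", "CB")))
  list(resno = resno[o], atom = atn[o], X = Xl[o, , drop = FALSE])
}

# rigid placement: map the canonical helix (axis +z, residue 1 at top) onto
# the segment from p_top to p_bottom, then roll about the new axis (deg)
.place_helix <- function(helix, p_top, p_bottom, roll = 0) {
  X <- helix$X
  z <- X[helix$atom == "CA", 3]
  ztop <- max(z); zbot <- min(z)
  # scale-free: axis span maps linearly onto the segment
  axis_new <- p_bottom - p_top
  L <- sqrt(sum(axis_new^2))
  w <- axis_new / L
  u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  rr <- roll * pi / 180
  ur <- cos(rr) * u + sin(rr) * v
  vr <- -sin(rr) * u + cos(rr) * v
  # canonical z decreases top -> bottom, so local +z maps onto -w
  R <- cbind(ur, vr, -w)
  Xn <- t(R %*% t(X))
  top_local <- as.numeric(R %*% c(0, 0, ztop))
  sweep(Xn, 2, as.numeric(p_top) - top_local, "+")
}

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Toy trimer parameters
#'
#' Parametric C3-symmetric two-helix-per-subunit transmembrane bundle
#' emulating the closed or open geometry of a trimeric P2X-like channel.
#' Distances are calibrated by the presets: the outer-site horizontal CB-CB
#' distance is ~16 A (closed) and ~24.7 A (open), the vertical outer-to-inner
#' distance ~19 A (closed) and ~17 A (open), the closed gate is sub-Angstrom
#' and the open gate ~3.5 A in radius (7 A diameter entryway).
#'
#' @param state \code{"closed"} or \code{"open"} preset; parameters below
#'   override the preset values.
#' @param tm2_top_radius,tm2_bottom_radius radial distance (A) of the
#'   pore-lining TM2 helix axis at its extracellular top and intracellular
#'   bottom.
#' @param tm2_top_az,tm2_bottom_az azimuth (deg) of the TM2 axis endpoints
#'   for subunit 1 (other subunits at +120/+240).
#' @param tm2_kink kink angle (deg) applied at the hinge residue, swinging
#'   the intracellular half of TM2 tangentially (negative = toward the
#'   next subunit clockwise); emulates gating-hinge bending.
#' @param hinge_resno author number of the gating-hinge residue.
#' @param z_top,z_bottom axial extent (A) of the TM segment.
#' @param tm1_radius radial distance of the peripheral TM1 helix.
#' @param outer_site,inner_site author numbers of the outer and inner anchor
#'   residues on TM2.
#' @return list of parameters (class \code{toy_trimer_params}).
#' @export
toy_trimer_params <- function(state = c("closed", "open"),
                              tm2_top_radius = NULL, tm2_bottom_radius = NULL,
                              tm2_top_az = NULL, tm2_bottom_az = NULL,
                              tm2_kink = NULL, hinge_resno = NULL,
                              z_top = 16, z_bottom = -16,
                              tm1_radius = 15.5,
                              outer_site = 328, inner_site = 345) {
  state <- match.arg(state)
  # preset values calibrated once against the stated gating geometry:
  # closed horizontal ~16.1 A, vertical ~19 A, sub-Angstrom gate; open
  # horizontal ~24.7 A, vertical ~17 A, ~3.6 A gate radius (7 A entryway)
  preset <- if (state == "closed") {
    list(tm2_top_radius = 7.15, tm2_bottom_radius = 10,
         tm2_top_az = 0, tm2_bottom_az = -55, tm2_kink = -38,
         hinge_resno = 333)
  } else {
    list(tm2_top_radius = 12.4, tm2_bottom_radius = 19,
         tm2_top_az = 0, tm2_bottom_az = -75, tm2_kink = -40,
         hinge_resno = 333)
  }
  p <- list(state = state,
            n_helices_per_subunit = 2,
            tm2_top_radius = tm2_top_radius %||% preset$tm2_top_radius,
            tm2_bottom_radius = tm2_bottom_radius %||% preset$tm2_bottom_radius,
            tm2_top_az = tm2_top_az %||% preset$tm2_top_az,
            tm2_bottom_az = tm2_bottom_az %||% preset$tm2_bottom_az,
            tm2_kink = tm2_kink %||% preset$tm2_kink,
            hinge_resno = hinge_resno %||% preset$hinge_resno,
            z_top = z_top, z_bottom = z_bottom, tm1_radius = tm1_radius,
            outer_site = outer_site, inner_site = inner_site,
            tm2_res = 328:355, tm1_res = 30:53)
  class(p) <- "toy_trimer_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic C3-symmetric toy trimer
#'
#' Builds a poly-alanine two-helix-per-subunit bundle (peripheral TM1,
#' pore-lining TM2) with exact three-fold symmetry about the z axis, in the
#' closed or open preset geometry. This is a synthetic stand-in used when
#' real channel coordinates are unavailable; only the gating geometry, not
#' the chemistry, is meaningful.
#'
#' @param params a [toy_trimer_params()].
#' @param seed integer; the generator is deterministic, the argument exists
#'   for interface uniformity.
#' @return a \code{channel_structure} (chains A, B, C).
#' @examples
#' tri <- make_toy_trimer(toy_trimer_params("closed"))
#' @export
make_toy_trimer <- function(params = toy_trimer_params("closed"), seed = 1) {
  stopifnot(inherits(params, "toy_trimer_params"))
  pol <- function(r, az_deg, z) c(r * cos(az_deg * pi / 180),
                                  r * sin(az_deg * pi / 180), z)
  # TM2: axis polyline top -> (hinge) -> bottom; kink bends the lower half
  tm2 <- .ideal_helix(length(params$tm2_res))
  n2 <- length(params$tm2_res)
  hinge_i <- match(params$hinge_resno, params$tm2_res)
  if (is.na(hinge_i)) hinge_i <- n2 %/% 2
  top <- pol(params$tm2_top_radius, params$tm2_top_az, params$z_top)
  bot <- pol(params$tm2_bottom_radius, params$tm2_bottom_az, params$z_bottom)
  X2 <- .place_helix(tm2, top, bot)
  if (params$tm2_kink != 0) {
    # rotate atoms below the hinge CA about the radial direction at the hinge
    ca_h <- X2[which(tm2$atom == "CA" & tm2$resno == hinge_i), ]
    axd <- bot - top; axd <- axd / sqrt(sum(axd^2))
    rad <- c(ca_h[1], ca_h[2], 0); rad <- rad / sqrt(sum(rad^2))
    k <- c(axd[2] * rad[3] - axd[3] * rad[2],
           axd[3] * rad[1] - axd[1] * rad[3],
           axd[1] * rad[2] - axd[2] * rad[1])
    k <- k / sqrt(sum(k^2))
    th <- params$tm2_kink * pi / 180
    Krot <- .rodrigues(k, th)
    low <- tm2$resno > hinge_i
    X2[low, ] <- sweep(sweep(X2[low, , drop = FALSE], 2, ca_h) %*% t(Krot),
                       2, ca_h, "+")
  }
  # TM1: straight peripheral helix, antiparallel, azimuth offset
  tm1 <- .ideal_helix(length(params$tm1_res))
  X1 <- .place_helix(tm1,
                     pol(params$tm1_radius, 38, params$z_bottom + 1),
                     pol(params$tm1_radius, 18, params$z_top - 1))
  sub <- function(Xh, hel, resnos) data.frame(
    atom = hel$atom, resid = "ALA", resno = resnos[hel$resno],
    x = Xh[, 1], y = Xh[, 2], z = Xh[, 3], stringsAsFactors = FALSE)
  asub <- rbind(sub(X1, tm1, params$tm1_res), sub(X2, tm2, params$tm2_res))
  chains <- c("A", "B", "C")
  all_atoms <- do.call(rbind, lapply(0:2, function(k) {
    R <- .rot_z(120 * k)
    Xr <- as.matrix(asub[, c("x", "y", "z")]) %*% t(R)
    data.frame(atom = asub$atom, altloc = "", resid = asub$resid,
               chain = chains[k + 1], resno = asub$resno, ins = "",
               x = Xr[, 1], y = Xr[, 2], z = Xr[, 3], occ = 1,
               element = substr(asub$atom, 1, 1), stringsAsFactors = FALSE)
  }))
  rownames(all_atoms) <- NULL
  structure(list(atoms = all_atoms, chains = chains, symmetry_order = 3,
                 params = params, synthetic = TRUE),
            class = "channel_structure")
}

.rodrigues <- function(k, th) {
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Surrogate linker distance samples
#'
#' Normal draws truncated at zero (resampled), deterministic per seed.
#'
#' @param mean,sd distribution parameters (A); \code{sd = 0} gives constant
#'   samples.
#' @param n sample count.
#' @param seed integer seed.
#' @return numeric vector of length n.
#' @export
make_linker_samples <- function(mean, sd, n, seed = 1) {
  stopifnot(n >= 1, sd >= 0)
  set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Synthetic macroscopic traces
#'
#' \code{"decay"}: I(t) = I0 + A exp(-t/tau); \code{"square"}: a rectangular
#' current pulse; both with additive Gaussian noise.
#'
#' @param kind \code{"decay"} or \code{"square"}.
#' @param params list: decay needs \code{i0, a, tau}; square needs
#'   \code{level, t_on, t_off}; both accept \code{duration} (s) and
#'   \code{rate} (Hz).
#' @param noise_sd additive Gaussian noise SD (pA).
#' @param seed integer seed.
#' @return a [current_trace()].
#' @export
make_trace <- function(kind = c("decay", "square"), params = list(),
                       noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(duration = 1, rate = 5000), params)
  t <- seq(0, p$duration, by = 1 / p$rate)
  y <- switch(kind,
    decay = {
      q <- utils::modifyList(list(i0 = 0, a = 1, tau = 0.131), p)
      q$i0 + q$a * exp(-t / q$tau)
    },
    square = {
      q <- utils::modifyList(list(level = -10, t_on = 0.1, t_off = 0.9,
                                  baseline = 0), p)
      ifelse(t >= q$t_on & t < q$t_off, q$level, q$baseline)
    })
  set.seed(seed)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  current_trace(t, y)
}

#' Synthetic Hill dose-response data
#'
#' Responses from the Hill equation at the given concentrations, with
#' additive Gaussian noise. Dose-response points in whole-cell protocols are
#' typically means over several cells; \code{n_cells} averages that many
#' independently noisy replicates per concentration.
#'
#' @param ec50 half-maximal concentration (M).
#' @param nh Hill coefficient.
#' @param imax maximal normalized response.
#' @param concentrations molar test concentrations (default: 7 half-decade
#'   steps centred on the EC50).
#' @param noise_sd additive per-cell response noise.
#' @param n_cells replicate cells averaged per point (default 1).
#' @param seed integer seed.
#' @return a [dose_response()].
#' @export
make_dose_response <- function(ec50 = 30e-6, nh = 1.8, imax = 1,
                               concentrations = ec50 * 10^seq(-1.5, 1.5,
                                                              by = 0.5),
                               noise_sd = 0, n_cells = 1, seed = 1) {
  y <- imax * concentrations^nh / (ec50^nh + concentrations^nh)
  set.seed(seed)
  if (noise_sd > 0)
    y <- y + rowMeans(matrix(stats::rnorm(length(y) * n_cells, 0, noise_sd),
                             ncol = n_cells))
  dose_response(concentrations, y, reference_concentration = max(concentrations))
}

#' Synthetic single-channel record (continuous-time Markov chain)
#'
#' Simulates a k-state Markov chain by the Gillespie algorithm, samples the
#' state trajectory on a uniform grid, emits the per-state current level and
#' adds Gaussian baseline noise.
#'
#' @param levels per-state current levels (pA); state 1 is taken as closed
#'   (baseline).
#' @param rates k x k transition-rate matrix (s^-1), off-diagonal entries
#'   used; rows are origin states.
#' @param noise_sd Gaussian noise SD (pA).
#' @param duration record length (s).
#' @param rate sampling rate (Hz, default 5000).
#' @param v_hold holding potential (mV), stored on the record.
#' @param seed integer seed.
#' @return a \code{single_channel_record} (a [current_trace()] with \code{v_hold},
#'   \code{states} and the generator parameters attached).
#' @export
make_single_channel <- function(levels, rates, noise_sd = 0.3, duration = 10,
                                rate = 5000, v_hold = -120, seed = 1) {
  k <- length(levels)
  stopifnot(is.matrix(rates), nrow(rates) == k, ncol(rates) == k)
  set.seed(seed)
  n <- floor(duration * rate) + 1L
  tgrid <- (seq_len(n) - 1L) / rate
  states <- integer(n)
  s <- 1L; tcur <- 0; i <- 1L
  while (i <= n) {
    out_rates <- rates[s, ]; out_rates[s] <- 0
    tot <- sum(out_rates)
    dwell <- if (tot > 0) stats::rexp(1, tot) else Inf
    tnext <- tcur + dwell
    j <- i
    while (j <= n && tgrid[j] < tnext) j <- j + 1L
    if (j > i) states[i:(j - 1L)] <- s
    i <- j
    if (!is.finite(tnext)) break
    tcur <- tnext
    s <- sample.int(k, 1L, prob = out_rates)
  }
  cur <- levels[states]
  if (noise_sd > 0) cur <- cur + stats::rnorm(n, 0, noise_sd)
  out <- current_trace(tgrid, cur)
  out$v_hold <- v_hold
  out$states <- states
  out$levels <- levels
  out$rates <- rates
  class(out) <- c("single_channel_record", "trace")
  out
}

#' Analytic stationary distribution of a rate matrix
#'
#' Solves pi Q = 0 with sum(pi) = 1 for the continuous-time chain whose
#' off-diagonal rates are given; used as the oracle for occupancy checks.
#'
#' @param rates k x k rate matrix (off-diagonals).
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(rates) {
  k <- nrow(rates)
  q <- rates
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  a <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  qr.solve(a, b)
}
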