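#' Dose-response container
#'
#' @param concentrations agonist concentrations (molar), strictly positive;
#'   stored sorted.
#' @param responses normalized currents, same length.
#' @param reference_concentration concentration the responses were normalized
#'   to (molar), or NA.
#' @return object of class \code{dose_response}.
#' @export
dose_response <- function(concentrations, responses,
                          reference_concentration = NA_real_) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0))
  o <- order(concentrations)
  structure(list(concentrations = concentrations[o], responses = responses[o],
                 reference_concentration = reference_concentration),
            class = "dose_response")
}

#' Hill-equation fit of a dose-response relationship
#'
#' Least-squares fit of I = Imax * c^nH / (EC50^nH + c^nH).
#'
#' @param dr a [dose_response()] with at least 4 concentrations.
#' @return object of class \code{hill_fit}: \code{EC50} (molar), \code{nH},
#'   \code{Imax}, \code{converged}.
#' @export
fit_hill <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  c_ <- dr$concentrations; y <- dr$responses
  if (length(c_) < 4) stop("need at least 4 concentrations")
  # starting values: EC50 at half-max crossing on the log grid, nH = 1
  ymax <- max(y)
  ec0 <- exp(stats::approx(y / ymax, log(c_), xout = 0.5, ties = "ordered",
                           rule = 2)$y)
  fit <- tryCatch(
    stats::nls(y ~ imax * c_^nh / (ec50^nh + c_^nh),
               start = list(imax = ymax, ec50 = ec0, nh = 1),
               algorithm = "port",
               lower = c(imax = 0, ec50 = min(c_) * 1e-3, nh = 0.1),
               upper = c(imax = Inf, ec50 = max(c_) * 1e3, nh = 10),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(EC50 = NA_real_, nH = NA_real_, Imax = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "hill_fit"))
  cf <- stats::coef(fit)
  structure(list(EC50 = unname(cf["ec50"]), nH = unname(cf["nh"]),
                 Imax = unname(cf["imax"]), converged = fit$convInfo$isConv),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: EC50 = %.3g M, nH = %.2f, Imax = %.3g (converged %s)\n",
              x$EC50, x$nH, x$Imax, x$converged))
  invisible(x)
}

#' Uniformly sampled current trace
#'
#' @param time time points (s), uniformly spaced.
#' @param current current (pA), same length.
#' @return object of class \code{trace} with the sampling rate attached.
#' @export
current_trace <- function(time, current) {
  stopifnot(length(time) == length(current), length(time) >= 2)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("sampling must be uniform")
  structure(list(time = time, current = current, sampling_rate = 1 / dt[1]),
            class = "trace")
}

#' Single-exponential decay fit
#'
#' Fits I(t) = I0 + A exp(-t / tau) over a time window by nonlinear least
#' squares. t is measured from the start of the window.
#'
#' @param tr a [current_trace()].
#' @param window numeric length-2 time window (s); NULL uses the full trace.
#' @return object of class \code{kinetics_fit}: \code{I0}, \code{A},
#'   \code{tau} (s), \code{converged}.
#' @export
fit_exponential <- function(tr, window = NULL) {
  stopifnot(inherits(tr, "trace"))
  sel <- if (is.null(window)) seq_along(tr$time)
         else which(tr$time >= window[1] & tr$time <= window[2])
  if (length(sel) < 4) stop("window too small")
  t <- tr$time[sel] - tr$time[sel[1]]
  y <- tr$current[sel]
  # robust starts: plateau from the trace tail, decay rate from a log-linear
  # regression on the early decay
  ntail <- max(5L, length(y) %/% 10L)
  i0_0 <- mean(y[(length(y) - ntail + 1):length(y)])
  a_0 <- mean(y[seq_len(min(5, length(y)))]) - i0_0
  if (abs(a_0) < 1e-12 && stats::sd(y) < 1e-12)
    return(structure(list(I0 = mean(y), A = 0, tau = NA_real_,
                          converged = FALSE,
                          diagnostics = "flat trace: tau unidentifiable"),
                     class = "kinetics_fit"))
  frac <- (y - i0_0) / a_0
  sel2 <- which(frac > 0.1)
  tau0 <- if (length(sel2) > 3) {
    sl <- stats::coef(stats::lm(log(frac[sel2]) ~ t[sel2]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else t[length(t)] / 3
  } else t[length(t)] / 3
  tau0 <- min(max(tau0, t[2]), t[length(t)] * 10)

  attempt <- function(tt) tryCatch(
    stats::nls(y ~ i0 + a * exp(-t / tau),
               start = list(i0 = i0_0, a = a_0, tau = tt),
               algorithm = "port", lower = c(i0 = -Inf, a = -Inf, tau = 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) e)
  fit <- attempt(tau0)
  ok <- function(f) !inherits(f, "error") && f$convInfo$isConv &&
    stats::coef(f)["tau"] > 1e-8
  if (!ok(fit)) for (mult in c(0.3, 3, 0.1)) {
    fit2 <- attempt(tau0 * mult)
    if (ok(fit2)) { fit <- fit2; break }
  }
  if (inherits(fit, "error"))
    return(structure(list(I0 = NA_real_, A = NA_real_, tau = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "kinetics_fit"))
  cf <- stats::coef(fit)
  structure(list(I0 = unname(cf["i0"]), A = unname(cf["a"]),
                 tau = unname(cf["tau"]),
                 converged = fit$convInfo$isConv && cf["tau"] > 1e-8),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: I0 = %.3g, A = %.3g, tau = %.4g s (converged %s)\n",
              x$I0, x$A, x$tau, x$converged))
  invisible(x)
}

#' Relative increase of the maximal agonist current under light
#'
#' (I_ATP+light - I_light) / I_ATP: the light-driven gain in the maximal
#' agonist response, normalized to the dark agonist current. A sign flag is
#' exposed because the subtraction order is stated ambiguously in some
#' descriptions; the default follows the formula as printed.
#'
#' @param i_atp_light maximal current with agonist during irradiation.
#' @param i_light maximal light-gated current without agonist.
#' @param i_atp maximal agonist current in the dark (non-zero).
#' @param flip_sign subtract in the opposite order.
#' @return dimensionless ratio.
#' @examples
#' relative_current(10, 4, 5)  # 1.2
#' @export
relative_current <- function(i_atp_light, i_light, i_atp, flip_sign = FALSE) {
  if (i_atp == 0) stop("I_ATP must be non-zero")
  d <- i_atp_light - i_light
  if (flip_sign) d <- -d
  d / i_atp
}

#' Apparent desensitization ratio
#'
#' Ratio of the remaining current just before the end of the agonist
#' application to the peak current during the same application, both taken as
#' magnitudes.
#'
#' @param tr a [current_trace()].
#' @param window numeric length-2 application window (s).
#' @return ratio in [0, Inf).
#' @export
desensitization_ratio <- function(tr, window) {
  stopifnot(inherits(tr, "trace"))
  sel <- which(tr$time >= window[1] & tr$time <= window[2])
  if (!length(sel)) stop("empty application window")
  y <- tr$current[sel]
  peak <- max(abs(y))
  if (peak == 0) stop("zero peak current in window")
  abs(y[length(y)]) / peak
}

# ---------------------------------------------------------------------------
# GHK permeability ratios

.RT_F <- function(temperature) 1000 * 8.314462618 * temperature / 96485.33212
# mV per unit of ln-argument

#' Permeability ratios from junction-corrected reversal potentials
#'
#' Converts measured reversal potentials into permeability ratios relative to
#' the reference cation (the internal cation, e.g. Na+) using the
#' Goldman-Hodgkin-Katz voltage equation. Three solution protocols are
#' supported, mirroring the standard ion-substitution experiments:
#' \describe{
#'   \item{bi-ionic monovalent}{test cation X+ outside, reference cation
#'     inside: P_X/P_ref = ([ref]_in / [X]_out) * exp(Erev F / RT).}
#'   \item{divalent (Lewis equation)}{test cation X2+ outside:
#'     P_X/P_ref = [ref]_in * exp(Erev F/RT) * (1 + exp(Erev F/RT)) /
#'     (4 [X]_out).}
#'   \item{dilution}{the same salt both sides at different activity; the
#'     anion-to-cation ratio P_anion/P_ref is solved from the full GHK
#'     equation.}
#' }
#'
#' @param erev named numeric of measured reversal potentials (mV), one per
#'   test solution.
#' @param solutions named list, one entry per test solution:
#'   \code{list(ion =, valence =, out =, in_ref =, protocol =)} where
#'   \code{out} is the outside test-ion concentration (M), \code{in_ref} the
#'   inside reference-cation concentration (M) and \code{protocol} one of
#'   \code{"biionic"}, \code{"divalent"}, \code{"dilution"}. For dilution,
#'   add \code{cation_out}, \code{cation_in}, \code{anion_out},
#'   \code{anion_in}.
#' @param junction_potentials named numeric (mV), subtracted from the
#'   measured values; defaults to 0.
#' @param temperature Kelvin (default 295).
#' @return object of class \code{permeability_result}: corrected Erev and the
#'   ratio P_X/P_ref per solution.
#' @export
permeability_ratios <- function(erev, solutions, junction_potentials = NULL,
                                temperature = 295) {
  rtf <- .RT_F(temperature)
  if (is.null(junction_potentials))
    junction_potentials <- setNames(rep(0, length(erev)), names(erev))
  out <- lapply(names(solutions), function(nm) {
    sol <- solutions[[nm]]
    e <- erev[[nm]] - junction_potentials[[nm]]
    xi <- exp(e / rtf)
    ratio <- switch(sol$protocol,
      biionic = {
        if (sol$valence != 1) stop("biionic protocol expects valence 1")
        sol$in_ref / sol$out * xi
      },
      divalent = {
        if (sol$valence != 2)
          stop("divalent protocol expects valence 2; got ", sol$valence)
        sol$in_ref * xi * (1 + xi) / (4 * sol$out)
      },
      dilution = {
        # GHK: xi = (cat_out + r * an_in) / (cat_in + r * an_out), solve for r
        r <- (sol$cation_out - xi * sol$cation_in) /
          (xi * sol$anion_out - sol$anion_in)
        if (is.nan(r)) r <- 0
        r
      },
      stop("unsupported protocol (ion valence?): ", sol$protocol))
    list(solution = nm, erev_corrected = e, ratio = ratio)
  })
  ratios <- setNames(vapply(out, `[[`, numeric(1), "ratio"), names(solutions))
  ratios[ratios < 0 & ratios > -1e-9] <- 0   # numerical zero
  if (any(ratios < 0))
    warning("negative permeability ratio; check Erev sign conventions")
  structure(list(
    erev_corrected = setNames(vapply(out, `[[`, numeric(1), "erev_corrected"),
                              names(solutions)),
    ratios = ratios, temperature = temperature),
    class = "permeability_result")
}

#' Forward GHK reversal potential
#'
#' Predicts Erev (mV) from a permeability ratio under the same protocols as
#' [permeability_ratios()]; the inverse operation, used for round-trip
#' checks.
#'
#' @param ratio P_X/P_ref.
#' @param sol one solution description (see [permeability_ratios()]).
#' @param temperature Kelvin.
#' @return Erev in mV.
#' @export
ghk_erev <- function(ratio, sol, temperature = 295) {
  rtf <- .RT_F(temperature)
  switch(sol$protocol,
    biionic = rtf * log(ratio * sol$out / sol$in_ref),
    divalent = {
      # solve xi (1 + xi) = 4 ratio [X]_out / [ref]_in for xi > 0
      q <- 4 * ratio * sol$out / sol$in_ref
      xi <- (-1 + sqrt(1 + 4 * q)) / 2
      rtf * log(xi)
    },
    dilution = rtf * log((sol$cation_out + ratio * sol$anion_in) /
                           (sol$cation_in + ratio * sol$anion_out)),
    stop("unsupported protocol: ", sol$protocol))
}

# ---------------------------------------------------------------------------
# all-points histograms and conductance levels

#' All-points amplitude histogram of a single-channel record
#'
#' Histogram of every sample in the record, binned at \code{bin} pA.
#'
#' @param record a [current_trace()] (typically from [make_single_channel()]).
#' @param bin bin width in pA (default 0.1).
#' @return list with \code{mids}, \code{counts}, \code{density}, \code{bin}
#'   and the total sample count \code{n}.
#' @export
all_points_histogram <- function(record, bin = 0.1) {
  y <- record$current
  idx <- floor(y / bin + 1e-9)
  lo <- min(idx); hi <- max(idx)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  mids <- (seq(lo, hi) + 0.5) * bin
  list(mids = mids, counts = counts, density = counts / sum(counts),
       bin = bin, n = length(y))
}

#' Gaussian-mixture fit of an all-points histogram
#'
#' Least-squares fit of a sum of k Gaussians to the binned all-points
#' histogram (means returned sorted increasing). Conductances are computed
#' from the fitted level means relative to the baseline (the component
#' closest to zero current by default) at the holding potential.
#'
#' @param hist an [all_points_histogram()].
#' @param k number of Gaussian components (1 to 5).
#' @param v_hold holding potential in mV (for conductances); NA to skip.
#' @param baseline index of the baseline component after sorting (default:
#'   component with mean closest to 0).
#' @return object of class \code{level_fit}: \code{means} (pA), \code{sds},
#'   \code{areas} (fraction of samples per component), \code{conductances_pS},
#'   \code{converged}.
#' @export
fit_levels <- function(hist, k, v_hold = NA_real_, baseline = NULL) {
  stopifnot(k >= 1, k <= 5)
  x <- hist$mids
  y <- hist$density
  # initial means at the k tallest well-separated peaks of the smoothed
  # density (rare conductance levels are peaks, not mass quantiles)
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- 0
  ord <- order(ys, decreasing = TRUE)
  m0 <- numeric(0)
  min_sep <- max(5 * hist$bin, diff(range(x)) / (4 * k))
  for (i in ord) {
    if (length(m0) == k) break
    if (!length(m0) || all(abs(x[i] - m0) >= min_sep)) m0 <- c(m0, x[i])
  }
  if (length(m0) < k) {
    cum <- cumsum(y)
    extra <- vapply((seq_len(k) - 0.5) / k, function(q)
      x[which.min(abs(cum - q))], numeric(1))
    m0 <- c(m0, extra)[seq_len(k)] + seq(0, 1e-6, length.out = k)
  }
  s0 <- rep(max(3 * hist$bin, diff(range(x)) / (10 * k)), k)
  w0 <- vapply(m0, function(m) max(ys[which.min(abs(x - m))], 1e-3), numeric(1))
  w0 <- w0 / sum(w0)
  par0 <- c(m0, log(s0), log(w0))
  model <- function(par) {
    m <- par[1:k]; s <- exp(par[k + 1:k]); w <- exp(par[2 * k + 1:k])
    rowSums(vapply(seq_len(k), function(j)
      w[j] * hist$bin * stats::dnorm(x, m[j], s[j]), numeric(length(x))))
  }
  obj <- function(par) sum((model(par) - y)^2)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  m <- opt$par[1:k]; s <- exp(opt$par[k + 1:k]); w <- exp(opt$par[2 * k + 1:k])
  o <- order(m)
  m <- m[o]; s <- s[o]; w <- w[o]
  merged <- k > 1 && any(diff(m) < hist$bin)
  if (is.null(baseline)) baseline <- which.min(abs(m))
  cond <- if (is.na(v_hold)) rep(NA_real_, k)
          else (m - m[baseline]) / v_hold * 1000  # pA / mV * 1000 = pS
  structure(list(means = m, sds = s, areas = w / sum(w),
                 total_mass = sum(w),
                 conductances_pS = cond, baseline = baseline,
                 converged = opt$convergence == 0 && !merged,
                 merged = merged, rss = opt$value),
            class = "level_fit")
}

#' @export
print.level_fit <- function(x, ...) {
  cat("level_fit:", length(x$means), "components\n")
  print(data.frame(mean_pA = round(x$means, 3), sd_pA = round(x$sds, 3),
                   area = round(x$areas, 3),
                   conductance_pS = round(x$conductances_pS, 1)))
  invisible(x)
}
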