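#' Pool stereoisomer distance samples
#'
#' Pools end-to-end distance samples over the three distinct stereoisomers of
#' the doubly reacted cross-linker, counting the meso R/S (= S/R) form twice,
#' i.e. pooled = RR + SS + RS + RS. With 25,000 samples per stereoisomer this
#' yields the n = 100,000 weighting used for the free-linker distributions.
#'
#' @param samples_rr,samples_ss,samples_rs numeric vectors of distances (A).
#' @return numeric vector of length `|RR| + |SS| + 2 |RS|`.
#' @examples
#' pool_stereoisomers(1, 2, 3)  # c(1, 2, 3, 3)
#' @export
pool_stereoisomers <- function(samples_rr, samples_ss, samples_rs) {
  if (!length(samples_rr) || !length(samples_ss) || !length(samples_rs))
    stop("all three stereoisomer sample vectors must be non-empty")
  c(samples_rr, samples_ss, samples_rs, samples_rs)
}

#' Binned, normalized distance distribution
#'
#' Bins distances into uniform bins of width \code{bin_width} whose edges are
#' aligned to multiples of \code{bin_width} starting at 0, and normalizes the
#' counts to probabilities.
#'
#' @param samples numeric vector of non-negative distances (A).
#' @param bin_width bin width in Angstrom (default 0.2, the convention used
#'   for the free-linker distributions).
#' @param source label, \code{"free"} or \code{"fused"}.
#' @return An object of class \code{distance_distribution} with
#'   \code{bin_edges}, \code{probabilities}, \code{n} and \code{source}.
#' @export
distance_histogram <- function(samples, bin_width = 0.2, source = "free") {
  if (!length(samples)) stop("need at least one sample")
  if (any(samples < 0)) stop("negative distances are not allowed")
  stopifnot(bin_width > 0)
  # epsilon guards against values sitting exactly on an edge in floating point
  idx <- floor(samples / bin_width + 1e-9)
  lo <- min(idx)
  hi <- max(idx) + 1
  edges <- seq(lo, hi) * bin_width
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo)
  out <- list(bin_edges = edges, probabilities = counts / length(samples),
              counts = counts, n = length(samples), bin_width = bin_width,
              source = source)
  class(out) <- "distance_distribution"
  out
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution (%s): n = %d, %d bins of %.2f A on [%.1f, %.1f)\n",
              x$source, x$n, length(x$probabilities), x$bin_width,
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

.bin_centers <- function(dist) {
  dist$bin_edges[-length(dist$bin_edges)] + dist$bin_width / 2
}

#' Gaussian least-squares fit of a binned distance distribution
#'
#' Fits a scaled normal density to the (bin centre, probability) pairs by
#' Levenberg-Marquardt-type (trust-region) least squares. In
#' \code{"peak-mean"} mode (the free-linker convention) the mean is fixed at
#' the bin centre of maximum probability (ties broken toward the lowest bin
#' centre) and only the width and amplitude are fitted; in \code{"free-mean"}
#' mode (the fused-linker convention) the mean is fitted as well.
#'
#' @param dist a [distance_histogram()] result with at least 3 non-empty bins.
#' @param mode \code{"peak-mean"} or \code{"free-mean"}.
#' @param tol convergence tolerance on the parameter change (default 1e-8).
#' @param max_iter iteration budget (default 200).
#' @return An object of class \code{gaussian_fit}: \code{mean}, \code{sd},
#'   \code{rss}, \code{converged} (plus the fitted amplitude).
#' @export
fit_gaussian <- function(dist, mode = c("peak-mean", "free-mean"),
                         tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(dist, "distance_distribution"))
  mode <- match.arg(mode)
  x <- .bin_centers(dist)
  p <- dist$probabilities
  if (sum(p > 0) < 3) stop("need at least 3 non-empty bins")

  peak <- x[which.max(p)]          # which.max already takes the lowest index
  mu0 <- sum(x * p)
  sd0 <- sqrt(max(sum(x^2 * p) - mu0^2, dist$bin_width^2))
  a0 <- max(p)
  ctl <- stats::nls.control(maxiter = max_iter, tol = tol, warnOnly = TRUE)

  fit <- tryCatch({
    if (mode == "peak-mean") {
      stats::nls(p ~ a * exp(-(x - peak)^2 / (2 * s^2)),
                 start = list(a = a0, s = sd0), algorithm = "port",
                 lower = c(a = 0, s = 1e-6), control = ctl)
    } else {
      stats::nls(p ~ a * exp(-(x - m)^2 / (2 * s^2)),
                 start = list(a = a0, m = mu0, s = sd0), algorithm = "port",
                 lower = c(a = 0, m = -Inf, s = 1e-6), control = ctl)
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(mean = NA_real_, sd = NA_real_, amplitude = NA_real_,
                rss = NA_real_, converged = FALSE, mode = mode,
                diagnostics = conditionMessage(fit))
  } else {
    cf <- stats::coef(fit)
    out <- list(mean = if (mode == "peak-mean") peak else unname(cf["m"]),
                sd = unname(cf["s"]), amplitude = unname(cf["a"]),
                rss = sum(stats::resid(fit)^2),
                converged = fit$convInfo$isConv, mode = mode,
                diagnostics = fit$convInfo$stopMessage)
  }
  class(out) <- "gaussian_fit"
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit (%s): mean %.2f A, sd %.2f A, rss %.3g, converged %s\n",
              x$mode, x$mean, x$sd, x$rss, x$converged))
  invisible(x)
}

#' Pooled free-linker distance statistics for one isomer
#'
#' Convenience pipeline: sample 3 stereoisomer ensembles (R/R, S/S, R/S),
#' pool with R/S counted twice, bin at \code{bin_width} and fit the
#' peak-mean Gaussian. With \code{n_per_stereo = 25000} this reproduces the
#' n = 100,000 free-linker protocol.
#'
#' @param isomer \code{"trans"} or \code{"cis"}.
#' @param n_per_stereo accepted conformers per stereoisomer.
#' @param seed integer seed (stereoisomer sub-seeds are derived from it).
#' @param bin_width histogram bin width (A).
#' @return list with the pooled samples, the distribution and the fit.
#' @export
free_linker_stats <- function(isomer, n_per_stereo = 25000, seed = 1,
                              bin_width = 0.2) {
  sub <- function(k) (seed * 7L + k) %% .Machine$integer.max
  ens <- lapply(seq_along(c("RR", "SS", "RS")), function(i)
    sample_conformers(linker_template(isomer, c("RR", "SS", "RS")[i]),
                      n = n_per_stereo, seed = sub(i)))
  pooled <- pool_stereoisomers(ens[[1]]$ss, ens[[2]]$ss, ens[[3]]$ss)
  dist <- distance_histogram(pooled, bin_width = bin_width, source = "free")
  fit <- fit_gaussian(dist, mode = "peak-mean")
  list(isomer = isomer, pooled = pooled, distribution = dist, fit = fit,
       ensembles = ens)
}
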