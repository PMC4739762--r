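#' Signed offset between the linker's reach and a structural distance
#'
#' The compatibility statistic: linker mean end-to-end distance minus the
#' structure's anchor-point distance, signed. A negative value means the
#' average linker is shorter than the structural gap. When the linker mean is
#' an S--S distance and the structural distance a C-beta--C-beta distance the
#' comparison is approximate; set \code{ss_vs_cb = TRUE} to flag it.
#'
#' @param linker_fit a [fit_gaussian()] result (must have converged), or a
#'   plain numeric mean in Angstrom.
#' @param structure_distance anchor-point distance (A).
#' @param ss_vs_cb logical flag recorded on the result.
#' @return numeric delta (A) with attribute \code{approximate}.
#' @examples
#' delta_from_structure(21.7, 27.7)  # -6.0
#' @export
delta_from_structure <- function(linker_fit, structure_distance,
                                 ss_vs_cb = TRUE) {
  m <- if (inherits(linker_fit, "gaussian_fit")) {
    if (!isTRUE(linker_fit$converged)) stop("linker fit did not converge")
    linker_fit$mean
  } else as.numeric(linker_fit)
  structure(m - structure_distance, approximate = ss_vs_cb)
}

#' Isomer/state compatibility call
#'
#' \code{"match"} when the structural gap lies within k standard deviations
#' of the linker's reach, \code{"short"} when the linker cannot span the gap
#' (delta below -k sd), \code{"long"} when the linker overshoots.
#'
#' @param delta signed offset from [delta_from_structure()] (A).
#' @param linker_sd linker distance SD (A), > 0.
#' @param k compatibility window in SD units (default 1).
#' @return \code{"match"}, \code{"short"} or \code{"long"}.
#' @export
compatibility <- function(delta, linker_sd, k = 1.0) {
  stopifnot(linker_sd > 0)
  d <- as.numeric(delta)
  if (abs(d) <= k * linker_sd) "match"
  else if (d < 0) "short"
  else "long"
}

#' Full linker-vs-structure ruler report
#'
#' Tabulates, for each channel state (closed, open) and each azo isomer
#' (cis, trans), the linker reach, the structural anchor distance, the signed
#' delta and the compatibility call.
#'
#' @param linker_fits named list \code{list(cis =, trans =)} of
#'   [fit_gaussian()] results (or \code{list(mean =, sd =)}).
#' @param structure_distances named numeric \code{c(closed =, open =)} (A).
#' @param k compatibility window multiplier.
#' @param ss_vs_cb flag the S--S vs C-beta comparison as approximate.
#' @param offset constant correction (A) added to the structural distances to
#'   account for the S--S vs C-beta anchor mismatch (default 0).
#' @return An object of class \code{ruler_report}: a data.frame of the four
#'   state x isomer rows plus the predicted opening wavelength.
#' @export
ruler_report <- function(linker_fits, structure_distances, k = 1.0,
                         ss_vs_cb = TRUE, offset = 0) {
  stopifnot(all(c("cis", "trans") %in% names(linker_fits)),
            all(c("closed", "open") %in% names(structure_distances)))
  rows <- expand.grid(state = c("closed", "open"), isomer = c("cis", "trans"),
                      stringsAsFactors = FALSE)
  rows$linker_mean <- vapply(rows$isomer, function(i)
    linker_fits[[i]]$mean, numeric(1))
  rows$linker_sd <- vapply(rows$isomer, function(i)
    linker_fits[[i]]$sd, numeric(1))
  rows$structure_distance <- structure_distances[rows$state] + offset
  rows$delta <- rows$linker_mean - rows$structure_distance
  rows$compatibility <- mapply(compatibility, rows$delta, rows$linker_sd,
                               MoreArgs = list(k = k))
  out <- list(table = rows,
              predicted_opening_wavelength = .photoresponse_rule(rows),
              k = k, approximate = ss_vs_cb, offset = offset)
  class(out) <- "ruler_report"
  out
}

# pure function of the four compatibility labels
.photoresponse_rule <- function(rows) {
  lab <- function(state, isomer)
    rows$compatibility[rows$state == state & rows$isomer == isomer]
  trans_open <- lab("open", "trans") == "match"
  trans_closed <- lab("closed", "trans") == "match"
  cis_open <- lab("open", "cis") == "match"
  cis_closed <- lab("closed", "cis") == "match"
  green <- trans_open && cis_closed   # trans spans the open state: 525 nm opens
  uv <- cis_open && trans_closed      # cis spans the open state: 365 nm opens
  if (green && !uv) "525" else if (uv && !green) "365" else "none"
}

#' Predicted photoresponse polarity
#'
#' Which wavelength is predicted to open the channel, given compatibility
#' calls for both isomers against both states: 525 nm (channel opens when the
#' linker relaxes to trans) when trans matches the open state and cis the
#' closed one; 365 nm when the roles are reversed; \code{"none"} when the
#' pattern is ambiguous or neither isomer is compatible with either state.
#'
#' @param report a [ruler_report()].
#' @return \code{"525"}, \code{"365"} or \code{"none"}.
#' @export
predict_photoresponse <- function(report) {
  stopifnot(inherits(report, "ruler_report"))
  report$predicted_opening_wavelength
}

#' @export
print.ruler_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("predicted opening wavelength: %s nm (k = %g SD%s)\n",
              x$predicted_opening_wavelength, x$k,
              if (x$approximate) "; S-S vs CB comparison is approximate" else ""))
  invisible(x)
}
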