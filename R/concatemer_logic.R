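#' Concatemer construct from a placement label
#'
#' Parses labels like \code{"OC/CO/CC"}: one two-letter group per concatenated
#' subunit, first letter the outer site (the TM2 apex position, rP2X2 I328),
#' second the inner site (the intracellular TM2 position, S345). \code{C}
#' marks a cysteine substitution, \code{O} the wild-type residue.
#'
#' @param label character label, three groups of two letters from {C, O}
#'   separated by "/".
#' @return An object of class \code{concatemer_construct} with logical
#'   \code{outer} and \code{inner} site vectors (length 3) and the label.
#' @examples
#' concatemer_construct("OC/CO/CC")
#' @export
concatemer_construct <- function(label) {
  parts <- strsplit(toupper(label), "/", fixed = TRUE)[[1]]
  if (length(parts) != 3 || !all(grepl("^[CO]{2}$", parts)))
    stop("label must be three two-letter groups from {C,O}, e.g. 'OC/CO/CC'")
  outer <- substr(parts, 1, 1) == "C"
  inner <- substr(parts, 2, 2) == "C"
  structure(list(outer = outer, inner = inner,
                 label = paste(parts, collapse = "/")),
            class = "concatemer_construct")
}

#' @export
format.concatemer_construct <- function(x, ...) x$label

#' @export
print.concatemer_construct <- function(x, ...) {
  cat("concatemer_construct:", x$label, "\n")
  invisible(x)
}

# interface index for the unordered subunit pair {i, j} in a trimer:
# {1,2} -> 1, {2,3} -> 2, {3,1} -> 3
.interface_index <- function(i, j) {
  p <- sort(c(i, j))
  if (all(p == c(1, 2))) 1L else if (all(p == c(2, 3))) 2L else 3L
}

# candidate cross-links on a construct: each row one link with its two sites
# (site ids: outer i -> i, inner i -> 3 + i), its type and interface
.candidate_links <- function(construct, orientation) {
  step <- if (orientation == "clockwise") 1L else -1L
  links <- list()
  addl <- function(type, s1, s2, iface)
    links[[length(links) + 1L]] <<- list(type = type, sites = c(s1, s2),
                                         interface = iface)
  for (i in 1:3) {
    j <- ((i - 1L + step) %% 3L) + 1L
    # vertical: outer cys of subunit i to inner cys of the next subunit
    if (construct$outer[i] && construct$inner[j] && i != j)
      addl("vertical", i, 3L + j, .interface_index(i, j))
    # intra: outer and inner cys of the same subunit
    if (construct$outer[i] && construct$inner[i])
      addl("intra", i, 3L + i, NA_integer_)
  }
  for (i in 1:2) for (j in (i + 1):3)
    if (construct$outer[i] && construct$outer[j])
      addl("horizontal", i, j, .interface_index(i, j))
  links
}

#' Enumerate maximal cross-link arrangements on a concatemer
#'
#' A bifunctional linker occupies exactly two cysteines and no site can be
#' used twice. Vertical links join the outer cysteine of subunit i to the
#' inner cysteine of subunit i+1 (clockwise; i-1 counterclockwise),
#' horizontal links join outer cysteines of adjacent subunits (every pair is
#' adjacent in a trimer), intra links join the outer and inner cysteine of
#' one subunit. Returns all maximal site-disjoint link sets.
#'
#' @param construct a [concatemer_construct()] (or its label).
#' @param orientation \code{"clockwise"} or \code{"counterclockwise"};
#'   shares the structure module's convention (chain i pairs with chain i+1
#'   in file order under clockwise).
#' @return list of arrangements; each has \code{links} (data.frame: type,
#'   subunit sites, interface) and \code{n_interfaces_bridged} (distinct
#'   interfaces with at least one vertical or horizontal link).
#' @export
enumerate_crosslinks <- function(construct,
                                 orientation = c("clockwise",
                                                 "counterclockwise")) {
  if (is.character(construct)) construct <- concatemer_construct(construct)
  stopifnot(inherits(construct, "concatemer_construct"))
  orientation <- match.arg(orientation)
  cand <- .candidate_links(construct, orientation)
  n <- length(cand)
  if (n == 0) {
    return(list(.arrangement(list())))
  }
  # depth-first enumeration of site-disjoint subsets, keeping maximal ones
  results <- list()
  recurse <- function(idx, chosen, used_sites) {
    extendable <- FALSE
    for (k in idx) {
      if (!any(cand[[k]]$sites %in% used_sites)) {
        extendable <- TRUE
        recurse(idx[idx > k], c(chosen, k),
                c(used_sites, cand[[k]]$sites))
      }
    }
    if (!extendable) {
      # maximal within this branch; check global maximality against all links
      all_blocked <- all(vapply(seq_len(n), function(k)
        k %in% chosen || any(cand[[k]]$sites %in% used_sites), logical(1)))
      if (all_blocked) results[[length(results) + 1L]] <<- chosen
    }
  }
  recurse(seq_len(n), integer(0), integer(0))
  results <- unique(results)
  lapply(results, function(ch) .arrangement(cand[ch]))
}

.arrangement <- function(links) {
  if (length(links)) {
    df <- data.frame(
      type = vapply(links, `[[`, "", "type"),
      site_a = vapply(links, function(l) l$sites[1], integer(1)),
      site_b = vapply(links, function(l) l$sites[2], integer(1)),
      interface = vapply(links, `[[`, integer(1), "interface"),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(type = character(0), site_a = integer(0),
                     site_b = integer(0), interface = integer(0))
  }
  bridged <- unique(df$interface[df$type %in% c("vertical", "horizontal")])
  structure(list(links = df,
                 n_interfaces_bridged = length(bridged[!is.na(bridged)])),
            class = "crosslink_arrangement")
}

#' Predicted light gating of a concatemer
#'
#' Vertical mode: the channel is light-gated when some arrangement bridges at
#' least two interfaces with vertical links (two linkers suffice to gate).
#' Horizontal mode: one horizontal link suffices. Intra-subunit links never
#' gate.
#'
#' @param arrangements output of [enumerate_crosslinks()].
#' @param mode \code{"vertical"} or \code{"horizontal"}.
#' @return list: \code{light_gated} (logical), \code{max_interfaces} (best
#'   count of interfaces bridged by links of the requested type), and
#'   \code{required_interfaces}.
#' @export
predict_gating <- function(arrangements, mode = c("vertical", "horizontal")) {
  mode <- match.arg(mode)
  required <- if (mode == "vertical") 2L else 1L
  count <- function(arr) {
    df <- arr$links
    length(unique(df$interface[df$type == mode & !is.na(df$interface)]))
  }
  mx <- if (length(arrangements)) max(vapply(arrangements, count, integer(1)))
        else 0L
  list(light_gated = mx >= required, max_interfaces = mx,
       required_interfaces = required, mode = mode)
}

#' All 64 concatemer labels
#'
#' Every combination of cysteine/wild-type placement at the outer and inner
#' site of the three concatenated subunits.
#'
#' @return character vector of 64 labels.
#' @export
all_constructs <- function() {
  g <- c("OO", "OC", "CO", "CC")
  apply(expand.grid(g, g, g, stringsAsFactors = FALSE), 1,
        paste, collapse = "/")
}
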