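#' The 16 directed triad type labels
#'
#' Holland-Leinhardt M-A-N labels in canonical order. The three digits give
#' the number of mutual, asymmetric and null dyads in the triad; suffixes
#' distinguish orientations (D = down, one sender to several receivers;
#' U = up, several senders to one receiver; C = cyclic; T = transitive).
#'
#' @format Character vector of length 16.
#' @export
triad_labels <- c("003", "012", "102", "021D", "021U", "021C",
                  "111D", "111U", "030T", "030C", "201",
                  "120D", "120U", "120C", "210", "300")

#' Create an empty directed network
#'
#' @param n Number of units.
#' @return An \code{n x n} integer adjacency matrix of zeros.
#' @export
empty_network <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  matrix(0L, n, n)
}

#' Validate a directed binary network
#'
#' Checks that \code{x} is a square 0/1 matrix with a zero diagonal (no
#' self-loops) and returns it in integer storage.
#'
#' @param x Adjacency matrix; \code{x[i, j] == 1} means an arc from i to j.
#' @return The validated integer adjacency matrix.
#' @export
as_network <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("a network must be a square adjacency matrix")
  if (!all(x %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(x) != 0))
    stop("self-loops are not allowed (non-zero diagonal)")
  storage.mode(x) <- "integer"
  x
}

#' Number of arcs in a network
#' @param net Adjacency matrix.
#' @return Integer arc count.
#' @export
arc_count <- function(net) sum(as_network(net))

# bit code of a labelled triple (a, b, c), a < b < c, matching the C++ order
triple_code <- function(net, a, b, c) {
  net[cbind(a, b)] + 2L * net[cbind(b, a)] +
    4L * net[cbind(a, c)] + 8L * net[cbind(c, a)] +
    16L * net[cbind(b, c)] + 32L * net[cbind(c, b)]
}

.triad_lut <- function() cpp_triad_code_table() + 1L  # 1-based type index

#' Classify a single triad from its three dyad states
#'
#' A triad on ordered units (a, b, c) is described by the states of its three
#' dyads: \code{d_ab}, \code{d_ac} and \code{d_bc}. Each state is one of
#' \code{"null"}, \code{"mutual"}, \code{"asym_ij"} (arc from the first-named
#' unit to the second) or \code{"asym_ji"} (the reverse).
#'
#' @param d_ab,d_ac,d_bc Dyad states.
#' @return One of the 16 labels in \code{\link{triad_labels}}.
#' @export
classify_triad <- function(d_ab, d_ac, d_bc) {
  states <- c("null", "mutual", "asym_ij", "asym_ji")
  s <- c(d_ab, d_ac, d_bc)
  if (!all(s %in% states))
    stop("dyad states must be one of: ", paste(states, collapse = ", "))
  bits <- function(state, fwd_bit, rev_bit) {
    switch(state,
           null = 0L,
           mutual = fwd_bit + rev_bit,
           asym_ij = fwd_bit,
           asym_ji = rev_bit)
  }
  code <- bits(d_ab, 1L, 2L) + bits(d_ac, 4L, 8L) + bits(d_bc, 16L, 32L)
  triad_labels[.triad_lut()[code + 1L]]
}

#' Directed triad census
#'
#' Counts the 16 triad types over all \code{choose(n, 3)} unordered unit
#' triples of a directed network.
#'
#' @param net Adjacency matrix.
#' @return Named integer vector over \code{\link{triad_labels}}; the counts
#'   sum to \code{choose(n, 3)}.
#' @export
triad_census <- function(net) {
  net <- as_network(net)
  if (nrow(net) < 3) {
    warning("network has fewer than 3 units; census is all zero")
    return(setNames(integer(16), triad_labels))
  }
  setNames(cpp_triad_census(net), triad_labels)
}

#' Incremental triad-census change for a sequence of arc toggles
#'
#' Computes the signed change in each triad-type count that results from
#' applying \code{toggles} to \code{net}, revisiting only triples that contain
#' both endpoints of a toggled dyad. Applying the toggles and recounting from
#' scratch gives \code{triad_census(net) + census_delta(net, toggles)}.
#'
#' @param net Adjacency matrix.
#' @param toggles Data frame with columns \code{i}, \code{j} (unit indices)
#'   and \code{op} (\code{"add"} or \code{"remove"}), applied in row order.
#' @return Named integer vector of count changes per triad type.
#' @export
census_delta <- function(net, toggles) {
  net <- as_network(net)
  n <- nrow(net)
  stopifnot(is.data.frame(toggles), all(c("i", "j", "op") %in% names(toggles)))
  lut <- .triad_lut()
  delta <- setNames(integer(16), triad_labels)
  for (t in seq_len(nrow(toggles))) {
    i <- toggles$i[t]; j <- toggles$j[t]; op <- toggles$op[t]
    if (i == j || i < 1 || j < 1 || i > n || j > n)
      stop(sprintf("invalid dyad (%d, %d)", i, j))
    newv <- switch(op, add = 1L, remove = 0L,
                   stop("op must be 'add' or 'remove'"))
    if (net[i, j] == newv)
      stop(sprintf("toggle %s (%d, %d) is not applicable: arc %s",
                   op, i, j, if (newv == 1L) "already present" else "absent"))
    k <- setdiff(seq_len(n), c(i, j))
    if (length(k)) {
      trip <- t(apply(cbind(i, j, k), 1, sort))
      before <- lut[triple_code(net, trip[, 1], trip[, 2], trip[, 3]) + 1L]
      net[i, j] <- newv
      after <- lut[triple_code(net, trip[, 1], trip[, 2], trip[, 3]) + 1L]
      delta <- delta - tabulate(before, 16L) + tabulate(after, 16L)
    } else {
      net[i, j] <- newv
    }
  }
  delta
}

#' Count directed paths of length three
#'
#' Counts ordered arc sequences (a -> b, b -> c, c -> d) built from three
#' distinct arcs. By default units may repeat (three-trails, so a = c or
#' b = d is allowed); with \code{distinct_units = TRUE} all four units must
#' differ (strict paths).
#'
#' @param net Adjacency matrix.
#' @param distinct_units Require all four units to be distinct?
#' @return Non-negative count.
#' @export
count_three_paths <- function(net, distinct_units = FALSE) {
  net <- as_network(net)
  if (distinct_units) cpp_three_paths_strict(net) else cpp_three_paths(net)
}
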