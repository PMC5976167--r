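# map statistic names to the integer ids used by the compiled core
stat_ids_of <- function(stats) {
  ids <- match(stats, triad_labels)
  ids[stats == "three_paths"] <- 17L
  ids[stats == "edges"] <- 18L
  if (anyNA(ids)) stop("unknown statistics: ",
                       paste(stats[is.na(ids)], collapse = ", "))
  as.integer(ids)
}

#' Comparison ratio between a current and a proposed statistic vector
#'
#' The relocating-links acceptance ratio: the squared Euclidean distance of
#' the current statistics from the target divided by that of the proposal,
#' so values above 1 mean the proposal is strictly closer to the target.
#' A zero proposal distance with a positive current distance gives
#' \code{Inf} (accept); two zero distances give 1 (a tie, rejected).
#'
#' @param target,current,proposed Numeric vectors of equal length.
#' @return Non-negative ratio (possibly \code{Inf}).
#' @export
cr_ratio <- function(target, current, proposed) {
  if (length(target) != length(current) || length(target) != length(proposed))
    stop("statistic vectors must have equal length")
  dc <- sum((current - target)^2)
  dp <- sum((proposed - target)^2)
  if (dp == 0) {
    if (dc == 0) 1 else Inf
  } else {
    dc / dp
  }
}

#' Density-matched random initial network for a blockmodel
#'
#' Uniform random digraph with the same number of arcs as the ideal network
#' of \code{spec}; the standard starting point for both generators.
#'
#' @param spec A \code{\link{blockmodel_spec}}.
#' @param seed Optional integer seed.
#' @return Adjacency matrix.
#' @export
initial_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "blockmodel_spec"))
  randomize_network(build_ideal(spec), seed)
}

#' Generate a network with the relocating-links algorithm
#'
#' Starting from \code{initial}, each iteration removes a uniformly chosen
#' arc and adds a uniformly chosen non-arc; the swap is kept exactly when it
#' brings the vector of network statistics strictly closer to \code{target}
#' (\code{\link{cr_ratio}} greater than 1). The arc count is invariant and
#' the distance to the target is non-increasing over accepted states.
#'
#' @param initial Adjacency matrix with at least one arc and one non-arc.
#' @param target Named numeric target vector as from
#'   \code{\link{target_vector}}; names select the statistics.
#' @param iters Number of iterations (default 6000).
#' @param seed Optional integer seed.
#' @return An object of class \code{"rl_result"}: list with the generated
#'   \code{network}, the \code{cr_trace}, the logical \code{accepted} vector,
#'   the final squared \code{distance} to the target, and the \code{target}.
#' @export
generate_rl <- function(initial, target, iters = 6000, seed = NULL) {
  initial <- as_network(initial)
  m <- sum(initial)
  n <- nrow(initial)
  if (m == 0 || m == n * (n - 1))
    stop("initial network must have at least one arc and one non-arc")
  stopifnot(iters >= 1, length(target) >= 1, !is.null(names(target)))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_rl(initial, stat_ids_of(names(target)), as.numeric(target),
                as.integer(iters))
  structure(list(network = res$adjacency, cr_trace = res$cr,
                 accepted = res$accepted, distance = res$distance,
                 target = target),
            class = "rl_result")
}

#' @export
print.rl_result <- function(x, ...) {
  cat("Relocating-links result:", nrow(x$network), "units,",
      sum(x$network), "arcs\n")
  cat("  accepted swaps:", sum(x$accepted), "of", length(x$accepted),
      " final squared distance:", x$distance, "\n")
  invisible(x)
}
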