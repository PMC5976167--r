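#' Fixed-coefficient exponential random graph model
#'
#' A model is an ordered set of network statistics (triad-type counts,
#' optionally the three-paths count and an edges term) with one fixed
#' coefficient per statistic. The model defines the unnormalized log
#' probability \code{theta . g(y)} of a network \code{y}; the normalizing
#' constant is never needed because it cancels from Metropolis-Hastings
#' acceptance ratios.
#'
#' @param statistics Character vector of statistic names (elements of
#'   \code{\link{triad_labels}}, \code{"three_paths"}, \code{"edges"}).
#' @param theta Numeric coefficients, one per statistic.
#' @return An object of class \code{"ergm_model"}.
#' @export
ergm_model <- function(statistics, theta) {
  if (length(statistics) != length(theta))
    stop("one coefficient per statistic is required")
  if (anyDuplicated(statistics)) stop("duplicated statistics")
  stat_ids_of(statistics)  # validates names
  structure(list(statistics = statistics, theta = setNames(theta, statistics)),
            class = "ergm_model")
}

#' @export
print.ergm_model <- function(x, ...) {
  cat("Fixed-coefficient ERGM with", length(x$statistics), "statistics:\n")
  print(x$theta)
  invisible(x)
}

#' Build the standard blockmodel ERGM from a triad-set choice
#'
#' Coefficients are +2 for allowed and -2 for forbidden triad types, the
#' standard fixed setting used throughout the package: allowed types are
#' pushed up, forbidden types pushed down, all with equal weight.
#'
#' @param spec A \code{\link{blockmodel_spec}}.
#' @param set Which triad types enter the model: \code{"all"},
#'   \code{"allowed"}, \code{"forbidden"}, \code{"selected"},
#'   \code{"selected_allowed"} or \code{"selected_forbidden"}.
#' @param theta_allowed,theta_forbidden Coefficients for allowed/forbidden
#'   types (defaults +2 / -2).
#' @param edges Optional coefficient for an edges term (used with
#'   free-density sampling; see \code{\link{tune_edges}}).
#' @param selected_forbidden,quiet Passed on to \code{\link{selected_sets}}.
#' @return An \code{\link{ergm_model}}.
#' @export
blockmodel_ergm_model <- function(spec, set = "all", theta_allowed = 2,
                                  theta_forbidden = -2, edges = NULL,
                                  selected_forbidden = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "blockmodel_spec"))
  cls <- classify_triads(spec)
  pick <- switch(set,
    all = triad_labels,
    allowed = cls$allowed,
    forbidden = cls$forbidden,
    selected = {
      s <- selected_sets(spec$type, spec$sizes, selected_forbidden, quiet)
      c(s$selected_allowed, s$selected_forbidden)
    },
    selected_allowed =
      selected_sets(spec$type, spec$sizes, selected_forbidden,
                    quiet = TRUE)$selected_allowed,
    selected_forbidden =
      selected_sets(spec$type, spec$sizes, selected_forbidden,
                    quiet)$selected_forbidden,
    stop("unknown triad set: ", set))
  theta <- ifelse(pick %in% cls$allowed, theta_allowed, theta_forbidden)
  if (!is.null(edges)) {
    pick <- c(pick, "edges")
    theta <- c(theta, edges)
  }
  ergm_model(pick, theta)
}

#' Metropolis-Hastings acceptance probability for a proposed network
#'
#' \code{min(1, exp(theta . (g(proposal) - g(current))))}; the proposal
#' distributions used by \code{\link{sample_ergm}} are symmetric, so no
#' proposal-ratio correction is needed.
#'
#' @param model An \code{\link{ergm_model}}.
#' @param current,proposal Adjacency matrices.
#' @return Probability in [0, 1].
#' @export
acceptance_probability <- function(model, current, proposal) {
  stopifnot(inherits(model, "ergm_model"))
  gc <- network_stats(current, model$statistics)
  gp <- network_stats(proposal, model$statistics)
  min(1, exp(sum(model$theta * (gp - gc))))
}

#' Evaluate model statistics on a network
#'
#' @param net Adjacency matrix.
#' @param statistics Character vector of statistic names.
#' @return Named numeric vector.
#' @export
network_stats <- function(net, statistics) {
  net <- as_network(net)
  cens <- triad_census(net)
  vapply(statistics, function(s) {
    if (s %in% triad_labels) as.numeric(cens[s])
    else if (s == "three_paths") count_three_paths(net)
    else if (s == "edges") as.numeric(sum(net))
    else stop("unknown statistic: ", s)
  }, numeric(1))
}

#' Sample a network from a fixed-coefficient ERGM
#'
#' Runs a Metropolis-Hastings chain for \code{iterations} steps and returns
#' the final state. In \code{"fixed"} mode each proposal swaps a uniformly
#' chosen arc with a uniformly chosen non-arc, so the arc count is conserved
#' exactly; in \code{"free"} mode each proposal toggles a uniformly chosen
#' ordered dyad and the density is governed by the model (typically through
#' a tuned edges term). The chain starts from \code{initial} if given,
#' otherwise from a randomized ideal network of \code{spec}.
#'
#' @param model An \code{\link{ergm_model}}.
#' @param spec A \code{\link{blockmodel_spec}} (used for the default start).
#' @param iterations Chain length (default 10000).
#' @param mode \code{"fixed"} or \code{"free"} density.
#' @param initial Optional starting adjacency matrix.
#' @param seed Optional integer seed.
#' @param thin Internal: when positive and n <= 5, record the bit-encoded
#'   state every \code{thin} steps (for stationary-distribution checks).
#' @return Adjacency matrix, or when \code{thin > 0} a list with elements
#'   \code{network} and \code{states}.
#' @export
sample_ergm <- function(model, spec = NULL, iterations = 10000,
                        mode = c("fixed", "free"), initial = NULL,
                        seed = NULL, thin = 0) {
  stopifnot(inherits(model, "ergm_model"), iterations >= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) {
    if (is.null(spec)) stop("either 'initial' or 'spec' must be given")
    initial <- randomize_network(build_ideal(spec))
  }
  initial <- as_network(initial)
  n <- nrow(initial)
  m <- sum(initial)
  if (mode == "fixed" && (m == 0 || m == n * (n - 1)))
    stop("fixed-density sampling needs a non-degenerate initial network")
  res <- cpp_ergm(initial, stat_ids_of(model$statistics),
                  as.numeric(model$theta), as.integer(iterations),
                  mode == "fixed", as.integer(thin))
  if (thin > 0) list(network = res$adjacency, states = res$states)
  else res$adjacency
}

#' Tune the edges coefficient for free-density sampling
#'
#' Bisection on the edges coefficient until the mean density of \code{reps}
#' freshly sampled networks lies within \code{window} of the ideal density of
#' \code{spec}. The mean density is monotone increasing in the edges
#' coefficient, so bisection on the signed density error converges.
#'
#' @param model An \code{\link{ergm_model}} without an edges term.
#' @param spec A \code{\link{blockmodel_spec}} supplying the ideal density
#'   and the randomized-ideal starting networks.
#' @param window Half-width of the acceptable density interval
#'   (default 0.05).
#' @param reps Networks sampled per evaluation (default 30).
#' @param iterations Chain length per network (default 10000).
#' @param bracket Initial coefficient bracket (default c(-40, 100); wide
#'   because strongly penalized statistics can demand large compensating
#'   edges coefficients).
#' @param max_steps Bisection step budget.
#' @param seed Optional integer seed.
#' @return List with \code{edges} (the coefficient), \code{mean_density},
#'   \code{ideal_density} and the augmented \code{model}.
#' @export
tune_edges <- function(model, spec, window = 0.05, reps = 30,
                       iterations = 10000, bracket = c(-40, 100),
                       max_steps = 30, seed = NULL) {
  stopifnot(inherits(model, "ergm_model"), inherits(spec, "blockmodel_spec"))
  if ("edges" %in% model$statistics)
    stop("model already contains an edges term")
  if (!is.null(seed)) set.seed(seed)
  ideal <- build_ideal(spec)
  n <- nrow(ideal)
  dens_ideal <- sum(ideal) / (n * (n - 1))
  with_edges <- function(coef)
    ergm_model(c(model$statistics, "edges"), c(unname(model$theta), coef))
  mean_density <- function(coef) {
    mdl <- with_edges(coef)
    d <- vapply(seq_len(reps), function(r) {
      net <- sample_ergm(mdl, iterations = iterations, mode = "free",
                         initial = randomize_network(ideal))
      sum(net) / (n * (n - 1))
    }, numeric(1))
    mean(d)
  }
  lo <- min(bracket); hi <- max(bracket)
  dlo <- mean_density(lo)
  if (abs(dlo - dens_ideal) <= window)
    return(list(edges = lo, mean_density = dlo, ideal_density = dens_ideal,
                model = with_edges(lo)))
  dhi <- mean_density(hi)
  if (abs(dhi - dens_ideal) <= window)
    return(list(edges = hi, mean_density = dhi, ideal_density = dens_ideal,
                model = with_edges(hi)))
  if ((dlo - dens_ideal) * (dhi - dens_ideal) > 0)
    stop("ideal density not bracketed; widen the 'bracket' range")
  for (s in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    dmid <- mean_density(mid)
    if (abs(dmid - dens_ideal) <= window)
      return(list(edges = mid, mean_density = dmid,
                  ideal_density = dens_ideal, model = with_edges(mid)))
    if ((dmid - dens_ideal) * (dlo - dens_ideal) > 0) {
      lo <- mid; dlo <- dmid
    } else {
      hi <- mid; dhi <- dmid
    }
  }
  stop("edges tuning did not reach the density window; ",
       "widen the bracket or increase max_steps")
}

#' Augmented model for the hierarchical blockmodel without complete
#' diagonal blocks
#'
#' Triads alone fail to reproduce this blockmodel: generated networks carry
#' arcs both up and down the hierarchy. The repair adds the directed
#' three-paths count as a forbidden statistic (coefficient -2), which removes
#' the downward arcs, and raises the coefficient of one 021-chain triad type
#' (default 021C, configurable to 021D) to \code{boost} to recover three
#' levels instead of two.
#'
#' @param boost Coefficient of the boosted 021 statistic (default 4; a value
#'   of 2 reduces it to an ordinary allowed type).
#' @param boost_label \code{"021C"} or \code{"021D"}.
#' @param three_paths_coef Coefficient of the three-paths statistic
#'   (default -2).
#' @param sizes Optional cluster sizes for the underlying spec.
#' @return An \code{\link{ergm_model}}.
#' @export
hierarchical_fix_model <- function(boost = 4, boost_label = c("021C", "021D"),
                                   three_paths_coef = -2, sizes = NULL) {
  boost_label <- match.arg(boost_label)
  spec <- blockmodel_spec("hierarchical_null_diag", sizes)
  base <- blockmodel_ergm_model(spec, set = "selected", quiet = TRUE)
  stats <- base$statistics
  theta <- unname(base$theta)
  if (boost_label %in% stats) {
    theta[stats == boost_label] <- boost
  } else {
    stats <- c(stats, boost_label)
    theta <- c(theta, boost)
  }
  stats <- c(stats, "three_paths")
  theta <- c(theta, three_paths_coef)
  ergm_model(stats, theta)
}
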