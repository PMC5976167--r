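#' Mean improvement value
#'
#' \code{MIV = 1 - mean(P_m / P_r)} over pairs of criterion values, where
#' \code{P_m} is the criterion of a generated network and \code{P_r} that of
#' its randomized counterpart. The MIV is 1 exactly when every generated
#' network fits its blockmodel perfectly, has expected value 0 when the
#' generated networks are themselves random, and can be negative when they
#' fit worse than random.
#'
#' @param p_m Numeric vector of generated-network criterion values, or a
#'   two-column matrix/data frame of (P_m, P_r) pairs.
#' @param p_r Numeric vector of randomized-network criterion values.
#' @return The mean improvement value (at most 1).
#' @export
miv <- function(p_m, p_r = NULL) {
  if (is.null(p_r)) {
    p_m <- as.matrix(p_m)
    stopifnot(ncol(p_m) == 2)
    p_r <- p_m[, 2]
    p_m <- p_m[, 1]
  }
  if (!length(p_m)) stop("at least one (P_m, P_r) pair is required")
  if (length(p_m) != length(p_r)) stop("P_m and P_r lengths differ")
  if (any(p_r <= 0)) stop("all P_r must be positive; drop degenerate pairs first")
  1 - mean(p_m / p_r)
}

#' Evaluate generated networks against randomized counterparts
#'
#' For each network, fits the pre-specified blockmodel of \code{spec} to the
#' network (P_m) and to an independently randomized network of the same
#' density (P_r), then combines the pairs into the mean improvement value.
#' A randomization with P_r = 0 is redrawn up to \code{max_redraws} times;
#' if still degenerate the pair is dropped with a warning.
#'
#' @param networks List of adjacency matrices.
#' @param spec A \code{\link{blockmodel_spec}} supplying the image.
#' @param restarts Restarts per fit (default 100).
#' @param seed Optional integer seed.
#' @param max_redraws Redraw budget for degenerate randomizations.
#' @return An object of class \code{"evaluation_result"}: list with the
#'   \code{pairs} data frame (P_m, P_r per replicate), \code{miv}, and the
#'   number of \code{dropped} pairs.
#' @export
evaluate_generated <- function(networks, spec, restarts = 100, seed = NULL,
                               max_redraws = 5) {
  stopifnot(inherits(spec, "blockmodel_spec"), length(networks) >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_m <- p_r <- numeric(0)
  dropped <- 0L
  for (net in networks) {
    pm <- fit_prespecified(net, spec$image, restarts)$criterion
    pr <- NA_real_
    for (try in seq_len(max_redraws + 1)) {
      cand <- fit_prespecified(randomize_network(net), spec$image,
                               restarts)$criterion
      if (cand > 0) { pr <- cand; break }
    }
    if (is.na(pr)) {
      warning("randomized counterpart fit perfectly repeatedly; pair dropped")
      dropped <- dropped + 1L
    } else {
      p_m <- c(p_m, pm)
      p_r <- c(p_r, pr)
    }
  }
  if (!length(p_m)) stop("all pairs were degenerate")
  structure(list(pairs = data.frame(p_m = p_m, p_r = p_r),
                 miv = miv(p_m, p_r), dropped = dropped),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("MIV =", round(x$miv, 4), "over", nrow(x$pairs), "pairs",
      if (x$dropped) paste0("(", x$dropped, " dropped)"), "\n")
  invisible(x)
}

# generate one network for a study cell
.generate_one <- function(generator, spec, set, iters_rl, iters_ergm,
                          tuned_model = NULL) {
  switch(generator,
    rl = {
      target <- target_vector(spec, set, quiet = TRUE)
      generate_rl(initial_network(spec), target, iters = iters_rl)$network
    },
    ergm_fixed = {
      model <- blockmodel_ergm_model(spec, set, quiet = TRUE)
      sample_ergm(model, spec, iterations = iters_ergm, mode = "fixed")
    },
    ergm_free = {
      sample_ergm(tuned_model, spec, iterations = iters_ergm, mode = "free")
    },
    stop("unknown generator: ", generator))
}

#' Run a simulation study over blockmodels, triad sets and generators
#'
#' For every combination in the grid, generates \code{round(50 * scale)}
#' networks, evaluates each cell with \code{\link{evaluate_generated}}, and
#' returns the cell-level mean improvement values together with the
#' replicate-level criterion pairs. Free-density cells tune the edges
#' coefficient once per cell before sampling.
#'
#' @param blockmodels Character vector of blockmodel types.
#' @param triad_sets Character vector of triad-set choices (see
#'   \code{\link{target_vector}}).
#' @param generators Subset of \code{c("rl", "ergm_fixed", "ergm_free")}.
#' @param scale Multiplier on the default 50 networks per cell.
#' @param iters_rl,iters_ergm Iteration budgets (defaults 6000 and 10000).
#' @param restarts Blockmodeling restarts per fit (default 100).
#' @param tune_reps Networks per density evaluation while tuning the edges
#'   coefficient (default 30).
#' @param seed Integer seed driving the whole study.
#' @return An object of class \code{"study_result"}: list with \code{cells}
#'   (one row per grid cell with its MIV) and \code{replicates} (long-format
#'   criterion pairs).
#' @export
run_study <- function(blockmodels = blockmodel_types,
                      triad_sets = "all",
                      generators = "rl",
                      scale = 1, iters_rl = 6000, iters_ergm = 10000,
                      restarts = 100, tune_reps = 30, seed = 1) {
  stopifnot(all(blockmodels %in% blockmodel_types),
            all(generators %in% c("rl", "ergm_fixed", "ergm_free")))
  set.seed(seed)
  n_nets <- max(1L, as.integer(round(50 * scale)))
  cells <- expand.grid(blockmodel = blockmodels, triad_set = triad_sets,
                       generator = generators, stringsAsFactors = FALSE)
  cells$miv <- NA_real_
  reps <- NULL
  for (ci in seq_len(nrow(cells))) {
    spec <- blockmodel_spec(cells$blockmodel[ci])
    tuned <- NULL
    if (cells$generator[ci] == "ergm_free") {
      base <- blockmodel_ergm_model(spec, cells$triad_set[ci], quiet = TRUE)
      tuned <- tune_edges(base, spec, reps = tune_reps,
                          iterations = iters_ergm)$model
    }
    nets <- lapply(seq_len(n_nets), function(r)
      .generate_one(cells$generator[ci], spec, cells$triad_set[ci],
                    iters_rl, iters_ergm, tuned))
    ev <- evaluate_generated(nets, spec, restarts = restarts)
    cells$miv[ci] <- ev$miv
    reps <- rbind(reps, data.frame(blockmodel = cells$blockmodel[ci],
                                   triad_set = cells$triad_set[ci],
                                   generator = cells$generator[ci],
                                   replicate = seq_len(nrow(ev$pairs)),
                                   ev$pairs))
  }
  structure(list(cells = cells, replicates = reps, seed = seed,
                 n_networks = n_nets),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", x$n_networks, "networks per cell, seed",
      x$seed, "\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}
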