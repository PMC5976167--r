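#' Classify triad types as allowed or forbidden for a blockmodel
#'
#' A triad type is allowed for a blockmodel when its count in the ideal
#' network is positive, and forbidden when that count is zero. The
#' classification is computed exactly from the ideal census (no sampling).
#'
#' @param x A \code{\link{blockmodel_spec}} or an ideal adjacency matrix.
#' @return List with character vectors \code{allowed} and \code{forbidden}
#'   and the integer \code{ideal_census}.
#' @export
classify_triads <- function(x) {
  ideal <- if (inherits(x, "blockmodel_spec")) build_ideal(x) else as_network(x)
  cens <- triad_census(ideal)
  list(allowed = names(cens)[cens > 0],
       forbidden = names(cens)[cens == 0],
       ideal_census = cens)
}

#' A-measure of triad over-representation
#'
#' For each triad type, the ratio between its count in the ideal blockmodel
#' network and its mean count over \code{reps} reference networks of the same
#' density. The reference is the totally randomized network at \code{le = 1}
#' (the default) or a block-aware perturbation of the ideal network at an
#' intermediate level of errors. Values above 1 mark triad types that the
#' blockmodel makes more frequent than density alone would; forbidden types
#' have A-measure 0 by construction.
#'
#' @param spec A \code{\link{blockmodel_spec}}.
#' @param reps Number of reference networks (the profile tables in this
#'   package's documentation use 10,000; smaller values are fine for
#'   exploration).
#' @param le Level of errors of the reference networks, in (0, 1]; 1 uses
#'   full randomization, smaller values use \code{\link{perturb}}.
#' @param seed Optional integer seed.
#' @param reference Optional override of the reference-network constructor,
#'   a function of the ideal adjacency matrix (used mainly for testing).
#' @return Named numeric vector over \code{\link{triad_labels}}; \code{Inf}
#'   marks a type present in the ideal network but never observed in the
#'   reference sample.
#' @export
a_measure <- function(spec, reps = 10000, le = 1, seed = NULL,
                      reference = NULL) {
  stopifnot(inherits(spec, "blockmodel_spec"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ideal <- build_ideal(spec)
  ideal_cens <- triad_census(ideal)
  if (is.null(reference)) {
    reference <- if (le >= 1) {
      function(net) randomize_network(net)
    } else {
      function(net) perturb(net, spec, le)
    }
  }
  tot <- numeric(16)
  for (r in seq_len(reps)) tot <- tot + triad_census(reference(ideal))
  mean_cens <- tot / reps
  a <- ifelse(ideal_cens == 0, 0,
              ifelse(mean_cens == 0, Inf, ideal_cens / mean_cens))
  setNames(a, triad_labels)
}

# selected-allowed exceptions: triad types dropped from the allowed set
.selected_allowed_drop <- list(hierarchical_null_diag = "021C",
                               transitivity_complete_diag = "300")

#' Selected triad-type subsets for a blockmodel type
#'
#' The selected allowed set equals the allowed set except that 021C is
#' dropped for the hierarchical blockmodel without complete diagonal blocks
#' and 300 is dropped for the transitivity blockmodel with complete diagonal
#' blocks. A reduced selected forbidden set can be supplied via
#' \code{selected_forbidden}; when omitted, the full forbidden set is used
#' and a note is emitted, since the package does not impose a particular
#' reduction.
#'
#' @param type One of \code{\link{blockmodel_types}}.
#' @param sizes Optional cluster sizes (affect only the allowed set through
#'   the ideal network; defaults to \code{\link{default_sizes}}).
#' @param selected_forbidden Optional character vector naming the reduced
#'   forbidden set; must be a subset of the forbidden types.
#' @param quiet Suppress the default-forbidden note.
#' @return List with \code{selected_allowed} and \code{selected_forbidden}.
#' @export
selected_sets <- function(type, sizes = NULL, selected_forbidden = NULL,
                          quiet = FALSE) {
  spec <- blockmodel_spec(type, sizes)
  cls <- classify_triads(spec)
  drop <- .selected_allowed_drop[[spec$type]]
  sel_allowed <- setdiff(cls$allowed, drop)
  if (is.null(selected_forbidden)) {
    if (!quiet)
      message("no reduced forbidden set supplied for '", spec$type,
              "'; using the full forbidden set")
    selected_forbidden <- cls$forbidden
  } else {
    if (!all(selected_forbidden %in% cls$forbidden))
      stop("selected_forbidden must be a subset of the forbidden triad types")
  }
  list(selected_allowed = sel_allowed, selected_forbidden = selected_forbidden)
}

#' Target statistic vector for the relocating-links generator
#'
#' Returns the exact counts, in the ideal network of \code{spec}, of the
#' statistics named by \code{set}: the 16 triad types (\code{"all"}), the
#' allowed or forbidden subsets, or the selected subsets. Forbidden-only sets
#' give all-zero targets. \code{extra_stats} may add \code{"three_paths"}
#' (directed three-trail count) and \code{"edges"}.
#'
#' @param spec A \code{\link{blockmodel_spec}}.
#' @param set One of \code{"all"}, \code{"allowed"}, \code{"forbidden"},
#'   \code{"selected"}, \code{"selected_allowed"},
#'   \code{"selected_forbidden"}.
#' @param extra_stats Character vector of additional statistics.
#' @param selected_forbidden Optional reduced forbidden set, passed on to
#'   \code{\link{selected_sets}}.
#' @param quiet Passed on to \code{\link{selected_sets}}.
#' @return Named numeric vector of target counts.
#' @export
target_vector <- function(spec,
                          set = c("all", "allowed", "forbidden", "selected",
                                  "selected_allowed", "selected_forbidden"),
                          extra_stats = character(),
                          selected_forbidden = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "blockmodel_spec"))
  set <- match.arg(set)
  cls <- classify_triads(spec)
  stats <- switch(set,
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
                    quiet)$selected_forbidden)
  stats <- c(stats, extra_stats)
  if (!length(stats)) stop("empty statistic set")
  ideal <- build_ideal(spec)
  vals <- vapply(stats, function(s) {
    if (s %in% triad_labels) as.numeric(cls$ideal_census[s])
    else if (s == "three_paths") count_three_paths(ideal)
    else if (s == "edges") as.numeric(sum(ideal))
    else stop("unknown statistic: ", s)
  }, numeric(1))
  setNames(vals, stats)
}

#' Triad profile table across blockmodel types
#'
#' Convenience summary mirroring the usual label-by-blockmodel layout: the
#' A-measure of every triad type for every blockmodel type, with zeros
#' marking forbidden types.
#'
#' @param types Blockmodel types to include.
#' @param reps Reference networks per type for the A-measure.
#' @param seed Optional integer seed.
#' @return Data frame with one row per triad type and one column per
#'   blockmodel type.
#' @export
triad_profile_table <- function(types = blockmodel_types, reps = 1000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(types, function(tp)
    round(a_measure(blockmodel_spec(tp), reps = reps), 2))
  out <- as.data.frame(setNames(cols, types))
  rownames(out) <- triad_labels
  out
}
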