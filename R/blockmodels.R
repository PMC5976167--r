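#' Supported blockmodel types
#'
#' @format Character vector of the seven blockmodel types: cohesive,
#'   symmetric and asymmetric core-periphery, hierarchical and transitivity
#'   (each with null or complete diagonal blocks).
#' @export
blockmodel_types <- c("cohesive",
                      "core_periphery_symmetric",
                      "core_periphery_asymmetric",
                      "hierarchical_null_diag",
                      "hierarchical_complete_diag",
                      "transitivity_null_diag",
                      "transitivity_complete_diag")

#' Default block image for a blockmodel type
#'
#' Returns the K x K image matrix (1 = complete block, 0 = null block) under
#' structural equivalence. Cluster 1 is the top of the hierarchy (or the
#' core); higher-numbered clusters are lower levels (or the periphery), and
#' lower clusters send arcs upward: in the hierarchical image cluster c + 1
#' sends to cluster c, and in the transitivity image every cluster sends to
#' all clusters above it.
#'
#' @param type One of \code{\link{blockmodel_types}}.
#' @param K Number of clusters; must be 2 for core-periphery types. Values
#'   other than 3 are accepted for the cohesive, hierarchical and
#'   transitivity types.
#' @return Integer image matrix with entries in \{0, 1\}.
#' @export
default_image <- function(type, K = if (grepl("core_periphery", type)) 2L else 3L) {
  type <- match.arg(type, blockmodel_types)
  K <- as.integer(K)
  img <- matrix(0L, K, K)
  switch(type,
    cohesive = {
      if (K < 1) stop("cohesive blockmodel needs K >= 1")
      diag(img) <- 1L
    },
    core_periphery_symmetric = {
      if (K != 2) stop("core-periphery blockmodels are defined for K = 2")
      img[1, 1] <- 1L; img[1, 2] <- 1L; img[2, 1] <- 1L
    },
    core_periphery_asymmetric = {
      if (K != 2) stop("core-periphery blockmodels are defined for K = 2")
      img[1, 1] <- 1L; img[2, 1] <- 1L  # only periphery -> core
    },
    hierarchical_null_diag = ,
    hierarchical_complete_diag = {
      if (K < 2) stop("hierarchical blockmodels need K >= 2")
      for (c in seq_len(K - 1)) img[c + 1, c] <- 1L
      if (type == "hierarchical_complete_diag") diag(img) <- 1L
    },
    transitivity_null_diag = ,
    transitivity_complete_diag = {
      if (K < 2) stop("transitivity blockmodels need K >= 2")
      img[lower.tri(img)] <- 1L
      if (type == "transitivity_complete_diag") diag(img) <- 1L
    })
  img
}

#' Default cluster sizes for a blockmodel type
#'
#' Core-periphery types use a core of \code{n/3} units (8 of 24 by default)
#' and the remainder as periphery; the three-cluster types split \code{n}
#' evenly.
#'
#' @param type One of \code{\link{blockmodel_types}}.
#' @param n Total number of units (default 24).
#' @return Integer vector of cluster sizes summing to \code{n}.
#' @export
default_sizes <- function(type, n = 24L) {
  type <- match.arg(type, blockmodel_types)
  if (grepl("core_periphery", type)) {
    core <- round(n / 3)
    c(core, n - core)
  } else {
    base <- n %/% 3
    sizes <- rep(base, 3)
    extra <- n - 3 * base
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    sizes
  }
}

#' Blockmodel specification
#'
#' Bundles a blockmodel type, cluster sizes and block image into a
#' specification object used by the generators, the perturbation model and
#' the evaluation pipeline.
#'
#' @param type One of \code{\link{blockmodel_types}}.
#' @param sizes Positive integer cluster sizes; defaults to
#'   \code{\link{default_sizes}} on 24 units.
#' @param image Optional image matrix; defaults to
#'   \code{\link{default_image}} for \code{length(sizes)} clusters.
#' @return An object of class \code{"blockmodel_spec"} with elements
#'   \code{type}, \code{sizes}, \code{n}, \code{K}, \code{image} and
#'   \code{membership} (cluster of each unit).
#' @export
blockmodel_spec <- function(type, sizes = NULL, image = NULL) {
  type <- match.arg(type, blockmodel_types)
  if (is.null(sizes)) sizes <- default_sizes(type)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("all cluster sizes must be at least 1")
  K <- length(sizes)
  if (is.null(image)) image <- default_image(type, K)
  image <- as.matrix(image)
  if (nrow(image) != K || ncol(image) != K)
    stop("image dimension must equal the number of clusters")
  storage.mode(image) <- "integer"
  structure(list(type = type, sizes = sizes, n = sum(sizes), K = K,
                 image = image, membership = rep(seq_len(K), sizes)),
            class = "blockmodel_spec")
}

#' @export
print.blockmodel_spec <- function(x, ...) {
  cat("Blockmodel spec:", x$type, "\n")
  cat("  units:", x$n, " clusters:", paste(x$sizes, collapse = "/"), "\n")
  cat("  image (1 = complete block):\n")
  print(x$image)
  invisible(x)
}

#' Build the ideal network of a blockmodel specification
#'
#' The arc (i, j) is present exactly when the image cell of
#' (cluster(i), cluster(j)) is a complete block and i != j.
#'
#' @param spec A \code{\link{blockmodel_spec}}.
#' @return Adjacency matrix of the ideal network.
#' @export
build_ideal <- function(spec) {
  stopifnot(inherits(spec, "blockmodel_spec"))
  adj <- spec$image[spec$membership, spec$membership]
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  adj
}

# nearest integer, ties rounded up
round_half_up <- function(x) floor(x + 0.5)

#' Number of links to relocate for a given level of errors
#'
#' The level of errors LE runs from 0 (ideal blockmodel) to 1 (totally
#' randomized network of the same density). The number of arcs that must be
#' moved from complete to null blocks to reach level LE is
#' \code{k = round(LE * (m - m^2 / (n^2 - n)))}: zero at LE = 0, and at
#' LE = 1 exactly enough relocations to equalize complete- and null-block
#' densities.
#'
#' @param m Number of arcs in the ideal network.
#' @param n Number of units.
#' @param le Level of errors in [0, 1].
#' @return Integer number of arcs to relocate.
#' @export
links_to_relocate <- function(m, n, le) {
  stopifnot(m >= 0, n >= 2)
  if (le < 0 || le > 1) stop("level of errors must be in [0, 1]")
  as.integer(round_half_up(le * (m - m^2 / (n^2 - n))))
}

#' Perturb an ideal network to a given level of errors
#'
#' Relocates \code{k = links_to_relocate(m, n, le)} arcs, sampled uniformly
#' without replacement from complete-block positions, to uniformly sampled
#' empty null-block positions. The arc count is preserved, and with the true
#' partition the blockmodeling criterion of the result is exactly \code{2k}
#' (each relocation creates one error of either kind).
#'
#' @param ideal Adjacency matrix from \code{\link{build_ideal}(spec)}.
#' @param spec The matching \code{\link{blockmodel_spec}}.
#' @param le Level of errors in [0, 1].
#' @param seed Optional integer seed for reproducibility.
#' @return Perturbed adjacency matrix.
#' @export
perturb <- function(ideal, spec, le, seed = NULL) {
  stopifnot(inherits(spec, "blockmodel_spec"))
  ideal <- as_network(ideal)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ideal)
  k <- links_to_relocate(sum(ideal), n, le)
  if (k == 0) return(ideal)
  complete <- spec$image[spec$membership, spec$membership] == 1
  diag(complete) <- FALSE
  offdiag <- row(ideal) != col(ideal)
  donors <- which(complete & ideal == 1L)
  acceptors <- which(!complete & offdiag & ideal == 0L)
  if (k > length(donors) || k > length(acceptors)) {
    warning("requested relocations exceed available positions; capping")
    k <- min(k, length(donors), length(acceptors))
  }
  out <- ideal
  out[donors[sample.int(length(donors), k)]] <- 0L
  out[acceptors[sample.int(length(acceptors), k)]] <- 1L
  out
}

#' Totally randomize a network at fixed density
#'
#' Draws a uniform random loop-free digraph on the same units with exactly
#' the same number of arcs.
#'
#' @param net Adjacency matrix.
#' @param seed Optional integer seed.
#' @return Randomized adjacency matrix.
#' @export
randomize_network <- function(net, seed = NULL) {
  net <- as_network(net)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(net)
  m <- sum(net)
  out <- matrix(0L, n, n)
  slots <- which(row(out) != col(out))
  out[sample(slots, m)] <- 1L
  out
}

#' Uniform random digraph with a given arc count
#'
#' @param n Number of units.
#' @param m Number of arcs (0 <= m <= n(n-1)).
#' @param seed Optional integer seed.
#' @return Adjacency matrix.
#' @export
random_digraph <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(m >= 0, m <= n * (n - 1))
  out <- matrix(0L, n, n)
  slots <- which(row(out) != col(out))
  out[sample(slots, m)] <- 1L
  out
}
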