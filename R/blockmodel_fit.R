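#' Blockmodeling criterion under structural equivalence
#'
#' Counts inconsistencies between a network and a pre-specified block image
#' given a partition: arcs present in null blocks plus absent ordered pairs
#' (excluding the diagonal) in complete blocks.
#'
#' @param net Adjacency matrix.
#' @param partition Integer cluster assignment per unit (values 1..K).
#' @param image K x K image matrix (1 = complete, 0 = null).
#' @return Non-negative integer criterion value.
#' @export
criterion <- function(net, partition, image) {
  net <- as_network(net)
  n <- nrow(net)
  stopifnot(length(partition) == n)
  K <- nrow(as.matrix(image))
  if (max(partition) > K || min(partition) < 1)
    stop("partition labels must lie in 1..K with K = nrow(image)")
  complete <- image[partition, partition] == 1
  offdiag <- row(net) != col(net)
  sum(net == 1L & !complete) + sum(net == 0L & complete & offdiag)
}

#' Fit a pre-specified blockmodel by relocation search
#'
#' Minimizes \code{\link{criterion}} over partitions into K non-empty
#' clusters. Each restart draws a uniform random non-empty partition and
#' applies steepest-descent local search over single-unit moves and pairwise
#' unit exchanges until no strictly improving step exists; the best value
#' across restarts is returned. Ties among equally improving steps are
#' broken by a seeded random scan order, so runs are reproducible.
#'
#' @param net Adjacency matrix.
#' @param image K x K image matrix, or a \code{\link{blockmodel_spec}} whose
#'   image is used.
#' @param restarts Number of random restarts (default 100).
#' @param seed Optional integer seed.
#' @return An object of class \code{"blockmodel_fit"}: list with
#'   \code{partition}, \code{criterion}, and \code{restart_values}.
#' @export
fit_prespecified <- function(net, image, restarts = 100, seed = NULL) {
  net <- as_network(net)
  if (inherits(image, "blockmodel_spec")) image <- image$image
  image <- as.matrix(image)
  storage.mode(image) <- "integer"
  stopifnot(nrow(image) == ncol(image), restarts >= 1)
  if (nrow(net) < nrow(image)) stop("fewer units than clusters")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_fit(net, image, as.integer(restarts))
  structure(list(partition = res$partition, criterion = res$criterion,
                 restart_values = res$restart_values),
            class = "blockmodel_fit")
}

#' @export
print.blockmodel_fit <- function(x, ...) {
  cat("Pre-specified blockmodel fit: criterion P =", x$criterion,
      "over", length(x$restart_values), "restarts\n")
  cat("  cluster sizes:",
      paste(tabulate(x$partition), collapse = "/"), "\n")
  invisible(x)
}
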