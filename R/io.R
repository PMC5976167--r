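#' Read a directed network from a file
#'
#' Supported formats: Pajek \code{.net} (\code{*Vertices} / \code{*Arcs}
#' sections, 1-based vertex ids), a directed edge-list CSV with columns
#' \code{from} and \code{to}, and a dense adjacency-matrix CSV. Duplicate
#' arcs are collapsed with a warning; self-loops are an error.
#'
#' @param path File path.
#' @param format \code{"pajek"}, \code{"edgelist_csv"} or
#'   \code{"adjacency_csv"}; guessed from the extension when missing.
#' @return Adjacency matrix.
#' @export
read_network <- function(path, format = c("pajek", "edgelist_csv",
                                          "adjacency_csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.net$", path, ignore.case = TRUE)) "pajek"
              else "edgelist_csv"
  }
  format <- match.arg(format)
  switch(format,
    pajek = read_pajek(path),
    edgelist_csv = {
      df <- read.csv(path)
      if (!all(c("from", "to") %in% names(df)))
        stop("edge-list CSV needs 'from' and 'to' columns")
      n <- if ("n" %in% names(df) && nrow(df)) df$n[1] else
        max(df$from, df$to, 0)
      keep <- !is.na(df$from) & !is.na(df$to)
      edges_to_adj(df$from[keep], df$to[keep], n)
    },
    adjacency_csv = {
      adj <- as.matrix(read.csv(path, header = FALSE))
      dimnames(adj) <- NULL
      as_network(adj)
    })
}

read_pajek <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  vhead <- grep("^\\*vertices", lines, ignore.case = TRUE)
  if (length(vhead) != 1) stop("malformed Pajek file: need one *Vertices header")
  n <- suppressWarnings(as.integer(strsplit(lines[vhead], "\\s+")[[1]][2]))
  if (is.na(n) || n < 1) stop("malformed *Vertices header")
  ahead <- grep("^\\*arcs", lines, ignore.case = TRUE)
  if (length(ahead) != 1) stop("malformed Pajek file: need one *Arcs section")
  other <- grep("^\\*", lines)
  stop_at <- other[other > ahead]
  stop_at <- if (length(stop_at)) min(stop_at) - 1 else length(lines)
  arc_lines <- if (ahead + 1 <= stop_at) lines[(ahead + 1):stop_at]
               else character(0)
  from <- to <- integer(0)
  if (length(arc_lines)) {
    parts <- strsplit(arc_lines, "\\s+")
    from <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    to <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  }
  edges_to_adj(from, to, n)
}

edges_to_adj <- function(from, to, n) {
  if (any(is.na(from)) || any(is.na(to))) stop("non-numeric arc endpoints")
  if (any(from < 1 | from > n | to < 1 | to > n))
    stop("arc endpoints out of 1..n")
  if (any(from == to)) stop("self-loops are not allowed")
  adj <- matrix(0L, n, n)
  idx <- cbind(from, to)
  if (anyDuplicated(idx)) {
    warning("duplicate arcs collapsed")
    idx <- unique(idx)
  }
  adj[idx] <- 1L
  adj
}

#' Write a directed network to a file
#'
#' Arcs are written in lexicographic order so output is byte-stable.
#'
#' @param net Adjacency matrix.
#' @param path Output file path.
#' @param format \code{"pajek"}, \code{"edgelist_csv"} or
#'   \code{"adjacency_csv"}.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, format = c("pajek", "edgelist_csv",
                                                "adjacency_csv")) {
  net <- as_network(net)
  format <- match.arg(format)
  n <- nrow(net)
  arcs <- which(net == 1L, arr.ind = TRUE)
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  switch(format,
    pajek = {
      lines <- c(paste0("*Vertices ", n),
                 sprintf('%d "v%d"', seq_len(n), seq_len(n)),
                 "*Arcs",
                 if (nrow(arcs)) sprintf("%d %d", arcs[, 1], arcs[, 2]))
      writeLines(lines, path)
    },
    edgelist_csv = {
      # a placeholder row keeps the unit count recoverable for arc-free nets
      df <- if (nrow(arcs)) {
        data.frame(from = arcs[, 1], to = arcs[, 2], n = rep(n, nrow(arcs)))
      } else {
        data.frame(from = NA_integer_, to = NA_integer_, n = n)
      }
      write.csv(df, path, row.names = FALSE)
    },
    adjacency_csv = {
      write.table(net, path, sep = ",", row.names = FALSE,
                  col.names = FALSE)
    })
  invisible(path)
}

#' Write the standard fixture set
#'
#' Writes, for each of the seven default blockmodels, the ideal network and
#' its perturbations at levels of errors 0.25, 0.5 and 1 (Pajek format),
#' together with a CSV of their triad censuses.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving the perturbations.
#' @return Data frame listing the written networks, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rows <- list()
  censuses <- list()
  for (type in blockmodel_types) {
    spec <- blockmodel_spec(type)
    ideal <- build_ideal(spec)
    nets <- list("0" = ideal)
    for (le in c(0.25, 0.5, 1)) {
      nets[[as.character(le)]] <- perturb(ideal, spec, le)
    }
    for (le in names(nets)) {
      file <- file.path(dir, sprintf("%s_le%s.net", type, gsub("\\.", "", le)))
      write_network(nets[[le]], file, "pajek")
      rows[[length(rows) + 1]] <- data.frame(blockmodel = type, le = le,
                                             file = file)
      censuses[[length(censuses) + 1]] <-
        data.frame(blockmodel = type, le = le,
                   label = triad_labels,
                   count = as.integer(triad_census(nets[[le]])))
    }
  }
  write.csv(do.call(rbind, censuses), file.path(dir, "censuses.csv"),
            row.names = FALSE)
  invisible(do.call(rbind, rows))
}
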