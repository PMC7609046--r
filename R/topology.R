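#' Cellular interaction topologies
#'
#' A `topology` is the unweighted, undirected graph of which cells in a
#' multicellular group may share viability returns with which. Cell indices
#' are 0-based everywhere, including on-disk formats. Self-edges are excluded:
#' self-sharing enters later through the sharing matrix, where each cell
#' counts itself among its `n_i = degree + 1` neighbors.
#'
#' @param kind One of `"ring"`, `"complete"`, `"disconnected"`,
#'   `"balanced_bipartite"`, `"filament"`, `"kary_tree"`, `"erdos_renyi"`.
#' @param n Number of cells (`>= 1`; `>= 3` for a ring; even for the balanced
#'   bipartite graph).
#' @param p Edge probability for `erdos_renyi`, the fraction of the
#'   `n(n-1)/2` possible connections present in expectation.
#' @param branching Maximum children per node for `kary_tree` (`>= 1`).
#' @param seed Optional integer seed making `erdos_renyi` reproducible.
#'
#' @details
#' Families:
#' * `ring`: cell `i` connected to `(i ± 1) mod n` (the nearest-neighbor
#'   topology).
#' * `complete`: every pair connected (a well-mixed group).
#' * `disconnected`: no edges (autonomous cells).
#' * `balanced_bipartite`: the complete bipartite graph on two equal halves
#'   `{0..n/2-1}` and `{n/2..n-1}`.
#' * `filament`: the open path `0-1-...-(n-1)`, the topology of unbranched
#'   cell chains such as algal filaments.
#' * `kary_tree`: rooted tree filled level by level, each node with up to
#'   `branching` children — branched growth forms such as snowflake yeast.
#' * `erdos_renyi`: each possible edge present independently with probability
#'   `p`. Disconnected realizations are kept, not resampled.
#'
#' @return An object of class `topology`: a list with `n_cells`, `edges`
#'   (two-column 0-based integer matrix, one row per edge, smaller index
#'   first), and `adjacency` (symmetric logical matrix with `FALSE` diagonal).
#' @examples
#' make_topology("ring", 4)
#' make_topology("erdos_renyi", 10, p = 0.3, seed = 1)
#' @export
make_topology <- function(kind = c("ring", "complete", "disconnected",
                                   "balanced_bipartite", "filament",
                                   "kary_tree", "erdos_renyi"),
                          n, p = NULL, branching = 2L, seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be a positive integer.", call. = FALSE)

  edges <- switch(kind,
    ring = {
      if (n < 3) stop("a ring needs at least 3 cells.", call. = FALSE)
      cbind(0:(n - 1), c(1:(n - 1), 0))
    },
    complete = if (n < 2) empty_edges() else t(utils::combn(0:(n - 1), 2)),
    disconnected = empty_edges(),
    balanced_bipartite = {
      if (n %% 2 != 0) {
        stop("a balanced bipartite graph needs an even number of cells.",
             call. = FALSE)
      }
      half <- n %/% 2
      as.matrix(expand.grid(left = 0:(half - 1), right = half:(n - 1)))
    },
    filament = if (n < 2) empty_edges() else cbind(0:(n - 2), 1:(n - 1)),
    kary_tree = {
      branching <- as.integer(branching)
      if (is.na(branching) || branching < 1) {
        stop("`branching` must be a positive integer.", call. = FALSE)
      }
      if (n < 2) empty_edges() else {
        child <- 1:(n - 1)
        cbind((child - 1L) %/% branching, child)
      }
    },
    erdos_renyi = {
      if (is.null(p) || is.na(p) || p < 0 || p > 1) {
        stop("`p` must be a probability in [0, 1].", call. = FALSE)
      }
      pairs <- if (n < 2) empty_edges() else t(utils::combn(0:(n - 1), 2))
      draw <- function() stats::runif(nrow(pairs)) < p
      keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
      pairs[keep, , drop = FALSE]
    }
  )
  new_topology(n, edges, kind = kind)
}

empty_edges <- function() matrix(integer(0), ncol = 2)

#' Build a topology from an explicit edge set
#'
#' @param n_cells Number of cells.
#' @param edges Two-column matrix (or empty) of 0-based endpoints.
#' @param kind Optional family label carried along for printing.
#' @return A `topology`.
#' @export
new_topology <- function(n_cells, edges, kind = "custom") {
  n_cells <- as.integer(n_cells)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 0 | edges >= n_cells)) {
      stop("edge endpoint outside [0, n_cells).", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-edges are not allowed.", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges)) stop("duplicate edges.", call. = FALSE)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  adj <- matrix(FALSE, n_cells, n_cells)
  if (nrow(edges) > 0) {
    adj[edges + 1L] <- TRUE
    adj[edges[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  structure(list(n_cells = n_cells, edges = edges, adjacency = adj,
                 kind = kind),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology: %s, %d cells, %d edges>\n",
              x$kind, x$n_cells, nrow(x$edges)))
  invisible(x)
}

#' Neighbor counts including self
#'
#' Each cell shares a fraction of its viability returns equally among its
#' neighbors *including itself*, so the relevant neighborhood size is
#' `degree + 1`.
#'
#' @param t A `topology`.
#' @return Integer vector of `degree(i) + 1`.
#' @export
degrees_with_self <- function(t) {
  stopifnot(inherits(t, "topology"))
  as.integer(rowSums(t$adjacency)) + 1L
}

#' Read and write interaction graphs
#'
#' Edge lists are plain text: two whitespace-separated 0-based integer columns,
#' one edge per line, `#` comments allowed. GraphML goes through igraph.
#' `read_graph_file(write_graph_file(t))` reproduces the edge set exactly.
#'
#' @param path File path.
#' @param format `"edge_list"` or `"graphml"`.
#' @param n_cells Optional cell count for edge lists whose highest index
#'   undercounts isolated trailing cells; defaults to `max index + 1`.
#' @return A `topology` (for `read_graph_file`); `write_graph_file` invisibly
#'   returns `path`.
#' @export
read_graph_file <- function(path, format = c("edge_list", "graphml"),
                            n_cells = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    edges <- igraph::as_edgelist(g, names = FALSE) - 1L
    return(new_topology(igraph::vcount(g), edges))
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_topology(n_cells %||% 0L, empty_edges()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.integer(parts))
    if (length(vals) != 2 || anyNA(vals)) {
      stop(sprintf("malformed edge-list line %d: '%s'", i, lines[[i]]),
           call. = FALSE)
    }
    vals
  })
  edges <- do.call(rbind, parsed)
  new_topology(n_cells %||% (max(edges) + 1L), edges)
}

#' @rdname read_graph_file
#' @param t A `topology` to write.
#' @export
write_graph_file <- function(t, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "topology"))
  if (format == "edge_list") {
    writeLines(c(sprintf("# %d cells", t$n_cells),
                 sprintf("%d %d", t$edges[, 1], t$edges[, 2])),
               path)
  } else {
    igraph::write_graph(as_igraph(t), path, format = "graphml")
  }
  invisible(path)
}

#' Convert a topology to an igraph graph
#'
#' @param t A `topology`.
#' @return An undirected `igraph` graph (1-based vertex ids).
#' @export
as_igraph <- function(t) {
  stopifnot(inherits(t, "topology"))
  g <- igraph::make_empty_graph(n = t$n_cells, directed = FALSE)
  if (nrow(t$edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(t$edges + 1L)))
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
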