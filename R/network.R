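#' Build an interaction graph over a declared node universe
#'
#' Edges with a combined score below \code{score_threshold} are dropped
#' (inclusive >= retains an edge at exactly the threshold, STRING's
#' medium-confidence default being 0.4). Unordered pairs are
#' canonicalized, duplicates and self-loops removed, and universe nodes
#' without any retained edge are kept as degree-0 nodes. Edges with an
#' endpoint outside the universe are dropped with a warning.
#'
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score} (scores in [0,1]).
#' @param node_universe character vector of all submitted node ids.
#' @param score_threshold minimum retained score (default 0.4).
#' @return list of class \code{interaction_graph}: \code{graph} (igraph),
#'   \code{node_universe}, \code{edges} (canonical data.frame),
#'   \code{score_threshold}, \code{n_dropped_foreign}.
#' @export
build_graph <- function(edges, node_universe, score_threshold = 0.4) {
  node_universe <- sort(unique(as.character(node_universe)))
  if (nrow(edges) > 0) {
    stopifnot(all(edges$score >= 0 & edges$score <= 1))
    foreign <- !(edges$node_a %in% node_universe &
                   edges$node_b %in% node_universe)
    if (any(foreign))
      warning(sum(foreign), " edge(s) with endpoint outside the node ",
              "universe dropped")
    e <- edges[!foreign & edges$score >= score_threshold &
                 edges$node_a != edges$node_b, , drop = FALSE]
    a <- pmin(e$node_a, e$node_b)
    b <- pmax(e$node_a, e$node_b)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    e <- data.frame(node_a = a[keep], node_b = b[keep],
                    score = e$score[keep], stringsAsFactors = FALSE)
    e <- e[order(e$node_a, e$node_b), , drop = FALSE]
    rownames(e) <- NULL
    n_foreign <- sum(foreign)
  } else {
    e <- data.frame(node_a = character(), node_b = character(),
                    score = numeric(), stringsAsFactors = FALSE)
    n_foreign <- 0L
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = node_universe)
  structure(list(graph = g, node_universe = node_universe, edges = e,
                 score_threshold = score_threshold,
                 n_dropped_foreign = n_foreign),
            class = "interaction_graph")
}

#' Connected-component summary of an interaction graph
#'
#' The main component is the largest connected component (ties broken by
#' the lexicographically smallest member); \emph{orphans} are all universe
#' nodes outside it — not merely degree-0 nodes, so the component sizes
#' always partition the universe and main + orphans = universe.
#'
#' @param graph an \code{\link{interaction_graph}}.
#' @return list of class \code{component_summary}: \code{sizes} (sorted
#'   decreasing), \code{main_component_ids}, \code{orphan_ids},
#'   \code{main_size}, \code{n_orphans}, \code{main_fraction}.
#' @export
component_summary <- function(graph) {
  comp <- igraph::components(graph$graph)
  members <- split(names(comp$membership), comp$membership)
  sizes <- vapply(members, length, 1L)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    firsts <- vapply(members[biggest], function(m) min(m), "")
    biggest <- biggest[order(firsts)][1]
  }
  main <- sort(members[[biggest]])
  orphans <- sort(setdiff(graph$node_universe, main))
  structure(list(sizes = sort(unname(sizes), decreasing = TRUE),
                 main_component_ids = main,
                 orphan_ids = orphans,
                 main_size = length(main),
                 n_orphans = length(orphans),
                 main_fraction = length(main) / length(graph$node_universe)),
            class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf(
    "component_summary: main %d of %d nodes (%.1f%%), %d orphan(s)\n",
    x$main_size, x$main_size + x$n_orphans, 100 * x$main_fraction,
    x$n_orphans))
  invisible(x)
}

#' Seed neighborhood of an interaction graph
#'
#' Induced subgraph on all nodes within \code{radius} hops of \code{seed}
#' (the seed itself included; radius 0 returns just the seed).
#'
#' @param graph an \code{\link{interaction_graph}}.
#' @param seed node id; must belong to the node universe.
#' @param radius hop count (>= 0).
#' @return an \code{\link{interaction_graph}} restricted to the
#'   neighborhood.
#' @export
extract_neighborhood <- function(graph, seed, radius = 1) {
  if (!(seed %in% graph$node_universe))
    stop("seed '", seed, "' is not in the node universe")
  stopifnot(radius >= 0)
  nb <- igraph::ego(graph$graph, order = radius, nodes = seed)[[1]]
  ids <- sort(names(nb))
  e <- graph$edges[graph$edges$node_a %in% ids & graph$edges$node_b %in% ids, ,
                   drop = FALSE]
  build_graph(e, ids, graph$score_threshold)
}

#' Flag unannotated proteins, partitioned by network membership
#'
#' @param nodes character vector of node ids to screen.
#' @param annotation data.frame with columns \code{id},
#'   \code{description}; an empty, NA or "unknown"-like description marks
#'   a node uncharacterized.
#' @param summary optional \code{\link{component_summary}} used to split
#'   the flagged nodes into orphan vs main-component members.
#' @return data.frame: \code{id}, \code{membership}
#'   ("orphan"/"main"/"unplaced").
#' @export
flag_uncharacterized <- function(nodes, annotation, summary = NULL) {
  desc <- annotation$description[match(nodes, annotation$id)]
  unk <- is.na(desc) | !nzchar(trimws(desc)) |
    grepl("^\\s*unknown\\s*$", desc, ignore.case = TRUE)
  flagged <- sort(nodes[unk])
  membership <- rep("unplaced", length(flagged))
  if (!is.null(summary)) {
    membership[flagged %in% summary$main_component_ids] <- "main"
    membership[flagged %in% summary$orphan_ids] <- "orphan"
  }
  data.frame(id = flagged, membership = membership, stringsAsFactors = FALSE)
}

#' Read a 3-column edge list (STRING export dialect tolerated)
#'
#' @param path TSV with columns node, node, score; a header line is
#'   skipped when detected; an optional id prefix (e.g. "3702.") is
#'   stripped when \code{strip_prefix} is given.
#' @param strip_prefix regular expression removed from both node columns
#'   (default NULL: none).
#' @return data.frame \code{node_a}, \code{node_b}, \code{score}.
#' @export
read_edge_list <- function(path, strip_prefix = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("\t[0-9.eE+-]+\\s*$", first) ||
    grepl("score", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           quote = "", stringsAsFactors = FALSE)
  tab <- tab[, 1:3]
  names(tab) <- c("node_a", "node_b", "score")
  if (!is.null(strip_prefix)) {
    tab$node_a <- sub(strip_prefix, "", tab$node_a)
    tab$node_b <- sub(strip_prefix, "", tab$node_b)
  }
  tab$score <- as.numeric(tab$score)
  tab
}

#' Write an interaction graph for external viewers
#'
#' @param graph an \code{\link{interaction_graph}}.
#' @param sif,graphml,membership optional output paths: SIF edge file,
#'   GraphML, and a component-membership TSV.
#' @return invisibly, the vector of files written.
#' @export
write_graph_files <- function(graph, sif = NULL, graphml = NULL,
                              membership = NULL) {
  written <- character()
  if (!is.null(sif)) {
    writeLines(paste(graph$edges$node_a, "pp", graph$edges$node_b,
                     sep = "\t"), sif)
    written <- c(written, sif)
  }
  if (!is.null(graphml)) {
    igraph::write_graph(graph$graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(membership)) {
    cs <- component_summary(graph)
    tab <- data.frame(id = graph$node_universe,
                      in_main_component =
                        graph$node_universe %in% cs$main_component_ids)
    utils::write.table(tab, membership, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, membership)
  }
  invisible(written)
}
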