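# MeSH disease hierarchy and the path-based semantic similarity used for
# side-effect pruning and validation matching.
#
# Sim(Ci, Cj) = (1 / MAX) * (-log(Dist / (2 * depth))),  MAX = log(2 * depth)
#             = 1 - log(Dist) / log(2 * depth)
#
# Dist is a node count along the shortest path through the hierarchy
# (identical concept = 1, parent-child = 2). With depth = 10 this gives
# 0.768 for a parent-child pair, 0.633 at a two-node distance and 0.231 at
# a nine-node distance; the log base cancels algebraically.

#' Read a MeSH disease vocabulary table
#'
#' @param path TSV with columns \code{mesh_ui, heading, tree_numbers}
#'   (tree numbers pipe-delimited, e.g. \code{C10.228.140|C16.320}).
#'   Such a table is straightforward to derive from an NLM MeSH descriptor
#'   ASCII export: take each descriptor's UI, heading and MN fields and
#'   pipe-join the MN tree numbers.
#' @return a \code{mesh_tree} object: a named list mapping each MeSH UI to
#'   its heading and character vector of dot-delimited tree numbers.
#' @export
read_mesh_tree <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("mesh_ui", "heading", "tree_numbers")
  if (!all(need %in% names(tab)))
    stop("mesh table requires columns: ", paste(need, collapse = ", "))
  mesh_tree(tab$mesh_ui, tab$heading, strsplit(tab$tree_numbers, "|",
                                               fixed = TRUE))
}

#' Construct a MeSH tree object
#'
#' @param ui character vector of MeSH UIs (unique).
#' @param heading character vector of headings.
#' @param trees list of character vectors of tree numbers, parallel to
#'   \code{ui}.
#' @return a \code{mesh_tree}.
#' @export
mesh_tree <- function(ui, heading, trees) {
  if (anyDuplicated(ui)) stop("duplicate MeSH UI(s): ",
                              paste(unique(ui[duplicated(ui)]),
                                    collapse = ", "))
  entries <- mapply(function(h, t) list(heading = h, trees = t),
                    heading, trees, SIMPLIFY = FALSE)
  names(entries) <- ui
  structure(list(entries = entries), class = "mesh_tree")
}

#' @export
print.mesh_tree <- function(x, ...) {
  cat(sprintf("mesh_tree: %d descriptors\n", length(x$entries)))
  invisible(x)
}

#' Similarity parameters
#'
#' @param depth maximum hierarchy depth (default 10); the maximum
#'   attainable score MAX is \code{log(2 * depth)}.
#' @param convention distance convention: \code{"node-count"} counts nodes
#'   on the shortest path (identical = 1, parent-child = 2, the default);
#'   \code{"edge-count"} counts edges (identical = 0).
#' @param log_base base of the logarithm; cancels in the similarity and is
#'   exposed only for inspection of intermediate quantities.
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(depth = 10, convention = c("node-count", "edge-count"),
                       log_base = exp(1)) {
  convention <- match.arg(convention)
  stopifnot(depth >= 1, log_base > 1)
  structure(list(depth = depth, convention = convention,
                 log_base = log_base, max_score = log(2 * depth, log_base)),
            class = "sim_params")
}

#' Shortest-path node distance between two MeSH concepts
#'
#' For every pair of tree numbers of the two concepts that share a common
#' dot-prefix, the path runs up from one tree number to the longest common
#' prefix and down to the other; the distance is the minimum over all such
#' pairs. Under the node-count convention an identical concept has
#' distance 1 and a parent-child pair distance 2. Concepts whose tree
#' numbers share no prefix (different top-level branches) are unreachable
#' and get \code{Inf}.
#'
#' @param tree a \code{mesh_tree}.
#' @param a,b MeSH UIs present in the tree.
#' @param params a \code{\link{sim_params}}.
#' @return numeric distance, or \code{Inf} if unreachable.
#' @export
node_distance <- function(tree, a, b, params = sim_params()) {
  ea <- tree$entries[[a]]; eb <- tree$entries[[b]]
  if (is.null(ea)) stop("unknown MeSH UI: ", a)
  if (is.null(eb)) stop("unknown MeSH UI: ", b)
  base <- if (params$convention == "node-count") 1 else 0
  if (identical(a, b)) return(base)
  ta <- strsplit(ea$trees, ".", fixed = TRUE)
  tb <- strsplit(eb$trees, ".", fixed = TRUE)
  best <- Inf
  for (pa in ta) for (pb in tb) {
    n <- min(length(pa), length(pb))
    if (n == 0L) next
    eq <- pa[seq_len(n)] == pb[seq_len(n)]
    lcp <- if (all(eq)) n else which(!eq)[1L] - 1L
    if (lcp == 0L) next
    d <- (length(pa) - lcp) + (length(pb) - lcp) + base
    if (d < best) best <- d
  }
  best
}

#' Semantic similarity between two MeSH concepts
#'
#' \code{sim_value} maps a precomputed distance to the similarity scale;
#' \code{mesh_sim} composes it with \code{\link{node_distance}}. The score
#' is \code{1 - log(Dist) / log(2 * depth)}, clamped to [0, 1]; unreachable
#' concepts score 0. It is symmetric, equals 1 only for an identical
#' concept, and decreases strictly in the distance until the clamp.
#'
#' @param tree a \code{mesh_tree}.
#' @param a,b MeSH UIs.
#' @param params a \code{\link{sim_params}}.
#' @return similarity in [0, 1].
#' @export
mesh_sim <- function(tree, a, b, params = sim_params()) {
  sim_value(node_distance(tree, a, b, params), params)
}

#' @rdname mesh_sim
#' @param dist a distance as returned by \code{\link{node_distance}}.
#' @export
sim_value <- function(dist, params = sim_params()) {
  if (!is.finite(dist)) return(0)
  if (dist <= 0) dist <- if (params$convention == "edge-count") dist + 1 else
    stop("non-positive distance under node-count convention")
  s <- 1 - log(dist, params$log_base) / params$max_score
  min(max(s, 0), 1)
}

# top-level area code of a tree number ("C10.228.140" -> "C10")
tree_top_level <- function(tree_numbers) {
  vapply(strsplit(tree_numbers, ".", fixed = TRUE), `[[`, character(1), 1L)
}

#' Build a mesh_tree from the disease nodes of a semantic graph
#'
#' Collects every disease node carrying \code{mesh_ui} (and, when present,
#' pipe-delimited \code{mesh_tree} numbers) into a \code{mesh_tree} so the
#' similarity can be evaluated directly against graph node ids' UIs.
#'
#' @param graph a \code{semantic_graph}.
#' @return a \code{mesh_tree}.
#' @export
graph_mesh_tree <- function(graph) {
  dis <- nodes_of_type(graph, DISEASE_TYPES)
  ui <- node_attr(graph, dis, "mesh_ui")
  keep <- !is.na(ui) & ui != ""
  dis <- dis[keep]; ui <- ui[keep]
  keep2 <- !duplicated(ui)
  dis <- dis[keep2]; ui <- ui[keep2]
  tn <- node_attr(graph, dis, "mesh_tree")
  hd <- node_attr(graph, dis, "heading")
  trees <- lapply(tn, function(x)
    if (is.na(x) || x == "") character() else
      strsplit(x, "|", fixed = TRUE)[[1]])
  mesh_tree(ui, ifelse(is.na(hd), "", hd), trees)
}
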