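# Typed property graph: nodes are drugs, proteins, genes and diseases;
# edges are the closed set of semantic relation types. Attributes are kept
# as text and parsed on demand so unknown attributes survive round-trips.

NODE_TYPES <- c("Small_Molecule", "Protein", "Gene",
                "Common_Disease", "Rare_Disease")

EDGE_TYPES <- c("binds_to", "encoded_by", "involved_in",
                "has_indication", "has_side_effect",
                "is_a", "part_of", "has_parent")

DISEASE_TYPES <- c("Common_Disease", "Rare_Disease")

# allowed (source type, target type) pairs per edge type
.edge_schema <- list(
  binds_to        = list(src = "Small_Molecule", dst = "Protein"),
  encoded_by      = list(src = "Protein",        dst = "Gene"),
  involved_in     = list(src = "Gene",           dst = DISEASE_TYPES),
  has_indication  = list(src = "Small_Molecule", dst = DISEASE_TYPES),
  has_side_effect = list(src = "Small_Molecule", dst = DISEASE_TYPES),
  is_a            = list(src = "Common_Disease", dst = "Common_Disease"),
  part_of         = list(src = "Rare_Disease",   dst = "Rare_Disease"),
  has_parent      = list(src = "Rare_Disease",   dst = "Rare_Disease")
)

#' Construct a semantic graph
#'
#' Builds the in-memory typed property graph used throughout the pipeline.
#' Nodes carry a type from the closed set (Small_Molecule, Protein, Gene,
#' Common_Disease, Rare_Disease) and a named-character attribute vector;
#' edges carry a type from the closed relation set plus attributes such as
#' \code{action}, \code{activity_type}, \code{activity_value} (binds_to) or
#' \code{association_score}, \code{directionality} (involved_in).
#'
#' @param nodes data.frame with columns \code{id}, \code{node_type} and a
#'   list column \code{attrs} of named character vectors (may be omitted).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{edge_type} and optionally \code{attrs}; an \code{edge_id} column
#'   is generated when absent.
#' @param validate run the structural validator (default TRUE).
#' @return an object of class \code{semantic_graph}.
#' @export
semantic_graph <- function(nodes = NULL, edges = NULL, validate = TRUE) {
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), node_type = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$attrs)) nodes$attrs <- rep(list(character()), nrow(nodes))
  if (is.null(edges$attrs)) edges$attrs <- rep(list(character()), nrow(edges))
  if (is.null(edges$edge_id)) {
    edges$edge_id <- if (nrow(edges)) sprintf("e%06d", seq_len(nrow(edges)))
                     else character()
  }
  nodes$id <- as.character(nodes$id)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges),
                 class = "semantic_graph")
  if (validate) validate_graph(g)
  g
}

#' Validate a semantic graph
#'
#' Checks the structural invariants: unique node ids, closed node/edge type
#' sets, no dangling endpoints, endpoint type compatibility per edge type,
#' positive activity values where present, and a MeSH UI on every common
#' disease. Errors name the offending record.
#'
#' @param graph a \code{semantic_graph}.
#' @return the graph, invisibly.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "semantic_graph"))
  nodes <- graph$nodes; edges <- graph$edges
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(nodes$node_type), NODE_TYPES)
  if (length(bad)) stop("unknown node type(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(edges$edge_type), EDGE_TYPES)
  if (length(bad)) stop("unknown edge type(s): ", paste(bad, collapse = ", "))
  ntype <- stats::setNames(nodes$node_type, nodes$id)
  dangle <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
  if (any(dangle)) {
    i <- which(dangle)[1L]
    stop(sprintf("dangling edge endpoint in edge %s (%s -> %s)",
                 edges$edge_id[i], edges$source[i], edges$target[i]))
  }
  for (i in seq_len(nrow(edges))) {
    sch <- .edge_schema[[edges$edge_type[i]]]
    st <- ntype[[edges$source[i]]]; tt <- ntype[[edges$target[i]]]
    if (!(st %in% sch$src) || !(tt %in% sch$dst)) {
      stop(sprintf(
        "edge %s: type %s not allowed between %s (%s) and %s (%s)",
        edges$edge_id[i], edges$edge_type[i],
        edges$source[i], st, edges$target[i], tt))
    }
  }
  act <- edge_attr_num(graph, "activity_value")
  if (any(!is.na(act) & act <= 0)) {
    i <- which(!is.na(act) & act <= 0)[1L]
    stop(sprintf("edge %s: activity_value must be > 0", edges$edge_id[i]))
  }
  cd <- nodes$id[nodes$node_type == "Common_Disease"]
  if (length(cd)) {
    ui <- node_attr(graph, cd, "mesh_ui")
    if (any(is.na(ui) | ui == "")) {
      stop("Common_Disease node without mesh_ui attribute: ",
           cd[which(is.na(ui) | ui == "")[1L]])
    }
  }
  invisible(graph)
}

#' @export
print.semantic_graph <- function(x, ...) {
  cat(sprintf("semantic_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$node_type))
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

#' Node attribute accessor
#'
#' @param graph a \code{semantic_graph}.
#' @param ids node ids (recycled lookup; unknown ids give NA).
#' @param key attribute name.
#' @return character vector, NA where the attribute is absent.
#' @export
node_attr <- function(graph, ids, key) {
  idx <- match(ids, graph$nodes$id)
  vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    a <- graph$nodes$attrs[[i]]
    if (key %in% names(a)) as.character(a[[key]]) else NA_character_
  }, character(1))
}

#' Edge attribute accessors
#'
#' \code{edge_attr_chr} returns the raw text value; \code{edge_attr_num}
#' parses it as numeric on demand (lazy typing: unparseable or absent
#' values give NA without error).
#'
#' @param graph a \code{semantic_graph}.
#' @param key attribute name.
#' @param rows optional integer row subset of the edge table.
#' @return vector aligned with the (subset) edge table.
#' @export
edge_attr_chr <- function(graph, key, rows = NULL) {
  at <- graph$edges$attrs
  if (!is.null(rows)) at <- at[rows]
  vapply(at, function(a) {
    if (key %in% names(a)) as.character(a[[key]]) else NA_character_
  }, character(1))
}

#' @rdname edge_attr_chr
#' @export
edge_attr_num <- function(graph, key, rows = NULL) {
  suppressWarnings(as.numeric(edge_attr_chr(graph, key, rows)))
}

## attribute-block (de)serialisation: key=value;key=value, URL-escaped

.encode_attrs <- function(attr_list) {
  vapply(attr_list, function(a) {
    if (!length(a)) return("")
    paste(sprintf("%s=%s",
                  vapply(names(a), utils::URLencode, character(1),
                         reserved = TRUE),
                  vapply(as.character(a), utils::URLencode, character(1),
                         reserved = TRUE)),
          collapse = ";")
  }, character(1))
}

.decode_attrs <- function(txt) {
  lapply(txt, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
    keys <- vapply(kv, function(p) utils::URLdecode(p[1]), character(1))
    vals <- vapply(kv, function(p)
      if (length(p) > 1) utils::URLdecode(p[2]) else "", character(1))
    stats::setNames(vals, keys)
  })
}

#' Load a semantic graph from TSV tables
#'
#' Two dialects are accepted, auto-detected by header. The two-file layout
#' has \code{nodes.tsv} (\code{id, node_type, attrs}) and \code{edges.tsv}
#' (\code{source_id, target_id, edge_type, attrs}); attribute blocks are
#' semicolon-delimited \code{key=value} pairs with URL-escaped keys and
#' values. The single-file edge-list dialect repeats node attributes on
#' each row (\code{source_id, source_type, source_attrs, target_id,
#' target_type, target_attrs, edge_type, attrs}).
#'
#' After loading, nodes with no incident edge are dropped (the integrated
#' network is defined over connected entities); the number dropped is
#' reported via message.
#'
#' @param nodes_table path to the node table, or to the single-file
#'   edge-list dialect.
#' @param edges_table path to the edge table; omit for the single-file
#'   dialect.
#' @param drop_isolated drop unconnected nodes after load (default TRUE).
#' @return a validated \code{semantic_graph}.
#' @export
load_graph <- function(nodes_table, edges_table = NULL,
                       drop_isolated = TRUE) {
  read_tsv <- function(p) utils::read.delim(
    p, sep = "\t", header = TRUE, colClasses = "character",
    stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (is.null(edges_table)) {
    tab <- read_tsv(nodes_table)
    need <- c("source_id", "source_type", "source_attrs",
              "target_id", "target_type", "target_attrs",
              "edge_type", "attrs")
    if (!all(need %in% names(tab)))
      stop("single-file dialect requires columns: ",
           paste(need, collapse = ", "))
    nid <- c(tab$source_id, tab$target_id)
    nty <- c(tab$source_type, tab$target_type)
    nat <- c(tab$source_attrs, tab$target_attrs)
    keep <- !duplicated(nid)
    nodes <- data.frame(id = nid[keep], node_type = nty[keep],
                        stringsAsFactors = FALSE)
    nodes$attrs <- .decode_attrs(nat[keep])
    edges <- data.frame(source = tab$source_id, target = tab$target_id,
                        edge_type = tab$edge_type, stringsAsFactors = FALSE)
    edges$attrs <- .decode_attrs(tab$attrs)
  } else {
    ntab <- read_tsv(nodes_table)
    etab <- read_tsv(edges_table)
    if (!all(c("id", "node_type") %in% names(ntab)))
      stop("node table requires columns id, node_type")
    if (!all(c("source_id", "target_id", "edge_type") %in% names(etab)))
      stop("edge table requires columns source_id, target_id, edge_type")
    nodes <- data.frame(id = ntab$id, node_type = ntab$node_type,
                        stringsAsFactors = FALSE)
    nodes$attrs <- .decode_attrs(if (is.null(ntab$attrs)) rep("", nrow(ntab))
                                 else ntab$attrs)
    edges <- data.frame(source = etab$source_id, target = etab$target_id,
                        edge_type = etab$edge_type, stringsAsFactors = FALSE)
    edges$attrs <- .decode_attrs(if (is.null(etab$attrs)) rep("", nrow(etab))
                                 else etab$attrs)
  }
  g <- semantic_graph(nodes, edges, validate = FALSE)
  validate_graph(g)
  if (drop_isolated && nrow(g$nodes)) {
    connected <- g$nodes$id %in% c(g$edges$source, g$edges$target)
    n_drop <- sum(!connected)
    if (n_drop > 0) {
      message(sprintf("load_graph: dropped %d unconnected node(s)", n_drop))
      g$nodes <- g$nodes[connected, , drop = FALSE]
      rownames(g$nodes) <- NULL
    }
  }
  g
}

#' Save a semantic graph to TSV tables
#'
#' Writes the two-file layout read by \code{\link{load_graph}}; the
#' round trip reproduces the graph exactly (same node and edge multisets
#' with attributes).
#'
#' @param graph a \code{semantic_graph}.
#' @param nodes_table,edges_table output paths.
#' @return invisibly, the two paths.
#' @export
save_graph <- function(graph, nodes_table, edges_table) {
  validate_graph(graph)
  ntab <- data.frame(id = graph$nodes$id,
                     node_type = graph$nodes$node_type,
                     attrs = .encode_attrs(graph$nodes$attrs),
                     stringsAsFactors = FALSE)
  etab <- data.frame(source_id = graph$edges$source,
                     target_id = graph$edges$target,
                     edge_type = graph$edges$edge_type,
                     attrs = .encode_attrs(graph$edges$attrs),
                     stringsAsFactors = FALSE)
  utils::write.table(ntab, nodes_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(etab, edges_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_table, edges_table))
}

#' Merge rare-disease MeSH synonyms
#'
#' Rare diseases may carry a synonymous MeSH UI. Wherever that UI is also
#' present as a Common_Disease node, the two nodes are merged into a single
#' Rare_Disease node: the common-disease node's edges are re-pointed to the
#' rare-disease node and its attributes (MeSH tree numbers, heading) are
#' copied in where the rare node lacks them. No edge is lost; node count
#' decreases by one per merge. If two rare diseases claim the same UI the
#' first in id order wins, with a warning.
#'
#' @param graph a \code{semantic_graph}.
#' @return a new merged \code{semantic_graph}.
#' @export
merge_rare_disease_synonyms <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  rare <- which(nodes$node_type == "Rare_Disease")
  if (!length(rare)) return(graph)
  rui <- node_attr(graph, nodes$id[rare], "mesh_ui")
  has_ui <- which(!is.na(rui) & rui != "")
  if (!length(has_ui)) return(graph)
  rare <- rare[has_ui]; rui <- rui[has_ui]
  ord <- order(nodes$id[rare])
  rare <- rare[ord]; rui <- rui[ord]
  if (anyDuplicated(rui)) {
    dupes <- unique(rui[duplicated(rui)])
    warning("multiple rare diseases claim MeSH UI(s) ",
            paste(dupes, collapse = ", "),
            "; merging into the first by id order")
    keep <- !duplicated(rui)
    rare <- rare[keep]; rui <- rui[keep]
  }
  common <- which(nodes$node_type == "Common_Disease")
  cui <- node_attr(graph, nodes$id[common], "mesh_ui")
  remap <- character()   # common node id -> rare node id
  drop_ids <- character()
  for (k in seq_along(rare)) {
    hit <- common[cui == rui[k]]
    if (!length(hit)) next
    cid <- nodes$id[hit[1L]]; rid <- nodes$id[rare[k]]
    remap[cid] <- rid
    drop_ids <- c(drop_ids, cid)
    ca <- nodes$attrs[[hit[1L]]]; ra <- nodes$attrs[[rare[k]]]
    add <- setdiff(names(ca), names(ra))
    nodes$attrs[[rare[k]]] <- c(ra, ca[add])
  }
  if (!length(remap)) return(graph)
  hit_s <- edges$source %in% names(remap)
  hit_t <- edges$target %in% names(remap)
  edges$source[hit_s] <- remap[edges$source[hit_s]]
  edges$target[hit_t] <- remap[edges$target[hit_t]]
  nodes <- nodes[!(nodes$id %in% drop_ids), , drop = FALSE]
  semantic_graph(nodes, edges)
}

#' Export to GraphML
#'
#' Flattens node and edge attributes to columns and writes GraphML via
#' igraph, for interoperability with graph databases and visualisers.
#'
#' @param graph a \code{semantic_graph}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
export_graphml <- function(graph, path) {
  validate_graph(graph)
  flat <- function(attr_list) {
    keys <- unique(unlist(lapply(attr_list, names)))
    out <- lapply(keys, function(k)
      vapply(attr_list, function(a) {
        if (k %in% names(a)) as.character(a[[k]]) else NA_character_
      }, character(1)))
    stats::setNames(out, keys)
  }
  vdf <- data.frame(name = graph$nodes$id,
                    node_type = graph$nodes$node_type,
                    stringsAsFactors = FALSE)
  for (kv in names(fl <- flat(graph$nodes$attrs))) {
    col <- if (kv %in% names(vdf)) paste0("attr_", kv) else kv
    vdf[[col]] <- fl[[kv]]
  }
  edf <- data.frame(from = graph$edges$source, to = graph$edges$target,
                    edge_type = graph$edges$edge_type,
                    edge_id = graph$edges$edge_id,
                    stringsAsFactors = FALSE)
  for (kv in names(fl <- flat(graph$edges$attrs))) {
    col <- if (kv %in% names(edf)) paste0("attr_", kv) else kv
    edf[[col]] <- fl[[kv]]
  }
  ig <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

# edges of a given type, as the edge-table subset
edges_of_type <- function(graph, type) {
  graph$edges[graph$edges$edge_type == type, , drop = FALSE]
}

# ids of nodes of a given type
nodes_of_type <- function(graph, type) {
  graph$nodes$id[graph$nodes$node_type %in% type]
}

# resolve a disease node id to its MeSH UI (NA if none: e.g. a rare
# disease without a synonymous UI)
disease_mesh_ui <- function(graph, ids) {
  node_attr(graph, ids, "mesh_ui")
}
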