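# Exhaustive enumeration of the four-node semantic subgraph
#
#   drug --binds_to--> protein --encoded_by--> gene --involved_in--> disease
#
# over approved small molecules. Each concrete match (a mapping) is scored
# as the mean of the normalised binding activity and the association score
# of its involved_in edge; mappings inferring the same (drug, disease)
# pair are then collapsed to the best-scoring one.

#' Candidate drug set for mining
#'
#' All Small_Molecule nodes whose \code{group} attribute (pipe- or
#' comma-delimited list) contains \code{approved}.
#'
#' @param graph a \code{semantic_graph}.
#' @return character vector of drug node ids.
#' @export
candidate_drugs <- function(graph) {
  drugs <- nodes_of_type(graph, "Small_Molecule")
  if (!length(drugs)) return(character())
  grp <- node_attr(graph, drugs, "group")
  has_approved <- vapply(grp, function(g) {
    if (is.na(g)) return(FALSE)
    "approved" %in% tolower(trimws(strsplit(g, "[|,;]")[[1]]))
  }, logical(1))
  drugs[has_approved]
}

#' Normalise a binding activity to the association-score scale
#'
#' A measured activity v (nM; IC50, Ki, Kd or Potency) maps to
#' \code{1 - scale * log10(v)} clamped to \code{[lo, hi]}, so 1 nM scores
#' 1.0 and 100 nM scores 0.8. A missing value (a binds_to edge recorded
#' without an activity, as for DrugBank interactions) is assigned 0.8 so
#' such mappings are neither lost nor over-weighted.
#'
#' @param value numeric vector of activities in nM; NA = missing.
#' @param missing_value score assigned to missing activities (default
#'   0.8).
#' @param scale log10 coefficient (default 0.1).
#' @param lo,hi clamp bounds (default 0 and 1).
#' @return numeric vector of normalised activities in \code{[lo, hi]}.
#' @export
normalize_activity <- function(value, missing_value = 0.8, scale = 0.1,
                               lo = 0, hi = 1) {
  if (any(!is.na(value) & value <= 0))
    stop("activity value must be > 0 nM")
  out <- ifelse(is.na(value), missing_value,
                pmin(pmax(1 - scale * log10(value), lo), hi))
  as.numeric(out)
}

#' Score one subgraph mapping
#'
#' The arithmetic mean of the normalised activity and the association
#' score; both must already lie in [0, 1].
#'
#' @param norm_activity,association_score numeric vectors in [0, 1].
#' @return mapping scores in [0, 1].
#' @export
score_mapping <- function(norm_activity, association_score) {
  if (any(norm_activity < 0 | norm_activity > 1, na.rm = FALSE) ||
      any(association_score < 0 | association_score > 1, na.rm = FALSE))
    stop("inputs must lie in [0, 1]")
  (norm_activity + association_score) / 2
}

#' Find all semantic-subgraph mappings
#'
#' Exhaustively enumerates every drug-protein-gene-disease path whose drug
#' is in the candidate set, following one binds_to, one encoded_by and one
#' involved_in edge; the disease end may be common or rare. Parallel
#' binds_to edges (several activity measurements for one drug-protein
#' pair) each yield their own mapping. Every involved_in edge traversed
#' must carry an \code{association_score} attribute. Output order is
#' deterministic: (drug, disease, decreasing score, edge ids).
#'
#' @param graph a \code{semantic_graph}.
#' @param candidates drug ids to mine from (default
#'   \code{\link{candidate_drugs}}).
#' @return data.frame with one row per mapping: \code{drug, protein, gene,
#'   disease, raw_activity_nM, norm_activity, association_score,
#'   mapping_score, action, directionality, binds_edge, encoded_edge,
#'   involved_edge}.
#' @export
find_mappings <- function(graph, candidates = candidate_drugs(graph)) {
  empty <- data.frame(drug = character(), protein = character(),
                      gene = character(), gene_symbol = character(),
                      disease = character(),
                      raw_activity_nM = numeric(),
                      norm_activity = numeric(),
                      association_score = numeric(),
                      mapping_score = numeric(),
                      action = character(), directionality = character(),
                      binds_edge = character(), encoded_edge = character(),
                      involved_edge = character(), stringsAsFactors = FALSE)
  bt <- edges_of_type(graph, "binds_to")
  bt <- bt[bt$source %in% candidates, , drop = FALSE]
  eb <- edges_of_type(graph, "encoded_by")
  ii <- edges_of_type(graph, "involved_in")
  if (!nrow(bt) || !nrow(eb) || !nrow(ii)) return(empty)
  b <- data.frame(drug = bt$source, protein = bt$target,
                  binds_edge = bt$edge_id, stringsAsFactors = FALSE)
  b$raw_activity_nM <- vapply(bt$attrs, function(a) {
    if ("activity_value" %in% names(a))
      suppressWarnings(as.numeric(a[["activity_value"]]))
    else NA_real_
  }, numeric(1))
  b$action <- vapply(bt$attrs, function(a) {
    if ("action" %in% names(a)) as.character(a[["action"]])
    else NA_character_
  }, character(1))
  e <- data.frame(protein = eb$source, gene = eb$target,
                  encoded_edge = eb$edge_id, stringsAsFactors = FALSE)
  i <- data.frame(gene = ii$source, disease = ii$target,
                  involved_edge = ii$edge_id, stringsAsFactors = FALSE)
  i$association_score <- vapply(ii$attrs, function(a) {
    if ("association_score" %in% names(a))
      suppressWarnings(as.numeric(a[["association_score"]]))
    else NA_real_
  }, numeric(1))
  if (anyNA(i$association_score))
    stop("involved_in edge without association_score: ",
         i$involved_edge[which(is.na(i$association_score))[1L]])
  i$directionality <- vapply(ii$attrs, function(a) {
    v <- if ("directionality" %in% names(a)) a[["directionality"]] else NA
    if (is.na(v) || !v %in% c("LoF", "GoF")) "unknown" else v
  }, character(1))
  m <- merge(b, e, by = "protein")
  if (!nrow(m)) return(empty)
  m <- merge(m, i, by = "gene")
  if (!nrow(m)) return(empty)
  m$norm_activity <- normalize_activity(m$raw_activity_nM)
  m$mapping_score <- score_mapping(m$norm_activity, m$association_score)
  sym <- node_attr(graph, m$gene, "symbol")
  m$gene_symbol <- ifelse(is.na(sym) | sym == "", m$gene, sym)
  m <- m[order(m$drug, m$disease, -m$mapping_score, m$binds_edge,
               m$encoded_edge, m$involved_edge),
         c("drug", "protein", "gene", "gene_symbol", "disease",
           "raw_activity_nM",
           "norm_activity", "association_score", "mapping_score",
           "action", "directionality", "binds_edge", "encoded_edge",
           "involved_edge")]
  rownames(m) <- NULL
  m
}

#' Collapse mappings to unique inferred indications
#'
#' Groups mappings by (drug, disease) and keeps the highest-scoring
#' mapping per group; score ties are broken by lexicographic (protein,
#' gene, binds edge id). Known indications are deliberately not excluded
#' (rediscovery of knowns is how the approach is validated).
#'
#' @param mappings output of \code{\link{find_mappings}} (possibly
#'   filtered).
#' @return data.frame with one row per (drug, disease): all mapping
#'   columns of the winning mapping plus \code{n_mappings}, sorted by
#'   decreasing score then (drug, disease).
#' @export
dedupe_mappings <- function(mappings) {
  if (!nrow(mappings)) {
    out <- mappings
    out$n_mappings <- integer()
    return(out)
  }
  o <- order(mappings$drug, mappings$disease, -mappings$mapping_score,
             mappings$protein, mappings$gene, mappings$binds_edge)
  m <- mappings[o, , drop = FALSE]
  key <- paste(m$drug, m$disease, sep = "\r")
  first <- !duplicated(key)
  out <- m[first, , drop = FALSE]
  out$n_mappings <- as.integer(table(key)[key[first]])
  out <- out[order(-out$mapping_score, out$drug, out$disease), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write mappings / indications to TSV
#'
#' @param mappings a mapping or indication data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mappings <- function(mappings, path) {
  utils::write.table(mappings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
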