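# Validation of inferred indications against known drug-disease
# indications, with similarity-tolerant matching: a known indication
# counts as identified when the same drug has an inferred indication
# whose disease is within a MeSH similarity threshold of the known
# disease (0.633, a two-node distance, by default).

#' Read known indications
#'
#' @param path TSV with columns \code{drug, mesh_ui} and optional
#'   \code{source}.
#' @return data.frame \code{drug, mesh_ui, source}, deduplicated on
#'   (drug, disease).
#' @export
read_known_indications <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("drug", "mesh_ui") %in% names(tab)))
    stop("known-indication table requires columns drug, mesh_ui")
  if (is.null(tab$source)) tab$source <- ""
  tab <- tab[!duplicated(tab[c("drug", "mesh_ui")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# resolve the disease column of an inferred-indication table to MeSH UIs
.inferred_uis <- function(inferred, graph) {
  if (!is.null(graph)) {
    ui <- disease_mesh_ui(graph, inferred$disease)
    ifelse(is.na(ui), inferred$disease, ui)
  } else {
    inferred$disease
  }
}

#' Match known indications to inferred ones
#'
#' A known (drug, disease) is identified iff some inferred indication of
#' the same drug involves a disease with \code{Sim >= threshold} to it;
#' an exact disease match counts as Sim 1 even when the disease has no
#' usable position in the tree (so rare diseases without a MeSH UI can
#' still be rediscovered exactly).
#'
#' @param inferred inferred indications (\code{\link{dedupe_mappings}}).
#' @param known known indications (\code{\link{read_known_indications}}).
#' @param tree a \code{mesh_tree}.
#' @param threshold Sim threshold in [0, 1] (default 0.633); values above
#'   1 restrict matching to exact identity.
#' @param graph optional \code{semantic_graph} used to resolve inferred
#'   disease node ids to MeSH UIs; without it the \code{disease} column is
#'   taken to hold UIs already.
#' @return logical vector along \code{known}: identified or not.
#' @export
match_known <- function(inferred, known, tree, threshold = 0.633,
                        graph = NULL) {
  if (!nrow(known)) return(logical())
  uis <- .inferred_uis(inferred, graph)
  by_drug <- split(seq_len(nrow(inferred)), inferred$drug)
  simcache <- new.env(parent = emptyenv())
  sim_pair <- function(a, b) {
    k <- paste(a, b, sep = "\r")
    if (!is.null(simcache[[k]])) return(simcache[[k]])
    v <- if (is.null(tree$entries[[a]]) || is.null(tree$entries[[b]])) 0
         else mesh_sim(tree, a, b)
    simcache[[k]] <- v
    v
  }
  vapply(seq_len(nrow(known)), function(j) {
    idx <- by_drug[[known$drug[j]]]
    if (is.null(idx)) return(FALSE)
    cand <- unique(uis[idx])
    if (known$mesh_ui[j] %in% cand) return(TRUE)   # exact match: Sim = 1
    if (threshold > 1) return(FALSE)
    for (u in cand) if (sim_pair(known$mesh_ui[j], u) >= threshold)
      return(TRUE)
    FALSE
  }, logical(1))
}

#' Recall of known indications across similarity thresholds
#'
#' @param inferred,known,tree,graph as in \code{\link{match_known}}.
#' @param thresholds ascending numeric grid of Sim thresholds.
#' @param prune_unreachable use as denominator only knowns whose drug
#'   produced at least one inference (default TRUE).
#' @return data.frame \code{threshold, n_identified, recall}; recall is
#'   non-increasing in the threshold.
#' @export
recall_curve <- function(inferred, known, tree,
                         thresholds = c(0.231, 0.633, 0.768, 1.0),
                         graph = NULL, prune_unreachable = TRUE) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  reachable <- known$drug %in% inferred$drug
  denom <- if (prune_unreachable) sum(reachable) else nrow(known)
  n_id <- vapply(thresholds, function(th)
    sum(match_known(inferred, known, tree, th, graph)), numeric(1))
  data.frame(threshold = thresholds, n_identified = as.integer(n_id),
             recall = if (denom > 0) n_id / denom else NA_real_)
}

#' ROC AUC of inferred-indication scores against known indications
#'
#' Labels every inferred indication positive iff it matches some known
#' indication of the same drug at the Sim threshold, then computes the
#' AUC of the mapping scores by the rank statistic (midranks for ties).
#'
#' @param inferred inferred indications with a \code{mapping_score}
#'   column.
#' @param known,tree,threshold,graph as in \code{\link{match_known}}.
#' @return the AUC in [0, 1].
#' @export
roc_auc <- function(inferred, known, tree, threshold = 0.633,
                    graph = NULL) {
  if (!nrow(inferred)) stop("no inferred indications")
  uis <- .inferred_uis(inferred, graph)
  kn_by_drug <- split(known$mesh_ui, known$drug)
  simcache <- new.env(parent = emptyenv())
  sim_pair <- function(a, b) {
    k <- paste(a, b, sep = "\r")
    if (!is.null(simcache[[k]])) return(simcache[[k]])
    v <- if (is.null(tree$entries[[a]]) || is.null(tree$entries[[b]])) 0
         else mesh_sim(tree, a, b)
    simcache[[k]] <- v
    v
  }
  labels <- vapply(seq_len(nrow(inferred)), function(j) {
    kn <- kn_by_drug[[inferred$drug[j]]]
    if (is.null(kn)) return(FALSE)
    if (uis[j] %in% kn) return(TRUE)
    if (threshold > 1) return(FALSE)
    for (u in kn) if (sim_pair(u, uis[j]) >= threshold) return(TRUE)
    FALSE
  }, logical(1))
  rank_auc(inferred$mapping_score, labels)
}

#' Validation report
#'
#' @param inferred,known,tree,threshold,graph as in
#'   \code{\link{match_known}}.
#' @return list: \code{n_known}, \code{n_known_reachable} (knowns whose
#'   drug produced at least one inference), \code{n_identified},
#'   \code{recall} (= identified / reachable), \code{auc} (NA when only
#'   one class is present), \code{sim_threshold}.
#' @export
validation_report <- function(inferred, known, tree, threshold = 0.633,
                              graph = NULL) {
  reachable <- known$drug %in% inferred$drug
  ident <- match_known(inferred, known, tree, threshold, graph)
  auc <- tryCatch(roc_auc(inferred, known, tree, threshold, graph),
                  error = function(e) NA_real_)
  list(n_known = nrow(known),
       n_known_reachable = sum(reachable),
       n_identified = sum(ident),
       recall = if (sum(reachable) > 0) sum(ident) / sum(reachable)
                else NA_real_,
       auc = auc,
       sim_threshold = threshold)
}
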