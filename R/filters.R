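# Three-stage pruning cascade over mined mappings:
#   1. side-effect similarity: an inferred indication too close (Sim >= ET)
#      to a known side effect of the same drug is a likely side effect;
#   2. mechanism contradiction: an inhibitory drug acting through a
#      loss-of-function association (or an activating drug through a
#      gain-of-function one) cannot plausibly treat the disease;
#   3. ADME genes: paths through absorption/distribution/metabolism/
#      excretion genes are pharmacokinetic artifacts.
# Each stage's removal predicate depends only on the mapping itself, so
# the final kept set is order-invariant; per-stage counts are not.

#' Filter configuration
#'
#' @param equivalence_threshold Sim value at or above which an inferred
#'   disease counts as equivalent to a known side effect (default 0.768,
#'   one node away in the MeSH hierarchy).
#' @param inhibitory_actions,activating_actions action-term sets for the
#'   directionality filter (case-insensitive; must be disjoint). The
#'   defaults are an editable classification, not a canonical table.
#' @param adme_genes character vector of ADME gene symbols (matched
#'   case-insensitively).
#' @param stage_order order in which the cascade applies the stages.
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(
    equivalence_threshold = 0.768,
    inhibitory_actions = c("antagonist", "inhibitor", "blocker",
                           "negative allosteric modulator",
                           "inverse agonist"),
    activating_actions = c("agonist", "activator",
                           "positive allosteric modulator",
                           "partial agonist", "opener", "inducer"),
    adme_genes = character(),
    stage_order = c("side_effect", "directionality", "adme")) {
  # ET > 1 is allowed: Sim never exceeds 1, so only exact node matches
  # are then removed
  stopifnot(equivalence_threshold >= 0)
  inhibitory_actions <- tolower(inhibitory_actions)
  activating_actions <- tolower(activating_actions)
  if (length(intersect(inhibitory_actions, activating_actions)))
    stop("inhibitory and activating action sets must be disjoint")
  stopifnot(all(stage_order %in% c("side_effect", "directionality",
                                   "adme")))
  structure(list(equivalence_threshold = equivalence_threshold,
                 inhibitory_actions = inhibitory_actions,
                 activating_actions = activating_actions,
                 adme_genes = toupper(adme_genes),
                 stage_order = stage_order),
            class = "filter_config")
}

#' Read an ADME gene list
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with \code{#} ignored.
#' @return character vector of symbols.
#' @export
read_adme_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# logical removal mask for the side-effect stage
.se_mask <- function(mappings, graph, tree, config) {
  if (!nrow(mappings)) return(logical())
  et <- config$equivalence_threshold
  se <- edges_of_type(graph, "has_side_effect")
  se_by_drug <- split(se$target, se$source)
  ui_of <- function(ids) {
    u <- disease_mesh_ui(graph, ids)
    ifelse(!is.na(u) & u != "" & vapply(u, function(x)
      !is.null(tree$entries[[x]]), logical(1)), u, NA_character_)
  }
  simcache <- new.env(parent = emptyenv())
  sim_pair <- function(a, b) {
    k <- paste(a, b, sep = "\r")
    if (!is.null(simcache[[k]])) return(simcache[[k]])
    v <- mesh_sim(tree, a, b)
    simcache[[k]] <- v
    v
  }
  map_ui <- ui_of(mappings$disease)
  vapply(seq_len(nrow(mappings)), function(j) {
    ses <- se_by_drug[[mappings$drug[j]]]
    if (is.null(ses)) return(FALSE)
    if (mappings$disease[j] %in% ses) return(TRUE)     # exact node match
    if (is.na(map_ui[j])) return(FALSE)  # no MeSH UI: exact matching only
    for (u in ui_of(unique(ses))) {
      if (!is.na(u) && sim_pair(map_ui[j], u) >= et) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# logical removal mask for the mechanism/directionality stage
.dir_mask <- function(mappings, config) {
  if (!nrow(mappings)) return(logical())
  act <- tolower(trimws(ifelse(is.na(mappings$action), "",
                               mappings$action)))
  dir <- mappings$directionality
  known <- act %in% c(config$inhibitory_actions, config$activating_actions)
  unrec <- unique(act[nzchar(act) & !known])
  if (length(unrec))
    message("filter_directionality: unrecognised action term(s) kept: ",
            paste(unrec, collapse = ", "))
  (act %in% config$inhibitory_actions & dir == "LoF") |
    (act %in% config$activating_actions & dir == "GoF")
}

# logical removal mask for the ADME stage
.adme_mask <- function(mappings, config) {
  if (!nrow(mappings)) return(logical())
  if (!length(config$adme_genes)) {
    warning("filter_adme: empty ADME gene list; nothing removed")
    return(rep(FALSE, nrow(mappings)))
  }
  toupper(mappings$gene_symbol) %in% config$adme_genes
}

#' Side-effect similarity filter
#'
#' Removes a mapping iff its drug has a recorded side effect on the same
#' disease node, or on any disease whose MeSH similarity to the inferred
#' disease is at least the equivalence threshold. Rare diseases without a
#' synonymous MeSH UI participate by exact node matching only.
#'
#' @param mappings mapping data.frame (\code{\link{find_mappings}}).
#' @param graph a \code{semantic_graph} (supplies has_side_effect edges).
#' @param tree a \code{mesh_tree}.
#' @param config a \code{\link{filter_config}}.
#' @return list with elements \code{kept} and \code{removed}.
#' @export
filter_side_effects <- function(mappings, graph, tree,
                                config = filter_config()) {
  m <- .se_mask(mappings, graph, tree, config)
  list(kept = mappings[!m, , drop = FALSE],
       removed = mappings[m, , drop = FALSE])
}

#' Mechanism/directionality contradiction filter
#'
#' Removes a mapping iff its binding action is inhibitory while the
#' gene-disease association is loss-of-function, or activating while the
#' association is gain-of-function. Missing annotations on either side
#' keep the mapping; unrecognised action terms are kept and reported for
#' triage.
#'
#' @inheritParams filter_side_effects
#' @return list with elements \code{kept} and \code{removed}.
#' @export
filter_directionality <- function(mappings, config = filter_config()) {
  m <- .dir_mask(mappings, config)
  list(kept = mappings[!m, , drop = FALSE],
       removed = mappings[m, , drop = FALSE])
}

#' ADME gene filter
#'
#' Removes a mapping iff its gene symbol is in the configured ADME list
#' (case-insensitive). An empty list is a warning no-op.
#'
#' @inheritParams filter_side_effects
#' @return list with elements \code{kept} and \code{removed}.
#' @export
filter_adme <- function(mappings, config = filter_config()) {
  m <- .adme_mask(mappings, config)
  list(kept = mappings[!m, , drop = FALSE],
       removed = mappings[m, , drop = FALSE])
}

#' Run the full pruning cascade
#'
#' Applies the three filters in the configured stage order and reports
#' per-stage removal counts under two accountings: \code{sequential}
#' (removals from the shrinking survivor set, order-dependent) and
#' \code{independent} (each predicate evaluated on the full input,
#' overlaps visible). The final kept set is identical under any stage
#' order.
#'
#' @inheritParams filter_side_effects
#' @return list with \code{kept} (surviving mappings), \code{counts}
#'   (named sequential removal counts), \code{counts_independent}, and
#'   \code{removed} (list of per-stage removed data.frames, sequential).
#' @export
run_cascade <- function(mappings, graph, tree, config = filter_config()) {
  masks <- list(
    side_effect = function(m) .se_mask(m, graph, tree, config),
    directionality = function(m) .dir_mask(m, config),
    adme = function(m) .adme_mask(m, config))
  indep <- vapply(config$stage_order,
                  function(s) sum(masks[[s]](mappings)), numeric(1))
  kept <- mappings
  counts <- stats::setNames(integer(length(config$stage_order)),
                            config$stage_order)
  removed <- list()
  for (s in config$stage_order) {
    msk <- masks[[s]](kept)
    counts[s] <- sum(msk)
    removed[[s]] <- kept[msk, , drop = FALSE]
    kept <- kept[!msk, , drop = FALSE]
  }
  rownames(kept) <- NULL
  list(kept = kept, counts = counts,
       counts_independent = indep, removed = removed)
}
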