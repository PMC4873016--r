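# End-to-end pipeline: rank evidence, build the integrated graph, score
# therapeutic areas, mine the semantic subgraph, run the pruning cascade,
# deduplicate to indications and validate against knowns. Every stage
# writes TSV intermediates and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the method's standard settings: D = 5, equivalence
#' threshold 0.768, validation Sim threshold 0.633, hierarchy depth 10.
#'
#' @param D weighted-sum divisor.
#' @param equivalence_threshold Sim threshold for the side-effect filter.
#' @param validation_sim Sim threshold for validation matching.
#' @param depth hierarchy depth for the similarity.
#' @param size_factor_mode TAU size-term mode (\code{\link{area_tau}}).
#' @param universe prior universe mode (\code{\link{ranking_config}}).
#' @param zero_cell zero-cell policy for the LLS
#'   (\code{\link{ranking_config}}).
#' @param inhibitory_actions,activating_actions action-term sets
#'   (\code{\link{filter_config}}).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed drives fixture generation when used).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(D = 5.0, equivalence_threshold = 0.768,
                            validation_sim = 0.633, depth = 10,
                            size_factor_mode = "linear",
                            universe = "captured",
                            zero_cell = "pseudocount",
                            inhibitory_actions = NULL,
                            activating_actions = NULL,
                            seed = 1L) {
  fc <- filter_config()
  structure(list(
    D = D, equivalence_threshold = equivalence_threshold,
    validation_sim = validation_sim, depth = depth,
    size_factor_mode = size_factor_mode, universe = universe,
    zero_cell = zero_cell,
    inhibitory_actions = if (is.null(inhibitory_actions))
      fc$inhibitory_actions else tolower(inhibitory_actions),
    activating_actions = if (is.null(activating_actions))
      fc$activating_actions else tolower(activating_actions),
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a fixture directory back into a bundle
#'
#' Reads the files written by \code{\link{write_fixture}} (the truth
#' manifest is loaded when present).
#'
#' @param dir directory path.
#' @return a \code{fixture_bundle}-shaped list.
#' @export
read_fixture <- function(dir) {
  rt <- function(name) utils::read.delim(
    file.path(dir, name), sep = "\t", header = TRUE,
    colClasses = "character", stringsAsFactors = FALSE, quote = "")
  tg <- rt("targets.tsv")
  tg$activity_value <- suppressWarnings(as.numeric(tg$activity_value))
  tg$action[tg$action %in% c("", "NA")] <- NA_character_
  bundle <- list(mesh = rt("mesh.tsv"), evidence = rt("evidence.tsv"),
                 mapping = rt("mapping.tsv"), drugs = rt("drugs.tsv"),
                 targets = tg, indications = rt("indications.tsv"),
                 side_effects = rt("side_effects.tsv"),
                 rare_diseases = rt("rare_diseases.tsv"),
                 adme_genes = read_adme_genes(file.path(dir,
                                                        "adme_genes.txt")),
                 truth = if (file.exists(file.path(dir, "truth.json")))
                   jsonlite::read_json(file.path(dir, "truth.json"),
                                       simplifyVector = TRUE) else NULL)
  class(bundle) <- "fixture_bundle"
  bundle
}

# evidence file layout -> internal evidence columns
as_evidence <- function(df) {
  ev <- data.frame(source_id = df$source_id, source_type = df$source_type,
                   gene = df$gene_symbol, mesh_ui = df$mesh_ui,
                   directionality = if (is.null(df$directionality))
                     "unknown" else ifelse(df$directionality %in%
                                             c("LoF", "GoF"),
                                           df$directionality, "unknown"),
                   stringsAsFactors = FALSE)
  ev[!duplicated(ev[c("source_id", "gene", "mesh_ui")]), , drop = FALSE]
}

drop_isolated_nodes <- function(graph) {
  connected <- graph$nodes$id %in% c(graph$edges$source,
                                     graph$edges$target)
  graph$nodes <- graph$nodes[connected, , drop = FALSE]
  rownames(graph$nodes) <- NULL
  graph
}

#' Build the integrated semantic graph
#'
#' Assembles drug, protein, gene and disease nodes and the typed edges
#' (binds_to with action/activity, encoded_by, involved_in carrying the
#' association scores, has_indication, has_side_effect, and is_a edges
#' derived from the disease hierarchy), drops unconnected nodes and
#' merges rare-disease MeSH synonyms.
#'
#' @param mesh mesh table (\code{mesh_ui, heading, tree_numbers}).
#' @param scored scored associations (\code{\link{score_all}}).
#' @param drugs data.frame \code{drug, name, group}.
#' @param targets data.frame \code{drug, protein, gene, action,
#'   activity_type, activity_value} (NA action/activity allowed).
#' @param indications data.frame \code{drug, mesh_ui}.
#' @param side_effects data.frame \code{drug, mesh_ui}.
#' @param rare_diseases optional data.frame \code{ordo_id, name,
#'   mesh_ui}.
#' @param merge_rare merge rare-disease synonyms after building (default
#'   TRUE).
#' @return a validated \code{semantic_graph}.
#' @export
build_graph <- function(mesh, scored, drugs, targets, indications,
                        side_effects,
                        rare_diseases = NULL, merge_rare = TRUE) {
  genes <- sort(unique(c(targets$gene, scored$gene)))
  proteins <- unique(targets[c("protein", "gene")])
  nodes <- rbind(
    data.frame(id = drugs$drug, node_type = "Small_Molecule",
               attrs = I(mapply(function(n, g) c(name = n, group = g),
                                drugs$name, drugs$group,
                                SIMPLIFY = FALSE)),
               stringsAsFactors = FALSE),
    data.frame(id = proteins$protein, node_type = "Protein",
               attrs = I(lapply(proteins$protein, function(p)
                 c(name = p))), stringsAsFactors = FALSE),
    data.frame(id = genes, node_type = "Gene",
               attrs = I(lapply(genes, function(g) c(symbol = g))),
               stringsAsFactors = FALSE),
    data.frame(id = mesh$mesh_ui, node_type = "Common_Disease",
               attrs = I(mapply(function(u, h, t)
                 c(mesh_ui = u, heading = h, mesh_tree = t),
                 mesh$mesh_ui, mesh$heading, mesh$tree_numbers,
                 SIMPLIFY = FALSE)), stringsAsFactors = FALSE))
  if (!is.null(rare_diseases) && nrow(rare_diseases)) {
    nodes <- rbind(nodes, data.frame(
      id = rare_diseases$ordo_id, node_type = "Rare_Disease",
      attrs = I(mapply(function(o, n, u) {
        a <- c(ordo_id = o, name = n)
        if (!is.na(u) && u != "") a <- c(a, mesh_ui = u)
        a
      }, rare_diseases$ordo_id, rare_diseases$name,
         rare_diseases$mesh_ui, SIMPLIFY = FALSE)),
      stringsAsFactors = FALSE))
  }
  bt_attrs <- lapply(seq_len(nrow(targets)), function(i) {
    a <- character()
    if (!is.na(targets$action[i])) a <- c(a, action = targets$action[i])
    if (!is.na(targets$activity_value[i])) {
      a <- c(a, activity_type = as.character(targets$activity_type[i]),
             activity_value = as.character(targets$activity_value[i]))
    }
    a
  })
  eb <- unique(targets[c("protein", "gene")])
  ii_attrs <- lapply(seq_len(nrow(scored)), function(i) {
    a <- c(association_score =
             format(scored$association_score[i], digits = 15))
    if (scored$directionality[i] != "unknown")
      a <- c(a, directionality = scored$directionality[i])
    a
  })
  # is_a edges from the hierarchy: child position -> labelled parent
  pos2ui <- new.env(parent = emptyenv())
  tn_list <- strsplit(mesh$tree_numbers, "|", fixed = TRUE)
  for (i in seq_along(tn_list)) for (p in tn_list[[i]])
    assign(p, mesh$mesh_ui[i], envir = pos2ui)
  isa <- list()
  for (i in seq_along(tn_list)) for (p in tn_list[[i]]) {
    parent <- sub("\\.[^.]*$", "", p)
    if (parent != p && !is.null(pu <- pos2ui[[parent]]) &&
        pu != mesh$mesh_ui[i]) {
      isa[[length(isa) + 1L]] <- c(mesh$mesh_ui[i], pu)
    }
  }
  isa_df <- if (length(isa)) unique(do.call(rbind, isa)) else
    matrix(character(), ncol = 2)
  mk <- function(src, dst, type, attrs = NULL) {
    if (!length(src)) return(NULL)
    df <- data.frame(source = src, target = dst, edge_type = type,
                     stringsAsFactors = FALSE)
    df$attrs <- if (is.null(attrs)) rep(list(character()), length(src))
                else attrs
    df
  }
  edges <- rbind(
    mk(targets$drug, targets$protein, "binds_to", bt_attrs),
    mk(eb$protein, eb$gene, "encoded_by"),
    mk(scored$gene, scored$mesh_ui, "involved_in", ii_attrs),
    mk(indications$drug, indications$mesh_ui, "has_indication"),
    mk(side_effects$drug, side_effects$mesh_ui, "has_side_effect"),
    mk(isa_df[, 1], isa_df[, 2], "is_a"))
  g <- semantic_graph(nodes, edges)
  g <- drop_isolated_nodes(g)
  if (merge_rare) g <- merge_rare_disease_synonyms(g)
  g
}

#' Run the full repositioning pipeline
#'
#' Executes the stages in order: gold-standard selection and association
#' scoring, integrated-graph construction, therapeutic-area scoring,
#' semantic-subgraph mining, the three-stage pruning cascade,
#' deduplication to unique inferred indications, and validation against
#' the known indications. Reruns with the same inputs and configuration
#' produce byte-identical outputs.
#'
#' @param bundle a \code{fixture_bundle} (or any list with the same
#'   tables), or a directory path readable by \code{\link{read_fixture}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, all intermediates and
#'   \code{manifest.json} are written there.
#' @return list with \code{gold_id, scored, graph, tree, areas, mappings,
#'   cascade, indications, validation, manifest}.
#' @export
run_all <- function(bundle, config = pipeline_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf(
    "[%6.2fs] %s", proc.time()[["elapsed"]] - t0, name))
  if (is.character(bundle)) bundle <- read_fixture(bundle)

  stage("ranking gene-disease associations")
  evidence <- as_evidence(bundle$evidence)
  rcfg <- ranking_config(D = config$D, zero_cell = config$zero_cell,
                         universe = config$universe)
  gold_id <- suppressWarnings(select_gold_standard(evidence, rcfg))
  scored <- suppressWarnings(score_all(evidence, gold_id, rcfg))

  stage("building integrated graph")
  graph <- build_graph(bundle$mesh, scored, bundle$drugs, bundle$targets,
                       bundle$indications, bundle$side_effects,
                       bundle$rare_diseases)
  tree <- mesh_tree(bundle$mesh$mesh_ui, bundle$mesh$heading,
                    strsplit(bundle$mesh$tree_numbers, "|", fixed = TRUE))

  stage("scoring therapeutic areas")
  areas <- suppressWarnings(
    score_areas(graph, size_factor_mode = config$size_factor_mode))

  stage("mining semantic subgraphs")
  candidates <- candidate_drugs(graph)
  mappings <- find_mappings(graph, candidates)

  stage("filter cascade")
  fcfg <- filter_config(
    equivalence_threshold = config$equivalence_threshold,
    inhibitory_actions = config$inhibitory_actions,
    activating_actions = config$activating_actions,
    adme_genes = bundle$adme_genes)
  cascade <- suppressWarnings(run_cascade(mappings, graph, tree, fcfg))
  indications <- dedupe_mappings(cascade$kept)

  stage("validation")
  known <- bundle$indications
  validation <- validation_report(indications, known, tree,
                                  config$validation_sim, graph)

  manifest <- list(
    package_version = as.character(utils::packageVersion("repograph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    gold_standard = as.character(gold_id),
    source_lls = as.list(attr(scored, "source_lls")),
    counts = list(
      n_sources = length(unique(evidence$source_id)),
      n_scored_associations = nrow(scored),
      n_nodes = nrow(graph$nodes),
      n_edges = nrow(graph$edges),
      n_candidate_drugs = length(candidates),
      n_mappings = nrow(mappings),
      removed_sequential = as.list(cascade$counts),
      removed_independent = as.list(cascade$counts_independent),
      n_surviving_mappings = nrow(cascade$kept),
      n_inferred_indications = nrow(indications),
      validation = validation))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) utils::write.table(
      as.data.frame(df), file.path(out_dir, name), sep = "\t",
      quote = FALSE, row.names = FALSE)
    wt(scored, "scored_associations.tsv")
    save_graph(graph, file.path(out_dir, "nodes.tsv"),
               file.path(out_dir, "edges.tsv"))
    wt(areas, "areas.tsv")
    wt(mappings, "mappings.tsv")
    wt(indications, "indications_inferred.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage("done")
  list(gold_id = as.character(gold_id), scored = scored, graph = graph,
       tree = tree, areas = areas, mappings = mappings,
       cascade = cascade, indications = indications,
       validation = validation, manifest = manifest)
}
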