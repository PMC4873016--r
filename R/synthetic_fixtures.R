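# Deterministic generator of toy pipeline inputs: a MeSH-like disease
# forest, per-source gene-disease evidence with a known ground truth,
# drug/target/indication/side-effect tables, identifier mappings and an
# ADME list — with planted repositioning opportunities (clean
# drug-protein-gene-disease chains), side-effect traps at chosen MeSH
# distances, mechanism contradictions and ADME hits, plus a truth
# manifest enabling parameter-recovery tests. Shape, not scale: sizes are
# toy, the statistical structure (source reliabilities, noise, hierarchy)
# is what real inputs share.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' Defaults define the generator's standard study conditions: three
#' top-level disease areas as depth-3 ternary trees (120 diseases), 60
#' genes, 60 true gene-disease pairs observed by four sources of
#' graduated reliability and noise, 15 background drugs (80\% approved)
#' with 2 targets each, five planted indications with clean support
#' chains, three side-effect traps at node distances 2, 2 and 3, one
#' planted mechanism contradiction and one planted ADME hit.
#'
#' @param seed integer seed; the same spec generates byte-identical
#'   bundles.
#' @param n_genes number of background genes.
#' @param n_areas,branching,mesh_depth disease-forest shape (one k-ary
#'   tree per top-level area; depth counts levels below the root).
#' @param n_gold number of true (gold) gene-disease pairs.
#' @param source_ids,source_types,reliabilities,noise_rates per-source
#'   design: a source observes each true pair with probability
#'   \code{reliability} and adds \code{round(noise_rate * n_gold)} false
#'   pairs.
#' @param n_drugs,targets_per_drug,fraction_approved background drug
#'   table shape.
#' @param n_rare number of rare diseases (each synonymous with a common
#'   disease via its MeSH UI).
#' @param n_multi_area diseases given a second tree number in another
#'   area.
#' @param n_planted_indications clean drug-protein-gene-disease chains
#'   planted for end-to-end recovery.
#' @param trap_dists node distances at which side-effect traps are
#'   planted next to planted indications (recycled over the first
#'   \code{length(trap_dists)} chains).
#' @param n_contradictions,n_adme_hits planted mappings removed by the
#'   directionality and ADME filters.
#' @param n_random_indications,n_random_side_effects background
#'   drug-disease edges.
#' @param n_adme_background extra (non-planted) ADME genes in the list.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 1,
                         n_genes = 60,
                         n_areas = 3, branching = 3, mesh_depth = 3,
                         n_gold = 60,
                         source_ids = c("curated_a", "experimental_b",
                                        "literature_c", "predicted_d"),
                         source_types = c("curated", "experimental",
                                          "literature", "predicted"),
                         reliabilities = c(0.9, 0.8, 0.6, 0.4),
                         noise_rates = c(0.05, 0.1, 0.2, 0.3),
                         n_drugs = 15, targets_per_drug = 2,
                         fraction_approved = 0.8,
                         n_rare = 2, n_multi_area = 2,
                         n_planted_indications = 5,
                         trap_dists = c(2, 2, 3),
                         n_contradictions = 1, n_adme_hits = 1,
                         n_random_indications = 10,
                         n_random_side_effects = 10,
                         n_adme_background = 4) {
  spec <- list(seed = seed, n_genes = n_genes, n_areas = n_areas,
               branching = branching, mesh_depth = mesh_depth,
               n_gold = n_gold, source_ids = source_ids,
               source_types = source_types, reliabilities = reliabilities,
               noise_rates = noise_rates, n_drugs = n_drugs,
               targets_per_drug = targets_per_drug,
               fraction_approved = fraction_approved, n_rare = n_rare,
               n_multi_area = n_multi_area,
               n_planted_indications = n_planted_indications,
               trap_dists = trap_dists,
               n_contradictions = n_contradictions,
               n_adme_hits = n_adme_hits,
               n_random_indications = n_random_indications,
               n_random_side_effects = n_random_side_effects,
               n_adme_background = n_adme_background)
  class(spec) <- "fixture_spec"
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  counts <- unlist(spec[c("n_genes", "n_areas", "branching", "mesh_depth",
                          "n_gold", "n_drugs", "targets_per_drug",
                          "n_rare", "n_multi_area",
                          "n_planted_indications", "n_contradictions",
                          "n_adme_hits", "n_random_indications",
                          "n_random_side_effects", "n_adme_background")])
  if (any(counts < 0)) stop("fixture counts must be >= 0")
  k <- length(spec$source_ids)
  if (k < 2) stop("need at least 2 sources")
  if (length(spec$source_types) != k || length(spec$reliabilities) != k ||
      length(spec$noise_rates) != k)
    stop("per-source vectors must all have length ", k)
  if (any(spec$reliabilities <= 0 | spec$reliabilities > 1))
    stop("reliabilities must be in (0, 1]")
  n_dis_area <- sum(spec$branching^(0:spec$mesh_depth))
  n_dis <- n_dis_area * spec$n_areas
  if (spec$n_gold > spec$n_genes * n_dis)
    stop("n_gold exceeds the gene x disease universe")
  n_planted <- spec$n_planted_indications + spec$n_contradictions +
    spec$n_adme_hits
  if (n_planted > n_dis_area * spec$n_areas)
    stop("not enough diseases for the planted chains")
  if (length(spec$trap_dists) > spec$n_planted_indications)
    stop("more side-effect traps than planted indications")
  if (any(spec$trap_dists < 2))
    stop("trap distances must be >= 2 (distance 1 is the disease itself)")
  invisible(spec)
}

# disease forest: one k-ary tree per area; returns the mesh table
.gen_mesh <- function(spec) {
  pos <- character(); area <- character()
  for (a in seq_len(spec$n_areas)) {
    top <- sprintf("C%02d", a)
    level <- top
    pos <- c(pos, top); area <- c(area, top)
    for (d in seq_len(spec$mesh_depth)) {
      level <- as.vector(vapply(level, function(p)
        paste0(p, ".", sprintf("%03d", 100 * seq_len(spec$branching))),
        character(spec$branching)))
      pos <- c(pos, level); area <- c(area, rep(top, length(level)))
    }
  }
  n <- length(pos)
  mesh <- data.frame(mesh_ui = sprintf("D%06d", seq_len(n)),
                     heading = sprintf("Disease %03d", seq_len(n)),
                     tree_numbers = pos, stringsAsFactors = FALSE)
  # secondary tree numbers: duplicate a few leaves into the next area
  if (spec$n_multi_area > 0 && spec$n_areas > 1) {
    leaves <- which(nchar(gsub("[^.]", "", pos)) == spec$mesh_depth)
    pick <- sample(leaves, min(spec$n_multi_area, length(leaves)))
    for (i in pick) {
      a_here <- tree_top_level(pos[i])
      other <- setdiff(unique(area), a_here)[1L]
      alt <- sub(a_here, other, pos[i], fixed = TRUE)
      mesh$tree_numbers[i] <- paste(pos[i], alt, sep = "|")
    }
  }
  mesh
}

# first disease at exactly the given node distance from `from`
.disease_at_dist <- function(tree, uis, from, dist) {
  for (u in uis) {
    if (u == from) next
    if (node_distance(tree, from, u) == dist) return(u)
  }
  stop("no disease at node distance ", dist, " from ", from,
       "; deepen or widen the disease forest")
}

#' Generate a synthetic fixture bundle
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{fixture_bundle}: list of data.frames (\code{mesh},
#'   \code{evidence}, \code{mapping}, \code{drugs}, \code{targets},
#'   \code{indications}, \code{side_effects}, \code{rare_diseases}),
#'   character vector \code{adme_genes}, and \code{truth} — the manifest
#'   of every planted item and the per-source gold membership.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  validate_fixture_spec(spec)
  with_seed(spec$seed, {
    mesh <- .gen_mesh(spec)
    tree <- mesh_tree(mesh$mesh_ui, mesh$heading,
                      strsplit(mesh$tree_numbers, "|", fixed = TRUE))
    uis <- mesh$mesh_ui
    depth_of <- nchar(gsub("[^.]", "", sub("\\|.*", "",
                                           mesh$tree_numbers)))
    leaves <- uis[depth_of == spec$mesh_depth]

    genes <- sprintf("GS%03d", seq_len(spec$n_genes))
    n_planted <- spec$n_planted_indications + spec$n_contradictions +
      spec$n_adme_hits
    planted_genes <- sprintf("GP%03d", seq_len(n_planted))
    planted_dis <- sample(leaves, n_planted)

    # ground-truth gene-disease pairs: background gold + planted pairs
    all_pairs <- expand.grid(gene = genes, mesh_ui = uis,
                             stringsAsFactors = FALSE)
    gold_idx <- sample(nrow(all_pairs), spec$n_gold)
    gold <- all_pairs[gold_idx, , drop = FALSE]
    planted_pairs <- data.frame(gene = planted_genes,
                                mesh_ui = planted_dis,
                                stringsAsFactors = FALSE)
    truth_pairs <- rbind(gold, planted_pairs)
    rownames(truth_pairs) <- NULL

    # which truth pairs are LoF (the planted contradictions)
    ci <- spec$n_planted_indications + seq_len(spec$n_contradictions)
    contra_key <- pair_key(planted_genes[ci], planted_dis[ci])

    # per-source evidence
    noise_pool <- all_pairs[-gold_idx, , drop = FALSE]
    ev <- list(); membership <- list()
    for (k in seq_along(spec$source_ids)) {
      take <- stats::runif(nrow(truth_pairs)) <= spec$reliabilities[k]
      take[nrow(gold) + seq_len(n_planted)] <- TRUE  # planted: always in
      got <- truth_pairs[take, , drop = FALSE]
      n_noise <- round(spec$noise_rates[k] * spec$n_gold)
      if (n_noise > 0) {
        got <- rbind(got, noise_pool[sample(nrow(noise_pool), n_noise), ,
                                     drop = FALSE])
      }
      dirn <- ifelse(pair_key(got$gene, got$mesh_ui) %in% contra_key,
                     "LoF", "unknown")
      ev[[k]] <- data.frame(source_id = spec$source_ids[k],
                            source_type = spec$source_types[k],
                            gene_symbol = got$gene, mesh_ui = got$mesh_ui,
                            directionality = dirn,
                            stringsAsFactors = FALSE)
      membership[[spec$source_ids[k]]] <-
        pair_key(got$gene, got$mesh_ui) %in%
          pair_key(truth_pairs$gene, truth_pairs$mesh_ui)
    }
    evidence <- do.call(rbind, ev)
    evidence <- evidence[!duplicated(
      evidence[c("source_id", "gene_symbol", "mesh_ui")]), , drop = FALSE]
    rownames(evidence) <- NULL

    # identifier mapping table: fake MIM numbers for every disease
    mapping <- data.frame(foreign_namespace = "MIM",
                          foreign_id = sprintf("%06d",
                                               100000 + seq_along(uis)),
                          mesh_ui = uis, stringsAsFactors = FALSE)

    # background drugs and targets
    drugs <- data.frame(
      drug = sprintf("DR%03d", seq_len(spec$n_drugs)),
      name = sprintf("drug-%03d", seq_len(spec$n_drugs)),
      group = ifelse(stats::runif(spec$n_drugs) <= spec$fraction_approved,
                     "approved", "experimental"),
      stringsAsFactors = FALSE)
    actions <- c(NA, "inhibitor", "agonist", "antagonist", "activator")
    atypes <- c("IC50", "Ki", "Kd", "Potency")
    tg <- do.call(rbind, lapply(seq_len(spec$n_drugs), function(i) {
      gs <- sample(genes, min(spec$targets_per_drug, length(genes)))
      data.frame(drug = drugs$drug[i], protein = paste0("P_", gs),
                 gene = gs,
                 action = sample(actions, length(gs), replace = TRUE),
                 activity_type = sample(atypes, length(gs),
                                        replace = TRUE),
                 activity_value = signif(10^stats::runif(length(gs), 0, 6),
                                         4),
                 stringsAsFactors = FALSE)
    }))

    # planted chains: indication / contradiction / ADME drugs
    p_ind <- seq_len(spec$n_planted_indications)
    chain <- function(idx, prefix, action) {
      if (!length(idx)) return(NULL)
      data.frame(drug = sprintf("%s%02d", prefix, seq_along(idx)),
                 protein = paste0("P_", planted_genes[idx]),
                 gene = planted_genes[idx],
                 action = action, activity_type = "IC50",
                 activity_value = 1,
                 stringsAsFactors = FALSE)
    }
    tg_ind <- chain(p_ind, "DRP", NA_character_)
    tg_con <- chain(ci, "DRC", "antagonist")
    ai <- spec$n_planted_indications + spec$n_contradictions +
      seq_len(spec$n_adme_hits)
    tg_adme <- chain(ai, "DRA", NA_character_)
    targets <- rbind(tg, tg_ind, tg_con, tg_adme)
    rownames(targets) <- NULL
    pdrug <- c(if (!is.null(tg_ind)) tg_ind$drug,
               if (!is.null(tg_con)) tg_con$drug,
               if (!is.null(tg_adme)) tg_adme$drug)
    if (length(pdrug)) {
      drugs <- rbind(drugs, data.frame(
        drug = pdrug, name = paste0("planted-", pdrug),
        group = "approved", stringsAsFactors = FALSE))
    }

    # known indications: planted chains are knowns (rediscovery), plus
    # random background indications on approved drugs
    ind_rows <- data.frame(drug = if (!is.null(tg_ind)) tg_ind$drug
                                  else character(),
                           mesh_ui = planted_dis[p_ind],
                           source = rep("planted", length(p_ind)),
                           stringsAsFactors = FALSE)
    appr <- drugs$drug[drugs$group == "approved" &
                         !startsWith(drugs$drug, "DRP") &
                         !startsWith(drugs$drug, "DRC") &
                         !startsWith(drugs$drug, "DRA")]
    if (spec$n_random_indications > 0 && length(appr)) {
      ind_rows <- rbind(ind_rows, data.frame(
        drug = sample(appr, spec$n_random_indications, replace = TRUE),
        mesh_ui = sample(uis, spec$n_random_indications, replace = TRUE),
        source = "background", stringsAsFactors = FALSE))
    }
    indications <- ind_rows[!duplicated(ind_rows[c("drug", "mesh_ui")]), ,
                            drop = FALSE]
    rownames(indications) <- NULL

    # side effects: traps near planted indications + background noise
    traps <- NULL
    if (length(spec$trap_dists)) {
      traps <- data.frame(
        drug = tg_ind$drug[seq_along(spec$trap_dists)],
        indication_ui = planted_dis[seq_along(spec$trap_dists)],
        dist = spec$trap_dists, stringsAsFactors = FALSE)
      traps$side_effect_ui <- vapply(seq_len(nrow(traps)), function(i)
        .disease_at_dist(tree, uis, traps$indication_ui[i],
                         traps$dist[i]), character(1))
    }
    se_rows <- if (is.null(traps)) NULL else
      data.frame(drug = traps$drug, mesh_ui = traps$side_effect_ui,
                 stringsAsFactors = FALSE)
    bg_drugs <- setdiff(drugs$drug,
                        if (is.null(tg_ind)) character() else tg_ind$drug)
    bg_drugs <- bg_drugs[!startsWith(bg_drugs, "DRC") &
                           !startsWith(bg_drugs, "DRA")]
    if (spec$n_random_side_effects > 0 && length(bg_drugs)) {
      se_rows <- rbind(se_rows, data.frame(
        drug = sample(bg_drugs, spec$n_random_side_effects,
                      replace = TRUE),
        mesh_ui = sample(uis, spec$n_random_side_effects, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    side_effects <- if (is.null(se_rows)) {
      data.frame(drug = character(), mesh_ui = character(),
                 stringsAsFactors = FALSE)
    } else {
      se_rows[!duplicated(se_rows[c("drug", "mesh_ui")]), , drop = FALSE]
    }
    rownames(side_effects) <- NULL

    # rare diseases synonymous with common ones
    rare <- data.frame(ordo_id = character(), name = character(),
                       mesh_ui = character(), stringsAsFactors = FALSE)
    if (spec$n_rare > 0) {
      syn <- sample(uis, spec$n_rare)
      rare <- data.frame(ordo_id = sprintf("ORPHA:%04d",
                                           seq_len(spec$n_rare)),
                         name = sprintf("rare-disease-%02d",
                                        seq_len(spec$n_rare)),
                         mesh_ui = syn, stringsAsFactors = FALSE)
    }

    # ADME list: planted ADME genes + background genes never planted
    adme <- character()
    if (spec$n_adme_hits > 0) adme <- planted_genes[ai]
    if (spec$n_adme_background > 0) {
      bg_adme <- sample(setdiff(genes, unique(tg$gene)),
                        min(spec$n_adme_background,
                            length(setdiff(genes, unique(tg$gene)))))
      adme <- c(adme, bg_adme)
    }

    truth <- list(
      spec = spec,
      gold_pairs = gold,
      truth_pairs = truth_pairs,
      source_membership = membership,
      planted_indications = if (is.null(tg_ind)) NULL else
        data.frame(drug = tg_ind$drug, protein = tg_ind$protein,
                   gene = tg_ind$gene, disease = planted_dis[p_ind],
                   stringsAsFactors = FALSE),
      side_effect_traps = traps,
      contradictions = if (is.null(tg_con)) NULL else
        data.frame(drug = tg_con$drug, gene = tg_con$gene,
                   disease = planted_dis[ci], action = "antagonist",
                   directionality = "LoF", stringsAsFactors = FALSE),
      adme_hits = if (is.null(tg_adme)) NULL else
        data.frame(drug = tg_adme$drug, gene = tg_adme$gene,
                   disease = planted_dis[ai], stringsAsFactors = FALSE))

    structure(list(mesh = mesh, evidence = evidence, mapping = mapping,
                   drugs = drugs, targets = targets,
                   indications = indications,
                   side_effects = side_effects, rare_diseases = rare,
                   adme_genes = adme, truth = truth),
              class = "fixture_bundle")
  })
}

#' Write a fixture bundle to a directory
#'
#' Emits every external-interface file: \code{mesh.tsv, evidence.tsv,
#' mapping.tsv, drugs.tsv, targets.tsv, indications.tsv,
#' side_effects.tsv, rare_diseases.tsv, adme_genes.txt} and the truth
#' manifest \code{truth.json}.
#'
#' @param bundle a \code{fixture_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ev <- bundle$evidence
  wt(bundle$mesh, "mesh.tsv")
  wt(ev, "evidence.tsv")
  wt(bundle$mapping, "mapping.tsv")
  wt(bundle$drugs, "drugs.tsv")
  wt(bundle$targets, "targets.tsv")
  wt(bundle$indications, "indications.tsv")
  wt(bundle$side_effects, "side_effects.tsv")
  wt(bundle$rare_diseases, "rare_diseases.tsv")
  writeLines(bundle$adme_genes, file.path(dir, "adme_genes.txt"))
  truth <- bundle$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Summary statistics of a fixture bundle
#'
#' @param bundle a \code{fixture_bundle}.
#' @return list: \code{pair_counts} (per-source), \code{overlap}
#'   (pairwise Jaccard-free overlap matrix: fraction of the row source's
#'   pairs also in the column source), \code{area_counts} (diseases per
#'   top-level area, duplicated for multi-area diseases).
#' @export
shape_report <- function(bundle) {
  ev <- bundle$evidence
  keys <- split(pair_key(ev$gene_symbol, ev$mesh_ui), ev$source_id)
  srcs <- names(keys)
  ov <- matrix(NA_real_, length(srcs), length(srcs),
               dimnames = list(srcs, srcs))
  for (a in srcs) for (b in srcs)
    ov[a, b] <- mean(keys[[a]] %in% keys[[b]])
  areas <- unlist(lapply(strsplit(bundle$mesh$tree_numbers, "|",
                                  fixed = TRUE),
                         function(t) unique(tree_top_level(t))))
  list(pair_counts = lengths(keys), overlap = ov,
       area_counts = table(areas))
}
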