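# in-code builders for small graphs and trees used across tests

# drug -> protein -> gene -> disease chain with the three typed edges
chain_graph <- function(assoc = 0.6, activity = 100,
                        action = NA_character_, dirn = "unknown",
                        disease_type = "Common_Disease",
                        mesh_ui = "D000001", mesh_tree = "C01.100") {
  nodes <- data.frame(
    id = c("DR1", "P1", "G1", "DIS1"),
    node_type = c("Small_Molecule", "Protein", "Gene", disease_type),
    stringsAsFactors = FALSE)
  nodes$attrs <- list(c(name = "drug-1", group = "approved"),
                      c(name = "P1"), c(symbol = "G1"),
                      if (disease_type == "Common_Disease")
                        c(mesh_ui = mesh_ui, mesh_tree = mesh_tree)
                      else c(ordo_id = "ORPHA:1"))
  bt <- c(if (!is.na(action)) c(action = action),
          if (!is.na(activity)) c(activity_type = "IC50",
                                  activity_value = as.character(activity)))
  ii <- c(association_score = as.character(assoc))
  if (dirn != "unknown") ii <- c(ii, directionality = dirn)
  edges <- data.frame(source = c("DR1", "P1", "G1"),
                      target = c("P1", "G1", "DIS1"),
                      edge_type = c("binds_to", "encoded_by",
                                    "involved_in"),
                      stringsAsFactors = FALSE)
  edges$attrs <- list(if (is.null(bt)) character() else bt,
                      character(), ii)
  semantic_graph(nodes, edges)
}

# random typed graph for oracle-equivalence tests; sizes kept small so
# the naive 4-tuple oracle stays cheap
random_typed_graph <- function(seed, n_drugs = 8, n_prot = 8, n_gene = 8,
                               n_dis = 10, p_bind = 0.25, p_enc = 0.3,
                               p_inv = 0.2, p_parallel = 0.1) {
  set.seed(seed)
  drugs <- sprintf("DR%02d", seq_len(n_drugs))
  prots <- sprintf("P%02d", seq_len(n_prot))
  genes <- sprintf("G%02d", seq_len(n_gene))
  dis <- sprintf("D%06d", seq_len(n_dis))
  nodes <- data.frame(
    id = c(drugs, prots, genes, dis),
    node_type = c(rep("Small_Molecule", n_drugs), rep("Protein", n_prot),
                  rep("Gene", n_gene), rep("Common_Disease", n_dis)),
    stringsAsFactors = FALSE)
  nodes$attrs <- c(
    lapply(drugs, function(d)
      c(name = d, group = sample(c("approved", "experimental",
                                   "approved|withdrawn"), 1))),
    lapply(prots, function(p) c(name = p)),
    lapply(genes, function(g) c(symbol = g)),
    lapply(seq_along(dis), function(i)
      c(mesh_ui = dis[i], mesh_tree = sprintf("C01.%03d", i))))
  src <- character(); dst <- character(); typ <- character()
  at <- list()
  for (d in drugs) for (p in prots) {
    n_par <- stats::rbinom(1, 1, p_bind) +
      stats::rbinom(1, 1, p_bind * p_parallel)
    for (k in seq_len(n_par)) {
      src <- c(src, d); dst <- c(dst, p); typ <- c(typ, "binds_to")
      at[[length(at) + 1]] <- if (stats::runif(1) < 0.5)
        c(activity_type = "IC50",
          activity_value = format(signif(10^stats::runif(1, 0, 6), 4),
                                  scientific = FALSE)) else character()
    }
  }
  for (p in prots) for (g in genes) if (stats::runif(1) < p_enc) {
    src <- c(src, p); dst <- c(dst, g); typ <- c(typ, "encoded_by")
    at[[length(at) + 1]] <- character()
  }
  for (g in genes) for (d in dis) if (stats::runif(1) < p_inv) {
    src <- c(src, g); dst <- c(dst, d); typ <- c(typ, "involved_in")
    at[[length(at) + 1]] <- c(association_score =
                                format(stats::runif(1), digits = 10))
  }
  edges <- data.frame(source = src, target = dst, edge_type = typ,
                      stringsAsFactors = FALSE)
  edges$attrs <- at
  semantic_graph(nodes, edges)
}

# naive oracle: count mappings for every (drug, protein, gene, disease)
# 4-tuple as (#binds edges) x (#encoded edges) x (#involved edges)
naive_mapping_counts <- function(graph, candidates) {
  e <- graph$edges
  cnt <- function(type) {
    sub <- e[e$edge_type == type, c("source", "target")]
    stats::aggregate(n ~ source + target,
                     cbind(sub, n = 1), FUN = sum)
  }
  bt <- cnt("binds_to"); eb <- cnt("encoded_by"); ii <- cnt("involved_in")
  bt <- bt[bt$source %in% candidates, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(bt))) for (j in seq_len(nrow(eb))) {
    if (eb$source[j] != bt$target[i]) next
    for (k in seq_len(nrow(ii))) {
      if (ii$source[k] != eb$target[j]) next
      out[[length(out) + 1]] <- data.frame(
        drug = bt$source[i], protein = bt$target[i],
        gene = eb$target[j], disease = ii$target[k],
        n = bt$n[i] * eb$n[j] * ii$n[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(drug = character(),
                                      protein = character(),
                                      gene = character(),
                                      disease = character(),
                                      n = numeric()))
  res <- do.call(rbind, out)
  res[order(res$drug, res$protein, res$gene, res$disease), , drop = FALSE]
}

# linear-chain mesh tree: n nodes, each the single child of the previous
chain_mesh_tree <- function(n, top = "C01") {
  pos <- top
  for (i in seq_len(n - 1)) pos <- c(pos, paste0(pos[i], ".001"))
  mesh_tree(sprintf("D%06d", seq_len(n)), sprintf("node %d", seq_len(n)),
            as.list(pos))
}

# small explicit forest used in similarity tests
toy_tree <- function() {
  mesh_tree(
    ui = c("Droot", "Dmid", "Dleaf1", "Dleaf2", "Dother", "Dmulti"),
    heading = c("root", "mid", "leaf1", "leaf2", "other top", "multi"),
    trees = list("C10", "C10.228", "C10.228.140", "C10.228.200",
                 "C04", c("C04.100", "C10.228.140.500")))
}

# (gene, disease) composite key, matching the package's internal keying
pair_key <- function(gene, mesh_ui) paste(gene, mesh_ui, sep = "\r")
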