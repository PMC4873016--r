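# graph with one approved drug whose inferred disease sits in a small
# hierarchy next to configurable side effects
filter_fixture <- function(se_uis = character(), action = NA_character_,
                           dirn = "unknown", adme = character()) {
  mesh <- data.frame(
    mesh_ui = sprintf("D%06d", 1:6),
    heading = sprintf("h%d", 1:6),
    tree_numbers = c("C01", "C01.100", "C01.100.100", "C01.100.200",
                     "C01.100.100.100", "C01.200"),
    stringsAsFactors = FALSE)
  # inferred disease = D000003 (C01.100.100); D000002 is its parent
  # (Dist 2), D000004 a sibling (Dist 3), D000005 its child (Dist 2)
  dis <- data.frame(id = mesh$mesh_ui, node_type = "Common_Disease",
                    stringsAsFactors = FALSE)
  dis$attrs <- lapply(seq_len(nrow(mesh)), function(i)
    c(mesh_ui = mesh$mesh_ui[i], mesh_tree = mesh$tree_numbers[i]))
  core <- data.frame(id = c("DR1", "P1", "G1"),
                     node_type = c("Small_Molecule", "Protein", "Gene"),
                     stringsAsFactors = FALSE)
  core$attrs <- list(c(group = "approved"), character(),
                     c(symbol = "G1"))
  bt <- if (is.na(action)) character() else c(action = action)
  ii <- c(association_score = "0.6")
  if (dirn != "unknown") ii <- c(ii, directionality = dirn)
  edges <- data.frame(
    source = c("DR1", "P1", "G1", rep("DR1", length(se_uis))),
    target = c("P1", "G1", "D000003", se_uis),
    edge_type = c("binds_to", "encoded_by", "involved_in",
                  rep("has_side_effect", length(se_uis))),
    stringsAsFactors = FALSE)
  edges$attrs <- c(list(bt, character(), ii),
                   rep(list(character()), length(se_uis)))
  g <- semantic_graph(rbind(core, dis), edges)
  tree <- mesh_tree(mesh$mesh_ui, mesh$heading,
                    as.list(mesh$tree_numbers))
  cfg <- filter_config(adme_genes = adme)
  list(graph = g, tree = tree, config = cfg,
       mappings = find_mappings(g))
}

test_that("side-effect filter removes by exact node and by similarity", {
  # no side effects: everything kept
  fx <- filter_fixture()
  r <- filter_side_effects(fx$mappings, fx$graph, fx$tree, fx$config)
  expect_equal(nrow(r$kept), 1); expect_equal(nrow(r$removed), 0)
  # identical disease (Sim 1)
  fx <- filter_fixture(se_uis = "D000003")
  r <- filter_side_effects(fx$mappings, fx$graph, fx$tree, fx$config)
  expect_equal(nrow(r$removed), 1)
  # parent of the inferred disease: Dist 2, Sim 0.768 >= ET -> removed
  fx <- filter_fixture(se_uis = "D000002")
  r <- filter_side_effects(fx$mappings, fx$graph, fx$tree, fx$config)
  expect_equal(nrow(r$removed), 1)
  # child: also Dist 2 -> removed
  fx <- filter_fixture(se_uis = "D000005")
  expect_equal(nrow(filter_side_effects(fx$mappings, fx$graph, fx$tree,
                                        fx$config)$removed), 1)
  # sibling: Dist 3, Sim 0.633 < 0.768 -> kept
  fx <- filter_fixture(se_uis = "D000004")
  r <- filter_side_effects(fx$mappings, fx$graph, fx$tree, fx$config)
  expect_equal(nrow(r$kept), 1)
  # ET above 1: only exact node matches removed
  cfg_exact <- filter_config(equivalence_threshold = 1.01)
  fx <- filter_fixture(se_uis = "D000002")
  expect_equal(nrow(filter_side_effects(fx$mappings, fx$graph, fx$tree,
                                        cfg_exact)$removed), 0)
  fx <- filter_fixture(se_uis = "D000003")
  expect_equal(nrow(filter_side_effects(fx$mappings, fx$graph, fx$tree,
                                        cfg_exact)$removed), 1)
})

test_that("side-effect removal is monotone non-increasing in ET", {
  fx <- filter_fixture(se_uis = c("D000002", "D000004", "D000006"))
  removed <- vapply(c(0.2, 0.633, 0.768, 1, 1.01), function(et)
    nrow(filter_side_effects(fx$mappings, fx$graph, fx$tree,
                             filter_config(equivalence_threshold =
                                             et))$removed), numeric(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("directionality filter removes only true contradictions", {
  case <- function(action, dirn) {
    fx <- filter_fixture(action = action, dirn = dirn)
    nrow(filter_directionality(fx$mappings, fx$config)$removed)
  }
  expect_equal(case("antagonist", "LoF"), 1)   # inhibitory vs LoF
  expect_equal(case("agonist", "GoF"), 1)      # activating vs GoF
  expect_equal(case("agonist", "LoF"), 0)      # mechanism-compatible
  expect_equal(case("antagonist", "GoF"), 0)
  expect_equal(case("antagonist", "unknown"), 0)
  expect_equal(case(NA_character_, "LoF"), 0)
  expect_equal(case("Inhibitor", "LoF"), 1)    # case-insensitive
  # unrecognised action terms are kept and reported
  fx <- filter_fixture(action = "chelator", dirn = "LoF")
  expect_message(r <- filter_directionality(fx$mappings, fx$config),
                 "chelator")
  expect_equal(nrow(r$removed), 0)
  expect_error(filter_config(inhibitory_actions = "agonist"),
               "disjoint")
})

test_that("ADME filter matches gene symbols case-insensitively", {
  fx <- filter_fixture(adme = "g1")
  r <- filter_adme(fx$mappings, fx$config)
  expect_equal(nrow(r$removed), 1)   # g1 matches G1
  fx <- filter_fixture(adme = "CYP3A4")
  expect_equal(nrow(filter_adme(fx$mappings, fx$config)$removed), 0)
  fx <- filter_fixture()
  expect_warning(r <- filter_adme(fx$mappings, fx$config), "empty ADME")
  expect_equal(nrow(r$kept), nrow(fx$mappings))
})

test_that("every filter is contractive and idempotent", {
  fx <- filter_fixture(se_uis = "D000002", action = "antagonist",
                       dirn = "LoF", adme = "G1")
  g <- random_typed_graph(21)
  tree <- graph_mesh_tree(g)
  m <- find_mappings(g)
  cfg <- filter_config(adme_genes = c("G01", "G05"))
  for (f in list(function(x) filter_side_effects(x, g, tree, cfg),
                 function(x) filter_directionality(x, cfg),
                 function(x) filter_adme(x, cfg))) {
    r1 <- f(m)
    expect_lte(nrow(r1$kept), nrow(m))
    expect_equal(nrow(r1$kept) + nrow(r1$removed), nrow(m))
    r2 <- f(r1$kept)
    expect_equal(nrow(r2$removed), 0)   # idempotent
  }
})

test_that("the cascade reports per-stage counts and an order-free kept set", {
  # engineered: 10 mappings, 2 side-effect hits, 1 contradiction, 1 ADME
  mesh <- data.frame(mesh_ui = sprintf("D%06d", 1:12),
                     heading = sprintf("h%d", 1:12),
                     tree_numbers = c("C01", paste0("C01.",
                                                    sprintf("%03d",
                                                            100 * 1:11))),
                     stringsAsFactors = FALSE)
  dis <- data.frame(id = mesh$mesh_ui, node_type = "Common_Disease",
                    stringsAsFactors = FALSE)
  dis$attrs <- lapply(seq_len(12), function(i)
    c(mesh_ui = mesh$mesh_ui[i], mesh_tree = mesh$tree_numbers[i]))
  drugs <- sprintf("DR%02d", 1:10)
  dd <- data.frame(id = drugs, node_type = "Small_Molecule",
                   stringsAsFactors = FALSE)
  dd$attrs <- rep(list(c(group = "approved")), 10)
  core <- data.frame(id = c(paste0("P", 1:10), paste0("GG", 1:10)),
                     node_type = rep(c("Protein", "Gene"), each = 10),
                     stringsAsFactors = FALSE)
  core$attrs <- c(rep(list(character()), 10),
                  lapply(paste0("GG", 1:10), function(s) c(symbol = s)))
  # drug i -> Pi -> GGi -> D00000(i+2); contradiction on drug 3,
  # ADME gene on drug 4, side effects for drugs 1 (exact) and 2 (parent)
  bt_at <- rep(list(character()), 10)
  bt_at[[3]] <- c(action = "antagonist")
  ii_at <- rep(list(c(association_score = "0.5")), 10)
  ii_at[[3]] <- c(association_score = "0.5", directionality = "LoF")
  edges <- data.frame(
    source = c(drugs, paste0("P", 1:10), paste0("GG", 1:10),
               "DR01", "DR02"),
    target = c(paste0("P", 1:10), paste0("GG", 1:10),
               sprintf("D%06d", 3:12), "D000003", "C_PARENT"),
    edge_type = c(rep("binds_to", 10), rep("encoded_by", 10),
                  rep("involved_in", 10), "has_side_effect",
                  "has_side_effect"),
    stringsAsFactors = FALSE)
  # drug 2's side effect is the hierarchy root, parent of its inferred
  # disease D000004? no: all leaves hang off C01 directly, so the root
  # D000001 is at Dist 2 from every leaf
  edges$target[edges$target == "C_PARENT"] <- "D000001"
  edges$attrs <- c(bt_at, rep(list(character()), 10), ii_at,
                   list(character(), character()))
  g <- semantic_graph(rbind(dd, core, dis), edges)
  tree <- mesh_tree(mesh$mesh_ui, mesh$heading,
                    as.list(mesh$tree_numbers))
  cfg <- filter_config(adme_genes = "GG4")
  m <- find_mappings(g)
  expect_equal(nrow(m), 10)
  r <- run_cascade(m, g, tree, cfg)
  expect_equal(unname(r$counts), c(2, 1, 1))
  expect_equal(nrow(r$kept), 6)
  # independent accounting sees the same removals here (no overlap)
  expect_equal(unname(r$counts_independent), c(2, 1, 1))
  # stage order changes per-stage counts, never the final kept set
  cfg2 <- filter_config(adme_genes = "GG4",
                        stage_order = c("adme", "side_effect",
                                        "directionality"))
  r2 <- run_cascade(m, g, tree, cfg2)
  expect_setequal(paste(r2$kept$drug, r2$kept$disease),
                  paste(r$kept$drug, r$kept$disease))
  # ET above 1 and an unmatched ADME list: only the exact side-effect
  # hit and the contradiction go
  r0 <- run_cascade(m, g, tree,
                    filter_config(equivalence_threshold = 1.01,
                                  adme_genes = "NOPE"))
  expect_equal(unname(r0$counts), c(1, 1, 0))
})
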