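test_that("loading handles the empty and minimal-chain cases", {
  nd <- withr::local_tempfile(fileext = ".tsv")
  ed <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tnode_type\tattrs", nd)
  writeLines("source_id\ttarget_id\tedge_type\tattrs", ed)
  g <- load_graph(nd, ed)
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)

  save_graph(chain_graph(), nd, ed)
  g <- load_graph(nd, ed)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 3)
})

test_that("isolated nodes are dropped at load with a message", {
  g <- chain_graph()
  g$nodes <- rbind(g$nodes, data.frame(
    id = "G_LONELY", node_type = "Gene",
    attrs = I(list(c(symbol = "G_LONELY"))), stringsAsFactors = FALSE))
  nd <- withr::local_tempfile(); ed <- withr::local_tempfile()
  save_graph(g, nd, ed)
  expect_message(g2 <- load_graph(nd, ed), "dropped 1 unconnected")
  expect_equal(nrow(g2$nodes), nrow(g$nodes) - 1)
  expect_false("G_LONELY" %in% g2$nodes$id)
})

test_that("save/load round trip is the identity on a random graph", {
  g <- random_typed_graph(1)
  nd <- withr::local_tempfile(); ed <- withr::local_tempfile()
  save_graph(g, nd, ed)
  g2 <- load_graph(nd, ed, drop_isolated = FALSE)
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$nodes$node_type, g$nodes$node_type)
  expect_equal(g2$edges[c("source", "target", "edge_type")],
               g$edges[c("source", "target", "edge_type")])
  # attributes survive field-by-field, including values needing escaping
  for (i in seq_len(nrow(g$nodes)))
    expect_equal(sort(g2$nodes$attrs[[i]]), sort(g$nodes$attrs[[i]]))
  for (i in seq_len(nrow(g$edges)))
    expect_equal(sort(g2$edges$attrs[[i]]), sort(g$edges$attrs[[i]]))
})

test_that("attribute values with delimiters survive the round trip", {
  g <- chain_graph()
  g$nodes$attrs[[1]] <- c(name = "a=b;c d%e\tf", group = "approved")
  nd <- withr::local_tempfile(); ed <- withr::local_tempfile()
  save_graph(g, nd, ed)
  g2 <- load_graph(nd, ed)
  expect_equal(node_attr(g2, "DR1", "name"), "a=b;c d%e\tf")
})

test_that("the single-file edge-list dialect is auto-detected", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("source_id", "source_type", "source_attrs", "target_id",
          "target_type", "target_attrs", "edge_type", "attrs",
          sep = "\t"),
    paste("DR1", "Small_Molecule", "group=approved", "P1", "Protein", "",
          "binds_to", "activity_type=IC50;activity_value=50",
          sep = "\t"),
    paste("P1", "Protein", "", "G1", "Gene", "symbol=G1", "encoded_by",
          "", sep = "\t")), p)
  g <- load_graph(p)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(node_attr(g, "DR1", "group"), "approved")
  expect_equal(edge_attr_num(g, "activity_value"), c(50, NA))
})

test_that("validation rejects malformed graphs with named offenders", {
  g <- chain_graph()
  bad <- g; bad$nodes$node_type[2] <- "Enzyme"
  expect_error(validate_graph(bad), "Enzyme")
  bad <- g; bad$edges$target[1] <- "NOPE"
  expect_error(validate_graph(bad), "dangling")
  # type-incompatible endpoints: binds_to must run drug -> protein
  bad <- g; bad$edges$target[1] <- "G1"
  expect_error(validate_graph(bad), "not allowed")
  bad <- g; bad$edges$attrs[[1]]["activity_value"] <- "-5"
  expect_error(validate_graph(bad), "activity_value")
  bad <- g; bad$nodes$attrs[[4]] <- character()
  expect_error(validate_graph(bad), "mesh_ui")
})

test_that("rare-disease synonym merge re-points edges and unions attrs", {
  nodes <- data.frame(
    id = c("DR1", "G1", "ORPHA:7", "D000001"),
    node_type = c("Small_Molecule", "Gene", "Rare_Disease",
                  "Common_Disease"),
    stringsAsFactors = FALSE)
  nodes$attrs <- list(c(name = "d", group = "approved"), c(symbol = "G1"),
                      c(ordo_id = "ORPHA:7", mesh_ui = "D000001"),
                      c(mesh_ui = "D000001", mesh_tree = "C01.100",
                        heading = "h"))
  edges <- data.frame(
    source = c("DR1", "G1", "DR1"),
    target = c("D000001", "D000001", "ORPHA:7"),
    edge_type = c("has_indication", "involved_in", "has_side_effect"),
    stringsAsFactors = FALSE)
  edges$attrs <- list(character(),
                      c(association_score = "0.5"), character())
  g <- semantic_graph(nodes, edges)
  m <- merge_rare_disease_synonyms(g)
  expect_equal(nrow(m$nodes), nrow(g$nodes) - 1)
  expect_equal(nrow(m$edges), nrow(g$edges))
  expect_false("D000001" %in% m$nodes$id)
  expect_equal(m$nodes$node_type[m$nodes$id == "ORPHA:7"],
               "Rare_Disease")
  # the two common-disease edges now point at the rare node
  expect_equal(sum(m$edges$target == "ORPHA:7"), 3)
  # attribute union: ORDO id kept, tree numbers gained
  expect_equal(node_attr(m, "ORPHA:7", "ordo_id"), "ORPHA:7")
  expect_equal(node_attr(m, "ORPHA:7", "mesh_tree"), "C01.100")
  validate_graph(m)
})

test_that("merge is a no-op without shared UIs and warns on conflicts", {
  g <- chain_graph()
  expect_identical(merge_rare_disease_synonyms(g)$nodes$id, g$nodes$id)

  nodes <- data.frame(
    id = c("R1", "R2", "D000009", "G1"),
    node_type = c("Rare_Disease", "Rare_Disease", "Common_Disease",
                  "Gene"),
    stringsAsFactors = FALSE)
  nodes$attrs <- list(c(ordo_id = "R1", mesh_ui = "D000009"),
                      c(ordo_id = "R2", mesh_ui = "D000009"),
                      c(mesh_ui = "D000009"), c(symbol = "G1"))
  edges <- data.frame(source = "G1", target = "D000009",
                      edge_type = "involved_in", stringsAsFactors = FALSE)
  edges$attrs <- list(c(association_score = "0.4"))
  g <- semantic_graph(nodes, edges)
  expect_warning(m <- merge_rare_disease_synonyms(g), "D000009")
  expect_equal(m$edges$target, "R1")  # first by id order wins
})

test_that("graphml export writes a file igraph can read back", {
  p <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(random_typed_graph(3), p)
  ig <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(random_typed_graph(3)$nodes))
})
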