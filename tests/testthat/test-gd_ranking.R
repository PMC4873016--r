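pairs_df <- function(keys) {
  data.frame(gene = sub("-.*", "", keys), mesh_ui = sub(".*-", "", keys),
             stringsAsFactors = FALSE)
}

test_that("contingency counts come from exact set intersections", {
  gold <- pairs_df(sprintf("g%02d-d", 1:10))
  universe <- pairs_df(sprintf("g%02d-d", 1:100))
  # source of 20 pairs, 8 of them gold
  src <- pairs_df(sprintf("g%02d-d", c(1:8, 21:32)))
  cc <- contingency(src, gold, universe)
  expect_equal(unclass(cc)[c("pos_in_source", "neg_in_source",
                             "pos_total", "neg_total")],
               list(pos_in_source = 8, neg_in_source = 12,
                    pos_total = 10, neg_total = 90))
  # source identical to gold and universe
  cc <- contingency(gold, gold, gold)
  expect_equal(cc$pos_in_source, 10)
  expect_equal(cc$neg_in_source, 0)
  expect_equal(cc$neg_total, 0)
  # disjoint source and gold
  other <- pairs_df(sprintf("g%02d-d", 41:60))
  cc <- contingency(other, gold, universe)
  expect_equal(cc$pos_in_source, 0)
  expect_equal(cc$neg_in_source, 20)
  expect_error(contingency(pairs_df(character()), gold, universe),
               "empty source")
})

test_that("the log-likelihood score matches hand arithmetic", {
  lls <- function(a, b, c, d, ...) lls_score(
    list(pos_in_source = a, neg_in_source = b, pos_total = c,
         neg_total = d), ...)
  expect_equal(lls(1, 9, 10, 90), 0)            # enrichment = prior
  expect_equal(lls(8, 12, 10, 90), log(6))      # (8/12)/(10/90) = 6
  expect_error(lls(10, 0, 10, 90), "zero negative count")
  expect_error(lls(0, 10, 10, 90), "zero positive")
  cfg <- ranking_config(zero_cell = "pseudocount")
  expect_equal(lls(10, 0, 10, 90, cfg),
               log((10.5 / 0.5) / (10.5 / 90.5)))
  cfg10 <- ranking_config(log_base = 10)
  expect_equal(lls(8, 12, 10, 90, cfg10), log10(6))
})

test_that("LLS is zero iff enrichment equals the prior and increases in hits", {
  set.seed(42)
  for (i in 1:50) {
    tot <- sample(50:500, 1)
    pos_tot <- sample(5:20, 1)
    neg_tot <- tot - pos_tot
    n_src <- sample(5:40, 1)
    k <- sample(seq_len(min(n_src, pos_tot) - 1), 1)
    v <- lls_score(list(pos_in_source = k, neg_in_source = n_src - k,
                        pos_total = pos_tot, neg_total = neg_tot))
    odds_equal <- isTRUE(all.equal(k / (n_src - k), pos_tot / neg_tot))
    expect_equal(v == 0, odds_equal)
    # strictly increasing in pos_in_source, other three cells fixed
    v2 <- lls_score(list(pos_in_source = k + 1, neg_in_source = n_src - k,
                         pos_total = pos_tot, neg_total = neg_tot))
    expect_gt(v2, v)
  }
})

test_that("weighted sum matches arithmetic and its loop oracle", {
  expect_equal(weighted_sum(0.5, D = 3), 0.5)
  expect_equal(weighted_sum(c(16.57, 10.95), D = 5), 18.76)
  expect_equal(weighted_sum(c(1, 1, 1), D = 5), 1.24)
  expect_error(weighted_sum(c(1, 2), D = 5), "descending")
  expect_error(weighted_sum(c(2, -1), D = 5), "> 0")
  expect_error(weighted_sum(numeric(), D = 5), "empty")
  expect_error(weighted_sum(1, D = 1), "D must be")
  ws_oracle <- function(cs, D) {
    acc <- 0
    for (i in seq_along(cs)) acc <- acc + cs[i] / D^(i - 1)
    acc
  }
  set.seed(7)
  for (i in 1:100) {
    cs <- sort(stats::runif(sample(1:8, 1), 0.01, 20), decreasing = TRUE)
    D <- stats::runif(1, 1.1, 9)
    expect_equal(weighted_sum(cs, D), ws_oracle(cs, D),
                 tolerance = 1e-12)
    # bounds: C1 <= WS <= C1 * D/(D-1)
    expect_gte(weighted_sum(cs, D) + 1e-12, cs[1])
    expect_lte(weighted_sum(cs, D), cs[1] * D / (D - 1))
  }
})

ev_row <- function(src, keys, type = "curated", dirn = "unknown") {
  p <- pairs_df(keys)
  data.frame(source_id = src, source_type = type, gene = p$gene,
             mesh_ui = p$mesh_ui, directionality = dirn,
             stringsAsFactors = FALSE)
}

test_that("gold-standard selection minimises the average round-robin rank", {
  # A is a superset of B's overlap with everyone; C is mostly noise.
  # Constructed so A ranks 1 in both rounds where it is tested.
  base <- sprintf("g%02d-d", 1:30)
  ev <- rbind(ev_row("A", base[1:20]),
              ev_row("B", c(base[1:10], sprintf("x%02d-d", 1:10))),
              ev_row("C", c(base[1:4], base[15:18],
                            sprintf("y%02d-d", 1:12))))
  cfg <- ranking_config(zero_cell = "pseudocount")
  g <- select_gold_standard(ev, cfg)
  expect_equal(as.character(g), "A")
  avg <- attr(g, "avg_ranks")
  expect_equal(unname(avg["A"]), 1)
  expect_true(all(avg["A"] <= avg))
  # identical pair sets: every LLS ties, lexicographic winner
  ev2 <- rbind(ev_row("s_b", base), ev_row("s_a", base),
               ev_row("s_c", base))
  expect_equal(as.character(select_gold_standard(ev2, cfg)), "s_a")
})

test_that("score_all combines per-source LLS into normalised scores", {
  cfg <- ranking_config(zero_cell = "pseudocount")
  # single source: its LLS against the universe it alone defines is 0,
  # every ws equals that LLS, the range degenerates and all scores are 1
  ev1 <- ev_row("A", sprintf("g%02d-d", 1:10))
  w <- testthat::capture_warnings(sc <- score_all(ev1, "A", cfg))
  expect_match(w, "degenerate", all = FALSE)
  expect_true(all(sc$ws == 0))
  expect_true(all(sc$association_score == 1))
  expect_equal(nrow(sc), 10)

  # two informative sources plus an uninformative one (negative LLS,
  # dropped with a warning): pairs in both informative sources get
  # WS = C1 + C2/D
  ev2 <- rbind(ev_row("A", sprintf("g%02d-d", 1:20)),
               ev_row("B", sprintf("g%02d-d", 11:25)),
               ev_row("C", sprintf("z%02d-d", 1:40)))
  expect_warning(sc <- score_all(ev2, "A", cfg), "LLS <= 0")
  lls <- attr(sc, "source_lls")
  expect_true(lls[["C"]] <= 0)
  both <- sc[sc$n_sources == 2, ]
  expect_equal(nrow(both), 10)   # g11..g20 sit in A and B
  cs <- sort(unname(lls[lls > 0]), decreasing = TRUE)
  expect_equal(unique(both$ws), weighted_sum(cs, 5))
  # min-max normalisation is rank-preserving
  expect_equal(stats::cor(sc$ws, sc$association_score,
                          method = "spearman"), 1)
  expect_true(all(sc$association_score >= 0 & sc$association_score <= 1))
})

test_that("directionality consensus propagates and conflicts collapse", {
  cfg <- ranking_config(zero_cell = "pseudocount")
  ev <- rbind(ev_row("A", c("g1-d1", "g2-d2", "g3-d3"), dirn = "LoF"),
              ev_row("A", sprintf("f%02d-d", 1:10)),
              ev_row("B", c("g1-d1", "g2-d2"),
                     dirn = c("LoF", "GoF")),
              ev_row("B", c("g9-d9", sprintf("f%02d-d", 1:6))),
              ev_row("C", sprintf("u%02d-d", 1:30)))
  sc <- suppressWarnings(score_all(ev, "A", cfg))
  get <- function(g) sc$directionality[sc$gene == g]
  expect_equal(get("g1"), "LoF")      # agreement
  expect_equal(get("g2"), "unknown")  # LoF vs GoF conflict
  expect_equal(get("g3"), "LoF")      # single annotation
  expect_equal(get("g9"), "unknown")
})

test_that("mapping foreign identifiers expands, dedupes and reports rate", {
  raw <- data.frame(source_id = "S", source_type = "curated",
                    gene_symbol = sprintf("g%02d", 1:10),
                    foreign_namespace = "MIM",
                    foreign_id = sprintf("1%05d", 1:10),
                    stringsAsFactors = FALSE)
  mapping <- data.frame(foreign_namespace = "MIM",
                        foreign_id = sprintf("1%05d", 1:7),
                        mesh_ui = sprintf("D%06d", 1:7),
                        stringsAsFactors = FALSE)
  out <- map_to_mesh(raw, mapping)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "mapping_rate"), 0.7)
  # identity: rows already in MeSH pass through
  raw$foreign_namespace <- "MESH"
  out <- map_to_mesh(raw, mapping)
  expect_equal(out$mesh_ui, raw$foreign_id)
  expect_equal(attr(out, "mapping_rate"), 1)
  # fan-out: one MIM id with two MeSH rows gives two pairs
  raw1 <- raw[1, ]; raw1$foreign_namespace <- "MIM"
  mapping2 <- rbind(mapping,
                    data.frame(foreign_namespace = "MIM",
                               foreign_id = "100001",
                               mesh_ui = "D000099",
                               stringsAsFactors = FALSE))
  out <- map_to_mesh(raw1, mapping2)
  expect_equal(nrow(out), 2)
  expect_warning(map_to_mesh(raw1, mapping[0, ]), "0%")
})

test_that("D tuning scores held-out gold labels and prefers smaller ties", {
  set.seed(11)
  gold_keys <- sprintf("g%02d-d", 1:40)
  # noisy copies of gold with private noise: both sources informative
  ev <- rbind(
    ev_row("GOLD", gold_keys),
    ev_row("near", c(sample(gold_keys, 30), sprintf("n%02d-d", 1:30))),
    ev_row("far", c(sample(gold_keys, 25), sprintf("m%02d-d", 1:35))))
  cfg <- ranking_config(zero_cell = "pseudocount")
  tuned <- tune_D(ev, "GOLD", candidate_Ds = c(2, 5), config = cfg)
  expect_true(all(tuned$auc > 0.5))
  # disjoint sources: every scored pair sits in exactly one source, so
  # its WS is a lone LLS and the AUC cannot depend on D; smallest
  # candidate returned on the tie
  ev1 <- rbind(ev_row("GOLD", gold_keys),
               ev_row("solo", c(gold_keys[1:25], sprintf("n%02d-d", 1:25))),
               ev_row("rest", c(gold_keys[26:35], sprintf("m%02d-d", 1:35))))
  tuned1 <- tune_D(ev1, "GOLD", candidate_Ds = c(1.5, 3, 6), config = cfg)
  expect_equal(unname(diff(range(tuned1$auc))), 0)
  expect_equal(tuned1$best_D, 1.5)
  # degenerate labels: every scored pair positive
  ev2 <- rbind(ev_row("GOLD", gold_keys), ev_row("sub", gold_keys[1:10]))
  expect_error(tune_D(ev2, "GOLD", candidate_Ds = 5, config = cfg),
               "both classes")
})
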