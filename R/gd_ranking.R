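# Bayesian integration of gene-disease evidence.
#
# Each evidence source is scored against a gold-standard source by a
# log-likelihood score comparing the source's conditional odds of being in
# the gold standard with the prior odds over the captured universe:
#
#   LLS(E) = log[ (P(L|E) / notP(L|E)) / (P(L) / notP(L)) ]
#
# Per-association confidences are combined by a weighted sum in which the
# i-th highest contribution is divided by D^(i-1); D models dependence
# between sources (curated databases seed each other).

pair_key <- function(gene, mesh_ui) paste(gene, mesh_ui, sep = "\r")

#' Ranking configuration
#'
#' @param D down-weighting divisor of the weighted sum (> 1; default 5).
#' @param log_base base for the log-likelihood score (default natural).
#' @param zero_cell policy when a contingency cell is zero:
#'   \code{"error"} (default) or \code{"pseudocount"} (add 0.5 to each of
#'   the four counts).
#' @param universe prior universe: \code{"captured"} (union of all mapped
#'   pairs across sources, default) or \code{"cartesian"} (all gene x
#'   disease combinations observed in the data).
#' @return a \code{ranking_config} list.
#' @export
ranking_config <- function(D = 5.0, log_base = exp(1),
                           zero_cell = c("error", "pseudocount"),
                           universe = c("captured", "cartesian")) {
  stopifnot(D > 1, log_base > 1)
  structure(list(D = D, log_base = log_base,
                 zero_cell = match.arg(zero_cell),
                 universe = match.arg(universe)),
            class = "ranking_config")
}

#' Read per-source gene-disease evidence
#'
#' @param path TSV with columns \code{source_id, source_type, gene_symbol,
#'   mesh_ui, directionality} (directionality in LoF/GoF/unknown; blank is
#'   read as unknown). Several files may be concatenated with
#'   \code{rbind}.
#' @return an evidence data.frame (columns \code{source_id, source_type,
#'   gene, mesh_ui, directionality}), deduplicated within source on
#'   (gene, disease).
#' @export
read_evidence <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("source_id", "source_type", "gene_symbol", "mesh_ui")
  if (!all(need %in% names(tab)))
    stop("evidence table requires columns: ", paste(need, collapse = ", "))
  dirn <- if (is.null(tab$directionality)) rep("unknown", nrow(tab))
          else ifelse(tab$directionality %in% c("LoF", "GoF"),
                      tab$directionality, "unknown")
  ev <- data.frame(source_id = tab$source_id, source_type = tab$source_type,
                   gene = tab$gene_symbol, mesh_ui = tab$mesh_ui,
                   directionality = dirn, stringsAsFactors = FALSE)
  ev <- ev[!duplicated(ev[c("source_id", "gene", "mesh_ui")]), , drop = FALSE]
  bad <- ev$gene == "" | ev$mesh_ui == ""
  if (any(bad)) stop("evidence rows with empty gene or disease: ",
                     sum(bad), " row(s)")
  rownames(ev) <- NULL
  ev
}

#' Map foreign disease identifiers to MeSH
#'
#' Expands evidence rows keyed by a foreign identifier (OMIM MIM number,
#' UMLS CUI, ...) to all MeSH UIs listed for it in a mapping table;
#' many-to-many mappings fan out, unmapped rows are dropped and counted.
#' Rows whose namespace is already \code{MESH} map to themselves.
#'
#' @param raw data.frame with columns \code{source_id, source_type,
#'   gene_symbol, foreign_namespace, foreign_id} and optional
#'   \code{directionality}.
#' @param mapping data.frame with columns \code{foreign_namespace,
#'   foreign_id, mesh_ui} (read one with \code{\link{read_mapping}}).
#' @return an evidence data.frame as in \code{\link{read_evidence}}, with
#'   attribute \code{mapping_rate} (fraction of input rows mapped).
#' @export
map_to_mesh <- function(raw, mapping) {
  stopifnot(all(c("source_id", "source_type", "gene_symbol",
                  "foreign_namespace", "foreign_id") %in% names(raw)))
  if (is.null(raw$directionality)) raw$directionality <- "unknown"
  self <- raw$foreign_namespace == "MESH"
  mapped <- data.frame(source_id = raw$source_id[self],
                       source_type = raw$source_type[self],
                       gene = raw$gene_symbol[self],
                       mesh_ui = raw$foreign_id[self],
                       directionality = raw$directionality[self],
                       stringsAsFactors = FALSE)
  n_hit <- sum(self)
  fore <- raw[!self, , drop = FALSE]
  if (nrow(fore)) {
    key <- paste(fore$foreign_namespace, fore$foreign_id, sep = "\r")
    mkey <- paste(mapping$foreign_namespace, mapping$foreign_id, sep = "\r")
    idx <- split(seq_along(mkey), mkey)
    hits <- lapply(key, function(k) idx[[k]])
    n_hit <- n_hit + sum(lengths(hits) > 0)
    rep_i <- rep(seq_len(nrow(fore)), lengths(hits))
    if (length(rep_i)) {
      mapped <- rbind(mapped, data.frame(
        source_id = fore$source_id[rep_i],
        source_type = fore$source_type[rep_i],
        gene = fore$gene_symbol[rep_i],
        mesh_ui = mapping$mesh_ui[unlist(hits)],
        directionality = fore$directionality[rep_i],
        stringsAsFactors = FALSE))
    }
  }
  rate <- if (nrow(raw)) n_hit / nrow(raw) else NA_real_
  if (!is.na(rate) && rate == 0) warning("map_to_mesh: 0% of rows mapped")
  mapped <- mapped[!duplicated(mapped[c("source_id", "gene", "mesh_ui")]), ,
                   drop = FALSE]
  rownames(mapped) <- NULL
  structure(mapped, mapping_rate = rate)
}

#' @rdname map_to_mesh
#' @param path TSV with columns \code{foreign_namespace, foreign_id,
#'   mesh_ui}.
#' @export
read_mapping <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("foreign_namespace", "foreign_id", "mesh_ui")
  if (!all(need %in% names(tab)))
    stop("mapping table requires columns: ", paste(need, collapse = ", "))
  tab
}

#' Contingency counts behind the log-likelihood score
#'
#' Counts, by exact set intersection on (gene, disease): the source pairs
#' in the gold standard, the source pairs outside it, the gold pairs, and
#' the non-gold pairs in the universe.
#'
#' @param source_pairs,gold_pairs,universe_pairs data.frames with columns
#'   \code{gene} and \code{mesh_ui} (extra columns ignored).
#' @return a \code{contingency_counts} list with elements
#'   \code{pos_in_source, neg_in_source, pos_total, neg_total}.
#' @export
contingency <- function(source_pairs, gold_pairs, universe_pairs) {
  sk <- unique(pair_key(source_pairs$gene, source_pairs$mesh_ui))
  gk <- unique(pair_key(gold_pairs$gene, gold_pairs$mesh_ui))
  uk <- unique(pair_key(universe_pairs$gene, universe_pairs$mesh_ui))
  if (!length(sk)) stop("empty source pair set")
  if (!length(gk)) stop("empty gold-standard pair set")
  pos <- sum(sk %in% gk)
  structure(list(pos_in_source = pos,
                 neg_in_source = length(sk) - pos,
                 pos_total = length(gk),
                 neg_total = length(uk) - sum(uk %in% gk)),
            class = "contingency_counts")
}

#' Log-likelihood score of a source
#'
#' \code{log[(pos_in_source / neg_in_source) / (pos_total / neg_total)]}
#' in the configured base. A zero in any cell either raises an error
#' naming the cell or, under the pseudocount policy, adds a 0.5 continuity
#' correction to each of the four counts.
#'
#' @param counts a \code{\link{contingency}} result (or a list with the
#'   same four fields).
#' @param config a \code{\link{ranking_config}}.
#' @return the LLS value (0 when the source's enrichment equals the
#'   prior).
#' @export
lls_score <- function(counts, config = ranking_config()) {
  cc <- as.numeric(counts[c("pos_in_source", "neg_in_source",
                            "pos_total", "neg_total")])
  if (any(cc < 0)) stop("negative contingency count")
  if (any(cc == 0)) {
    if (config$zero_cell == "error") {
      nm <- c("zero positive count in source", "zero negative count",
              "zero gold-standard total", "zero non-gold total")
      stop("lls_score: ", nm[which(cc == 0)[1L]])
    }
    cc <- cc + 0.5
  }
  log((cc[1] / cc[2]) / (cc[3] / cc[4]), base = config$log_base)
}

#' Select the gold-standard source by round-robin ranking
#'
#' Every source takes a turn as the gold standard; in each round every
#' other source is LLS-scored against it and ranked (1 = highest score).
#' Each source's ranks are averaged over the rounds in which it is tested,
#' and the source with the lowest average rank is returned (ties broken by
#' lexicographic source id, with a message). Rounds in which scoring
#' degenerates (e.g. a zero cell under the error policy) are skipped with
#' a warning.
#'
#' @param evidence evidence data.frame (\code{\link{read_evidence}}).
#' @param config a \code{\link{ranking_config}}.
#' @return the winning source id, with attribute \code{avg_ranks} (named
#'   numeric vector) and \code{rank_table}.
#' @export
select_gold_standard <- function(evidence, config = ranking_config()) {
  sources <- sort(unique(evidence$source_id))
  if (length(sources) < 2) stop("need at least 2 sources")
  universe <- evidence[!duplicated(pair_key(evidence$gene,
                                            evidence$mesh_ui)), ,
                       drop = FALSE]
  by_src <- split(evidence, evidence$source_id)
  rank_rows <- list()
  for (g in sources) {
    test <- setdiff(sources, g)
    lls <- rep(NA_real_, length(test)); names(lls) <- test
    for (s in test) {
      lls[s] <- tryCatch(
        lls_score(contingency(by_src[[s]], by_src[[g]], universe), config),
        error = function(e) {
          warning(sprintf("gold %s / test %s skipped: %s",
                          g, s, conditionMessage(e)))
          NA_real_
        })
    }
    ok <- !is.na(lls)
    if (!any(ok)) next
    # rank 1 = highest LLS; ties get the average rank
    r <- rank(-lls[ok], ties.method = "average")
    rank_rows[[g]] <- data.frame(gold = g, source = names(r),
                                 lls = lls[ok], rank = as.numeric(r),
                                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rank_rows)
  if (is.null(tab)) stop("all scoring rounds degenerate")
  avg <- tapply(tab$rank, tab$source, mean)
  winners <- names(avg)[avg == min(avg)]
  if (length(winners) > 1)
    message("select_gold_standard: tie between ",
            paste(sort(winners), collapse = ", "),
            "; choosing lexicographic first")
  structure(sort(winners)[1L], avg_ranks = avg[order(names(avg))],
            rank_table = tab)
}

#' Weighted sum of descending confidence contributions
#'
#' \code{WS = sum_i C_i / D^(i-1)}: the highest contribution enters
#' unchanged, the rest are progressively down-weighted. Input must already
#' be sorted descending and strictly positive (sorting is the caller's
#' responsibility and is verified).
#'
#' @param contributions numeric vector of confidence scores, descending.
#' @param D divisor (> 1).
#' @return the weighted sum, in \code{[C_1, C_1 * D / (D - 1))}.
#' @export
weighted_sum <- function(contributions, D = 5.0) {
  if (!length(contributions)) stop("empty contribution list")
  if (D <= 1) stop("D must be > 1")
  if (any(contributions <= 0)) stop("contributions must be > 0")
  if (is.unsorted(rev(contributions)))
    stop("contributions must be sorted descending")
  sum(contributions / D^(seq_along(contributions) - 1))
}

#' Score every gene-disease association in the universe
#'
#' Computes each source's LLS against the chosen gold-standard source,
#' then for every (gene, disease) pair the weighted sum of the LLS values
#' of the sources containing it, and finally a min-max normalised
#' association score in [0, 1]. Only sources with LLS > 0 enter the
#' weighted sums (non-positive evidence is anti-informative under the
#' model); a pair supported by no such source falls back to its best LLS
#' so every universe pair is scored, and a warning reports the
#' non-informative sources. Directionality is the consensus of the
#' contributing
#' sources' annotations: a single annotated direction propagates,
#' conflicting annotations collapse to unknown.
#'
#' @param evidence evidence data.frame.
#' @param gold_id the gold-standard source id (see
#'   \code{\link{select_gold_standard}}); ignored when \code{gold_pairs}
#'   is supplied.
#' @param config a \code{\link{ranking_config}}.
#' @param gold_pairs optional explicit gold-standard pair set (data.frame
#'   with \code{gene}, \code{mesh_ui}), used e.g. when the gold source is
#'   held out of the scoring inputs during D tuning.
#' @return data.frame \code{gene, mesh_ui, ws, association_score,
#'   n_sources, directionality}, one row per universe pair, sorted by
#'   decreasing \code{ws}; attribute \code{source_lls} carries the
#'   per-source LLS values.
#' @export
score_all <- function(evidence, gold_id = NULL, config = ranking_config(),
                      gold_pairs = NULL) {
  sources <- sort(unique(evidence$source_id))
  if (is.null(gold_pairs)) {
    if (is.null(gold_id) || !gold_id %in% sources)
      stop("unknown gold source: ",
           if (is.null(gold_id)) "<missing>" else gold_id)
  }
  universe <- evidence[!duplicated(pair_key(evidence$gene,
                                            evidence$mesh_ui)), ,
                       drop = FALSE]
  by_src <- split(evidence, evidence$source_id)
  gold_set <- if (is.null(gold_pairs)) by_src[[gold_id]] else gold_pairs
  lls <- vapply(sources, function(s)
    lls_score(contingency(by_src[[s]], gold_set, universe), config),
    numeric(1))
  names(lls) <- sources
  if (any(lls <= 0)) {
    warning("score_all: source(s) with LLS <= 0 contribute only as a ",
            "fallback: ", paste(names(lls)[lls <= 0], collapse = ", "))
  }
  key <- pair_key(evidence$gene, evidence$mesh_ui)
  contrib <- split(lls[evidence$source_id], key)
  dirs <- split(evidence$directionality, key)
  ukey <- pair_key(universe$gene, universe$mesh_ui)
  out <- universe[c("gene", "mesh_ui")]
  # positive contributions enter the weighted sum; a pair supported only
  # by non-informative sources keeps its best LLS so every universe pair
  # is scored (with a lone source this reduces to ws = that LLS)
  out$ws <- vapply(contrib[ukey], function(cs) {
    pos <- cs[cs > 0]
    if (length(pos))
      weighted_sum(sort(unname(pos), decreasing = TRUE), config$D)
    else max(cs)
  }, numeric(1))
  out$n_sources <- as.integer(lengths(contrib[ukey]))
  out$directionality <- vapply(dirs[ukey], function(d) {
    d <- unique(d[d != "unknown"])
    if (length(d) == 1L) d else "unknown"
  }, character(1))
  rng <- range(out$ws)
  if (diff(rng) == 0) {
    warning("score_all: degenerate weighted-sum range; ",
            "all association scores set to 1")
    out$association_score <- rep(1, nrow(out))
  } else {
    out$association_score <- (out$ws - rng[1]) / diff(rng)
  }
  out <- out[order(-out$ws, out$gene, out$mesh_ui),
             c("gene", "mesh_ui", "ws", "association_score", "n_sources",
               "directionality")]
  rownames(out) <- NULL
  structure(out, source_lls = lls)
}

#' Write scored associations to TSV
#'
#' @param scored result of \code{\link{score_all}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_scored_associations <- function(scored, path) {
  utils::write.table(as.data.frame(scored), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# AUC by the rank statistic (midranks for ties); labels logical
rank_auc <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Tune the down-weighting divisor D by ROC AUC
#'
#' For each candidate D, associations are scored with the gold-standard
#' source excluded from the scoring inputs while its pair set provides the
#' positive labels; the AUC of the weighted sums against those labels is
#' computed by the rank statistic, and the D with the highest AUC is
#' returned (ties go to the smaller D).
#'
#' @param evidence evidence data.frame.
#' @param gold_id the gold-standard source id.
#' @param candidate_Ds numeric grid of divisors, each > 1 (default 1.5 to
#'   8 in steps of 0.5).
#' @param config a \code{\link{ranking_config}} (its D is ignored).
#' @return list with \code{best_D} and \code{auc} (named numeric vector,
#'   one entry per candidate).
#' @export
tune_D <- function(evidence, gold_id, candidate_Ds = seq(1.5, 8, by = 0.5),
                   config = ranking_config()) {
  if (!length(candidate_Ds)) stop("empty candidate grid")
  rest <- evidence[evidence$source_id != gold_id, , drop = FALSE]
  if (!nrow(rest)) stop("no non-gold sources to score")
  gold_pairs <- evidence[evidence$source_id == gold_id, , drop = FALSE]
  gk <- unique(pair_key(gold_pairs$gene, gold_pairs$mesh_ui))
  aucs <- vapply(candidate_Ds, function(D) {
    cfg <- ranking_config(D = D, log_base = config$log_base,
                          zero_cell = config$zero_cell,
                          universe = config$universe)
    sc <- suppressWarnings(score_all(rest, config = cfg,
                                     gold_pairs = gold_pairs))
    labels <- pair_key(sc$gene, sc$mesh_ui) %in% gk
    rank_auc(sc$ws, labels)
  }, numeric(1))
  names(aucs) <- format(candidate_Ds)
  best <- candidate_Ds[which.max(aucs)]   # which.max: first max -> smallest D
  list(best_D = best, auc = aucs)
}
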