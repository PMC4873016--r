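# Therapeutic-area prioritisation. For each top-level MeSH area the
# coverage probabilities are the fraction of its diseases with at least
# one gene association (P(G-D)) and the fraction with at least one
# marketed-drug indication (P(Dr-D)). The unmet score is
#
#   TAU(ta) = (1 - P(Dr-D)) * P(G-D) * f(|ta|)
#
# where f rewards large areas and equals 1 for the largest; the richness
# score is RTA(ta) = P(Dr-D) * P(G-D). Small areas are excluded by the
# 100 / n_areas percent minimum-size rule (3.448% with 29 areas).

#' Map diseases to top-level therapeutic areas
#'
#' A disease belongs to every top-level MeSH code (e.g. C10) that prefixes
#' one of its tree numbers; diseases under several areas are counted once
#' per area. Diseases without tree numbers are excluded with a warning.
#'
#' @param graph a \code{semantic_graph}.
#' @return named list: area code -> character vector of disease node ids.
#' @export
area_membership <- function(graph) {
  dis <- nodes_of_type(graph, DISEASE_TYPES)
  if (!length(dis)) return(stats::setNames(list(), character()))
  tn <- node_attr(graph, dis, "mesh_tree")
  missing <- is.na(tn) | tn == ""
  if (any(missing))
    warning(sprintf("area_membership: %d disease(s) without tree numbers",
                    sum(missing)))
  dis <- dis[!missing]; tn <- tn[!missing]
  if (!length(dis)) return(stats::setNames(list(), character()))
  trees <- strsplit(tn, "|", fixed = TRUE)
  areas <- lapply(trees, function(t) unique(tree_top_level(t)))
  df <- data.frame(area = unlist(areas),
                   id = rep(dis, lengths(areas)),
                   stringsAsFactors = FALSE)
  out <- split(df$id, df$area)
  out[order(names(out))]
}

#' Coverage probabilities of a disease set
#'
#' @param graph a \code{semantic_graph}.
#' @param members non-empty character vector of disease node ids.
#' @return named numeric: \code{p_gd} (fraction with >= 1 involved_in
#'   edge) and \code{p_drd} (fraction with >= 1 has_indication edge).
#' @export
coverage <- function(graph, members) {
  if (!length(members)) stop("empty member set")
  gd_targets <- unique(edges_of_type(graph, "involved_in")$target)
  drd_targets <- unique(edges_of_type(graph, "has_indication")$target)
  c(p_gd = mean(members %in% gd_targets),
    p_drd = mean(members %in% drd_targets))
}

#' Therapeutic-area unmet score (TAU)
#'
#' @param p_gd,p_drd coverage probabilities (\code{\link{coverage}}).
#' @param n_diseases size of the area.
#' @param max_size size of the largest area (> 0).
#' @param size_factor_mode how the size term f(|ta|) is formed:
#'   \code{"linear"} (default) \code{|ta|/MAX}, increasing and 1 at the
#'   largest area; \code{"complement"} \code{1 - |ta|/MAX}; or
#'   \code{"reciprocal"} \code{1 - 1/(MAX * |ta|)}. The non-default modes
#'   are provided for sensitivity analysis.
#' @return TAU in [0, 1].
#' @export
area_tau <- function(p_gd, p_drd, n_diseases, max_size,
                     size_factor_mode = c("linear", "complement",
                                          "reciprocal")) {
  size_factor_mode <- match.arg(size_factor_mode)
  if (max_size <= 0) stop("max_size must be > 0")
  f <- switch(size_factor_mode,
              linear = n_diseases / max_size,
              complement = 1 - n_diseases / max_size,
              reciprocal = 1 - 1 / (max_size * n_diseases))
  (1 - p_drd) * p_gd * f
}

#' Rich-therapeutic-area score (RTA)
#'
#' @param p_gd,p_drd coverage probabilities.
#' @return \code{p_drd * p_gd}.
#' @export
area_rta <- function(p_gd, p_drd) p_drd * p_gd

#' Flag areas passing the minimum-size rule
#'
#' An area is eligible iff its share of the total disease-area
#' memberships (counted with duplication) strictly exceeds
#' \code{1 / n_areas} (100/29 = 3.448\% with the full MeSH's 29 areas).
#'
#' @param sizes named integer vector of area sizes.
#' @param total total memberships; defaults to \code{sum(sizes)}.
#' @param n_areas number of areas for the threshold; defaults to
#'   \code{length(sizes)}.
#' @return named logical vector.
#' @export
eligible_areas <- function(sizes, total = sum(sizes),
                           n_areas = length(sizes)) {
  if (n_areas <= 0) stop("n_areas must be > 0")
  sizes / total > 1 / n_areas
}

#' Score all therapeutic areas of a graph
#'
#' Combines \code{\link{area_membership}}, \code{\link{coverage}},
#' \code{\link{area_tau}}, \code{\link{area_rta}} and
#' \code{\link{eligible_areas}} into one table.
#'
#' @param graph a \code{semantic_graph}.
#' @param size_factor_mode passed to \code{\link{area_tau}}.
#' @param n_areas threshold denominator for eligibility; defaults to the
#'   number of areas observed.
#' @return data.frame \code{ta, n_diseases, p_gd, p_drd, tau, rta,
#'   eligible}, sorted by decreasing tau.
#' @export
score_areas <- function(graph, size_factor_mode = "linear",
                        n_areas = NULL) {
  members <- area_membership(graph)
  if (!length(members)) {
    return(data.frame(ta = character(), n_diseases = integer(),
                      p_gd = numeric(), p_drd = numeric(),
                      tau = numeric(), rta = numeric(),
                      eligible = logical(), stringsAsFactors = FALSE))
  }
  sizes <- lengths(members)
  cov <- vapply(members, function(m) coverage(graph, m), numeric(2))
  out <- data.frame(ta = names(members),
                    n_diseases = as.integer(sizes),
                    p_gd = cov["p_gd", ],
                    p_drd = cov["p_drd", ],
                    stringsAsFactors = FALSE)
  out$tau <- mapply(area_tau, out$p_gd, out$p_drd, out$n_diseases,
                    MoreArgs = list(max_size = max(sizes),
                                    size_factor_mode = size_factor_mode))
  out$rta <- area_rta(out$p_gd, out$p_drd)
  out$eligible <- eligible_areas(
    sizes, n_areas = if (is.null(n_areas)) length(sizes) else n_areas)
  out <- out[order(-out$tau, out$ta), , drop = FALSE]
  rownames(out) <- NULL
  out
}
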