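#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least `k` pathway
#' members when `n` query compounds are drawn without replacement from a
#' reference metabolome of `N` compounds of which `m` belong to the
#' pathway. Exact tail sum; `k = 0` gives exactly 1.
#'
#' @param N universe (reference metabolome) size.
#' @param m pathway size.
#' @param n query size.
#' @param k observed hits.
#' @return the enrichment p-value.
#' @export
hypergeometric_enrichment <- function(N, m, n, k) {
  if (m > N || n > N) stop("pathway and query must be subsets of the universe")
  if (k > min(m, n) || k < 0) stop("infeasible hit count k = ", k)
  if (k == 0) return(1)
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

pathway_graph <- function(pathway) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(pathway$members),
                            name = pathway$members)
  if (nrow(pathway$edges))
    g <- igraph::add_edges(g, t(pathway$edges))
  g
}

#' Relative betweenness centrality of pathway members
#'
#' Betweenness centrality of every node of the undirected, unweighted
#' pathway graph, with shortest-path ties split fractionally, normalized
#' by `(|V| - 1)(|V| - 2) / 2` so a node lying on every shortest path
#' scores 1. Isolated nodes score 0.
#'
#' @param pathway a pathway definition from [read_pathway_library()] (a
#'   list with `members` and a 2-column `edges` matrix).
#' @return named numeric vector, one centrality per member.
#' @export
relative_betweenness <- function(pathway) {
  nv <- length(pathway$members)
  if (nv == 0) return(stats::setNames(numeric(0), character(0)))
  if (nv <= 2)
    return(stats::setNames(rep(0, nv), pathway$members))
  g <- pathway_graph(pathway)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), pathway$members)
}

#' Topology-based pathway impact
#'
#' Fraction of the pathway's total relative-betweenness centrality carried
#' by the hit compounds: `sum(centrality[hits]) / sum(centrality)`, and 0
#' when the pathway carries no centrality at all (e.g. an edgeless
#' pathway). Hits with zero centrality (peripheral nodes) contribute
#' nothing; a sole central hit scores 1.
#'
#' @param pathway a pathway definition.
#' @param hits character vector of hit compound ids (must be members).
#' @return impact in `[0, 1]`.
#' @export
pathway_impact <- function(pathway, hits) {
  if (length(setdiff(hits, pathway$members)))
    stop("hits must be pathway members")
  cb <- relative_betweenness(pathway)
  tot <- sum(cb)
  if (tot == 0) return(0)
  sum(cb[hits]) / tot
}

#' Pathway over-representation analysis of a compound list
#'
#' For each pathway of the library: hit count, hypergeometric enrichment
#' p-value against the reference metabolome (by default the union of all
#' library members), and topology impact from relative betweenness.
#' Results are sorted by ascending p-value. Query ids outside the universe
#' are dropped with a warning.
#'
#' @param query character vector of compound ids (e.g. KEGG ids).
#' @param library a pathway library from [read_pathway_library()].
#' @param universe reference metabolome; defaults to all library members.
#' @param adjust `"none"` (default; raw pathway p-values) or `"holm"`.
#' @return data.frame of class `PathwayResult`: `pathway`, `size`, `hits`,
#'   `p`, `p_adj`, `impact`, plus attribute `n_query_used`.
#' @export
analyze_pathways <- function(query, library,
                             universe = unique(unlist(
                               lapply(library, `[[`, "members"))),
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!length(library)) stop("pathway library is empty")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    warning(length(dropped), " query id(s) outside the universe dropped")
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(library, function(p) {
    members <- intersect(p$members, universe)
    hits <- intersect(query, members)
    data.frame(pathway = p$name, size = length(members),
               hits = length(hits),
               p = hypergeometric_enrichment(N, length(members), n,
                                             length(hits)),
               impact = if (length(hits)) pathway_impact(p, hits) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else
    out$p
  out <- out[order(out$p, -out$impact, out$pathway),
             c("pathway", "size", "hits", "p", "p_adj", "impact")]
  rownames(out) <- NULL
  attr(out, "n_query_used") <- n
  class(out) <- c("PathwayResult", "data.frame")
  out
}
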