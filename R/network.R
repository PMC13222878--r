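#' Pairwise correlation screen across taxa
#'
#' Spearman (default, robust for abundance data) or Pearson correlations
#' between all taxon pairs, with two-sided p-values from the t
#' approximation on n - 2 degrees of freedom (the convention of the
#' classic rcorr screen). Zero-variance taxa are excluded with a message.
#' Input defaults to relative abundances; set \code{useRelative = FALSE}
#' to screen raw counts (the choice is reported in the result).
#'
#' @param at an \linkS4class{AbundanceTable} (>= 4 samples).
#' @param method "spearman" or "pearson".
#' @param useRelative correlate relative abundances (default) or counts.
#' @return list: \code{rho} and \code{p} symmetric matrices, \code{n}
#'   sample count, \code{method}, \code{useRelative}, \code{dropped}
#'   zero-variance taxa.
#' @export
correlationScreen <- function(at, method = c("spearman", "pearson"),
                              useRelative = TRUE) {
  method <- match.arg(method)
  x <- if (useRelative) relativeAbundance(at) else t(counts(at))
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples, found ", n)
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped))
    message("excluding ", length(dropped), " zero-variance taxa")
  x <- x[, v > 0, drop = FALSE]
  rho <- stats::cor(x, method = method)
  r <- rho
  diag(r) <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[r^2 >= 1] <- 0
  diag(p) <- NA
  diag(rho) <- 1
  list(rho = rho, p = p, n = n, method = method,
       useRelative = useRelative, dropped = dropped)
}

#' Build a co-occurrence network from a correlation screen
#'
#' An undirected edge joins two taxa when the screen p-value is strictly
#' below \code{edgeAlpha}; the edge keeps the correlation as weight and
#' its sign as an attribute (negative correlations form edges too).
#' Isolated taxa are dropped by default so the node count reflects
#' connected genera.
#'
#' @param screen result of \code{\link{correlationScreen}}, or a list
#'   with symmetric aligned matrices \code{rho} and \code{p}.
#' @param edgeAlpha edge significance threshold (paper convention 0.01).
#' @param condition named character (site, compartment, treatment).
#' @param keepIsolated retain unconnected taxa as isolated nodes.
#' @return a \linkS4class{CooccurrenceNetwork}.
#' @export
buildNetwork <- function(screen, edgeAlpha = 0.01,
                         condition = c(site = NA, compartment = NA,
                                       treatment = NA),
                         keepIsolated = FALSE) {
  rho <- screen$rho; p <- screen$p
  if (!identical(dim(rho), dim(p)) ||
      !identical(dimnames(rho), dimnames(p)))
    stop("rho and p matrices are misaligned")
  if (edgeAlpha <= 0 || edgeAlpha > 1) stop("edgeAlpha must be in (0, 1]")
  ut <- upper.tri(p)
  sel <- which(ut & p < edgeAlpha, arr.ind = TRUE)
  labs <- colnames(rho)
  el <- data.frame(from = labs[sel[, 1]], to = labs[sel[, 2]],
                   rho = rho[sel], p = p[sel],
                   sign = ifelse(rho[sel] >= 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = labs))
  if (!keepIsolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g <- igraph::set_graph_attr(g, "edge_alpha", edgeAlpha)
  g <- igraph::set_graph_attr(g, "method",
                              if (!is.null(screen$method)) screen$method
                              else "unknown")
  net <- methods::new("CooccurrenceNetwork", graph = g,
                      condition = as.character(condition),
                      edgeAlpha = edgeAlpha,
                      method = if (!is.null(screen$method)) screen$method
                      else "unknown")
  net
}

#' Node and network topology metrics
#'
#' Degree and betweenness per node (edges treated as unweighted for path
#' computations), global clustering coefficient (transitivity), average
#' path length over connected pairs only, and the modularity of the
#' partition found by \code{\link{detectModules}}.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param seed RNG seed for the modularity partition.
#' @return list: n_nodes, n_edges, degree, betweenness,
#'   clustering_coefficient, average_path_length, modularity. Metrics
#'   undefined on an empty graph are NA.
#' @export
topologyMetrics <- function(net, seed = 1) {
  g <- net@graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0)
    return(list(n_nodes = 0L, n_edges = 0L, degree = integer(0),
                betweenness = numeric(0),
                clustering_coefficient = NA_real_,
                average_path_length = NA_real_, modularity = NA_real_))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  cc <- igraph::transitivity(g, type = "global")
  apl <- if (m == 0) NA_real_
  else igraph::mean_distance(g, unconnected = TRUE)
  mod <- if (m == 0) NA_real_
  else igraph::modularity(g, detectModules(net, seed = seed)@membership,
                          weights = abs(igraph::E(g)$rho %||% rep(1, m)))
  list(n_nodes = n, n_edges = m, degree = deg, betweenness = btw,
       clustering_coefficient = cc, average_path_length = apl,
       modularity = mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.null_metric <- function(g, metric) {
  switch(metric,
         clustering = igraph::transitivity(g, type = "global"),
         average_path_length = igraph::mean_distance(g, unconnected = TRUE),
         modularity = igraph::modularity(
           g, igraph::membership(igraph::cluster_louvain(g))),
         stop("unknown metric: ", metric))
}

#' Compare observed topology with an Erdos-Renyi G(n, m) null ensemble
#'
#' Generates \code{nGraphs} uniform random graphs with exactly the
#' observed node and edge counts, recomputes each requested metric on
#' every null graph, and reports a two-sided empirical p per metric
#' (add-one convention; "at least as extreme" means at least as far from
#' the null mean as the observed value). The network is declared
#' non-random when any tested metric has p < \code{nullAlpha}.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param nGraphs ensemble size (>= 99).
#' @param seed integer RNG seed.
#' @param metrics subset of c("clustering", "average_path_length",
#'   "modularity").
#' @param nullAlpha verdict significance level (paper convention 0.05).
#' @return a \linkS4class{NullComparison}.
#' @export
nullEnsemble <- function(net, nGraphs = 999, seed = 1,
                         metrics = c("clustering", "average_path_length",
                                     "modularity"),
                         nullAlpha = 0.05) {
  if (nGraphs < 99) stop("nGraphs must be >= 99")
  g <- net@graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (m > n * (n - 1) / 2) stop("edge count exceeds the simple-graph maximum")
  obs <- vapply(metrics, function(mt) .null_metric(g, mt), numeric(1))
  restore <- .with_seed(seed)
  on.exit(restore())
  null_vals <- matrix(NA_real_, nGraphs, length(metrics),
                      dimnames = list(NULL, metrics))
  for (i in seq_len(nGraphs)) {
    gn <- igraph::sample_gnm(n, m)
    stopifnot(igraph::vcount(gn) == n, igraph::ecount(gn) == m)
    null_vals[i, ] <- vapply(metrics, function(mt) .null_metric(gn, mt),
                             numeric(1))
  }
  mu <- colMeans(null_vals, na.rm = TRUE)
  sdv <- apply(null_vals, 2, stats::sd, na.rm = TRUE)
  pv <- vapply(seq_along(metrics), function(j) {
    dev_obs <- abs(obs[j] - mu[j])
    dev_null <- abs(null_vals[, j] - mu[j])
    (1 + sum(dev_null >= dev_obs, na.rm = TRUE)) / (1 + nGraphs)
  }, numeric(1))
  df <- data.frame(metric = metrics, observed = unname(obs),
                   nullMean = unname(mu), nullSd = unname(sdv),
                   p = pv, stringsAsFactors = FALSE)
  methods::new("NullComparison", metrics = df,
               nGraphs = as.integer(nGraphs), seed = as.integer(seed),
               nonRandom = any(pv < nullAlpha), nullAlpha = nullAlpha)
}

#' Top-k hub genera by degree
#'
#' The k highest-degree nodes; ties are broken by betweenness (desc),
#' then label order, and a tie crossing the k-th position triggers a
#' warning so the arbitrary cut is visible.
#'
#' @param net a \linkS4class{CooccurrenceNetwork} with >= k nodes.
#' @param k hub-list size (paper convention 10).
#' @return character vector of k genus labels, ordered.
#' @export
topHubs <- function(net, k = 10) {
  g <- net@graph
  if (igraph::vcount(g) < k)
    stop("network has fewer than k = ", k, " nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  ord <- order(-deg, -btw, names(deg))
  ranked <- names(deg)[ord]
  if (k < length(ranked) &&
      deg[ranked[k]] == deg[ranked[k + 1]] &&
      btw[ranked[k]] == btw[ranked[k + 1]])
    warning("tie at the k-th hub broken by label order")
  ranked[seq_len(k)]
}

#' Classify hub turnover between untreated and treated networks
#'
#' @param untreatedHubs,treatedHubs hub lists of equal length k with no
#'   duplicates.
#' @return a \linkS4class{HubShift}: maintained = intersection, lost =
#'   untreated only, gained = treated only.
#' @export
hubShift <- function(untreatedHubs, treatedHubs) {
  if (anyDuplicated(untreatedHubs) || anyDuplicated(treatedHubs))
    stop("duplicated labels within a hub list")
  if (length(untreatedHubs) != length(treatedHubs))
    stop("hub lists must have equal length")
  methods::new("HubShift",
               maintained = intersect(untreatedHubs, treatedHubs),
               lost = setdiff(untreatedHubs, treatedHubs),
               gained = setdiff(treatedHubs, untreatedHubs),
               k = length(untreatedHubs))
}
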