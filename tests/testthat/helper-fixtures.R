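# Fixture builders shared across the suite; everything is generated in
# code so no binary data ships with the package.

toy_metadata <- function(ids, site = "non_urban",
                         compartment = "rhizosphere",
                         treatment = "untreated") {
  data.frame(sample_id = ids, site = site, compartment = compartment,
             treatment = treatment, rhizobox_id = paste0("R", seq_along(ids)),
             stringsAsFactors = FALSE)
}

toy_table <- function(counts, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  AbundanceTable(counts, toy_metadata(rownames(counts), ...))
}

constant_zymogram <- function(value, nr = 10, nc = 10, pixelSize = 0.01)
  Zymogram(matrix(value, nr, nc), pixelSize)

# a CooccurrenceNetwork wrapped around an arbitrary igraph graph, giving
# every edge a dummy significant correlation
wrap_network <- function(g, edgeAlpha = 0.05) {
  m <- igraph::ecount(g)
  if (m > 0) {
    igraph::E(g)$rho <- igraph::E(g)$rho %||% rep(0.9, m)
    igraph::E(g)$p <- igraph::E(g)$p %||% rep(1e-6, m)
    igraph::E(g)$sign <- ifelse(igraph::E(g)$rho >= 0, "positive",
                                "negative")
  }
  methods::new("CooccurrenceNetwork", graph = g,
               condition = c("non_urban", "rhizosphere", "untreated"),
               edgeAlpha = edgeAlpha, method = "spearman")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# partition constructed from a planted truth (for recovery comparisons)
truth_partition <- function(moduleOf) {
  ids <- sort(unique(moduleOf))
  sizes <- vapply(ids, function(i) sum(moduleOf == i), integer(1))
  memb <- stats::setNames(as.integer(moduleOf), names(moduleOf))
  methods::new("ModulePartition", membership = memb,
               sizes = sizes, algorithm = "truth", seed = 0L)
}

# majority-vote mapping of detected modules onto planted truth ids
map_modules_to_truth <- function(part, moduleOf) {
  memb <- part@membership
  truth <- moduleOf[names(memb)]
  vapply(sort(unique(memb)), function(m) {
    tab <- table(truth[memb == m])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

# adjusted Rand index from the contingency table (Hubert & Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# --- independent small-graph oracles (adjacency-matrix based) ----------

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(A) {
  triangles <- sum(diag(A %*% A %*% A)) / 6
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) NaN else 3 * triangles / triples
}

oracle_apl <- function(A) {
  D <- oracle_distances(A)
  off <- D[upper.tri(D)]
  mean(off[is.finite(off)])
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  # shortest-path counts by dynamic programming over increasing distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(D[is.finite(D)])
  for (d in seq_len(maxd)) for (s in seq_len(n)) for (t in seq_len(n))
    if (D[s, t] == d) {
      pred <- which(A[, t] > 0 & D[s, ] == d - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n))
    if (s < t && s != v && t != v && is.finite(D[s, t]) &&
        D[s, v] + D[v, t] == D[s, t])
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  btw
}
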