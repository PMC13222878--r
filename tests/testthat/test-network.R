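test_that("correlation screen is rcorr-compatible and guards degeneracies", {
  set.seed(20)
  cnt <- matrix(rpois(10 * 5, 40), 10, 5,
                dimnames = list(paste0("S", 1:10), paste0("t", 1:5)))
  cnt[, 5] <- cnt[, 4]  # duplicated taxon
  cnt <- cbind(cnt, t6 = 7)  # zero variance (constant relative? no: counts)
  at <- toy_table(cnt)
  expect_message(scr <- correlationScreen(at, useRelative = FALSE),
                 "zero-variance")
  expect_equal(scr$rho["t4", "t5"], 1)
  expect_equal(scr$p["t4", "t5"], 0)
  expect_false("t6" %in% colnames(scr$rho))
  expect_equal(scr$rho, t(scr$rho))
  # p-values follow the t approximation on n - 2 df
  r <- scr$rho["t1", "t2"]
  tt <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(scr$p["t1", "t2"], 2 * pt(-abs(tt), 8))
  # pearson branch agrees with cor.test exactly
  scr_p <- suppressMessages(correlationScreen(at, method = "pearson",
                                              useRelative = FALSE))
  ct <- cor.test(cnt[, 1], cnt[, 2])
  expect_equal(scr_p$p["t1", "t2"], ct$p.value, tolerance = 1e-12)
  expect_error(correlationScreen(at[, 1:3]), "at least 4 samples")
})

test_that("Spearman screen p at n = 6 tracks exact permutation enumeration", {
  set.seed(21)
  x <- c(12, 45, 23, 67, 34, 51)
  y <- c(14, 40, 30, 60, 31, 55)
  rho_obs <- cor(x, y, method = "spearman")
  # enumerate all 720 rank arrangements of y
  idx <- expand.grid(rep(list(1:6), 6))
  idx <- idx[apply(idx, 1, function(v) length(unique(v)) == 6), ]
  rho_all <- apply(idx, 1, function(v) cor(x, y[v], method = "spearman"))
  p_exact <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  cnt <- cbind(a = x, b = y, c = rev(x), d = x + y)
  rownames(cnt) <- paste0("S", 1:6)
  scr <- correlationScreen(toy_table(cnt), useRelative = FALSE)
  # t approximation versus the exact null: documented tolerance 0.1
  expect_equal(scr$p["a", "b"], p_exact, tolerance = 0.1)
})

test_that("network construction screens edges and drops isolated nodes", {
  labs <- c("a", "b", "c")
  rho <- matrix(0.9, 3, 3, dimnames = list(labs, labs)); diag(rho) <- 1
  p <- matrix(1, 3, 3, dimnames = list(labs, labs)); diag(p) <- NA
  scr <- list(rho = rho, p = p, method = "spearman")
  expect_equal(igraph::ecount(networkGraph(buildNetwork(scr, 0.01))), 0)
  p2 <- p; p2["a", "b"] <- p2["b", "a"] <- 1e-4
  net <- buildNetwork(list(rho = rho, p = p2, method = "spearman"), 0.01)
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("a", "b"))  # c isolated, dropped
  net_k <- buildNetwork(list(rho = rho, p = p2, method = "spearman"),
                        0.01, keepIsolated = TRUE)
  expect_equal(igraph::vcount(networkGraph(net_k)), 3)
  bad <- list(rho = rho, p = p2[1:2, 1:2])
  expect_error(buildNetwork(bad), "misaligned")
})

test_that("edge screen is monotone in alpha and keeps degree identity", {
  sim <- generateCommunity(30, 25, 3, coupling = 1.5, seed = 23)
  scr <- correlationScreen(sim$table)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  edges <- lapply(alphas, function(a) {
    g <- networkGraph(buildNetwork(scr, a))
    el <- igraph::as_data_frame(g, "edges")
    paste(el$from, el$to)
  })
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(edges[[i]] %in% edges[[i + 1]]))
  g <- networkGraph(buildNetwork(scr, 0.05))
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("topology metrics match closed forms on star and K4", {
  star <- wrap_network(igraph::make_star(5, "undirected", center = 1) |>
                         igraph::set_vertex_attr("name",
                                                 value = paste0("n", 1:5)))
  tm <- topologyMetrics(star)
  expect_equal(unname(tm$degree["n1"]), 4)
  expect_equal(unname(tm$degree[paste0("n", 2:5)]), rep(1, 4))
  expect_equal(unname(tm$betweenness["n1"]), 6)  # all C(4,2) leaf pairs
  expect_equal(unname(tm$betweenness["n2"]), 0)
  k4 <- wrap_network(igraph::make_full_graph(4) |>
                       igraph::set_vertex_attr("name",
                                               value = paste0("k", 1:4)))
  tm4 <- topologyMetrics(k4)
  expect_equal(tm4$clustering_coefficient, 1)
  expect_equal(tm4$average_path_length, 1)
  empty <- wrap_network(igraph::make_empty_graph(0, directed = FALSE))
  tme <- topologyMetrics(empty)
  expect_equal(tme$n_nodes, 0L)
  expect_true(is.na(tme$clustering_coefficient))
})

test_that("topology metrics equal independent matrix-based oracles", {
  set.seed(24)
  for (i in 1:12) {
    g <- igraph::sample_gnp(9, 0.35)
    igraph::V(g)$name <- paste0("v", 1:9)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    net <- wrap_network(g)
    tm <- topologyMetrics(net)
    expect_equal(unname(tm$degree), unname(rowSums(A)))
    expect_equal(unname(tm$betweenness), oracle_betweenness(A),
                 tolerance = 1e-10)
    cc <- oracle_clustering(A)
    if (is.nan(cc)) expect_true(is.nan(tm$clustering_coefficient))
    else expect_equal(tm$clustering_coefficient, cc)
    if (igraph::ecount(g) > 0)
      expect_equal(tm$average_path_length, oracle_apl(A))
  }
})

test_that("null ensemble preserves (n, m) and flags structured graphs", {
  cliques <- igraph::disjoint_union(igraph::make_full_graph(6),
                                    igraph::make_full_graph(6))
  igraph::V(cliques)$name <- paste0("c", 1:12)
  net <- wrap_network(cliques)
  nc <- nullEnsemble(net, nGraphs = 99, seed = 3, metrics = "clustering")
  expect_equal(nc@metrics$observed, 1)
  expect_equal(nc@metrics$p, 1 / 100)  # minimal attainable p
  expect_true(nc@nonRandom)
  expect_error(nullEnsemble(net, nGraphs = 50), ">= 99")
  # determinism of the ensemble under a fixed seed
  nc2 <- nullEnsemble(net, nGraphs = 99, seed = 3, metrics = "clustering")
  expect_identical(nc@metrics, nc2@metrics)
})

test_that("hub ranking follows degree, betweenness, then label", {
  star <- wrap_network(igraph::make_star(5, "undirected", center = 1) |>
                         igraph::set_vertex_attr("name",
                                                 value = paste0("n", 1:5)))
  expect_equal(topHubs(star, 1), "n1")
  # all degrees tied: documented order is by label, with a warning
  ring <- wrap_network(igraph::make_ring(6) |>
                         igraph::set_vertex_attr("name",
                                                 value = rev(letters[1:6])))
  expect_warning(h <- topHubs(ring, 3), "tie")
  expect_equal(h, c("a", "b", "c"))
  expect_error(topHubs(ring, 10), "fewer than k")
  # random graph: hub set equals a full degree-sort oracle
  set.seed(25)
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- sprintf("g%02d", 1:30)
  net <- wrap_network(g)
  h10 <- suppressWarnings(topHubs(net, 10))
  deg <- igraph::degree(g)
  expect_gte(min(deg[h10]), max(deg[setdiff(names(deg), h10)]))
})

test_that("hub shift set algebra matches the study's reported shapes", {
  same <- paste0("g", 1:10)
  hs <- hubShift(same, same)
  expect_length(hs@maintained, 10)
  expect_length(hs@lost, 0)
  hs2 <- hubShift(paste0("u", 1:10), paste0("t", 1:10))
  expect_length(hs2@maintained, 0)
  expect_length(hs2@lost, 10)
  expect_length(hs2@gained, 10)
  # one shared hub of ten: the non-urban rhizoplane pattern
  hs3 <- hubShift(c("shared", paste0("u", 1:9)),
                  c("shared", paste0("t", 1:9)))
  expect_length(hs3@maintained, 1)
  expect_length(hs3@lost, 9)
  expect_length(hs3@gained, 9)
  expect_error(hubShift(c("a", "a", "b"), c("c", "d", "e")), "duplicated")
})
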