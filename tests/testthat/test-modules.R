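test_that("module detection resolves unambiguous structure", {
  cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                    igraph::make_full_graph(5))
  igraph::V(cliques)$name <- letters[1:10]
  part <- detectModules(wrap_network(cliques), seed = 1)
  memb <- moduleMembership(part)
  expect_length(unique(memb), 2)
  expect_length(unique(memb[letters[1:5]]), 1)
  expect_length(unique(memb[letters[6:10]]), 1)
  expect_equal(part@sizes, c(5L, 5L))
  # degenerate single edge: behaviour pinned to one shared module
  single <- wrap_network(igraph::make_graph(~ a - b))
  p1 <- detectModules(single, seed = 1)
  expect_equal(unname(moduleMembership(p1)), c(1L, 1L))
  expect_error(detectModules(wrap_network(
    igraph::make_empty_graph(0, directed = FALSE))), "empty")
})

test_that("module ranking is stable under node relabelling", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("x", 1:10)
  p <- detectModules(wrap_network(g), seed = 2)
  expect_equal(p@sizes, c(6L, 4L))  # module 1 is the larger
  g2 <- igraph::permute(g, c(5:10, 1:4))
  p2 <- detectModules(wrap_network(g2), seed = 2)
  expect_equal(p2@sizes, p@sizes)
  expect_equal(sort(names(moduleMembership(p2))[moduleMembership(p2) == 1]),
               sort(names(moduleMembership(p))[moduleMembership(p) == 1]))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  sim <- generateCommunity(50, 40, 4, coupling = 2, seed = 5)
  scr <- correlationScreen(sim$table)
  net <- buildNetwork(scr, 0.01)
  part <- detectModules(net, seed = 5)
  truth <- sim$truth@moduleOf[names(moduleMembership(part))]
  a <- ari(moduleMembership(part), truth)
  expect_gte(a, 0.8)
  # the in-suite ARI helper agrees with mclust's reference implementation
  expect_equal(a, mclust::adjustedRandIndex(moduleMembership(part), truth))
})

test_that("module profiles summarise member abundances", {
  sim <- generateCommunity(30, 12, 3, coupling = 2, seed = 6)
  part <- truth_partition(sim$truth@moduleOf)
  prof <- moduleProfile(sim$table, part, 1)
  expect_length(prof, 30)
  # one-taxon module: profile equals that taxon's z-scored abundance
  set.seed(6)
  cnt3 <- matrix(rpois(60, 40) + 1, 20, 3,
                 dimnames = list(paste0("S", 1:20), c("a", "b", "c")))
  at3 <- toy_table(cnt3)
  solo <- methods::new("ModulePartition",
                       membership = setNames(c(2L, 2L, 1L), c("a", "b", "c")),
                       sizes = c(1L, 2L), algorithm = "truth", seed = 0L)
  p1 <- moduleProfile(at3, solo, 1)
  ra <- relativeAbundance(at3)[, "c"]
  expect_equal(unname(p1), unname((ra - mean(ra)) / sd(ra)))
  # two proportionally identical members: profile correlates 1 with either
  raw <- cbind(a = rpois(20, 30) + 1, b = 0, c = 0)
  raw[, "b"] <- seq_len(20); raw[, "c"] <- 2 * seq_len(20)
  rownames(raw) <- paste0("S", 1:20)
  att <- toy_table(raw)
  pp <- moduleProfile(att, methods::new(
    "ModulePartition",
    membership = setNames(c(2L, 1L, 1L), c("a", "b", "c")),
    sizes = c(2L, 1L), algorithm = "truth", seed = 0L), 1)
  rb <- relativeAbundance(att)[, "b"]
  expect_equal(abs(cor(pp, rb)), 1, tolerance = 1e-12)
  expect_error(moduleProfile(sim$table, part, 99), "no members")
})

test_that("association screening keeps sign and monotone invariance", {
  set.seed(7)
  prof <- matrix(rnorm(40), 20, 2,
                 dimnames = list(paste0("S", 1:20), c("M1", "M2")))
  tv <- cbind(copy = prof[, "M1"],
              mono = -exp(prof[, "M1"]),
              noise = rnorm(20))
  rownames(tv) <- rownames(prof)
  am <- associate(prof, tv, alpha = 0.01)
  expect_equal(am@rho["M1", "copy"], 1)
  expect_true(am@significant["M1", "copy"])
  expect_equal(am@rho["M1", "mono"], -1)  # monotone transform: |rho| = 1
  expect_true(am@p["M1", "mono"] < 0.01)
  expect_error(associate(prof[1:3, ], tv[1:3, ]), "fewer than 4")
  # missing trait values fall back to pairwise-complete observations
  tv_na <- tv; tv_na[1:4, "copy"] <- NA
  am_na <- associate(prof, tv_na, alpha = 0.01)
  expect_equal(am_na@rho["M1", "copy"], 1)
})

test_that("null association calls occur at about the nominal 1% rate", {
  set.seed(8)
  n_rep <- 400
  hits <- 0L
  prof <- matrix(rnorm(50), 50, 1, dimnames = list(paste0("S", 1:50), "M1"))
  for (i in seq_len(n_rep)) {
    tv <- matrix(rnorm(50), 50, 1, dimnames = list(rownames(prof), "x"))
    am <- associate(prof, tv, alpha = 0.01)
    hits <- hits + sum(am@significant)
  }
  rate <- hits / n_rep
  # binomial: 4 * sqrt(.01 * .99 / 400) ~ 0.02
  expect_lt(abs(rate - 0.01), 0.02)
})

test_that("Mantel test matches exhaustive enumeration at n = 5", {
  set.seed(9)
  x <- matrix(rnorm(10), 5, 2)
  d1 <- as.matrix(dist(x))
  d2 <- as.matrix(dist(x + rnorm(10, sd = 0.4)))
  res <- mantelTest(d1, d2, nPerm = 999, seed = 1)
  lt <- lower.tri(d1)
  perms <- rbind(1:5)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  r_all <- vapply(all_perms(1:5), function(idx)
    cor(d1[lt], d2[idx, idx][lt]), numeric(1))
  p_exact <- mean(r_all >= res$mantel_r - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 0.05)
  # r agrees with vegan's implementation
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(res$mantel_r, unname(ref$statistic), tolerance = 1e-12)
  # identical matrices: r = 1 at the minimum attainable p (n large
  # enough that no sampled permutation reproduces the identity)
  d10 <- as.matrix(dist(rnorm(10)))
  res_id <- mantelTest(d10, d10, nPerm = 199, seed = 2)
  expect_equal(res_id$mantel_r, 1)
  expect_equal(res_id$p_value, 1 / 200)
  expect_error(mantelTest(d1, d2[1:4, 1:4]), "mismatched")
})

test_that("Mantel r is invariant to positive affine rescaling of distances", {
  set.seed(10)
  d1 <- as.matrix(dist(rnorm(8)))
  d2 <- as.matrix(dist(rnorm(8)))
  r0 <- mantelTest(d1, d2, nPerm = 99, seed = 1)$mantel_r
  r1 <- mantelTest(2.5 * d1, d2, nPerm = 99, seed = 1)$mantel_r
  d2s <- 0.3 * d2 + 1; diag(d2s) <- 0  # affine on off-diagonal entries
  r2 <- mantelTest(d1, d2s, nPerm = 99, seed = 1)$mantel_r
  expect_equal(r1, r0)
  expect_equal(r2, r0, tolerance = 1e-12)
})

test_that("module matching and shift classification obey set identities", {
  memb_a <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), letters[1:6])
  memb_b <- setNames(c(2L, 2L, 2L, 1L, 1L, 3L), letters[1:6])
  pa <- methods::new("ModulePartition", membership = memb_a,
                     sizes = c(3L, 2L, 1L), algorithm = "truth", seed = 0L)
  pb <- methods::new("ModulePartition", membership = memb_b,
                     sizes = c(3L, 2L, 1L), algorithm = "truth", seed = 0L)
  mm <- matchModules(pa, pb)
  expect_equal(mm$other[mm$reference == 1], 2L)
  expect_equal(mm$other[mm$reference == 2], 1L)
  expect_equal(mm$jaccard[mm$reference == 1], 1)

  mk_am <- function(sig_cells, modules = c("M1", "M2"),
                    traits = c("pH", "NN", "TOC")) {
    p <- matrix(0.5, length(modules), length(traits),
                dimnames = list(modules, traits))
    for (cell in sig_cells) p[cell[1], cell[2]] <- 0.001
    methods::new("AssociationMatrix", rho = sign(0.5 - p), p = p,
                 significant = p < 0.01, alpha = 0.01)
  }
  u <- mk_am(list(c("M1", "pH"), c("M2", "NN")))
  t_same <- mk_am(list(c("M1", "pH"), c("M2", "NN")))
  s1 <- classifyShift(u, t_same)
  expect_length(s1@maintained, 2)
  expect_length(s1@new, 0)
  expect_length(s1@missed, 0)
  t_null <- mk_am(list())
  s2 <- classifyShift(u, t_null)
  expect_length(s2@missed, 2)
  # identities: new + maintained = treated-significant,
  #             missed + maintained = untreated-significant
  t_mix <- mk_am(list(c("M1", "pH"), c("M1", "NN"), c("M2", "TOC")))
  s3 <- classifyShift(u, t_mix)
  expect_setequal(c(s3@new, s3@maintained),
                  c("M1|pH", "M1|NN", "M2|TOC"))
  expect_setequal(c(s3@missed, s3@maintained), c("M1|pH", "M2|NN"))
  expect_error(classifyShift(u, mk_am(list(), traits = c("pH", "NN"))),
               "trait sets")
})

test_that("shift counts reproduce the rhizosphere 22/29/2 pattern", {
  # constructed matrices with 22 shared, 29 treated-only and 2
  # untreated-only significant cells (4 modules x 14 traits = 56 cells)
  modules <- paste0("M", 1:4)
  traits <- paste0("tr", 1:14)
  cells <- as.matrix(expand.grid(modules, traits,
                                 stringsAsFactors = FALSE))
  u_sig <- cells[1:24, , drop = FALSE]          # 22 shared + 2 missed
  t_sig <- cells[c(1:22, 25:53), , drop = FALSE] # 22 shared + 29 new
  mk <- function(sig) {
    p <- matrix(0.9, 4, 14, dimnames = list(modules, traits))
    for (i in seq_len(nrow(sig))) p[sig[i, 1], sig[i, 2]] <- 1e-4
    methods::new("AssociationMatrix", rho = p * 0, p = p,
                 significant = p < 0.01, alpha = 0.01)
  }
  s <- classifyShift(mk(u_sig), mk(t_sig))
  expect_length(s@maintained, 22)
  expect_length(s@new, 29)
  expect_length(s@missed, 2)
})
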