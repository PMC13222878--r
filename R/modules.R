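#' Detect network modules by greedy modularity optimization
#'
#' Louvain multilevel modularity optimization on absolute correlation
#' weights (modularity is undefined for negative weights). Module ids are
#' relabelled dense from 1 in ranking order: by node count (desc), ties
#' by summed degree (desc), then by smallest member label.
#'
#' @param net a non-empty \linkS4class{CooccurrenceNetwork}.
#' @param seed integer RNG seed making the partition reproducible.
#' @return a \linkS4class{ModulePartition}.
#' @export
detectModules <- function(net, seed = 1) {
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("empty network")
  w <- if (igraph::ecount(g) > 0 && !is.null(igraph::E(g)$rho))
    abs(igraph::E(g)$rho) else NULL
  restore <- .with_seed(seed)
  on.exit(restore())
  cl <- igraph::cluster_louvain(g, weights = w)
  memb <- igraph::membership(cl)
  deg <- igraph::degree(g)
  ids <- sort(unique(as.integer(memb)))
  size <- vapply(ids, function(i) sum(memb == i), integer(1))
  sumdeg <- vapply(ids, function(i) sum(deg[memb == i]), numeric(1))
  firstlab <- vapply(ids, function(i) min(names(memb)[memb == i]), "")
  ord <- order(-size, -sumdeg, firstlab)
  relabel <- integer(max(ids))
  relabel[ids[ord]] <- seq_along(ids)
  new_memb <- stats::setNames(relabel[as.integer(memb)], names(memb))
  methods::new("ModulePartition", membership = new_memb,
               sizes = size[ord], algorithm = "louvain",
               seed = as.integer(seed))
}

#' Top-ranked modules of a partition
#'
#' @param part a \linkS4class{ModulePartition}.
#' @param n how many modules (paper convention: top four per network).
#' @return integer vector of module ids (1 = largest).
#' @export
topModules <- function(part, n = 4)
  seq_len(min(n, length(part@sizes)))

#' Per-sample summary profile of one module
#'
#' The mean, per sample, of the z-scored relative abundances of the
#' module's member taxa: a sample-level stand-in for the module's joint
#' abundance, comparable across modules of different size. Member taxa
#' with zero variance contribute a zero z-score.
#'
#' @param at an \linkS4class{AbundanceTable} covering the member taxa.
#' @param part a \linkS4class{ModulePartition}.
#' @param moduleId module id present in the partition.
#' @return named numeric vector, one value per sample.
#' @export
moduleProfile <- function(at, part, moduleId) {
  members <- names(part@membership)[part@membership == moduleId]
  if (!length(members)) stop("module ", moduleId, " has no members")
  members <- intersect(members, taxa(at))
  if (!length(members))
    stop("module ", moduleId, " has no member taxa in the table")
  ra <- relativeAbundance(at)[, members, drop = FALSE]
  z <- apply(ra, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  rowMeans(matrix(z, nrow = nrow(ra),
                  dimnames = list(rownames(ra), members)))
}

#' Module-trait Spearman association matrix
#'
#' Spearman correlation and two-sided p-value (t approximation on
#' pairwise-complete observations) for every (module profile, trait)
#' pair; a pair is significant when p < alpha (paper convention 0.01).
#'
#' @param profiles samples x modules matrix of module summary profiles
#'   (column names are module labels).
#' @param traits a \linkS4class{TraitTable} (or units x traits matrix)
#'   aligned to the profile rows by unit id.
#' @param alpha significance level.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
associate <- function(profiles, traits, alpha = 0.01) {
  tv <- if (methods::is(traits, "TraitTable")) traits@values
  else as.matrix(traits)
  profiles <- as.matrix(profiles)
  common <- intersect(rownames(profiles), rownames(tv))
  if (length(common) < 4) stop("fewer than 4 aligned units")
  profiles <- profiles[common, , drop = FALSE]
  tv <- tv[common, , drop = FALSE]
  nm <- ncol(profiles); nt <- ncol(tv)
  rho <- p <- matrix(NA_real_, nm, nt,
                     dimnames = list(colnames(profiles), colnames(tv)))
  for (i in seq_len(nm)) for (j in seq_len(nt)) {
    ok <- stats::complete.cases(profiles[, i], tv[, j])
    if (sum(ok) < 4) next
    r <- stats::cor(profiles[ok, i], tv[ok, j], method = "spearman")
    rho[i, j] <- r
    n <- sum(ok)
    if (abs(r) >= 1) p[i, j] <- 0
    else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  sig <- !is.na(p) & p < alpha
  methods::new("AssociationMatrix", rho = rho, p = p, significant = sig,
               alpha = alpha)
}

#' Mantel test between two distance matrices
#'
#' mantel r is the Pearson correlation of the off-diagonal entries; the
#' p-value permutes rows and columns of the second matrix simultaneously
#' (add-one convention, one-sided on r >= observed, the standard Mantel
#' direction).
#'
#' @param d1,d2 symmetric distance matrices over the same units, same
#'   order.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list: mantel_r, p_value, n_permutations.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    stop("distance matrices have mismatched dimensions")
  if (nPerm < 99) stop("nPerm must be >= 99")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt])
  restore <- .with_seed(seed)
  on.exit(restore())
  r_perm <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(n)
    stats::cor(d1[lt], d2[idx, idx][lt])
  }, numeric(1))
  list(mantel_r = r_obs,
       p_value = (1 + sum(r_perm >= r_obs)) / (1 + nPerm),
       n_permutations = nPerm)
}

#' Match module labels across two partitions by maximum Jaccard overlap
#'
#' Greedy assignment: the pair of modules with the highest Jaccard index
#' of member sets is matched first, then the next among the remaining,
#' and so on. Used to give untreated and treated networks a comparable
#' module labelling before shift classification.
#'
#' @param reference,other \linkS4class{ModulePartition}s.
#' @return data.frame: reference module, other module, jaccard.
#' @export
matchModules <- function(reference, other) {
  ref_ids <- seq_along(reference@sizes)
  oth_ids <- seq_along(other@sizes)
  memb_r <- reference@membership; memb_o <- other@membership
  jac <- outer(ref_ids, oth_ids, Vectorize(function(a, b) {
    sa <- names(memb_r)[memb_r == a]; sb <- names(memb_o)[memb_o == b]
    u <- length(union(sa, sb))
    if (u == 0) 0 else length(intersect(sa, sb)) / u
  }))
  out <- data.frame(reference = integer(0), other = integer(0),
                    jaccard = numeric(0))
  while (length(ref_ids) && length(oth_ids) && any(jac > 0)) {
    best <- which(jac == max(jac), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(reference = ref_ids[best[1]],
                                 other = oth_ids[best[2]],
                                 jaccard = jac[best[1], best[2]]))
    ref_ids <- ref_ids[-best[1]]; oth_ids <- oth_ids[-best[2]]
    jac <- jac[-best[1], -best[2], drop = FALSE]
  }
  out[order(out$reference), ]
}

#' Classify biochar-induced shifts in module-trait associations
#'
#' Compares two association matrices sharing a module labelling
#' convention and trait set: \code{new} = significant only under
#' treatment, \code{maintained} = significant in both, \code{missed} =
#' significant only untreated.
#'
#' @param untreated,treated \linkS4class{AssociationMatrix} objects with
#'   identical trait sets.
#' @return an \linkS4class{AssociationShift}; elements are
#'   \code{"module|trait"} keys.
#' @export
classifyShift <- function(untreated, treated) {
  if (!setequal(colnames(untreated@p), colnames(treated@p)))
    stop("trait sets differ between the two association matrices")
  keyset <- function(am) {
    idx <- which(am@significant, arr.ind = TRUE)
    if (!nrow(idx)) return(character(0))
    paste(rownames(am@p)[idx[, 1]], colnames(am@p)[idx[, 2]], sep = "|")
  }
  u <- keyset(untreated); t <- keyset(treated)
  methods::new("AssociationShift",
               new = sort(setdiff(t, u)),
               maintained = sort(intersect(u, t)),
               missed = sort(setdiff(u, t)))
}
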