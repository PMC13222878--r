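#' Remove extremely rare taxa by overall relative abundance
#'
#' A taxon is retained when its study-wide relative abundance
#' (taxon total / grand total * 100) is greater than or equal to the
#' threshold; the boundary case is kept. Samples are never removed.
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param thresholdPercent percent threshold in [0, 100]; the 0.005
#'   default removes likely sequencing artefacts.
#' @return a filtered \linkS4class{AbundanceTable}.
#' @export
filterRare <- function(at, thresholdPercent = 0.005) {
  if (thresholdPercent < 0 || thresholdPercent > 100)
    stop("thresholdPercent must lie in [0, 100]")
  cnt <- counts(at)
  grand <- sum(cnt)
  if (grand == 0) stop("empty table: grand total is zero")
  keep <- 100 * rowSums(cnt) / grand >= thresholdPercent
  at[keep, ]
}

#' Relative abundances (per-sample proportions)
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param percent return percentages instead of proportions.
#' @return samples x taxa numeric matrix.
#' @export
relativeAbundance <- function(at, percent = FALSE) {
  cnt <- t(counts(at))
  tot <- rowSums(cnt)
  if (any(tot == 0)) stop("sample(s) with zero total count: ",
                          paste(rownames(cnt)[tot == 0], collapse = ", "))
  out <- cnt / tot
  if (percent) out * 100 else out
}

#' Aggregate taxa to a higher rank
#'
#' Counts are summed within identical rank labels; taxa without an
#' annotation are pooled into \code{"unclassified"}.
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param rank "phylum" or "genus".
#' @return an \linkS4class{AbundanceTable} at the requested rank.
#' @export
aggregateRank <- function(at, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  lab <- SummarizedExperiment::rowData(at)[[rank]]
  if (is.null(lab)) stop("rank annotation '", rank, "' missing")
  lab <- as.character(lab)
  lab[is.na(lab) | lab == ""] <- "unclassified"
  cnt <- counts(at)
  agg <- rowsum(cnt, lab)
  AbundanceTable(t(agg), sampleData(at))
}

#' Shannon diversity index (natural log)
#'
#' \code{H = -sum(p_i * ln(p_i))} over taxa with positive count,
#' \code{p_i = count_i / total}.
#'
#' @param x a count vector, or an \linkS4class{AbundanceTable}
#'   (one H per sample).
#' @return numeric H in nats.
#' @export
shannonIndex <- function(x) {
  if (methods::is(x, "AbundanceTable"))
    return(apply(counts(x), 2, shannonIndex))
  if (all(x == 0)) stop("all-zero sample: Shannon undefined")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Alpha diversity with Kruskal-Wallis group comparison
#'
#' Shannon H per sample plus a Kruskal-Wallis test per requested metadata
#' factor, with Benjamini-Hochberg q-values across the factors tested.
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param factors metadata factor names to test.
#' @return list: \code{shannon} (named per-sample H) and \code{tests}
#'   (data.frame factor, statistic, p_value, q_value).
#' @export
alphaDiversity <- function(at, factors = c("site", "compartment",
                                           "treatment")) {
  H <- shannonIndex(at)
  md <- sampleData(at)
  rows <- lapply(factors, function(f) {
    g <- factor(md[[f]])
    if (nlevels(g) < 2)
      return(data.frame(factor = f, statistic = NA_real_,
                        p_value = NA_real_))
    kw <- stats::kruskal.test(H, g)
    data.frame(factor = f, statistic = unname(kw$statistic),
               p_value = kw$p.value)
  })
  tests <- do.call(rbind, rows)
  tests$q_value <- stats::p.adjust(tests$p_value, method = "BH")
  list(shannon = H, tests = tests)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)} over taxa, computed on
#' counts or relative abundances as supplied.
#'
#' @param at an \linkS4class{AbundanceTable}, or a samples x taxa matrix.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
brayCurtis <- function(at) {
  x <- if (methods::is(at, "AbundanceTable")) t(counts(at)) else as.matrix(at)
  if (nrow(x) < 2) stop("need at least 2 samples")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(rownames(x)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Permutation PERMANOVA on a dissimilarity matrix
#'
#' One-factor PERMANOVA in Anderson's formulation: total and within-group
#' sums of squares are taken from squared dissimilarities
#' (\code{SS_T = sum d_ij^2 / n} over all pairs, \code{SS_W} analogously
#' within groups), \code{pseudo-F = (SS_A / (a - 1)) / (SS_W / (n - a))}.
#' The p-value permutes group labels with the add-one convention
#' \code{p = (1 + #permuted F >= observed F) / (1 + nPerm)}.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @param groups group label per sample; >= 2 groups of >= 2 samples.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer RNG seed fixing the permutation stream.
#' @return list: pseudo_F, p_value, df, n_permutations.
#' @export
permanova <- function(d, groups, nPerm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups must match the matrix dimension")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group(s) not allowed")
  if (nPerm < 99) stop("nPerm must be >= 99")
  d2 <- d^2
  pseudoF <- function(g) {
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      if (length(i) > 1) {
        sub <- d2[i, i]
        ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(i)
      }
    }
    a <- nlevels(g)
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudoF(groups)
  restore <- .with_seed(seed)
  on.exit(restore())
  f_perm <- vapply(seq_len(nPerm), function(i)
    pseudoF(groups[sample.int(n)]), numeric(1))
  list(pseudo_F = f_obs,
       p_value = (1 + sum(f_perm >= f_obs)) / (1 + nPerm),
       df = c(among = nlevels(groups) - 1L, within = n - nlevels(groups)),
       n_permutations = nPerm)
}

#' Two-group differential abundance on relative abundances
#'
#' Per-taxon two-sided Wilcoxon rank-sum test on relative abundances
#' between the two levels of a metadata factor, Benjamini-Hochberg
#' corrected; direction is the sign of the mean relative-abundance
#' difference. Taxa absent from all samples are skipped with a message.
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param contrast metadata factor name with exactly two levels in the
#'   (possibly pre-subset) table.
#' @param alphaQ q-value threshold for the enriched/depleted call.
#' @param test a function(x, y) returning a list with \code{statistic} and
#'   \code{p.value}; defaults to \code{wilcox.test}.
#' @return data.frame: taxon, direction (level enriched in), statistic,
#'   p_value, q_value, called.
#' @export
differentialAbundance <- function(at, contrast = "treatment",
                                  alphaQ = 0.05, test = NULL) {
  md <- sampleData(at)
  g <- factor(md[[contrast]])
  g <- droplevels(g)
  if (nlevels(g) != 2)
    stop("contrast '", contrast, "' must have exactly two levels, found ",
         nlevels(g))
  if (is.null(test))
    test <- function(x, y)
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  ra <- relativeAbundance(at)
  empty <- colSums(ra) == 0
  if (any(empty))
    message("skipping ", sum(empty), " taxa absent from all samples")
  ra <- ra[, !empty, drop = FALSE]
  lv <- levels(g)
  rows <- lapply(colnames(ra), function(tx) {
    x <- ra[g == lv[1], tx]; y <- ra[g == lv[2], tx]
    tst <- test(x, y)
    data.frame(taxon = tx,
               direction = if (mean(x) >= mean(y)) lv[1] else lv[2],
               statistic = unname(tst$statistic), p_value = tst$p.value)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$called <- !is.na(res$q_value) & res$q_value < alphaQ
  res[order(res$q_value, res$p_value), ]
}
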