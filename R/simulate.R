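#' Generate a synthetic genus abundance table with planted modules
#'
#' Taxa are assigned round-robin to \code{nModules} co-occurrence modules.
#' Each module has one latent per-sample factor (standard normal); a
#' taxon's log mean abundance is \code{baselineLog + coupling * factor} and
#' counts are drawn negative-binomial with the given overdispersion, so
#' taxa sharing a module co-vary while taxa in different modules are
#' independent. \code{coupling = 0} yields a structure-free (null) table.
#'
#' @param nSamples,nTaxa table dimensions; \code{nTaxa >= nModules >= 1}.
#' @param nModules number of planted modules.
#' @param coupling latent-factor loading on the log scale (>= 0);
#'   2 gives strongly recoverable modules, 0 independence.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed); 5 approximates a 16S genus table.
#' @param seed integer RNG seed; identical arguments give identical tables.
#' @param baselineLog baseline log mean count per taxon.
#' @param site,compartment,treatment condition labels stamped on every
#'   sample's metadata.
#' @return list with elements \code{table} (an
#'   \linkS4class{AbundanceTable}) and \code{truth}
#'   (a \linkS4class{CommunityTruth}).
#' @export
generateCommunity <- function(nSamples, nTaxa, nModules, coupling = 2,
                              dispersion = 5, seed = 1,
                              baselineLog = log(50),
                              site = "non_urban",
                              compartment = "rhizosphere",
                              treatment = "untreated") {
  if (nSamples < 1 || nTaxa < 1) stop("dimensions must be positive")
  if (nModules < 1 || nTaxa < nModules)
    stop("need nTaxa >= nModules >= 1")
  if (coupling < 0) stop("coupling must be >= 0")
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  moduleOf <- as.integer(((seq_len(nTaxa) - 1L) %% nModules) + 1L)
  factors <- matrix(stats::rnorm(nSamples * nModules), nSamples, nModules)
  mu <- exp(baselineLog + coupling * factors[, moduleOf, drop = FALSE])
  cnt <- matrix(stats::rnbinom(nSamples * nTaxa, mu = mu,
                               size = dispersion),
                nSamples, nTaxa)
  tax_names <- sprintf("genus%03d", seq_len(nTaxa))
  colnames(cnt) <- tax_names
  ids <- sprintf("S%03d", seq_len(nSamples))
  rownames(cnt) <- ids
  md <- data.frame(sample_id = ids, site = site, compartment = compartment,
                   treatment = treatment,
                   rhizobox_id = sprintf("R%03d", ((seq_len(nSamples) - 1L)
                                                   %/% 3L) + 1L),
                   stringsAsFactors = FALSE)
  phylum <- sprintf("phylum%02d", ((seq_len(nTaxa) - 1L) %% 6L) + 1L)
  truth <- methods::new("CommunityTruth",
                        moduleOf = stats::setNames(moduleOf, tax_names),
                        latentFactors = factors,
                        loadings = rep(coupling, nTaxa),
                        dispersion = dispersion, seed = as.integer(seed))
  list(table = AbundanceTable(cnt, md, phylum = phylum), truth = truth)
}

.with_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate traits linearly coupled to planted community modules
#'
#' Each requested module m contributes one trait
#' \code{effect * latentFactor[, m] + N(0, noiseSd)}; module id 0 requests
#' a pure-noise trait (no coupling). Units are the samples of the
#' community the truth came from.
#'
#' @param truth a \linkS4class{CommunityTruth}.
#' @param linkedModules integer vector of module ids (0 allowed, see above).
#' @param effect linear coupling strength.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @return a \linkS4class{TraitTable} with one trait per requested module,
#'   named \code{trait_M<m>} (noise traits \code{trait_noise<i>}).
#' @export
generateTraits <- function(truth, linkedModules, effect = 2,
                           noiseSd = 0.1, seed = 1) {
  nm <- ncol(truth@latentFactors)
  bad <- setdiff(linkedModules, 0:nm)
  if (length(bad))
    stop("unknown module id(s): ", paste(bad, collapse = ", "))
  restore <- .with_seed(seed)
  on.exit(restore())
  n <- nrow(truth@latentFactors)
  vals <- vapply(linkedModules, function(m) {
    base <- if (m == 0) 0 else effect * truth@latentFactors[, m]
    base + stats::rnorm(n, sd = noiseSd)
  }, numeric(n))
  vals <- matrix(vals, nrow = n)
  noise_i <- cumsum(linkedModules == 0)
  colnames(vals) <- ifelse(linkedModules == 0,
                           paste0("trait_noise", noise_i),
                           paste0("trait_M", linkedModules))
  rownames(vals) <- sprintf("S%03d", seq_len(n))
  TraitTable(vals)
}

#' Generate a synthetic zymogram with known root and hotspot ground truth
#'
#' A branching root footprint is drawn as a seeded random walk from the top
#' of the image; background pixels get Gaussian grey noise
#' (\code{backgroundMean}, \code{backgroundSd}) while root pixels and
#' planted hotspot sites along the root get \code{backgroundMean +
#' hotspotGain} plus the same noise. The true hotspot mask (root pixels
#' plus planted sites) is returned for recovery tests.
#'
#' @param shape integer (rows, cols), each >= 32.
#' @param backgroundMean,backgroundSd background grey statistics.
#' @param hotspotGain grey-value elevation of hotspot pixels; a value
#'   <= 0 warns that the planted truth is undetectable.
#' @param bandWidthPx rhizosphere band width recorded in the truth.
#' @param nBranches number of lateral-root branch points.
#' @param seed integer RNG seed.
#' @param pixelSize cm per pixel recorded on the zymogram.
#' @return list with elements \code{zymogram} (a
#'   \linkS4class{Zymogram}) and \code{truth}
#'   (a \linkS4class{ZymogramTruth}).
#' @export
generateZymogram <- function(shape = c(128L, 128L), backgroundMean = 100,
                             backgroundSd = 10, hotspotGain = 100,
                             bandWidthPx = 3L, nBranches = 3L, seed = 1,
                             pixelSize = 0.01) {
  if (any(shape < 32)) stop("shape must be at least 32 x 32")
  if (hotspotGain <= 0)
    warning("hotspotGain <= 0: planted hotspots are undetectable")
  restore <- .with_seed(seed)
  on.exit(restore())
  nr <- shape[1]; nc <- shape[2]
  root <- matrix(FALSE, nr, nc)
  walk <- function(r, c, len) {
    for (i in seq_len(len)) {
      if (r > nr || c < 1 || c > nc) break
      root[r, c] <<- TRUE
      r <- r + 1L
      c <- c + sample(c(-1L, 0L, 0L, 1L), 1L)
    }
  }
  start_c <- as.integer(round(nc / 2))
  walk(1L, start_c, nr)
  root_cells <- which(root, arr.ind = TRUE)
  for (b in seq_len(nBranches)) {
    org <- root_cells[sample(nrow(root_cells), 1L), ]
    dir <- sample(c(-1L, 1L), 1L)
    r <- org[1]; c <- org[2]
    for (i in seq_len(as.integer(nr / 3))) {
      r <- r + 1L; c <- c + dir * sample(0:1, 1L)
      if (r > nr || c < 1 || c > nc) break
      root[r, c] <- TRUE
    }
  }
  hotspot <- root
  img <- matrix(stats::rnorm(nr * nc, backgroundMean, backgroundSd), nr, nc)
  img[hotspot] <- img[hotspot] + hotspotGain
  truth <- methods::new("ZymogramTruth", rootMask = root,
                        hotspotMask = hotspot,
                        bandWidthPx = as.integer(bandWidthPx),
                        backgroundMean = backgroundMean,
                        backgroundSd = backgroundSd,
                        hotspotGain = hotspotGain, seed = as.integer(seed))
  list(zymogram = Zymogram(img, pixelSize,
                           exposure = list(synthetic = TRUE)),
       truth = truth)
}
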