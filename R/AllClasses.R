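#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.SITE_LEVELS        <- c("non_urban", "peri_urban")
.COMPARTMENT_LEVELS <- c("rhizosphere", "rhizoplane")
.TREATMENT_LEVELS   <- c("untreated", "biochar")

#' AbundanceTable: genus-level counts with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a taxa-by-samples
#' count matrix (assay \code{"counts"}), per-taxon rank annotation
#' (\code{rowData} columns \code{phylum}, \code{genus}) and per-sample
#' metadata (\code{colData} columns \code{sample_id}, \code{site},
#' \code{compartment}, \code{treatment}, \code{rhizobox_id}).
#'
#' Counts must be non-negative and finite, taxon labels and sample ids
#' unique, and the three design factors restricted to their study levels
#' (\code{site}: non_urban/peri_urban; \code{compartment}:
#' rhizosphere/rhizoplane; \code{treatment}: untreated/biochar).
#'
#' @aliases AbundanceTable-class
#' @exportClass AbundanceTable
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cnt) || any(!is.finite(cnt)))
    msg <- c(msg, "counts must be finite and non-missing")
  else if (any(cnt < 0))
    msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon labels must be unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "site", "compartment", "treatment", "rhizobox_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing metadata column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "duplicate sample_id in metadata")
    for (fld in c("site", "compartment", "treatment")) {
      lev <- switch(fld, site = .SITE_LEVELS,
                    compartment = .COMPARTMENT_LEVELS,
                    treatment = .TREATMENT_LEVELS)
      bad <- setdiff(unique(as.character(cd[[fld]])), lev)
      if (anyNA(cd[[fld]]) || length(bad))
        msg <- c(msg, paste0("invalid ", fld, " level(s): ",
                             paste(c(bad, if (anyNA(cd[[fld]])) "NA"),
                                   collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TraitTable: per-rhizobox soil, root and enzyme measurements
#'
#' Units (rhizoboxes or samples) in rows, traits in columns. Missing values
#' are permitted and propagate as pairwise-complete deletion in downstream
#' correlations.
#'
#' @slot values numeric matrix, units x traits; rownames are unit ids.
#' @aliases TraitTable-class
#' @exportClass TraitTable
setClass("TraitTable", representation(values = "matrix"))

setValidity("TraitTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "trait values must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "unit ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "trait names (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Zymogram: a grey-value enzyme-activity membrane image
#'
#' @slot image numeric matrix of grey values (arbitrary integer or real
#'   grey units, kept exactly as read; never rescaled).
#' @slot pixelSize length of one pixel side in cm (must be > 0).
#' @slot exposure free-form acquisition metadata.
#' @aliases Zymogram-class
#' @exportClass Zymogram
setClass("Zymogram", representation(image = "matrix", pixelSize = "numeric",
                                    exposure = "list"),
         prototype(exposure = list()))

setValidity("Zymogram", function(object) {
  msg <- character()
  if (!is.numeric(object@image) || any(!is.finite(object@image)))
    msg <- c(msg, "image grey values must be finite numbers")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CompartmentMasks: rhizoplane / rhizosphere / background partition
#'
#' Three pairwise-disjoint logical masks of identical shape whose union is
#' the analysed region of interest.
#'
#' @slot rhizoplane,rhizosphere,background logical matrices.
#' @aliases CompartmentMasks-class
#' @exportClass CompartmentMasks
setClass("CompartmentMasks",
         representation(rhizoplane = "matrix", rhizosphere = "matrix",
                        background = "matrix"))

setValidity("CompartmentMasks", function(object) {
  m <- list(object@rhizoplane, object@rhizosphere, object@background)
  if (!all(vapply(m, is.logical, TRUE)))
    return("masks must be logical matrices")
  d <- vapply(m, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    return("masks must share one shape")
  if (any(m[[1]] & m[[2]]) || any(m[[1]] & m[[3]]) || any(m[[2]] & m[[3]]))
    return("masks must be pairwise disjoint")
  TRUE
})

#' CalibrationCurve: grey value as a linear function of enzyme activity
#'
#' Ordinary least squares fit grey = slope * activity + intercept over the
#' calibration standards; inverted to convert images to activity in
#' nmol cm-2 h-1.
#'
#' @slot slope,intercept,rSquared numeric scalars.
#' @slot standards data.frame with columns \code{activity}, \code{grey}.
#' @aliases CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", standards = "data.frame"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (nrow(object@standards) < 2)
    msg <- c(msg, "at least 2 calibration standards are required")
  if (length(object@slope) != 1 || !is.finite(object@slope) ||
      object@slope == 0)
    msg <- c(msg, "slope must be a single non-zero number")
  if (length(msg)) msg else TRUE
})

#' HotspotResult: mean + 2 SD hotspot detection summary
#'
#' @slot threshold grey-unit threshold (region mean + 2 standard deviations).
#' @slot mask logical matrix of detected hotspot pixels (within the ROI).
#' @slot percentArea percent of ROI pixels in the hotspot.
#' @slot nHotspot,nBackground pixel counts partitioning the ROI.
#' @aliases HotspotResult-class
#' @exportClass HotspotResult
setClass("HotspotResult",
         representation(threshold = "numeric", mask = "matrix",
                        percentArea = "numeric", nHotspot = "integer",
                        nBackground = "integer"))

setValidity("HotspotResult", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (is.finite(object@percentArea) &&
      (object@percentArea < -100 || object@percentArea > 100))
    msg <- c(msg, "percentArea out of range")
  if (length(msg)) msg else TRUE
})

#' ActivityMap: per-pixel enzyme activity with region summaries
#'
#' @slot activity numeric matrix, nmol cm-2 h-1.
#' @slot nClamped number of pixels whose back-calculated activity was
#'   negative and clamped to zero.
#' @aliases ActivityMap-class
#' @exportClass ActivityMap
setClass("ActivityMap",
         representation(activity = "matrix", nClamped = "integer"))

#' CooccurrenceNetwork: per-condition genus co-occurrence graph
#'
#' Undirected simple graph whose edges are correlations that passed the
#' significance screen (p < edgeAlpha); edge attributes \code{rho},
#' \code{p} and \code{sign}.
#'
#' @slot graph an \pkg{igraph} object.
#' @slot condition named character: site, compartment, treatment.
#' @slot edgeAlpha the p-value threshold used at construction.
#' @slot method correlation method used ("spearman" or "pearson").
#' @aliases CooccurrenceNetwork-class
#' @exportClass CooccurrenceNetwork
setClass("CooccurrenceNetwork",
         representation(graph = "ANY", condition = "character",
                        edgeAlpha = "numeric", method = "character"))

setValidity("CooccurrenceNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g)))
    msg <- c(msg, "duplicate edges are not allowed")
  if (igraph::ecount(g) > 0) {
    p <- igraph::E(g)$p
    if (is.null(p) || any(p >= object@edgeAlpha))
      msg <- c(msg, "every edge must satisfy p < edgeAlpha")
  }
  if (length(msg)) msg else TRUE
})

#' NullComparison: observed topology versus a G(n, m) null ensemble
#'
#' @slot metrics data.frame with one row per metric: observed, nullMean,
#'   nullSd, p (two-sided empirical, add-one convention).
#' @slot nGraphs ensemble size.
#' @slot seed RNG seed used for the ensemble.
#' @slot nonRandom verdict: TRUE when any tested metric has p < nullAlpha.
#' @slot nullAlpha significance level of the verdict.
#' @aliases NullComparison-class
#' @exportClass NullComparison
setClass("NullComparison",
         representation(metrics = "data.frame", nGraphs = "integer",
                        seed = "integer", nonRandom = "logical",
                        nullAlpha = "numeric"))

#' HubShift: hub-genus turnover between untreated and treated networks
#'
#' @slot maintained,lost,gained disjoint sets of genus labels.
#' @slot k the hub-list size the sets were derived from.
#' @aliases HubShift-class
#' @exportClass HubShift
setClass("HubShift",
         representation(maintained = "character", lost = "character",
                        gained = "character", k = "integer"))

setValidity("HubShift", function(object) {
  msg <- character()
  if (length(intersect(object@maintained, object@lost)) ||
      length(intersect(object@maintained, object@gained)) ||
      length(intersect(object@lost, object@gained)))
    msg <- c(msg, "maintained/lost/gained must be disjoint")
  if (length(object@maintained) + length(object@lost) != object@k)
    msg <- c(msg, "|maintained| + |lost| must equal k")
  if (length(object@maintained) + length(object@gained) != object@k)
    msg <- c(msg, "|maintained| + |gained| must equal k")
  if (length(msg)) msg else TRUE
})

#' ModulePartition: community-detection modules of a network
#'
#' Module ids are dense from 1 and ranked: module 1 is the largest (ties
#' broken by summed degree, then label order).
#'
#' @slot membership named integer vector, node -> module id.
#' @slot sizes integer vector of module sizes, indexed by module id.
#' @slot algorithm community-detection algorithm name.
#' @slot seed RNG seed used.
#' @aliases ModulePartition-class
#' @exportClass ModulePartition
setClass("ModulePartition",
         representation(membership = "integer", sizes = "integer",
                        algorithm = "character", seed = "integer"))

setValidity("ModulePartition", function(object) {
  ids <- sort(unique(object@membership))
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("module ids must be dense from 1")
  if (is.null(names(object@membership)))
    return("membership must be named by node")
  TRUE
})

#' AssociationMatrix: module-by-trait Spearman association grid
#'
#' @slot rho,p numeric matrices (modules x traits).
#' @slot significant logical matrix: p < alpha.
#' @slot alpha the significance level applied.
#' @slot mantel data.frame of Mantel confirmations (one row per tested
#'   matrix pair), possibly empty.
#' @aliases AssociationMatrix-class
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
         representation(rho = "matrix", p = "matrix",
                        significant = "matrix", alpha = "numeric",
                        mantel = "data.frame"),
         prototype(mantel = data.frame()))

setValidity("AssociationMatrix", function(object) {
  if (!identical(dim(object@rho), dim(object@p)) ||
      !identical(dim(object@rho), dim(object@significant)))
    return("rho, p and significant must share one shape")
  ok <- object@significant & !is.na(object@p)
  if (any(object@p[ok] >= object@alpha))
    return("significant cells must have p < alpha")
  TRUE
})

#' AssociationShift: new / maintained / missed module-trait associations
#'
#' @slot new,maintained,missed character vectors of "module|trait" keys.
#' @aliases AssociationShift-class
#' @exportClass AssociationShift
setClass("AssociationShift",
         representation(new = "character", maintained = "character",
                        missed = "character"))

setValidity("AssociationShift", function(object) {
  if (length(intersect(object@new, object@maintained)) ||
      length(intersect(object@new, object@missed)) ||
      length(intersect(object@maintained, object@missed)))
    return("new/maintained/missed must be pairwise disjoint")
  TRUE
})

#' CommunityTruth: planted structure behind a synthetic community
#'
#' @slot moduleOf named integer, taxon -> planted module id (0 = unstructured).
#' @slot latentFactors numeric matrix, samples x modules.
#' @slot loadings per-taxon coupling strength.
#' @slot dispersion negative-binomial size parameter.
#' @slot seed generator seed.
#' @aliases CommunityTruth-class
#' @exportClass CommunityTruth
setClass("CommunityTruth",
         representation(moduleOf = "integer", latentFactors = "matrix",
                        loadings = "numeric", dispersion = "numeric",
                        seed = "integer"))

#' ZymogramTruth: planted structure behind a synthetic zymogram
#'
#' @slot rootMask,hotspotMask logical matrices.
#' @slot bandWidthPx rhizosphere band width in pixels.
#' @slot backgroundMean,backgroundSd,hotspotGain grey units.
#' @slot seed generator seed.
#' @aliases ZymogramTruth-class
#' @exportClass ZymogramTruth
setClass("ZymogramTruth",
         representation(rootMask = "matrix", hotspotMask = "matrix",
                        bandWidthPx = "integer", backgroundMean = "numeric",
                        backgroundSd = "numeric", hotspotGain = "numeric",
                        seed = "integer"))
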