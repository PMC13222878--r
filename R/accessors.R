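#' @importFrom BiocGenerics counts
NULL

#' Accessors for rhizoChar classes
#'
#' @param object,x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors taxa-by-samples count matrix of an
#'   \linkS4class{AbundanceTable}.
#' @export
setMethod("counts", "AbundanceTable", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn accessors taxon labels.
#' @export
taxa <- function(x) rownames(x)

#' @describeIn accessors per-sample metadata as a data.frame.
#' @export
sampleData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn accessors trait value matrix (units x traits).
#' @export
traitValues <- function(x) x@values

#' @describeIn accessors grey-value image matrix of a Zymogram.
#' @export
greyValues <- function(x) x@image

#' @describeIn accessors pixel size (cm per pixel) of a Zymogram.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn accessors underlying igraph object of a
#'   \linkS4class{CooccurrenceNetwork}.
#' @export
networkGraph <- function(x) x@graph

#' @describeIn accessors condition labels (site, compartment, treatment).
#' @export
condition <- function(x) x@condition

#' @describeIn accessors node -> module id vector of a
#'   \linkS4class{ModulePartition}.
#' @export
moduleMembership <- function(x) x@membership

#' @describeIn accessors per-pixel activity matrix of an
#'   \linkS4class{ActivityMap}.
#' @export
activityValues <- function(x) x@activity

#' @describeIn accessors hotspot mask of a \linkS4class{HotspotResult}.
#' @export
hotspotMask <- function(x) x@mask

#' @describeIn accessors percent hotspot area of a
#'   \linkS4class{HotspotResult}.
#' @export
percentArea <- function(x) x@percentArea

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object), "taxa x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  conditions:",
      paste(sort(unique(paste(cd$site, cd$compartment, cd$treatment,
                              sep = "/"))), collapse = ", "), "\n")
})

setMethod("show", "TraitTable", function(object) {
  cat("TraitTable:", nrow(object@values), "units x",
      ncol(object@values), "traits\n")
})

setMethod("show", "Zymogram", function(object) {
  cat(sprintf("Zymogram: %d x %d px, pixel size %g cm, grey range [%g, %g]\n",
              nrow(object@image), ncol(object@image), object@pixelSize,
              min(object@image), max(object@image)))
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("CooccurrenceNetwork (%s): %d nodes, %d edges (p < %g, %s)\n",
              paste(object@condition, collapse = "/"),
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@edgeAlpha, object@method))
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition (%s): %d nodes in %d modules; sizes: %s\n",
              object@algorithm, length(object@membership),
              length(object@sizes),
              paste(object@sizes, collapse = ", ")))
})

setMethod("show", "HotspotResult", function(object) {
  cat(sprintf(
    "HotspotResult: threshold %.4g, %d hotspot / %d background px (%.2f%%)\n",
    object@threshold, object@nHotspot, object@nBackground,
    object@percentArea))
})

setMethod("show", "HubShift", function(object) {
  cat(sprintf("HubShift (k = %d): %d maintained, %d lost, %d gained\n",
              object@k, length(object@maintained), length(object@lost),
              length(object@gained)))
})

setMethod("show", "NullComparison", function(object) {
  cat(sprintf("NullComparison: %d G(n,m) graphs, verdict %s (alpha %g)\n",
              object@nGraphs,
              if (object@nonRandom) "non-random" else "random-like",
              object@nullAlpha))
  print(object@metrics, digits = 4)
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d modules x %d traits, %d significant at p < %g\n",
              nrow(object@rho), ncol(object@rho),
              sum(object@significant, na.rm = TRUE), object@alpha))
})

setMethod("show", "AssociationShift", function(object) {
  cat(sprintf("AssociationShift: %d new, %d maintained, %d missed\n",
              length(object@new), length(object@maintained),
              length(object@missed)))
})
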