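#' Construct an AbundanceTable
#'
#' @param counts numeric matrix of counts, samples in rows and taxa in
#'   columns (the canonical file orientation); stored internally as
#'   taxa-by-samples.
#' @param metadata data.frame with one row per sample and columns
#'   \code{sample_id}, \code{site}, \code{compartment}, \code{treatment},
#'   \code{rhizobox_id}.
#' @param phylum optional character vector of per-taxon phylum labels;
#'   missing annotations become \code{"unclassified"}.
#' @return a validated \linkS4class{AbundanceTable}.
#' @export
AbundanceTable <- function(counts, metadata, phylum = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% colnames(metadata))
    stop("metadata must contain a sample_id column")
  metadata$sample_id <- as.character(metadata$sample_id)
  if (is.null(rownames(counts)))
    rownames(counts) <- metadata$sample_id[seq_len(nrow(counts))]
  missing_md <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_md))
    stop("sample(s) missing from metadata: ",
         paste(missing_md, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  if (is.null(phylum)) phylum <- rep(NA_character_, ncol(counts))
  phylum[is.na(phylum)] <- "unclassified"
  rd <- S4Vectors::DataFrame(genus = colnames(counts), phylum = phylum,
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    rowData = rd,
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id))
  methods::validObject(at <- methods::new("AbundanceTable", se))
  at
}

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L, encoding = "UTF-8")
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

.read_table <- function(path) {
  utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                    row.names = 1L, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    comment.char = "")
}

#' Read an abundance table and its sample metadata
#'
#' @param path TSV/CSV of counts, samples in rows and taxa in columns by
#'   default (first column = sample ids).
#' @param metadataPath TSV/CSV of sample metadata keyed by \code{sample_id}.
#' @param taxaAsRows set TRUE when the counts file has taxa in rows.
#' @param phylumColumn optional name of a metadata-free taxon annotation:
#'   when the counts file carries taxa labels of the form
#'   \code{"Phylum|Genus"} the phylum is split off automatically.
#' @return a validated \linkS4class{AbundanceTable}.
#' @export
readAbundanceTable <- function(path, metadataPath, taxaAsRows = FALSE,
                               phylumColumn = NULL) {
  tab <- as.matrix(.read_table(path))
  if (taxaAsRows) tab <- t(tab)
  storage.mode(tab) <- "numeric"
  md <- utils::read.table(metadataPath, sep = .detect_sep(metadataPath),
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", "))
  phylum <- NULL
  if (any(grepl("|", colnames(tab), fixed = TRUE))) {
    parts <- strsplit(colnames(tab), "|", fixed = TRUE)
    phylum <- vapply(parts, `[`, "", 1L)
    colnames(tab) <- vapply(parts, function(p) p[length(p)], "")
  }
  AbundanceTable(tab, md, phylum = phylum)
}

#' Write an abundance table (and optionally its metadata) to TSV
#'
#' Samples are written as rows, the canonical orientation.
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param path output counts TSV.
#' @param metadataPath optional output metadata TSV.
#' @export
writeAbundanceTable <- function(at, path, metadataPath = NULL) {
  tab <- t(counts(at))
  df <- data.frame(sample_id = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(metadataPath))
    utils::write.table(sampleData(at), metadataPath, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a TraitTable
#'
#' @param values numeric matrix (units x traits) with unit ids as rownames.
#' @return a validated \linkS4class{TraitTable}.
#' @export
TraitTable <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "numeric"
  methods::validObject(tt <- methods::new("TraitTable", values = values))
  tt
}

#' Read a trait table (soil chemistry, root traits, enzyme activities)
#'
#' @param path TSV/CSV with unit ids in the first column, traits in columns.
#' @return a validated \linkS4class{TraitTable}.
#' @export
readTraitTable <- function(path) TraitTable(as.matrix(.read_table(path)))

#' Write a trait table to TSV
#' @param tt a \linkS4class{TraitTable}.
#' @param path output TSV.
#' @export
writeTraitTable <- function(tt, path) {
  df <- data.frame(unit_id = rownames(tt@values), tt@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset an AbundanceTable to one experimental condition
#'
#' @param at an \linkS4class{AbundanceTable}.
#' @param site,compartment,treatment optional condition levels; omitted
#'   factors are not filtered on.
#' @param dropEmptyTaxa drop taxa with zero total count in the subset.
#' @return an \linkS4class{AbundanceTable}.
#' @export
subsetCondition <- function(at, site = NULL, compartment = NULL,
                            treatment = NULL, dropEmptyTaxa = FALSE) {
  cd <- SummarizedExperiment::colData(at)
  keep <- rep(TRUE, ncol(at))
  if (!is.null(site)) keep <- keep & cd$site == site
  if (!is.null(compartment)) keep <- keep & cd$compartment == compartment
  if (!is.null(treatment)) keep <- keep & cd$treatment == treatment
  out <- at[, keep]
  if (dropEmptyTaxa) out <- out[rowSums(counts(out)) > 0, ]
  out
}

#' Construct a Zymogram
#'
#' @param image numeric matrix of grey values.
#' @param pixelSize cm per pixel, > 0.
#' @param exposure free-form acquisition metadata list.
#' @return a validated \linkS4class{Zymogram}.
#' @export
Zymogram <- function(image, pixelSize, exposure = list()) {
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  methods::validObject(z <- methods::new("Zymogram", image = image,
                                         pixelSize = pixelSize,
                                         exposure = exposure))
  z
}

.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

#' Read a greyscale zymogram image
#'
#' Grey values are loaded as-is: 8-bit images give values in 0..255,
#' 16-bit in 0..65535, with no rescaling. RGB input is converted to grey
#' with the Rec. 709 luminance rule 0.2126 R + 0.7152 G + 0.0722 B.
#'
#' @param path a PNG or TIFF file (8- or 16-bit).
#' @param pixelSize cm per pixel, > 0.
#' @return a \linkS4class{Zymogram}.
#' @export
readZymogram <- function(path, pixelSize) {
  if (length(pixelSize) != 1 || !is.finite(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be a single positive number")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    scale <- 2^.png_bit_depth(path) - 1
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    scale <- 1
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    img <- if (ch >= 3L)
      0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img[, , 1L]
  }
  Zymogram(img * scale, pixelSize, exposure = list(source = path))
}

#' Write a zymogram image
#'
#' @param z a \linkS4class{Zymogram}; grey values must lie in the range of
#'   the requested bit depth.
#' @param path output PNG or TIFF path.
#' @param bits 8 or 16.
#' @export
writeZymogram <- function(z, path, bits = 16L) {
  scale <- 2^bits - 1
  img <- pmin(pmax(round(z@image), 0), scale) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Write a co-occurrence network to disk
#'
#' \code{edge_list} writes a TSV with a \code{# nodes:} header line (so
#' isolated nodes survive the round trip) and columns from, to, rho, p,
#' sign; \code{graphml} delegates to \pkg{igraph}. Both formats round-trip
#' losslessly through \code{\link{readNetwork}}.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param path output file.
#' @param format "edge_list" or "graphml".
#' @export
writeNetwork <- function(net, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  g <- net@graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# nodes: ", paste(igraph::V(g)$name, collapse = ";")),
    paste0("# condition: ", paste(net@condition, collapse = ";")),
    paste0("# edge_alpha: ", format(net@edgeAlpha, digits = 17)),
    paste0("# method: ", net@method),
    "from\tto\trho\tp\tsign"), con)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_data_frame(g, what = "edges")
    writeLines(paste(el$from, el$to,
                     format(el$rho, digits = 17),
                     format(el$p, digits = 17),
                     el$sign, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network written by \code{\link{writeNetwork}}
#'
#' @param path the file to read.
#' @param format "edge_list" or "graphml".
#' @return a \linkS4class{CooccurrenceNetwork}.
#' @export
readNetwork <- function(path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(methods::new("CooccurrenceNetwork", graph = g,
                        condition = c(site = NA_character_,
                                      compartment = NA_character_,
                                      treatment = NA_character_),
                        edgeAlpha = if (!is.null(g$edge_alpha)) g$edge_alpha
                        else 1, method = if (!is.null(g$method)) g$method
                        else "unknown"))
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  field <- function(key) sub(paste0("# ", key, ": "), "",
                             hdr[startsWith(hdr, paste0("# ", key, ":"))])
  nodes <- strsplit(field("nodes"), ";", fixed = TRUE)[[1]]
  cond <- strsplit(field("condition"), ";", fixed = TRUE)[[1]]
  alpha <- as.numeric(field("edge_alpha"))
  body <- lines[!startsWith(lines, "#")]
  el <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  methods::new("CooccurrenceNetwork", graph = g,
               condition = stats::setNames(
                 cond, c("site", "compartment", "treatment")[seq_along(cond)]),
               edgeAlpha = alpha, method = field("method"))
}
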