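#' File-backed measurement description
#'
#' @slot id,name identifier and display name.
#' @slot uri file location (local path or URL).
#' @slot indexUri Tabix index location (tabix format only).
#' @slot format "bigwig", "bigbed" or "tabix".
#' @slot annotations arbitrary key-value metadata (tissue, assay, ...).
#' @slot columns declared names for rest-of-line / value columns.
#' @slot genome genome tag (e.g. "hg19"); informational.
#' @export
setClass("FileMeasurement",
  representation(id = "character", name = "character", uri = "character",
                 indexUri = "character", format = "character",
                 annotations = "list", columns = "character",
                 genome = "character"),
  validity = function(object) {
    if (!object@format %in% c("bigwig", "bigbed", "tabix"))
      return(paste0("unknown format: ", object@format))
    TRUE
  })

#' @describeIn FileMeasurement-class constructor.
#' @param id,name,uri,indexUri,format,annotations,columns,genome see slots.
#' @export
fileMeasurement <- function(id, uri, format, name = id,
                            indexUri = paste0(uri, ".tbi"),
                            annotations = list(), columns = character(),
                            genome = NA_character_) {
  new("FileMeasurement", id = id, name = name, uri = uri,
      indexUri = indexUri, format = format, annotations = annotations,
      columns = as.character(columns), genome = genome)
}

#' Genome annotation measurement
#'
#' A Tabix-indexed gene table supporting both range queries and gene-name
#' lookups (for navigational queries like "go to GENE1"). The gene-name
#' column must be declared in \code{columns}; the name-to-range map is built
#' by a linear scan on first use and cached (Tabix indexes position, not
#' names).
#'
#' @slot id identifier.
#' @slot uri,indexUri BGZF table and .tbi index locations.
#' @slot columns names of the non-coordinate columns.
#' @slot geneColumn which of \code{columns} holds the gene name.
#' @export
setClass("GenomeAnnotation",
  representation(id = "character", uri = "character", indexUri = "character",
                 columns = "character", geneColumn = "character"))

#' @describeIn GenomeAnnotation-class constructor.
#' @param id,uri,indexUri,columns,geneColumn see slots.
#' @export
genomeAnnotation <- function(id, uri, indexUri = paste0(uri, ".tbi"),
                             columns = c("gene", "strand"),
                             geneColumn = "gene") {
  if (!geneColumn %in% columns)
    configError("geneColumn must be among the declared columns")
  new("GenomeAnnotation", id = id, uri = uri, indexUri = indexUri,
      columns = columns, geneColumn = geneColumn)
}

#' Catalog of queryable measurements
#'
#' Holds file-backed tracks, genome annotations and computed measurements
#' under unique ids, in insertion order. Files are opened lazily: loading a
#' configuration performs zero backend reads; the first query against a
#' measurement opens and parses its file, after which the parsed handle and
#' its pinned metadata live in the catalog's shared block cache.
#'
#' @slot entries named list of [FileMeasurement-class],
#'   [ComputeSpec-class] or [GenomeAnnotation-class] objects.
#' @slot runtime environment holding the shared [BlockCache-class] and
#'   lazily opened file handles.
#' @export
setClass("MeasurementCatalog",
  representation(entries = "list", runtime = "environment"))

#' Create an empty measurement catalog
#'
#' @param cacheBytes capacity of the shared block cache.
#' @return a [MeasurementCatalog-class].
#' @export
measurementCatalog <- function(cacheBytes = 256 * 1024^2) {
  rt <- new.env(parent = emptyenv())
  rt$cache <- blockCache(cacheBytes)
  rt$open <- new.env(parent = emptyenv())   # id -> opened BBIFile/TabixTrack
  rt$genes <- new.env(parent = emptyenv())  # annotation id -> name->range map
  new("MeasurementCatalog", entries = list(), runtime = rt)
}

#' @describeIn measurementCatalog ids in insertion order.
#' @param catalog a [MeasurementCatalog-class].
#' @export
measurementIds <- function(catalog) names(catalog@entries)

#' @describeIn measurementCatalog fetch one entry by id.
#' @param id measurement id.
#' @export
getMeasurement <- function(catalog, id) {
  if (!id %in% names(catalog@entries)) unknownMeasurementError(id)
  catalog@entries[[id]]
}

#' @export
setMethod("length", "MeasurementCatalog", function(x) length(x@entries))

#' @export
setMethod("show", "MeasurementCatalog", function(object) {
  cat(sprintf("MeasurementCatalog with %d measurement(s)\n",
              length(object@entries)))
  for (id in names(object@entries)) {
    e <- object@entries[[id]]
    kind <- if (is(e, "ComputeSpec")) "computed"
            else if (is(e, "GenomeAnnotation")) "genome"
            else e@format
    cat(sprintf("  %s [%s]\n", id, kind))
  }
})

#' Register a measurement in a catalog
#'
#' @param catalog a [MeasurementCatalog-class].
#' @param m a [FileMeasurement-class], [GenomeAnnotation-class] or
#'   [ComputeSpec-class].
#' @return the updated catalog (entries are value-semantic; the runtime
#'   cache environment is shared).
#' @export
addMeasurement <- function(catalog, m) {
  if (m@id %in% names(catalog@entries)) duplicateIdError(m@id)
  catalog@entries[[m@id]] <- m
  catalog
}

#' Register a computed measurement
#'
#' All source ids must already be registered (file-backed or themselves
#' computed — evaluation recurses).
#'
#' @param catalog a [MeasurementCatalog-class].
#' @param spec a [ComputeSpec-class].
#' @return the updated catalog.
#' @export
addComputedMeasurement <- function(catalog, spec) {
  for (s in spec@sources)
    if (!s %in% names(catalog@entries)) unknownMeasurementError(s)
  addMeasurement(catalog, spec)
}

#' Register a genome annotation
#'
#' @param catalog a [MeasurementCatalog-class].
#' @param id annotation id (e.g. "hg19").
#' @param uri Tabix-indexed gene table.
#' @param ... passed to [genomeAnnotation()].
#' @return the updated catalog.
#' @export
addGenome <- function(catalog, id, uri, ...) {
  addMeasurement(catalog, genomeAnnotation(id, uri, ...))
}

#' Look up a gene's range in a genome annotation
#'
#' @param catalog a [MeasurementCatalog-class].
#' @param genomeId id of a registered [GenomeAnnotation-class].
#' @param gene gene name.
#' @return a [GenomicQuery-class] covering the gene.
#' @export
geneLookup <- function(catalog, genomeId, gene) {
  g <- getMeasurement(catalog, genomeId)
  if (!is(g, "GenomeAnnotation"))
    configError(paste0(genomeId, " is not a genome annotation"))
  rt <- catalog@runtime
  if (!exists(genomeId, envir = rt$genes, inherits = FALSE)) {
    track <- openEntry(catalog, g)
    map <- new.env(parent = emptyenv())
    for (ch in track@index$names) {
      f <- queryTabix(track, ch, 0, 2^29)
      nm <- as.character(frameValues(f)[[g@geneColumn]])
      for (i in seq_along(nm))
        assign(nm[i], c(frameStart(f)[i], frameEnd(f)[i], match(ch, track@index$names)),
               envir = map)
    }
    assign(genomeId, list(map = map, chroms = track@index$names),
           envir = rt$genes)
  }
  gm <- get(genomeId, envir = rt$genes, inherits = FALSE)
  if (!exists(gene, envir = gm$map, inherits = FALSE)) unknownGeneError(gene)
  v <- get(gene, envir = gm$map, inherits = FALSE)
  genomicQuery(gm$chroms[v[3]], v[1], v[2])
}

## lazily open (and memoize) the file behind an entry
openEntry <- function(catalog, e) {
  rt <- catalog@runtime
  if (exists(e@id, envir = rt$open, inherits = FALSE))
    return(get(e@id, envir = rt$open, inherits = FALSE))
  obj <- if (is(e, "GenomeAnnotation")) {
    openTabix(e@uri, e@indexUri, cache = rt$cache, columns = e@columns)
  } else if (e@format == "tabix") {
    openTabix(e@uri, e@indexUri, cache = rt$cache, columns = e@columns)
  } else {
    f <- openBBI(e@uri, cache = rt$cache, columns = e@columns)
    if (f@header$kind != e@format)
      configError(sprintf("'%s': file magic says %s but config says %s",
                          e@id, f@header$kind, e@format))
    f
  }
  assign(e@id, obj, envir = rt$open)
  obj
}

## ---- JSON configuration ----

#' Load a measurement catalog from JSON configuration
#'
#' The configuration is a JSON array of objects with keys \code{id},
#' \code{name}, \code{url}, \code{file_type} ("bigwig"/"bigbed"/"tabix"),
#' and optionally \code{index_url}, \code{annotation} (object),
#' \code{columns} (array), \code{genome} (string). Unknown keys are ignored
#' with a warning. No file is opened or probed at load time.
#'
#' @param config path to a JSON file, or a JSON string.
#' @param cacheBytes shared block-cache capacity.
#' @return a [MeasurementCatalog-class].
#' @export
loadConfig <- function(config, cacheBytes = 256 * 1024^2) {
  txt <- if (file.exists(config)) paste(readLines(config, warn = FALSE),
                                        collapse = "\n") else config
  entries <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                      error = function(e) configError(conditionMessage(e)))
  if (!is.list(entries)) configError("top level must be an array of objects")
  catalog <- measurementCatalog(cacheBytes)
  known <- c("id", "name", "url", "index_url", "file_type", "annotation",
             "columns", "genome")
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    label <- if (!is.null(e$id)) e$id else paste0("entry ", i)
    for (k in c("id", "url", "file_type"))
      if (is.null(e[[k]]))
        configError(sprintf("%s: missing required key '%s'", label, k))
    if (!e$file_type %in% c("bigwig", "bigbed", "tabix"))
      configError(sprintf("%s: unknown format '%s'", label, e$file_type))
    extra <- setdiff(names(e), known)
    if (length(extra))
      warning(sprintf("config %s: ignoring unknown key(s) %s", label,
                      paste(extra, collapse = ", ")), call. = FALSE)
    m <- fileMeasurement(
      id = e$id, uri = e$url, format = e$file_type,
      name = if (is.null(e$name)) e$id else e$name,
      indexUri = if (is.null(e$index_url)) paste0(e$url, ".tbi") else e$index_url,
      annotations = if (is.null(e$annotation)) list() else e$annotation,
      columns = unlist(e$columns),
      genome = if (is.null(e$genome)) NA_character_ else e$genome)
    catalog <- addMeasurement(catalog, m)
  }
  catalog
}

#' Serialize a catalog's file measurements back to JSON configuration
#'
#' @param catalog a [MeasurementCatalog-class].
#' @return JSON string; \code{loadConfig(serializeConfig(x))} reproduces an
#'   equivalent catalog.
#' @export
serializeConfig <- function(catalog) {
  entries <- lapply(catalog@entries, function(e) {
    if (!is(e, "FileMeasurement")) return(NULL)
    out <- list(id = e@id, name = e@name, url = e@uri,
                index_url = e@indexUri, file_type = e@format)
    if (length(e@annotations)) out$annotation <- e@annotations
    if (length(e@columns)) out$columns <- as.list(e@columns)
    if (!is.na(e@genome)) out$genome <- e@genome
    out
  })
  entries <- entries[!vapply(entries, is.null, logical(1))]
  jsonlite::toJSON(unname(entries), auto_unbox = TRUE, pretty = TRUE)
}

#' Import file measurements from a tab-delimited manifest
#'
#' The manifest must have a header row with columns \code{id}, \code{uri},
#' \code{format}; any further columns are folded into each measurement's
#' annotation map.
#'
#' @param path manifest file.
#' @return list of [FileMeasurement-class].
#' @export
importManifest <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE,
                                   check.names = FALSE),
                 error = function(e) configError(conditionMessage(e)))
  need <- c("id", "uri", "format")
  if (!all(need %in% names(df)))
    configError(paste0("manifest must have columns ",
                       paste(need, collapse = ", ")))
  extra <- setdiff(names(df), c(need, "name"))
  lapply(seq_len(nrow(df)), function(i) {
    if (!df$format[i] %in% c("bigwig", "bigbed", "tabix"))
      configError(sprintf("row %d: unsupported format '%s'", i, df$format[i]))
    ann <- as.list(df[i, extra, drop = FALSE])
    fileMeasurement(id = df$id[i], uri = df$uri[i], format = df$format[i],
                    name = if ("name" %in% names(df)) df$name[i] else df$id[i],
                    annotations = ann)
  })
}
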