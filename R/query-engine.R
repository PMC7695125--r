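## Resolution-aware query orchestration: route (measurement, range, bins)
## through zoom-level selection, raw query, binning and transformation.

#' Result of a catalog query
#'
#' @slot measurement_id queried measurement.
#' @slot query the [GenomicQuery-class].
#' @slot frame the resulting [IntervalFrame-class].
#' @slot resolution "raw", "zoom:<reduction>" or "binned:<n>" — what was
#'   actually used.
#' @slot timing wall milliseconds spent (informational).
#' @export
setClass("QueryResult",
  representation(measurement_id = "character", query = "GenomicQuery",
                 frame = "IntervalFrame", resolution = "character",
                 timing = "numeric"))

#' @export
setMethod("show", "QueryResult", function(object) {
  cat(sprintf("QueryResult '%s' %s:%.0f-%.0f (%s, %.1f ms)\n",
              object@measurement_id, object@query@chrom,
              object@query@start, object@query@end, object@resolution,
              object@timing))
  show(object@frame)
})

#' @describeIn getData the result's [IntervalFrame-class].
#' @param result a [QueryResult-class].
#' @export
resultFrame <- function(result) result@frame

#' Choose the zoom level for a requested screen resolution
#'
#' The target resolution is \code{floor(rangeWidth / nBins)} bp per bin
#' (e.g. a 10,000 bp region drawn into 800 screen bins targets 12 bp/bin);
#' the zoom level chosen is the one with the largest reduction level not
#' exceeding that target, so each screen bin is backed by at least one zoom
#' record. Returns \code{NULL} — full resolution, binned afterwards — when
#' no zoom level is coarse enough... i.e. when even the finest zoom exceeds
#' the target, or the file has no zoom levels.
#'
#' @param zooms data.frame from [bbiZoomLevels()].
#' @param rangeWidth query width in bp.
#' @param nBins requested number of bins.
#' @return 1-based zoom index, or \code{NULL}.
#' @export
selectZoomLevel <- function(zooms, rangeWidth, nBins) {
  stopifnot(nBins >= 1)
  desired <- floor(rangeWidth / nBins)
  if (!nrow(zooms)) return(NULL)
  ok <- which(zooms$reduction_level <= desired)
  if (!length(ok)) return(NULL)
  ok[which.max(zooms$reduction_level[ok])]
}

#' Summarize an interval frame into screen bins
#'
#' The query range is split into \code{nBins} near-equal half-open bins
#' (when the width is not divisible, the first bins carry one extra bp).
#' Each bin's value is the coverage-weighted mean of the overlapping
#' records — every base covered by a record contributes that record's value
#' equally, so the bin value equals the mean over the covered bases. Bins no
#' record touches are \code{NA}. The output always has exactly \code{nBins}
#' rows partitioning the query range.
#'
#' @param frame an [IntervalFrame-class]; the first numeric column is
#'   summarized (records of tracks without one, e.g. plain BED regions,
#'   count 1 per covered base, giving per-bin occupancy).
#' @param query a [GenomicQuery-class].
#' @param nBins number of bins (>= 1).
#' @return an [IntervalFrame-class] with \code{nBins} rows and a
#'   \code{value} column.
#' @export
binIntervals <- function(frame, query, nBins) {
  stopifnot(nBins >= 1)
  width <- query@end - query@start
  base <- floor(width / nBins)
  rem <- width - base * nBins
  widths <- rep(base, nBins) + c(rep(1, rem), rep(0, nBins - rem))
  ends <- query@start + cumsum(widths)
  starts <- c(query@start, ends[-nBins])
  val <- numericColumn(frame)
  keep <- frameChrom(frame) == query@chrom & frameStart(frame) < query@end &
    frameEnd(frame) > query@start & !is.na(val)
  s <- pmax(frameStart(frame)[keep], query@start)
  e <- pmin(frameEnd(frame)[keep], query@end)
  v <- val[keep]
  acc_w <- rep(0, nBins)
  acc_v <- rep(0, nBins)
  if (length(s)) {
    bins_ir <- IRanges::IRanges(start = starts + 1, end = ends)
    rec_ir <- IRanges::IRanges(start = s + 1, end = e)
    hits <- IRanges::findOverlaps(bins_ir, rec_ir)
    bi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
    w <- pmin(ends[bi], e[ri]) - pmax(starts[bi], s[ri])
    acc_w <- as.numeric(tapply(w, factor(bi, levels = seq_len(nBins)), sum,
                               default = 0))
    acc_v <- as.numeric(tapply(w * v[ri], factor(bi, levels = seq_len(nBins)),
                               sum, default = 0))
  }
  value <- ifelse(acc_w > 0, acc_v / acc_w, NA_real_)
  intervalFrame(rep(query@chrom, nBins), starts, ends,
                S4Vectors::DataFrame(value = value))
}

## the column a summarizer works on: first numeric value column, else
## constant 1 per record (occupancy)
numericColumn <- function(frame) {
  v <- frameValues(frame)
  for (j in seq_len(ncol(v)))
    if (is.numeric(v[[j]])) return(as.numeric(v[[j]]))
  rep(1, length(frame))
}

## raw (full-resolution, unclipped) records for any measurement kind
queryRawMeasurement <- function(catalog, id, query) {
  e <- getMeasurement(catalog, id)
  if (is(e, "ComputeSpec")) return(evaluateComputed(e, catalog, query))
  obj <- openEntry(catalog, e)
  if (is(obj, "TabixTrack"))
    queryTabix(obj, query@chrom, query@start, query@end)
  else
    queryBBI(obj, query@chrom, query@start, query@end)
}

#' Evaluate a computed measurement over a query range
#'
#' Queries every source (recursing through computed sources), aligns them on
#' the disjoint partition of their record boundaries ([disjoinFrames()]) and
#' applies the spec's function ([applyCompute()]). The result is identical
#' to applying the function to an eagerly materialized aligned table; source
#' completion order cannot affect it. Errors raised while querying a source
#' are annotated with the failing source id.
#'
#' @param spec a [ComputeSpec-class].
#' @param catalog the [MeasurementCatalog-class] resolving the sources.
#' @param query a [GenomicQuery-class].
#' @param bins optional bin count; when given the computed track is
#'   summarized with [binIntervals()] after evaluation.
#' @return an [IntervalFrame-class].
#' @export
evaluateComputed <- function(spec, catalog, query, bins = NULL) {
  frames <- lapply(spec@sources, function(sid) {
    tryCatch(queryRawMeasurement(catalog, sid, query),
             trackserve_error = function(e) {
               if (inherits(e, "trackserve_unknown_measurement")) stop(e)
               tsError("source_failed",
                       sprintf("source '%s' of '%s': %s", sid, spec@id,
                               conditionMessage(e)))
             })
  })
  names(frames) <- spec@sources
  aligned <- disjoinFrames(frames, query)
  out <- applyCompute(aligned, spec)
  if (!is.null(bins)) out <- binIntervals(out, query, bins)
  out
}

#' Query a measurement, optionally summarized to screen bins
#'
#' Without \code{bins}, all raw records overlapping the range are returned
#' with their original (unclipped) coordinates. With \code{bins}, BigWig
#' measurements first try a zoom level matching the implied bp-per-bin
#' resolution ([selectZoomLevel()]); the zoom (or raw) records are then
#' summarized into exactly \code{bins} coverage-weighted mean bins clipped
#' to the range. Computed measurements are evaluated at full resolution and
#' then binned.
#'
#' @param catalog a [MeasurementCatalog-class].
#' @param id measurement id.
#' @param query a [GenomicQuery-class] (or use \code{chrom}, \code{start},
#'   \code{end}).
#' @param bins number of screen bins, or \code{NULL} for raw records.
#' @param chrom,start,end alternative to \code{query}.
#' @return a [QueryResult-class].
#' @examples
#' \dontrun{
#' res <- getData(catalog, "signal1", chrom = "chr1", start = 0, end = 10000,
#'                bins = 800)
#' resultFrame(res)
#' }
#' @export
getData <- function(catalog, id, query = NULL, bins = NULL,
                    chrom = NULL, start = NULL, end = NULL) {
  if (is.null(query)) query <- genomicQuery(chrom, start, end)
  t0 <- proc.time()[["elapsed"]]
  e <- getMeasurement(catalog, id)
  resolution <- "raw"
  if (is(e, "ComputeSpec")) {
    frame <- evaluateComputed(e, catalog, query, bins = bins)
    if (!is.null(bins)) resolution <- paste0("binned:", bins)
  } else {
    obj <- openEntry(catalog, e)
    if (is.null(bins)) {
      frame <- if (is(obj, "TabixTrack"))
        queryTabix(obj, query@chrom, query@start, query@end)
      else queryBBI(obj, query@chrom, query@start, query@end)
    } else {
      zi <- NULL
      if (is(obj, "BBIFile") && obj@header$kind == "bigwig")
        zi <- selectZoomLevel(bbiZoomLevels(obj), query@end - query@start,
                              bins)
      raw <- if (is(obj, "TabixTrack"))
        queryTabix(obj, query@chrom, query@start, query@end)
      else queryBBI(obj, query@chrom, query@start, query@end, zoomIndex = zi)
      frame <- binIntervals(raw, query, bins)
      resolution <- if (!is.null(zi))
        sprintf("zoom:%d+binned:%d", as.integer(bbiZoomLevels(obj)$reduction_level[zi]), bins)
      else paste0("binned:", bins)
    }
  }
  new("QueryResult", measurement_id = id, query = query, frame = frame,
      resolution = resolution,
      timing = (proc.time()[["elapsed"]] - t0) * 1000)
}
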