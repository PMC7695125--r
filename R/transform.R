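## Computed measurements: align interval frames from several tracks onto a
## common disjoint partition, then apply a user-supplied function either
## across measurements (row-wise) or along rows (column-wise). Nothing is
## precomputed — evaluation happens per query, and the result is identical
## to eagerly materializing the aligned table first (tested property).

#' Genomic query range
#'
#' The universal query key: chromosome plus a 0-based half-open coordinate
#' pair.
#'
#' @slot chrom chromosome name.
#' @slot start,end 0-based half-open bounds (\code{0 <= start < end}).
#' @export
setClass("GenomicQuery",
  representation(chrom = "character", start = "numeric", end = "numeric"),
  validity = function(object) {
    if (object@start < 0) return("start must be >= 0")
    if (object@start >= object@end) return("start must be < end")
    TRUE
  })

#' @describeIn GenomicQuery-class constructor.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @export
genomicQuery <- function(chrom, start, end) {
  new("GenomicQuery", chrom = as.character(chrom), start = as.double(start),
      end = as.double(end))
}

#' @export
setMethod("show", "GenomicQuery", function(object) {
  cat(sprintf("GenomicQuery: %s:%.0f-%.0f\n", object@chrom, object@start,
              object@end))
})

#' Specification of a computed measurement
#'
#' A named, lazy transformation over an ordered list of source measurements.
#' With \code{axis = "across_measurements"} the function receives, per
#' aligned row, the vector of source values (one per source, in
#' \code{sources} order) and returns one value (or a fixed small number of
#' values). With \code{axis = "along_rows"} it receives each source column
#' in full and must return a vector of the same length (e.g. mean-centering
#' a signal). Missing values — rows where a source has no covering record —
#' are handled per \code{missing}: \code{"propagate"} hands \code{NA} to the
#' function, \code{"drop_row"} removes incomplete rows first,
#' \code{"fill_zero"} substitutes 0.
#'
#' @slot id,name identifier and display name.
#' @slot sources ordered character vector of source measurement ids.
#' @slot func the transformation.
#' @slot axis \code{"across_measurements"} or \code{"along_rows"}.
#' @slot missing missing-value policy.
#' @export
setClass("ComputeSpec",
  representation(id = "character", name = "character", sources = "character",
                 func = "function", axis = "character",
                 missing = "character"),
  validity = function(object) {
    if (!length(object@sources)) return("at least one source is required")
    if (!object@axis %in% c("across_measurements", "along_rows"))
      return("axis must be across_measurements or along_rows")
    if (!object@missing %in% c("propagate", "drop_row", "fill_zero"))
      return("missing must be propagate, drop_row or fill_zero")
    TRUE
  })

#' @describeIn ComputeSpec-class constructor.
#' @param id,name identifier and display name.
#' @param sources ordered source measurement ids.
#' @param func transformation function.
#' @param axis evaluation axis.
#' @param missing missing-value policy.
#' @export
computeSpec <- function(id, sources, func,
                        axis = c("across_measurements", "along_rows"),
                        name = id,
                        missing = c("propagate", "drop_row", "fill_zero")) {
  new("ComputeSpec", id = id, name = name, sources = as.character(sources),
      func = func, axis = match.arg(axis), missing = match.arg(missing))
}

#' @export
setMethod("show", "ComputeSpec", function(object) {
  cat(sprintf("ComputeSpec '%s' (%s) over [%s], missing=%s\n", object@id,
              object@axis, paste(object@sources, collapse = ", "),
              object@missing))
})

## assert a source frame has no internally overlapping records (clipped set)
assertNoWithinOverlap <- function(start, end, id) {
  if (length(start) > 1) {
    o <- order(start, end)
    if (any(start[o][-1] < end[o][-length(end)]))
      overlapWithinSourceError(id)
  }
}

#' Align several interval frames onto a disjoint partition
#'
#' Breakpoints are the union of all record boundaries clipped into the query
#' range (plus the query bounds); each output row is a maximal sub-interval
#' covered by at least one source, and cell (row, source) holds the source
#' record's value over that sub-interval, or \code{NA} where the source has
#' no covering record. Sub-intervals covered by no source are omitted.
#'
#' @param frames named list of [IntervalFrame-class]s, one per source, each
#'   internally non-overlapping; the first value column of each is used.
#' @param query a [GenomicQuery-class].
#' @return an [IntervalFrame-class] with one numeric column per source,
#'   named after \code{names(frames)}.
#' @export
disjoinFrames <- function(frames, query) {
  stopifnot(is.list(frames), length(frames) > 0)
  ids <- names(frames)
  if (is.null(ids)) ids <- paste0("source", seq_along(frames))
  clipped <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    keep <- frameChrom(f) == query@chrom & frameStart(f) < query@end &
      frameEnd(f) > query@start
    s <- pmax(frameStart(f)[keep], query@start)
    e <- pmin(frameEnd(f)[keep], query@end)
    v <- frameValues(f)
    val <- if (ncol(v)) as.numeric(v[keep, 1]) else rep(NA_real_, sum(keep))
    assertNoWithinOverlap(s, e, ids[i])
    list(start = s, end = e, value = val)
  })
  all_ir <- IRanges::IRanges(
    start = unlist(lapply(clipped, `[[`, "start")) + 1,
    end = unlist(lapply(clipped, `[[`, "end")))
  if (!length(all_ir)) return(emptyIntervalFrame(ids))
  parts <- IRanges::disjoin(all_ir)
  cols <- lapply(clipped, function(cl) {
    out <- rep(NA_real_, length(parts))
    if (length(cl$start)) {
      src <- IRanges::IRanges(start = cl$start + 1, end = cl$end)
      hits <- IRanges::findOverlaps(parts, src, type = "within")
      out[S4Vectors::queryHits(hits)] <- cl$value[S4Vectors::subjectHits(hits)]
    }
    out
  })
  values <- S4Vectors::DataFrame(cols)
  names(values) <- ids
  intervalFrame(rep(query@chrom, length(parts)),
                IRanges::start(parts) - 1, IRanges::end(parts), values)
}

applyMissingPolicy <- function(mat, policy) {
  if (policy == "fill_zero") {
    mat[is.na(mat)] <- 0
    list(mat = mat, keep = rep(TRUE, nrow(mat)))
  } else if (policy == "drop_row") {
    keep <- stats::complete.cases(mat)
    list(mat = mat[keep, , drop = FALSE], keep = keep)
  } else {
    list(mat = mat, keep = rep(TRUE, nrow(mat)))
  }
}

#' Apply a computed-measurement function to an aligned frame
#'
#' @param aligned output of [disjoinFrames()] with columns in
#'   \code{spec@sources} order.
#' @param spec a [ComputeSpec-class].
#' @return an [IntervalFrame-class]; for \code{across_measurements} the
#'   output column(s) are named by the spec id, for \code{along_rows} one
#'   column per source named \code{<spec id>.<source id>}.
#' @export
applyCompute <- function(aligned, spec) {
  v <- frameValues(aligned)
  if (!setequal(names(v), spec@sources) ||
      !identical(names(v), spec@sources))
    shapeError(spec@id, "aligned columns do not match spec sources")
  mat <- as.matrix(as.data.frame(v))
  mp <- applyMissingPolicy(mat, spec@missing)
  rows <- frameSlice(aligned, mp$keep)
  n <- nrow(mp$mat)
  wrap <- function(expr) tryCatch(expr, error = function(e)
    computeError(spec@id, conditionMessage(e)))
  if (spec@axis == "across_measurements") {
    if (!n) return(emptyIntervalFrame(spec@id))
    res <- wrap(lapply(seq_len(n), function(i) as.numeric(spec@func(mp$mat[i, ]))))
    m <- length(res[[1]])
    if (m < 1 || any(lengths(res) != m))
      shapeError(spec@id, "row-wise function output length varies")
    out <- do.call(rbind, res)
    values <- S4Vectors::DataFrame(as.data.frame(out))
    names(values) <- if (m == 1) spec@id else paste0(spec@id, ".", seq_len(m))
  } else {
    res <- wrap(lapply(seq_len(ncol(mp$mat)),
                       function(j) as.numeric(spec@func(mp$mat[, j]))))
    if (any(lengths(res) != n))
      shapeError(spec@id, "column-wise function must preserve length")
    values <- S4Vectors::DataFrame(res)
    names(values) <- paste0(spec@id, ".", spec@sources)
  }
  intervalFrame(frameChrom(rows), frameStart(rows), frameEnd(rows), values)
}
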