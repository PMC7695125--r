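## Seeded synthetic track generator. Every generated file comes with its
## full ground truth (the exact interval list written), so parsers can be
## checked bit-for-bit and query engines against brute-force oracles,
## without any external data. File *writing* delegates to established
## tooling (rtracklayer for BigWig/BigBed, Rsamtools for BGZF/Tabix); the
## parsers under test are this package's own.

#' Specification for a synthetic genomic track
#'
#' @param seed integer RNG seed; the same spec and seed always yield the
#'   identical ground-truth interval list.
#' @param chromSizes named integer vector of chromosome lengths (bp).
#' @param model \code{"tiled_fixed_step"} (contiguous fixed-width tiles, the
#'   shape of coverage tracks), \code{"random_intervals"} (non-overlapping
#'   intervals with random gaps, the shape of bedGraph signal), or
#'   \code{"peaks"} (Poisson-placed summits with triangular signal, the
#'   shape of ChIP-seq enrichment).
#' @param tile tile width for \code{tiled_fixed_step}.
#' @param lengthRange min/max interval length for \code{random_intervals}.
#' @param gapRange min/max gap between intervals.
#' @param values value distribution: \code{list(kind = "uniform_int", min,
#'   max)} or \code{list(kind = "normal", mean, sd)}. Values are quantized
#'   to 32-bit floats, the precision the file format carries.
#' @param peakRate expected summits per bp for \code{"peaks"}.
#' @param peakHalfWidth half-width of the triangular peak (bp).
#' @return a list of class \code{"syntheticTrackSpec"}.
#' @export
syntheticTrackSpec <- function(seed = 1L,
                               chromSizes = c(chr1 = 100000L),
                               model = c("tiled_fixed_step",
                                         "random_intervals", "peaks"),
                               tile = 100L,
                               lengthRange = c(50L, 500L),
                               gapRange = c(0L, 300L),
                               values = list(kind = "uniform_int",
                                             min = 0, max = 100),
                               peakRate = 1 / 5000,
                               peakHalfWidth = 500L) {
  structure(list(seed = as.integer(seed), chromSizes = chromSizes,
                 model = match.arg(model), tile = tile,
                 lengthRange = lengthRange, gapRange = gapRange,
                 values = values, peakRate = peakRate,
                 peakHalfWidth = peakHalfWidth),
            class = "syntheticTrackSpec")
}

## round-trip doubles through 32-bit floats: the precision BBI files store
quantizeFloat32 <- function(v) {
  if (!length(v)) return(numeric())
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

drawValues <- function(n, dist) {
  if (!n) return(numeric())
  v <- switch(dist$kind,
    uniform_int = sample(seq(dist$min, dist$max), n, replace = TRUE),
    normal = stats::rnorm(n, dist$mean, dist$sd),
    uniform = stats::runif(n, dist$min, dist$max),
    generationError(paste0("unknown value distribution: ", dist$kind)))
  quantizeFloat32(v)
}

## intervals for one chromosome under the spec's model; 0-based half-open
modelIntervals <- function(spec, chromLen) {
  if (spec$model == "tiled_fixed_step") {
    starts <- seq(0, chromLen - spec$tile, by = spec$tile)
    data.frame(start = starts, end = starts + spec$tile)
  } else if (spec$model == "random_intervals") {
    starts <- numeric(); ends <- numeric(); pos <- 0
    repeat {
      pos <- pos + sample(seq(spec$gapRange[1], spec$gapRange[2]), 1)
      len <- sample(seq(spec$lengthRange[1], spec$lengthRange[2]), 1)
      if (pos + len > chromLen) break
      starts <- c(starts, pos); ends <- c(ends, pos + len)
      pos <- pos + len
    }
    data.frame(start = starts, end = ends)
  } else {
    ## peaks: sequential summit placement with exponential spacing, wide
    ## enough apart that triangles never overlap
    step <- max(10L, spec$peakHalfWidth %/% 10L)
    minGap <- 2L * spec$peakHalfWidth + step
    pos <- 0; summits <- numeric()
    repeat {
      pos <- pos + minGap + stats::rexp(1, spec$peakRate)
      if (pos + spec$peakHalfWidth >= chromLen) break
      summits <- c(summits, round(pos))
    }
    out <- list()
    for (s in summits) {
      offs <- seq(-spec$peakHalfWidth, spec$peakHalfWidth - step, by = step)
      h <- 1 - abs(offs + step / 2) / spec$peakHalfWidth
      out[[length(out) + 1L]] <- data.frame(start = s + offs,
                                            end = s + offs + step,
                                            height = h)
    }
    if (!length(out)) return(data.frame(start = numeric(), end = numeric()))
    do.call(rbind, out)
  }
}

truthForSpec <- function(spec) {
  set.seed(spec$seed)
  frames <- lapply(names(spec$chromSizes), function(ch) {
    iv <- modelIntervals(spec, spec$chromSizes[[ch]])
    if (!nrow(iv))
      return(intervalFrame(character(), numeric(), numeric(),
                           S4Vectors::DataFrame(value = numeric())))
    v <- drawValues(nrow(iv), spec$values)
    if (spec$model == "peaks")
      v <- quantizeFloat32(abs(v) * iv$height + 1)
    intervalFrame(rep(ch, nrow(iv)), iv$start, iv$end,
                  S4Vectors::DataFrame(value = v))
  })
  bindFrames(frames)
}

truthToGRanges <- function(truth, chromSizes) {
  gr <- GenomicRanges::GRanges(
    frameChrom(truth),
    IRanges::IRanges(start = frameStart(truth) + 1, end = frameEnd(truth)),
    seqlengths = vapply(chromSizes, as.integer, integer(1)))
  gr
}

#' Generate a synthetic BigWig signal track with recorded ground truth
#'
#' @param spec a [syntheticTrackSpec()].
#' @param path output path (\code{.bw}).
#' @param compress compress data sections (the BBI default).
#' @return list with \code{path}, \code{truth} (the exact
#'   [IntervalFrame-class] written, values quantized to 32-bit floats) and
#'   \code{spec}.
#' @export
makeSignalTrack <- function(spec, path = tempfile(fileext = ".bw"),
                            compress = TRUE) {
  truth <- truthForSpec(spec)
  if (!length(truth)) generationError("spec produced no intervals")
  gr <- truthToGRanges(truth, spec$chromSizes)
  gr$score <- frameValues(truth)$value
  rtracklayer::export.bw(gr, path, compress = compress)
  list(path = path, truth = truth, spec = spec)
}

#' Generate a synthetic BigBed region track with recorded ground truth
#'
#' Records carry \code{name} (\code{peak1, peak2, ...}) and an integer
#' \code{score} (0-1000) as BED rest-of-line fields.
#'
#' @inheritParams makeSignalTrack
#' @param path output path (\code{.bb}).
#' @return list with \code{path}, \code{truth} (columns \code{name},
#'   \code{score}) and \code{spec}.
#' @export
makeRegionTrack <- function(spec, path = tempfile(fileext = ".bb"),
                            compress = TRUE) {
  set.seed(spec$seed)
  frames <- lapply(names(spec$chromSizes), function(ch) {
    iv <- modelIntervals(spec, spec$chromSizes[[ch]])
    iv <- iv[, c("start", "end")]
    if (!nrow(iv)) return(NULL)
    intervalFrame(rep(ch, nrow(iv)), iv$start, iv$end,
                  S4Vectors::DataFrame(name = character(nrow(iv)),
                                       score = numeric(nrow(iv))))
  })
  truth <- bindFrames(frames[!vapply(frames, is.null, logical(1))])
  if (!length(truth)) generationError("spec produced no intervals")
  truth@values$name <- paste0("peak", seq_len(length(truth)))
  truth@values$score <- as.numeric(sample(0:1000, length(truth),
                                          replace = TRUE))
  ## rtracklayer's bigBed writer stores start(gr) verbatim as the 0-based
  ## BED start, so the GRanges is built without the usual +1 shift
  gr <- GenomicRanges::GRanges(
    frameChrom(truth),
    IRanges::IRanges(start = frameStart(truth), end = frameEnd(truth)),
    seqlengths = vapply(spec$chromSizes, as.integer, integer(1)))
  gr$name <- truth@values$name
  gr$score <- as.integer(truth@values$score)
  suppressWarnings(rtracklayer::export.bb(gr, path))
  list(path = path, truth = truth, spec = spec,
       columns = c("name", "score"))
}

#' Generate a synthetic BGZF + Tabix tabular track with recorded ground truth
#'
#' Writes a bedGraph-dialect table (chrom, start, end, value; 0-based
#' half-open), BGZF-compresses it and builds a .tbi index.
#'
#' @inheritParams makeSignalTrack
#' @param path output path for the uncompressed text; the BGZF file is
#'   \code{path + ".bgz"} and the index \code{path + ".bgz.tbi"}.
#' @return list with \code{path} (BGZF file), \code{index} (.tbi path),
#'   \code{truth} and \code{spec}.
#' @export
makeTabularTrack <- function(spec, path = tempfile(fileext = ".bedgraph")) {
  truth <- truthForSpec(spec)
  if (!length(truth)) generationError("spec produced no intervals")
  lines <- sprintf("%s\t%.0f\t%.0f\t%s", frameChrom(truth),
                   frameStart(truth), frameEnd(truth),
                   format(frameValues(truth)$value, digits = 15,
                          scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  bgz <- Rsamtools::bgzip(path, overwrite = TRUE)
  tbi <- Rsamtools::indexTabix(bgz, format = "bed")
  list(path = bgz, index = tbi, truth = truth, spec = spec,
       columns = "value")
}

#' Generate a synthetic gene-annotation table (Tabix-indexed)
#'
#' A bedGraph-style BED table with columns (chrom, start, end, gene,
#' strand), one row per gene, named \code{GENE1 ... GENEn}, for navigational
#' lookups by gene name.
#'
#' @param seed RNG seed.
#' @param chromSizes named chromosome lengths.
#' @param nGenes genes per chromosome.
#' @param path output path for the uncompressed text.
#' @return list with \code{path} (BGZF), \code{index}, \code{truth}
#'   (columns \code{gene}, \code{strand}).
#' @export
makeGeneAnnotation <- function(seed = 1L, chromSizes = c(chr1 = 100000L),
                               nGenes = 20L,
                               path = tempfile(fileext = ".bed")) {
  set.seed(seed)
  frames <- lapply(names(chromSizes), function(ch) {
    len <- chromSizes[[ch]]
    width <- pmax(200L, as.integer(stats::rgamma(nGenes, 2, 2 / 2000)))
    start <- sort(sample(seq(0L, max(1L, len - max(width) - 1L)), nGenes))
    intervalFrame(rep(ch, nGenes), start, start + width,
                  S4Vectors::DataFrame(
                    gene = character(nGenes),
                    strand = sample(c("+", "-"), nGenes, replace = TRUE)))
  })
  truth <- bindFrames(frames)
  truth@values$gene <- paste0("GENE", seq_len(length(truth)))
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%s", frameChrom(truth),
                   frameStart(truth), frameEnd(truth), truth@values$gene,
                   truth@values$strand)
  writeLines(lines, path)
  bgz <- Rsamtools::bgzip(path, overwrite = TRUE)
  tbi <- Rsamtools::indexTabix(bgz, format = "bed")
  list(path = bgz, index = tbi, truth = truth,
       columns = c("gene", "strand"))
}

#' Corrupt a fixture file for error-path testing
#'
#' @param path file to mutate (the original is left untouched).
#' @param mutation \code{"flip"} (invert every bit of one byte) or
#'   \code{"truncate"} (drop everything from \code{offset} on).
#' @param offset 0-based byte offset of the mutation.
#' @param out destination path.
#' @return \code{out}.
#' @export
corruptFixture <- function(path, mutation = c("flip", "truncate"), offset,
                           out = tempfile(fileext = ".corrupt")) {
  mutation <- match.arg(mutation)
  raw <- readBin(path, "raw", file.size(path))
  if (offset < 0 || offset >= length(raw))
    generationError("mutation offset outside file")
  if (mutation == "flip") {
    raw[offset + 1] <- xor(raw[offset + 1], as.raw(255))
  } else {
    raw <- raw[seq_len(offset)]
  }
  writeBin(raw, out)
  out
}
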