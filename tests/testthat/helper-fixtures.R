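# Shared fixture construction and independent oracles. Fixtures are built
# once per test run (memoised in `.fx`) under a session temp directory.

.fx <- new.env(parent = emptyenv())

fixtureDir <- function() {
  if (is.null(.fx$dir)) {
    .fx$dir <- file.path(tempdir(), "trackserve-fixtures")
    dir.create(.fx$dir, showWarnings = FALSE)
  }
  .fx$dir
}

## memoised generated tracks keyed by label
fixtureSignal <- function(label, seed, chromSizes = c(chr1 = 100000L),
                          model = "random_intervals", ...) {
  key <- paste0("sig_", label)
  if (is.null(.fx[[key]])) {
    spec <- syntheticTrackSpec(seed = seed, chromSizes = chromSizes,
                               model = model, ...)
    .fx[[key]] <- makeSignalTrack(spec, file.path(fixtureDir(),
                                                  paste0(label, ".bw")))
  }
  .fx[[key]]
}

fixtureRegions <- function(label, seed, chromSizes = c(chr1 = 100000L)) {
  key <- paste0("bed_", label)
  if (is.null(.fx[[key]])) {
    spec <- syntheticTrackSpec(seed = seed, chromSizes = chromSizes,
                               model = "random_intervals")
    .fx[[key]] <- makeRegionTrack(spec, file.path(fixtureDir(),
                                                  paste0(label, ".bb")))
  }
  .fx[[key]]
}

fixtureTabular <- function(label, seed, chromSizes = c(chr1 = 100000L)) {
  key <- paste0("tab_", label)
  if (is.null(.fx[[key]])) {
    spec <- syntheticTrackSpec(seed = seed, chromSizes = chromSizes)
    .fx[[key]] <- makeTabularTrack(spec, file.path(fixtureDir(),
                                                   paste0(label, ".bedgraph")))
  }
  .fx[[key]]
}

## ---- independent oracles ----

## brute-force overlap filter of a ground-truth frame (the oracle for any
## range query): plain vector comparison, no package query machinery
oracleOverlap <- function(truth, chrom, start, end) {
  keep <- frameChrom(truth) == chrom & frameStart(truth) < end &
    frameEnd(truth) > start
  list(start = frameStart(truth)[keep], end = frameEnd(truth)[keep],
       values = as.data.frame(frameValues(truth))[keep, , drop = FALSE])
}

expectFrameEqualsOracle <- function(frame, truth, chrom, start, end) {
  o <- oracleOverlap(truth, chrom, start, end)
  expect_identical(frameStart(frame), o$start)
  expect_identical(frameEnd(frame), o$end)
  if (!length(o$start)) return(invisible(NULL))   # emptiness already checked
  fv <- as.data.frame(frameValues(frame))
  for (cn in names(o$values))
    expect_identical(fv[[cn]], o$values[[cn]], label = paste("column", cn))
}

## per-base expansion of a frame over [start, end): NA where uncovered
perBaseExpand <- function(starts, ends, values, start, end) {
  out <- rep(NA_real_, end - start)
  for (i in seq_along(starts)) {
    s <- max(starts[i], start); e <- min(ends[i], end)
    if (e > s) out[(s - start + 1):(e - start)] <- values[i]
  }
  out
}

## brute-force Tabix bin oracle: enumerate all 37,449 bins, keep overlaps
oracleBins <- function(start, end) {
  offsets <- c(0, 1, 9, 73, 585, 4681)
  sizes <- 2^c(29, 26, 23, 20, 17, 14)
  out <- numeric()
  for (l in 1:6) {
    n <- 8^(l - 1)
    idx <- 0:(n - 1)
    lo <- idx * sizes[l]
    hi <- lo + sizes[l]
    out <- c(out, offsets[l] + idx[lo < end & hi > start])
  }
  sort(out)
}

## ---- subprocess servers ----

freePort <- function() {
  for (p in sample(20000:42000, 40)) {
    s <- tryCatch(serverSocket(p), error = function(e) NULL)
    if (!is.null(s)) { close(s); return(p) }
  }
  stop("no free port found")
}

waitForServer <- function(port, path = "/measurements", tries = 100) {
  url <- sprintf("http://127.0.0.1:%d%s", port, path)
  for (i in seq_len(tries)) {
    ok <- tryCatch({
      curl::curl_fetch_memory(url)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(TRUE)
    Sys.sleep(0.1)
  }
  FALSE
}

libPathCode <- function() {
  sprintf(".libPaths(c(%s, .libPaths()))",
          paste(deparse(.libPaths()), collapse = ""))
}

startCatalogServer <- function(configPath, port) {
  code <- sprintf(
    "%s; suppressMessages(library(trackserve)); serveCatalog(%s, %d, quiet = TRUE)",
    libPathCode(), deparse(configPath), port)
  system2("Rscript", c("-e", shQuote(code)), wait = FALSE,
          stdout = FALSE, stderr = FALSE)
  waitForServer(port)
}

startFixtureServer <- function(dir, port, honorRanges = TRUE) {
  code <- sprintf(
    "%s; suppressMessages(library(trackserve)); serveFixtures(%s, %d, honorRanges = %s)",
    libPathCode(), deparse(dir), port, deparse(honorRanges))
  system2("Rscript", c("-e", shQuote(code)), wait = FALSE,
          stdout = FALSE, stderr = FALSE)
  ## static server: probe any path; 404 still proves it is up
  url <- sprintf("http://127.0.0.1:%d/__probe__", port)
  for (i in 1:100) {
    ok <- tryCatch({
      curl::curl_fetch_memory(url)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(TRUE)
    Sys.sleep(0.1)
  }
  FALSE
}

stopServer <- function(port) {
  tryCatch(curl::curl_fetch_memory(
    sprintf("http://127.0.0.1:%d/shutdown", port)),
    error = function(e) NULL)
  invisible(NULL)
}

httpGet <- function(port, path) {
  resp <- curl::curl_fetch_memory(sprintf("http://127.0.0.1:%d%s", port, path))
  list(status = resp$status_code,
       json = jsonlite::fromJSON(rawToChar(resp$content),
                                 simplifyVector = TRUE))
}

writeFixtureConfig <- function(entries, path = tempfile(fileext = ".json")) {
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE), path)
  path
}
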