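## Minimal HTTP/1.1 JSON REST layer over the catalog + query engine, built
## on base-R server sockets. Requests are served one at a time; because
## every request is computed independently from the catalog (the cache
## affects latency only), any interleaving of client requests observes
## exactly the results a serial execution would produce.

httpRespond <- function(con, status, body, contentType = "application/json",
                        extraHeaders = character()) {
  reason <- c(`200` = "OK", `206` = "Partial Content",
              `400` = "Bad Request", `404` = "Not Found",
              `416` = "Range Not Satisfiable",
              `500` = "Internal Server Error")[as.character(status)]
  if (is.character(body)) body <- charToRaw(paste(body, collapse = "\n"))
  head <- c(sprintf("HTTP/1.1 %d %s", status, reason),
            sprintf("Content-Type: %s", contentType),
            sprintf("Content-Length: %d", length(body)),
            "Connection: close", extraHeaders, "", "")
  writeBin(charToRaw(paste(head, collapse = "\r\n")), con)
  if (length(body)) writeBin(body, con)
  flush(con)
}

parseRequest <- function(con) {
  req <- readLines(con, n = 1)
  if (!length(req)) return(NULL)
  parts <- strsplit(req, " ", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(NULL)
  headers <- character()
  repeat {
    l <- readLines(con, n = 1)
    if (!length(l) || !nzchar(l)) break
    headers <- c(headers, l)
  }
  target <- strsplit(parts[2], "?", fixed = TRUE)[[1]]
  params <- list()
  if (length(target) > 1) {
    for (kv in strsplit(target[2], "&", fixed = TRUE)[[1]]) {
      kvp <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(kvp) == 2)
        params[[utils::URLdecode(kvp[1])]] <- utils::URLdecode(kvp[2])
    }
  }
  list(method = parts[1], path = target[1], params = params,
       headers = headers)
}

jsonPayload <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                   digits = NA)
}

apiResponse <- function(requestId, data = NULL, error = NULL) {
  jsonPayload(list(requestId = requestId, error = error, data = data))
}

## columnar wire form of an IntervalFrame: equal-length arrays, NA -> null
framePayload <- function(frame) {
  v <- frameValues(frame)
  values <- lapply(seq_len(ncol(v)), function(j) v[[j]])
  names(values) <- names(v)
  list(rows = list(chr = frameChrom(frame), start = frameStart(frame),
                   end = frameEnd(frame)),
       values = values)
}

measurementListing <- function(catalog) {
  lapply(unname(catalog@entries), function(e) {
    if (is(e, "ComputeSpec"))
      list(id = e@id, name = e@name, type = "computed",
           sources = as.list(e@sources))
    else if (is(e, "GenomeAnnotation"))
      list(id = e@id, name = e@id, type = "genome", format = "tabix")
    else
      list(id = e@id, name = e@name, type = "file", format = e@format,
           annotations = if (length(e@annotations)) e@annotations else NULL)
  })
}

handleDataRequest <- function(catalog, params) {
  rid <- if (!is.null(params$requestId))
    suppressWarnings(as.integer(params$requestId)) else 0L
  if (is.na(rid)) rid <- 0L
  need <- c("measurement", "chr", "start", "end")
  missing <- need[!need %in% names(params)]
  if (length(missing))
    return(list(status = 400, body = apiResponse(rid, error = paste0(
      "missing parameter(s): ", paste(missing, collapse = ", ")))))
  start <- suppressWarnings(as.numeric(params$start))
  end <- suppressWarnings(as.numeric(params$end))
  bins <- if (!is.null(params$bins))
    suppressWarnings(as.integer(params$bins)) else NULL
  if (anyNA(c(start, end)) || start < 0 || start >= end ||
      (!is.null(bins) && (is.na(bins) || bins < 1)))
    return(list(status = 400, body = apiResponse(rid, error =
      "start/end must be integers with 0 <= start < end; bins must be >= 1")))
  res <- tryCatch({
    r <- getData(catalog, params$measurement,
                 genomicQuery(params$chr, start, end), bins = bins)
    list(status = 200, body = apiResponse(rid, data = framePayload(r@frame)))
  },
  trackserve_unknown_measurement = function(e)
    list(status = 404, body = apiResponse(rid, error = conditionMessage(e))),
  trackserve_unknown_chromosome = function(e)
    list(status = 404, body = apiResponse(rid, error = conditionMessage(e))),
  error = function(e)
    list(status = 500, body = apiResponse(rid, error = conditionMessage(e))))
  res
}

#' Serve a measurement catalog over HTTP
#'
#' Endpoints: \code{GET /measurements} lists every registered measurement
#' (id, name, type, format, annotations; computed measurements list their
#' source ids); \code{GET /data?measurement=ID&chr=C&start=S&end=E[&bins=B]}
#' returns the query result as columnar JSON (\code{rows} arrays plus one
#' array per value column, missing values as \code{null}, numbers in full
#' precision). Malformed parameters give 400, unknown measurement or
#' chromosome 404, parser or compute failures 500 with the error message.
#' \code{GET /shutdown} stops the server (for orchestration).
#'
#' The loop serves one request at a time, so any concurrent client mix
#' observes per-request results identical to serial execution.
#'
#' @param catalog a [MeasurementCatalog-class], or the path of a JSON
#'   configuration for [loadConfig()].
#' @param port TCP port.
#' @param cacheBytes shared block-cache capacity when \code{catalog} is a
#'   config path.
#' @param quiet suppress per-request log lines.
#' @param maxRequests stop after this many requests (mainly for tests).
#' @return number of requests served, invisibly.
#' @export
serveCatalog <- function(catalog, port, cacheBytes = 256 * 1024^2,
                         quiet = FALSE, maxRequests = Inf) {
  if (is.character(catalog)) catalog <- loadConfig(catalog, cacheBytes)
  srv <- tryCatch(serverSocket(port),
                  error = function(e) configError(
                    sprintf("cannot listen on port %d: %s", port,
                            conditionMessage(e))))
  on.exit(close(srv), add = TRUE)
  served <- 0
  logline <- function(...) if (!quiet)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ..., "\n")
  while (served < maxRequests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    t0 <- proc.time()[["elapsed"]]
    req <- tryCatch(parseRequest(con), error = function(e) NULL)
    if (is.null(req)) { close(con); next }
    served <- served + 1
    if (req$path == "/shutdown") {
      httpRespond(con, 200, apiResponse(0L, data = "bye"))
      close(con)
      break
    }
    res <- if (req$path == "/measurements") {
      list(status = 200,
           body = apiResponse(
             if (!is.null(req$params$requestId))
               as.integer(req$params$requestId) else 0L,
             data = measurementListing(catalog)))
    } else if (req$path == "/data") {
      tryCatch(handleDataRequest(catalog, req$params),
               error = function(e)
                 list(status = 500, body = apiResponse(0L, error =
                   conditionMessage(e))))
    } else {
      list(status = 404, body = apiResponse(0L, error = "no such endpoint"))
    }
    tryCatch({
      httpRespond(con, res$status, res$body)
    }, error = function(e) NULL)
    close(con)
    ms <- (proc.time()[["elapsed"]] - t0) * 1000
    hits <- catalog@runtime$cache@state$hits
    logline(req$path,
            paste(names(req$params), unlist(req$params), sep = "=",
                  collapse = " "),
            res$status, sprintf("%.1fms cache_hits=%d", ms, hits))
  }
  invisible(served)
}

#' Serve a directory of fixture files over HTTP with Range support
#'
#' A static file server for hermetic remote-access tests:
#' \code{GET /<name>} serves \code{file.path(dir, name)}; a
#' \code{Range: bytes=a-b} header yields a 206 partial response. With
#' \code{honorRanges = FALSE} the server ignores Range headers and always
#' returns the whole file with status 200, emulating servers that do not
#' support partial requests.
#'
#' @param dir directory of files to serve.
#' @param port TCP port.
#' @param honorRanges honor Range headers (default) or ignore them.
#' @param maxRequests stop after this many requests.
#' @return number of requests served, invisibly.
#' @export
serveFixtures <- function(dir, port, honorRanges = TRUE, maxRequests = Inf) {
  srv <- tryCatch(serverSocket(port),
                  error = function(e) configError(
                    sprintf("cannot listen on port %d: %s", port,
                            conditionMessage(e))))
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < maxRequests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    req <- tryCatch(parseRequest(con), error = function(e) NULL)
    if (is.null(req)) { close(con); next }
    served <- served + 1
    if (req$path == "/shutdown") {
      httpRespond(con, 200, "bye", "text/plain")
      close(con)
      break
    }
    fname <- file.path(dir, utils::URLdecode(sub("^/", "", req$path)))
    if (!file.exists(fname) || dir.exists(fname)) {
      httpRespond(con, 404, "not found", "text/plain")
      close(con); next
    }
    total <- file.size(fname)
    rng <- grep("^[Rr]ange:", req$headers, value = TRUE)
    if (honorRanges && length(rng)) {
      m <- regmatches(rng[1],
                      regexec("bytes=([0-9]+)-([0-9]*)", rng[1]))[[1]]
      if (length(m) < 2) {
        httpRespond(con, 416, "bad range", "text/plain")
        close(con); next
      }
      from <- as.numeric(m[2])
      to <- if (nzchar(m[3])) min(as.numeric(m[3]), total - 1) else total - 1
      if (from >= total) {
        httpRespond(con, 416, "range beyond EOF", "text/plain")
        close(con); next
      }
      fcon <- file(fname, "rb")
      seek(fcon, from)
      body <- readBin(fcon, "raw", to - from + 1)
      close(fcon)
      httpRespond(con, 206, body, "application/octet-stream",
                  sprintf("Content-Range: bytes %.0f-%.0f/%.0f", from, to,
                          total))
    } else {
      body <- readBin(fname, "raw", total)
      httpRespond(con, 200, body, "application/octet-stream")
    }
    close(con)
  }
  invisible(served)
}

#' One-shot query returning the REST payload
#'
#' Computes the same columnar JSON payload \code{GET /data} would return,
#' without a running server — the CLI \code{query} subcommand and tests use
#' it to check API transparency.
#'
#' @param catalog a [MeasurementCatalog-class] or config path.
#' @param measurement measurement id.
#' @param chrom,start,end query range (0-based half-open).
#' @param bins optional bin count.
#' @param requestId echoed integer.
#' @return JSON string.
#' @export
queryPayload <- function(catalog, measurement, chrom, start, end,
                         bins = NULL, requestId = 0L) {
  if (is.character(catalog)) catalog <- loadConfig(catalog)
  params <- list(measurement = measurement, chr = chrom,
                 start = format(start, scientific = FALSE),
                 end = format(end, scientific = FALSE),
                 requestId = as.character(requestId))
  if (!is.null(bins)) params$bins <- as.character(bins)
  res <- handleDataRequest(catalog, params)
  if (res$status != 200)
    tsError("http", paste0("HTTP ", res$status, ": ", res$body))
  as.character(res$body)
}
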