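#' Block cache for byte-range reads
#'
#' A \code{BlockCache} stores raw byte blocks keyed by
#' \code{(uri, offset, length)} so that repeated genomic-range queries against
#' the same file re-fetch nothing from the backend. Entries holding file
#' metadata (headers, chromosome tree, zoom headers, indexes) are
#' \emph{pinned}: they are never evicted, mirroring the policy of keeping
#' header, zoom-level and chromosome-tree information resident for the
#' lifetime of a file object. Unpinned data blocks are evicted
#' least-frequently-used first, with least-recently-used breaking ties,
#' whenever the cache exceeds its byte capacity.
#'
#' The object has reference semantics (state lives in an environment), as a
#' cache shared between file handles must.
#'
#' @slot state environment holding entries and counters.
#'
#' @seealso [readRange()], [cacheStats()], [cacheEvict()]
#' @export
setClass("BlockCache", representation(state = "environment"))

#' Create a block cache
#'
#' @param maxBytes capacity in bytes for \emph{unpinned} entries; the default
#'   is 256 MiB. Pinned metadata never counts against eviction (it survives
#'   regardless), but is included in reported \code{bytes_cached}.
#' @return a [BlockCache-class] object.
#' @examples
#' bc <- blockCache(1024 * 1024)
#' cacheStats(bc)
#' @export
blockCache <- function(maxBytes = 256 * 1024^2) {
  st <- new.env(parent = emptyenv())
  st$entries <- new.env(parent = emptyenv())   # key -> raw
  st$freq <- new.env(parent = emptyenv())      # key -> access count
  st$tick <- new.env(parent = emptyenv())      # key -> last access tick
  st$pinned <- new.env(parent = emptyenv())    # key -> TRUE
  st$clock <- 0
  st$hits <- 0
  st$misses <- 0
  st$evictions <- 0
  st$max_bytes <- as.double(maxBytes)
  new("BlockCache", state = st)
}

cacheKey <- function(uri, offset, length) {
  sprintf("%s|%.0f|%.0f", uri, offset, length)
}

cacheGet <- function(cache, key) {
  st <- cache@state
  if (exists(key, envir = st$entries, inherits = FALSE)) {
    st$hits <- st$hits + 1
    st$freq[[key]] <- st$freq[[key]] + 1
    st$clock <- st$clock + 1
    st$tick[[key]] <- st$clock
    get(key, envir = st$entries, inherits = FALSE)
  } else {
    st$misses <- st$misses + 1
    NULL
  }
}

cachePut <- function(cache, key, value, pin = FALSE) {
  st <- cache@state
  assign(key, value, envir = st$entries)
  st$freq[[key]] <- 1
  st$clock <- st$clock + 1
  st$tick[[key]] <- st$clock
  if (pin) assign(key, TRUE, envir = st$pinned)
  cacheEvict(cache)
  invisible(NULL)
}

cacheBytes <- function(cache) {
  st <- cache@state
  keys <- ls(st$entries)
  if (!length(keys)) return(0)
  sum(vapply(keys, function(k) length(st$entries[[k]]), numeric(1)))
}

#' Evict cold blocks until the cache fits its capacity
#'
#' Unpinned entries are removed in ascending (frequency, recency) order until
#' the cached bytes fit \code{maxBytes}. Pinned entries always survive, so a
#' cache holding only pinned metadata may legitimately report more cached
#' bytes than its capacity.
#'
#' @param cache a [BlockCache-class].
#' @return the cache's [cacheStats()] after eviction, invisibly.
#' @export
cacheEvict <- function(cache) {
  st <- cache@state
  total <- cacheBytes(cache)
  if (total > st$max_bytes) {
    keys <- setdiff(ls(st$entries), ls(st$pinned))
    if (length(keys)) {
      freq <- vapply(keys, function(k) st$freq[[k]], numeric(1))
      tick <- vapply(keys, function(k) st$tick[[k]], numeric(1))
      for (k in keys[order(freq, tick)]) {
        if (total <= st$max_bytes) break
        total <- total - length(st$entries[[k]])
        rm(list = k, envir = st$entries)
        suppressWarnings(rm(list = k, envir = st$freq))
        suppressWarnings(rm(list = k, envir = st$tick))
        st$evictions <- st$evictions + 1
      }
    }
  }
  invisible(cacheStats(cache))
}

#' Cache statistics
#'
#' @param cache a [BlockCache-class].
#' @return a list with \code{hits}, \code{misses}, \code{bytes_cached},
#'   \code{evictions} and \code{entries}.
#' @export
cacheStats <- function(cache) {
  st <- cache@state
  list(hits = st$hits, misses = st$misses,
       bytes_cached = cacheBytes(cache),
       evictions = st$evictions,
       entries = length(ls(st$entries)))
}

setMethod("show", "BlockCache", function(object) {
  s <- cacheStats(object)
  cat(sprintf(
    "BlockCache: %d entries, %.0f bytes (cap %.0f), %d hits / %d misses, %d evictions\n",
    s$entries, s$bytes_cached, object@state$max_bytes, s$hits, s$misses,
    s$evictions))
})
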