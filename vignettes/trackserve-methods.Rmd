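---
title: "In-situ querying of indexed genomic track files"
author: "trackserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-situ querying of indexed genomic track files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackserve)
```

# The problem

Genome browsers and exploratory tools need millisecond answers to questions
like "what does this signal track look like on chr11:10,550,488-11,554,489,
drawn into 1,000 screen pixels?" — against collections of files that are
gigabytes in aggregate and often live on remote web servers. Loading those
files into a database first is expensive and freezes the analysis at import
time; re-reading whole files per query is worse. The indexed binary formats
the genomics community already uses — BigWig and BigBed (the BBI container
family) and Tabix-indexed tab-delimited tables — embed spatial indexes that
make it possible to answer a genomic-range query by reading only a few
kilobytes of a file, wherever it lives. `trackserve` is an engine built on
that observation: it parses these formats itself at the byte level, fetches
only the byte ranges a query needs (via positional reads locally, HTTP
range requests remotely), caches what it fetched, aligns tracks by interval
overlap so user-defined transformations can be evaluated lazily at query
time, and serves everything over a small JSON REST API.

# File access and caching

All file access goes through a `ResourceHandle`, which issues positional
reads against local files or `Range: bytes=a-b` requests (RFC 7233) against
HTTP servers. A remote handle is opened with a one-byte probe: a `206
Partial Content` answer resolves the file size from `Content-Range`; a
`200` answer means the server ignores ranges, and the handle refuses to
proceed rather than silently streaming whole files. Every backend read is
counted and logged, which is how the test suite *proves* minimal fetching:
for a query touching one data block of a 118-block file, the logged reads
are exactly the 64-byte header, the zoom-header table, the chromosome tree,
the R-tree nodes on the overlapping root-to-leaf path, and that one block —
under 2% of the file.

Reads are memoized in a `BlockCache` keyed by `(uri, offset, length)`.
File metadata — header, zoom headers, chromosome tree, Tabix index — is
*pinned*: it stays resident for the life of the file object. Data blocks
are evicted least-frequently-used first, least-recently-used breaking
ties, whenever unpinned bytes exceed the capacity (default 256 MiB,
configurable; the formats themselves suggest no particular value, so the
default is sized for a workstation serving a few dozen tracks). The cache
is semantically transparent: with it on or off, query results are
byte-identical, a property the suite checks over random query sequences.
Parsed file objects (metadata plus pinned blocks) can be spilled to disk
with `storeBBI()` and restored with `restoreBBI()`; the container is a
magic-string-plus-version format so truncated or corrupted spills fail
fast, and a restored object re-reads only data blocks.

# The parsers

The BBI parser implements the standard bit-for-bit: magic-number format
detection in either byte order (BigWig `0x888FFC26`, BigBed `0x8789F2EB`),
the 64-byte header, 24-byte zoom headers, the chromosome B+ tree (magic
`0x78CA8C91`), and the R-tree spatial index (magic `0x2468ACE0`) whose
leaves address data blocks; blocks are zlib-inflated when the header's
`uncompressBufSize` says they are compressed. BigWig sections decode in
all three layouts (bedGraph-style, variable step, fixed step); BigBed
items carry tab-separated rest-of-line fields split into named columns
per the measurement's declared schema; zoom blocks decode into 32-byte
summary records whose mean is `sum / validCount`.

Query results are returned *unclipped*: a record partially overlapping the
query keeps its original coordinates. Clipping and weighting belong to the
summarizer; keeping the parser lossless means the same raw answer serves
binning, transformation and display. Values decode as the 32-bit floats
the format stores, and round-trip tests compare them bit-exactly.

The Tabix path parses the `.tbi` index (itself BGZF-compressed): per
sequence, a bin table mapping the standard 6-level binning scheme
(smallest bin 16 kb, coordinates to 2^29) to chunks of virtual offsets
(`compressed_block_offset * 2^16 + in_block_offset`), plus a linear index
of 16 kb windows that lower-bounds where a query can start. A range query
enumerates the bins overlapping the region, prunes chunks by the linear
bound, merges them, and decompresses only the BGZF blocks those chunks
touch. Coordinates are normalized at parse time to 0-based half-open —
1-based-inclusive dialects (GFF-style presets) are shifted on input — so
every downstream structure speaks one convention.

# Interval alignment and computed measurements

A *computed measurement* is a named, lazily evaluated transformation over
an ordered list of source measurements. At query time each source is
queried for its raw records, the records are clipped into the query range,
and the union of their boundaries induces a partition: `disjoinFrames()`
produces one row per maximal sub-interval covered by at least one source,
with one numeric column per source and `NA` where a source has no covering
record. Sub-intervals covered by nothing are omitted (sparse payloads
render faster and an all-missing row carries no information). A source
whose own records overlap is rejected outright — BigWig semantics forbid
within-track overlap, and an explicit error beats silently averaging.

The user function is applied either *across measurements* (per row, over
the length-k vector of source values — e.g. a difference or mean across
tracks) or *along rows* (per column, over the whole vector — e.g.
mean-centering a signal). Missing values follow a per-spec policy:
`propagate` (default; the function sees `NA` and arithmetic yields `NA`,
matching what array libraries do), `drop_row`, or `fill_zero`. The
function's output arity is validated on first use; failures are re-raised
carrying the spec id. Computed measurements can themselves be sources;
evaluation recurses.

Because evaluation is a pure function of the aligned table, the lazy
result is identical to eagerly materializing the aligned table and
applying the function — and independent of the order in which sources
happen to complete. The suite checks both properties against per-base
expansions of ground truth, for source counts 2, 5, 10 and 20. With more
than two sources and a non-symmetric function (such as successive
differences), operand order is simply the declared source order.

# Summarization to screen resolution

A browser drawing a region of width $W$ into $b$ screen bins needs roughly
$\lfloor W/b \rfloor$ bp per bin — for the canonical 10,000 bp region on
an 800-pixel canvas, 12 bp per bin. When the file has zoom levels, the
engine picks the one with the largest reduction level *not exceeding* that
target, so every screen bin is backed by at least one zoom record; if even
the finest zoom is too coarse (or there are no zooms), it falls back to
raw records. Either way the records are then summarized into exactly $b$
near-equal half-open bins (the first bins absorb the remainder when $b
\nmid W$). A bin's value is the coverage-weighted mean of overlapping
record values — each covered base contributes its record's value equally —
which makes the bin value equal to the per-base mean, the unambiguous
reading of "mean across the bin". Uncovered bins are `NA`, serialized as
`null`. Only the mean aggregator is provided; min/max/sum would be
mechanical extensions.

Computed measurements are evaluated on raw-resolution aligned rows first
and binned afterwards (values-first): binning before transformation would
change non-linear functions' results, while values-first keeps lazy
evaluation equal to its eager oracle at every resolution.

Two numerical caveats are deliberate. First, binned output is clipped to
the query; raw output is not. Second, zoom queries return whole zoom
records overlapping the query without interpolating partial overlap at the
edges; the records carry their own spans, so a consumer can weight them.

# The catalog and the REST API

Measurements — file-backed tracks, genome annotations, computed
measurements — live in a catalog keyed by unique ids, loaded from a JSON
configuration (`id`, `name`, `url`, `file_type`, optional `index_url`,
`annotation`, `columns`, `genome`; unknown keys warn and are ignored) or
registered programmatically. Loading is lazy: no file is opened or probed
until its first query, so cataloguing thousands of tracks costs nothing.
A tab-delimited manifest importer covers batch registration from any
locally saved listing. Genome annotations are Tabix-indexed gene tables;
gene-name lookup builds a name-to-range map by linear scan on first use
(Tabix indexes position, not names) and caches it.

`GET /measurements` lists the catalog; `GET /data?measurement=ID&chr=C&
start=S&end=E[&bins=B]` returns a columnar JSON payload (`rows` arrays
plus one array per value column) whose numbers decode to exactly the
in-process result — full precision, `NA` as `null`. Parameter errors map
to 400, unknown measurement or chromosome to 404, parser and compute
failures to 500 with the message. The server is a single-threaded request
loop on base-R server sockets: each request is computed independently from
the catalog, and the cache affects latency only, so any concurrent client
mix observes per-request results identical to serial execution — the
contract the test suite verifies with a 10-request concurrent batch. A
thin CLI (`inst/scripts/trackserve`) wraps the same functions: `serve`
runs the server against a config, `query` prints one payload and exits.

# The synthetic-data generator

Every test input is produced by the package's own seeded generator, so the
suite is hermetic and every file comes with its exact ground truth. Three
interval models emulate the shapes of real tracks: `tiled_fixed_step`
(contiguous fixed-width tiles, like coverage tracks), `random_intervals`
(intervals with random gaps, like bedGraph output; default lengths
50-500 bp with 0-300 bp gaps), and `peaks` (summits placed by an
exponential-spacing process, ~one per 5 kb, with triangular signal of
500 bp half-width, the shape of ChIP-seq enrichment). Values default to
uniform integers in [0, 100] — integer-valued floats survive 32-bit
storage and summation exactly, which keeps round-trip and binning oracles
bit-exact; normal values are also available and are quantized through
32-bit floats before becoming ground truth. Test chromosomes are tens to
hundreds of kilobases so a full run stays in minutes; the layout-sensitive
fixture (118 data blocks at 10 bp tiles over 1.2 Mb) is sized so
single-block fetch accounting is meaningful.

File writing delegates to rtracklayer and Rsamtools — established writers
produce bona fide files, and the parsers under test are this package's
own, so round-trip tests are a genuine cross-implementation check. One
consequence: the writer builds zoom records item-aligned, crediting an
item that straddles a record boundary to one record in full, so zoom
statistics can differ from per-base summaries by up to one item per
record. Tests bound that effect (at most one item's width and weight)
rather than asserting exact equality; raw-record paths remain bit-exact.
What the fixtures do not emulate: real ChIP-seq autocorrelation and
mappability artifacts, multi-gigabase genomes, or server latency — passing
tests demonstrate correctness of parsing, alignment, summarization and
transport, not performance at biobank scale.

# Known limitations

CSI indexes (coordinates beyond 2^29) are not supported, only `.tbi`.
BigBed `extraIndex`/autoSql metadata is not interpreted beyond
tab-splitting rest fields. Cross-chromosome queries must be issued per
chromosome. The server is plain HTTP without authentication, intended to
sit behind a reverse proxy. Whole-genome summary statistics from the BBI
total-summary block are not exposed.
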