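chromMap1 <- data.frame(name = "chr1", id = 0, length = 1e6)

## hand-built BigWig data sections for the decoder contract
wigSectionRaw <- function(type, chromStart = 0, chromEnd = 200, step = 100,
                          span = 100, items = list()) {
  con <- rawConnection(raw(), "wb")
  on.exit(close(con))
  writeBin(as.integer(c(0, chromStart, chromEnd, step, span)), con, size = 4,
           endian = "little")
  writeBin(as.integer(type), con, size = 1)
  writeBin(as.integer(0), con, size = 1)
  writeBin(as.integer(length(items)), con, size = 2, endian = "little")
  for (it in items) {
    if (type == 1) {
      writeBin(as.integer(it$start), con, size = 4, endian = "little")
      writeBin(as.integer(it$end), con, size = 4, endian = "little")
    } else if (type == 2) {
      writeBin(as.integer(it$start), con, size = 4, endian = "little")
    }
    writeBin(it$value, con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

test_that("fixed-step, variable-step and bedGraph sections decode per the encoding rules", {
  fixed <- decodeWigSection(
    wigSectionRaw(3, chromStart = 0, step = 100, span = 100,
                  items = list(list(value = 1.5), list(value = 2.5))),
    chromMap1)
  expect_equal(as.data.frame(fixed),
               data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                          value = c(1.5, 2.5)))

  bg <- decodeWigSection(
    wigSectionRaw(1, items = list(list(start = 10, end = 20, value = 3))),
    chromMap1)
  expect_equal(as.data.frame(bg),
               data.frame(chrom = "chr1", start = 10, end = 20, value = 3))

  vs <- decodeWigSection(
    wigSectionRaw(2, span = 25, items = list(list(start = 40, value = -1))),
    chromMap1)
  expect_equal(as.data.frame(vs),
               data.frame(chrom = "chr1", start = 40, end = 65, value = -1))

  expect_error(decodeWigSection(wigSectionRaw(0), chromMap1),
               class = "trackserve_corrupt_block")
})

bedBlockRaw <- function(items) {
  con <- rawConnection(raw(), "wb")
  on.exit(close(con))
  for (it in items) {
    writeBin(as.integer(c(0, it$start, it$end)), con, size = 4,
             endian = "little")
    writeBin(charToRaw(it$rest), con)
    writeBin(as.raw(0), con)
  }
  rawConnectionValue(con)
}

test_that("BigBed blocks decode rest-of-line fields into named columns", {
  raw <- bedBlockRaw(list(list(start = 0, end = 50, rest = "peak1\t960"),
                          list(start = 60, end = 90, rest = "peak2\t400")))
  f <- decodeBedBlock(raw, chromMap1, columns = c("name", "score"))
  expect_equal(frameValues(f)$name, c("peak1", "peak2"))
  expect_equal(frameValues(f)$score, c(960, 400))

  ## empty rest: no extra columns
  f2 <- decodeBedBlock(bedBlockRaw(list(list(start = 5, end = 9, rest = ""))),
                       chromMap1)
  expect_equal(ncol(frameValues(f2)), 0)
  expect_equal(frameStart(f2), 5)

  ## truncated item (missing terminator) is rejected
  bad <- raw[-length(raw)]
  expect_error(decodeBedBlock(bad, chromMap1),
               class = "trackserve_corrupt_block")
})

test_that("zoom records decode with sum/validCount means, bad lengths rejected", {
  con <- rawConnection(raw(), "wb")
  writeBin(as.integer(c(0, 0, 1000, 10)), con, size = 4, endian = "little")
  writeBin(c(1, 4, 25, 80), con, size = 4, endian = "little")
  rec <- rawConnectionValue(con); close(con)

  z <- decodeZoomBlock(rec)
  expect_equal(z$mean, 2.5)
  expect_equal(z$valid_count, 10)
  expect_equal(nrow(decodeZoomBlock(raw())), 0)
  expect_error(decodeZoomBlock(as.raw(1:33)), class = "trackserve_corrupt_block")
})

test_that("headers parse for both formats and garbage is rejected", {
  sig <- fixtureSignal("hdr", seed = 3, chromSizes = c(chr1 = 60000L))
  bw <- openBBI(sig$path)
  expect_equal(bbiHeader(bw)$kind, "bigwig")
  expect_gte(bbiHeader(bw)$zoom_levels, 1)
  expect_equal(nrow(bbiZoomLevels(bw)), bbiHeader(bw)$zoom_levels)

  reg <- fixtureRegions("hdr", seed = 3, chromSizes = c(chr1 = 60000L))
  bb <- openBBI(reg$path)
  expect_equal(bbiHeader(bb)$kind, "bigbed")

  zeros <- tempfile()
  writeBin(raw(128), zeros)
  expect_error(openBBI(zeros), class = "trackserve_unrecognized_format")
})

test_that("chromosome tree lists every chromosome; corrupt magic is detected", {
  fx <- fixtureSignal("tree", seed = 4,
                      chromSizes = c(chr1 = 1000000L, chr2 = 500000L),
                      model = "tiled_fixed_step", tile = 1000L)
  bw <- openBBI(fx$path)
  ch <- bbiChroms(bw)
  expect_setequal(ch$name, c("chr1", "chr2"))
  expect_equal(ch$length[match(c("chr1", "chr2"), ch$name)], c(1e6, 5e5))
  expect_false("chrX" %in% ch$name)
  expect_false(anyDuplicated(ch$id) > 0)

  bad <- corruptFixture(fx$path, "flip",
                        offset = bbiHeader(bw)$chrom_tree_offset)
  expect_error(openBBI(bad), class = "trackserve_corrupt_index")
})

test_that("R-tree search returns exactly the overlapping leaf blocks", {
  fx <- fixtureSignal("rtree", seed = 5, chromSizes = c(chr1 = 400000L),
                      model = "tiled_fixed_step", tile = 20L)
  bw <- openBBI(fx$path)
  all_blocks <- trackserve:::findBlocks(
    bw@handle, bw@cache, bw@header$endian, bw@header$full_index_offset,
    0, 0, 400000)
  expect_gte(length(all_blocks), 2)

  ## a query inside the first block returns just that block
  b1 <- all_blocks[[1]]
  one <- trackserve:::findBlocks(
    bw@handle, bw@cache, bw@header$endian, bw@header$full_index_offset,
    0, b1$base_start + 1, b1$base_end - 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$offset, b1$offset)

  ## spanning the boundary between two leaves returns both
  two <- trackserve:::findBlocks(
    bw@handle, bw@cache, bw@header$endian, bw@header$full_index_offset,
    0, all_blocks[[1]]$base_end - 10, all_blocks[[2]]$base_start + 10)
  expect_equal(vapply(two, `[[`, numeric(1), "offset"),
               c(all_blocks[[1]]$offset, all_blocks[[2]]$offset))

  ## absent chromosome id: nothing
  none <- trackserve:::findBlocks(
    bw@handle, bw@cache, bw@header$endian, bw@header$full_index_offset,
    7, 0, 1000)
  expect_length(none, 0)
})

test_that("whole-chromosome queries reproduce generated ground truth exactly", {
  for (model in c("tiled_fixed_step", "random_intervals", "peaks")) {
    fx <- fixtureSignal(paste0("rt_", model), seed = 17,
                        chromSizes = c(chr1 = 120000L), model = model)
    bw <- openBBI(fx$path)
    q <- queryBBI(bw, "chr1", 0, 120000)
    expect_identical(frameStart(q), frameStart(fx$truth), label = model)
    expect_identical(frameEnd(q), frameEnd(fx$truth), label = model)
    expect_identical(frameValues(q)$value, frameValues(fx$truth)$value,
                     label = model)
  }
})

test_that("random region queries agree with brute-force overlap filtering", {
  fx <- fixtureSignal("oracle", seed = 19, chromSizes = c(chr1 = 150000L))
  bw <- openBBI(fx$path)
  set.seed(101)
  for (i in 1:200) {
    s <- sample(0:149000, 1)
    e <- s + sample(1:20000, 1)
    expectFrameEqualsOracle(queryBBI(bw, "chr1", s, e), fx$truth, "chr1", s, e)
  }
})

test_that("overlapping records are returned unclipped; empty regions give empty frames", {
  fx <- fixtureSignal("clip", seed = 21, chromSizes = c(chr1 = 50000L),
                      model = "tiled_fixed_step", tile = 100L)
  bw <- openBBI(fx$path)
  q <- queryBBI(bw, "chr1", 120, 150)   # inside the [100,200) tile
  expect_equal(frameStart(q), 100)
  expect_equal(frameEnd(q), 200)

  gap <- fixtureSignal("gap", seed = 22, chromSizes = c(chr1 = 50000L),
                       model = "random_intervals",
                       gapRange = c(2000L, 3000L), lengthRange = c(50L, 80L))
  bw2 <- openBBI(gap$path)
  s <- frameEnd(gap$truth)[1] + 10
  e <- frameStart(gap$truth)[2] - 10
  if (e > s) expect_length(queryBBI(bw2, "chr1", s, e), 0)
  expect_error(queryBBI(bw2, "chrMISSING", 0, 100),
               class = "trackserve_unknown_chromosome")
})

test_that("zoom record statistics match per-base summaries of the raw signal", {
  ## zoom records are written item-aligned: an item straddling a record
  ## boundary is credited to one record in full, so a record's statistics
  ## can differ from the per-base summary by at most one item's worth
  fx <- fixtureSignal("zoom", seed = 29, chromSizes = c(chr1 = 200000L),
                      model = "tiled_fixed_step", tile = 50L)
  bw <- openBBI(fx$path)
  expect_gte(nrow(bbiZoomLevels(bw)), 1)
  z <- queryBBI(bw, "chr1", 0, 200000, zoomIndex = 1)
  expect_gt(length(z), 1)
  reduction <- bbiZoomLevels(bw)$reduction_level[1]
  truthPB <- perBaseExpand(frameStart(fx$truth), frameEnd(fx$truth),
                           frameValues(fx$truth)$value, 0, 200000)
  maxVal <- max(frameValues(fx$truth)$value)
  for (i in seq_len(length(z))) {
    covered <- truthPB[(frameStart(z)[i] + 1):min(frameEnd(z)[i], 200000)]
    covered <- covered[!is.na(covered)]
    expect_lte(abs(frameValues(z)$valid_count[i] - length(covered)), 50)
    expect_lte(abs(frameValues(z)$value[i] - mean(covered)),
               maxVal * 50 / reduction + 1e-6)
  }
  ## and the records tile the signal without overlap, in order
  expect_true(all(frameStart(z)[-1] >= frameEnd(z)[-length(z)]))
})

test_that("a single-block query reads only header, trees, index path and that block", {
  fx <- fixtureSignal("minfetch", seed = 1, chromSizes = c(chr1 = 1200000L),
                      model = "tiled_fixed_step", tile = 10L)
  cache <- blockCache()
  bw <- openBBI(fx$path, cache = cache)
  all_blocks <- trackserve:::findBlocks(
    bw@handle, bw@cache, bw@header$endian, bw@header$full_index_offset,
    0, 0, 1200000)
  expect_gte(length(all_blocks), 100)

  ## fresh handle + cache so accounting starts clean
  cache2 <- blockCache()
  bw2 <- openBBI(fx$path, cache = cache2)
  b <- all_blocks[[5]]
  mid <- (b$base_start + b$base_end) / 2
  q <- queryBBI(bw2, "chr1", mid, mid + 2)
  expect_gt(length(q), 0)

  st <- fetchStats(bw2@handle)
  hd <- bbiHeader(bw2)
  reads <- do.call(rbind, st$reads)
  ## classify every backend read: header/zoom, chrom tree, R-tree node, data
  meta <- reads[, 1] < hd$chrom_tree_offset
  tree <- reads[, 1] >= hd$chrom_tree_offset & reads[, 1] < hd$full_data_offset
  index <- reads[, 1] >= hd$full_index_offset
  data_blocks <- !meta & !tree & !index
  expect_equal(sum(data_blocks), 1)
  expect_equal(reads[data_blocks, 1], b$offset)
  expect_equal(reads[data_blocks, 2], b$size)
  ## far less than the file was touched
  expect_lt(st$bytes_fetched, 0.05 * file.size(fx$path))
})
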