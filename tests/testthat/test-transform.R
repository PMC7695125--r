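# Frames used across the alignment tests; the expected partitions were
# derived with the per-base oracle (expand each track to per-base arrays,
# group maximal runs of identical column vectors).

frameA <- intervalFrame("chr1", 0, 10, S4Vectors::DataFrame(value = 2))
frameB <- intervalFrame("chr1", 5, 15, S4Vectors::DataFrame(value = 4))

test_that("disjoin aligns overlapping tracks on their boundary partition", {
  al <- disjoinFrames(list(A = frameA, B = frameB),
                      genomicQuery("chr1", 0, 15))
  df <- as.data.frame(al)
  expect_equal(df$start, c(0, 5, 10))
  expect_equal(df$end, c(5, 10, 15))
  expect_equal(df$A, c(2, 2, NA))
  expect_equal(df$B, c(NA, 4, 4))
})

test_that("single-source disjoin is the identity (clipped to the query)", {
  f <- intervalFrame("chr1", c(2, 20), c(8, 30),
                     S4Vectors::DataFrame(value = c(1, 9)))
  al <- disjoinFrames(list(only = f), genomicQuery("chr1", 0, 25))
  df <- as.data.frame(al)
  expect_equal(df$start, c(2, 20))
  expect_equal(df$end, c(8, 25))     # clipped at the query end
  expect_equal(df$only, c(1, 9))
})

test_that("uncovered gaps produce no rows; within-source overlap is rejected", {
  a <- intervalFrame("chr1", 0, 5, S4Vectors::DataFrame(value = 1))
  b <- intervalFrame("chr1", 10, 15, S4Vectors::DataFrame(value = 9))
  al <- disjoinFrames(list(a = a, b = b), genomicQuery("chr1", 0, 15))
  df <- as.data.frame(al)
  expect_equal(nrow(df), 2)
  expect_false(any(df$start < 10 & df$end > 5))   # the gap [5,10) is absent
  expect_equal(sum(is.na(df$a)) + sum(is.na(df$b)), 2)

  bad <- intervalFrame("chr1", c(0, 5), c(10, 15),
                       S4Vectors::DataFrame(value = c(1, 2)))
  expect_error(disjoinFrames(list(x = bad), genomicQuery("chr1", 0, 20)),
               class = "trackserve_overlap_within_source")
})

test_that("per-base expansion of aligned frames reproduces the sources exactly", {
  set.seed(201)
  for (rep in 1:20) {
    mk <- function() {
      s <- numeric(); e <- numeric(); pos <- 0
      while (pos < 180) {
        pos <- pos + sample(0:20, 1)
        len <- sample(1:15, 1)
        if (pos + len > 200) break
        s <- c(s, pos); e <- c(e, pos + len)
        pos <- pos + len
      }
      intervalFrame("chr1", s, e,
                    S4Vectors::DataFrame(value = stats::runif(length(s))))
    }
    fs <- list(x = mk(), y = mk())
    q <- genomicQuery("chr1", 0, 200)
    al <- disjoinFrames(fs, q)
    for (nm in names(fs)) {
      want <- perBaseExpand(frameStart(fs[[nm]]), frameEnd(fs[[nm]]),
                            frameValues(fs[[nm]])$value, 0, 200)
      got <- perBaseExpand(frameStart(al), frameEnd(al),
                           frameValues(al)[[nm]], 0, 200)
      ## aligned rows exist only where >= 1 source covers; restrict to those
      covered <- !is.na(perBaseExpand(frameStart(al), frameEnd(al),
                                      rep(1, length(al)), 0, 200))
      expect_identical(got[covered], want[covered])
      expect_true(all(is.na(want[!covered]) | !is.na(got[!covered]) == FALSE))
    }
    ## partition validity: disjoint sorted rows
    expect_true(all(frameStart(al)[-1] >= frameEnd(al)[-length(al)]))
  }
})

test_that("row-wise functions apply across measurements with missing propagation", {
  al <- disjoinFrames(list(A = frameA, B = frameB),
                      genomicQuery("chr1", 0, 15))
  spec <- computeSpec("d", c("A", "B"), function(v) diff(v))
  out <- applyCompute(al, spec)
  expect_equal(frameValues(out)$d, c(NA, 2, NA))

  spec0 <- computeSpec("d0", c("A", "B"), function(v) diff(v),
                       missing = "fill_zero")
  expect_equal(frameValues(applyCompute(al, spec0))$d0, c(-2, 2, 4))

  specd <- computeSpec("dd", c("A", "B"), function(v) diff(v),
                       missing = "drop_row")
  outd <- applyCompute(al, specd)
  expect_equal(length(outd), 1)
  expect_equal(frameStart(outd), 5)
})

test_that("column-wise functions transform whole columns (mean-centering)", {
  f1 <- intervalFrame("chr1", c(0, 10, 20), c(10, 20, 30),
                      S4Vectors::DataFrame(value = c(1, 2, 3)))
  al <- disjoinFrames(list(s = f1), genomicQuery("chr1", 0, 30))
  spec <- computeSpec("norm", "s", function(col) col - mean(col),
                      axis = "along_rows")
  out <- applyCompute(al, spec)
  expect_equal(frameValues(out)[["norm.s"]], c(-1, 0, 1))
})

test_that("failing or shape-violating functions raise spec-labelled errors", {
  al <- disjoinFrames(list(A = frameA, B = frameB),
                      genomicQuery("chr1", 0, 15))
  boom <- computeSpec("boomspec", c("A", "B"),
                      function(v) stop("deliberate"))
  err <- tryCatch(applyCompute(al, boom), error = function(e) e)
  expect_s3_class(err, "trackserve_compute_error")
  expect_match(conditionMessage(err), "boomspec")

  ragged <- computeSpec("rag", c("A", "B"),
                        function(v) if (is.na(v[1])) c(1, 2) else 3)
  expect_error(applyCompute(al, ragged), class = "trackserve_shape_error")
})

## catalog-level evaluation over real files

makeComputedCatalog <- function() {
  if (is.null(.fx$computed_catalog)) {
    a <- fixtureSignal("cm_a", seed = 41, chromSizes = c(chr1 = 60000L))
    b <- fixtureSignal("cm_b", seed = 43, chromSizes = c(chr1 = 60000L))
    catalog <- measurementCatalog()
    catalog <- addMeasurement(catalog, fileMeasurement("a", a$path, "bigwig"))
    catalog <- addMeasurement(catalog, fileMeasurement("b", b$path, "bigwig"))
    .fx$computed_catalog <- list(catalog = catalog, a = a, b = b)
  }
  .fx$computed_catalog
}

test_that("lazy evaluation equals the eagerly precomputed transformation", {
  cc <- makeComputedCatalog()
  catalog <- addComputedMeasurement(
    cc$catalog, computeSpec("mean2", c("a", "b"),
                            function(v) mean(v), missing = "drop_row"))
  set.seed(301)
  for (i in 1:25) {
    s <- sample(0:55000, 1); e <- s + sample(500:5000, 1)
    lazy <- evaluateComputed(getMeasurement(catalog, "mean2"), catalog,
                             genomicQuery("chr1", s, e))
    ## eager oracle: per-base expansion of the ground truths
    pa <- perBaseExpand(frameStart(cc$a$truth), frameEnd(cc$a$truth),
                        frameValues(cc$a$truth)$value, s, e)
    pb <- perBaseExpand(frameStart(cc$b$truth), frameEnd(cc$b$truth),
                        frameValues(cc$b$truth)$value, s, e)
    eager <- (pa + pb) / 2
    got <- perBaseExpand(frameStart(lazy), frameEnd(lazy),
                         frameValues(lazy)$mean2, s, e)
    expect_identical(got, eager)
  }
})

test_that("identity computed measurement equals querying the source directly", {
  cc <- makeComputedCatalog()
  catalog <- addComputedMeasurement(
    cc$catalog, computeSpec("ident", "a", function(v) v))
  q <- genomicQuery("chr1", 1000, 9000)
  direct <- trackserve:::queryRawMeasurement(cc$catalog, "a", q)
  viaSpec <- evaluateComputed(getMeasurement(catalog, "ident"), catalog, q)
  ## identity spec yields the clipped partition of the same data
  pbDirect <- perBaseExpand(frameStart(direct), frameEnd(direct),
                            frameValues(direct)$value, 1000, 9000)
  pbSpec <- perBaseExpand(frameStart(viaSpec), frameEnd(viaSpec),
                          frameValues(viaSpec)$ident, 1000, 9000)
  expect_identical(pbSpec, pbDirect)
})

test_that("computed-over-computed recurses and matches manual composition", {
  cc <- makeComputedCatalog()
  catalog <- addComputedMeasurement(
    cc$catalog, computeSpec("sum2", c("a", "b"), sum, missing = "drop_row"))
  catalog <- addComputedMeasurement(
    catalog, computeSpec("half", "sum2", function(v) v / 2))
  q <- genomicQuery("chr1", 0, 30000)
  got <- evaluateComputed(getMeasurement(catalog, "half"), catalog, q)
  pa <- perBaseExpand(frameStart(cc$a$truth), frameEnd(cc$a$truth),
                      frameValues(cc$a$truth)$value, 0, 30000)
  pb <- perBaseExpand(frameStart(cc$b$truth), frameEnd(cc$b$truth),
                      frameValues(cc$b$truth)$value, 0, 30000)
  want <- (pa + pb) / 2
  pbGot <- perBaseExpand(frameStart(got), frameEnd(got),
                         frameValues(got)$half, 0, 30000)
  expect_identical(pbGot, want)
})

test_that("specs referencing unknown sources fail with UnknownMeasurement", {
  cc <- makeComputedCatalog()
  expect_error(
    addComputedMeasurement(cc$catalog,
                           computeSpec("bad", c("a", "ghost"), sum)),
    class = "trackserve_unknown_measurement")
  sp <- computeSpec("later", c("ghost"), sum)
  expect_error(evaluateComputed(sp, cc$catalog, genomicQuery("chr1", 0, 10)),
               class = "trackserve_unknown_measurement")
})

test_that("source order permutations never change evaluated values", {
  cc <- makeComputedCatalog()
  q <- genomicQuery("chr1", 2000, 12000)
  c1 <- addComputedMeasurement(cc$catalog,
                               computeSpec("m", c("a", "b"), function(v)
                                 mean(v), missing = "drop_row"))
  c2 <- addComputedMeasurement(cc$catalog,
                               computeSpec("m", c("b", "a"), function(v)
                                 mean(v), missing = "drop_row"))
  r1 <- evaluateComputed(getMeasurement(c1, "m"), c1, q)
  r2 <- evaluateComputed(getMeasurement(c2, "m"), c2, q)
  expect_identical(frameValues(r1)$m, frameValues(r2)$m)
  expect_identical(frameStart(r1), frameStart(r2))
})
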