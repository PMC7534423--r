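# one small error-free simulation shared by the classification tests
sm <- small_sim(seed = 71, chrom = 150000, coverage = 3)
UNIT <- RepeatUnit(sm$cfg$unit)
IDX <- buildAnchorIndex(sm$sim$assembly)
LOCI <- findInterstitialLoci(sm$sim$assembly, UNIT)

test_that("the read length filter is strictly greater-than", {
  reads <- Biostrings::DNAStringSet(c(a = randomDNA(39999, seed = 73),
    b = randomDNA(40000), c = randomDNA(40001)))
  kept <- filterReadsByLength(reads, 40000)
  expect_identical(names(kept), "c")
  expect_identical(names(filterReadsByLength(reads, 0)), c("a", "b", "c"))
  expect_length(filterReadsByLength(Biostrings::DNAStringSet(), 40000), 0L)
})

test_that("anchor index keeps exactly the k-mers unique genome-wide", {
  two <- Biostrings::DNAStringSet(c(a = randomDNA(5000, seed = 75)))
  two <- c(two, Biostrings::DNAStringSet(c(b = as.character(two[[1]]))))
  expect_equal(anchorCount(buildAnchorIndex(two)), 0L) # nothing unique

  polyA <- Biostrings::DNAStringSet(c(a = strrep("A", 2000)))
  expect_equal(anchorCount(buildAnchorIndex(polyA)), 0L)

  one <- Biostrings::DNAStringSet(c(a = randomDNA(100000, seed = 77)))
  idx <- buildAnchorIndex(one, k = 21)
  expect_gt(anchorCount(idx), 0.99 * (100000 - 21 + 1))
  expect_lte(anchorCount(idx), 100000 - 21 + 1)

  # exhaustive string-level oracle on a small sequence
  s <- randomDNA(3000, seed = 79)
  k <- 15L
  kmers <- substring(s, 1:(3000 - k + 1), k:3000)
  canon <- pmin(kmers, vapply(kmers, revComp, character(1)))
  uniq <- names(table(canon))[table(canon) == 1]
  idx2 <- buildAnchorIndex(Biostrings::DNAStringSet(c(a = s)), k = k)
  expect_equal(anchorCount(idx2), length(uniq))
  expect_error(buildAnchorIndex(one, k = 11), ">= 15")
})

test_that("a read crossing a chromosome end is telomere support with its arm", {
  chrom <- as.character(sm$sim$assembly[["X"]])
  n <- nchar(chrom)
  read <- substr(chrom, n - 60000 + 1, n) # array flush with the 3' terminus
  cls <- classifyRead(read, UNIT, IDX, LOCI, read_id = "endread")
  expect_identical(cls$label, "telomere_at_end")
  expect_identical(cls$arm, "X")
  expect_lte(cls$read_length - cls$array_end, 500)

  cls2 <- classifyRead(revComp(read), UNIT, IDX, LOCI)
  expect_identical(cls2$label, "telomere_at_start")
  expect_identical(cls2$arm, "X")

  # a read without any unit copies
  mid <- substr(chrom, 50000, 95000)
  expect_identical(classifyRead(mid, UNIT, IDX, LOCI)$label, "no_array")
})

test_that("a two-arm fusion read is chimeric with both segments reported", {
  x <- as.character(sm$sim$assembly[["X"]])
  r2 <- as.character(sm$sim$assembly[["2R"]])
  # ~39 kb ending at the 2R terminus (carries its array) + ~23 kb of X core
  seg1 <- substr(r2, nchar(r2) - 39000 + 1, nchar(r2))
  seg2 <- substr(x, 40000, 40000 + 23000 - 1)
  cls <- classifyRead(paste0(seg2, seg1), UNIT, IDX, LOCI,
    read_id = "chimera")
  expect_identical(cls$label, "chimeric")
  segs <- strsplit(cls$segments, ";")[[1]]
  arms <- vapply(strsplit(segs, ":"), `[`, character(1), 1)
  expect_setequal(arms, c("X", "2R"))
  spans <- as.integer(vapply(strsplit(segs, ":"), `[`, character(1), 3))
  expect_equal(sort(spans), c(23000, 39000 - 3100), tolerance = 0.06)

  # raising the span threshold never increases chimeric calls
  spansLadder <- c(5000, 10000, 20000, 26000)
  calls <- vapply(spansLadder, function(ms)
    classifyRead(paste0(seg2, seg1), UNIT, IDX, LOCI,
      min_chimera_span = ms)$label == "chimeric", logical(1))
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("reads over an interstitial locus are excluded from support", {
  x <- as.character(sm$sim$assembly[["X"]])
  loc <- LOCI[as.character(GenomicRanges::seqnames(LOCI)) == "X"][1]
  a <- GenomicRanges::start(loc); b <- GenomicRanges::end(loc)
  read <- substr(x, a - 20000, b + 20000) # array internal to the read
  cls <- classifyRead(read, UNIT, IDX, LOCI)
  expect_identical(cls$label, "interstitial")

  # even an array at the read's terminus is rejected when it projects
  # onto the known locus
  readEdge <- substr(x, a - 45000, b - 15) # read ends inside the locus array
  clsEdge <- classifyRead(readEdge, UNIT, IDX, LOCI)
  expect_identical(clsEdge$label, "interstitial")
})

test_that("every read receives exactly one known label", {
  keep <- filterReadsByLength(sm$rd$reads, 40000)
  cls <- classifyReads(keep, UNIT, IDX, LOCI)
  expect_equal(nrow(cls), length(keep))
  expect_true(all(cls$label %in% c("telomere_at_start", "telomere_at_end",
    "interstitial", "chimeric", "ambiguous", "no_array")))
  expect_equal(sum(table(cls$label)), length(keep))
})

test_that("support summaries count and average per arm", {
  mk <- function(arm, label, len) data.frame(read_id = "r",
    read_length = len, label = label, arm = arm, array_start = 1L,
    array_end = 93L, copy_number = 3, identity = 1, segments = "",
    stringsAsFactors = FALSE)
  cls <- rbind(
    do.call(rbind, replicate(6, mk("X", "telomere_at_start", 50000),
      simplify = FALSE)),
    do.call(rbind, replicate(4, mk("X", "telomere_at_end", 50000),
      simplify = FALSE)),
    mk("X", "chimeric", 70000), mk("X", "interstitial", 70000))
  tab <- summarizeSupport(cls, min_length_note = 40000)
  expect_equal(tab$n_reads_beginning_with_TRU[tab$arm == "X"], 6L)
  expect_equal(tab$n_reads_terminating_with_TRU[tab$arm == "X"], 4L)
  expect_match(attr(tab, "footnote"), "40000")

  empty <- summarizeSupport(cls[0, ], arms = c("X", "2R"))
  expect_equal(empty$n_reads_beginning_with_TRU, c(0L, 0L))

  cls3 <- rbind(mk("2L", "telomere_at_end", 50000),
    mk("2L", "telomere_at_end", 60000), mk("2L", "telomere_at_end", 70000))
  expect_equal(summarizeSupport(cls3)$mean_read_length, 60000)
})

test_that("coverage is total read bases over genome length", {
  reads <- Biostrings::DNAStringSet(rep(randomDNA(1000, seed = 83), 10))
  expect_equal(computeCoverage(reads, 10000), 1)
  expect_equal(computeCoverage(Biostrings::DNAStringSet(), 10000), 0)
  expect_equal(computeCoverage(c(5000, 5000), 2000), 5)
})

test_that("in-silico end resection shortens terminal arrays only", {
  chrom <- as.character(sm$sim$assembly[["X"]])
  n0 <- nchar(chrom)
  loc <- LOCI[as.character(GenomicRanges::seqnames(LOCI)) == "X"][1]
  locLen <- GenomicRanges::width(loc)
  distEnd <- n0 - GenomicRanges::end(loc)
  telLen <- 3100
  prevLens <- NULL
  for (t in c(0, 500, 1500, 3000)) {
    trimmed <- substr(chrom, t + 1, n0 - t)
    arr <- annotateArrays(trimmed, UNIT, min_identity = 0.85)
    w <- GenomicRanges::width(arr)
    d <- pmin(GenomicRanges::start(arr) - 1,
      nchar(trimmed) - GenomicRanges::end(arr))
    termLens <- w[d <= 10]
    intLens <- w[d > 10]
    # terminal arrays shrink by ~min(t, length); the interstitial one does
    # not while the trim stays short of its distance to the end (detected
    # lengths are whole-copy multiples, so allow up to two unit lengths)
    expect_true(all(abs(termLens - max(telLen - t, 0)) <= 62))
    expect_true(all(abs(intLens - locLen) <= 62))
    expect_lt(t, distEnd)
    if (!is.null(prevLens) && length(termLens))
      expect_true(max(termLens) <= max(prevLens) + 2)
    if (length(termLens)) prevLens <- termLens
  }
})
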