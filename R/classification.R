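#' Keep reads strictly longer than a length threshold
#'
#' Long-read telomere validation restricts analysis to reads long enough
#' that a terminal repeat array plus an anchorable single-copy flank fit in
#' one read; the threshold is read strictly ("longer than").
#'
#' @param reads Named `DNAStringSet`.
#' @param min_length Length threshold in bp; reads of exactly this length
#'   are dropped.
#' @return The subset of `reads` with width > `min_length`, order preserved.
#' @export
filterReadsByLength <- function(reads, min_length) {
  stopifnot(min_length >= 0)
  reads <- Biostrings::DNAStringSet(reads)
  reads[Biostrings::width(reads) > min_length]
}

#' Build an index of k-mers unique across an assembly
#'
#' Scans every chromosome arm for k-mers occurring exactly once genome-wide
#' (a k-mer and its reverse complement count as one key; windows containing
#' N are skipped) and records the (arm, position) of each. Matching these
#' anchors in a read attributes its single-copy portions to arms.
#'
#' @param assembly Named `DNAStringSet` of chromosome arms.
#' @param k k-mer size, >= 15 (default 21).
#' @return An [AnchorIndex-class].
#' @export
buildAnchorIndex <- function(assembly, k = 21L) {
  k <- as.integer(k)
  if (k < 15L) stop("k must be >= 15")
  assembly <- Biostrings::DNAStringSet(assembly)
  hh <- list(); aa <- list(); pp <- list()
  for (i in seq_along(assembly)) {
    code <- codeDNA(assembly[[i]])
    hf <- rollingHashes(code, k)
    hr <- rollingHashesRC(code, k)
    canon <- pmin(hf, hr)
    ok <- !is.na(canon)
    hh[[i]] <- canon[ok]
    aa[[i]] <- rep(names(assembly)[i], sum(ok))
    pp[[i]] <- which(ok)
  }
  h <- unlist(hh); a <- unlist(aa); p <- unlist(pp)
  multi <- duplicated(h) | duplicated(h, fromLast = TRUE)
  h <- h[!multi]; a <- a[!multi]; p <- p[!multi]
  o <- order(h)
  new("AnchorIndex", k = k, hashes = h[o], arm = a[o], pos = as.integer(p[o]))
}

# anchor matches of a read against the index:
# data.frame(read_pos, arm, genome_pos), ordered by read_pos
anchorHits <- function(read, index) {
  code <- codeDNA(read)
  k <- index@k
  canon <- pmin(rollingHashes(code, k), rollingHashesRC(code, k))
  m <- length(canon)
  if (!m || !length(index@hashes))
    return(data.frame(read_pos = integer(0), arm = character(0),
      genome_pos = integer(0), stringsAsFactors = FALSE))
  idx <- findInterval(canon, index@hashes)
  hit <- !is.na(canon) & idx >= 1L & index@hashes[pmax(idx, 1L)] == canon
  hit[is.na(hit)] <- FALSE
  data.frame(
    read_pos = which(hit),
    arm = index@arm[idx[hit]],
    genome_pos = index@pos[idx[hit]],
    stringsAsFactors = FALSE)
}

#' Classify a long read by its repeat-array content
#'
#' The core per-read decision of terminus validation. A read supports a
#' telomere only when a repeat array sits flush with (within
#' `terminal_tolerance` of) one of the read's own termini; an array internal
#' to the read, or one whose flank projects onto a known interstitial locus,
#' does not count; a read whose single-copy portions anchor to two different
#' arms with substantial span on each is a chimeric artifact.
#'
#' Decision order: (1) no annotated array: `no_array`. (2) two or more
#' anchored segments on distinct arms, each spanning at least
#' `min_chimera_span` bases: `chimeric`. (3) each array is projected onto
#' the assembly through its nearest flank anchors; arrays landing within
#' `flank_window` of a known interstitial locus are discarded from terminal
#' consideration. (4) a remaining array within `terminal_tolerance` of the
#' read start (resp. end) gives `telomere_at_start` (resp.
#' `telomere_at_end`); an array touching both ends, or a read with no
#' anchored flank, is `ambiguous`. (5) otherwise `interstitial`. The arm is
#' the majority-anchor arm of the flank.
#'
#' @param read A `DNAString` or character(1).
#' @param unit A [RepeatUnit-class].
#' @param index An [AnchorIndex-class] built from the assembly.
#' @param interstitial `GRanges` of known interstitial loci (seqnames =
#'   arms), e.g. from [findInterstitialLoci()]; may be empty.
#' @param terminal_tolerance Max distance (bp) between array edge and read
#'   terminus (default 500; ONT read ends carry adapter/noise).
#' @param min_chimera_span Minimum anchored span (bp) per arm to call a
#'   chimera (default 10,000).
#' @param flank_window Window (bp) around an interstitial locus within which
#'   a projected array is attributed to it (default 5,000).
#' @param min_identity,min_copies Array emission thresholds for the read
#'   (defaults 0.75 and 3, the raw-read settings).
#' @param min_run_anchors Minimum anchors per segment run; shorter runs are
#'   treated as noise (default 5).
#' @param read_id Identifier used in the result row.
#' @return One-row `data.frame`: `read_id`, `read_length`, `label`, `arm`,
#'   `array_start`, `array_end`, `copy_number`, `identity`, `segments`
#'   (semicolon-separated `arm:start-end:anchored_bases`).
#' @export
classifyRead <- function(read, unit, index, interstitial = NULL,
                         terminal_tolerance = 500L,
                         min_chimera_span = 10000L, flank_window = 5000L,
                         min_identity = 0.75, min_copies = 3,
                         min_run_anchors = 5L, read_id = "read") {
  s <- toupper(as.character(read))
  n <- nchar(s)
  row <- function(label, arm = NA_character_, arr = NULL, segments = "") {
    data.frame(read_id = read_id, read_length = n, label = label, arm = arm,
      array_start = if (is.null(arr)) NA_integer_ else arr$start,
      array_end = if (is.null(arr)) NA_integer_ else arr$end,
      copy_number = if (is.null(arr)) NA_real_ else arr$copy_number,
      identity = if (is.null(arr)) NA_real_ else arr$mean_identity,
      segments = segments, stringsAsFactors = FALSE)
  }

  gr <- annotateArrays(s, unit, min_identity = min_identity,
    min_copies = min_copies, seq_id = read_id)
  if (!length(gr)) return(row("no_array"))
  arrays <- data.frame(
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    copy_number = gr$copy_number, mean_identity = gr$mean_identity)

  anch <- anchorHits(s, index)
  if (nrow(anch)) {
    inArray <- rep(FALSE, nrow(anch))
    for (i in seq_len(nrow(arrays)))
      inArray <- inArray | (anch$read_pos + index@k - 1L >= arrays$start[i] &
        anch$read_pos <= arrays$end[i])
    anch <- anch[!inArray, , drop = FALSE]
  }

  segs <- anchorSegments(anch, index@k, min_run_anchors)
  segTxt <- if (nrow(segs)) paste(sprintf("%s:%d-%d:%d", segs$arm,
    segs$start, segs$end, segs$anchor_bases), collapse = ";") else ""

  big <- segs[segs$anchor_bases >= min_chimera_span, , drop = FALSE]
  if (length(unique(big$arm)) >= 2L)
    return(row("chimeric", NA_character_,
      arrays[which.max(arrays$copy_number), ], segTxt))

  armTab <- if (nrow(anch)) sort(table(anch$arm), decreasing = TRUE) else NULL
  arm <- if (is.null(armTab)) NA_character_ else
    sort(names(armTab)[armTab == max(armTab)], method = "radix")[1L]

  isInter <- vapply(seq_len(nrow(arrays)), function(i) {
    arrayNearLocus(arrays$start[i], arrays$end[i], anch, interstitial,
      flank_window)
  }, logical(1))

  term <- arrays[!isInter, , drop = FALSE]
  if (nrow(term)) {
    dStart <- term$start - 1L
    dEnd <- n - term$end
    both <- dStart <= terminal_tolerance & dEnd <= terminal_tolerance
    if (any(both)) return(row("ambiguous", arm, term[which(both)[1L], ], segTxt))
    atStart <- any(dStart <= terminal_tolerance)
    atEnd <- any(dEnd <= terminal_tolerance)
    if (atStart && atEnd)
      return(row("ambiguous", arm, term[which.min(dStart), ], segTxt))
    if (atStart || atEnd) {
      if (is.na(arm)) # flank anchors nowhere: conservative, not support
        return(row("ambiguous", NA_character_,
          term[which.max(term$copy_number), ], segTxt))
      i <- if (atStart) which.min(dStart) else which.min(dEnd)
      return(row(if (atStart) "telomere_at_start" else "telomere_at_end",
        arm, term[i, ], segTxt))
    }
  }
  row("interstitial", arm, arrays[which.max(arrays$copy_number), ], segTxt)
}

# collapse anchor hits into maximal same-arm runs (noise runs dropped,
# adjacent same-arm runs re-merged)
anchorSegments <- function(anch, k, min_run_anchors) {
  emptySeg <- data.frame(arm = character(0), start = integer(0),
    end = integer(0), anchor_bases = integer(0), n_anchors = integer(0),
    stringsAsFactors = FALSE)
  if (!nrow(anch)) return(emptySeg)
  r <- rle(anch$arm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(arm = r$values,
    start = anch$read_pos[starts],
    end = anch$read_pos[ends] + k - 1L,
    n_anchors = r$lengths, stringsAsFactors = FALSE)
  segs <- segs[segs$n_anchors >= min_run_anchors, , drop = FALSE]
  if (!nrow(segs)) return(emptySeg)
  # re-merge same-arm neighbours once noise runs are gone
  grp <- cumsum(c(1L, segs$arm[-1L] != segs$arm[-nrow(segs)]))
  segs <- do.call(rbind, lapply(split(segs, grp), function(g) {
    data.frame(arm = g$arm[1L], start = min(g$start), end = max(g$end),
      n_anchors = sum(g$n_anchors), stringsAsFactors = FALSE)
  }))
  segs$anchor_bases <- segs$end - segs$start + 1L
  segs[order(segs$start), c("arm", "start", "end", "anchor_bases",
    "n_anchors")]
}

# project an array edge onto the assembly through the nearest flank anchors
# and test proximity to a known interstitial locus
arrayNearLocus <- function(aStart, aEnd, anch, interstitial, flank_window) {
  if (is.null(interstitial) || !length(interstitial) || !nrow(anch))
    return(FALSE)
  for (edge in c(aStart, aEnd)) {
    proj <- projectReadPos(edge, anch)
    if (is.null(proj)) next
    loc <- interstitial[as.character(GenomicRanges::seqnames(interstitial)) ==
      proj$arm]
    if (!length(loc)) next
    if (any(proj$pos >= GenomicRanges::start(loc) - flank_window &
        proj$pos <= GenomicRanges::end(loc) + flank_window))
      return(TRUE)
  }
  FALSE
}

projectReadPos <- function(readPos, anch, n_near = 30L) {
  if (!nrow(anch)) return(NULL)
  o <- order(abs(anch$read_pos - readPos))
  near <- anch[o[seq_len(min(n_near, nrow(anch)))], , drop = FALSE]
  armTab <- sort(table(near$arm), decreasing = TRUE)
  arm <- names(armTab)[1L]
  near <- near[near$arm == arm, , drop = FALSE]
  dir <- if (nrow(near) >= 2L) {
    cv <- stats::cov(near$read_pos, near$genome_pos)
    if (is.na(cv) || cv >= 0) 1 else -1
  } else 1
  list(arm = arm,
    pos = stats::median(near$genome_pos + dir * (readPos - near$read_pos)))
}

#' Classify a set of reads
#'
#' Vectorised wrapper around [classifyRead()].
#'
#' @param reads Named `DNAStringSet`.
#' @inheritParams classifyRead
#' @param ... Passed to [classifyRead()].
#' @return `data.frame` with one row per read (see [classifyRead()]).
#' @export
classifyReads <- function(reads, unit, index, interstitial = NULL, ...) {
  reads <- Biostrings::DNAStringSet(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    classifyRead(reads[[i]], unit, index, interstitial,
      read_id = ids[i], ...)
  })
  do.call(rbind, rows)
}

#' Summarise per-arm telomere support
#'
#' Builds the per-arm support table: for each chromosome arm, the number of
#' reads beginning with the repeat unit, the number terminating with it, and
#' the mean length of those reads. Chimeric, interstitial, ambiguous and
#' array-free reads are excluded from the counts.
#'
#' @param classifications `data.frame` from [classifyReads()].
#' @param arms Optional character vector of arms to report (zero rows for
#'   arms without support); defaults to the arms observed among supporting
#'   reads.
#' @param min_length_note Optional length filter (bp) recorded as the
#'   table's footnote attribute.
#' @return `data.frame` with columns `arm`, `n_reads_beginning_with_TRU`,
#'   `n_reads_terminating_with_TRU`, `mean_read_length` (input units, `NA`
#'   when an arm has no supporting reads); the footnote is in
#'   `attr(, "footnote")`.
#' @export
summarizeSupport <- function(classifications, arms = NULL,
                             min_length_note = NULL) {
  sup <- classifications[classifications$label %in%
    c("telomere_at_start", "telomere_at_end") &
    !is.na(classifications$arm), , drop = FALSE]
  if (is.null(arms))
    arms <- sort(unique(sup$arm))
  rows <- lapply(arms, function(a) {
    sa <- sup[sup$arm == a, , drop = FALSE]
    nb <- sum(sa$label == "telomere_at_start")
    nt <- sum(sa$label == "telomere_at_end")
    data.frame(arm = a,
      n_reads_beginning_with_TRU = nb,
      n_reads_terminating_with_TRU = nt,
      mean_read_length = if (nb + nt > 0) mean(sa$read_length) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(arm = character(0), n_reads_beginning_with_TRU = integer(0),
      n_reads_terminating_with_TRU = integer(0),
      mean_read_length = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(min_length_note))
    attr(out, "footnote") <- sprintf(
      "Only reads longer than %d bp were analyzed.",
      as.integer(min_length_note))
  out
}

#' Fold coverage of a read set over a genome
#'
#' @param reads `DNAStringSet` (or vector of read lengths).
#' @param genome_length Genome size in bp, > 0.
#' @return Total read bases / `genome_length`.
#' @export
computeCoverage <- function(reads, genome_length) {
  stopifnot(genome_length > 0)
  w <- if (is.numeric(reads)) reads else
    Biostrings::width(Biostrings::DNAStringSet(reads))
  sum(as.numeric(w)) / genome_length
}
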