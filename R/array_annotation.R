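#' Annotate tandem arrays of a repeat unit in a sequence
#'
#' Native tandem-array annotation: exact k-mer seeds drawn from a tandem
#' concatenation of the unit (so every rotation of the unit is seeded) are
#' matched on both strands, seed hits separated by at most `max_gap` are
#' chained into candidate arrays, and each candidate is scored by one
#' semi-global alignment against a tandem reference of the unit. Arrays
#' reaching `min_identity` and `min_copies` are emitted, sorted by start,
#' as a disjoint interval set (overlapping calls on opposite strands are
#' resolved in favour of the longer, then higher-identity, array).
#'
#' Identity is matches / alignment columns, so indels count against it.
#' With the default `k = 12`, an exact 12-mer survives ~10% per-base read
#' error often enough that any array of >= 3 copies is seeded.
#'
#' @param seq A `DNAString`, character(1), or single-sequence `DNAStringSet`.
#' @param unit A [RepeatUnit-class].
#' @param min_identity Minimum mean identity (default 0.75, the raw-read
#'   setting; use 0.9 for assemblies).
#' @param min_copies Minimum copy number (span / unit length; default 3).
#' @param max_gap Maximum gap (bp) bridged when chaining seed hits; default
#'   two unit lengths (the unit-dimer scale), so a substitution-dense patch
#'   inside a divergent array does not split the call.
#' @param seed_k Seed k-mer size (default 12; capped at the unit length).
#' @param seq_id Sequence name used in the result (defaults to the name of
#'   `seq` or `"seq"`).
#' @return A [GenomicRanges::GRanges] (1-based) with metadata columns
#'   `unit`, `copy_number`, `mean_identity`, `name`, `score`
#'   (`round(1000 * mean_identity)`).
#' @examples
#' u <- RepeatUnit("GTTCCTATAGCTTCTCTCACTCAAGTAGCCT")
#' annotateArrays(strrep(unitCanonical(u), 10), u)
#' @export
annotateArrays <- function(seq, unit, min_identity = 0.75, min_copies = 3,
                           max_gap = NULL, seed_k = 12L, seq_id = NULL) {
  stopifnot(is(unit, "RepeatUnit"))
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    if (is.null(seq_id)) seq_id <- names(seq)
    seq <- seq[[1L]]
  }
  s <- toupper(as.character(seq))
  if (is.null(seq_id) || !length(seq_id)) seq_id <- "seq"
  n <- nchar(s)
  L <- unitLength(unit)
  u <- unitCanonical(unit)
  if (is.null(max_gap)) max_gap <- 2L * L

  empty <- GenomicRanges::GRanges(seqinfo = seqInfoFor(seq_id, n))
  if (L > n || n < seed_k) return(empty)
  k <- min(seed_k, L)

  # all k-mers of every rotation of the unit, both strands
  tandem <- strrep(u, ceiling((k - 1L) / L) + 1L)
  fwdSet <- unique(rollingHashes(codeDNA(tandem), k))
  revSet <- unique(rollingHashes(codeDNA(revComp(tandem)), k))

  h <- rollingHashes(codeDNA(s), k)
  hits <- list("+" = which(h %in% fwdSet), "-" = which(h %in% revSet))

  cand <- list()
  for (strand in names(hits)) {
    pos <- hits[[strand]]
    if (!length(pos)) next
    grp <- cumsum(c(1L, diff(pos) > max_gap + k))
    for (g in split(pos, grp)) {
      a <- min(g); b <- max(g) + k - 1L
      # snap to whole unit copies: a flank base can continue the tandem
      # pattern by chance and drag the seed chain past the last full copy
      excess <- (b - a + 1L) %% L
      if (excess) {
        if (strand == "+") b <- b - excess else a <- a + excess
      }
      span <- b - a + 1L
      if (span / L < min_copies) next
      refStrand <- if (strand == "+") u else revComp(u)
      ident <- arrayIdentity(substr(s, a, b), refStrand, L)
      if (ident < min_identity) next
      cand[[length(cand) + 1L]] <- list(
        start = a, end = b, strand = strand,
        copy_number = span / L, mean_identity = ident)
    }
  }
  if (!length(cand)) return(empty)

  df <- do.call(rbind, lapply(cand, as.data.frame))
  # disjointness: greedily keep longer (then higher-identity) arrays
  df <- df[order(-(df$end - df$start), -df$mean_identity, df$start), ,
    drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(df)) > i)
    ov <- df$start[later] <= df$end[i] & df$end[later] >= df$start[i]
    keep[later[ov]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]

  GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    unit = u,
    copy_number = df$copy_number,
    mean_identity = df$mean_identity,
    name = u,
    score = as.integer(round(1000 * df$mean_identity)),
    seqinfo = seqInfoFor(seq_id, n))
}

seqInfoFor <- function(seq_id, n) {
  GenomeInfoDb::Seqinfo(seqnames = as.character(seq_id), seqlengths = n)
}

# one semi-global alignment of the array region against a tandem reference
# of the unit (phase absorbed by the local subject ends)
arrayIdentity <- function(region, unitStrand, L) {
  ncop <- ceiling(nchar(region) / L) + 2L
  ref <- strrep(unitStrand, ncop)
  pa <- Biostrings::pairwiseAlignment(region, ref, type = "global-local",
    substitutionMatrix = unitSubstitutionMatrix(),
    gapOpening = 4, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / cols
}

#' Find interstitial (subtelomeric) repeat loci in an assembly
#'
#' Interstitial telomeric sequences — arrays of the unit lying well inside a
#' chromosome rather than at its terminus — are the main confounder when
#' counting telomere-supporting reads. This reports every annotated array
#' whose interval lies entirely more than `interstitial_min_distance` from
#' both ends of its chromosome, with its distance to the nearest end and the
#' maximal per-copy identity to the unit.
#'
#' @param assembly Named `DNAStringSet`.
#' @param unit A [RepeatUnit-class].
#' @param interstitial_min_distance Minimum distance (bp) from both
#'   chromosome ends (default 10,000).
#' @param min_identity,min_copies Passed to [annotateArrays()] (assembly
#'   defaults 0.9 and 3).
#' @return A `GRanges` with metadata columns
#'   `distance_to_nearest_chromosome_end`, `max_identity_to_unit`,
#'   `copy_number`, `mean_identity`.
#' @export
findInterstitialLoci <- function(assembly, unit,
                                 interstitial_min_distance = 10000L,
                                 min_identity = 0.9, min_copies = 3) {
  assembly <- Biostrings::DNAStringSet(assembly)
  loci <- list()
  for (i in seq_along(assembly)) {
    seqid <- names(assembly)[i]
    n <- Biostrings::width(assembly)[i]
    arr <- annotateArrays(assembly[[i]], unit, min_identity = min_identity,
      min_copies = min_copies, seq_id = seqid)
    if (!length(arr)) next
    dStart <- GenomicRanges::start(arr) - 1L
    dEnd <- n - GenomicRanges::end(arr)
    inner <- dStart > interstitial_min_distance &
      dEnd > interstitial_min_distance
    arr <- arr[inner]
    if (!length(arr)) next
    arr$distance_to_nearest_chromosome_end <- pmin(dStart, dEnd)[inner]
    arr$max_identity_to_unit <- vapply(seq_along(arr), function(j) {
      region <- substr(as.character(assembly[[i]]),
        GenomicRanges::start(arr)[j], GenomicRanges::end(arr)[j])
      us <- if (as.character(GenomicRanges::strand(arr))[j] == "-")
        revComp(unitCanonical(unit)) else unitCanonical(unit)
      max(perCopyIdentities(region, us, unitLength(unit)))
    }, numeric(1))
    loci[[length(loci) + 1L]] <- arr
  }
  if (!length(loci))
    return(GenomicRanges::GRanges(
      distance_to_nearest_chromosome_end = integer(0),
      max_identity_to_unit = numeric(0)))
  ans <- suppressWarnings(do.call(c, loci))
  ans[order(as.character(GenomicRanges::seqnames(ans)),
    GenomicRanges::start(ans))]
}

# identity of each unit-length chunk of an array against the unit dimer
perCopyIdentities <- function(region, unitStrand, L) {
  nc <- max(1L, nchar(region) %/% L)
  starts <- seq.int(1L, by = L, length.out = nc)
  dimer <- strrep(unitStrand, 2L)
  vapply(substring(region, starts, pmin(starts + L - 1L, nchar(region))),
    function(chunk) {
      pa <- Biostrings::pairwiseAlignment(chunk, dimer,
        type = "global-local",
        substitutionMatrix = unitSubstitutionMatrix(),
        gapOpening = 4, gapExtension = 2)
      Biostrings::nmatch(pa) /
        nchar(as.character(Biostrings::alignedPattern(pa)))
    }, numeric(1), USE.NAMES = FALSE)
}
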