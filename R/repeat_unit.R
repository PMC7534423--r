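#' Canonicalize a tandem repeat unit over rotation and strand
#'
#' A tandem repeat unit has no intrinsic phase (any rotation describes the
#' same array) and no intrinsic strand. The canonical form is the
#' lexicographically smallest string among all rotations of the unit and all
#' rotations of its reverse complement, which gives every equivalent unit a
#' single unique representative. Idempotent.
#'
#' @param unit character(1) over {A,C,G,T}; lowercase accepted.
#' @return character(1), the canonical form.
#' @examples
#' canonicalizeUnit("GTAC") # "ACGT"
#' canonicalizeUnit("ACG") == canonicalizeUnit("CGA")
#' @export
canonicalizeUnit <- function(unit) {
  unit <- toupper(as.character(unit))
  if (length(unit) != 1L || is.na(unit) || !nzchar(unit))
    stop("unit must be a single non-empty string")
  if (grepl("[^ACGT]", unit))
    stop("unit must contain only A, C, G, T")
  cands <- c(rotationsOf(unit), rotationsOf(revComp(unit)))
  sort(cands, method = "radix")[1L]
}

rotationsOf <- function(s) {
  n <- nchar(s)
  i <- seq_len(n) - 1L
  paste0(substring(s, i + 1L, n), substring(s, 1L, i))
}

#' Consensus repeat unit from observed copies
#'
#' Builds a consensus unit from tandem copies extracted from an array (the
#' alignment-of-variants step). Copies may differ by substitutions and single
#' indels and may be given in arbitrary phase or strand. The procedure is:
#'
#' 1. each copy is canonicalized; the modal canonical string is the seed
#'    (ties broken lexicographically), so the result does not depend on the
#'    order copies are given in;
#' 2. each copy is re-phased to the rotation/strand with minimal edit
#'    distance to the seed;
#' 3. re-phased copies are globally aligned to the seed (star alignment) and
#'    a column-majority consensus is called, ties between bases broken
#'    alphabetically (A < C < G < T); a deletion column is called only on a
#'    strict majority, and an insertion between seed columns only when more
#'    than half of the copies carry one.
#'
#' @param copies character vector (or `DNAStringSet`) of >= 3 unit copies,
#'   each within 20 percent of the median copy length.
#' @return A [RepeatUnit-class]; `variants` holds the distinct input copies
#'   verbatim (original phase/strand), in order of first occurrence.
#' @examples
#' consensusUnit(rep("GTTCCTATAGCTTCTCTCACTCAAGTAGCCT", 5))
#' @export
consensusUnit <- function(copies) {
  copies <- toupper(as.character(copies))
  if (length(copies) < 3L)
    stop("insufficient data: need at least 3 copies, got ", length(copies))
  if (any(grepl("[^ACGT]", copies)))
    stop("copies must contain only A, C, G, T")
  med <- stats::median(nchar(copies))
  if (any(abs(nchar(copies) - med) > 0.2 * med))
    stop("copy lengths must be within 20% of the median (", med, " bp)")

  canon <- vapply(copies, canonicalizeUnit, character(1), USE.NAMES = FALSE)
  tab <- table(canon)
  top <- names(tab)[tab == max(tab)]
  seed <- sort(top, method = "radix")[1L]

  rephased <- vapply(copies, function(cp) {
    cands <- unique(c(rotationsOf(cp), rotationsOf(revComp(cp))))
    d <- utils::adist(cands, seed)[, 1L]
    best <- cands[d == min(d)]
    sort(best, method = "radix")[1L]
  }, character(1), USE.NAMES = FALSE)

  cons <- profileConsensus(seed, rephased)
  RepeatUnit(cons, variants = unique(copies))
}

# Star alignment of copies against a seed; column-majority call in seed
# coordinates with insertion slots between seed columns.
profileConsensus <- function(seed, copies) {
  m <- nchar(seed)
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 5L, ncol = m, dimnames = list(c(bases, "-"), NULL))
  insertions <- vector("list", length(copies)) # per copy: named char vec by slot

  submat <- unitSubstitutionMatrix()
  for (ci in seq_along(copies)) {
    cp <- copies[ci]
    if (cp == seed) {
      sc <- strsplit(seed, "")[[1L]]
      for (j in seq_len(m)) votes[sc[j], j] <- votes[sc[j], j] + 1L
      next
    }
    pa <- Biostrings::pairwiseAlignment(cp, seed,
      type = "global", substitutionMatrix = submat,
      gapOpening = 4, gapExtension = 2)
    pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    j <- 0L
    ins <- character()
    for (k in seq_along(sc)) {
      if (sc[k] == "-") {
        slot <- as.character(j)
        ins[slot] <- paste0(if (slot %in% names(ins)) ins[slot] else "", pc[k])
      } else {
        j <- j + 1L
        votes[pc[k], j] <- votes[pc[k], j] + 1L
      }
    }
    insertions[[ci]] <- ins
  }

  n <- length(copies)
  cols <- character(m)
  for (j in seq_len(m)) {
    bc <- votes[bases, j]
    top <- bases[bc == max(bc)][1L] # alphabetical tie-break, A<C<G<T
    cols[j] <- if (votes["-", j] > max(bc)) "" else top
  }
  out <- character(0)
  for (j in 0:m) {
    if (j > 0L) out <- c(out, cols[j])
    slot <- as.character(j)
    ins <- vapply(insertions, function(x) {
      if (!is.null(x) && slot %in% names(x)) x[[slot]] else ""
    }, character(1))
    ins <- ins[nzchar(ins)]
    if (length(ins) > n / 2) {
      tab <- table(ins)
      win <- names(tab)[tab == max(tab)]
      out <- c(out, sort(win, method = "radix")[1L])
    }
  }
  paste(out, collapse = "")
}

# match +2, mismatch -2; N never matches anything (including N)
unitSubstitutionMatrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(-2, 5L, 5L, dimnames = list(letters, letters))
  diag(mat) <- 2
  mat["N", "N"] <- -2
  mat
}

#' Plain-text alignment report of unit variants
#'
#' Renders the variant alignment behind a [consensusUnit()] call: each
#' re-phased variant on its own row under the consensus, mismatches in
#' lowercase.
#'
#' @param unit A [RepeatUnit-class].
#' @return character vector of report lines.
#' @export
formatUnitAlignment <- function(unit) {
  stopifnot(is(unit, "RepeatUnit"))
  cons <- unitCanonical(unit)
  lines <- c(sprintf("consensus  %s", cons))
  for (v in unitVariants(unit)) {
    cands <- unique(c(rotationsOf(v), rotationsOf(revComp(v))))
    d <- utils::adist(cands, cons)[, 1L]
    ph <- sort(cands[d == min(d)], method = "radix")[1L]
    cc <- strsplit(cons, "")[[1L]]
    vc <- strsplit(ph, "")[[1L]]
    k <- min(length(cc), length(vc))
    vc[seq_len(k)] <- ifelse(vc[seq_len(k)] == cc[seq_len(k)],
      vc[seq_len(k)], tolower(vc[seq_len(k)]))
    lines <- c(lines, sprintf("variant    %s", paste(vc, collapse = "")))
  }
  lines
}
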