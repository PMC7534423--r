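#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' RepeatUnit: a canonical tandem repeat unit with its observed variants
#'
#' A `RepeatUnit` represents a short tandem repeat unit such as a telomeric
#' repeat unit (TRU). Because a tandem array has no defined phase or strand,
#' the unit is stored in a canonical form: the lexicographically smallest
#' string among all rotations of the unit and all rotations of its reverse
#' complement (see [canonicalizeUnit()]). Observed unit variants (e.g. the
#' 30/31/32 bp length variants seen at different chromosome ends) are kept
#' verbatim so reports can display them in their original phase.
#'
#' @slot canonical character(1). The canonical unit sequence (A/C/G/T).
#' @slot length integer(1). Unit length in bp; equals `nchar(canonical)`.
#' @slot variants character. Observed variant sequences, stored verbatim.
#'
#' @seealso [canonicalizeUnit()], [consensusUnit()]
#' @examples
#' RepeatUnit("GTTCCTATAGCTTCTCTCACTCAAGTAGCCT")
#' @export
setClass("RepeatUnit",
  representation(
    canonical = "character",
    length = "integer",
    variants = "character"
  )
)

setValidity("RepeatUnit", function(object) {
  msgs <- character()
  if (length(object@canonical) != 1L || !nzchar(object@canonical))
    msgs <- c(msgs, "'canonical' must be a single non-empty string")
  else {
    if (grepl("[^ACGT]", object@canonical))
      msgs <- c(msgs, "'canonical' must contain only A, C, G, T")
    else if (object@canonical != canonicalizeUnit(object@canonical))
      msgs <- c(msgs, "'canonical' is not in canonical form")
    if (object@length != nchar(object@canonical))
      msgs <- c(msgs, "'length' must equal nchar(canonical)")
    if (length(object@variants)) {
      vl <- nchar(object@variants)
      if (any(abs(vl - object@length) > 2L))
        msgs <- c(msgs, "every variant length must be within 2 bp of the unit length")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RepeatUnit
#'
#' @param unit character(1). A repeat unit in any phase/strand; it is
#'   canonicalized internally.
#' @param variants character. Observed variant sequences (kept verbatim).
#' @return A [RepeatUnit-class] object.
#' @export
RepeatUnit <- function(unit, variants = character()) {
  canon <- canonicalizeUnit(unit)
  new("RepeatUnit",
    canonical = canon,
    length = nchar(canon),
    variants = toupper(as.character(variants))
  )
}

#' @describeIn RepeatUnit-class canonical unit sequence
#' @param x A `RepeatUnit`.
#' @export
unitCanonical <- function(x) x@canonical

#' @describeIn RepeatUnit-class unit length in bp
#' @export
unitLength <- function(x) x@length

#' @describeIn RepeatUnit-class observed variants, verbatim
#' @export
unitVariants <- function(x) x@variants

setMethod("show", "RepeatUnit", function(object) {
  cat("RepeatUnit of length ", object@length, " bp\n", sep = "")
  cat("  canonical: ", object@canonical, "\n", sep = "")
  if (length(object@variants))
    cat("  variants:  ", length(object@variants), " observed\n", sep = "")
})

#' AnchorIndex: unique k-mer anchors for arm assignment
#'
#' An index of k-mers that occur exactly once across all chromosome arms of
#' an assembly (a k-mer and its reverse complement count as one key). Each
#' stored k-mer maps to its unique (arm, position); matching such anchors in
#' a read places the read's non-repetitive portion on a chromosome arm, which
#' is how reads are attributed to arms and how chimeric fusions of two arms
#' are detected.
#'
#' k-mers are encoded as base-4 integers stored in doubles (exact for
#' k <= 26), so lookups are exact, collision-free hash comparisons.
#'
#' @slot k integer(1). k-mer size (>= 15).
#' @slot hashes numeric. Sorted canonical k-mer codes (min of the forward and
#'   reverse-complement encodings).
#' @slot arm character. Arm identifier per stored k-mer.
#' @slot pos integer. 1-based start of the k-mer on its arm.
#'
#' @seealso [buildAnchorIndex()]
#' @export
setClass("AnchorIndex",
  representation(
    k = "integer",
    hashes = "numeric",
    arm = "character",
    pos = "integer"
  )
)

setValidity("AnchorIndex", function(object) {
  msgs <- character()
  if (object@k < 15L)
    msgs <- c(msgs, "'k' must be >= 15")
  n <- length(object@hashes)
  if (length(object@arm) != n || length(object@pos) != n)
    msgs <- c(msgs, "'hashes', 'arm' and 'pos' must have equal length")
  if (n > 1L && is.unsorted(object@hashes, strictly = TRUE))
    msgs <- c(msgs, "'hashes' must be strictly sorted (each k-mer unique)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AnchorIndex", function(object) {
  cat("AnchorIndex: ", length(object@hashes), " unique ", object@k,
    "-mers over ", length(unique(object@arm)), " arm(s)\n", sep = "")
})

#' @describeIn AnchorIndex-class k-mer size used by the index
#' @param x An `AnchorIndex`.
#' @export
anchorK <- function(x) x@k

#' @describeIn AnchorIndex-class number of anchors stored
#' @export
anchorCount <- function(x) length(x@hashes)
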