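#' Detect the primitive tandem-repeat period of a sequence window
#'
#' Scores every candidate period `p` by its shifted-match fraction: the
#' fraction of positions `i` with `base(i) == base(i + p)` (N never matches).
#' Reports the smallest *primitive* period in `[min_period, max_period]`
#' whose match fraction reaches `min_match`; a period is non-primitive when
#' some proper divisor `d` already explains the repeat, i.e. has match
#' fraction `>= min_match - 0.02` (the margin keeps a 31 bp unit from being
#' reported as 62).
#'
#' @param seq character(1) or `DNAString`; must be at least `3 * max_period`
#'   long so every candidate period is supported by >= 2 full shifts.
#' @param min_period,max_period Search range in bp.
#' @param min_match Minimum match fraction in `[0, 1]`.
#' @return A list of class `PeriodicityProfile`: `period` (integer or `NA`),
#'   `match_fraction`, `primitive`, and `profile` (match fraction for every
#'   period `1..max_period`).
#' @examples
#' detectPeriod(strrep("AC", 50), 1, 10, 0.9)$period # 2
#' @export
detectPeriod <- function(seq, min_period = 6L, max_period = 2000L,
                         min_match = 0.8) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (min_period < 1L || min_period > max_period)
    stop("need 1 <= min_period <= max_period")
  if (n < 3L * max_period)
    stop("insufficient data: window of ", n,
      " bp is shorter than 3 x max_period (", 3L * max_period, " bp)")
  x <- utf8ToInt(s)
  nCode <- utf8ToInt("N")
  profile <- vapply(seq_len(max_period), function(p) {
    a <- x[seq_len(n - p)]
    b <- x[seq.int(p + 1L, n)]
    sum(a == b & a != nCode) / (n - p)
  }, numeric(1))

  period <- NA_integer_
  for (p in seq.int(min_period, max_period)) {
    if (profile[p] < min_match) next
    divs <- seq_len(p - 1L)
    divs <- divs[p %% divs == 0L]
    if (any(profile[divs] >= min_match - 0.02)) next
    period <- p
    break
  }
  structure(list(
    period = period,
    match_fraction = if (is.na(period)) 0 else profile[period],
    primitive = !is.na(period),
    profile = profile
  ), class = "PeriodicityProfile")
}

#' @export
print.PeriodicityProfile <- function(x, ...) {
  if (is.na(x$period))
    cat("PeriodicityProfile: no period detected\n")
  else
    cat(sprintf("PeriodicityProfile: period %d bp (match fraction %.3f)\n",
      x$period, x$match_fraction))
  invisible(x)
}

#' Discover tandem repeat units at chromosome termini
#'
#' For each end of each assembly sequence, takes the terminal window (the
#' 3' window is reverse-complemented so both ends are scanned
#' terminus-inward), detects tandem periodicity, extracts consecutive unit
#' copies phased from the terminus, and calls their consensus. A terminal
#' array usually occupies only part of the window, so periodicity is probed
#' over a doubling ladder of terminus-proximal prefixes (1, 2, 4, ... kb up
#' to the window) and the shortest prefix showing a period wins; this keeps
#' a ~3 kb array detectable inside a 20 kb window.
#'
#' @param assembly Named `DNAStringSet` of assembled chromosomes/contigs.
#' @param window_bp Terminal window size (default 20,000 bp; covers both a
#'   ~30 bp unit and satellite units up to the period range).
#' @param min_period,max_period,min_match Passed to [detectPeriod()];
#'   defaults 6, 2000, 0.8.
#' @param max_copies Maximum unit copies fed to the consensus (default 50).
#' @return A named list of [RepeatUnit-class], one entry per terminus with
#'   detectable periodicity, named `"<seq_id>:start"` / `"<seq_id>:end"`.
#'   Ends without periodicity are absent.
#' @export
discoverTerminalUnits <- function(assembly, window_bp = 20000L,
                                  min_period = 6L, max_period = 2000L,
                                  min_match = 0.8, max_copies = 50L) {
  assembly <- Biostrings::DNAStringSet(assembly)
  out <- list()
  for (i in seq_along(assembly)) {
    s <- as.character(assembly[[i]])
    n <- nchar(s)
    w <- min(window_bp, n %/% 2L)
    windows <- list(
      start = substr(s, 1L, w),
      end = revComp(substr(s, n - w + 1L, n))
    )
    for (which_end in names(windows)) {
      unit <- terminalUnitFromWindow(windows[[which_end]], min_period,
        max_period, min_match, max_copies)
      if (!is.null(unit))
        out[[paste0(names(assembly)[i], ":", which_end)]] <- unit
    }
  }
  out
}

#' Detect tandem periodicity at a sequence terminus
#'
#' [detectPeriod()] scores a whole window, so a terminal array occupying
#' only part of it dilutes the match fraction below threshold. This variant
#' probes a doubling ladder of terminus-proximal prefixes (1, 2, 4, 8 kb up
#' to the window), capping the period range at a third of each prefix, and
#' returns the first prefix's result showing a period.
#'
#' @param win character(1): the terminal window, terminus first (reverse
#'   complement the 3' window before calling).
#' @inheritParams detectPeriod
#' @return A `PeriodicityProfile` (see [detectPeriod()]) with an extra
#'   `window_bp` element: the prefix length that revealed the period
#'   (`NA` if none did).
#' @export
detectTerminalPeriod <- function(win, min_period = 6L, max_period = 2000L,
                                 min_match = 0.8) {
  win <- toupper(as.character(win))
  w <- nchar(win)
  ladder <- unique(pmin(w, c(1000L, 2000L, 4000L, 8000L, w)))
  for (ws in ladder) {
    maxp <- min(max_period, ws %/% 3L)
    if (maxp < min_period) next
    prof <- detectPeriod(substr(win, 1L, ws), min_period, maxp, min_match)
    if (!is.na(prof$period)) {
      prof$window_bp <- ws
      return(prof)
    }
  }
  structure(list(period = NA_integer_, match_fraction = 0,
    primitive = FALSE, profile = NULL, window_bp = NA_integer_),
    class = "PeriodicityProfile")
}

terminalUnitFromWindow <- function(win, min_period, max_period, min_match,
                                   max_copies) {
  prof <- detectTerminalPeriod(win, min_period, max_period, min_match)
  if (is.na(prof$period)) return(NULL)
  copies <- extractPhasedCopies(win, prof$period, max_copies)
  if (length(copies) >= 3L) consensusUnit(copies) else NULL
}

# Chop the terminus-proximal sequence into period-length copies and keep the
# maximal initial run still resembling the first copy (tolerates ~30%
# per-copy divergence, i.e. well beyond polished ONT residual error).
extractPhasedCopies <- function(win, p, max_copies) {
  nc <- min(nchar(win) %/% p, max_copies)
  if (nc < 1L) return(character())
  starts <- seq.int(1L, by = p, length.out = nc)
  chunks <- substring(win, starts, starts + p - 1L)
  chunks <- chunks[!grepl("N", chunks, fixed = TRUE)]
  if (!length(chunks)) return(character())
  ref <- utf8ToInt(chunks[1L])
  keep <- vapply(chunks, function(ch) {
    mean(utf8ToInt(ch) != ref) <= 0.3
  }, logical(1))
  run <- cumprod(keep) > 0
  chunks[run]
}

#' Call terminal repeat arrays on assembly ends
#'
#' Annotates arrays of `unit` on each assembly sequence and reports, for
#' each terminus, whether an array lies within `terminal_tolerance` of it —
#' the assembly-level check that chromosome arms truly end in telomeric
#' repeats (a truncated assembly leaves its arrays tens of kb inside and
#' every call comes back `FALSE`).
#'
#' @param assembly Named `DNAStringSet`.
#' @param unit A [RepeatUnit-class].
#' @param terminal_tolerance Max distance (bp) between array edge and the
#'   sequence end (default 1000; assemblies may retain small non-telomeric
#'   overhangs).
#' @param min_identity,min_copies Array emission thresholds passed to
#'   [annotateArrays()] (defaults 0.9 and 3, the assembly settings).
#' @return A `data.frame` with one row per terminus: `seq_id`, `which_end`
#'   (`start`/`end`), `has_terminal_array`, `array_start`, `array_end`
#'   (1-based, `NA` when no array on the sequence), and
#'   `distance_to_terminus` (bp from the nearest array edge to that end).
#' @export
callAssemblyTermini <- function(assembly, unit, terminal_tolerance = 1000L,
                                min_identity = 0.9, min_copies = 3) {
  assembly <- Biostrings::DNAStringSet(assembly)
  rows <- list()
  for (i in seq_along(assembly)) {
    seqid <- names(assembly)[i]
    n <- Biostrings::width(assembly)[i]
    arr <- annotateArrays(assembly[[i]], unit,
      min_identity = min_identity, min_copies = min_copies)
    for (which_end in c("start", "end")) {
      if (length(arr)) {
        d <- if (which_end == "start") GenomicRanges::start(arr) - 1L
          else n - GenomicRanges::end(arr)
        j <- which.min(d)
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seqid, which_end = which_end,
          has_terminal_array = d[j] <= terminal_tolerance,
          array_start = GenomicRanges::start(arr)[j],
          array_end = GenomicRanges::end(arr)[j],
          distance_to_terminus = d[j],
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seqid, which_end = which_end,
          has_terminal_array = FALSE,
          array_start = NA_integer_, array_end = NA_integer_,
          distance_to_terminus = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
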