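#' Simulation configuration for telomere-bearing genomes and long reads
#'
#' Bundles and validates the parameters of the synthetic study design:
#' chromosome arms whose both termini carry tandem arrays of a telomeric
#' repeat unit, interstitial (subtelomeric) array loci tens of kb inside
#' two arms, and ONT-like long reads with substitution/indel errors, a
#' small chimeric fraction, and a length floor.
#'
#' Defaults emulate the validated study design at desk scale: five 300 kb
#' arms (X, 2R, 2L, 3R, 3L) rather than a full 172.6 Mb genome; 100 copies
#' of the 31 bp unit `GTTCCTATAGCTTCTCTCACTCAAGTAGCCT` per terminus
#' (kilobase-scale arrays) at 2 percent per-copy divergence; interstitial
#' loci 77.8 kb inside 2L and 78.1 kb inside X; reads of mean 55 kb
#' (sd 8 kb, minimum 40 kb) at 5-fold coverage with 4/3/3 percent
#' substitution/insertion/deletion error and 1 percent chimeras.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param arms Character vector of arm names.
#' @param chromosome_length Arm length in bp.
#' @param unit Repeat unit sequence (any phase/strand).
#' @param telomere_copies Unit copies per terminal array.
#' @param unit_divergence Per-base substitution rate within array copies.
#' @param interstitial_loci `data.frame` with columns `arm`, `distance`
#'   (bp from the telomeric end to the locus), `copies`.
#' @param read_length_mean,read_length_sd,read_length_min Read length
#'   distribution (bp); lengths below the minimum are redrawn.
#' @param error_sub,error_ins,error_del Per-base error rates.
#' @param chimera_fraction Fraction of reads that are two-arm fusions.
#' @param target_coverage Fold coverage to draw.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      arms = c("X", "2R", "2L", "3R", "3L"),
                      chromosome_length = 300000L,
                      unit = "GTTCCTATAGCTTCTCTCACTCAAGTAGCCT",
                      telomere_copies = 100L,
                      unit_divergence = 0.02,
                      interstitial_loci = data.frame(
                        arm = c("2L", "X"),
                        distance = c(77800L, 78100L),
                        copies = c(50L, 50L)),
                      read_length_mean = 55000,
                      read_length_sd = 8000,
                      read_length_min = 40000,
                      error_sub = 0.04, error_ins = 0.03, error_del = 0.03,
                      chimera_fraction = 0.01,
                      target_coverage = 5) {
  cfg <- list(seed = as.integer(seed), arms = as.character(arms),
    chromosome_length = as.integer(chromosome_length),
    unit = toupper(as.character(unit)),
    telomere_copies = as.integer(telomere_copies),
    unit_divergence = unit_divergence,
    interstitial_loci = interstitial_loci,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    read_length_min = read_length_min,
    error_sub = error_sub, error_ins = error_ins, error_del = error_del,
    chimera_fraction = chimera_fraction, target_coverage = target_coverage)
  rates <- c(cfg$unit_divergence, cfg$error_sub, cfg$error_ins,
    cfg$error_del, cfg$chimera_fraction)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop("all rates must be in [0, 1]")
  if (cfg$chromosome_length <= 0 || cfg$telomere_copies <= 0 ||
      cfg$read_length_min <= 0 || cfg$read_length_mean <= 0)
    stop("lengths must be positive")
  if (grepl("[^ACGT]", cfg$unit))
    stop("unit must contain only A, C, G, T")
  if (!length(cfg$arms) || anyDuplicated(cfg$arms))
    stop("arm names must be non-empty and unique")
  tl <- cfg$telomere_copies * nchar(cfg$unit)
  if (2L * tl >= cfg$chromosome_length)
    stop("terminal arrays do not fit in the chromosome length")
  il <- cfg$interstitial_loci
  if (nrow(il)) {
    if (!all(il$arm %in% cfg$arms))
      stop("interstitial locus arm not among 'arms'")
    if (any(il$distance + il$copies * nchar(cfg$unit) + tl >
        cfg$chromosome_length - tl))
      stop("interstitial locus does not fit inside the chromosome core")
  }
  structure(cfg, class = "SimConfig")
}

# set the RNG locally; returns a restore function for on.exit()
localSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

randomCoreDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tandem array of `copies` unit copies, each substituted at `rate`
mutatedArray <- function(unit, copies, rate) {
  s <- strrep(unit, copies)
  if (rate <= 0) return(s)
  x <- strsplit(s, "")[[1L]]
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(x[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

#' Simulate a telomere-bearing genome with truth annotations
#'
#' Builds each arm as `[terminal array][random core with optional
#' interstitial arrays][terminal array]`. The two terminal arrays of an arm
#' run in opposite orientations (the 5' array is the reverse complement of
#' the unit tandem), as telomeric repeats do; every array copy is mutated
#' at `unit_divergence`. Deterministic under the config seed.
#'
#' @param config A [simConfig()] object.
#' @return A list: `assembly` (named `DNAStringSet`), `truth` with
#'   `terminal` (`GRanges` of the terminal arrays, one per terminus, with
#'   `which_end`) and `interstitial` (`GRanges` of interstitial loci with
#'   `distance`), and `unit`.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  restore <- localSeed(config$seed)
  on.exit(restore())
  L <- nchar(config$unit)
  tl <- config$telomere_copies * L
  Lc <- config$chromosome_length
  seqs <- character(length(config$arms))
  termRows <- list(); interRows <- list()
  for (i in seq_along(config$arms)) {
    arm <- config$arms[i]
    core <- randomCoreDNA(Lc - 2L * tl)
    il <- config$interstitial_loci
    il <- il[il$arm == arm, , drop = FALSE]
    if (nrow(il)) for (j in seq_len(nrow(il))) {
      arr <- mutatedArray(config$unit, il$copies[j], config$unit_divergence)
      gEnd <- Lc - il$distance[j]           # 1-based genome end of locus
      gStart <- gEnd - nchar(arr) + 1L
      cStart <- gStart - tl                 # core coordinates
      substr(core, cStart, cStart + nchar(arr) - 1L) <- arr
      interRows[[length(interRows) + 1L]] <- data.frame(arm = arm,
        start = gStart, end = gEnd, distance = il$distance[j],
        stringsAsFactors = FALSE)
    }
    leftTel <- revComp(mutatedArray(config$unit, config$telomere_copies,
      config$unit_divergence))
    rightTel <- mutatedArray(config$unit, config$telomere_copies,
      config$unit_divergence)
    seqs[i] <- paste0(leftTel, core, rightTel)
    termRows[[length(termRows) + 1L]] <- data.frame(
      arm = arm, start = c(1L, Lc - tl + 1L), end = c(tl, Lc),
      strand = c("-", "+"), which_end = c("start", "end"),
      stringsAsFactors = FALSE)
  }
  assembly <- Biostrings::DNAStringSet(seqs)
  names(assembly) <- config$arms
  tr <- do.call(rbind, termRows)
  terminal <- GenomicRanges::GRanges(tr$arm,
    IRanges::IRanges(tr$start, tr$end), strand = tr$strand,
    which_end = tr$which_end)
  interstitial <- if (length(interRows)) {
    ir <- do.call(rbind, interRows)
    GenomicRanges::GRanges(ir$arm, IRanges::IRanges(ir$start, ir$end),
      distance = ir$distance)
  } else GenomicRanges::GRanges()
  list(assembly = assembly,
    truth = list(terminal = terminal, interstitial = interstitial),
    unit = RepeatUnit(config$unit))
}

#' Simulate long reads with truth labels
#'
#' Draws reads from a simulated genome to the configured coverage: lengths
#' from a truncated normal, uniform start positions, random strand,
#' independent per-base substitution/insertion/deletion errors, and a
#' configured fraction of chimeric reads (head-to-tail fusions of segments
#' from two distinct arms with independent orientations). Every read
#' carries a geometric truth label in the classification vocabulary; a
#' terminal or interstitial array counts toward the label only when the
#' read contains at least three unit copies of it, mirroring the
#' annotator's emission floor. Deterministic under the config seed.
#'
#' @param sim Output of [simulateGenome()].
#' @param config The same [simConfig()].
#' @return A list: `reads` (named `DNAStringSet`) and `labels`
#'   (`data.frame`: `read_id`, `true_label`, `true_arm`, `true_start`,
#'   `true_end` — the array interval on the read, `NA` when label-free).
#' @export
simulateReads <- function(sim, config) {
  stopifnot(inherits(config, "SimConfig"))
  restore <- localSeed(config$seed + 1L)
  on.exit(restore())
  assembly <- sim$assembly
  chromStr <- as.character(assembly)
  arms <- names(assembly)
  widths <- Biostrings::width(assembly)
  L <- nchar(config$unit)
  tl <- config$telomere_copies * L
  floorBp <- 3L * L
  maxLen <- min(widths) - 1L
  if (config$read_length_min >= maxLen)
    stop("read length distribution incompatible with chromosome length")
  il <- sim$truth$interstitial

  drawLen <- function() {
    repeat {
      len <- round(stats::rnorm(1, config$read_length_mean,
        config$read_length_sd))
      if (len > config$read_length_min && len <= maxLen) return(len)
    }
  }

  target <- config$target_coverage * sum(as.numeric(widths))
  total <- 0; i <- 0L
  seqs <- character(); labs <- list()
  while (total < target) {
    i <- i + 1L
    id <- sprintf("read%05d", i)
    for (attempt in 1:5) {
      if (stats::runif(1) < config$chimera_fraction) {
        a2 <- sample(arms, 2L)
        len <- drawLen()
        l1 <- round(len * stats::runif(1, 0.35, 0.65)); l2 <- len - l1
        seg <- vapply(1:2, function(j) {
          lj <- c(l1, l2)[j]; armj <- a2[j]
          sj <- sample.int(widths[match(armj, arms)] - lj + 1L, 1L)
          ss <- substr(chromStr[armj], sj, sj + lj - 1L)
          if (stats::runif(1) < 0.5) revComp(ss) else ss
        }, character(1))
        raw <- paste0(seg[1L], seg[2L])
        lab <- data.frame(read_id = id, true_label = "chimeric",
          true_arm = NA_character_, true_start = NA_integer_,
          true_end = NA_integer_, stringsAsFactors = FALSE)
      } else {
        arm <- sample(arms, 1L, prob = widths)
        Lc <- widths[match(arm, arms)]
        len <- drawLen()
        s <- sample.int(Lc - len + 1L, 1L)
        e <- s + len - 1L
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        raw <- substr(chromStr[arm], s, e)
        if (strand == "-") raw <- revComp(raw)
        lab <- truthLabel(id, arm, s, e, strand, Lc, tl, floorBp, il)
      }
      err <- applyReadErrors(raw, config$error_sub, config$error_ins,
        config$error_del)
      if (nchar(err) >= config$read_length_min) break
    }
    seqs[i] <- err
    labs[[i]] <- lab
    total <- total + nchar(err)
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read%05d", seq_along(reads))
  list(reads = reads, labels = do.call(rbind, labs))
}

# geometric truth for a non-chimeric read drawn from [s, e] of an arm
truthLabel <- function(id, arm, s, e, strand, Lc, tl, floorBp, il) {
  len <- e - s + 1L
  leftOv <- max(0L, min(e, tl) - s + 1L)
  rightOv <- max(0L, e - max(s, Lc - tl + 1L) + 1L)
  leftTouch <- s <= tl && leftOv >= floorBp
  rightTouch <- e >= Lc - tl + 1L && rightOv >= floorBp
  lab <- "no_array"; ts <- NA_integer_; te <- NA_integer_
  if (leftTouch || rightTouch) {
    # which read terminus carries the array depends on the read strand
    if (leftTouch) {
      lab <- if (strand == "+") "telomere_at_start" else "telomere_at_end"
      ov <- leftOv
    } else {
      lab <- if (strand == "+") "telomere_at_end" else "telomere_at_start"
      ov <- rightOv
    }
    if (lab == "telomere_at_start") { ts <- 1L; te <- ov }
    else { ts <- len - ov + 1L; te <- len }
  } else if (length(il)) {
    armLoc <- il[as.character(GenomicRanges::seqnames(il)) == arm]
    for (j in seq_along(armLoc)) {
      os <- max(s, GenomicRanges::start(armLoc)[j])
      oe <- min(e, GenomicRanges::end(armLoc)[j])
      if (oe - os + 1L >= floorBp) {
        lab <- "interstitial"
        if (strand == "+") { ts <- os - s + 1L; te <- oe - s + 1L }
        else { ts <- e - oe + 1L; te <- e - os + 1L }
        break
      }
    }
  }
  data.frame(read_id = id, true_label = lab, true_arm = arm,
    true_start = ts, true_end = te, stringsAsFactors = FALSE)
}

# independent per-base substitution / insertion / deletion
applyReadErrors <- function(s, psub, pins, pdel) {
  if (psub + pins + pdel <= 0) return(s)
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  bases <- c("A", "C", "G", "T")
  u <- stats::runif(n)
  del <- u < pdel
  sub <- !del & u < pdel + psub
  if (any(sub)) {
    cur <- match(x[sub], bases)
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    x[sub] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  ins <- stats::runif(n) < pins
  insBase <- character(n)
  if (any(ins))
    insBase[ins] <- bases[sample.int(4L, sum(ins), replace = TRUE)]
  x[del] <- ""
  paste(paste0(x, insBase), collapse = "")
}
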