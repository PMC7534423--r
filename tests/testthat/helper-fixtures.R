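# shared fixtures; all data is generated in code

TELOMERE_UNIT <- "GTTCCTATAGCTTCTCTCACTCAAGTAGCCT"   # 31 bp telomeric unit
CY3_PROBE <- "AGGCTACTTGAGTGAGAGAAGCTATAGGAAC"       # its reverse complement

randomDNA <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently at `rate`
mutate_seq <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(x)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1L)
  paste(x, collapse = "")
}

# a small two-arm genome+reads simulation, error-free unless stated
small_sim <- function(seed = 11, arms = c("X", "2R"), chrom = 120000,
                      coverage = 2, err = c(0, 0, 0),
                      loci = data.frame(arm = "X", distance = 30000,
                        copies = 40)) {
  cfg <- simConfig(seed = seed, arms = arms, chromosome_length = chrom,
    target_coverage = coverage, interstitial_loci = loci,
    error_sub = err[1], error_ins = err[2], error_del = err[3])
  sim <- simulateGenome(cfg)
  rd <- simulateReads(sim, cfg)
  list(cfg = cfg, sim = sim, rd = rd)
}
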