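# Base-4 k-mer encodings stored in doubles: exact (collision-free) for
# k <= 26 since 4^26 < 2^53. Windows containing N encode as NA.

codeDNA <- function(s) {
  x <- utf8ToInt(toupper(as.character(s)))
  code <- rep(NA_real_, length(x))
  code[x == utf8ToInt("A")] <- 0
  code[x == utf8ToInt("C")] <- 1
  code[x == utf8ToInt("G")] <- 2
  code[x == utf8ToInt("T")] <- 3
  code
}

# forward-strand codes of all k-mers (most significant digit first)
rollingHashes <- function(code, k) {
  n <- length(code)
  m <- n - k + 1L
  if (m < 1L) return(numeric(0))
  h <- numeric(m)
  for (j in 0:(k - 1L))
    h <- h + code[seq.int(1L + j, m + j)] * 4^(k - 1L - j)
  h
}

# codes of the reverse complement of each forward k-mer, same positions
rollingHashesRC <- function(code, k) {
  n <- length(code)
  m <- n - k + 1L
  if (m < 1L) return(numeric(0))
  h <- numeric(m)
  for (j in 0:(k - 1L))
    h <- h + (3 - code[seq.int(1L + j, m + j)]) * 4^j
  h
}
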