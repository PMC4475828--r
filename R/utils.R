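# internal helpers shared across modules

# derive a reproducible per-stage seed from a master seed; kept < 2^31
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629L)
}

# run expr with a local RNG state seeded by `seed` (NULL = use current state)
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Hamming distance between two equal-length strings
hammingDist <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  sum(x != y)
}

# pairwise Hamming distance matrix over a character vector of sequences
hammingMatrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

DNA_BASES4 <- c("A", "C", "G", "T")

# substitute the base at `pos` with a base differing from the reference at
# pos-1, pos and pos+1, so the substitution neither creates a homopolymer
# run nor lets a frameshift alignment slide a gap onto it for free
substituteBase <- function(chars, pos, refChars = chars) {
  L <- length(refChars)
  excl <- refChars[unique(pmax(pmin(c(pos - 1L, pos, pos + 1L), L), 1L))]
  choices <- setdiff(DNA_BASES4, excl)
  chars[pos] <- if (length(choices) == 1L) choices else sample(choices, 1L)
  chars
}

# reference positions where a substitution cannot be confused with a
# homopolymer indel by the frameshift-excision alignment: the two adjacent
# base pairs on either side must all differ (no run within 2 nt)
eligibleMutationSites <- function(refChars) {
  L <- length(refChars)
  if (L < 5) return(integer())
  adj <- refChars[-1] != refChars[-L]        # adj[i]: ref[i] != ref[i+1]
  j <- 3:(L - 2)
  j[adj[j - 2] & adj[j - 1] & adj[j] & adj[j + 1]]
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single value >= %d", name, min))
}
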