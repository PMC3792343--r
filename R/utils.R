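#' @importFrom Biostrings DNAString reverseComplement
#' @importFrom utils read.delim write.table head tail
#' @importFrom stats coef lm rnorm runif sd setNames
NULL

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_dna <- function(x) {
  nchar(x) == 0L || grepl("^[ACGT]+$", x)
}

# DNA -> RNA (sense transcription).
transcribe <- function(x) chartr("T", "U", toupper(x))

loxtron_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "loxtron_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Run code with a private RNG stream; leaves the caller's RNG state untouched.
# All generators in the package route their randomness through this so that
# fixtures are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 0-based offset of the lexicographically least rotation of a string.
# Vectorized prefix comparison with tie extension; ties surviving k = n mean
# the string is periodic and any tied offset is equivalent.
least_rotation_offset <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  d <- paste0(s, s)
  k <- min(64L, n)
  starts <- seq_len(n)
  keys <- substring(d, starts, starts + k - 1L)
  cand <- starts[keys == min(keys)]
  while (length(cand) > 1L && k < n) {
    k <- min(2L * k, n)
    keys <- substring(d, cand, cand + k - 1L)
    cand <- cand[keys == min(keys)]
  }
  cand[1] - 1L
}

# Lexicographically least rotation of a string.
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  off <- least_rotation_offset(s)
  substr(paste0(s, s), off + 1L, off + n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
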