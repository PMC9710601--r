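# Internal helpers: base encoding, seeded RNG scopes, stable per-cloud seeds.

# Map A/C/G/T -> 0..3, anything else (N, lower case not expected) -> NA.
.BASE_CODE <- local({
  v <- rep(NA_real_, 256L)
  v[utf8ToInt("A") + 1L] <- 0
  v[utf8ToInt("C") + 1L] <- 1
  v[utf8ToInt("G") + 1L] <- 2
  v[utf8ToInt("T") + 1L] <- 3
  v
})

.CODE_BASE <- c("A", "C", "G", "T")

# Encode a concatenated base stream (ints from utf8ToInt) to 0..3/NA.
base_codes <- function(chars_int) .BASE_CODE[chars_int + 1L]

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. All stochastic steps in the package go through this
# so that a single integer seed pins the whole run.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stable per-key seed from a global seed
#'
#' Deconvolution processes read clouds independently; each cloud's clustering
#' seed is derived from the global seed and the cloud's barcode with a
#' polynomial string hash, so results do not depend on the order in which
#' clouds are processed (or how they are partitioned among workers).
#'
#' @param seed integer global seed.
#' @param key character scalar (e.g. a barcode).
#' @return integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps h * 31 + 255 < 2^53 exact in doubles
  h <- as.double(seed %% m)
  for (b in utf8ToInt(paste0("s", key))) h <- (h * 31 + b) %% m
  as.integer(h)
}

# stopifnot with a formatted message
.check <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
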