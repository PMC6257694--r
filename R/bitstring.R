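#' Binary fingerprint vectors
#'
#' Fingerprints and functional-group descriptors are fixed-length bit vectors
#' that can always be viewed as a sequence of unsigned 32-bit integers
#' (segment `i` holds bits `32*i .. 32*i+31`, with global bit position `p`
#' mapping to bit `p %% 32` of segment `p %/% 32`).  Segments are returned as
#' doubles because an unsigned 32-bit value can exceed R's integer range.
#'
#' @param length number of bits; must be a positive multiple of 32 for the
#'   segment view to be exact (all descriptors in this package use 512, 256,
#'   or a dictionary size rounded up to 32).
#' @return an object of class `bitstring`: a logical vector of `length` bits.
#' @examples
#' b <- bitstring(64)
#' b <- bs_set(b, c(3, 33, 38))
#' bs_segments(b)   # 8, 66
#' @export
bitstring <- function(length) {
  stopifnot(is.numeric(length), length >= 0)
  structure(logical(length), class = "bitstring")
}

#' @export
print.bitstring <- function(x, ...) {
  cat(sprintf("<bitstring: %d bits, %d set>\n", length(x), sum(x)))
  invisible(x)
}

#' Set bits by global 0-based position
#' @param b a [bitstring()]
#' @param positions 0-based bit positions to set
#' @return the updated bitstring
#' @export
bs_set <- function(b, positions) {
  if (length(positions) == 0) return(b)
  stopifnot(all(positions >= 0), all(positions < length(b)))
  b[positions + 1] <- TRUE
  b
}

#' Test bits by global 0-based position
#' @param b a [bitstring()]
#' @param positions 0-based bit positions to query
#' @export
bs_get <- function(b, positions) {
  as.logical(b)[positions + 1]
}

#' Number of set bits
#' @param b a [bitstring()]
#' @export
bs_popcount <- function(b) sum(b)

#' Unsigned 32-bit segment view
#'
#' @param b a [bitstring()]
#' @return a double vector of `ceiling(length(b)/32)` unsigned 32-bit values.
#' @export
bs_segments <- function(b) {
  n <- ceiling(length(b) / 32)
  if (n == 0) return(numeric(0))
  bits <- c(as.logical(b), logical(n * 32 - length(b)))
  vapply(seq_len(n), function(i) {
    seg <- bits[((i - 1) * 32 + 1):(i * 32)]
    sum(seg * 2^(0:31))
  }, numeric(1))
}

#' Rebuild a bitstring from its unsigned 32-bit segments
#' @param segments double vector of unsigned 32-bit values
#' @param length total number of bits (default `32 * length(segments)`)
#' @export
bs_from_segments <- function(segments, length = 32 * base::length(segments)) {
  b <- bitstring(length)
  for (i in seq_along(segments)) {
    v <- segments[i]
    stopifnot(v >= 0, v < 2^32, v == floor(v))
    for (j in 0:31) {
      if (v %% 2 == 1) b[(i - 1) * 32 + j + 1] <- TRUE
      v <- v %/% 2
    }
  }
  b
}

#' ASCII 0/1 rendering of a bitstring
#'
#' Position 0 is the first character, mirroring the clear-text descriptor
#' output style of the analyzer.
#' @param b a [bitstring()]
#' @export
bs_ascii <- function(b) paste(as.integer(b), collapse = "")

#' Parse an ASCII 0/1 string into a bitstring
#' @param s a string of "0"/"1" characters
#' @export
bs_from_ascii <- function(s) {
  v <- strsplit(s, "")[[1]]
  stopifnot(all(v %in% c("0", "1")))
  structure(v == "1", class = "bitstring")
}

bs_and <- function(a, b) structure(unclass(a) & unclass(b), class = "bitstring")
bs_or  <- function(a, b) structure(unclass(a) | unclass(b), class = "bitstring")

#' Is every set bit of `a` also set in `b`?
#' @param a,b bitstrings of equal length
#' @export
bs_subset <- function(a, b) {
  stopifnot(length(a) == length(b))
  !any(a & !b)
}

#' Tanimoto similarity of two equal-length bitstrings
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both operands are all-zero.
#' @param a,b bitstrings of equal length
#' @return a fraction in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("tanimoto: bitstring lengths differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
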