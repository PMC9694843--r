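#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper used throughout the package;
#' sequences are held as single uppercase strings over A, C, G, T, N.
#'
#' @param seq character scalar, nucleotide sequence.
#' @return character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ATGCCC")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# split into codons; returns list(codons = chr vector, remnant = chr scalar)
chunk_codons <- function(seq) {
  n <- nchar(seq)
  nc <- n %/% 3L
  codons <- if (nc > 0L) {
    substring(seq, seq(1L, by = 3L, length.out = nc),
              seq(3L, by = 3L, length.out = nc))
  } else character(0L)
  list(codons = codons, remnant = if (n %% 3L) substr(seq, nc * 3L + 1L, n) else "")
}

# nucleotide sampling probabilities from composition targets.
# at_content in percent; skews are (A-T)/(A+T), (G-C)/(G+C).
base_probs <- function(at_content, at_skew = 0, gc_skew = 0) {
  stopifnot(at_content >= 50, at_content <= 95,
            abs(at_skew) < 1, abs(gc_skew) < 1)
  at <- at_content / 100
  c(A = at * (1 + at_skew) / 2,
    C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2,
    T = at * (1 - at_skew) / 2)
}

# sample a random sequence of length n with the given base probabilities
random_seq <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# rotate the origin of a circular sequence so that old position `new_start`
# becomes position 1; returns the rotated string
rotate_seq <- function(seq, new_start) {
  n <- nchar(seq)
  new_start <- ((new_start - 1L) %% n) + 1L
  if (new_start == 1L) return(seq)
  paste0(substr(seq, new_start, n), substr(seq, 1L, new_start - 1L))
}

# extract a (possibly origin-wrapping) slice of a circular sequence,
# 1-based inclusive; end < start means wrap through the origin
circular_slice <- function(seq, start, end) {
  n <- nchar(seq)
  if (start < 1L || start > n || end < 1L || end > n)
    stop("coordinates outside genome (length ", n, "): ", start, "..", end)
  if (end >= start) substr(seq, start, end)
  else paste0(substr(seq, start, n), substr(seq, 1L, end))
}

# length of a circular feature given 1-based inclusive start/end
circular_length <- function(start, end, genome_length) {
  if (end >= start) end - start + 1L else genome_length - start + 1L + end
}
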