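#' Reverse complement of DNA sequences
#'
#' Complements A<->T and C<->G and reverses the sequence. Any letter outside
#' `{A, C, G, T}` (IUPAC ambiguity codes included) maps to `N`, so ambiguous
#' positions stay ambiguous on the opposite strand.
#'
#' @param seq character vector of upper-case DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTTCGAACG")  # "CGTTCGAACGT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || any(!nzchar(seq)))
    stop("sequences must be non-empty strings")
  vapply(seq, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

# single-base one-hot rows under the fixed letter map
BASE_ONEHOT <- matrix(
  c(0, 0, 0, 1,   # A
    0, 0, 1, 0,   # C
    0, 1, 0, 0,   # G
    1, 0, 0, 0),  # T
  nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL)
)

#' Base one-hot matrix of a fragment
#'
#' Encodes the forward strand followed by the reverse-complement strand, one
#' row per base, under the map A=\[0,0,0,1\], C=\[0,0,1,0\], G=\[0,1,0,0\],
#' T=\[1,0,0,0\]. Ambiguous bases give all-zero rows. The result has exactly
#' `2 * nchar(seq)` rows and 4 columns.
#'
#' @param seq a single upper-case DNA string.
#' @return numeric matrix, `2L x 4`, entries in `{0, 1}`.
#' @export
encode_boh <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- c(strsplit(seq, "", fixed = TRUE)[[1]],
             strsplit(revcomp_cpp(seq), "", fixed = TRUE)[[1]])
  m <- matrix(0, nrow = length(chars), ncol = 4L)
  hit <- chars %in% rownames(BASE_ONEHOT)
  m[hit, ] <- BASE_ONEHOT[chars[hit], , drop = FALSE]
  m
}

#' Expand a fragment into its six codon reading frames
#'
#' Returns, in fixed order, the non-overlapping codon lists of the forward
#' strand at offsets 0, 1, 2 followed by those of the reverse-complement
#' strand at offsets 0, 1, 2. Trailing bases that cannot complete a codon are
#' discarded, so the total codon count over the six frames is `2 * (L - 2)`.
#'
#' @param seq a single upper-case DNA string of length >= 3.
#' @return list of 6 character vectors of codons.
#' @export
expand_codon_frames <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < 3L) stop("no codon can be formed from a sequence shorter than 3 bp")
  frame_of <- function(s, off) {
    n <- (nchar(s) - off) %/% 3L
    if (n == 0L) return(character(0))
    starts <- off + 1L + 3L * (seq_len(n) - 1L)
    substring(s, starts, starts + 2L)
  }
  rc <- revcomp_cpp(seq)
  c(lapply(0:2, function(o) frame_of(seq, o)),
    lapply(0:2, function(o) frame_of(rc, o)))
}

#' Lexicographic codon index
#'
#' Column index (1-based) of a codon in the 64-wide one-hot alphabet ordered
#' lexicographically over A < C < G < T (AAA = 1, AAC = 2, ..., TTT = 64).
#' Codons containing ambiguous bases get `NA`.
#'
#' @param codon character vector of 3-letter codons.
#' @return integer vector of 1-based indices, `NA` for ambiguous codons.
#' @export
codon_index <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  lex <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  a <- lex[substr(codon, 1, 1)]
  b <- lex[substr(codon, 2, 2)]
  c_ <- lex[substr(codon, 3, 3)]
  unname(16L * a + 4L * b + c_ + 1L)
}

#' Codon one-hot matrix of a fragment
#'
#' Concatenates the six reading-frame codon lists (order as in
#' [expand_codon_frames()]) into one row sequence; each codon maps to a
#' 64-wide one-hot row at its lexicographic index. Codons containing an
#' ambiguous base give all-zero rows. The result has exactly `2 * (L - 2)`
#' rows.
#'
#' @param seq a single upper-case DNA string of length >= 3.
#' @return numeric matrix, `2*(L-2) x 64`, entries in `{0, 1}`.
#' @export
encode_coh <- function(seq) {
  codons <- unlist(expand_codon_frames(seq))
  idx <- codon_index(codons)
  m <- matrix(0, nrow = length(codons), ncol = 64L)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Zero-pad encodings to a group's fixed input shape
#'
#' Appends all-zero rows after the data rows so both matrices have
#' `2 * L_max` rows, where `L_max` is 400, 800 or 1,200 bp for groups A, B, C.
#' Padding is applied identically at training and prediction time.
#'
#' @param boh base one-hot matrix of the fragment.
#' @param coh codon one-hot matrix of the fragment.
#' @param group network group, one of `"A"`, `"B"`, `"C"`.
#' @return a `padded_encoding` list with elements `boh`, `coh`, `group`,
#'   `original_length`.
#' @export
pad_for_group <- function(boh, coh, group) {
  group <- match.arg(group, names(GROUP_LMAX))
  L <- nrow(boh) / 2L
  target <- 2L * GROUP_LMAX[[group]]
  if (nrow(boh) > target)
    stop("fragment of length ", L, " exceeds the group ", group,
         " maximum of ", GROUP_LMAX[[group]], " bp")
  pad <- function(m) rbind(m, matrix(0, nrow = target - nrow(m), ncol = ncol(m)))
  structure(
    list(boh = pad(boh), coh = pad(coh), group = group, original_length = L),
    class = "padded_encoding"
  )
}

# integer index encodings feeding the network (one fragment per column);
# see src/encode.cpp for the index conventions
encode_for_network <- function(seqs, group) {
  encode_indices_cpp(seqs, group_max_length(group))
}
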