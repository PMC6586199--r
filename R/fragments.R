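#' DNA fragment set
#'
#' The package's fragment container: a data frame with columns `id`, `seq`
#' and `label` (one of phage / chromosome / plasmid, or `NA` when unknown).
#' Sequences are upper-cased on ingestion; every sequence must be non-empty.
#'
#' @param id character vector of identifiers.
#' @param seq character vector of DNA sequences.
#' @param label optional class labels (`NA` allowed).
#' @return a `dna_fragments` data frame.
#' @export
dna_fragments <- function(id, seq, label = NA_character_) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("all sequences must have length >= 1")
  label <- rep_len(as.character(label), length(id))
  bad <- !is.na(label) & !label %in% CLASSES
  if (any(bad))
    stop("unknown class label(s): ", paste(unique(label[bad]), collapse = ", "))
  structure(
    data.frame(id = as.character(id), seq = seq, label = label,
               stringsAsFactors = FALSE),
    class = c("dna_fragments", "data.frame")
  )
}

#' @export
print.dna_fragments <- function(x, ...) {
  cat(sprintf("<dna_fragments> %d fragment(s), lengths %d-%d bp\n",
              nrow(x), min(nchar(x$seq)), max(nchar(x$seq))))
  if (!all(is.na(x$label)))
    print(table(x$label, useNA = "ifany"))
  invisible(x)
}

#' Read a FASTA file into a fragment set
#'
#' Parses standard multi-line FASTA. The record id is the first
#' whitespace-delimited token of the header; a header token of the form
#' `label=<class>` (as written by [write_fasta()]) is parsed into the `label`
#' column. Sequences are upper-cased; Windows line endings are accepted.
#' Malformed input (sequence data before the first header, records with no
#' sequence) raises an error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return a [dna_fragments()] data frame in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (!any(is_header)) stop("no FASTA records found in ", path)
  first_data <- which(nonblank & !is_header)
  if (length(first_data) && first_data[1] < which(is_header)[1])
    stop("line ", first_data[1], ": sequence data before the first header")

  rec <- cumsum(is_header)
  headers <- lines[is_header]
  header_lines <- which(is_header)
  seqs <- vapply(seq_along(headers), function(i) {
    body <- lines[rec == i & !is_header & nonblank]
    paste(body, collapse = "")
  }, character(1))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("line ", header_lines[which(empty)[1]], ": record '",
         sub("^>", "", headers[which(empty)[1]]), "' has an empty sequence")

  tokens <- strsplit(sub("^>", "", headers), "\\s+")
  ids <- vapply(tokens, `[`, character(1), 1L)
  labels <- vapply(tokens, function(tk) {
    hit <- grep("^label=", tk, value = TRUE)
    if (length(hit)) sub("^label=", "", hit[1]) else NA_character_
  }, character(1))
  dna_fragments(ids, seqs, labels)
}

#' Write a fragment set to FASTA
#'
#' Labelled fragments get the class encoded in the header as `label=<class>`
#' (plus `group=<group>` when supplied) so a round trip through
#' [read_fasta()] preserves the labels.
#'
#' @param fragments a [dna_fragments()] data frame.
#' @param path output path.
#' @param group optional group tag written into each header.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(fragments, path, group = NULL, width = 70L) {
  hdr <- paste0(">", fragments$id,
                ifelse(is.na(fragments$label), "",
                       paste0(" label=", fragments$label)),
                if (is.null(group)) "" else paste0(" group=", group))
  wrap <- function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    substring(s, starts, pmin(starts + width - 1L, n))
  }
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(fragments))) {
    writeLines(c(hdr[i], wrap(fragments$seq[i])), con, sep = "\n")
  }
  invisible(path)
}
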