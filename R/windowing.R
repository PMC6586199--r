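#' Route a (sub)sequence length to a network group
#'
#' Group A serves lengths up to 400 bp (including sub-100 bp remainder
#' windows produced by the scanner), group B lengths 401-800 bp, group C
#' lengths 801-1,200 bp. Boundaries belong to the lower group. Lengths above
#' 1,200 bp are an error: the caller must window the sequence first.
#'
#' @param length sequence length in bp.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
select_group_for_length <- function(length) {
  stopifnot(length >= 1)
  if (length > 1200) stop("length ", length, " exceeds 1,200 bp; window first")
  if (length <= 400) "A" else if (length <= 800) "B" else "C"
}

#' Plan non-overlapping scan windows over a sequence
#'
#' Windows of 1,200 bp move across the sequence without overlapping; the
#' final window is shorter if the sequence boundary is reached. Each window
#' is routed to a group via [select_group_for_length()] and weighted by its
#' length relative to the whole sequence, so a 2,500 bp sequence yields
#' windows of 1,200, 1,200 and 100 bp (groups C, C, A) with weights
#' 1200/2500, 1200/2500 and 100/2500.
#'
#' @param length total sequence length in bp (>= 1).
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `window_length`, `group`, `weight`; weights sum to 1.
#' @export
plan_windows <- function(length) {
  stopifnot(length >= 1)
  starts <- seq.int(0L, length - 1L, by = 1200L)
  ends <- pmin(starts + 1200L, length)
  wl <- ends - starts
  data.frame(
    start = starts, end = ends, window_length = wl,
    group = vapply(wl, select_group_for_length, character(1)),
    weight = wl / length
  )
}

#' Length-weighted average of window score triples
#'
#' @param scores numeric matrix, one row of (phage, chromosome, plasmid)
#'   scores per window.
#' @param weights window weights summing to 1.
#' @return numeric score triple.
#' @export
aggregate_scores <- function(scores, weights) {
  stopifnot(nrow(scores) == length(weights))
  drop(crossprod(scores, weights))
}

#' Label a score triple with an uncertainty threshold
#'
#' The label is the argmax class (ties broken in the fixed order phage >
#' chromosome > plasmid), prefixed with `"uncertain "` when the maximum
#' score falls below `threshold`. At the default threshold 0 the label is
#' always certain.
#'
#' @param scores numeric vector of 3 scores, or an `n x 3` matrix.
#' @param threshold numeric in `[0, 1]`.
#' @return character label(s), one of the six output categories.
#' @export
label_with_threshold <- function(scores, threshold = 0) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(ncol(scores) == 3)
  best <- apply(scores, 1L, which.max)  # which.max takes the first maximum
  mx <- scores[cbind(seq_len(nrow(scores)), best)]
  paste0(ifelse(mx < threshold, "uncertain ", ""), CLASSES[best])
}

#' Predict full-length sequences with windowed scanning
#'
#' Sequences up to 1,200 bp are scored directly by the length-matched model;
#' longer sequences are cut into non-overlapping 1,200 bp windows (final
#' window shorter), each window is scored by its group's model, and the
#' window triples are combined by length-weighted averaging. Remainder
#' windows shorter than 100 bp are still scored (routed to group A) and
#' weighted by their true length. Whole fragments shorter than 100 bp are
#' below the smallest training length: they are skipped with a warning and
#' produce no row.
#'
#' @param models named list of trained `group_model`s (names among
#'   `"A"`, `"B"`, `"C"`); every group required by the input must be present.
#' @param fragments [dna_fragments()].
#' @param threshold uncertainty threshold in `[0, 1]` (default 0).
#' @return data frame with columns `id`, `length`, `phage_score`,
#'   `chromosome_score`, `plasmid_score`, `label`.
#' @export
predict_sequences <- function(models, fragments, threshold = 0) {
  stopifnot(inherits(fragments, "dna_fragments"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  len <- nchar(fragments$seq)
  short <- len < 100L
  if (any(short)) {
    warning(sum(short), " fragment(s) shorter than 100 bp skipped: ",
            paste(utils::head(fragments$id[short], 5L), collapse = ", "),
            if (sum(short) > 5L) ", ..." else "")
  }
  keep <- which(!short)
  if (!length(keep)) {
    return(data.frame(id = character(0), length = integer(0),
                      phage_score = numeric(0), chromosome_score = numeric(0),
                      plasmid_score = numeric(0), label = character(0)))
  }

  # one window table across all fragments, then batch per group
  plans <- lapply(keep, function(i) {
    p <- plan_windows(len[i])
    p$frag <- i
    p
  })
  windows <- do.call(rbind, plans)
  windows$seq <- substring(fragments$seq[windows$frag],
                           windows$start + 1L, windows$end)
  windows$score <- matrix(NA_real_, nrow(windows), 3L)
  for (g in unique(windows$group)) {
    if (is.null(models[[g]]))
      stop("no model supplied for group ", g,
           " (needed by the window plan of the input)")
    sel <- windows$group == g
    wf <- dna_fragments(paste0("w", which(sel)), windows$seq[sel])
    windows$score[sel, ] <- predict_batch(models[[g]], wf)
  }

  agg <- t(vapply(keep, function(i) {
    sel <- windows$frag == i
    aggregate_scores(windows$score[sel, , drop = FALSE], windows$weight[sel])
  }, numeric(3)))
  data.frame(
    id = fragments$id[keep],
    length = len[keep],
    phage_score = agg[, 1], chromosome_score = agg[, 2],
    plasmid_score = agg[, 3],
    label = label_with_threshold(agg, threshold),
    stringsAsFactors = FALSE
  )
}
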