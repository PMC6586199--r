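#' Compositional "genome" model for one class
#'
#' An order-`k` Markov chain over `{A, C, G, T}` standing in for a real
#' reference genome of the class. When no transition matrix is given, each
#' context row is drawn from a symmetric Dirichlet; a small `alpha` gives
#' peaky, class-specific composition so the three classes are statistically
#' distinguishable the way phage / chromosome / plasmid sequences are.
#'
#' @param label class label, one of phage / chromosome / plasmid.
#' @param order Markov order `k` (default 3; contexts are k-mers).
#' @param trans optional `4^k x 4` row-stochastic transition matrix.
#' @param alpha Dirichlet concentration used when `trans` is `NULL`
#'   (default 0.3).
#' @param seed integer seed for drawing the transition matrix.
#' @return a `class_genome_model`.
#' @export
class_genome_model <- function(label, order = 3L, trans = NULL, alpha = 0.3,
                               seed = 1L) {
  label <- match.arg(label, CLASSES)
  nctx <- 4L^order
  if (is.null(trans)) {
    trans <- with_seed(seed, {
      g <- matrix(rgamma(nctx * 4L, shape = alpha), nrow = nctx)
      g / rowSums(g)
    })
  }
  if (!is.matrix(trans) || nrow(trans) != nctx || ncol(trans) != 4L)
    stop("transition matrix must be ", nctx, " x 4")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("transition rows must be non-negative and sum to 1")
  structure(
    list(label = label, order = as.integer(order), trans = trans,
         seed = as.integer(seed)),
    class = "class_genome_model"
  )
}

# mean total-variation distance between the context rows of two models
model_tv_distance <- function(m1, m2) {
  mean(0.5 * rowSums(abs(m1$trans - m2$trans)))
}

#' Default trio of class-distinguishable genome models
#'
#' Draws one order-`k` model per class from independent Dirichlet seeds and
#' verifies that every pair is separated by a mean per-row total-variation
#' distance above `min_tv`; failing trios (rare) are redrawn
#' deterministically from the next seed.
#'
#' @param seed integer base seed.
#' @param order Markov order (default 3).
#' @param alpha Dirichlet concentration (default 0.3).
#' @param min_tv minimum mean pairwise total-variation distance (default 0.25).
#' @return named list of three `class_genome_model`s.
#' @export
default_class_models <- function(seed = 1L, order = 3L, alpha = 0.3,
                                 min_tv = 0.25) {
  base <- as.integer(seed)
  for (attempt in 0:99) {
    models <- lapply(seq_along(CLASSES), function(i) {
      class_genome_model(CLASSES[i], order = order, alpha = alpha,
                         seed = base + 1000L * attempt + i)
    })
    names(models) <- CLASSES
    tv <- c(model_tv_distance(models[[1]], models[[2]]),
            model_tv_distance(models[[1]], models[[3]]),
            model_tv_distance(models[[2]], models[[3]]))
    if (all(tv > min_tv)) return(models)
  }
  stop("could not draw class models separated by min_tv = ", min_tv)
}

#' Sample a synthetic genome from a class model
#'
#' @param model a [class_genome_model()].
#' @param length genome length in bases.
#' @param seed integer seed; the same (model, length, seed) always returns
#'   the identical sequence.
#' @return a DNA string.
#' @export
synth_genome <- function(model, length, seed = 1L) {
  stopifnot(inherits(model, "class_genome_model"))
  markov_sample_cpp(model$trans, as.integer(length), model$order,
                    as.integer(seed))
}

#' Draw error-free fragments from a genome
#'
#' Fragment lengths are i.i.d. uniform over the group's closed range
#' (100-400, 400-800, 800-1,200 or 5,000-10,000 bp for groups A-D) and start
#' positions uniform over the admissible range, emulating a uniform
#' clone-size fragmenter in its exact (error-free) mode: every fragment is a
#' verbatim substring of the genome.
#'
#' @param genome DNA string longer than the group maximum.
#' @param group fragment group `"A"`-`"D"`.
#' @param n number of fragments (> 0).
#' @param seed integer seed.
#' @param label optional class label attached to every fragment.
#' @param prefix id prefix.
#' @return [dna_fragments()].
#' @export
draw_fragments <- function(genome, group, n, seed = 1L, label = NA_character_,
                           prefix = "frag") {
  group <- match.arg(group, names(GROUP_RANGES))
  if (n <= 0) stop("n must be positive")
  rng <- GROUP_RANGES[[group]]
  G <- nchar(genome)
  if (G <= rng[2]) stop("genome (", G, " bp) must be longer than the group ",
                        group, " maximum of ", rng[2], " bp")
  with_seed(seed, {
    lens <- sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) + rng[1] - 1L
    starts <- vapply(lens, function(l) sample.int(G - l + 1L, 1L), integer(1))
    dna_fragments(sprintf("%s_%06d", prefix, seq_len(n)),
                  substring(genome, starts, starts + lens - 1L),
                  label)
  })
}

#' Apply a substitution error channel
#'
#' Each `A/C/G/T` position is independently replaced, with probability
#' `p_sub`, by a base chosen uniformly from the three other bases; length is
#' preserved. Ambiguous positions are left untouched.
#'
#' @param seqs character vector of DNA strings.
#' @param p_sub per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return character vector of mutated sequences.
#' @export
apply_substitutions <- function(seqs, p_sub, seed = 1L) {
  stopifnot(p_sub >= 0, p_sub <= 1)
  if (p_sub == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  others <- sapply(bases, function(b) setdiff(bases, b))  # 3 x 4
  with_seed(seed, {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      eligible <- ch %in% bases
      hit <- eligible & runif(length(ch)) < p_sub
      if (any(hit)) {
        pick <- sample.int(3L, sum(hit), replace = TRUE)
        ch[hit] <- others[cbind(pick, match(ch[hit], bases))]
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Apply an insertion/deletion error channel
#'
#' Each position independently triggers an event with probability `p_indel`;
#' the event is an insertion of a uniformly drawn base before the position,
#' or a deletion of the position, with probabilities `insertion_frac` and
#' `1 - insertion_frac` (default: an even split, the reading of equal
#' insertion and deletion error settings in a fragment simulator).
#'
#' @param seqs character vector of DNA strings.
#' @param p_indel per-position event probability in `[0, 1]`.
#' @param seed integer seed.
#' @param insertion_frac fraction of events that are insertions (default 0.5).
#' @return character vector of mutated sequences (lengths vary).
#' @export
apply_indels <- function(seqs, p_indel, seed = 1L, insertion_frac = 0.5) {
  stopifnot(p_indel >= 0, p_indel <= 1,
            insertion_frac >= 0, insertion_frac <= 1)
  if (p_indel == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      L <- length(ch)
      event <- runif(L) < p_indel
      out <- ch
      if (any(event)) {
        is_ins <- runif(L) < insertion_frac  # drawn for all, used at events
        ins <- event & is_ins
        del <- event & !is_ins
        out[del] <- ""
        out[ins] <- paste0(sample(bases, sum(ins), replace = TRUE), ch[ins])
      }
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Simulate a labelled fragment set end to end
#'
#' Draws (or accepts) one genome model per class, samples one synthetic
#' genome per class, extracts `n_per_class` uniform-length fragments per
#' class for the requested group, and optionally passes them through the
#' substitution and indel error channels. Balanced by construction. The
#' whole procedure is a pure function of `(seed, arguments)`.
#'
#' @param n_per_class fragments per class.
#' @param group fragment group `"A"`-`"D"`.
#' @param seed integer seed driving every random choice.
#' @param p_sub substitution rate (default 0: exact fragments).
#' @param p_indel indel event rate (default 0: exact fragments).
#' @param models optional named list of three `class_genome_model`s; drawn
#'   via [default_class_models()] when absent.
#' @param genome_length length of each synthetic genome (default 100,000 bp,
#'   comfortably above every group maximum).
#' @return list with elements `fragments` ([dna_fragments()]) and `truth`
#'   (data frame: `id`, `label`, `length`, `source`, `errors`).
#' @export
simulate_fragment_set <- function(n_per_class, group, seed = 1L, p_sub = 0,
                                  p_indel = 0, models = NULL,
                                  genome_length = 1e5) {
  group <- match.arg(group, names(GROUP_RANGES))
  if (genome_length < GROUP_RANGES[[group]][2] + 1)
    stop("genome_length must exceed the group maximum")
  if (is.null(models)) models <- default_class_models(seed)
  seed <- as.integer(seed)

  per_class <- lapply(seq_along(CLASSES), function(i) {
    cls <- CLASSES[i]
    genome <- synth_genome(models[[cls]], genome_length, seed = seed + 10L * i)
    fr <- draw_fragments(genome, group, n_per_class, seed = seed + 10L * i + 1L,
                         label = cls, prefix = paste0(cls, "_", group))
    if (p_sub > 0)
      fr$seq <- apply_substitutions(fr$seq, p_sub, seed = seed + 10L * i + 2L)
    if (p_indel > 0)
      fr$seq <- apply_indels(fr$seq, p_indel, seed = seed + 10L * i + 3L)
    fr
  })
  fragments <- do.call(rbind, per_class)
  class(fragments) <- c("dna_fragments", "data.frame")
  errors <- paste0("sub=", p_sub, ";indel=", p_indel)
  truth <- data.frame(
    id = fragments$id, label = fragments$label,
    length = nchar(fragments$seq),
    source = paste0("markov", models[[1]]$order, "_", group),
    errors = errors, stringsAsFactors = FALSE
  )
  list(fragments = fragments, truth = truth)
}

#' Write the simulator's truth table
#'
#' Tab-separated companion of the simulated FASTA: one row per fragment with
#' id, label, length, source and the error channel settings.
#'
#' @param truth truth data frame from [simulate_fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Naive k-mer nearest-centroid classifier
#'
#' Separability control for the simulator: classifies test fragments by the
#' Euclidean-nearest class centroid of normalised k-mer frequency vectors
#' learned from labelled training fragments. A deliberately simple baseline;
#' generated data is considered "easy" when this classifier already performs
#' well.
#'
#' @param train labelled [dna_fragments()].
#' @param test [dna_fragments()] to classify.
#' @param k k-mer size (default 3).
#' @return character vector of predicted labels for `test`.
#' @export
kmer_nearest_centroid <- function(train, test, k = 3L) {
  stopifnot(!anyNA(train$label))
  freqs <- function(seqs) {
    m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              width = k)
    m / pmax(rowSums(m), 1)
  }
  ftr <- freqs(train$seq)
  fte <- freqs(test$seq)
  centroids <- do.call(rbind, lapply(CLASSES, function(cls) {
    colMeans(ftr[train$label == cls, , drop = FALSE])
  }))
  d2 <- outer(rowSums(fte^2), rep(1, 3)) - 2 * fte %*% t(centroids) +
    outer(rep(1, nrow(fte)), rowSums(centroids^2))
  CLASSES[max.col(-d2, ties.method = "first")]
}
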