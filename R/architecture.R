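#' Build an (untrained) dual-path network for a length group
#'
#' Instantiates the fixed architecture: per path, conv(64 kernels, length 6,
#' ReLU) -> maxpool(3) -> batchnorm+dropout -> conv(128, length 3, ReLU) ->
#' maxpool(3) -> batchnorm+dropout -> conv(256, length 3, ReLU) -> global
#' average pooling; the path outputs are concatenated and passed through a
#' dense layer of the same width as its input, then a 3-way softmax scoring
#' (phage, chromosome, plasmid). Convolutions use no implicit padding: the
#' input is already zero-padded to the group's fixed shape (`2 * L_max` rows,
#' `L_max` = 400/800/1,200 bp for groups A/B/C). Weights are Glorot-uniform
#' initialised from `seed`.
#'
#' @param group length group, one of `"A"`, `"B"`, `"C"`.
#' @param dropout_rate dropout fraction in `(0, 1)` applied after each
#'   batchnorm block during training (default 0.3).
#' @param paths `"both"` for the dual-path network, `"base"` or `"codon"`
#'   for single-path ablations (the dense width follows the concatenation
#'   width: 512 dual, 256 single).
#' @param seed integer seed for weight initialisation.
#' @return a `group_model` object.
#' @export
build_architecture <- function(group, dropout_rate = 0.3, paths = "both",
                               seed = 1L) {
  group <- match.arg(group, names(GROUP_LMAX))
  paths <- match.arg(paths, c("both", "base", "codon"))
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  L_max <- GROUP_LMAX[[group]]
  model <- structure(
    list(
      spec = list(group = group, L_max = L_max, dropout_rate = dropout_rate,
                  paths = paths, class_order = CLASSES,
                  optimizer = "adam", loss = "categorical_crossentropy",
                  activation = "relu"),
      weights = cnn_init_cpp(L_max, paths, as.integer(seed)),
      trained = FALSE,
      metadata = list(init_seed = as.integer(seed), epochs = 0L,
                      loss_history = numeric(0))
    ),
    class = "group_model"
  )
  model
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf(
    "<group_model> group %s (inputs %d x 4 and %d x 64), paths = %s, %s\n",
    x$spec$group, 2L * x$spec$L_max, 2L * x$spec$L_max, x$spec$paths,
    if (x$trained) sprintf("trained %d epoch(s)", x$metadata$epochs)
    else "untrained"))
  invisible(x)
}

#' Layer-by-layer description of a built model
#'
#' Walks the model's actual weight matrices and reports the realised layer
#' configuration (kernel counts, kernel lengths, pooling lengths, pooling
#' type, head widths). Used to audit the architecture against its
#' declaration; the numbers are derived from the stored weights, not from
#' the spec fields.
#'
#' @param model a `group_model`.
#' @return data frame with columns `path`, `layer`, `type`, `units`,
#'   `kernel_length`.
#' @export
architecture_layers <- function(model) {
  w <- model$weights
  path_rows <- function(p, input_channels) {
    W1 <- w[[paste0(p, "_W1")]]
    W2 <- w[[paste0(p, "_W2")]]
    W3 <- w[[paste0(p, "_W3")]]
    data.frame(
      path = p,
      layer = c("conv1", "pool1", "batchnorm_dropout1",
                "conv2", "pool2", "batchnorm_dropout2",
                "conv3", "global_average_pooling"),
      type = c("conv1d", "maxpool", "batchnorm+dropout",
               "conv1d", "maxpool", "batchnorm+dropout",
               "conv1d", "gap"),
      units = c(nrow(W1), NA, length(w[[paste0(p, "_g1")]]),
                nrow(W2), NA, length(w[[paste0(p, "_g2")]]),
                nrow(W3), nrow(W3)),
      kernel_length = c(ncol(W1) / input_channels, 3, NA,
                        ncol(W2) / nrow(W1), 3, NA,
                        ncol(W3) / nrow(W2), NA)
    )
  }
  out <- list()
  if (model$spec$paths %in% c("both", "base")) out$b <- path_rows("b", 4L)
  if (model$spec$paths %in% c("both", "codon")) out$c <- path_rows("c", 64L)
  head <- data.frame(
    path = "head",
    layer = c("concatenate", "dense", "softmax"),
    type = c("concat", "dense", "softmax"),
    units = c(ncol(w$Wd), nrow(w$Wd), nrow(w$Wo)),
    kernel_length = NA
  )
  do.call(rbind, c(out, list(head)))
}

# fragment length checks shared by train/predict
check_lengths <- function(fragments, group, strict_range) {
  len <- nchar(fragments$seq)
  L_max <- GROUP_LMAX[[group]]
  if (strict_range) {
    rng <- GROUP_RANGES[[group]]
    bad <- which(len < rng[1] | len > rng[2])
    if (length(bad))
      stop("fragment '", fragments$id[bad[1]], "' has length ", len[bad[1]],
           ", outside the group ", group, " range [", rng[1], ", ", rng[2], "]")
  } else {
    bad <- which(len > L_max)
    if (length(bad))
      stop("fragment '", fragments$id[bad[1]], "' has length ", len[bad[1]],
           ", above the group ", group, " maximum of ", L_max, " bp")
  }
  invisible(len)
}

#' Train a group model
#'
#' Minibatch Adam on softmax cross-entropy. All three classes must be
#' present and every fragment must lie within the group's length range.
#' Training is reproducible given `seed` (shuffling, dropout and the weight
#' initialisation all derive from explicit seeds). Adam moment estimates are
#' kept for the duration of this call; calling `train_model()` again
#' continues from the current weights with fresh moments.
#'
#' @param model a `group_model` from [build_architecture()].
#' @param fragments labelled [dna_fragments()].
#' @param epochs number of passes over the data (default 20).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed for shuffling and dropout.
#' @return the trained `group_model`; `metadata$loss_history` holds the mean
#'   training loss per epoch.
#' @export
train_model <- function(model, fragments, epochs = 20L, batch_size = 128L,
                        learning_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(model, "group_model"), inherits(fragments, "dna_fragments"))
  if (anyNA(fragments$label))
    stop("all training fragments must be labelled")
  missing_cls <- setdiff(CLASSES, unique(fragments$label))
  if (length(missing_cls))
    stop("training data lacks class(es): ", paste(missing_cls, collapse = ", "))
  check_lengths(fragments, model$spec$group, strict_range = TRUE)

  enc <- encode_for_network(fragments$seq, model$spec$group)
  labels <- match(fragments$label, CLASSES) - 1L
  fit <- cnn_train_cpp(model$weights, enc$boh, enc$coh, labels,
                       model$spec$L_max, model$spec$paths,
                       model$spec$dropout_rate, as.integer(epochs),
                       as.integer(batch_size), learning_rate,
                       as.integer(seed))
  model$weights <- fit$weights
  model$trained <- TRUE
  model$metadata$epochs <- model$metadata$epochs + as.integer(epochs)
  model$metadata$loss_history <- c(model$metadata$loss_history, fit$loss)
  model$metadata$train_seed <- as.integer(seed)
  model
}

#' Score fragments with a group model
#'
#' Returns one probability triple per fragment, in input order. Fragments
#' must not exceed the group's maximum input length; shorter fragments
#' (including sub-100 bp remainder windows routed here by the scanner) are
#' zero-padded exactly as during training. Deterministic for fixed weights.
#'
#' @param model a `group_model`.
#' @param fragments [dna_fragments()] (labels ignored).
#' @param batch_size inference batch size.
#' @return numeric matrix `n x 3` with columns `phage`, `chromosome`,
#'   `plasmid`; rows sum to 1.
#' @export
predict_batch <- function(model, fragments, batch_size = 128L) {
  stopifnot(inherits(model, "group_model"), inherits(fragments, "dna_fragments"))
  check_lengths(fragments, model$spec$group, strict_range = FALSE)
  enc <- encode_for_network(fragments$seq, model$spec$group)
  scores <- cnn_predict_cpp(model$weights, enc$boh, enc$coh, model$spec$L_max,
                            model$spec$paths, as.integer(batch_size))
  dimnames(scores) <- list(fragments$id, CLASSES)
  scores
}

#' Save a group model to a directory
#'
#' Writes the weights in R's native serialisation (`weights.rds`) plus a
#' plain-text `manifest.txt` recording group, maximum input length, dropout
#' rate, paths, seeds, epochs and the class order.
#'
#' @param model a `group_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  manifest <- c(
    paste0("group\t", model$spec$group),
    paste0("L_max\t", model$spec$L_max),
    paste0("dropout_rate\t", model$spec$dropout_rate),
    paste0("paths\t", model$spec$paths),
    paste0("class_order\t", paste(model$spec$class_order, collapse = ",")),
    paste0("init_seed\t", model$metadata$init_seed),
    paste0("epochs\t", model$metadata$epochs),
    paste0("trained\t", model$trained)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Load a group model saved by [save_model()]
#'
#' @param dir directory containing `weights.rds` and `manifest.txt`.
#' @return a `group_model`.
#' @export
load_model <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.txt"), header = FALSE,
                    col.names = c("key", "value"), stringsAsFactors = FALSE)
  val <- function(k) man$value[man$key == k]
  model <- structure(
    list(
      spec = list(group = val("group"), L_max = as.integer(val("L_max")),
                  dropout_rate = as.numeric(val("dropout_rate")),
                  paths = val("paths"),
                  class_order = strsplit(val("class_order"), ",")[[1]],
                  optimizer = "adam", loss = "categorical_crossentropy",
                  activation = "relu"),
      weights = readRDS(file.path(dir, "weights.rds")),
      trained = as.logical(val("trained")),
      metadata = list(init_seed = as.integer(val("init_seed")),
                      epochs = as.integer(val("epochs")),
                      loss_history = numeric(0))
    ),
    class = "group_model"
  )
  if (!identical(model$spec$class_order, CLASSES))
    stop("model manifest declares an unexpected class order")
  model
}
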