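# ---- AT-domain substrate specificity ---------------------------------------
#
# The substrate loaded by each extension module is determined by its
# acyltransferase (AT) domain.  Specificity is predicted from the 24
# active-site residues of the AT pocket: each domain is aligned to a packaged
# reference with 24 marked columns, the aligned residues are one-hot encoded
# (24 x 20 = 480 bits) and classified with an extremely-randomized-trees
# ensemble.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Load the packaged AT reference profile
#'
#' The packaged reference is a constructed stand-in AT-like sequence (see the
#' file header of `at_reference_synthetic.fasta`); its 24 marked active-site
#' columns are listed 0-based in the companion TSV.  Any reference may be
#' substituted via the `fasta`/`columns` arguments.
#'
#' @param fasta path to a single-record FASTA file.
#' @param columns path to a TSV with a `column` field of 0-based indices.
#' @return list with `sequence` and `columns` (24 marked columns, 0-based).
#' @export
load_at_reference <- function(
    fasta = system.file("extdata", "at_reference_synthetic.fasta",
                        package = "pksline"),
    columns = system.file("extdata", "at_reference_columns.tsv",
                          package = "pksline")) {
  seqs <- Biostrings::readAAStringSet(fasta)
  cols <- utils::read.delim(columns, comment.char = "#")$column
  if (length(cols) != 24L) stop("reference must mark exactly 24 columns")
  ref <- as.character(seqs[[1]])
  if (any(cols < 0L | cols >= nchar(ref))) stop("marked column outside reference")
  list(sequence = ref, columns = as.integer(sort(cols)))
}

#' Extract the 24-residue AT active-site signature
#'
#' Globally aligns an AT domain sequence against the reference
#' (Needleman-Wunsch, BLOSUM62, affine gaps 10/1) and reads off the query
#' residues aligned to the 24 marked reference columns; reference columns
#' aligned to gaps yield `-`.
#'
#' @param at_sequence amino-acid sequence (length >= 50).
#' @param reference a reference profile from [load_at_reference].
#' @param min_score alignment-score floor below which the sequence is
#'   rejected as not an AT domain.
#' @return a length-24 signature string.
#' @export
extract_signature <- function(at_sequence, reference = load_at_reference(),
                              min_score = 0) {
  at_sequence <- toupper(gsub("[^A-Za-z]", "", at_sequence))
  if (nchar(at_sequence) < 50L) stop("AT sequence too short (< 50 aa)")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    at_sequence, reference$sequence, type = "global",
    substitutionMatrix = get("BLOSUM62"), gapOpening = 10, gapExtension = 1)
  if (Biostrings::score(aln) < min_score)
    stop("not an AT domain: alignment score ", round(Biostrings::score(aln), 1),
         " below floor ", min_score)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refpos <- cumsum(sub != "-") - 1L  # 0-based reference position per column
  sig <- vapply(reference$columns, function(cl) {
    i <- which(sub != "-" & refpos == cl)
    if (length(i) != 1L) "-" else pat[i]
  }, "")
  paste(sig, collapse = "")
}

#' One-hot encode a 24-residue signature
#'
#' Each position maps to a 20-dimensional indicator block (alphabet
#' ACDEFGHIKLMNPQRSTVWY); gaps give an all-zero block, as does the ambiguous
#' residue X (with a warning).
#'
#' @param sig a length-24 signature string.
#' @return integer vector of length 480.
#' @export
encode_signature <- function(sig) {
  chars <- strsplit(sig, "")[[1]]
  if (length(chars) != 24L) stop("signature must have length 24, got ",
                                 length(chars))
  if (any(chars == "X"))
    warning("ambiguous residue X encoded as all-zero block", call. = FALSE)
  v <- integer(24L * 20L)
  idx <- match(chars, .AA20)
  hit <- which(!is.na(idx))
  v[(hit - 1L) * 20L + idx[hit]] <- 1L
  v
}

#' Decode a one-hot vector back to a signature
#' @param bits integer vector of length 480.
#' @return a length-24 signature string (all-zero blocks decode to `-`).
#' @export
decode_signature <- function(bits) {
  if (length(bits) != 480L) stop("encoded signature must have length 480")
  m <- matrix(bits, nrow = 20L)
  paste(vapply(seq_len(24L), function(i) {
    j <- which(m[, i] == 1L)
    if (length(j) == 1L) .AA20[j] else "-"
  }, ""), collapse = "")
}

encode_matrix <- function(sigs) {
  x <- t(vapply(sigs, encode_signature, integer(480L)))
  colnames(x) <- paste0("b", seq_len(480L))
  rownames(x) <- NULL
  x
}

#' Train the substrate-specificity classifier
#'
#' Fits an extremely-randomized-trees ensemble (150 trees, depth 10 by
#' default) on one-hot encoded signatures.
#'
#' @param signatures character vector of length-24 signatures.
#' @param labels substrate labels (e.g. `mal`, `mmal`).
#' @param n_trees,max_depth ensemble size and depth cap.
#' @param seed RNG seed; results are deterministic given the seed.
#' @return a `specificity_model`.
#' @export
train_specificity_model <- function(signatures, labels, n_trees = 150L,
                                    max_depth = 10L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(signatures) == length(labels), length(labels) >= 1L)
  vocab <- sort(unique(labels))
  if (length(vocab) < 2L)
    warning("single-label training set: degenerate model always predicts '",
            vocab, "'", call. = FALSE)
  x <- encode_matrix(signatures)
  fp <- tools::md5sum({
    tf <- tempfile()
    writeLines(paste(signatures, labels, sep = "\t"), tf)
    tf
  })
  names(fp) <- NULL
  if (length(vocab) >= 2L) {
    fit <- ranger::ranger(
      x = as.data.frame(x), y = factor(labels, levels = vocab),
      num.trees = n_trees, max.depth = max_depth,
      splitrule = "extratrees", num.random.splits = 1L,
      mtry = ncol(x), replace = FALSE, sample.fraction = 1,
      probability = TRUE, seed = seed)
  } else fit <- NULL
  structure(list(fit = fit, label_vocabulary = vocab,
                 hyperparameters = list(n_trees = n_trees,
                                        max_depth = max_depth),
                 training_fingerprint = fp, seed = seed),
            class = "specificity_model")
}

#' @export
print.specificity_model <- function(x, ...) {
  cat("<specificity_model> ", x$hyperparameters$n_trees, " extra trees, depth <= ",
      x$hyperparameters$max_depth, "; labels: ",
      paste(x$label_vocabulary, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict substrate specificity
#'
#' @param model a `specificity_model`.
#' @param signatures character vector of length-24 signatures (or a
#'   precomputed 480-column matrix).
#' @return data.frame with `label` (argmax, ties broken lexicographically)
#'   and one probability column per vocabulary label.
#' @export
predict_specificity <- function(model, signatures) {
  x <- if (is.matrix(signatures)) signatures else encode_matrix(signatures)
  if (ncol(x) != 480L) stop("encoded signatures must have 480 columns")
  vocab <- model$label_vocabulary
  if (is.null(model$fit)) {
    p <- matrix(1, nrow = nrow(x), ncol = 1L, dimnames = list(NULL, vocab))
  } else {
    p <- stats::predict(model$fit, data = as.data.frame(x))$predictions
    p <- p[, sort(colnames(p)), drop = FALSE]
  }
  # lexicographic tie-break: first column wins on ties (columns are sorted)
  lab <- vocab[max.col(p, ties.method = "first")]
  out <- data.frame(label = lab, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(p))
}

#' Augment a specificity model with confidently self-labelled signatures
#'
#' Optional self-training refinement: unlabeled signatures predicted above a
#' probability threshold are added to the training set with their predicted
#' label and the model is refit. Off by default in the pipeline.
#'
#' @param model a `specificity_model`.
#' @param signatures,labels the original labeled training data.
#' @param unlabeled character vector of unlabeled signatures.
#' @param threshold minimum top-label probability for inclusion.
#' @return a refit `specificity_model`.
#' @export
refine_specificity_model <- function(model, signatures, labels, unlabeled,
                                     threshold = 0.9) {
  pr <- predict_specificity(model, unlabeled)
  top <- apply(as.matrix(pr[model$label_vocabulary]), 1, max)
  keep <- top >= threshold
  if (!any(keep)) return(model)
  train_specificity_model(c(signatures, unlabeled[keep]),
                          c(labels, pr$label[keep]),
                          n_trees = model$hyperparameters$n_trees,
                          max_depth = model$hyperparameters$max_depth,
                          seed = model$seed)
}

# minimum Hamming distance from each test signature to any training signature
min_hamming <- function(train_sigs, test_sigs) {
  tr <- do.call(rbind, strsplit(train_sigs, ""))
  te <- do.call(rbind, strsplit(test_sigs, ""))
  vapply(seq_len(nrow(te)), function(i)
    min(rowSums(tr != matrix(te[i, ], nrow(tr), 24L, byrow = TRUE))), 0)
}

#' Stratify test signatures into Hamming-distance bins
#'
#' Bin `Bk+` contains the test points whose minimum Hamming distance to any
#' training point is at least `k`; bins are nested (`B(k+1)+` inside `Bk+`).
#' Accuracy per bin is reported when labels and predictions are supplied.
#'
#' @param train_sigs,test_sigs character vectors of length-24 signatures.
#' @param ks integer thresholds.
#' @param test_labels,predictions optional true labels and predicted labels
#'   for the test signatures.
#' @return data.frame with columns `k`, `n`, and (optionally) `accuracy`,
#'   plus a `members` attribute (list of test indices per bin).
#' @export
hamming_bins <- function(train_sigs, test_sigs, ks = 0:8,
                         test_labels = NULL, predictions = NULL) {
  if (!length(train_sigs)) stop("empty training set")
  stopifnot(all(nchar(c(train_sigs, test_sigs)) == 24L))
  d <- min_hamming(train_sigs, test_sigs)
  members <- lapply(ks, function(k) which(d >= k))
  out <- data.frame(k = ks, n = lengths(members))
  if (!is.null(test_labels) && !is.null(predictions)) {
    out$accuracy <- vapply(members, function(ix)
      if (length(ix)) mean(predictions[ix] == test_labels[ix]) else NA_real_,
      0)
  }
  attr(out, "members") <- members
  out
}

#' Cross-validate the specificity classifier
#'
#' Repeated k-fold cross-validation: for each shuffle the data are randomly
#' split into `folds` near-equal disjoint subsets; each subset serves as test
#' data once.  Reported accuracy is the mean over all shuffles and folds; the
#' confusion matrix is averaged over shuffles and rounded to integers.
#'
#' @param signatures,labels the labeled dataset.
#' @param folds,shuffles number of folds and independent reshuffles.
#' @param seed RNG seed.
#' @param n_trees,max_depth forwarded to [train_specificity_model].
#' @return list with `accuracy`, `fold_accuracy` (shuffle x fold matrix),
#'   `confusion` (rounded mean counts), and `assignments` (per-shuffle fold
#'   index of each datum).
#' @export
crossvalidate_specificity <- function(signatures, labels, folds = 5L,
                                      shuffles = 5L, seed = 1L,
                                      n_trees = 150L, max_depth = 10L) {
  n <- length(signatures)
  if (folds > n) stop("folds (", folds, ") exceeds dataset size (", n, ")")
  labels <- as.character(labels)
  vocab <- sort(unique(labels))
  acc <- matrix(NA_real_, shuffles, folds)
  conf <- matrix(0, length(vocab), length(vocab),
                 dimnames = list(truth = vocab, predicted = vocab))
  assignments <- matrix(NA_integer_, shuffles, n)
  for (s in seq_len(shuffles)) {
    set.seed(seed + s - 1L)
    fold <- sample(rep_len(seq_len(folds), n))
    assignments[s, ] <- fold
    for (f in seq_len(folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      m <- train_specificity_model(signatures[tr], labels[tr],
                                   n_trees = n_trees, max_depth = max_depth,
                                   seed = seed + s * 1000L + f)
      pr <- predict_specificity(m, signatures[te])$label
      acc[s, f] <- mean(pr == labels[te])
      for (i in seq_along(te))
        conf[labels[te[i]], pr[i]] <- conf[labels[te[i]], pr[i]] + 1
    }
  }
  list(accuracy = mean(acc), fold_accuracy = acc,
       confusion = round(conf / shuffles), assignments = assignments)
}

#' Read an AT-domain training table
#'
#' TSV with columns `id`, `sequence_or_signature`, `label`.  Entries of
#' length 24 are taken as ready signatures; longer entries are full AT
#' sequences and are passed through [extract_signature].
#'
#' @param path TSV path.
#' @param reference reference profile for signature extraction.
#' @return data.frame with `id`, `signature`, `label`.
#' @export
read_at_training <- function(path, reference = load_at_reference()) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence_or_signature", "label")
  if (!all(need %in% names(tb)))
    stop("training TSV must have columns: ", paste(need, collapse = ", "))
  sig <- vapply(tb$sequence_or_signature, function(s) {
    if (nchar(s) == 24L) toupper(s) else extract_signature(s, reference)
  }, "", USE.NAMES = FALSE)
  data.frame(id = tb$id, signature = sig, label = tb$label,
             stringsAsFactors = FALSE)
}
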