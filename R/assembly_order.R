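# ---- assembly-order prediction from docking domains ------------------------
#
# Consecutive PKS proteins in the assembly line recognise each other through
# short terminal docking regions.  Compatibility of a (tail, head) pair is
# scored by a logistic model over pairwise-nearest-neighbour (PNN) features:
# BLOSUM62 local-alignment bit-scores to the top-n interacting and top-n
# non-interacting training pairs.  Candidate gene orders are ranked by the
# pathway score, which sums consecutive-pair interaction scores with
# configurable rewards for pairs that preserve (or invert) genomic
# adjacency.

# BLAST gapped BLOSUM62(11,1) Karlin-Altschul constants
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Local-alignment bit-score between two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 (gap open 11, extend 1);
#' the raw score `S` is converted to bits as `(lambda * S - ln K) / ln 2`
#' with the standard gapped-BLOSUM62 constants. Empty input scores 0 bits.
#'
#' @param a,b amino-acid strings.
#' @return bit-score (symmetric in its arguments).
#' @export
bitscore <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  bitscore_matrix(a, b)[1, 1]
}

#' Bit-score matrix between two sets of sequences
#' @param queries,refs character vectors of amino-acid strings.
#' @return `length(queries)` x `length(refs)` matrix of bit-scores.
#' @export
bitscore_matrix <- function(queries, refs) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62")
  out <- matrix(0, length(queries), length(refs))
  ok_q <- nzchar(queries)
  for (j in seq_along(refs)) {
    if (!nzchar(refs[j]) || !any(ok_q)) next
    s <- Biostrings::pairwiseAlignment(
      queries[ok_q], refs[j], type = "local", substitutionMatrix = B62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    out[ok_q, j] <- (.KA_LAMBDA * pmax(s, 0) - log(.KA_K)) / log(2)
  }
  out
}

#' Construct a docking pair
#' @param tail_seq C-terminal docking region of the upstream gene.
#' @param head_seq N-terminal docking region of the downstream gene.
#' @param label optional logical interaction label (training data only).
#' @param id identifier.
#' @return a `docking_pair`.
#' @export
docking_pair <- function(tail_seq, head_seq, label = NULL, id = NA_character_) {
  stopifnot(nzchar(tail_seq), nzchar(head_seq))
  structure(list(tail_seq = toupper(tail_seq), head_seq = toupper(head_seq),
                 label = label, id = id),
            class = "docking_pair")
}

#' Similarity between two head-tail pairs
#'
#' Sum of the head-head and tail-tail bit-scores (larger = more similar).
#'
#' @param p,q `docking_pair` objects.
#' @return summed bit-score.
#' @export
pair_distance <- function(p, q) {
  bitscore(p$head_seq, q$head_seq) + bitscore(p$tail_seq, q$tail_seq)
}

#' Extract docking regions from a BGC
#'
#' The head docking region is the first `head_len` N-terminal residues of
#' each gene's protein and the tail region the last `tail_len` C-terminal
#' residues.  The head of the pathway's first gene and the tail of its last
#' gene take no part in docking and are marked excluded; the start anchor is
#' a gene whose first module lacks a KS domain, the end anchor a gene
#' containing a TE domain (no exclusion when no anchor is found).  Proteins
#' shorter than `head_len + tail_len` contribute their whole sequence to
#' both regions, with a warning.
#'
#' @param bgc a `pks_bgc`.
#' @param head_len,tail_len region lengths in residues.
#' @return data.frame with `gene`, `head_seq`, `tail_seq`,
#'   `head_excluded`, `tail_excluded`.
#' @export
extract_docking <- function(bgc, head_len = 100L, tail_len = 50L) {
  genes <- bgc$genes
  recs <- lapply(genes, function(g) {
    n <- nchar(g$protein)
    if (n < head_len + tail_len) {
      warning("protein of gene ", g$id, " shorter than head+tail (", n,
              " aa); regions truncated to the whole protein", call. = FALSE)
      head <- g$protein; tail <- g$protein
    } else {
      head <- substr(g$protein, 1L, head_len)
      tail <- substr(g$protein, n - tail_len + 1L, n)
    }
    has_te <- any(vapply(g$modules, function(m)
      !is.null(module_domain(m, "TE")), TRUE))
    first_mod_no_ks <- length(g$modules) > 0L &&
      is.null(module_domain(g$modules[[1]], "KS"))
    data.frame(gene = g$id, head_seq = head, tail_seq = tail,
               is_start_anchor = first_mod_no_ks, is_end_anchor = has_te,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  df$head_excluded <- FALSE; df$tail_excluded <- FALSE
  if (sum(df$is_start_anchor) == 1L) df$head_excluded[df$is_start_anchor] <- TRUE
  if (sum(df$is_end_anchor) == 1L) df$tail_excluded[df$is_end_anchor] <- TRUE
  df$is_start_anchor <- NULL; df$is_end_anchor <- NULL
  df
}

#' Read a docking-pair training table
#'
#' TSV columns: `id_tail`, `id_head`, `tail_seq`, `head_seq`, `label`
#' (1/0 or TRUE/FALSE).
#'
#' @param path TSV path.
#' @return list of `docking_pair` objects with labels.
#' @export
read_docking_training <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id_tail", "id_head", "tail_seq", "head_seq", "label")
  if (!all(need %in% names(tb)))
    stop("docking TSV must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tb)), function(i)
    docking_pair(tb$tail_seq[i], tb$head_seq[i],
                 label = as.logical(as.integer(tb$label[i])),
                 id = paste(tb$id_tail[i], tb$id_head[i], sep = "~")))
}

# bit-score caches between query pairs and training pairs
.docking_scores <- function(queries, training) {
  qh <- vapply(queries, `[[`, "", "head_seq")
  qt <- vapply(queries, `[[`, "", "tail_seq")
  th <- vapply(training, `[[`, "", "head_seq")
  tt <- vapply(training, `[[`, "", "tail_seq")
  list(head = bitscore_matrix(qh, th), tail = bitscore_matrix(qt, tt))
}

#' Pairwise-nearest-neighbour features for a docking pair
#'
#' The `n` most similar interacting and `n` most similar non-interacting
#' training pairs (by [pair_distance], ties broken by id) are selected.  In
#' mode `per_score` the head and tail bit-scores to each neighbour are
#' emitted separately (4n features); in mode `summed` the summed score per
#' neighbour is emitted (2n features).
#'
#' @param query a `docking_pair`.
#' @param training list of labeled `docking_pair` objects.
#' @param n neighbours per class.
#' @param feature_mode `"per_score"` or `"summed"`.
#' @param exclude_id training id to leave out (self-exclusion during
#'   training-set feature construction).
#' @return numeric feature vector.
#' @export
pnn_features <- function(query, training, n = 3L,
                         feature_mode = c("per_score", "summed"),
                         exclude_id = NULL) {
  feature_mode <- match.arg(feature_mode)
  sc <- .docking_scores(list(query), training)
  .pnn_features_row(sc$head[1, ], sc$tail[1, ], training, n, feature_mode,
                    exclude_id)
}

.pnn_features_row <- function(head_bs, tail_bs, training, n, feature_mode,
                              exclude_id = NULL) {
  labs <- vapply(training, function(p) isTRUE(p$label), TRUE)
  ids <- vapply(training, `[[`, "", "id")
  use <- if (is.null(exclude_id)) rep(TRUE, length(training)) else ids != exclude_id
  feats <- lapply(c(TRUE, FALSE), function(cls) {
    ix <- which(labs == cls & use)
    if (length(ix) < n)
      stop("insufficient ", if (cls) "interacting" else "non-interacting",
           " training pairs (need ", n, ", have ", length(ix), ")")
    d <- head_bs[ix] + tail_bs[ix]
    ord <- ix[order(-d, ids[ix])][seq_len(n)]
    if (feature_mode == "per_score")
      as.numeric(rbind(head_bs[ord], tail_bs[ord]))
    else head_bs[ord] + tail_bs[ord]
  })
  unlist(feats)
}

#' Train the docking-interaction model
#'
#' Negative pairs are subsampled (seeded) to the positive count to balance
#' the classes; a logistic regression is fit on PNN features, with each
#' training pair's features computed against the training set excluding
#' itself.
#'
#' @param pairs list of labeled `docking_pair` objects.
#' @param n neighbours per class.
#' @param feature_mode `"per_score"` (4n features) or `"summed"` (2n).
#' @param seed RNG seed for the balancing subsample.
#' @return an `interaction_model` (carries its training set for PNN
#'   feature construction at prediction time).
#' @export
train_interaction_model <- function(pairs, n = 3L,
                                    feature_mode = c("per_score", "summed"),
                                    seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  labs <- vapply(pairs, function(p) isTRUE(p$label), TRUE)
  if (!any(labs) || all(labs))
    stop("both interacting and non-interacting pairs are required")
  pos <- which(labs); neg <- which(!labs)
  set.seed(seed)
  if (length(neg) > length(pos)) neg <- sort(sample(neg, length(pos)))
  train <- pairs[c(pos, neg)]
  sc <- .docking_scores(train, train)
  ids <- vapply(train, `[[`, "", "id")
  x <- t(vapply(seq_along(train), function(i)
    .pnn_features_row(sc$head[i, ], sc$tail[i, ], train, n, feature_mode,
                      exclude_id = ids[i]),
    numeric(if (feature_mode == "per_score") 4L * n else 2L * n)))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- vapply(train, function(p) isTRUE(p$label), TRUE)
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
  structure(list(fit = fit, training = train, n = n,
                 feature_mode = feature_mode,
                 n_pos = length(pos), n_neg = length(neg), seed = seed),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("<interaction_model> logistic over PNN features (n = ", x$n, ", mode ",
      x$feature_mode, "); trained on ", x$n_pos, " + / ", x$n_neg, " -\n",
      sep = "")
  invisible(x)
}

#' Interaction probability for docking pairs
#' @param model an `interaction_model`.
#' @param pairs a `docking_pair` or list of them.
#' @return numeric vector of interaction probabilities in (0, 1).
#' @export
predict_interaction <- function(model, pairs) {
  if (inherits(pairs, "docking_pair")) pairs <- list(pairs)
  sc <- .docking_scores(pairs, model$training)
  x <- t(vapply(seq_along(pairs), function(i)
    .pnn_features_row(sc$head[i, ], sc$tail[i, ], model$training, model$n,
                      model$feature_mode),
    numeric(if (model$feature_mode == "per_score") 4L * model$n
            else 2L * model$n)))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- stats::predict(model$fit, newdata = as.data.frame(x), type = "response")
  pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
}

#' Pathway score of a gene order
#'
#' Each consecutive pair in the order is classed by its genomic relation:
#' `Forward` (downstream rank = upstream rank + 1), `Backward` (reversed
#' adjacency), else `Non-adj`; the score sums pair scores with the class
#' weights.  With unit weights this collapses to the plain sum of
#' consecutive-pair scores.
#'
#' @param order character vector of gene ids (a permutation).
#' @param pair_score matrix of pair scores, rows = upstream (tail) gene,
#'   columns = downstream (head) gene, dimnames = gene ids.
#' @param ranks named integer vector of genomic ranks per gene id.
#' @param w_forward,w_backward class weights (default 1).
#' @return the pathway score.
#' @export
score_pathway <- function(order, pair_score, ranks, w_forward = 1,
                          w_backward = 1) {
  if (length(order) < 2L) return(0)
  ranks <- stats::setNames(rank(ranks), names(ranks))  # adjacency by rank order
  up <- order[-length(order)]; dn <- order[-1L]
  s <- pair_score[cbind(up, dn)]
  if (anyNA(s)) stop("missing pair score for pair ",
                     paste(up[is.na(s)][1], dn[is.na(s)][1], sep = "->"))
  dr <- ranks[dn] - ranks[up]
  w <- ifelse(dr == 1L, w_forward, ifelse(dr == -1L, w_backward, 1))
  sum(s * w)
}

# all permutations of 1..n as an (n!) x n integer matrix, lexicographic rows
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), i)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Rank candidate assembly pathways
#'
#' For BGCs of up to `exhaustive_limit` genes, all permutations are scored
#' and sorted (descending score, ties by lexicographic permutation).  Larger
#' BGCs are searched best-first with an admissible per-slot bound, returning
#' the top `cap` orders.
#'
#' @param bgc a `pks_bgc`.
#' @param model an `interaction_model`; `NULL` scores every pair 0.5 (used
#'   for single-gene clusters or diagnostics).
#' @param w_forward,w_backward pathway-score class weights.
#' @param cap maximum number of orders returned.
#' @param head_len,tail_len forwarded to [extract_docking].
#' @param exhaustive_limit largest gene count enumerated exhaustively.
#' @return list with `orders` (data.frame: rank, order, score,
#'   probability), `pair_score` matrix, `n_candidates` (count of orders
#'   considered: g! in exhaustive mode).
#' @export
rank_pathways <- function(bgc, model, w_forward = 1, w_backward = 1,
                          cap = 1000L, head_len = 100L, tail_len = 50L,
                          exhaustive_limit = 9L) {
  if (cap < 1L) stop("cap must be >= 1")
  genes <- vapply(bgc$genes, `[[`, "", "id")
  ranks <- rank(vapply(bgc$genes, `[[`, 1L, "genomic_rank"))
  names(ranks) <- genes
  g <- length(genes)
  if (g == 1L) {
    return(list(orders = data.frame(rank = 1L, order = genes, score = 0,
                                    probability = 1),
                pair_score = matrix(NA_real_, 1, 1,
                                    dimnames = list(genes, genes)),
                n_candidates = 1L))
  }
  dock <- extract_docking(bgc, head_len, tail_len)
  S <- matrix(NA_real_, g, g, dimnames = list(genes, genes))
  qpairs <- list(); qi <- integer(0); qj <- integer(0)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    qpairs[[length(qpairs) + 1L]] <-
      docking_pair(dock$tail_seq[i], dock$head_seq[j],
                   id = paste(genes[i], genes[j], sep = "->"))
    qi <- c(qi, i); qj <- c(qj, j)
  }
  p <- if (is.null(model)) rep(0.5, length(qpairs))
       else predict_interaction(model, qpairs)
  S[cbind(qi, qj)] <- p

  if (g <= exhaustive_limit) {
    P <- .perms(g)
    up <- P[, -g, drop = FALSE]; dn <- P[, -1L, drop = FALSE]
    sc <- matrix(S[cbind(as.vector(up), as.vector(dn))], nrow(P))
    dr <- matrix(ranks[as.vector(dn)] - ranks[as.vector(up)], nrow(P))
    w <- ifelse(dr == 1L, w_forward, ifelse(dr == -1L, w_backward, 1))
    total <- rowSums(sc * w)
    ord <- do.call(order, c(list(-total),
                            lapply(seq_len(g), function(k) P[, k])))
    n_cand <- nrow(P)
    top <- ord[seq_len(min(cap, n_cand))]
    perm_ids <- matrix(genes[P[top, ]], length(top))
    orders <- data.frame(
      rank = seq_along(top),
      order = apply(perm_ids, 1, paste, collapse = ","),
      score = total[top])
  } else {
    res <- .branch_and_bound(S, ranks, w_forward, w_backward, cap)
    orders <- data.frame(
      rank = seq_len(nrow(res$perm)),
      order = apply(matrix(genes[res$perm], nrow(res$perm)), 1,
                    paste, collapse = ","),
      score = res$score)
    n_cand <- factorial(g)
  }
  orders$probability <- {
    e <- exp(orders$score - max(orders$score))
    e / sum(e)
  }
  list(orders = orders, pair_score = S, n_candidates = n_cand)
}

# best-first search over partial orders; bound adds, for each unplaced
# slot, the maximum pair score achievable into any remaining gene
.branch_and_bound <- function(S, ranks, w_forward, w_backward, cap) {
  g <- nrow(S)
  wS <- function(i, j) {
    dr <- ranks[j] - ranks[i]
    S[i, j] * if (dr == 1L) w_forward else if (dr == -1L) w_backward else 1
  }
  Wmax <- max(1, w_forward, w_backward)
  colmax <- apply(S, 2, max, na.rm = TRUE) * Wmax
  # priority queue as a list sorted by bound (small scale: g! pruned hard)
  heap <- list(list(perm = integer(0), score = 0,
                    bound = sum(sort(colmax, decreasing = TRUE)[seq_len(g - 1L)])))
  out_perm <- NULL; out_score <- numeric(0)
  while (length(heap)) {
    bounds <- vapply(heap, `[[`, 0, "bound")
    k <- which.max(bounds)
    node <- heap[[k]]; heap[[k]] <- NULL
    if (length(node$perm) == g) {
      out_perm <- rbind(out_perm, node$perm)
      out_score <- c(out_score, node$score)
      if (length(out_score) >= cap) break
      next
    }
    rest <- setdiff(seq_len(g), node$perm)
    for (nx in rest) {
      sc <- node$score +
        if (length(node$perm)) wS(node$perm[length(node$perm)], nx) else 0
      remaining <- setdiff(rest, nx)
      b <- sc + if (length(remaining))
        sum(colmax[remaining]) else 0
      heap[[length(heap) + 1L]] <- list(perm = c(node$perm, nx), score = sc,
                                        bound = b)
    }
  }
  list(perm = out_perm, score = out_score)
}
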