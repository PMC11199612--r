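# ---- deterministic synthetic fixtures --------------------------------------
#
# Generators for synthetic BGCs, labeled AT-signature sets, docking-pair
# training sets and synthetic spectra with known ground truth, so that
# every pipeline stage is testable without external data.  The sequences
# carry only the planted signals (label-determining signature residues,
# cognate docking motifs, catalytic-domain patterns) on a random background;
# they do not attempt biological realism beyond that.

.rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

.embed <- function(seq, motif, at) {
  paste0(substr(seq, 1L, at - 1L), motif,
         substr(seq, at + nchar(motif), nchar(seq)))
}

# label -> 3 distinguishing residues planted at signature positions 3, 9, 15
.label_code <- function(label, labels) {
  l <- match(label, sort(labels))
  .AA20[((l - 1L) * 3L + c(0L, 7L, 14L)) %% 20L + 1L]
}

.SIG_POSITIONS <- c(3L, 9L, 15L)

# signature string for a label: reference signature with planted residues
# and `wobble` random non-informative positions
.label_signature <- function(label, labels, reference, wobble = 4L) {
  base <- strsplit(reference$sequence, "")[[1]][reference$columns + 1L]
  base[.SIG_POSITIONS] <- .label_code(label, labels)
  free <- setdiff(seq_len(24L), .SIG_POSITIONS)
  w <- sample(free, wobble)
  base[w] <- sample(.AA20, wobble, replace = TRUE)
  paste(base, collapse = "")
}

#' Generate a separable labeled AT-signature training set
#'
#' Each label is assigned three distinguishing residues planted at fixed
#' signature positions; remaining positions wobble randomly, so the set is
#' perfectly separable by construction.
#'
#' @param seed RNG seed.
#' @param labels substrate labels.
#' @param n_per_label examples per label.
#' @param reference AT reference profile.
#' @return data.frame with `id`, `signature`, `label`.
#' @export
make_at_training <- function(seed = 1L, labels = c("mal", "mmal"),
                             n_per_label = 30L,
                             reference = load_at_reference()) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(id = paste0(lab, "_", seq_len(n_per_label)),
               signature = vapply(seq_len(n_per_label), function(i)
                 .label_signature(lab, labels, reference), ""),
               label = lab, stringsAsFactors = FALSE)
  }))
  recs[sample(nrow(recs)), , drop = FALSE]
}

# deterministic pool of cognate docking-motif codes (tail motif, head motif)
.docking_code_pool <- function(pool_seed = 777L, n_codes = 8L,
                               motif_len = 12L) {
  set.seed(pool_seed)
  lapply(seq_len(n_codes), function(i)
    list(tail = .rand_aa(motif_len), head = .rand_aa(motif_len)))
}

#' Generate a docking-pair training set with planted cognate motifs
#'
#' Interacting pairs share a cognate motif code: the tail carries the
#' code's tail motif and the head its head motif.  Non-interacting pairs
#' carry mismatched codes or none.  The code pool is drawn from
#' `pool_seed`, so training sets and fixture BGCs built from the same pool
#' share the planted docking chemistry.
#'
#' @param seed RNG seed for this set.
#' @param n_codes size of the cognate code pool.
#' @param pos_per_code interacting pairs per code.
#' @param n_neg non-interacting pairs.
#' @param pool_seed seed of the shared code pool.
#' @param head_len,tail_len docking-region lengths.
#' @return list of labeled `docking_pair` objects.
#' @export
make_docking_training <- function(seed = 1L, n_codes = 8L, pos_per_code = 6L,
                                  n_neg = 4L * n_codes * pos_per_code,
                                  pool_seed = 777L, head_len = 100L,
                                  tail_len = 50L) {
  pool <- .docking_code_pool(pool_seed, n_codes)
  set.seed(seed)
  pos <- list()
  for (c in seq_len(n_codes)) for (i in seq_len(pos_per_code)) {
    tail <- .embed(.rand_aa(tail_len), pool[[c]]$tail, 20L)
    head <- .embed(.rand_aa(head_len), pool[[c]]$head, 41L)
    pos[[length(pos) + 1L]] <-
      docking_pair(tail, head, label = TRUE,
                   id = sprintf("pos_c%02d_%02d", c, i))
  }
  neg <- list()
  for (i in seq_len(n_neg)) {
    if (i %% 2L == 0L) {
      cc <- sample(n_codes, 2L)  # mismatched cognate codes
      tail <- .embed(.rand_aa(tail_len), pool[[cc[1]]]$tail, 20L)
      head <- .embed(.rand_aa(head_len), pool[[cc[2]]]$head, 41L)
    } else {
      tail <- .rand_aa(tail_len); head <- .rand_aa(head_len)
    }
    neg[[length(neg) + 1L]] <-
      docking_pair(tail, head, label = FALSE, id = sprintf("neg_%03d", i))
  }
  c(pos, neg)
}

#' Fixture specification for a synthetic BGC
#'
#' @param seed RNG seed.
#' @param n_genes gene count.
#' @param modules_per_gene modules per gene (scalar or vector).
#' @param labels substrate label per module, recycled (list of character
#'   vectors, one per gene, or a single vector recycled across modules).
#' @param order planted assembly order as a permutation of gene indices
#'   (default: identity = colinear).
#' @param reductive per-module reductive-domain sets, recycled: each entry
#'   a subset of `c("KR","DH","ER")`.
#' @param enzymes tailoring-enzyme tags carried by the BGC.
#' @param dropout,jitter_sd,n_decoy_peaks spectrum noise model.
#' @param pool_seed docking code pool seed (shared with the training
#'   generator).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 3L, modules_per_gene = 2L,
                         labels = c("mal", "mmal"),
                         order = seq_len(n_genes),
                         reductive = list(character(0), "KR",
                                          c("KR", "DH"), c("KR", "DH", "ER")),
                         enzymes = character(0),
                         dropout = 0, jitter_sd = 0, n_decoy_peaks = 0L,
                         pool_seed = 777L) {
  stopifnot(setequal(order, seq_len(n_genes)), dropout >= 0, dropout <= 1)
  structure(list(seed = seed, n_genes = n_genes,
                 modules_per_gene = rep_len(modules_per_gene, n_genes),
                 labels = labels, order = as.integer(order),
                 reductive = reductive, enzymes = enzymes,
                 dropout = dropout, jitter_sd = jitter_sd,
                 n_decoy_peaks = as.integer(n_decoy_peaks),
                 pool_seed = pool_seed),
            class = "fixture_spec")
}

#' Generate a synthetic BGC with planted ground truth
#'
#' Genes are emitted in genomic order; the planted assembly order may
#' differ.  Consecutive genes in the planted order receive cognate docking
#' motifs from the shared code pool; AT domains carry label-determining
#' signature residues; KR/DH/ER domains carry their catalytic patterns;
#' the first assembly gene's first module lacks a KS (start anchor) and the
#' last assembly gene ends in a TE (end anchor).
#'
#' @param spec a [fixture_spec].
#' @param reference AT reference profile.
#' @return list with `bgc` (a `pks_bgc`) and `truth` (planted order as
#'   gene ids, per-gene module labels, reductive sets, enzyme tags).
#' @export
make_bgc <- function(spec, reference = load_at_reference()) {
  pool <- .docking_code_pool(spec$pool_seed,
                             n_codes = max(8L, spec$n_genes))
  set.seed(spec$seed)
  n <- spec$n_genes
  ids <- sprintf("pksA%d", seq_len(n))
  # junction j sits between planted order position j and j+1
  codes <- sample(length(pool), max(n - 1L, 0L))
  pos_of <- match(seq_len(n), spec$order)  # gene index -> position in order

  labels_all <- list(); reduct_all <- list()
  mk_domain_block <- function(kind, label = NULL, reduct = character(0)) {
    switch(kind,
      KS = .embed(.rand_aa(60L), "GPAAAAAAC", 11L),
      AT = {
        sig <- .label_signature(label, spec$labels, reference)
        ref_chars <- strsplit(reference$sequence, "")[[1]]
        ref_chars[reference$columns + 1L] <- strsplit(sig, "")[[1]]
        paste(ref_chars, collapse = "")
      },
      KR = .embed(.rand_aa(60L), "GAGLLG", 11L),
      DH = .embed(.rand_aa(60L), "HAAAGAAAAP", 11L),
      ER = .embed(.rand_aa(60L), "GAGLLA", 11L),
      ACP = .rand_aa(60L),
      TE = .embed(.rand_aa(60L), "GYSYG", 11L))
  }
  genes <- vector("list", n)
  li <- 0L
  for (gi in seq_len(n)) {
    p <- pos_of[gi]
    head <- .rand_aa(100L)
    if (p > 1L) head <- .embed(head, pool[[codes[p - 1L]]]$head, 41L)
    tail <- .rand_aa(50L)
    if (p < n) tail <- .embed(tail, pool[[codes[p]]]$tail, 20L)
    body <- ""
    modules <- list()
    glabels <- character(0); greduct <- list()
    offset <- nchar(head)
    for (mi in seq_len(spec$modules_per_gene[gi])) {
      li <- li + 1L
      lab <- rep_len(spec$labels, 100L)[li]
      red <- spec$reductive[[(li - 1L) %% length(spec$reductive) + 1L]]
      glabels <- c(glabels, lab); greduct <- c(greduct, list(red))
      kinds <- c(if (!(p == 1L && mi == 1L)) "KS", "AT", red, "ACP",
                 if (p == n && mi == spec$modules_per_gene[gi]) "TE")
      doms <- list()
      for (k in kinds) {
        blk <- mk_domain_block(k, label = lab)
        doms[[length(doms) + 1L]] <-
          pks_domain(k, blk, start = offset, end = offset + nchar(blk))
        body <- paste0(body, blk)
        offset <- offset + nchar(blk)
      }
      modules[[length(modules) + 1L]] <- pks_module(doms, index = mi - 1L)
    }
    protein <- paste0(head, body, tail)
    genes[[gi]] <- pks_gene(ids[gi], protein, modules, genomic_rank = gi,
                            strand = "+",
                            start = (gi - 1L) * 20000 + 1,
                            end = (gi - 1L) * 20000 + nchar(protein) * 3)
    labels_all[[gi]] <- glabels; reduct_all[[gi]] <- greduct
  }
  tes <- lapply(spec$enzymes, function(tg) pks_domain(tg, .rand_aa(120L)))
  bgc <- pks_bgc(genes, tes, source = list(fixture_seed = spec$seed))
  list(bgc = bgc,
       truth = list(order = ids[spec$order], labels = labels_all,
                    reductive = reduct_all, enzymes = spec$enzymes,
                    codes = codes))
}

#' Generate a synthetic spectrum for a molecule
#'
#' Peaks are the depth-2 fragment masses as singly-protonated ions, thinned
#' by `dropout`, jittered with Gaussian noise, plus uniform random decoy
#' peaks; the precursor is the protonated molecule.
#'
#' @param mg a [molgraph] (or `candidate_compound`).
#' @param seed RNG seed.
#' @param dropout peak dropout probability.
#' @param jitter_sd m/z jitter standard deviation (Da).
#' @param n_decoy_peaks uniform background peaks added.
#' @param id spectrum identifier.
#' @return a `pks_spectrum`.
#' @export
make_spectrum <- function(mg, seed = 1L, dropout = 0, jitter_sd = 0,
                          n_decoy_peaks = 0L, id = "synthetic") {
  if (inherits(mg, "candidate_compound")) mg <- mg$mg
  set.seed(seed)
  fr <- fragment(mg, 2L)
  mz <- fr$mass + .PROTON_MASS
  keep <- stats::runif(length(mz)) >= dropout
  mz <- mz[keep]
  if (jitter_sd > 0) mz <- mz + stats::rnorm(length(mz), 0, jitter_sd)
  if (n_decoy_peaks > 0L && length(mz))
    mz <- c(mz, stats::runif(n_decoy_peaks, min(mz), max(mz) + 10))
  intensity <- stats::runif(length(mz), 50, 100)
  pks_spectrum(mg_mass(mg) + .PROTON_MASS, 1L, mz, intensity, id = id)
}
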