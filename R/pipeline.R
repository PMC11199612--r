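# ---- pipeline orchestration ------------------------------------------------

#' Assemble cores for a ranked gene order
#'
#' Builds the per-module substrates (AT specificity + reduction ladder) for
#' every extension module of the BGC, in the given assembly order, and
#' releases core structures.  Modules without an AT domain (unpredictable
#' starter units) are skipped with a notice; downstream spectral search
#' should then run in variable mode.
#'
#' @param bgc a `pks_bgc`.
#' @param order character vector of gene ids (assembly order).
#' @param labels named character vector: predicted substrate label per
#'   module, names `"<gene>:<module index>"`.
#' @param library monomer library.
#' @param motif_table catalytic motifs for inactive-domain detection
#'   (`NULL` to skip detection and trust input flags).
#' @return list with `cores` (list of `core_structure`), `skipped_starter`
#'   (TRUE when a module lacked an AT).
#' @export
build_cores <- function(bgc, order, labels,
                        library = load_monomer_library(),
                        motif_table = load_catalytic_motifs()) {
  genes <- stats::setNames(bgc$genes, vapply(bgc$genes, `[[`, "", "id"))
  substrates <- list()
  skipped <- FALSE
  te_present <- FALSE
  for (gid in order) {
    g <- genes[[gid]]
    for (m in g$modules) {
      if (!is.null(motif_table)) m <- detect_inactive_domains(m, motif_table)
      if (!is.null(module_domain(m, "TE"))) te_present <- TRUE
      if (is.null(module_domain(m, "AT"))) {
        skipped <- TRUE
        message("module ", m$index, " of gene ", gid,
                " has no AT (starter unit?); skipped - use variable search")
        next
      }
      lab <- labels[[paste0(gid, ":", m$index)]]
      substrates[[length(substrates) + 1L]] <-
        module_substrate(m, lab, library)
    }
  }
  if (!length(substrates)) stop("no extension modules with AT domains")
  chain <- assemble_core(substrates)
  list(cores = release_products(chain, te_present = te_present),
       skipped_starter = skipped)
}

#' Run the full prediction pipeline
#'
#' parse -> specificity -> substrates -> order -> cores -> modifications ->
#' (optional) spectral search -> (optional) FDR.  Stage outputs are written
#' under `out_dir` together with a manifest recording the configuration and
#' completed stages; outputs are pure functions of (inputs, config, seed).
#'
#' @param bgc a `pks_bgc`, or path to a BGC JSON / GenBank file.
#' @param at_training path to the AT training TSV, or a data.frame from
#'   [read_at_training] / [make_at_training].
#' @param docking_training path to the docking TSV, or a list of
#'   `docking_pair`; `NULL` ranks orders with uninformative pair scores.
#' @param spectra optional path to an MGF/mzML file, or list of
#'   `pks_spectrum`.
#' @param out_dir output directory (created).
#' @param seed master seed for all stochastic stages.
#' @param top_orders number of ranked orders carried into core assembly.
#' @param search_mode `"exact"`, `"variable"`, or `"auto"` (variable when a
#'   starter module was skipped).
#' @param fdr_threshold score threshold for the optional FDR stage
#'   (requires spectra; `NULL` skips).
#' @param db modification rule database.
#' @param cap candidate enumeration cap.
#' @param frag_tol,prec_tol,max_shift scoring tolerances (Da).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(bgc, at_training, docking_training = NULL,
                         spectra = NULL, out_dir, seed = 1L,
                         top_orders = 1L,
                         search_mode = c("auto", "exact", "variable"),
                         fdr_threshold = NULL,
                         db = load_modification_db(), cap = 1e5,
                         frag_tol = 0.02, prec_tol = 0.02, max_shift = 400) {
  search_mode <- match.arg(search_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = character(0),
                   config = list(top_orders = top_orders,
                                 search_mode = search_mode,
                                 fdr_threshold = fdr_threshold, cap = cap,
                                 frag_tol = frag_tol, prec_tol = prec_tol,
                                 max_shift = max_shift))
  save_manifest <- function() jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null", force = TRUE)
  done <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    save_manifest()
  }

  # -- parse
  if (is.character(bgc)) {
    bgc <- if (grepl("\\.(gb|gbk|genbank)$", bgc, ignore.case = TRUE))
      parse_genbank_region(bgc) else parse_bgc_json(bgc)
  }
  if (!is.null(spectra) && is.character(spectra) && !file.exists(spectra))
    stop("spectral search requested but spectra file not found: ", spectra)
  write_bgc_json(bgc, file.path(out_dir, "bgc.json"))
  done("parse")

  # -- specificity
  if (is.character(at_training)) at_training <- read_at_training(at_training)
  sp_model <- train_specificity_model(at_training$signature,
                                      at_training$label, seed = seed)
  reference <- load_at_reference()
  mods <- list()
  for (g in bgc$genes) for (m in g$modules) {
    at <- module_domain(m, "AT")
    if (is.null(at)) next
    key <- paste0(g$id, ":", m$index)
    mods[[key]] <- extract_signature(at$sequence, reference)
  }
  labels <- character(0)
  if (length(mods)) {
    pred <- predict_specificity(sp_model, unlist(mods))
    labels <- stats::setNames(pred$label, names(mods))
    utils::write.table(
      data.frame(module = names(mods), signature = unlist(mods),
                 label = labels),
      file.path(out_dir, "specificity.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  done("specificity")

  # -- order
  if (!is.null(docking_training) && is.character(docking_training))
    docking_training <- read_docking_training(docking_training)
  io_model <- if (is.null(docking_training)) NULL
              else train_interaction_model(docking_training, seed = seed)
  ranking <- rank_pathways(bgc, io_model)
  utils::write.table(utils::head(ranking$orders, 1000L),
                     file.path(out_dir, "orders.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  done("order")

  # -- cores (+ substrates)
  lib <- load_monomer_library()
  all_cores <- list()
  skipped_starter <- FALSE
  for (r in seq_len(min(top_orders, nrow(ranking$orders)))) {
    ord <- strsplit(ranking$orders$order[r], ",")[[1]]
    built <- build_cores(bgc, ord, labels, lib)
    skipped_starter <- skipped_starter || built$skipped_starter
    for (co in built$cores) {
      co$provenance <- paste0("rank", r, ":", co$provenance)
      all_cores[[length(all_cores) + 1L]] <- co
    }
  }
  utils::write.table(
    data.frame(provenance = vapply(all_cores, `[[`, "", "provenance"),
               smiles = vapply(all_cores, function(c) mg_to_smiles(c$mg), ""),
               mass = vapply(all_cores, function(c) mg_mass(c$mg), 0)),
    file.path(out_dir, "cores.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  done("cores")

  # -- modifications
  tags <- vapply(bgc$tailoring_enzymes, `[[`, "", "kind")
  enum <- enumerate_candidates(all_cores, tags, db, cap = cap)
  utils::write.table(
    data.frame(smiles = vapply(enum$candidates, `[[`, "", "key"),
               mass = vapply(enum$candidates, `[[`, 0, "mass"),
               core = vapply(enum$candidates, `[[`, 0L, "core"),
               applied = vapply(enum$candidates, `[[`, "", "applied")),
    file.path(out_dir, "candidates.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  manifest$enumeration <- list(k = enum$report$k,
                               raw_count = enum$report$raw_count,
                               dedup_count = enum$report$dedup_count,
                               failed_count = enum$report$failed_count)
  done("modifications")

  # -- spectral search
  if (!is.null(spectra)) {
    if (is.character(spectra)) {
      spectra <- if (grepl("\\.mzml$", spectra, ignore.case = TRUE))
        read_mzml(spectra) else read_mgf(spectra)
    }
    mode <- if (search_mode == "auto") {
      if (skipped_starter) "variable" else "exact"
    } else search_mode
    rows <- list()
    for (cand in enum$candidates) {
      fr <- fragment(cand$mg, 2L)
      for (sp in spectra) {
        m <- if (mode == "exact")
          score_exact(cand, sp, frag_tol, prec_tol, frags = fr)
        else score_variable(cand, sp, frag_tol, max_shift)
        if (!is.null(m))
          rows[[length(rows) + 1L]] <-
            data.frame(compound = cand$key, spectrum = sp$id,
                       score = m$score, shift = m$shift)
      }
    }
    matches <- if (length(rows)) do.call(rbind, rows)
               else data.frame(compound = character(0),
                               spectrum = character(0),
                               score = numeric(0), shift = numeric(0))
    matches <- matches[order(-matches$score), , drop = FALSE]
    utils::write.table(matches, file.path(out_dir, "matches.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    done("search")

    # -- fdr
    if (!is.null(fdr_threshold)) {
      target_keys <- vapply(enum$candidates, function(c) mg_inchikey(c$mg), "")
      decoy_rows <- list()
      for (i in seq_along(enum$candidates)) {
        cand <- enum$candidates[[i]]
        dec <- generate_decoy(cand$mg, steps = 25L, seed = seed + i,
                              targets = target_keys)
        fr <- fragment(dec, 2L)
        for (sp in spectra) {
          m <- if (mode == "exact")
            score_exact(dec, sp, frag_tol, prec_tol, frags = fr)
          else score_variable(dec, sp, frag_tol, max_shift)
          if (!is.null(m))
            decoy_rows[[length(decoy_rows) + 1L]] <- m$score
        }
      }
      fdr <- estimate_fdr(matches$score, unlist(decoy_rows), fdr_threshold)
      jsonlite::write_json(
        list(threshold = fdr$threshold, n_target = fdr$n_target,
             n_decoy = fdr$n_decoy,
             fdr = if (fdr$undefined) "undefined" else fdr$fdr),
        file.path(out_dir, "fdr.json"), auto_unbox = TRUE, digits = NA)
      done("fdr")
    }
  }
  invisible(manifest)
}
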