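# ---- core assembly and tailoring modifications -----------------------------
#
# Module substrates are chained by Claisen-type condensation (alpha carbon of
# each downstream unit onto the carbonyl carbon of the upstream chain),
# released as the linear free acid and, when a thioesterase is present, as
# macrolactones at each eligible chain hydroxyl.  Tailoring enzymes are then
# applied combinatorially: each enzyme either skips or fires once at one of
# its motif-match sites, giving k * prod(m_i + 1) raw candidates.

#' Assemble module substrates into a linear chain
#'
#' @param substrates list of `module_substrate` in assembly-pathway order
#'   (first module first).
#' @return list with `mg`, `trace` (per-atom module index, 1-based),
#'   `acid_carbon` (the terminal carbonyl carbon), `alpha_atoms`.
#' @export
assemble_core <- function(substrates) {
  stopifnot(length(substrates) >= 1L)
  chain <- NULL
  for (i in seq_along(substrates)) {
    s <- substrates[[i]]
    if (is.null(s$alpha_atom) || is.null(s$carbonyl_atom))
      stop("substrate ", i, " lacks attachment-atom annotation")
    if (is.null(chain)) {
      chain <- list(mg = s$mg, trace = rep(i, length(s$mg$atoms)),
                    acid_carbon = s$carbonyl_atom,
                    alpha_atoms = s$alpha_atom)
    } else {
      u <- mg_union(chain$mg, s$mg)
      alpha <- s$alpha_atom + u$offset
      mg <- mg_add_bond(u$mg, chain$acid_carbon, alpha, 1L)
      chain <- list(mg = mg,
                    trace = c(chain$trace, rep(i, length(s$mg$atoms))),
                    acid_carbon = s$carbonyl_atom + u$offset,
                    alpha_atoms = c(chain$alpha_atoms, alpha))
    }
  }
  mg_validate(chain$mg)
  chain
}

#' Release core structures from an assembled chain
#'
#' The linear free acid (an -OH added at the terminal carbonyl carbon) is
#' always produced.  With a thioesterase present, one macrolactone is added
#' per eligible chain hydroxyl: a single-bonded, singly-connected oxygen at
#' least `min_ring - 1` bonds from the acid carbon (ester ring size >=
#' `min_ring` atoms), formed by bonding the acid carbon to that oxygen with
#' loss of water.
#'
#' @param chain output of [assemble_core].
#' @param te_present logical: does the pathway end in a TE domain?
#' @param min_ring smallest permitted lactone ring size (atoms).
#' @return list of `core_structure` objects: `mg`, `provenance`
#'   (`"linear"` or `"macrolactone@<atom>"`), `trace`.
#' @export
release_products <- function(chain, te_present = TRUE, min_ring = 5L) {
  acid <- chain$acid_carbon
  linear <- mg_add_atom(chain$mg, "O", attach = acid, order = 1L)
  mg_validate(linear)
  cores <- list(structure(
    list(mg = linear, provenance = "linear",
         trace = c(chain$trace, chain$trace[acid])),
    class = "core_structure"))
  if (te_present) {
    deg <- tabulate(as.integer(chain$mg$bonds[, 1:2]),
                    nbins = length(chain$mg$atoms))
    ords <- mg_bond_order_sums(chain$mg)
    hydroxyls <- which(chain$mg$atoms == "O" & deg == 1L & ords == 1L)
    if (length(hydroxyls)) {
      d <- igraph::distances(mg_to_igraph(chain$mg), v = acid)[1, ]
      hydroxyls <- hydroxyls[d[hydroxyls] >= min_ring - 1L]
    }
    for (o in hydroxyls) {
      mg <- mg_add_bond(chain$mg, acid, o, 1L)
      mg_validate(mg)
      cores[[length(cores) + 1L]] <- structure(
        list(mg = mg, provenance = paste0("macrolactone@", o),
             trace = chain$trace),
        class = "core_structure")
    }
  }
  cores
}

#' @export
print.core_structure <- function(x, ...) {
  cat("<core_structure> ", x$provenance, " ", mg_formula(x$mg), " (",
      round(mg_mass(x$mg), 4), " Da)\n", sep = "")
  invisible(x)
}

# ---- modification rules ----------------------------------------------------

.EDIT_OPS <- c("add_atom", "remove_atom", "add_bond", "remove_bond",
               "set_bond", "add_group")

#' Load a tailoring-modification rule database
#'
#' JSON schema: `[{enzyme_tag, motif, edits:[{op, ...}], citation}]` where
#' `motif` is a SMILES substructure and each edit addresses atoms by their
#' 1-based motif index (atoms introduced by `add_atom`/`add_group` extend
#' the index space in order of addition).  Every rule is validated at load:
#' the motif must parse and the edit script applied to the motif itself must
#' yield a valid molecule.  Duplicate (motif, edits) combinations under
#' different tags are kept with a warning.
#'
#' @param path JSON path; defaults to the packaged database.
#' @return a `modification_db`: list of validated rules.
#' @export
load_modification_db <- function(
    path = system.file("extdata", "modification_rules.json",
                       package = "pksline")) {
  js <- jsonlite::read_json(path)
  errs <- character(0)
  rules <- lapply(js, function(r) {
    tryCatch({
      stopifnot(!is.null(r$enzyme_tag), !is.null(r$motif), !is.null(r$edits))
      motif <- mg_from_smiles(r$motif)
      rule <- structure(list(enzyme_tag = r$enzyme_tag, motif = motif,
                             motif_smiles = r$motif, edits = r$edits,
                             require_h = r$require_h,
                             citation = r$citation %||% ""),
                        class = "modification_rule")
      # self-application: the script must transform the motif into a valid
      # molecule
      apply_rule(motif, rule, seq_along(motif$atoms))
      rule
    }, error = function(e) {
      errs <<- c(errs, paste0(r$enzyme_tag %||% "?", ": ", conditionMessage(e)))
      NULL
    })
  })
  if (length(errs))
    stop("invalid modification rule(s):\n  ", paste(errs, collapse = "\n  "))
  key <- vapply(rules, function(r)
    paste(r$motif_smiles, jsonlite::toJSON(r$edits)), "")
  if (anyDuplicated(key))
    warning("duplicate (motif, edits) under tags: ",
            paste(vapply(rules[duplicated(key) | duplicated(key, fromLast = TRUE)],
                         `[[`, "", "enzyme_tag"), collapse = ", "),
            call. = FALSE)
  structure(rules, class = "modification_db")
}

#' @export
print.modification_db <- function(x, ...) {
  cat("<modification_db> ", length(x), " rules, ",
      length(unique(vapply(x, `[[`, "", "enzyme_tag"))), " enzyme tags\n",
      sep = "")
  invisible(x)
}

.element_codes <- function(els) match(els, names(.MG_VALENCES))

#' Find all motif embeddings in a molecule
#'
#' Subgraph-isomorphism search (VF2) with element vertex-colours and
#' bond-order edge-colours; embeddings mapping to the same atom set
#' (automorphic re-mappings) are collapsed to the representative with the
#' smallest mapped index sequence, and matches are returned sorted by their
#' atom indices.  Optional per-motif-atom minimum implicit-hydrogen
#' constraints (`rule$require_h`) distinguish e.g. free hydroxyls from
#' ester oxygens.
#'
#' @param core a [molgraph] (or `core_structure`).
#' @param rule a `modification_rule`.
#' @return list of integer vectors; each maps motif atom i to a core atom.
#' @export
match_motif <- function(core, rule) {
  if (inherits(core, "core_structure")) core <- core$mg
  motif <- rule$motif
  if (length(motif$atoms) > length(core$atoms)) return(list())
  g <- mg_to_igraph(core); p <- mg_to_igraph(motif)
  both_edged <- nrow(core$bonds) > 0L && nrow(motif$bonds) > 0L
  maps <- igraph::subgraph_isomorphisms(
    p, g, method = "vf2",
    vertex.color1 = .element_codes(core$atoms),
    vertex.color2 = .element_codes(motif$atoms),
    edge.color1 = if (both_edged) core$bonds[, 3] else NULL,
    edge.color2 = if (both_edged) motif$bonds[, 3] else NULL)
  maps <- lapply(maps, as.integer)
  if (!is.null(rule$require_h) && length(maps)) {
    h <- mg_implicit_h(core)
    maps <- Filter(function(m) {
      all(vapply(rule$require_h, function(rq)
        h[m[[rq$atom]]] >= rq$min_h, TRUE))
    }, maps)
  }
  if (!length(maps)) return(list())
  # collapse automorphic re-mappings: one representative per atom set
  sets <- vapply(maps, function(m) paste(sort(m), collapse = ","), "")
  reps <- lapply(split(seq_along(maps), sets), function(ix) {
    cand <- maps[ix]
    cand[[do.call(order, as.data.frame(do.call(rbind, cand)))[1]]]
  })
  reps[order(vapply(reps, function(m) paste(sprintf("%06d", sort(m)),
                                            collapse = ","), ""))]
}

#' Apply a modification rule at a matched site
#'
#' Executes the rule's edit script against the mapped atom indices.
#' Supported ops: `add_atom {element, attach, order}`, `add_group {smiles,
#' attach, group_attach, order}`, `add_bond`/`remove_bond`/`set_bond`
#' `{a, b, order}`, `remove_atom {atom}` (removals are deferred to the end
#' of the script so indices remain stable).  The result is valence-checked.
#'
#' @param mol a [molgraph] (or `core_structure`).
#' @param rule a `modification_rule`.
#' @param match integer vector mapping motif atoms to `mol` atoms.
#' @return the modified [molgraph].
#' @export
apply_rule <- function(mol, rule, match) {
  trace <- NULL
  if (inherits(mol, "core_structure")) { trace <- mol$trace; mol <- mol$mg }
  addr <- as.integer(match)       # script index -> current atom index
  to_remove <- integer(0)
  mg <- mol
  for (k in seq_along(rule$edits)) {
    e <- rule$edits[[k]]
    res <- tryCatch(switch(
      e$op,
      add_atom = {
        mg <- mg_add_atom(mg, e$element, attach = addr[[e$attach]],
                          order = e$order %||% 1L)
        addr <- c(addr, length(mg$atoms))
        mg
      },
      add_group = {
        grp <- mg_from_smiles(e$smiles)
        u <- mg_union(mg, grp)
        mg <- mg_add_bond(u$mg, addr[[e$attach]],
                          u$offset + (e$group_attach %||% 1L),
                          e$order %||% 1L)
        addr <- c(addr, u$offset + seq_along(grp$atoms))
        mg
      },
      add_bond = mg <- mg_add_bond(mg, addr[[e$a]], addr[[e$b]],
                                   e$order %||% 1L),
      remove_bond = mg <- mg_remove_bond(mg, addr[[e$a]], addr[[e$b]]),
      set_bond = mg <- mg_set_bond(mg, addr[[e$a]], addr[[e$b]], e$order),
      remove_atom = { to_remove <- c(to_remove, addr[[e$atom]]); mg },
      stop("unknown edit op '", e$op, "'")
    ), error = function(err)
      stop("rule '", rule$enzyme_tag, "' edit step ", k, " (", e$op, "): ",
           conditionMessage(err), call. = FALSE))
    mg <- res
  }
  if (length(to_remove)) {
    mg <- mg_remove_atoms(mg, to_remove)
    if (!is.null(trace)) trace <- trace[-to_remove]
  }
  mg_validate(mg)
  mg
}

#' Enumerate candidate mature compounds
#'
#' For each core and enzyme, the enzyme's motif-match sites on the core are
#' counted (`m_i`); each enzyme independently either skips or fires at one
#' chosen site, so the raw candidate count is `k * prod(m_i + 1)` over the
#' `k` cores.  Candidates are generated in deterministic order (cores, then
#' mixed-radix choice vectors) up to `cap`; structures whose combined edits
#' are chemically impossible are counted but skipped with a notice.
#'
#' @param cores list of `core_structure` objects.
#' @param enzyme_tags character vector of tailoring-enzyme tags present in
#'   the BGC; tags with no rule in `db` are skipped with a warning.
#' @param db a `modification_db`.
#' @param cap maximum number of candidates materialised.
#' @return list with `candidates` (list of `candidate_compound`: `mg`,
#'   `applied`, `mass`, `core`, `key`) and `report` (an
#'   `enumeration_report`: `k`, `site_counts`, `raw_count`,
#'   `dedup_count`, `truncated`).
#' @export
enumerate_candidates <- function(cores, enzyme_tags, db, cap = 1e6) {
  if (cap < 1L) stop("cap must be >= 1")
  tags <- vapply(db, `[[`, "", "enzyme_tag")
  known <- enzyme_tags %in% tags
  if (any(!known))
    warning("no modification rule for enzyme tag(s): ",
            paste(unique(enzyme_tags[!known]), collapse = ", "),
            "; skipped", call. = FALSE)
  enzymes <- enzyme_tags[known]
  rules <- lapply(enzymes, function(tg) db[[match(tg, tags)]])
  k <- length(cores)
  out <- list(); keys <- character(0)
  all_sites <- lapply(cores, function(core)
    lapply(rules, function(r) match_motif(core, r)))
  site_counts <- lapply(all_sites, function(s)
    stats::setNames(lengths(s), enzymes))
  raw <- sum(vapply(site_counts, function(m) prod(m + 1), 0))
  truncated <- FALSE
  failed <- 0
  for (ci in seq_len(k)) {
    core <- cores[[ci]]
    sites <- all_sites[[ci]]
    m <- lengths(sites)
    # mixed-radix enumeration over choice vectors (0 = skip, s = site s)
    choice <- rep(0L, length(m))
    repeat {
      if (length(out) < cap) {
        mg <- tryCatch({
          x <- core
          for (ei in seq_along(choice)) if (choice[ei] > 0L)
            x <- apply_rule(x, rules[[ei]], sites[[ei]][[choice[ei]]])
          if (inherits(x, "core_structure")) x$mg else x
        }, error = function(e) NULL)
        if (is.null(mg)) failed <- failed + 1
        if (!is.null(mg)) {
          key <- mg_to_smiles(mg)
          applied <- if (any(choice > 0L))
            paste(enzymes[choice > 0L], choice[choice > 0L], sep = "@",
                  collapse = ";")
          else ""
          out[[length(out) + 1L]] <- structure(
            list(mg = mg, applied = applied, mass = mg_mass(mg),
                 core = ci, key = key),
            class = "candidate_compound")
          keys <- c(keys, key)
        }
      } else truncated <- TRUE
      # increment mixed-radix counter
      pos <- 1L
      while (pos <= length(m)) {
        choice[pos] <- choice[pos] + 1L
        if (choice[pos] <= m[pos]) break
        choice[pos] <- 0L; pos <- pos + 1L
      }
      if (pos > length(m)) break
      if (truncated) break
    }
    if (truncated) break
  }
  if (truncated)
    message("candidate stream truncated at cap = ", cap,
            " (raw count ", raw, ")")
  if (failed > 0)
    message(failed, " enzyme combination(s) were chemically incompatible ",
            "and were skipped (still counted in the raw total)")
  report <- structure(
    list(k = k, site_counts = site_counts, raw_count = raw,
         dedup_count = length(unique(keys)), truncated = truncated,
         failed_count = failed),
    class = "enumeration_report")
  list(candidates = out, report = report)
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat("<enumeration_report> k = ", x$k, " cores, raw = ", x$raw_count,
      ", dedup = ", x$dedup_count,
      if (x$truncated) " (truncated)" else "", "\n", sep = "")
  invisible(x)
}
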