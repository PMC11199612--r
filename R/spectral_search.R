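# ---- spectral matching and target-decoy FDR --------------------------------
#
# Candidate compounds are matched to tandem mass spectra by in-silico
# fragmentation: one or two rounds of bond breaking (one acyclic single
# bond, or any two bonds of one ring, per round), fragments scored as
# singly-protonated ions, and the score is the shared-peak count.  The
# variable mode tolerates one unknown mass offset (e.g. an unpredicted
# starter unit).  FDR is estimated against edge-switching decoys.

#' Construct a spectrum object
#' @param precursor_mz precursor m/z.
#' @param charge precursor charge (>= 1).
#' @param mz,intensity peak arrays (sorted by m/z on construction).
#' @param id spectrum identifier.
#' @return a `pks_spectrum`.
#' @export
pks_spectrum <- function(precursor_mz, charge = 1L, mz = numeric(0),
                         intensity = numeric(0), id = NA_character_) {
  stopifnot(length(mz) == length(intensity), charge >= 1L)
  o <- order(mz)
  structure(list(precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
                 id = id),
            class = "pks_spectrum")
}

#' @export
print.pks_spectrum <- function(x, ...) {
  cat("<pks_spectrum> ", x$id, ": precursor ", round(x$precursor_mz, 4),
      " (", x$charge, "+), ", length(x$mz), " peaks\n", sep = "")
  invisible(x)
}

# neutral (uncharged) precursor mass
spectrum_neutral_mass <- function(spec) {
  spec$charge * (spec$precursor_mz - .PROTON_MASS)
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: `BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, optional `CHARGE` (defaulted to 1 with a message) and `TITLE`.
#' Records without a precursor are skipped with a warning; peak lists are
#' sorted on load.
#'
#' @param path MGF file path.
#' @return list of `pks_spectrum` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- list()
  defaulted <- 0L
  for (i in seq_along(begins)) {
    blk <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", blk, fixed = TRUE)
    hdr <- blk[kv]; pk <- trimws(blk[!kv])
    pk <- pk[nzchar(pk)]
    get <- function(key) {
      m <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(m)) sub(paste0("^", key, "="), "", m[1]) else NULL
    }
    pep <- get("PEPMASS")
    if (is.null(pep)) {
      warning("MGF record ", i, " missing PEPMASS; skipped", call. = FALSE)
      next
    }
    ch <- get("CHARGE")
    if (is.null(ch)) { charge <- 1L; defaulted <- defaulted + 1L }
    else charge <- as.integer(gsub("[^0-9]", "", ch))
    mzint <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"), function(x)
      as.numeric(x[1:2])))
    if (is.null(mzint)) mzint <- matrix(numeric(0), ncol = 2)
    rec <- tryCatch(
      pks_spectrum(as.numeric(strsplit(pep, "[ \t]")[[1]][1]), charge,
                   mzint[, 1], mzint[, 2],
                   id = get("TITLE") %||% paste0("spectrum_", i)),
      error = function(e) {
        warning("malformed MGF record ", i, " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (defaulted) message(defaulted, " spectra without CHARGE defaulted to 1+")
  if (!length(out)) stop("no spectra read from ", path)
  out
}

#' Read spectra from an mzML file (via mzR)
#' @param path mzML file path.
#' @return list of `pks_spectrum` objects (MS2 scans with a precursor).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- NULL
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  ms2 <- which(h$msLevel == 2L & h$precursorMZ > 0)
  if (!length(ms2)) stop("no MS2 spectra with precursors in ", path)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(fh, i)
    ch <- h$precursorCharge[i]
    pks_spectrum(h$precursorMZ[i], if (is.na(ch) || ch < 1L) 1L else ch,
                 pk[, 1], pk[, 2], id = paste0("scan_", h$acquisitionNum[i]))
  })
}

#' Write spectra to an MGF file
#' @param spectra list of `pks_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$id),
                 paste0("PEPMASS=", format(s$precursor_mz, digits = 12)),
                 paste0("CHARGE=", s$charge, "+"),
                 paste(format(s$mz, digits = 12),
                       format(s$intensity, digits = 8)),
                 "END IONS", ""), con)
  }
  invisible(path)
}

# ---- in-silico fragmentation -----------------------------------------------

# fragment mass of an atom subset: elements + implicit H completed against
# the bonds internal to the subset (each cut bond end gains a hydrogen)
.subset_mass <- function(mg, atoms) {
  sub <- mg_subgraph(mg, atoms)
  sum(.MG_MONOISO[sub$atoms]) + sum(mg_implicit_h(sub)) * .MG_MONOISO[["H"]]
}

# one round of the cut operator on an atom subset of mg:
# returns list of child subsets (connected, as sorted integer vectors)
.cut_once <- function(mg, atoms) {
  sub <- mg_subgraph(mg, atoms)
  nb <- nrow(sub$bonds)
  if (nb == 0L) return(list())
  g <- mg_to_igraph(sub)
  br <- igraph::bridges(g)
  children <- list()
  push <- function(memb) {
    for (cid in unique(memb))
      children[[length(children) + 1L]] <<- atoms[which(memb == cid)]
  }
  # single cuts: acyclic (bridge) single-order bonds
  single <- intersect(as.integer(br), which(sub$bonds[, 3] == 1L))
  for (e in single) {
    g2 <- igraph::delete_edges(g, e)
    push(igraph::components(g2)$membership)
  }
  # double cuts: pairs of ring (non-bridge) bonds whose removal disconnects
  ring <- setdiff(seq_len(nb), as.integer(br))
  if (length(ring) >= 2L) {
    prs <- utils::combn(ring, 2L)
    for (k in seq_len(ncol(prs))) {
      g2 <- igraph::delete_edges(g, prs[, k])
      cmp <- igraph::components(g2)
      if (cmp$no >= 2L) push(cmp$membership)
    }
  }
  children
}

#' Fragment a molecule by one or two rounds of bond breaking
#'
#' Round one removes one acyclic single bond, or any two bonds of one ring;
#' round two applies the same operator to every round-one fragment.  Open
#' valences created by a cut are saturated with hydrogen.  The parent mass
#' is always present (depth 0); masses are deduplicated within 1e-6 Da,
#' keeping the smallest depth.
#'
#' @param mg a [molgraph] (or `candidate_compound`).
#' @param depth 1 or 2 rounds.
#' @return a `fragment_set`: data.frame with `mass`, `depth`, `n_atoms`.
#' @export
fragment <- function(mg, depth = 2L) {
  if (inherits(mg, "candidate_compound")) mg <- mg$mg
  stopifnot(depth %in% c(1L, 2L))
  all_atoms <- seq_along(mg$atoms)
  seen <- new.env(parent = emptyenv())
  recs <- list()
  note <- function(atoms, d) {
    key <- paste(atoms, collapse = ",")
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && prev <= d) return(FALSE)
    assign(key, d, envir = seen)
    recs[[length(recs) + 1L]] <<- list(atoms = atoms, depth = d)
    TRUE
  }
  note(all_atoms, 0L)
  frontier <- list(all_atoms)
  for (d in seq_len(depth)) {
    nxt <- list()
    for (atoms in frontier) {
      for (child in .cut_once(mg, atoms)) {
        if (length(child) && note(sort(child), d))
          nxt[[length(nxt) + 1L]] <- sort(child)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  mass <- vapply(recs, function(r) .subset_mass(mg, r$atoms), 0)
  dep <- vapply(recs, function(r) r$depth, 0L)
  nat <- lengths(lapply(recs, `[[`, "atoms"))
  o <- order(mass, dep)
  mass <- mass[o]; dep <- dep[o]; nat <- nat[o]
  keep <- c(TRUE, diff(mass) > 1e-6)
  out <- data.frame(mass = mass[keep], depth = dep[keep], n_atoms = nat[keep])
  class(out) <- c("fragment_set", class(out))
  attr(out, "atom_sets") <- lapply(recs[o][keep], `[[`, "atoms")
  out
}

# ---- scoring ---------------------------------------------------------------

.filter_peaks <- function(spec, min_rel_intensity) {
  if (!length(spec$mz)) return(spec)
  keep <- spec$intensity >= min_rel_intensity * max(spec$intensity)
  spec$mz <- spec$mz[keep]; spec$intensity <- spec$intensity[keep]
  spec
}

# shared-peak count: peaks within tol of any value in `ions`, each peak
# matched at most once
.count_matched <- function(peaks, ions, tol) {
  if (!length(peaks) || !length(ions)) return(list(n = 0L, hit = logical(0)))
  ions <- sort(ions)
  hit <- vapply(peaks, function(p) {
    i <- findInterval(p, ions)
    (i >= 1L && p - ions[i] <= tol) ||
      (i < length(ions) && ions[i + 1L] - p <= tol)
  }, TRUE)
  list(n = sum(hit), hit = hit)
}

#' Exact-mode compound-spectrum match
#'
#' The candidate is considered only when the spectrum's neutral precursor
#' mass matches the molecule mass within `prec_tol`; the score is the
#' number of filtered spectrum peaks within `frag_tol` of any
#' singly-protonated fragment m/z.
#'
#' @param mol a [molgraph] or `candidate_compound`.
#' @param spectrum a `pks_spectrum`.
#' @param frag_tol,prec_tol fragment / precursor tolerances (Da).
#' @param depth fragmentation depth.
#' @param min_rel_intensity peak filter (fraction of base peak).
#' @param frags precomputed [fragment] result (optional).
#' @return a `compound_spectrum_match` (score, matched peaks, shift 0) or
#'   `NULL` when the precursor gate fails.
#' @export
score_exact <- function(mol, spectrum, frag_tol = 0.02, prec_tol = 0.02,
                        depth = 2L, min_rel_intensity = 0.01, frags = NULL) {
  stopifnot(frag_tol > 0, prec_tol > 0)
  mg <- if (inherits(mol, "candidate_compound")) mol$mg else mol
  pm <- spectrum_neutral_mass(spectrum)
  if (abs(pm - mg_mass(mg)) > prec_tol) return(NULL)
  if (is.null(frags)) frags <- fragment(mg, depth)
  sp <- .filter_peaks(spectrum, min_rel_intensity)
  res <- .count_matched(sp$mz, frags$mass + .PROTON_MASS, frag_tol)
  structure(list(compound = if (inherits(mol, "candidate_compound"))
                   mol$key else mg_to_smiles(mg),
                 spectrum = spectrum$id, score = res$n,
                 shift = 0, matched_mz = sp$mz[res$hit],
                 n_peaks = length(sp$mz)),
            class = "compound_spectrum_match")
}

#' @export
print.compound_spectrum_match <- function(x, ...) {
  cat("<match> ", x$spectrum, " ~ ", x$compound, ": score ", x$score,
      if (x$shift != 0) paste0(" (shift ", round(x$shift, 4), " Da)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Variable-mode (mass-shift tolerant) compound-spectrum match
#'
#' The precursor gate is replaced by a shift: `delta = neutral precursor
#' mass - molecule mass`, accepted when `|delta| <= max_shift`.  Every
#' fragment may then match at its own m/z or shifted by delta; when the
#' molecule declares an `attachment_atom` (the unknown moiety's attachment
#' point, e.g. the starter unit position), only fragments containing that
#' atom may take the shift.
#'
#' @param mol a [molgraph] or `candidate_compound`.
#' @param spectrum a `pks_spectrum`.
#' @param frag_tol fragment tolerance (Da).
#' @param max_shift largest tolerated |delta| (Da).
#' @param depth,min_rel_intensity as in [score_exact].
#' @param attachment_atom optional atom index carrying the unknown moiety.
#' @return a `compound_spectrum_match` (with `shift`) or `NULL`.
#' @export
score_variable <- function(mol, spectrum, frag_tol = 0.02, max_shift = 400,
                           depth = 2L, min_rel_intensity = 0.01,
                           attachment_atom = NULL) {
  stopifnot(frag_tol > 0, max_shift >= 0)
  mg <- if (inherits(mol, "candidate_compound")) mol$mg else mol
  pm <- spectrum_neutral_mass(spectrum)
  delta <- pm - mg_mass(mg)
  if (abs(delta) > max_shift) return(NULL)
  frags <- fragment(mg, depth)
  ions <- frags$mass + .PROTON_MASS
  if (delta != 0) {
    shiftable <- if (is.null(attachment_atom)) rep(TRUE, nrow(frags))
    else vapply(attr(frags, "atom_sets"), function(a)
      attachment_atom %in% a, TRUE)
    ions <- c(ions, ions[shiftable] + delta)
  }
  sp <- .filter_peaks(spectrum, min_rel_intensity)
  res <- .count_matched(sp$mz, ions, frag_tol)
  structure(list(compound = if (inherits(mol, "candidate_compound"))
                   mol$key else mg_to_smiles(mg),
                 spectrum = spectrum$id, score = res$n,
                 shift = delta, matched_mz = sp$mz[res$hit],
                 n_peaks = length(sp$mz)),
            class = "compound_spectrum_match")
}

# ---- decoys and FDR --------------------------------------------------------

#' Generate an edge-switching decoy molecule
#'
#' The molecule is modelled as a connected multigraph (a bond of order `o`
#' contributes `o` parallel edges).  Each step picks two multigraph edges
#' and swaps one endpoint pair, accepting the swap only if it creates no
#' self-loop, keeps every bond order at most 3, and leaves the graph
#' connected; accepted swaps preserve every atom's total bond-order (and
#' hence the heavy-atom formula and implicit hydrogens).  A step with no
#' valid swap within the retry budget is skipped.  A finished decoy whose
#' canonical key appears in `targets` is rejected and regenerated from a
#' fresh seed stream.
#'
#' @param mg a [molgraph] with at least 2 bonds.
#' @param steps number of edge-switching steps (default 25).
#' @param seed RNG seed.
#' @param targets character vector of target InChIKeys to exclude.
#' @param retry per-step retry budget.
#' @param max_regen regeneration attempts for target collisions.
#' @return a `molgraph` decoy.
#' @export
generate_decoy <- function(mg, steps = 25L, seed = 1L, targets = character(0),
                           retry = 100L, max_regen = 20L) {
  if (nrow(mg$bonds) < 2L) stop("decoy generation needs >= 2 bonds")
  if (steps == 0L) return(mg)
  for (attempt in seq_len(max_regen)) {
    set.seed(seed + (attempt - 1L) * 100003L)
    dec <- .edge_switch(mg, steps, retry)
    if (is.null(dec)) next
    if (!length(targets) || !(mg_inchikey(dec) %in% targets)) return(dec)
  }
  stop("decoy generation failed: retry budget exhausted")
}

.edge_switch <- function(mg, steps, retry) {
  # expand to multigraph edge list
  e <- mg$bonds[rep(seq_len(nrow(mg$bonds)), mg$bonds[, 3]), 1:2, drop = FALSE]
  n <- length(mg$atoms)
  rebuild <- function(e) {
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    tb <- table(key)
    ab <- do.call(rbind, strsplit(names(tb), " "))
    molgraph(mg$atoms,
             cbind(as.integer(ab[, 1]), as.integer(ab[, 2]),
                   as.integer(tb)),
             validate = FALSE)
  }
  connected <- function(e) {
    g <- igraph::make_graph(t(e), n = n, directed = FALSE)
    igraph::is_connected(g)
  }
  for (s in seq_len(steps)) {
    done <- FALSE
    for (r in seq_len(retry)) {
      ij <- sample(nrow(e), 2L)
      e1 <- e[ij[1], ]; e2 <- e[ij[2], ]
      # random orientation of the swap
      if (stats::runif(1) < 0.5) e2 <- rev(e2)
      new1 <- c(e1[1], e2[2]); new2 <- c(e2[1], e1[2])
      if (new1[1] == new1[2] || new2[1] == new2[2]) next
      e_try <- e
      e_try[ij[1], ] <- new1; e_try[ij[2], ] <- new2
      key <- paste(pmin(e_try[, 1], e_try[, 2]), pmax(e_try[, 1], e_try[, 2]))
      if (max(table(key)) > 3L) next          # bond order cap
      if (!connected(e_try)) next
      dec <- tryCatch({ d <- rebuild(e_try); mg_validate(d); d },
                      error = function(err) NULL)
      if (is.null(dec)) next
      e <- e_try; done <- TRUE; break
    }
    # a step with no valid swap is skipped (retry budget exhausted)
  }
  tryCatch({ d <- rebuild(e); mg_validate(d); d }, error = function(err) NULL)
}

#' Estimate the false discovery rate by target-decoy competition
#'
#' `FDR = N_decoy / N_target` where the counts are matches at or above the
#' score threshold in the decoy and target searches (run against the same
#' spectra with identical settings).
#'
#' @param target_scores,decoy_scores numeric score vectors.
#' @param threshold score threshold.
#' @return an `fdr_result`: `n_target`, `n_decoy`, `threshold`, `fdr`
#'   (NaN with `undefined = TRUE` when no target passes).
#' @export
estimate_fdr <- function(target_scores, decoy_scores, threshold) {
  nt <- sum(target_scores >= threshold)
  nd <- sum(decoy_scores >= threshold)
  structure(list(n_target = nt, n_decoy = nd, threshold = threshold,
                 fdr = if (nt > 0L) nd / nt else NaN,
                 undefined = nt == 0L),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> threshold ", x$threshold, ": ", x$n_decoy, " decoy / ",
      x$n_target, " target = ",
      if (x$undefined) "undefined" else signif(x$fdr, 4), "\n", sep = "")
  invisible(x)
}
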