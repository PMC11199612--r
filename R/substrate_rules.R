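# ---- substrate maturation rules --------------------------------------------
#
# Each extension module contributes one two-carbon unit whose beta-position
# oxidation state is set by the module's reductive domains, following the
# standard PKS reduction ladder:
#
#   no active KR            -> ketone     (unreduced beta-keto)
#   KR only                 -> hydroxyl   (carbonyl reduced to C-OH)
#   KR + DH                 -> enoyl      (water eliminated, alpha-beta C=C)
#   KR + DH + ER            -> saturated  (double bond reduced)
#
# Inactive-flagged domains are skipped; inconsistent domain sets (DH without
# KR, ER without DH) fall back to the deepest consistent state with a
# warning.

#' Load a monomer (extender-unit) library
#'
#' JSON schema: `{label: {smiles, alpha_atom, carbonyl_atom}}` with 1-based
#' atom indices into the SMILES atom order.  Every block is validated: the
#' attachment atoms must exist, and the carbonyl atom must carry a
#' double-bonded oxygen (the unreduced base state).
#'
#' @param path JSON path; defaults to the packaged library.
#' @return named list of monomer entries, each with `mg` (a [molgraph]),
#'   `alpha_atom` and `carbonyl_atom`.
#' @export
load_monomer_library <- function(
    path = system.file("extdata", "monomers.json", package = "pksline")) {
  js <- jsonlite::read_json(path)
  js <- js[setdiff(names(js), "_comment")]
  lib <- lapply(names(js), function(lab) {
    e <- js[[lab]]
    m <- mg_from_smiles(e$smiles)
    a <- as.integer(e$alpha_atom); cc <- as.integer(e$carbonyl_atom)
    if (a > length(m$atoms) || cc > length(m$atoms))
      stop("monomer '", lab, "': attachment atom index outside block")
    ox <- which((m$bonds[, 1] == cc | m$bonds[, 2] == cc) & m$bonds[, 3] == 2L)
    ox_atom <- setdiff(as.integer(m$bonds[ox, 1:2]), cc)
    if (length(ox_atom) != 1L || m$atoms[ox_atom] != "O")
      stop("monomer '", lab, "': carbonyl atom lacks a double-bonded oxygen")
    list(label = lab, mg = m, alpha_atom = a, carbonyl_atom = cc,
         carbonyl_oxygen = ox_atom, smiles = e$smiles)
  })
  names(lib) <- names(js)
  lib
}

#' Load the catalytic-motif table used for inactive-domain detection
#' @param path JSON path (`{domain_kind: regex}`); defaults to the packaged
#'   table.
#' @return named character vector of patterns.
#' @export
load_catalytic_motifs <- function(
    path = system.file("extdata", "catalytic_motifs.json", package = "pksline")) {
  js <- jsonlite::read_json(path)
  unlist(js[setdiff(names(js), "_comment")])
}

#' Flag inactive domains by catalytic-motif presence
#'
#' A domain is flagged inactive when its sequence lacks the catalytic
#' pattern for its kind.  Flags already set to inactive in the input are
#' never overridden; domain kinds without a packaged pattern are left active
#' with a warning.
#'
#' @param module a [pks_module].
#' @param motif_table named vector of patterns from [load_catalytic_motifs].
#' @return the module with updated `active` flags.
#' @export
detect_inactive_domains <- function(module,
                                    motif_table = load_catalytic_motifs()) {
  module$domains <- lapply(module$domains, function(d) {
    if (!d$active) return(d)  # pre-set inactive flags survive
    pat <- if (d$kind %in% names(motif_table)) motif_table[[d$kind]] else NULL
    if (is.null(pat)) {
      if (d$kind %in% c("KR", "DH", "ER", "AT", "KS", "TE"))
        warning("no catalytic pattern for domain kind '", d$kind,
                "'; left active", call. = FALSE)
      return(d)
    }
    d$active <- grepl(pat, d$sequence)
    d
  })
  module
}

.OX_STATES <- c("ketone", "hydroxyl", "enoyl", "saturated")

#' Build a module's mature substrate
#'
#' Starts from the extender block selected by the AT label and applies the
#' reduction ladder according to the module's active KR/DH/ER domains.
#'
#' @param module a [pks_module] (its AT/KR/DH/ER content and activity flags
#'   determine the oxidation state).
#' @param at_label substrate label predicted for the module's AT domain.
#' @param library monomer library from [load_monomer_library].
#' @return a `module_substrate`: list with `mg`, `oxidation_state`,
#'   `alpha_atom`, `carbonyl_atom`, `at_label`.
#' @export
module_substrate <- function(module, at_label,
                             library = load_monomer_library()) {
  if (is.null(module_domain(module, "AT")))
    stop("module has no AT domain; cannot assign an extender unit")
  if (!at_label %in% names(library))
    stop("substrate label '", at_label, "' not in monomer library")
  has <- function(kind) {
    d <- module_domain(module, kind)
    !is.null(d) && d$active
  }
  kr <- has("KR"); dh <- has("DH"); er <- has("ER")
  if (dh && !kr)
    warning("DH without KR in module ", module$index,
            ": falling back to deepest consistent state", call. = FALSE)
  if (er && !(dh && kr))
    warning("ER without KR+DH in module ", module$index,
            ": falling back to deepest consistent state", call. = FALSE)
  state <- if (kr && dh && er) "saturated"
           else if (kr && dh)  "enoyl"
           else if (kr)        "hydroxyl"
           else                "ketone"
  ent <- library[[at_label]]
  m <- ent$mg; a <- ent$alpha_atom; cc <- ent$carbonyl_atom
  ox <- ent$carbonyl_oxygen
  if (state == "hydroxyl") {
    m <- mg_set_bond(m, cc, ox, 1L)
  } else if (state %in% c("enoyl", "saturated")) {
    m <- mg_remove_atoms(m, ox)
    # removal renumbers atoms after the oxygen
    shift <- function(i) if (i > ox) i - 1L else i
    a <- shift(a); cc <- shift(cc)
    if (state == "enoyl") m <- mg_set_bond(m, a, cc, 2L)
  }
  structure(list(mg = m, oxidation_state = state, alpha_atom = a,
                 carbonyl_atom = cc, at_label = at_label),
            class = "module_substrate")
}

#' @export
print.module_substrate <- function(x, ...) {
  cat("<module_substrate> ", x$at_label, " / ", x$oxidation_state, " (",
      mg_formula(x$mg), ")\n", sep = "")
  invisible(x)
}
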