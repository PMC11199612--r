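# ---- lightweight molecular graphs ------------------------------------------
#
# Molecules are stored as a heavy-atom graph: a vector of element symbols and
# an integer bond table (a, b, order).  Hydrogens are implicit and derived
# from fixed element valences, which is sufficient for the neutral,
# non-aromatic (Kekule) structures handled by the assembly and modification
# engines.  SMILES parsing/writing and InChIKey generation are delegated to
# Open Babel via ChemmineR/ChemmineOB.

.MG_VALENCES <- list(
  C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L, Se = c(2L, 4L, 6L)
)

.MG_MONOISO <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371, I = 126.904473, B = 11.0093054, Si = 27.9769265325,
  Se = 79.9165213
)

.PROTON_MASS <- 1.007276466

#' Construct a molecular graph
#'
#' @param atoms character vector of element symbols (heavy atoms only).
#' @param bonds integer matrix with columns `a`, `b`, `order` (1-based atom
#'   indices; order 1-3). May have zero rows.
#' @param validate check valences and bond-table sanity.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = NULL, validate = TRUE) {
  atoms <- as.character(atoms)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)[, 1:3, drop = FALSE]), ncol = 3,
                    dimnames = list(NULL, c("a", "b", "order")))
    swap <- bonds[, 1] > bonds[, 2]
    if (any(swap)) bonds[swap, 1:2] <- bonds[swap, 2:1, drop = FALSE]
  }
  mg <- structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
  if (validate) mg_validate(mg)
  mg
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", length(x$atoms), " heavy atoms, ", nrow(x$bonds),
      " bonds, formula ", mg_formula(x), "\n", sep = "")
  invisible(x)
}

#' Validate a molecular graph
#'
#' Checks element symbols, bond indices, duplicate bonds, self-loops and
#' implicit-hydrogen feasibility (no atom may exceed its maximal valence).
#'
#' @param mg a `molgraph`.
#' @return `mg`, invisibly; stops on violation.
#' @export
mg_validate <- function(mg) {
  n <- length(mg$atoms)
  bad <- setdiff(unique(mg$atoms), names(.MG_VALENCES))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  b <- mg$bonds
  if (nrow(b)) {
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n)) stop("bond index out of range")
    if (any(b[, 1] == b[, 2])) stop("self-loop bond")
    if (any(b[, 3] < 1L | b[, 3] > 3L)) stop("bond order must be 1-3")
    key <- paste(b[, 1], b[, 2])
    if (anyDuplicated(key)) stop("duplicate bond between atoms ",
                                 key[duplicated(key)][1])
  }
  h <- mg_implicit_h(mg, strict = FALSE)
  if (anyNA(h)) {
    i <- which(is.na(h))[1]
    stop("valence violation at atom ", i, " (", mg$atoms[i], ")")
  }
  invisible(mg)
}

# per-atom sum of incident bond orders
mg_bond_order_sums <- function(mg) {
  n <- length(mg$atoms)
  s <- integer(n)
  b <- mg$bonds
  if (nrow(b)) {
    s1 <- tapply(b[, 3], factor(b[, 1], levels = seq_len(n)), sum)
    s2 <- tapply(b[, 3], factor(b[, 2], levels = seq_len(n)), sum)
    s <- as.integer(ifelse(is.na(s1), 0L, s1) + ifelse(is.na(s2), 0L, s2))
  }
  s
}

#' Implicit hydrogen counts
#'
#' For each heavy atom, the smallest allowed valence at least the sum of its
#' bond orders determines the hydrogen count.
#'
#' @param mg a `molgraph`.
#' @param strict stop (rather than return `NA`) when an atom exceeds every
#'   allowed valence.
#' @return integer vector of hydrogen counts per atom.
#' @export
mg_implicit_h <- function(mg, strict = TRUE) {
  s <- mg_bond_order_sums(mg)
  h <- integer(length(s))
  for (i in seq_along(s)) {
    val <- .MG_VALENCES[[mg$atoms[i]]]
    fit <- val[val >= s[i]]
    if (!length(fit)) {
      if (strict) stop("valence violation at atom ", i, " (", mg$atoms[i], ")")
      h[i] <- NA_integer_
    } else h[i] <- fit[1] - s[i]
  }
  h
}

#' Molecular formula (Hill order)
#' @param mg a `molgraph`.
#' @return a string such as `"C4H6O3"`.
#' @export
mg_formula <- function(mg) {
  cnt <- table(mg$atoms)
  nh <- sum(mg_implicit_h(mg))
  els <- c(cnt)
  if (nh > 0) els <- c(els, H = nh)
  ord <- c(intersect(c("C", "H"), names(els)),
           sort(setdiff(names(els), c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (els[[e]] > 1) els[[e]] else ""), ""), collapse = "")
}

#' Monoisotopic mass of a molecular graph
#' @param mg a `molgraph`.
#' @return mass in Da.
#' @export
mg_mass <- function(mg) {
  sum(.MG_MONOISO[mg$atoms]) + sum(mg_implicit_h(mg)) * .MG_MONOISO[["H"]]
}

# ---- SMILES / molblock boundary (Open Babel) -------------------------------

#' Parse a SMILES string into a molecular graph
#'
#' Open Babel performs the parse; the heavy-atom graph is lifted from the
#' resulting molblock. Aromatic input is kekulized by Open Babel.
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph`.
#' @export
mg_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- ChemmineOB::convertFormat("SMI", "MOL", smiles)
  lines <- strsplit(mol, "\n")[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("SMILES did not parse: ", smiles)
  atoms <- lines[4L + seq_len(na)]
  els <- trimws(substr(atoms, 32, 34))
  bb <- if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    cbind(a = as.integer(substr(bl, 1, 3)),
          b = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else matrix(integer(0), ncol = 3)
  keep <- els != "H"
  if (!all(keep)) {
    # drop explicit hydrogens; renumber bonds
    map <- cumsum(keep)
    bb <- bb[bb[, 1] %in% which(keep) & bb[, 2] %in% which(keep), , drop = FALSE]
    if (nrow(bb)) { bb[, 1] <- map[bb[, 1]]; bb[, 2] <- map[bb[, 2]] }
    els <- els[keep]
  }
  molgraph(els, if (NROW(bb)) bb else NULL)
}

# V2000 molblock text for a molgraph
mg_to_molblock <- function(mg) {
  n <- length(mg$atoms)
  b <- mg$bonds
  hdr <- c("", " pksline", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mg$atoms)
  bonds <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3])
           else character(0)
  paste(c(hdr, atoms, bonds, "M  END", "$$$$"), collapse = "\n")
}

#' Write a molecular graph as canonical SMILES
#' @param mg a `molgraph`.
#' @return a canonical SMILES string.
#' @export
mg_to_smiles <- function(mg) {
  out <- ChemmineOB::convertFormat("MOL", "CAN", mg_to_molblock(mg))
  strsplit(out, "[\t\n ]")[[1]][1]
}

#' Canonical structure key (InChIKey)
#'
#' Used for candidate deduplication and target/decoy overlap filtering.
#'
#' @param mg a `molgraph`.
#' @return a 27-character InChIKey string.
#' @export
mg_inchikey <- function(mg) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("MOL", "INCHIKEY", mg_to_molblock(mg)))
  gsub("[\n ]", "", out)
}

# ---- graph utilities -------------------------------------------------------

mg_to_igraph <- function(mg) {
  g <- igraph::make_empty_graph(n = length(mg$atoms), directed = FALSE)
  if (nrow(mg$bonds))
    g <- igraph::add_edges(g, t(mg$bonds[, 1:2, drop = FALSE]))
  g
}

mg_is_connected <- function(mg) {
  if (length(mg$atoms) <= 1L) return(TRUE)
  igraph::is_connected(mg_to_igraph(mg))
}

# adjacency list: for each atom, integer vector of (neighbour, bond row)
mg_adjacency <- function(mg) {
  n <- length(mg$atoms)
  adj <- vector("list", n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  adj
}

#' Induced subgraph on a set of atoms
#' @param mg a `molgraph`.
#' @param atoms integer atom indices to keep.
#' @return a `molgraph` on the selected atoms (renumbered in `atoms` order).
#' @export
mg_subgraph <- function(mg, atoms) {
  atoms <- as.integer(atoms)
  map <- integer(length(mg$atoms)); map[atoms] <- seq_along(atoms)
  b <- mg$bonds
  keep <- b[, 1] %in% atoms & b[, 2] %in% atoms
  b <- b[keep, , drop = FALSE]
  if (nrow(b)) { b[, 1] <- map[b[, 1]]; b[, 2] <- map[b[, 2]] }
  molgraph(mg$atoms[atoms], b, validate = FALSE)
}

# disjoint union; returns list(mg, offset) where offset indexes the second part
mg_union <- function(x, y) {
  off <- length(x$atoms)
  b2 <- y$bonds
  if (nrow(b2)) { b2[, 1] <- b2[, 1] + off; b2[, 2] <- b2[, 2] + off }
  list(mg = molgraph(c(x$atoms, y$atoms), rbind(x$bonds, b2), validate = FALSE),
       offset = off)
}

mg_add_atom <- function(mg, element, attach = NULL, order = 1L) {
  mg$atoms <- c(mg$atoms, element)
  if (!is.null(attach))
    mg$bonds <- rbind(mg$bonds,
                      c(a = min(attach, length(mg$atoms)),
                        b = max(attach, length(mg$atoms)),
                        order = as.integer(order)))
  mg
}

mg_bond_row <- function(mg, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  which(mg$bonds[, 1] == lo & mg$bonds[, 2] == hi)
}

mg_add_bond <- function(mg, a, b, order = 1L) {
  if (length(mg_bond_row(mg, a, b))) stop("bond already present: ", a, "-", b)
  mg$bonds <- rbind(mg$bonds, c(min(a, b), max(a, b), as.integer(order)))
  mg
}

mg_remove_bond <- function(mg, a, b) {
  r <- mg_bond_row(mg, a, b)
  if (!length(r)) stop("no bond between atoms ", a, " and ", b)
  mg$bonds <- mg$bonds[-r, , drop = FALSE]
  mg
}

mg_set_bond <- function(mg, a, b, order) {
  r <- mg_bond_row(mg, a, b)
  if (!length(r)) stop("no bond between atoms ", a, " and ", b)
  mg$bonds[r, 3] <- as.integer(order)
  mg
}

# remove atoms (and incident bonds), renumbering the rest; returns molgraph
mg_remove_atoms <- function(mg, atoms) {
  keep <- setdiff(seq_along(mg$atoms), as.integer(atoms))
  mg_subgraph(mg, keep)
}
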