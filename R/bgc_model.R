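# ---- BGC data model --------------------------------------------------------
#
# A BGC is a list of genes sorted by genomic rank; each gene carries its
# protein translation and an ordered list of modules; each module is an
# ordered list of catalytic domains.  Coordinates are 0-based half-open
# residue intervals within the protein; GenBank input (1-based inclusive)
# is converted at the parser boundary.

.CORE_DOMAINS <- c("AT", "KS", "ACP", "KR", "DH", "ER", "TE")
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a catalytic domain
#'
#' @param kind domain label: one of AT, KS, ACP, KR, DH, ER, TE, or a
#'   tailoring-enzyme family tag.
#' @param sequence amino-acid sequence of the domain.
#' @param active logical activity flag; inactive domains are skipped by the
#'   substrate maturation rules.
#' @param start,end 0-based half-open residue interval within the parent
#'   protein (optional for free-standing tailoring enzymes).
#' @return a `pks_domain`.
#' @export
pks_domain <- function(kind, sequence, active = TRUE, start = NA_integer_,
                       end = NA_integer_) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("domain sequence must be non-empty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), .AA_ALPHABET)
  if (length(bad)) stop("domain sequence contains non amino-acid letter(s): ",
                        paste(bad, collapse = ""))
  if (!is.na(start) && !is.na(end) && start >= end)
    stop("domain coords must satisfy start < end (0-based half-open)")
  structure(list(kind = as.character(kind), sequence = sequence,
                 active = isTRUE(active), start = as.integer(start),
                 end = as.integer(end)),
            class = "pks_domain")
}

#' Construct a PKS module
#'
#' @param domains list of [pks_domain] in N- to C-terminal order.
#' @param index 0-based position of the module within its gene.
#' @return a `pks_module`.
#' @export
pks_module <- function(domains, index = 0L) {
  kinds <- vapply(domains, function(d) d$kind, "")
  for (k in c("AT", "KR", "DH", "ER")) {
    if (sum(kinds == k) > 1L)
      stop("module may contain at most one ", k, " domain")
  }
  structure(list(domains = domains, index = as.integer(index)),
            class = "pks_module")
}

#' Find the first domain of a given kind in a module
#' @param module a [pks_module].
#' @param kind domain label (e.g. `"AT"`).
#' @return the [pks_domain], or `NULL` when absent.
#' @export
module_domain <- function(module, kind) {
  for (d in module$domains) if (d$kind == kind) return(d)
  NULL
}

#' Construct a PKS gene
#'
#' @param id gene identifier.
#' @param protein amino-acid sequence of the translated ORF.
#' @param modules list of [pks_module].
#' @param genomic_rank integer order of the gene on the BGC.
#' @param strand `"+"` or `"-"`.
#' @param start,end optional genomic coordinates (bp) used by [window_bgc].
#' @return a `pks_gene`.
#' @export
pks_gene <- function(id, protein, modules = list(), genomic_rank = 1L,
                     strand = "+", start = NA_real_, end = NA_real_) {
  protein <- toupper(as.character(protein))
  plen <- nchar(protein)
  for (m in modules) for (d in m$domains) {
    if (!is.na(d$start) && (d$start < 0L || d$end > plen))
      stop("domain coords [", d$start, ",", d$end, ") outside protein of gene ",
           id, " (length ", plen, ")")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(id = as.character(id), protein = protein, modules = modules,
                 genomic_rank = as.integer(genomic_rank), strand = strand,
                 start = start, end = end),
            class = "pks_gene")
}

#' Construct a BGC
#'
#' Genes are re-sorted by `genomic_rank`; duplicate ranks are an error.
#'
#' @param genes list of [pks_gene].
#' @param tailoring_enzymes list of [pks_domain] with tailoring-family tags.
#' @param source free-form provenance record.
#' @return a `pks_bgc`.
#' @export
pks_bgc <- function(genes, tailoring_enzymes = list(), source = list()) {
  if (!length(genes)) stop("a BGC must contain at least one gene")
  ranks <- vapply(genes, function(g) g$genomic_rank, 1L)
  if (anyDuplicated(ranks))
    stop("duplicate genomic_rank: ", ranks[duplicated(ranks)][1])
  genes <- genes[order(ranks)]
  structure(list(genes = genes, tailoring_enzymes = tailoring_enzymes,
                 source = source),
            class = "pks_bgc")
}

#' @export
print.pks_bgc <- function(x, ...) {
  nm <- sum(vapply(x$genes, function(g) length(g$modules), 1L))
  cat("<pks_bgc> ", length(x$genes), " gene(s), ", nm, " module(s), ",
      length(x$tailoring_enzymes), " tailoring enzyme(s)\n", sep = "")
  for (g in x$genes)
    cat("  ", g$id, " (rank ", g$genomic_rank, ", ", g$strand, ", ",
        nchar(g$protein), " aa, ", length(g$modules), " module(s))\n", sep = "")
  invisible(x)
}

# ---- JSON I/O --------------------------------------------------------------

#' Read a BGC from declarative JSON
#'
#' Schema: `{genes:[{id, genomic_rank, strand, protein,
#' modules:[{domains:[{kind, start, end, active}]}]}],
#' tailoring_enzymes:[{kind, sequence}]}`.  Domain sequences are sliced from
#' the gene protein using the 0-based half-open coords.
#'
#' @param path path to a BGC JSON file.
#' @return a `pks_bgc` with genes sorted by genomic rank.
#' @export
parse_bgc_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  js <- jsonlite::read_json(path)
  if (is.null(js$genes)) stop("BGC JSON missing required field 'genes'")
  genes <- lapply(js$genes, function(g) {
    for (f in c("id", "genomic_rank", "protein"))
      if (is.null(g[[f]])) stop("gene record missing required field '", f, "'")
    mods <- lapply(seq_along(g$modules %||% list()), function(i) {
      m <- g$modules[[i]]
      if (is.null(m$domains)) stop("module record missing field 'domains'")
      doms <- lapply(m$domains, function(d) {
        for (f in c("kind", "start", "end"))
          if (is.null(d[[f]])) stop("domain record missing field '", f, "'")
        pks_domain(d$kind,
                   substr(g$protein, d$start + 1L, d$end),
                   active = d$active %||% TRUE,
                   start = d$start, end = d$end)
      })
      pks_module(doms, index = i - 1L)
    })
    pks_gene(g$id, g$protein, mods, genomic_rank = g$genomic_rank,
             strand = g$strand %||% "+",
             start = g$start %||% NA_real_, end = g$end %||% NA_real_)
  })
  tes <- lapply(js$tailoring_enzymes %||% list(), function(t)
    pks_domain(t$kind, t$sequence))
  pks_bgc(genes, tes, source = list(path = path, format = "bgc-json"))
}

#' Serialize a BGC to declarative JSON
#' @param bgc a `pks_bgc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bgc_json <- function(bgc, path) {
  genes <- lapply(bgc$genes, function(g) {
    mods <- lapply(g$modules, function(m) {
      list(domains = lapply(m$domains, function(d) {
        rec <- list(kind = d$kind, start = d$start, end = d$end,
                    active = d$active)
        rec
      }))
    })
    rec <- list(id = g$id, genomic_rank = g$genomic_rank, strand = g$strand,
                protein = g$protein, modules = mods)
    if (!is.na(g$start)) { rec$start <- g$start; rec$end <- g$end }
    rec
  })
  tes <- lapply(bgc$tailoring_enzymes, function(t)
    list(kind = t$kind, sequence = t$sequence))
  jsonlite::write_json(list(genes = genes, tailoring_enzymes = tes), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- GenBank reader --------------------------------------------------------

#' Read an annotated GenBank region into a BGC
#'
#' A minimal flat-file reader for pre-annotated PKS regions. `CDS` features
#' must carry `/locus_tag` and `/translation` qualifiers (minus-strand genes
#' use the annotated translation; nothing is re-translated). Domain
#' annotations are read from `aSDomain` features carrying `/label` (the
#' domain kind, e.g. `PKS_AT` or `AT`), `/locus_tag`, `/protein_start`,
#' `/protein_end` (1-based inclusive, converted internally), and optional
#' `/module` (0-based module number) and `/active` qualifiers.  Without
#' `/module` qualifiers, modules are split at each KS domain.  `CDS`
#' features with a `/tailoring` qualifier contribute tailoring enzymes.
#'
#' @param path path to a GenBank flat file.
#' @return a `pks_bgc`.
#' @export
parse_genbank_region <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  f0 <- grep("^FEATURES", lines)
  if (!length(f0)) stop("no FEATURES table in ", path)
  end <- grep("^(ORIGIN|//)", lines)
  end <- if (length(end)) min(end[end > f0[1]]) - 1L else length(lines)
  ft <- lines[(f0[1] + 1L):end]

  # split the feature table into (key, location, qualifiers) records
  starts <- grep("^ {5}\\S", ft)
  if (!length(starts)) stop("no PKS genes: empty feature table in ", path)
  feats <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(ft)
    block <- ft[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    qual <- paste(trimws(block[-1]), collapse = "\n")
    # qualifiers start with '/'; values may wrap across lines
    qlines <- strsplit(qual, "\n/")[[1]]
    qlines <- sub("^/", "", qlines)
    quals <- list()
    for (q in qlines[nzchar(qlines)]) {
      kv <- regmatches(q, regexec('^([A-Za-z_0-9]+)=?"?([^"]*)"?$',
                                  gsub("\n", "", q)))[[1]]
      if (length(kv) == 3L) quals[[kv[2]]] <- kv[3]
    }
    list(key = key, location = loc, quals = quals)
  })

  cds <- Filter(function(f) f$key == "CDS", feats)
  doms <- Filter(function(f) f$key == "aSDomain", feats)
  if (!length(cds)) stop("no PKS genes: no CDS features in ", path)

  genes <- list(); tes <- list(); rank <- 0L
  for (f in cds) {
    lt <- f$quals$locus_tag %||% f$quals$gene
    if (is.null(lt)) stop("CDS without locus_tag in ", path)
    tr <- f$quals$translation
    if (is.null(tr)) stop("CDS ", lt, " has no /translation qualifier")
    tr <- gsub("\\s", "", tr)
    strand <- if (grepl("complement", f$location)) "-" else "+"
    coords <- as.numeric(regmatches(f$location,
                                    gregexpr("[0-9]+", f$location))[[1]])
    if (!is.null(f$quals$tailoring)) {
      tes <- c(tes, list(pks_domain(f$quals$tailoring, tr)))
      next
    }
    rank <- rank + 1L
    mine <- Filter(function(d) identical(d$quals$locus_tag, lt), doms)
    dl <- lapply(mine, function(d) {
      kind <- sub("^PKS_", "", d$quals$label %||% d$quals$aSDomain %||% "?")
      if (!kind %in% .CORE_DOMAINS) {
        warning("unknown domain tag '", kind, "' kept as opaque", call. = FALSE)
      }
      ps <- as.integer(d$quals$protein_start)  # 1-based inclusive
      pe <- as.integer(d$quals$protein_end)
      list(domain = pks_domain(kind, substr(tr, ps, pe),
                               active = !identical(d$quals$active, "false"),
                               start = ps - 1L, end = pe),
           module = if (!is.null(d$quals$module)) as.integer(d$quals$module)
                    else NA_integer_,
           start = ps)
    })
    dl <- dl[order(vapply(dl, function(x) x$start, 1L))]
    # group into modules: explicit /module qualifier, else split at KS
    mods <- list()
    if (length(dl)) {
      mnum <- vapply(dl, function(x) x$module, 1L)
      if (all(!is.na(mnum))) {
        for (u in sort(unique(mnum)))
          mods[[length(mods) + 1L]] <-
            pks_module(lapply(dl[mnum == u], `[[`, "domain"),
                       index = length(mods))
      } else {
        cur <- list()
        for (x in dl) {
          if (x$domain$kind == "KS" && length(cur)) {
            mods[[length(mods) + 1L]] <- pks_module(cur, index = length(mods))
            cur <- list()
          }
          cur <- c(cur, list(x$domain))
        }
        if (length(cur))
          mods[[length(mods) + 1L]] <- pks_module(cur, index = length(mods))
      }
    }
    genes[[length(genes) + 1L]] <-
      pks_gene(lt, tr, mods, genomic_rank = rank, strand = strand,
               start = if (length(coords)) min(coords) else NA_real_,
               end = if (length(coords)) max(coords) else NA_real_)
  }
  if (!length(genes)) stop("no PKS genes in ", path)
  pks_bgc(genes, tes, source = list(path = path, format = "genbank"))
}

# ---- windowing -------------------------------------------------------------

#' Restrict a gene list to the neighbourhood of anchor enzymes
#'
#' Keeps genes overlapping the interval from `min(anchors) - flank` to
#' `max(anchors) + flank`, emulating the convention that a PKS BGC is the
#' genomic region within a fixed distance of its signature enzymes.
#'
#' @param anchor_positions genomic coordinates (bp) of anchor enzymes.
#' @param flank flank size in bp (default 10000).
#' @param genes list of [pks_gene] with genomic `start`/`end` coordinates.
#' @param tailoring_enzymes passed through to the windowed BGC.
#' @return a `pks_bgc` containing the overlapping genes (ranks preserved).
#' @export
window_bgc <- function(anchor_positions, flank = 10000, genes,
                       tailoring_enzymes = list()) {
  stopifnot(length(anchor_positions) >= 1L, flank >= 0)
  lo <- min(anchor_positions) - flank
  hi <- max(anchor_positions) + flank
  keep <- Filter(function(g) {
    if (is.na(g$start)) stop("gene ", g$id, " lacks genomic coordinates")
    g$start <= hi && g$end >= lo
  }, genes)
  if (!length(keep))
    stop("empty BGC: no gene overlaps window [", lo, ", ", hi, "]")
  pks_bgc(keep, tailoring_enzymes,
          source = list(window = c(lo, hi), flank = flank))
}
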