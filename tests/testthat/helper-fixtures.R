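# shared objects, loaded once per test run

ref <- load_at_reference()
monolib <- load_monomer_library()
moddb <- load_modification_db()

aa_mod <- function(kinds, active = NULL) {
  # quick module: AT always present plus the given reductive kinds
  seqs <- list(AT = strrep("A", 60), KR = "AAAAGAGLLGAAAA",
               DH = "AAAAHAAAGAAAAPAAAA", ER = "AAAAGAGLLAAAAA",
               KS = "AAGPAAAAAACAA", TE = "AAGYSYGAA", ACP = strrep("A", 20))
  doms <- lapply(kinds, function(k) {
    act <- if (!is.null(active) && k %in% names(active)) active[[k]] else TRUE
    pks_domain(k, seqs[[k]], active = act)
  })
  pks_module(doms)
}

tiny_bgc <- function(g, protein_len = 300L, seed = 1L) {
  set.seed(seed)
  genes <- lapply(seq_len(g), function(i)
    pks_gene(paste0("g", i),
             paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          protein_len, replace = TRUE), collapse = ""),
             list(), genomic_rank = i))
  pks_bgc(genes)
}

# independent recursive oracle for candidate enumeration counts:
# each enzyme picks one of (skip, site_1 .. site_m)
enumeration_oracle <- function(ms) {
  if (!length(ms)) return(1)
  count <- 0
  for (choice in 0:ms[1]) count <- count + enumeration_oracle(ms[-1])
  count
}

# independent recursive generator: applies every enzyme-choice combination
# depth-first and collects the canonical keys of the chemically valid ones
brute_force_candidates <- function(cores, rules) {
  keys <- character(0)
  recurse <- function(mol, sites, ei) {
    if (ei > length(rules)) {
      keys <<- c(keys, mg_to_smiles(if (inherits(mol, "core_structure"))
        mol$mg else mol))
      return(invisible())
    }
    recurse(mol, sites, ei + 1L)          # skip this enzyme
    for (s in sites[[ei]]) {
      mod <- tryCatch(apply_rule(mol, rules[[ei]], s),
                      error = function(e) NULL)
      if (!is.null(mod)) recurse(mod, sites, ei + 1L)
    }
  }
  for (core in cores) {
    sites <- lapply(rules, function(r) match_motif(core, r))
    recurse(core, sites, 1L)
  }
  keys
}

# brute-force minimum Hamming distance oracle
hamming_oracle <- function(train, test) {
  vapply(test, function(te) {
    min(vapply(train, function(tr) {
      sum(strsplit(tr, "")[[1]] != strsplit(te, "")[[1]])
    }, 0L))
  }, 0L)
}
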