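# Small fixtures built in code for the unit tests.

# alignment from a named character vector of sequence strings
aln_from <- function(...) {
  as_alignment(c(...))
}

# minimal two-region map: one 12-base exon (phase 0) and one 12-base intron
tiny_map <- function() {
  region_map(data.frame(
    name = c("exonA", "intronA"),
    start = c(1L, 13L), end = c(12L, 24L),
    kind = c("exon", "intron"), phase = c(0L, NA),
    stringsAsFactors = FALSE
  ))
}

# a sequence of length n with given codon planted at the anchor of `residue`
planted_anchor_seq <- function(map, residue, codon, fill = "A") {
  n <- max(map$regions$end)
  s <- rep(fill, n)
  s[anchor_codon_sites(map, residue)] <- strsplit(codon, "")[[1]]
  paste(s, collapse = "")
}

# brute-force minimum-likelihood two-sided Fisher P for a 2x2 table
fisher_bruteforce <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  ks <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  pr <- dhyper(ks, cs[1], cs[2], rs[1])
  p0 <- dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# independent pathway-enumeration oracle for Nei-Gojobori codon differences:
# depth-first search over all orders of single-base changes from c1 to c2,
# skipping paths whose intermediate codons are stops; returns mean syn/nonsyn
ng_pathway_oracle <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  paths <- list()
  walk <- function(cur, syn, nonsyn) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) {
      paths[[length(paths) + 1]] <<- c(syn, nonsyn)
      return(invisible())
    }
    for (p in dp) {
      nb <- strsplit(cur, "")[[1]]
      nb[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(nb, collapse = "")
      if (gc_tab[[nxt]] == "*" && nxt != c2) next
      walk(nxt,
           syn + (gc_tab[[cur]] == gc_tab[[nxt]]),
           nonsyn + (gc_tab[[cur]] != gc_tab[[nxt]]))
    }
  }
  walk(c1, 0, 0)
  if (!length(paths)) return(NULL)
  m <- do.call(rbind, paths)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# number of mutational pathways that never enter a stop codon
ng_pathway_count <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- 0
  walk <- function(cur) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) { n <<- n + 1; return(invisible()) }
    for (p in dp) {
      nb <- strsplit(cur, "")[[1]]
      nb[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(nb, collapse = "")
      if (gc_tab[[nxt]] == "*" && nxt != c2) next
      walk(nxt)
    }
  }
  walk(c1)
  n
}

sense_codons <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  names(gc_tab)[gc_tab != "*"]
}

# random sense-codon sequence as one string
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}
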