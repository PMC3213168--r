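#' Classify alignment sites as fixed, polymorphic or invariant by site class
#'
#' For each retained site, the status is `fixed` when both groups are
#' internally monomorphic with different bases (a fixed inter-group
#' difference), `polymorphic` when either group segregates, and `invariant`
#' otherwise. Coding sites are classed `synonymous` when every observed
#' base change at the site -- holding the other two codon positions at
#' their observed consensus across the analyzed records -- is synonymous,
#' else `nonsynonymous`; codons with more than one varying position are
#' flagged `ambiguous_codon` but classed by the same rule. Coding bases in
#' partial codons at the region edges are classed `exon_partial` and
#' excluded from synonymous/non-synonymous tallies.
#'
#' @param aln An `lm_alignment`.
#' @param ids_a,ids_b Record IDs of the two groups (e.g. the L and M group
#'   of one species, restricted to single-copy males).
#' @param map A `region_map`.
#' @param columns Retained sites; default complete deletion over both groups.
#' @return Data frame with one row per retained site: `site`, `status`,
#'   `site_class`, `ambiguous_codon`.
#' @export
classify_alignment_sites <- function(aln, ids_a, ids_b, map, columns = NULL) {
  if (length(ids_a) == 0 || length(ids_b) == 0) stop("empty group")
  ids <- c(ids_a, ids_b)
  if (is.null(columns)) columns <- complete_deletion_columns(aln, ids)
  ma <- aln$seq[ids_a, columns, drop = FALSE]
  mb <- aln$seq[ids_b, columns, drop = FALSE]
  status <- vapply(seq_along(columns), function(j) {
    ua <- unique(ma[, j]); ub <- unique(mb[, j])
    if (length(ua) == 1 && length(ub) == 1) {
      if (ua == ub) "invariant" else "fixed"
    } else "polymorphic"
  }, "")

  cf <- coding_frame(map)
  kind_of <- rep("intron", n_sites(aln))
  for (i in seq_len(nrow(map$regions))) {
    r <- map$regions[i, ]
    kind_of[r$start:r$end] <- r$kind
  }
  site_class <- rep(NA_character_, length(columns))
  ambiguous <- rep(FALSE, length(columns))

  m_all <- rbind(ma, mb)
  codon_of_site <- rep(NA_integer_, n_sites(aln))
  codon_of_site[cf$sites] <- cf$codon
  pos_of_site <- rep(NA_integer_, n_sites(aln))
  pos_of_site[cf$sites] <- cf$pos_in_codon
  codon_sites <- matrix(cf$sites, nrow = 3)

  # precomputed lookups: majority base per coding column among analyzed
  # records, and whether a retained column segregates
  need <- sort(unique(as.vector(codon_sites)))
  cons <- vapply(need, function(col_idx) {
    b <- aln$seq[ids, col_idx]
    b <- b[b %in% ALN_BASES]
    if (!length(b)) NA_character_ else names(which.max(table(b)))
  }, "")
  names(cons) <- need
  seg <- rep(FALSE, n_sites(aln))
  seg[columns] <- apply(m_all, 2, function(col) length(unique(col)) > 1)
  retained <- rep(FALSE, n_sites(aln))
  retained[columns] <- TRUE
  gc_tab <- Biostrings::GENETIC_CODE

  for (j in seq_along(columns)) {
    s <- columns[j]
    if (kind_of[s] == "intron") { site_class[j] <- "intron"; next }
    ci <- codon_of_site[s]
    if (is.na(ci)) { site_class[j] <- "exon_partial"; next }
    trio <- codon_sites[, ci]
    others <- setdiff(trio, s)
    ambiguous[j] <- any(retained[others] & seg[others])
    ctx <- cons[as.character(trio)]
    obs <- unique(m_all[, j])
    cd <- ctx
    aas <- vapply(obs, function(b) {
      cd[pos_of_site[s]] <- b
      if (anyNA(cd) || !all(cd %in% ALN_BASES)) return(NA_character_)
      unname(gc_tab[paste(cd, collapse = "")])
    }, "")
    if (anyNA(aas)) {
      site_class[j] <- "exon_partial"  # unresolvable context
    } else {
      site_class[j] <- if (length(unique(aas)) == 1) "synonymous" else "nonsynonymous"
    }
  }
  data.frame(site = columns, status = status, site_class = site_class,
             ambiguous_codon = ambiguous, stringsAsFactors = FALSE)
}

#' 2x2 divergence/polymorphism table by site class
#'
#' @param cls Output of [classify_alignment_sites()].
#' @param classes Two site classes to contrast (default synonymous sites vs
#'   introns).
#' @return 2x2 integer matrix, rows `divergence`/`polymorphism`, columns
#'   `classes`.
#' @export
site_class_table <- function(cls, classes = c("synonymous", "intron")) {
  stopifnot(length(classes) == 2)
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("divergence", "polymorphism"), classes))
  for (k in 1:2) {
    sub <- cls[cls$site_class == classes[k], , drop = FALSE]
    tab[1, k] <- sum(sub$status == "fixed")
    tab[2, k] <- sum(sub$status == "polymorphic")
  }
  tab
}

#' Two-sided Fisher's exact test (minimum-likelihood rule)
#'
#' Exact hypergeometric test of a 2x2 contingency table; the two-sided P is
#' the sum of probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table. A zero
#' margin makes association impossible: P = 1 with a flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `p` and `degenerate` flag.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, degenerate = TRUE))
  }
  list(p = stats::fisher.test(tab)$p.value, degenerate = FALSE)
}

#' McDonald-Kreitman test between two species
#'
#' Contrasts fixed inter-specific differences against intra-specific
#' polymorphism at non-synonymous vs synonymous sites for one gene, using
#' [classify_alignment_sites()] with the two species' (orthologous,
#' single-copy male) sequence groups, and evaluates the 2x2 table with the
#' two-sided Fisher's exact test.
#'
#' @param aln An `lm_alignment`.
#' @param ids_a,ids_b Record IDs of the same gene in two species.
#' @param map A `region_map`.
#' @param columns Retained sites; default complete deletion over both groups.
#' @return List with `table` (2x2) and `p`.
#' @export
mcdonald_kreitman <- function(aln, ids_a, ids_b, map, columns = NULL) {
  cls <- classify_alignment_sites(aln, ids_a, ids_b, map, columns)
  tab <- site_class_table(cls, classes = c("nonsynonymous", "synonymous"))
  list(table = tab, p = fisher_exact_two_sided(tab)$p)
}

#' Two-locus HKA test
#'
#' Classic chi-square comparison of polymorphism-to-divergence ratios across
#' two loci under neutrality. Method-of-moments estimates of the per-locus
#' population mutation parameters and the shared divergence time are
#' obtained from the moment conditions, and
#' `X^2 = sum (obs - exp)^2 / Var` over the four cells with the standard
#' variance forms (Var S = E S + (x theta)^2 * b_n with b_n = sum 1/i^2;
#' Var D = E D + (x theta)^2), referred to chi-square with 1 df.
#'
#' @param S1,S2 Segregating-site counts at locus 1 / locus 2.
#' @param D1,D2 Divergence counts (differences to the other species).
#' @param n1,n2 Sample sizes (sequences) underlying `S1`, `S2`.
#' @param L1,L2 Locus lengths in sites (informational; counts are totals).
#' @param x_scale Per-locus inheritance scaling of theta (e.g. `3/4` for an
#'   X-linked locus compared against autosomal references).
#' @return List with `chisq`, `p`, `theta` (per-locus totals), `tau`
#'   (divergence time + 1, in 2N generations), `expected` counts.
#' @export
hka_test <- function(S1, D1, n1, L1, S2, D2, n2, L2, x_scale = c(1, 1)) {
  S <- c(S1, S2); D <- c(D1, D2); n <- c(n1, n2); x <- x_scale
  if (all(S + D == 0)) stop("degenerate input: all counts zero")
  a <- vapply(n, function(k) sum(1 / seq_len(k - 1)), 0)
  b <- vapply(n, function(k) sum(1 / seq_len(k - 1)^2), 0)
  theta_of <- function(tau) (S + D) / (x * a + tau + x)
  gap <- function(tau) sum(S) - sum(x * theta_of(tau) * a)
  # gap is increasing in tau; bracket and solve
  lo <- 0; hi <- 1
  while (gap(hi) < 0 && hi < 1e8) hi <- hi * 2
  tau <- if (gap(lo) >= 0) 0 else uniroot(gap, c(lo, hi), tol = 1e-10)$root
  theta <- theta_of(tau)
  ES <- x * theta * a
  ED <- theta * (tau + x)
  VS <- ES + (x * theta)^2 * b
  VD <- ED + (x * theta)^2
  cells_S <- ifelse(VS > 0, (S - ES)^2 / VS, 0)
  cells_D <- ifelse(VD > 0, (D - ED)^2 / VD, 0)
  chisq <- sum(cells_S) + sum(cells_D)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       theta = theta, tau = tau,
       expected = list(S = ES, D = ED))
}

#' Normalized linkage disequilibrium D' between two sites
#'
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` with the standard
#' frequency-dependent bound, in `[0, 1]`.
#'
#' @param haps Character matrix of haplotypes (rows) x sites (columns),
#'   e.g. male single-copy sequences.
#' @param i,j Column indices of two biallelic sites.
#' @return `D'`, or `NA` (with a warning) for a monomorphic site.
#' @export
d_prime <- function(haps, i, j) {
  a <- haps[, i]; b <- haps[, j]
  ua <- sort(unique(a)); ub <- sort(unique(b))
  if (length(ua) != 2 || length(ub) != 2) {
    warning("site not biallelic; D' undefined")
    return(NA_real_)
  }
  pA <- mean(a == ua[1]); pB <- mean(b == ub[1])
  pAB <- mean(a == ua[1] & b == ub[1])
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (Dmax == 0) return(NA_real_)
  abs(D) / Dmax
}

#' Pairwise D' matrix over the biallelic sites of a haplotype set
#'
#' @param aln An `lm_alignment` of phased (male single-copy) sequences.
#' @param ids Record IDs; default all.
#' @param columns Retained sites; default complete deletion over `ids`.
#' @return List with `sites` (indices of biallelic sites) and `dprime`
#'   (symmetric matrix).
#' @export
d_prime_matrix <- function(aln, ids = rownames(aln$seq), columns = NULL) {
  if (is.null(columns)) columns <- complete_deletion_columns(aln, ids)
  m <- aln$seq[ids, columns, drop = FALSE]
  biall <- which(apply(m, 2, function(col) length(unique(col)) == 2))
  k <- length(biall)
  dm <- matrix(NA_real_, k, k,
               dimnames = list(columns[biall], columns[biall]))
  if (k >= 2) {
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        dm[u, v] <- dm[v, u] <- d_prime(m, biall[u], biall[v])
      }
    }
  }
  diag(dm) <- 1
  list(sites = columns[biall], dprime = dm)
}
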