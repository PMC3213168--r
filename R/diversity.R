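#' Distance estimate container
#'
#' @param value Proportion of differing sites.
#' @param se Bootstrap standard error (NA when not computed).
#' @param n_sites Number of sites (or site equivalents) used.
#' @param site_class One of `"all"`, `"synonymous"`, `"nonsynonymous"`,
#'   `"intron"`, `"exon"`.
#' @param kind `"pi"` (within-group diversity) or `"d"` (between-group
#'   divergence).
#' @return A list of class `distance_estimate`.
#' @export
distance_estimate <- function(value, se = NA_real_, n_sites = NA_real_,
                              site_class = "all", kind = "d") {
  stopifnot(value >= 0, value <= 1, is.na(se) || se >= 0)
  structure(list(value = value, se = se, n_sites = n_sites,
                 site_class = site_class, kind = kind),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("%s[%s] = %.5f (SE %s, %s sites)\n", x$kind, x$site_class,
              x$value, ifelse(is.na(x$se), "-", sprintf("%.5f", x$se)),
              format(x$n_sites)))
  invisible(x)
}

#' Uncorrected pairwise p-distance over retained columns
#'
#' @param a,b Character vectors of bases (full-length sequences).
#' @param columns Retained site indices (no gaps allowed there).
#' @return Proportion of mismatching retained sites.
#' @export
pairwise_p_distance <- function(a, b, columns) {
  if (length(columns) == 0) stop("no retained columns")
  mean(a[columns] != b[columns])
}

#' Within-group nucleotide diversity (pi)
#'
#' Unweighted mean of pairwise p-distances over all unordered pairs of the
#' group, computed on complete-deletion columns.
#'
#' @param aln An `lm_alignment`.
#' @param ids Record IDs of the group (>= 2).
#' @param columns Retained site indices; default complete deletion over `ids`.
#' @param boot Bootstrap replicates for the standard error (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A `distance_estimate` of kind `"pi"`.
#' @export
nucleotide_diversity <- function(aln, ids, columns = NULL, boot = 0,
                                 seed = NULL) {
  if (length(ids) < 2) stop("need at least two sequences for pi")
  if (is.null(columns)) columns <- complete_deletion_columns(aln, ids)
  m <- aln$seq[ids, columns, drop = FALSE]
  pr <- combn(length(ids), 2)
  stat <- function(cols) {
    mean(apply(pr, 2, function(p) mean(m[p[1], cols] != m[p[2], cols])))
  }
  est <- stat(seq_along(columns))
  se <- if (boot > 0) {
    bootstrap_se(stat, length(columns), reps = boot, seed = seed)
  } else NA_real_
  distance_estimate(est, se, length(columns), "all", "pi")
}

#' Between-group nucleotide divergence (d)
#'
#' Unweighted mean of pairwise p-distances over all between-group pairs
#' (no net correction, i.e. within-group diversity is not subtracted).
#'
#' @param aln An `lm_alignment`.
#' @param ids_a,ids_b Record IDs of the two groups.
#' @param columns Retained site indices; default complete deletion over the
#'   union of both groups.
#' @param boot Bootstrap replicates for the standard error (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A `distance_estimate` of kind `"d"`.
#' @export
nucleotide_divergence <- function(aln, ids_a, ids_b, columns = NULL,
                                  boot = 0, seed = NULL) {
  if (length(ids_a) == 0 || length(ids_b) == 0) stop("empty group")
  if (is.null(columns)) columns <- complete_deletion_columns(aln, c(ids_a, ids_b))
  ma <- aln$seq[ids_a, columns, drop = FALSE]
  mb <- aln$seq[ids_b, columns, drop = FALSE]
  stat <- function(cols) {
    tot <- 0
    for (i in seq_len(nrow(ma))) {
      for (j in seq_len(nrow(mb))) {
        tot <- tot + mean(ma[i, cols] != mb[j, cols])
      }
    }
    tot / (nrow(ma) * nrow(mb))
  }
  est <- stat(seq_along(columns))
  se <- if (boot > 0) {
    bootstrap_se(stat, length(columns), reps = boot, seed = seed)
  } else NA_real_
  distance_estimate(est, se, length(columns), "all", "d")
}

## ---- Nei-Gojobori synonymous/non-synonymous counting ----------------------

# Per-codon synonymous site fraction: for each position the fraction of the
# three possible changes that are synonymous; changes creating a stop codon
# count as non-synonymous, so syn + nonsyn sites sum to exactly 3 per codon.
ng_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- names(Biostrings::GENETIC_CODE)
    syn <- setNames(numeric(64), codons)
    for (cd in codons) {
      if (Biostrings::GENETIC_CODE[[cd]] == "*") { syn[cd] <- NA; next }
      b <- strsplit(cd, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        for (alt in setdiff(ALN_BASES, b[pos])) {
          nb <- b; nb[pos] <- alt
          ncd <- paste(nb, collapse = "")
          if (Biostrings::GENETIC_CODE[[ncd]] == Biostrings::GENETIC_CODE[[cd]]) {
            s <- s + 1
          }
        }
      }
      syn[cd] <- s / 3
    }
    tab <<- syn
    tab
  }
})

#' Synonymous site count of a single codon (Nei-Gojobori)
#' @param codon Codon string (e.g. `"TTT"`).
#' @return Fractional number of synonymous sites (0..3); `NA` for stops.
#' @export
ng_syn_sites <- function(codon) unname(ng_site_table()[codon])

# Count syn/nonsyn differences between two codons, averaging over all
# mutational pathways; pathways passing through a stop codon are excluded.
ng_codon_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffpos <- which(b1 != b2)
  nd <- length(diffpos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  gc <- Biostrings::GENETIC_CODE
  step <- function(from, pos, toBase) {
    nb <- strsplit(from, "")[[1]]
    nb[pos] <- toBase
    paste(nb, collapse = "")
  }
  perms <- if (nd == 1) list(diffpos) else {
    do.call(c, lapply(seq_len(nd), function(i) {
      rest <- diffpos[-i]
      if (length(rest) == 1) list(c(diffpos[i], rest))
      else list(c(diffpos[i], rest[1], rest[2]), c(diffpos[i], rest[2], rest[1]))
    }))
  }
  acc <- matrix(0, nrow = 0, ncol = 2)
  for (ord in perms) {
    cur <- c1
    syn <- 0; nonsyn <- 0; valid <- TRUE
    for (k in seq_along(ord)) {
      nxt <- step(cur, ord[k], b2[ord[k]])
      if (gc[[nxt]] == "*" && k < length(ord)) { valid <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (valid) acc <- rbind(acc, c(syn, nonsyn))
  }
  if (nrow(acc) == 0) {
    # all pathways pass through a stop; fall back to averaging over all
    warning("all mutational pathways between ", c1, " and ", c2,
            " pass through a stop codon; averaging over all pathways")
    for (ord in perms) {
      cur <- c1; syn <- 0; nonsyn <- 0
      for (k in seq_along(ord)) {
        nxt <- step(cur, ord[k], b2[ord[k]])
        if (gc[[cur]] == gc[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      acc <- rbind(acc, c(syn, nonsyn))
    }
  }
  c(syn = mean(acc[, 1]), nonsyn = mean(acc[, 2]))
}

#' Nei-Gojobori counts for a pair of codon sequences
#'
#' Synonymous/non-synonymous site counts are per-codon fractions from the
#' standard genetic code, averaged over the two sequences; multi-site codon
#' differences are averaged over all mutational pathways, excluding pathways
#' through stop codons.
#'
#' @param codons_a,codons_b Equal-length character vectors of codon strings.
#' @return List with `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`.
#' @export
nei_gojobori_pair <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  sa <- ng_syn_sites(codons_a)
  sb <- ng_syn_sites(codons_b)
  if (anyNA(sa)) stop("stop codon in first sequence at codon ", which(is.na(sa))[1])
  if (anyNA(sb)) stop("stop codon in second sequence at codon ", which(is.na(sb))[1])
  syn <- 0; nonsyn <- 0
  for (i in seq_along(codons_a)) {
    if (codons_a[i] != codons_b[i]) {
      d <- ng_codon_diffs(codons_a[i], codons_b[i])
      syn <- syn + d["syn"]
      nonsyn <- nonsyn + d["nonsyn"]
    }
  }
  list(syn_sites = mean(c(sum(sa), sum(sb))),
       nonsyn_sites = 3 * length(codons_a) - mean(c(sum(sa), sum(sb))),
       syn_diffs = unname(syn), nonsyn_diffs = unname(nonsyn))
}

#' Codon matrix of the coding region
#'
#' Concatenates the exon regions in frame and keeps only codons whose three
#' sites are all among the retained columns (complete deletion at codon
#' resolution, preserving codon integrity).
#'
#' @param aln An `lm_alignment`.
#' @param map A `region_map`.
#' @param ids Record IDs; default all.
#' @param columns Retained site indices; default complete deletion over `ids`.
#' @return Character matrix (records x codons) of codon strings; attribute
#'   `"codon_sites"` holds a 3-row matrix of the alignment positions used.
#' @export
codon_matrix <- function(aln, map, ids = rownames(aln$seq), columns = NULL) {
  if (is.null(columns)) columns <- complete_deletion_columns(aln, ids)
  cf <- coding_frame(map)
  keep_codon <- tapply(cf$sites %in% columns, cf$codon, all)
  cods <- as.integer(names(keep_codon)[keep_codon])
  sites <- matrix(cf$sites, nrow = 3)[, cods, drop = FALSE]
  m <- matrix("", nrow = length(ids), ncol = length(cods),
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    s <- aln$seq[ids[i], ]
    m[i, ] <- apply(sites, 2, function(p) paste(s[p], collapse = ""))
  }
  attr(m, "codon_sites") <- sites
  m
}

#' Synonymous / non-synonymous diversity or divergence (Nei-Gojobori)
#'
#' Averages pairwise `diffs/sites` over all within-group pairs (`ids_b`
#' missing: diversity) or all between-group pairs (divergence). The
#' bootstrap resampling unit is the whole codon.
#'
#' @param aln An `lm_alignment`.
#' @param map A `region_map`.
#' @param ids_a First (or only) group.
#' @param ids_b Second group; omit for within-group diversity.
#' @param type `"synonymous"` or `"nonsynonymous"`.
#' @param columns Retained sites; default complete deletion over all ids used.
#' @param boot Bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A `distance_estimate`.
#' @export
ng_distance <- function(aln, map, ids_a, ids_b = NULL,
                        type = c("synonymous", "nonsynonymous"),
                        columns = NULL, boot = 0, seed = NULL) {
  type <- match.arg(type)
  ids <- c(ids_a, ids_b)
  if (is.null(columns)) columns <- complete_deletion_columns(aln, ids)
  cm <- codon_matrix(aln, map, ids, columns)
  pairs <- if (is.null(ids_b)) {
    if (length(ids_a) < 2) stop("need at least two sequences for pi")
    asplit(combn(ids_a, 2), 2)
  } else {
    unlist(lapply(ids_a, function(a) lapply(ids_b, function(b) c(a, b))),
           recursive = FALSE)
  }
  # per-pair per-codon counts, cached so the bootstrap only re-aggregates
  percodon <- lapply(pairs, function(p) {
    ca <- cm[p[1], ]; cb <- cm[p[2], ]
    sa <- ng_syn_sites(ca); sb <- ng_syn_sites(cb)
    if (anyNA(c(sa, sb))) stop("stop codon in sequence ", p[anyNA(sa) + 1])
    d <- vapply(seq_along(ca), function(i) {
      if (ca[i] == cb[i]) c(0, 0) else unname(ng_codon_diffs(ca[i], cb[i]))
    }, numeric(2))
    list(sites = (sa + sb) / 2, syn = d[1, ], nonsyn = d[2, ])
  })
  n_cod <- ncol(cm)
  stat <- function(idx) {
    mean(vapply(percodon, function(pc) {
      s_syn <- sum(pc$sites[idx])
      if (type == "synonymous") {
        if (s_syn == 0) return(0)
        sum(pc$syn[idx]) / s_syn
      } else {
        s_non <- 3 * length(idx) - s_syn
        if (s_non == 0) return(0)
        sum(pc$nonsyn[idx]) / s_non
      }
    }, 0))
  }
  est <- stat(seq_len(n_cod))
  se <- if (boot > 0) bootstrap_se(stat, n_cod, reps = boot, seed = seed) else NA_real_
  mean_sites <- mean(vapply(percodon, function(pc) sum(pc$sites), 0))
  n_sites <- if (type == "synonymous") mean_sites else 3 * n_cod - mean_sites
  distance_estimate(min(est, 1), se, n_sites, type,
                    if (is.null(ids_b)) "pi" else "d")
}

#' Bootstrap standard error of a resampleable statistic
#'
#' Resamples `n_units` sampling units (sites, or whole codons for
#' synonymous/non-synonymous statistics) with replacement and returns the
#' standard deviation of the statistic across replicates.
#'
#' @param statistic Function taking a vector of unit indices.
#' @param n_units Number of resampling units.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed RNG seed; same seed gives identical results.
#' @return Bootstrap standard error.
#' @export
bootstrap_se <- function(statistic, n_units, reps = 1000, seed = NULL) {
  stopifnot(reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    statistic(sample.int(n_units, n_units, replace = TRUE))
  }, 0)
  stats::sd(vals)
}

#' One-tailed Z comparison of two distance estimates
#'
#' Tests H1: `e1 > e2` with `Z = (v1 - v2) / sqrt(se1^2 + se2^2)` and an
#' upper-tail standard normal P. When both standard errors are zero the Z
#' statistic is undefined: equal values report P = 1 with a flag, otherwise
#' P is 0 or 1 by the sign of the difference.
#'
#' @param e1,e2 `distance_estimate` objects (or lists with `value` and `se`).
#' @return List with `z`, `p` and `degenerate` flag.
#' @export
z_test_one_tailed <- function(e1, e2) {
  v1 <- e1$value; v2 <- e2$value
  s <- sqrt(e1$se^2 + e2$se^2)
  if (is.na(s)) stop("both estimates need standard errors")
  if (s == 0) {
    p <- if (v1 > v2) 0 else 1
    return(list(z = NA_real_, p = p, degenerate = TRUE))
  }
  z <- (v1 - v2) / s
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE), degenerate = FALSE)
}

#' Scale an autosomal diversity to the X-chromosome expectation
#'
#' Under neutrality the X carries 3/4 of the autosomal effective copies, so
#' autosomal diversities are multiplied by 3/4 before comparison with
#' X-linked loci.
#'
#' @param pi Autosomal nucleotide diversity (proportion).
#' @return `0.75 * pi`.
#' @export
scale_autosomal_to_x <- function(pi) {
  stopifnot(all(pi >= 0))
  0.75 * pi
}
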