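#' Condensed polymorphic-site profile of an alignment
#'
#' Drops monomorphic columns and every column containing a gap, `N` or
#' ambiguity code among the chosen records; the retained columns' original
#' alignment indices are kept for back-mapping fragment coordinates.
#'
#' @param aln An `lm_alignment`.
#' @param ids Record IDs (>= 2); default all records.
#' @param columns Candidate site indices; default all sites.
#' @return A list of class `poly_profile` with `site_indices` (strictly
#'   increasing original indices) and `mat` (records x polymorphic sites).
#'   An invariant alignment gives an empty profile.
#' @export
build_profile <- function(aln, ids = rownames(aln$seq), columns = NULL) {
  if (length(ids) < 2) stop("need at least two records")
  if (is.null(columns)) columns <- seq_len(n_sites(aln))
  m <- aln$seq[ids, columns, drop = FALSE]
  clean <- colSums(matrix(!(m %in% ALN_BASES), nrow = nrow(m))) == 0
  npoly <- apply(m, 2, function(col) length(unique(col))) >= 2
  keep <- which(clean & npoly)
  structure(list(site_indices = columns[keep],
                 mat = m[, keep, drop = FALSE]),
            class = "poly_profile")
}

#' @export
print.poly_profile <- function(x, ...) {
  cat(sprintf("poly_profile: %d records x %d polymorphic sites\n",
              nrow(x$mat), length(x$site_indices)))
  invisible(x)
}

# Ruzzo-Tompa maximal scoring subsequences for the mismatch-penalty mode.
# scores: numeric vector; returns data.frame(start, end, score) of all
# maximal scoring segments (indices into scores).
max_scoring_segments <- function(scores) {
  segs <- list()  # each: list(Lpos, Rpos, Lcum, Rcum)
  cum <- 0
  for (i in seq_along(scores)) {
    s <- scores[i]
    cum <- cum + s
    if (s <= 0) next
    cand <- list(Lpos = i, Rpos = i, Lcum = cum - s, Rcum = cum)
    repeat {
      # step 1: find rightmost j with Lcum[j] < cand$Lcum
      j <- NULL
      if (length(segs)) {
        for (k in rev(seq_along(segs))) {
          if (segs[[k]]$Lcum < cand$Lcum) { j <- k; break }
        }
      }
      if (is.null(j)) { segs[[length(segs) + 1]] <- cand; break }
      if (segs[[j]]$Rcum >= cand$Rcum) { segs[[length(segs) + 1]] <- cand; break }
      # merge segment j..end into cand and retry
      cand$Lpos <- segs[[j]]$Lpos
      cand$Lcum <- segs[[j]]$Lcum
      segs <- segs[seq_len(j - 1)]
    }
  }
  if (!length(segs)) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  data.frame(start = vapply(segs, `[[`, 0L, "Lpos"),
             end = vapply(segs, `[[`, 0L, "Rpos"),
             score = vapply(segs, function(s) s$Rcum - s$Lcum, 0))
}

#' Candidate conversion fragments for one sequence pair
#'
#' With the mismatch penalty disabled (`penalty = 0`, the default),
#' fragments are the maximal runs of consecutive polymorphic sites at which
#' the pair agrees, scored by run length. With `penalty > 0` fragments are
#' BLAST-like maximal scoring segments (match +1, mismatch `-penalty`,
#' Ruzzo-Tompa decomposition). Bounds are back-mapped to original alignment
#' coordinates, spanning from the first to the last matching polymorphic
#' site (the data cannot localize a conversion boundary between polymorphic
#' sites).
#'
#' @param profile A `poly_profile`.
#' @param id1,id2 Record IDs present in the profile.
#' @param penalty Mismatch penalty `g >= 0`; 0 disables mismatches inside
#'   fragments.
#' @return Data frame: `id1`, `id2`, `start`, `end` (1-based inclusive
#'   original coordinates), `n_poly_sites`, `score`.
#' @export
pairwise_fragments <- function(profile, id1, id2, penalty = 0) {
  for (id in c(id1, id2)) {
    if (!(id %in% rownames(profile$mat))) stop("unknown record ID: ", id)
  }
  empty <- data.frame(id1 = character(), id2 = character(), start = integer(),
                      end = integer(), n_poly_sites = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  S <- length(profile$site_indices)
  if (S == 0) return(empty)
  agree <- profile$mat[id1, ] == profile$mat[id2, ]
  if (penalty == 0) {
    r <- rle(agree)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(empty)
    segs <- data.frame(start = starts[keep], end = ends[keep],
                       score = as.numeric(r$lengths[keep]))
  } else {
    segs <- max_scoring_segments(ifelse(agree, 1, -penalty))
    if (!nrow(segs)) return(empty)
    # trim to first/last matching site (segments begin/end on matches anyway)
  }
  data.frame(id1 = id1, id2 = id2,
             start = profile$site_indices[segs$start],
             end = profile$site_indices[segs$end],
             n_poly_sites = segs$end - segs$start + 1L,
             score = segs$score, stringsAsFactors = FALSE)
}

all_pair_fragments <- function(profile, penalty = 0, pairs = NULL) {
  ids <- rownames(profile$mat)
  if (is.null(pairs)) pairs <- combn(ids, 2)
  # vectorized collection (one rle per pair) -- equivalent to rbind-ing
  # pairwise_fragments() over all pairs but without per-pair data frames
  id1 <- list(); id2 <- list(); st <- list(); en <- list(); sc <- list()
  np <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- profile$mat[pairs[1, k], ] == profile$mat[pairs[2, k], ]
    if (!length(a)) next
    if (penalty == 0) {
      r <- rle(a)
      ends <- cumsum(r$lengths)
      keep <- which(r$values)
      if (!length(keep)) next
      segs <- data.frame(start = ends[keep] - r$lengths[keep] + 1,
                         end = ends[keep],
                         score = as.numeric(r$lengths[keep]))
    } else {
      segs <- max_scoring_segments(ifelse(a, 1, -penalty))
      if (!nrow(segs)) next
    }
    id1[[k]] <- rep(pairs[1, k], nrow(segs))
    id2[[k]] <- rep(pairs[2, k], nrow(segs))
    st[[k]] <- profile$site_indices[segs$start]
    en[[k]] <- profile$site_indices[segs$end]
    sc[[k]] <- segs$score
    np[[k]] <- segs$end - segs$start + 1L
  }
  out <- data.frame(id1 = unlist(id1), id2 = unlist(id2),
                    start = as.integer(unlist(st)),
                    end = as.integer(unlist(en)),
                    n_poly_sites = as.integer(unlist(np)),
                    score = unlist(sc), stringsAsFactors = FALSE)
  if (is.null(out$id1)) {
    out <- data.frame(id1 = character(), id2 = character(),
                      start = integer(), end = integer(),
                      n_poly_sites = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Global permutation test of fragment scores
#'
#' The null hypothesis is that nucleotide differences are randomly
#' distributed along the sequences: polymorphic-site columns are permuted
#' and, for each permutation, the maximum weighted fragment score over all
#' sequence pairs is recorded. Because pairs differ enormously in overall
#' similarity (near-identical within-group haplotypes would otherwise
#' dominate the alignment-wide maximum and mask every true tract), each
#' pair's run length is weighted by its information content
#' `-log(1 - mismatch fraction)`: a long run is strong evidence only in a
#' pair that disagrees often elsewhere. The weight is a per-pair constant,
#' so the column-permutation null remains exchangeable. A fragment's global
#' P is `(1 + #{permutation max >= its weighted score}) / (n_perm + 1)`;
#' taking the alignment-wide maximum as the reference distribution is the
#' multiple-comparison correction.
#'
#' @param profile A `poly_profile`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @param penalty Mismatch penalty passed to [pairwise_fragments()].
#' @return List with `fragments` (all observed fragments, with `score` =
#'   run length, `weighted_score` and `global_sim_p` columns) and
#'   `null_max` (per-permutation weighted maxima).
#' @export
global_permutation_test <- function(profile, n_perm = 10000, seed = NULL,
                                    penalty = 0) {
  stopifnot(n_perm >= 1)
  frags <- all_pair_fragments(profile, penalty)
  S <- length(profile$site_indices)
  if (S == 0 || nrow(frags) == 0) {
    frags$weighted_score <- numeric(0)
    frags$global_sim_p <- numeric(0)
    return(list(fragments = frags, null_max = numeric(0)))
  }
  ids <- rownames(profile$mat)
  pr <- combn(length(ids), 2)
  agree <- matrix(0L, ncol(pr), S)
  for (k in seq_len(ncol(pr))) {
    agree[k, ] <- as.integer(profile$mat[pr[1, k], ] == profile$mat[pr[2, k], ])
  }
  mism <- 1 - rowMeans(agree)
  w <- ifelse(mism >= 1, 0, -log1p(-mism))
  names(w) <- paste(pr[1, ], pr[2, ])
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(r) sample.int(S), integer(S))
  null_max <- perm_max_stat_cpp(agree, perms, penalty, w)
  pair_key <- paste(match(frags$id1, ids), match(frags$id2, ids))
  frags$weighted_score <- frags$score * unname(w[pair_key])
  nm_sorted <- sort(null_max)
  n_ge <- n_perm - findInterval(frags$weighted_score - 1e-9, nm_sorted)
  frags$global_sim_p <- (1 + n_ge) / (n_perm + 1)
  list(fragments = frags, null_max = null_max)
}

#' Detect gene-conversion tracts in an alignment
#'
#' Runs the Sawyer-style fragment search and global permutation test over
#' all pairs of the chosen records and reports the significant fragments
#' with exon/intron composition. Haplotype-requiring emulation of the
#' original study restricts `ids` to single-copy male sequences; that
#' restriction is the caller's responsibility.
#'
#' @param aln An `lm_alignment`.
#' @param map A `region_map` used to annotate tract composition.
#' @param ids Record IDs to analyze; default all.
#' @param groups Optional named vector (record ID -> group key, e.g. from
#'   [group_labels()]) used to annotate each fragment's pair of groups.
#' @param alpha Significance level on the global P (default 0.05).
#' @param n_perm Permutations (default 10000).
#' @param seed RNG seed.
#' @param penalty Mismatch penalty (default 0, mismatch-free inner
#'   fragments).
#' @return Data frame of significant fragments: pair, `start`, `end`,
#'   `n_poly_sites`, `score`, `weighted_score`, `global_sim_p`,
#'   `regions_hit` (overlap fractions) and `intron_fraction` (fraction of
#'   tract length in introns); with `groups`, also `group1`/`group2`. The
#'   full fragment table and the null maxima are attached as attributes
#'   `"all_fragments"` and `"null_max"`.
#' @export
detect_conversions <- function(aln, map, ids = rownames(aln$seq),
                               groups = NULL, alpha = 0.05, n_perm = 10000,
                               seed = NULL, penalty = 0) {
  profile <- build_profile(aln, ids)
  res <- global_permutation_test(profile, n_perm = n_perm, seed = seed,
                                 penalty = penalty)
  fr <- res$fragments
  if (!is.null(groups)) {
    fr$group1 <- unname(groups[fr$id1])
    fr$group2 <- unname(groups[fr$id2])
  }
  sig <- fr[!is.na(fr$global_sim_p) &
              (fr$global_sim_p < alpha | alpha >= 1), , drop = FALSE]
  if (nrow(sig)) {
    ann <- t(vapply(seq_len(nrow(sig)), function(i) {
      annotate_tract(map, sig$start[i], sig$end[i])
    }, c(regions_hit = "", intron_fraction = "")))
    sig$regions_hit <- ann[, "regions_hit"]
    sig$intron_fraction <- as.numeric(ann[, "intron_fraction"])
  } else {
    sig$regions_hit <- character(0)
    sig$intron_fraction <- numeric(0)
  }
  rownames(sig) <- NULL
  attr(sig, "all_fragments") <- fr
  attr(sig, "null_max") <- res$null_max
  sig
}

annotate_tract <- function(map, start, end) {
  len <- end - start + 1
  ov <- pmax(0, pmin(map$regions$end, end) - pmax(map$regions$start, start) + 1)
  hit <- which(ov > 0)
  desc <- paste(sprintf("%s:%.3f", map$regions$name[hit], ov[hit] / len),
                collapse = ";")
  c(regions_hit = desc,
    intron_fraction = sprintf("%.6f",
                              sum(ov[map$regions$kind == "intron"]) / len))
}
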