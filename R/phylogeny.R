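#' Jukes-Cantor correction of a p-distance
#'
#' @param p Proportion of differing sites, `0 <= p < 0.75`.
#' @return Expected substitutions per site, `-(3/4) log(1 - 4p/3)`.
#' @export
jukes_cantor_correct <- function(p) {
  if (any(p < 0)) stop("negative p-distance")
  if (any(p >= 0.75)) stop("p-distance saturated (p >= 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Among-group distance matrix
#'
#' Between-group nucleotide divergence for every pair of groups, computed on
#' jointly retained (complete-deletion) columns and, by default, corrected
#' for multiple substitutions with the Jukes-Cantor formula.
#'
#' @param aln An `lm_alignment`.
#' @param groups Named list: group label -> record IDs. Single-sequence
#'   groups (e.g. an outgroup) are allowed.
#' @param columns Retained sites; default complete deletion over all records
#'   of all groups jointly.
#' @param jc Apply the Jukes-Cantor correction (default TRUE).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
among_group_distance_matrix <- function(aln, groups, columns = NULL, jc = TRUE) {
  if (length(groups) < 3) stop("need at least three groups")
  if (is.null(columns)) {
    columns <- complete_deletion_columns(aln, unlist(groups))
  }
  k <- length(groups)
  labs <- names(groups)
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- nucleotide_divergence(aln, groups[[i]], groups[[j]], columns)$value
      if (jc) {
        if (p >= 0.75) stop("saturated pair: ", labs[i], " vs ", labs[j])
        p <- jukes_cantor_correct(p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via [ape::nj()]). Negative branch
#' lengths are clamped to zero for output; the raw lengths are kept in
#' attribute `"raw_edge_length"`. When an outgroup label is given the tree
#' is rooted on it.
#'
#' @param d Symmetric distance matrix (labelled).
#' @param outgroup Optional leaf label to root on.
#' @param clamp Clamp negative branch lengths to zero (default TRUE).
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d, outgroup = NULL, clamp = TRUE) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix is not symmetric")
  tr <- ape::nj(d)
  raw <- tr$edge.length
  if (clamp) tr$edge.length <- pmax(tr$edge.length, 0)
  if (!is.null(outgroup)) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    raw <- tr$edge.length  # rooting reorders edges; keep consistent copy
  }
  attr(tr, "raw_edge_length") <- raw
  tr
}

#' Among-group NJ tree with bootstrap supports
#'
#' Resamples alignment columns (from the retained set) with replacement,
#' recomputes the Jukes-Cantor corrected among-group distance matrix and the
#' NJ tree for each replicate, and reports for every internal branch of the
#' point-estimate tree the percentage of replicates containing the same
#' bipartition. In replicates a saturated pairwise distance is clamped just
#' below the Jukes-Cantor domain boundary rather than aborting.
#'
#' @param aln An `lm_alignment`.
#' @param groups Named list: group label -> record IDs.
#' @param columns Retained sites; default complete deletion over all groups.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param outgroup Optional leaf label to root the reported tree on.
#' @return An [ape::phylo] tree whose `node.label` holds support percentages
#'   (in 0..100) and with attribute `"boot_trees"` (a `multiPhylo`).
#' @export
bootstrap_supports <- function(aln, groups, columns = NULL, reps = 1000,
                               seed = NULL, outgroup = NULL) {
  stopifnot(reps >= 1)
  if (is.null(columns)) {
    columns <- complete_deletion_columns(aln, unlist(groups))
  }
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(among_group_distance_matrix(aln, groups, columns))
  one_rep <- function() {
    cols <- sample(columns, length(columns), replace = TRUE)
    k <- length(groups)
    D <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- nucleotide_divergence(aln, groups[[i]], groups[[j]], cols)$value
        D[i, j] <- D[j, i] <- jukes_cantor_correct(min(p, 0.7499))
      }
    }
    neighbor_joining(D)
  }
  bt <- lapply(seq_len(reps), function(r) one_rep())
  class(bt) <- "multiPhylo"
  counts <- ape::prop.clades(main, bt, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / reps, 1)
  if (!is.null(outgroup)) {
    main <- ape::root(main, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  attr(main, "boot_trees") <- bt
  main
}

#' Does a tree contain the all-L vs all-M duplication split?
#'
#' Checks whether the unrooted tree has a bipartition separating every
#' `*_L` leaf from every `*_M` leaf, i.e. whether the ancient gene
#' duplication is basal to all species.
#'
#' @param tree An [ape::phylo] whose leaf labels end in `_L` / `_M`.
#' @return Logical.
#' @export
has_duplication_split <- function(tree) {
  lset <- grep("_L$", tree$tip.label, value = TRUE)
  mset <- grep("_M$", tree$tip.label, value = TRUE)
  if (length(lset) < 2 || length(mset) < 2) return(NA)
  bp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(bp, "labels")
  for (part in bp) {
    side <- labs[part]
    if (setequal(side, lset) || setequal(side, mset)) return(TRUE)
  }
  FALSE
}

#' Which species' L and M groups form a pair in the tree?
#'
#' For every species represented by leaves `<sp>_L` and `<sp>_M`, checks
#' whether `{<sp>_L, <sp>_M}` is a bipartition (cherry) of the unrooted
#' tree -- the signature of recent interlocus homogenization.
#'
#' @param tree An [ape::phylo] with `<sp>_L` / `<sp>_M` leaf labels.
#' @return Named logical vector, one element per species.
#' @export
paralog_pairs_monophyletic <- function(tree) {
  sp <- unique(sub("_[LM]$", "", grep("_[LM]$", tree$tip.label, value = TRUE)))
  bp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(bp, "labels")
  sides <- lapply(bp, function(part) labs[part])
  vapply(sp, function(s) {
    pair <- paste0(s, c("_L", "_M"))
    if (!all(pair %in% tree$tip.label)) return(NA)
    any(vapply(sides, function(side) {
      setequal(side, pair) || setequal(side, setdiff(tree$tip.label, pair))
    }, TRUE))
  }, TRUE)
}
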