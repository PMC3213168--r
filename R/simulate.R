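#' Default species tree for simulations
#'
#' Five species in three lineages, the most basal one splitting first, with
#' branch lengths (expected substitutions/site) chosen so that neutral
#' intron diversity and ortholog divergence fall in the range typical of
#' closely related ape species (intron pi of a few tenths of a percent).
#'
#' @return Newick string.
#' @export
default_species_tree <- function() {
  "(Nle:0.016,(Ssy:0.012,(Hag:0.008,Hla:0.008,Hpi:0.008):0.004):0.004);"
}

#' Simulation configuration for a duplicated gene pair
#'
#' The simulator evolves an L/M paralog pair along a species tree under
#' Jukes-Cantor mutation, interlocus gene conversion (uniform start,
#' geometric tract length, random direction) and purifying selection
#' modeled as rejection of any event that would alter the amino acid at a
#' masked spectral-tuning codon. By default events creating a premature
#' stop codon in the reading frame are also rejected (frame-destroying
#' changes are lethal), so simulated coding sequences stay translatable.
#'
#' @param species_tree Newick string with branch lengths in expected
#'   substitutions/site.
#' @param stem_length Branch length between the gene duplication and the
#'   species-tree root (the duplication predates the radiation).
#' @param region_map Region layout; defaults to [default_region_map()]
#'   (exon3 169, intron3 1550, exon4 166, intron4 1550, exon5 240 sites).
#' @param theta Target within-species pairwise diversity per site
#'   (the population mutation parameter; 4Ne*mu autosomal / 3Ne*mu X-linked).
#' @param conv_rate Conversion initiations per site per unit branch length.
#' @param tract_mean Mean of the geometric tract-length distribution (sites).
#' @param p_purge Probability that an event altering a masked amino acid is
#'   rejected (1 = deterministic purifying selection).
#' @param n_samples Haplotypes sampled per species per locus.
#' @param extra_divergent_codons Additional constrained codons (indices into
#'   the coding frame of `region_map`) at which the two paralogs are forced
#'   to divergent amino acids at duplication and which join the selection
#'   mask. The L and M opsin proteins differ at over a dozen constrained
#'   residues beyond the three tuning sites; without them exon divergence
#'   would eventually be eroded by conversion tracts slipping between the
#'   tuning codons. The default places five through exons 3 and 5 (none in
#'   exon 4, where selection against conversion is weakest).
#' @param reject_stops Reject events creating a premature stop codon in the
#'   reading frame (default TRUE; disable for fully neutral simulations).
#' @param seed RNG seed; the same seed reproduces the data set byte for byte.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       stem_length = 0.014,
                       region_map = default_region_map(),
                       theta = 0.003,
                       conv_rate = 1,
                       tract_mean = 300,
                       p_purge = 1,
                       n_samples = 10L,
                       extra_divergent_codons = c(7L, 55L, 117L, 159L, 184L),
                       reject_stops = TRUE,
                       seed = NULL) {
  stopifnot(theta >= 0, conv_rate >= 0, tract_mean >= 1,
            p_purge >= 0, p_purge <= 1, n_samples >= 1, stem_length >= 0)
  structure(list(species_tree = species_tree, stem_length = stem_length,
                 region_map = region_map, theta = theta,
                 conv_rate = conv_rate, tract_mean = tract_mean,
                 p_purge = p_purge, n_samples = as.integer(n_samples),
                 extra_divergent_codons = as.integer(extra_divergent_codons),
                 reject_stops = isTRUE(reject_stops), seed = seed),
            class = "sim_config")
}

# L- and M-type codons at the three tuning residues
TUNING_CODONS <- list(
  L = c(`180` = "TCC", `277` = "TAC", `285` = "ACC"),  # Ser, Tyr, Thr
  M = c(`180` = "GCC", `277` = "TTC", `285` = "GCC")   # Ala, Phe, Ala
)

# codon pair used at the extra constrained residues: Ser vs Ala chosen with
# synonymous codons differing at all three positions, so no partial tract
# overlap is silent
EXTRA_DIV_CODONS <- c(L = "AGT", M = "GCA")

#' Forward-simulate a duplicated-gene data set with ground truth
#'
#' The generative model: (1) a random ancestral sequence with a stop-free
#' reading frame; (2) duplication into an L and an M copy with divergent
#' states forced at the masked tuning codons (L: Ser180/Tyr277/Thr285,
#' M: Ala/Phe/Ala); (3) along the stem and every species-tree branch,
#' Poisson numbers of Jukes-Cantor mutations per copy and
#' Poisson(`conv_rate` * sites * length) conversion events with uniform
#' start, geometric tract length and random direction, interleaved in
#' random order; an event that would alter a masked amino acid is rejected
#' with probability `p_purge`, and (with `reject_stops`) an event creating
#' a premature stop codon is rejected; (4) within each species,
#' `n_samples` haplotypes per
#' locus under a star genealogy, each receiving Poisson(sites * theta / 2)
#' private mutations so the expected pairwise diversity equals `theta`;
#' (5) records named `<i>_<Sp>_M_<L|M>`.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignment` (an `lm_alignment`), `truth` (event log,
#'   tree and config echo) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- cfg$region_map
  L <- max(map$regions$end)
  tree <- ape::read.tree(text = cfg$species_tree)
  if (is.null(tree) || is.null(tree$edge.length)) stop("invalid species tree")
  if (sum(tree$edge.length) + cfg$stem_length <= 0) stop("zero-length tree")

  cf <- coding_frame(map)
  codon_sites <- matrix(cf$sites, nrow = 3)
  mask <- lapply(names(map$anchors), function(res) anchor_codon_sites(map, res))
  names(mask) <- names(map$anchors)
  if (length(cfg$extra_divergent_codons)) {
    if (any(cfg$extra_divergent_codons < 1 |
            cfg$extra_divergent_codons > ncol(codon_sites))) {
      stop("extra_divergent_codons outside the coding frame")
    }
    extra <- lapply(cfg$extra_divergent_codons,
                    function(ci) codon_sites[, ci])
    names(extra) <- paste0("codon", cfg$extra_divergent_codons)
    mask <- c(mask, extra)
  }
  in_mask <- logical(L)
  in_mask[unlist(mask)] <- TRUE
  codon_of_site <- rep(NA_integer_, L)
  codon_of_site[cf$sites] <- cf$codon
  gc_tab <- Biostrings::GENETIC_CODE
  base_others <- lapply(setNames(ALN_BASES, ALN_BASES),
                        function(b) setdiff(ALN_BASES, b))
  aa_of <- function(s, trio) gc_tab[[paste(s[trio], collapse = "")]]

  events <- list()   # one chunk (data frame) per branch

  # Apply one mutation at `pos` -> `alt`; returns modified sequence or NULL
  # if the event is purged (masked-residue change or new stop codon).
  try_mutation <- function(s, pos, alt) {
    ci <- codon_of_site[pos]
    if (!is.na(ci)) {
      trio <- codon_sites[, ci]
      old_aa <- aa_of(s, trio)
      s2 <- s
      s2[pos] <- alt
      new_aa <- aa_of(s2, trio)
      if (cfg$reject_stops && new_aa == "*") return(NULL)
      if (in_mask[pos] && new_aa != old_aa && cfg$p_purge > 0 &&
          runif(1) < cfg$p_purge) {
        return(NULL)
      }
      return(s2)
    }
    s[pos] <- alt
    s
  }

  # boundary codons of a tract (interior fully-covered codons come straight
  # from the stop-free donor, so only the mixed boundary codons can gain a
  # stop)
  boundary_codons <- function(start, end) {
    unique(stats::na.omit(codon_of_site[c(start, end)]))
  }

  evolve_branch <- function(pair, b, branch) {
    n_mut_L <- rpois(1, L * b)
    n_mut_M <- rpois(1, L * b)
    n_conv <- rpois(1, cfg$conv_rate * L * b)
    n_ev <- n_mut_L + n_mut_M + n_conv
    if (n_ev == 0) return(pair)
    kind <- sample(rep(c("mL", "mM", "cv"), c(n_mut_L, n_mut_M, n_conv)))
    rec_type <- character(n_ev); rec_locus <- character(n_ev)
    rec_start <- integer(n_ev); rec_end <- integer(n_ev)
    rec_acc <- logical(n_ev)
    for (k in seq_len(n_ev)) {
      if (kind[k] != "cv") {
        locus <- if (kind[k] == "mL") "L" else "M"
        s <- pair[[locus]]
        pos <- sample.int(L, 1)
        alt <- base_others[[s[pos]]][sample.int(3, 1)]
        s2 <- try_mutation(s, pos, alt)
        acc <- !is.null(s2)
        if (acc) pair[[locus]] <- s2
        rec_type[k] <- "mutation"; rec_locus[k] <- locus
        rec_start[k] <- pos; rec_end[k] <- pos; rec_acc[k] <- acc
      } else {
        from <- if (runif(1) < 0.5) "L" else "M"
        to <- if (from == "L") "M" else "L"
        start <- sample.int(L, 1)
        len <- rgeom(1, 1 / cfg$tract_mean) + 1
        end <- min(L, start + len - 1)
        cand <- pair[[to]]
        cand[start:end] <- pair[[from]][start:end]
        acc <- TRUE
        if (cfg$reject_stops) {
          for (ci in boundary_codons(start, end)) {
            if (aa_of(cand, codon_sites[, ci]) == "*") { acc <- FALSE; break }
          }
        }
        if (acc && cfg$p_purge > 0) {
          for (m in mask) {
            if (aa_of(cand, m) != aa_of(pair[[to]], m)) {
              if (runif(1) < cfg$p_purge) acc <- FALSE
              break
            }
          }
        }
        if (acc) pair[[to]] <- cand
        rec_type[k] <- "conversion"; rec_locus[k] <- paste0(from, "->", to)
        rec_start[k] <- start; rec_end[k] <- end; rec_acc[k] <- acc
      }
    }
    events[[length(events) + 1]] <<- data.frame(
      branch = branch, type = rec_type, locus = rec_locus,
      start = rec_start, end = rec_end, accepted = rec_acc,
      stringsAsFactors = FALSE)
    pair
  }

  # ancestral sequence: random, then resample any stop codon in frame
  anc <- sample(ALN_BASES, L, replace = TRUE)
  sense <- names(gc_tab)[gc_tab != "*"]
  for (ci in seq_len(ncol(codon_sites))) {
    trio <- codon_sites[, ci]
    if (gc_tab[[paste(anc[trio], collapse = "")]] == "*") {
      anc[trio] <- strsplit(sample(sense, 1), "")[[1]]
    }
  }
  rootL <- anc
  rootM <- anc
  for (res in names(TUNING_CODONS$L)) {
    sites <- anchor_codon_sites(map, res)
    rootL[sites] <- strsplit(TUNING_CODONS$L[[res]], "")[[1]]
    rootM[sites] <- strsplit(TUNING_CODONS$M[[res]], "")[[1]]
  }
  for (ci in cfg$extra_divergent_codons) {
    trio <- codon_sites[, ci]
    rootL[trio] <- strsplit(EXTRA_DIV_CODONS[["L"]], "")[[1]]
    rootM[trio] <- strsplit(EXTRA_DIV_CODONS[["M"]], "")[[1]]
  }
  pair0 <- evolve_branch(list(L = rootL, M = rootM), cfg$stem_length, "stem")

  # preorder traversal of the species tree
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1]] <- pair0
  eord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(eord$edge))) {
    par <- eord$edge[e, 1]; child <- eord$edge[e, 2]
    lab <- if (child <= ntip) tree$tip.label[child] else paste0("node", child)
    states[[child]] <- evolve_branch(states[[par]], eord$edge.length[e], lab)
  }

  # within-species star-genealogy sampling (mutation-only "branches")
  seqs <- character(0)
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    for (i in seq_len(cfg$n_samples)) {
      hap <- list(L = states[[t]]$L, M = states[[t]]$M)
      for (locus in c("L", "M")) {
        n_mut <- rpois(1, L * cfg$theta / 2)
        s <- hap[[locus]]
        br <- paste0("tip:", sp, ":", i, ":", locus)
        if (n_mut > 0) {
          rec_pos <- integer(n_mut); rec_acc <- logical(n_mut)
          for (k in seq_len(n_mut)) {
            pos <- sample.int(L, 1)
            alt <- base_others[[s[pos]]][sample.int(3, 1)]
            s2 <- try_mutation(s, pos, alt)
            rec_pos[k] <- pos
            rec_acc[k] <- !is.null(s2)
            if (!is.null(s2)) s <- s2
          }
          events[[length(events) + 1]] <- data.frame(
            branch = br, type = "mutation", locus = locus,
            start = rec_pos, end = rec_pos, accepted = rec_acc,
            stringsAsFactors = FALSE)
        }
        seqs[[paste(i, sp, "M", locus, sep = "_")]] <- paste(s, collapse = "")
      }
    }
  }

  aln <- as_alignment(seqs)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), type = character(), locus = character(),
               start = integer(), end = integer(), accepted = logical())
  truth <- list(
    species_tree = cfg$species_tree,
    stem_length = cfg$stem_length,
    n_sites = L,
    params = list(theta = cfg$theta, conv_rate = cfg$conv_rate,
                  tract_mean = cfg$tract_mean, p_purge = cfg$p_purge,
                  n_samples = cfg$n_samples, seed = cfg$seed),
    mask = lapply(mask, as.integer),
    events = ev
  )
  list(alignment = aln, truth = truth, config = cfg)
}

#' Write / read the simulator's ground-truth record as JSON
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param path JSON file path.
#' @return `path` invisibly (writer); the truth list (reader).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  y <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyVector = TRUE)
  y$events <- as.data.frame(y$events, stringsAsFactors = FALSE)
  y
}

#' Event log of a truth record as a data frame
#' @param truth A truth record.
#' @return Data frame of events (branch, type, locus, start, end, accepted).
#' @export
truth_events <- function(truth) {
  as.data.frame(truth$events, stringsAsFactors = FALSE)
}
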