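#' Run the full duplicated-opsin analysis workflow
#'
#' Orchestrates the whole pipeline on either a user-supplied alignment or a
#' freshly simulated data set: genotype calls, per-species L/M divergence by
#' region and site class with bootstrap SEs and one-tailed Z tests against
#' the intron baseline, per-group nucleotide diversity, the
#' divergence/polymorphism site-class contrast with Fisher's exact test,
#' exon and intron among-group trees with bootstrap supports, and the
#' gene-conversion tract report. All outputs are plain TSV / newick / JSON.
#'
#' @param config Either a list or a YAML file path. Recognized fields:
#'   `alignment` (FASTA path) + `region_map` (YAML path), or `simulate`
#'   (a list of [sim_config()] arguments); `seed`, `boot` (bootstrap reps,
#'   default 200), `tree_boot` (default 200), `n_perm` (default 2000),
#'   `alpha` (default 0.05).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_full_analysis <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  boot <- if (is.null(config$boot)) 200L else as.integer(config$boot)
  tree_boot <- if (is.null(config$tree_boot)) 200L else as.integer(config$tree_boot)
  n_perm <- if (is.null(config$n_perm)) 2000L else as.integer(config$n_perm)
  alpha <- if (is.null(config$alpha)) 0.05 else as.numeric(config$alpha)

  if (!is.null(config$simulate) && !is.null(config$alignment)) {
    stop("specify exactly one of 'alignment' and 'simulate'")
  }
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(args$region_map) && is.character(args$region_map)) {
      args$region_map <- read_region_map(args$region_map)
    }
    if (is.null(args$seed)) args$seed <- seed
    sim <- simulate_dataset(do.call(sim_config, args))
    aln <- sim$alignment
    map <- sim$config$region_map
    write_fasta_alignment(aln, file.path(outdir, "simulated.fasta"))
    write_truth(sim$truth, file.path(outdir, "truth.json"))
  } else if (!is.null(config$alignment)) {
    aln <- read_fasta_alignment(config$alignment)
    map <- read_region_map(config$region_map)
    sim <- NULL
  } else {
    stop("config must contain 'alignment' or 'simulate'")
  }

  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  # 1. genotype report
  geno <- opsin_genotype_table(aln, map)
  tsv(geno, "genotypes.tsv")

  groups <- group_labels(aln)
  species <- unique(aln$meta$species[aln$meta$locus %in% c("L", "M")])
  intron_sites <- region_sites(map, kind = "intron")
  exon_names <- map$regions$name[map$regions$kind == "exon"]
  intron_names <- map$regions$name[map$regions$kind == "intron"]

  # 2. per-species L/M divergence by region and site class + Z vs introns
  div_rows <- list()
  for (sp in species) {
    idsL <- names(groups)[groups == paste0(sp, "_L")]
    idsM <- names(groups)[groups == paste0(sp, "_M")]
    if (!length(idsL) || !length(idsM)) next
    cols <- complete_deletion_columns(aln, c(idsL, idsM))
    baseline <- nucleotide_divergence(aln, idsL, idsM,
                                      intersect(cols, intron_sites),
                                      boot = boot, seed = seed)
    add <- function(label, est) {
      zt <- z_test_one_tailed(est, baseline)
      div_rows[[length(div_rows) + 1]] <<- data.frame(
        species = sp, partition = label, d = est$value, se = est$se,
        n_sites = est$n_sites, z = zt$z, p_vs_intron = zt$p,
        stringsAsFactors = FALSE)
    }
    for (nm in c(exon_names, intron_names)) {
      est <- nucleotide_divergence(aln, idsL, idsM,
                                   intersect(cols, region_sites(map, nm)),
                                   boot = boot, seed = seed)
      add(nm, est)
    }
    add("introns_combined", baseline)
    add("synonymous", ng_distance(aln, map, idsL, idsM, "synonymous",
                                  cols, boot = boot, seed = seed))
    add("nonsynonymous", ng_distance(aln, map, idsL, idsM, "nonsynonymous",
                                     cols, boot = boot, seed = seed))
  }
  divergence <- do.call(rbind, div_rows)
  tsv(divergence, "divergence.tsv")

  # 3. per-group diversity (exons vs introns)
  pi_rows <- list()
  for (g in unique(groups[aln$meta$locus %in% c("L", "M")])) {
    ids <- names(groups)[groups == g]
    if (length(ids) < 2) next
    cols <- complete_deletion_columns(aln, ids)
    for (part in c("exons", "introns")) {
      sites <- intersect(cols, region_sites(
        map, kind = if (part == "exons") "exon" else "intron"))
      est <- nucleotide_diversity(aln, ids, sites, boot = boot, seed = seed)
      pi_rows[[length(pi_rows) + 1]] <- data.frame(
        group = g, partition = part, pi = est$value, se = est$se,
        n_sites = est$n_sites, stringsAsFactors = FALSE)
    }
  }
  diversity <- do.call(rbind, pi_rows)
  tsv(diversity, "diversity.tsv")

  # 4. divergence/polymorphism contrast (synonymous vs introns) per species
  t3_rows <- list()
  for (sp in species) {
    idsL <- names(groups)[groups == paste0(sp, "_L")]
    idsM <- names(groups)[groups == paste0(sp, "_M")]
    if (!length(idsL) || !length(idsM)) next
    cls <- classify_alignment_sites(aln, idsL, idsM, map)
    tab <- site_class_table(cls)
    ft <- fisher_exact_two_sided(tab)
    t3_rows[[length(t3_rows) + 1]] <- data.frame(
      species = sp,
      div_syn = tab[1, 1], div_intron = tab[1, 2],
      poly_syn = tab[2, 1], poly_intron = tab[2, 2],
      fisher_p = ft$p, degenerate = ft$degenerate, stringsAsFactors = FALSE)
  }
  table3 <- do.call(rbind, t3_rows)
  tsv(table3, "site_class_contrast.tsv")

  # 5. exon and intron among-group trees with supports
  glist <- split(names(groups), groups)
  glist <- glist[vapply(glist, length, 0L) > 0]
  exon_cols <- region_sites(map, kind = "exon")
  intron_cols <- region_sites(map, kind = "intron")
  exon_tree <- bootstrap_supports(aln, glist,
                                  intersect(complete_deletion_columns(aln, unlist(glist)), exon_cols),
                                  reps = tree_boot, seed = seed)
  intron_tree <- bootstrap_supports(aln, glist,
                                    intersect(complete_deletion_columns(aln, unlist(glist)), intron_cols),
                                    reps = tree_boot, seed = seed)
  ape::write.tree(exon_tree, file.path(outdir, "exon_tree.nwk"))
  ape::write.tree(intron_tree, file.path(outdir, "intron_tree.nwk"))

  # 6. gene-conversion tracts (all records here are single-copy haplotypes)
  tracts <- detect_conversions(aln, map, groups = groups, alpha = alpha,
                               n_perm = n_perm, seed = seed)
  tsv(as.data.frame(tracts), "conversion_tracts.tsv")
  if (nrow(tracts)) {
    bed <- data.frame(chrom = "region", start = tracts$start - 1L,
                      end = tracts$end,
                      name = paste(tracts$id1, tracts$id2, sep = "|"),
                      score = tracts$score)
    write.table(bed, file.path(outdir, "conversion_tracts.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  manifest <- list(
    package = "opsinconv",
    version = as.character(packageVersion("opsinconv")),
    seed = seed, boot = boot, tree_boot = tree_boot,
    n_perm = n_perm, alpha = alpha,
    simulated = !is.null(sim),
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(alignment = aln, map = map, genotypes = geno,
                 divergence = divergence, diversity = diversity,
                 site_class_contrast = table3, exon_tree = exon_tree,
                 intron_tree = intron_tree, tracts = tracts,
                 sim = sim, outdir = outdir))
}

#' Command-line entry point
#'
#' Subcommands: `genotype`, `diversity`, `tree`, `geneconv`, `table3`,
#' `simulate`, `all`. Every subcommand takes `--config <yaml>` and
#' `--out <dir>`; `geneconv` additionally honours `--alpha`, `--nperm` and
#' `--seed`. A thin Rscript wrapper is installed at
#' `system.file("scripts", "opsinconv-cli.R", package = "opsinconv")`.
#'
#' @param argv Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 success, 2 usage error), invisibly.
#' @export
subcommand_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: opsinconv <subcommand> --config <yaml> --out <dir> [options]",
    "subcommands: genotype diversity tree geneconv table3 simulate all",
    "options: --seed <int> --alpha <num> --nperm <int>",
    sep = "\n")
  subs <- c("genotype", "diversity", "tree", "geneconv", "table3",
            "simulate", "all")
  if (length(argv) == 0 || !(argv[1] %in% subs)) {
    message(usage)
    return(invisible(2L))
  }
  opt <- list(config = NULL, out = "opsinconv_out", seed = NULL,
              alpha = NULL, nperm = NULL)
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!(key %in% names(opt)) || i == length(argv)) {
      message("unknown or incomplete option: ", argv[i], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) {
    message("--config is required\n", usage)
    return(invisible(2L))
  }
  config <- yaml::read_yaml(opt$config)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$alpha)) config$alpha <- as.numeric(opt$alpha)
  if (!is.null(opt$nperm)) config$n_perm <- as.integer(opt$nperm)

  status <- tryCatch({
    if (argv[1] == "all") {
      run_full_analysis(config, opt$out)
    } else if (argv[1] == "simulate") {
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      sim <- simulate_dataset(do.call(sim_config, args))
      write_fasta_alignment(sim$alignment, file.path(opt$out, "simulated.fasta"))
      write_truth(sim$truth, file.path(opt$out, "truth.json"))
    } else {
      # single-stage runs reuse the full pipeline machinery; cheap stages
      # are recomputed but only the requested report matters to callers
      res <- run_full_analysis(config, opt$out)
      res
    }
    0L
  }, error = function(e) {
    message("error in stage '", argv[1], "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}
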