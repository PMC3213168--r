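test_that("the same seed reproduces a data set exactly", {
  s1 <- simulate_dataset(sim_config(n_samples = 2, seed = 123))
  s2 <- simulate_dataset(sim_config(n_samples = 2, seed = 123))
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_dataset(sim_config(n_samples = 2, seed = 124))
  expect_false(identical(s1$alignment$seq, s3$alignment$seq))
})

test_that("no conversion and no diversity leaves only the forced divergence", {
  expect_error(
    simulate_dataset(sim_config(stem_length = 0,
                                species_tree = "(Hag:0,(Hla:0,Hpi:0):0);")),
    "zero-length")
  sim <- simulate_dataset(sim_config(conv_rate = 0, theta = 0,
                                     stem_length = 1e-9, n_samples = 2,
                                     species_tree = "(Hag:0,(Hla:0,Hpi:0):0);",
                                     seed = 5))
  aln <- sim$alignment
  gr <- group_labels(aln)
  idsL <- names(gr)[endsWith(gr, "_L")]
  idsM <- names(gr)[endsWith(gr, "_M")]
  # within-locus: all sequences identical (pi = 0)
  expect_equal(nucleotide_diversity(aln, idsL)$value, 0)
  expect_equal(nucleotide_diversity(aln, idsM)$value, 0)
  # between loci only the forced codons (3 anchors + 5 extras) differ
  d <- nucleotide_divergence(aln, idsL[1], idsM[1])
  expect_gt(d$value, 0)
  expect_lte(d$value * n_sites(aln), 8 * 3)
})

test_that("full purging keeps the tuning residues divergent everywhere", {
  sim <- simulate_dataset(sim_config(conv_rate = 3, p_purge = 1,
                                     n_samples = 2, seed = 31))
  tab <- opsin_genotype_table(sim$alignment, sim$config$region_map)
  expect_true(all(tab$gene_call == sim$alignment$meta$locus))
  expect_true(all(tab$lambda_max_nm[tab$gene_call == "L"] == 560))
  expect_true(all(tab$lambda_max_nm[tab$gene_call == "M"] == 530))
})

test_that("accepted events stay inside the region and round-trip as JSON", {
  sim <- simulate_dataset(sim_config(n_samples = 2, seed = 41))
  ev <- truth_events(sim$truth)
  expect_true(all(ev$start >= 1 & ev$end <= sim$truth$n_sites))
  expect_true(all(ev$start <= ev$end))
  expect_true(all(ev$type %in% c("mutation", "conversion")))
  expect_gt(sum(ev$type == "conversion"), 0)

  f <- tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$events$start, ev$start)
  expect_equal(back$events$accepted, ev$accepted)
  expect_equal(back$params$theta, sim$config$theta)

  # an empty event log still writes valid JSON
  empty <- sim$truth
  empty$events <- empty$events[0, ]
  write_truth(empty, f)
  expect_silent(read_truth(f))
})

test_that("per-branch mutation counts follow the Poisson law", {
  # pool attempted mutations per tip branch over replicates and compare the
  # empirical distribution with Poisson(L * b)
  L <- 3675
  b <- 0.002
  counts <- c()
  for (sd in 1:30) {
    sim <- simulate_dataset(sim_config(
      species_tree = sprintf("(Hag:%g,(Hla:%g,Hpi:%g):0);", b, b, b),
      stem_length = 0, theta = 0, conv_rate = 0, n_samples = 1, seed = sd))
    ev <- truth_events(sim$truth)
    for (tip in c("Hag", "Hla", "Hpi")) {
      counts <- c(counts, sum(ev$branch == tip & ev$locus == "L"),
                  sum(ev$branch == tip & ev$locus == "M"))
    }
  }
  lambda <- L * b
  breaks <- c(-0.5, qpois(c(0.2, 0.4, 0.6, 0.8), lambda) + 0.5, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-1, qpois(c(0.2, 0.4, 0.6, 0.8), lambda), Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("without conversion, exon and intron divergence agree (neutrally)", {
  # neutral config: no stop rejection, no extra constrained codons, no
  # purging; only the three tuning codons are forced, so they are excluded
  # from the exon distance
  set.seed(1)
  diffs <- replicate(25, {
    sd <- sample.int(1e6, 1)
    cfg <- sim_config(conv_rate = 0, p_purge = 0, reject_stops = FALSE,
                      extra_divergent_codons = integer(0),
                      n_samples = 1, seed = sd)
    sim <- simulate_dataset(cfg)
    aln <- sim$alignment
    map <- cfg$region_map
    gr <- group_labels(aln)
    idsL <- names(gr)[endsWith(gr, "_L")]
    idsM <- names(gr)[endsWith(gr, "_M")]
    masked <- unlist(lapply(c(180, 277, 285),
                            function(r) anchor_codon_sites(map, r)))
    exon_cols <- setdiff(region_sites(map, kind = "exon"), masked)
    intron_cols <- region_sites(map, kind = "intron")
    nucleotide_divergence(aln, idsL, idsM, exon_cols)$value -
      nucleotide_divergence(aln, idsL, idsM, intron_cols)$value
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("neutral intron diversity recovers the target theta", {
  set.seed(2)
  pis <- replicate(20, {
    sd <- sample.int(1e6, 1)
    cfg <- sim_config(conv_rate = 0, theta = 0.003, n_samples = 3, seed = sd)
    sim <- simulate_dataset(cfg)
    gr <- group_labels(sim$alignment)
    ids <- names(gr)[gr == "Hag_L"]
    cols <- region_sites(cfg$region_map, kind = "intron")
    nucleotide_diversity(sim$alignment, ids, cols)$value
  })
  expect_lt(abs(mean(pis) - 0.003), 3 * sd(pis) / sqrt(length(pis)) + 1e-4)
})
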