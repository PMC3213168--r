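test_that("site classification separates fixed, polymorphic and invariant", {
  map <- tiny_map()
  # exonA codons 1-4 (sites 1-12), intronA sites 13-24
  aln <- aln_from(
    L1 = "TTTGATAAACCCAAAAAAAAAAAA",
    L2 = "TTTGATAAACCCAAAAAAAAAAAA",
    M1 = "TTCGATAAACCCGAAAAAAAAAAC",
    M2 = "TTCGATAAACCCGAAAAAAAAAAA"
  )
  cls <- classify_alignment_sites(aln, c("L1", "L2"), c("M1", "M2"), map)
  expect_equal(nrow(cls), 24)
  # totals partition the retained sites exactly
  expect_equal(sum(cls$status %in% c("fixed", "polymorphic", "invariant")), 24)

  # site 3: TTT vs TTC, both groups monomorphic -> fixed synonymous
  expect_equal(cls$status[3], "fixed")
  expect_equal(cls$site_class[3], "synonymous")
  # site 13: L all A, M all G -> fixed intron difference
  expect_equal(cls$status[13], "fixed")
  expect_equal(cls$site_class[13], "intron")
  # site 24: M segregates A/C -> polymorphic, not fixed
  expect_equal(cls$status[24], "polymorphic")

  tab <- site_class_table(cls)
  expect_equal(tab["divergence", "synonymous"], 1)
  expect_equal(tab["divergence", "intron"], 1)
  expect_equal(tab["polymorphism", "intron"], 1)
})

test_that("a site segregating within a group is never counted as fixed", {
  map <- tiny_map()
  aln <- aln_from(
    L1 = paste0(strrep("A", 12), "GAAAAAAAAAAA"),
    L2 = paste0(strrep("A", 12), "AAAAAAAAAAAA"),
    M1 = paste0(strrep("A", 12), "AAAAAAAAAAAA"),
    M2 = paste0(strrep("A", 12), "AAAAAAAAAAAA")
  )
  cls <- classify_alignment_sites(aln, c("L1", "L2"), c("M1", "M2"), map)
  expect_equal(cls$status[13], "polymorphic")
  expect_equal(sum(cls$status == "fixed"), 0)
})

test_that("two-sided Fisher P reproduces the printed species contrasts", {
  # the three tables whose printed P values are exactly reproducible
  expect_equal(signif(fisher_exact_two_sided(rbind(c(8, 13), c(1, 41)))$p, 2),
               3.7e-4)
  expect_equal(signif(fisher_exact_two_sided(rbind(c(9, 27), c(0, 21)))$p, 2),
               1.9e-2)
  expect_equal(signif(fisher_exact_two_sided(rbind(c(9, 4), c(1, 26)))$p, 2),
               2.3e-5)
  expect_equal(fisher_exact_two_sided(rbind(c(1, 1), c(1, 1)))$p, 1)

  zm <- fisher_exact_two_sided(rbind(c(0, 0), c(3, 4)))
  expect_true(zm$degenerate)
  expect_equal(zm$p, 1)
})

test_that("Fisher P equals brute-force minimum-likelihood enumeration", {
  set.seed(2)
  for (r in 1:30) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab)$p, fisher_bruteforce(tab),
                 tolerance = 1e-9)
  }
})

test_that("McDonald-Kreitman builds its table from site classification", {
  map <- tiny_map()
  # species A vs species B, one gene: one fixed synonymous difference
  # (TTT/TTC), one fixed nonsynonymous (GAT/GAA), one synonymous polymorphism
  # in B (CCC/CCA at codon 4)
  aln <- aln_from(
    A1 = "TTTGATAAACCCAAAAAAAAAAAA",
    A2 = "TTTGATAAACCCAAAAAAAAAAAA",
    B1 = "TTCGAAAAACCCAAAAAAAAAAAA",
    B2 = "TTCGAAAAACCAAAAAAAAAAAAA"
  )
  mk <- mcdonald_kreitman(aln, c("A1", "A2"), c("B1", "B2"), map)
  expect_equal(mk$table["divergence", "synonymous"], 1)
  expect_equal(mk$table["divergence", "nonsynonymous"], 1)
  expect_equal(mk$table["polymorphism", "synonymous"], 1)
  expect_equal(mk$table["polymorphism", "nonsynonymous"], 0)
  expect_equal(mk$p,
               fisher_exact_two_sided(mk$table)$p)
  # a balanced table carries no signal
  expect_equal(fisher_exact_two_sided(rbind(c(2, 2), c(2, 2)))$p, 1)
})

test_that("HKA fits perfectly proportional loci and flags 10x divergence", {
  perfect <- hka_test(S1 = 20, D1 = 40, n1 = 10, L1 = 1000,
                      S2 = 10, D2 = 20, n2 = 10, L2 = 500)
  expect_lt(perfect$chisq, 1e-10)
  expect_equal(perfect$p, 1, tolerance = 1e-8)

  excess <- hka_test(S1 = 20, D1 = 400, n1 = 10, L1 = 1000,
                     S2 = 20, D2 = 40, n2 = 10, L2 = 1000)
  expect_lt(excess$p, 0.05)
  expect_error(hka_test(0, 0, 10, 100, 0, 0, 10, 100), "degenerate")
})

test_that("HKA rejection rate under a neutral coalescent is near nominal", {
  # simulate the two-locus neutral model the test assumes: S_j from a
  # coalescent tree's total length, D_j from 2T + ancestral coalescence
  sim_locus <- function(theta, n, T) {
    tt <- sum((2:n) * rexp(n - 1, rate = choose(2:n, 2)))
    S <- rpois(1, theta / 2 * tt)
    D <- rpois(1, theta * (T + rexp(1)))
    c(S = S, D = D)
  }
  set.seed(77)
  reps <- 300
  rej <- 0
  used <- 0
  for (r in seq_len(reps)) {
    l1 <- sim_locus(12, 8, 5)
    l2 <- sim_locus(8, 8, 5)
    out <- try(hka_test(l1["S"], l1["D"], 8, 1000, l2["S"], l2["D"], 8, 700),
               silent = TRUE)
    if (inherits(out, "try-error")) next
    used <- used + 1
    rej <- rej + (out$p < 0.05)
  }
  expect_gt(used, reps * 0.9)
  expect_lt(rej / used, 0.10)
})

test_that("D' matches direct haplotype-table computation", {
  # perfectly associated alleles
  h1 <- rbind(c("A", "G"), c("A", "G"), c("C", "T"), c("C", "T"))
  expect_equal(d_prime(h1, 1, 2), 1)

  # independent alleles at frequency 1/2 with equal haplotype counts
  h2 <- rbind(c("A", "G"), c("A", "T"), c("C", "G"), c("C", "T"))
  expect_equal(d_prime(h2, 1, 2), 0)

  # {AB x4, aB x1, ab x5}: D = 0.4 - 0.4*0.5 = 0.2 = Dmax -> D' = 1
  h3 <- rbind(matrix(rep(c("A", "B"), 4), ncol = 2, byrow = TRUE),
              c("C", "B"),
              matrix(rep(c("C", "D"), 5), ncol = 2, byrow = TRUE))
  expect_equal(d_prime(h3, 1, 2), 1)

  expect_warning(nd <- d_prime(rbind(c("A", "G"), c("A", "T")), 1, 2),
                 "biallelic")
  expect_true(is.na(nd))
})

test_that("the D' matrix covers exactly the biallelic sites", {
  aln <- aln_from(h1 = "AAGT", h2 = "ACGT", h3 = "CCGA", h4 = "CAGA")
  dm <- d_prime_matrix(aln)
  expect_equal(dm$sites, c(1, 2, 4))
  expect_true(isSymmetric(dm$dprime))
  expect_equal(unname(dm$dprime["1", "4"]), 1)  # sites 1 and 4 perfectly linked
})
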