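test_that("profiles keep polymorphic, gap-free columns with original indices", {
  aln <- aln_from(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(length(build_profile(aln)$site_indices), 0)

  # polymorphic at sites 2, 5, 9; gap column 7 excluded even though variable
  aln2 <- aln_from(a = "AAAAAAAAAA",
                   b = "ACAACAAAGA",
                   c = "ACAACA-AGA")
  pr <- build_profile(aln2)
  expect_equal(pr$site_indices, c(2, 5, 9))
  expect_equal(rownames(pr$mat), c("a", "b", "c"))
})

test_that("fragments decompose agreement runs and back-map coordinates", {
  # 20 polymorphic columns, pair fully identical: one fragment of score 20
  m <- rbind(a = rep("A", 20), b = rep("A", 20), c = rep("C", 20))
  pr <- structure(list(site_indices = seq(5, 100, by = 5), mat = m),
                  class = "poly_profile")
  fr <- pairwise_fragments(pr, "a", "b")
  expect_equal(nrow(fr), 1)
  expect_equal(fr$score, 20)
  expect_equal(c(fr$start, fr$end), c(5, 100))

  # agreement pattern 1,1,1,0,1,1: runs of 3 and 2
  m2 <- rbind(a = c("A", "A", "A", "A", "A", "A"),
              b = c("A", "A", "A", "C", "A", "A"),
              c = rep("G", 6))
  pr2 <- structure(list(site_indices = c(10, 20, 30, 40, 50, 60), mat = m2),
                   class = "poly_profile")
  fr2 <- pairwise_fragments(pr2, "a", "b")
  expect_equal(fr2$score, c(3, 2))
  expect_equal(fr2$start, c(10, 50))
  expect_equal(fr2$end, c(30, 60))

  # with mismatch penalty 1 the two runs merge: 3 + 2 - 1 = 4
  fr3 <- pairwise_fragments(pr2, "a", "b", penalty = 1)
  expect_equal(fr3$score, 4)
  expect_equal(c(fr3$start, fr3$end), c(10, 60))

  expect_error(pairwise_fragments(pr2, "a", "zz"), "unknown record")
})

test_that("run decomposition partitions the agreeing sites", {
  set.seed(5)
  for (r in 1:10) {
    agree <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    m <- rbind(a = rep("A", 40), b = ifelse(agree, "A", "C"))
    pr <- structure(list(site_indices = 1:40, mat = m),
                    class = "poly_profile")
    fr <- pairwise_fragments(pr, "a", "b")
    covered <- unlist(mapply(seq, fr$start, fr$end, SIMPLIFY = FALSE))
    expect_setequal(covered[agree[covered]], which(agree))
    expect_equal(sum(fr$score), sum(agree))
  }
})

test_that("maximal-scoring segments match brute force under a penalty", {
  brute_max <- function(sc) {
    best <- 0
    for (i in seq_along(sc)) for (j in i:length(sc)) {
      best <- max(best, sum(sc[i:j]))
    }
    best
  }
  set.seed(8)
  for (r in 1:15) {
    agree <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    g <- sample(c(0.5, 1, 2), 1)
    m <- rbind(a = rep("A", 25), b = ifelse(agree, "A", "C"))
    pr <- structure(list(site_indices = 1:25, mat = m),
                    class = "poly_profile")
    fr <- pairwise_fragments(pr, "a", "b", penalty = g)
    sc <- ifelse(agree, 1, -g)
    if (nrow(fr) > 0) {
      expect_equal(max(fr$score), brute_max(sc))
      # segments are disjoint
      ord <- order(fr$start)
      if (nrow(fr) > 1) {
        expect_true(all(fr$start[ord][-1] > fr$end[ord][-nrow(fr)]))
      }
    } else {
      expect_equal(brute_max(sc), 0)
    }
  }
})

test_that("global permutation P-values behave and reproduce under a seed", {
  set.seed(31)
  mat <- rbind(a = sample(c("A", "C"), 40, TRUE),
               b = sample(c("A", "C"), 40, TRUE),
               c = sample(c("A", "C"), 40, TRUE))
  pr <- structure(list(site_indices = 1:40, mat = mat),
                  class = "poly_profile")
  r1 <- global_permutation_test(pr, n_perm = 300, seed = 4)
  r2 <- global_permutation_test(pr, n_perm = 300, seed = 4)
  expect_identical(r1$fragments$global_sim_p, r2$fragments$global_sim_p)
  expect_true(all(r1$fragments$global_sim_p > 0 &
                  r1$fragments$global_sim_p <= 1))
  # within a pair, a longer run never has a larger P
  fr <- r1$fragments[r1$fragments$id1 == "a" & r1$fragments$id2 == "b", ]
  ord <- order(fr$score)
  expect_true(all(diff(fr$global_sim_p[ord]) <= 0))
})

test_that("fragment scores are invariant to site-order reversal", {
  set.seed(13)
  mat <- rbind(a = sample(c("A", "C"), 30, TRUE),
               b = sample(c("A", "C"), 30, TRUE),
               c = sample(c("A", "C"), 30, TRUE))
  pr <- structure(list(site_indices = 1:30, mat = mat),
                  class = "poly_profile")
  prR <- structure(list(site_indices = 1:30, mat = mat[, 30:1]),
                   class = "poly_profile")
  f1 <- opsinconv:::all_pair_fragments(pr)
  f2 <- opsinconv:::all_pair_fragments(prR)
  expect_equal(sort(f1$score), sort(f2$score))
  # null distribution is the same in law: compare extreme quantiles loosely
  n1 <- global_permutation_test(pr, n_perm = 400, seed = 2)$null_max
  n2 <- global_permutation_test(prR, n_perm = 400, seed = 3)$null_max
  expect_lt(abs(quantile(n1, 0.9) - quantile(n2, 0.9)) /
              max(quantile(n1, 0.9), 1), 0.25)
})

test_that("permutation P matches exhaustive enumeration on a tiny profile", {
  set.seed(17)
  mat <- rbind(a = c("A", "A", "C", "A", "A", "C"),
               b = c("A", "A", "A", "A", "C", "C"),
               c = c("C", "A", "A", "C", "A", "A"))
  pr <- structure(list(site_indices = 1:6, mat = mat),
                  class = "poly_profile")
  ids <- rownames(mat)
  prs <- combn(3, 2)
  agree <- t(apply(prs, 2, function(p) mat[p[1], ] == mat[p[2], ]))
  mism <- 1 - rowMeans(agree)
  w <- ifelse(mism >= 1, 0, -log1p(-mism))
  max_run <- function(x) {
    r <- rle(x)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0
  }
  # exact null over all 720 column orders
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 6), ]
  exact_max <- apply(perms, 1, function(ord) {
    max(vapply(1:3, function(k) max_run(agree[k, ord]) * w[k], 0))
  })
  res <- global_permutation_test(pr, n_perm = 4000, seed = 9)
  fr <- res$fragments
  for (i in seq_len(nrow(fr))) {
    exact_p <- mean(exact_max >= fr$weighted_score[i] - 1e-9)
    expect_lt(abs(fr$global_sim_p[i] - exact_p), 0.05)
  }
})

test_that("a planted identical tract in a divergent pair is detected", {
  set.seed(23)
  n <- 60
  s1 <- rep("A", n)
  s2 <- ifelse(seq_len(n) %in% 10:49, "A", "C")  # 40-site identical tract
  s3 <- sample(c("A", "C", "G", "T"), n, TRUE)
  s4 <- sample(c("A", "C", "G", "T"), n, TRUE)
  aln <- as_alignment(c(x1 = paste(s1, collapse = ""),
                        x2 = paste(s2, collapse = ""),
                        x3 = paste(s3, collapse = ""),
                        x4 = paste(s4, collapse = "")))
  pr <- build_profile(aln)
  res <- global_permutation_test(pr, n_perm = 2000, seed = 5)
  fr <- res$fragments
  hit <- fr[fr$id1 == "x1" & fr$id2 == "x2" & fr$score >= 30, ]
  expect_gte(nrow(hit), 1)
  expect_lt(min(hit$global_sim_p), 0.05)
})

test_that("detected tracts carry region composition and honour alpha", {
  sim <- simulate_dataset(sim_config(n_samples = 3, seed = 700))
  aln <- sim$alignment
  map <- sim$config$region_map
  all_fr <- detect_conversions(aln, map, alpha = 1.0, n_perm = 150, seed = 1)
  some_fr <- detect_conversions(aln, map, alpha = 0.05, n_perm = 150, seed = 1)
  expect_gte(nrow(all_fr), nrow(some_fr))
  expect_equal(nrow(all_fr), nrow(attr(all_fr, "all_fragments")))
  if (nrow(some_fr)) {
    expect_true(all(some_fr$global_sim_p < 0.05))
    expect_true(all(some_fr$intron_fraction >= 0 & some_fr$intron_fraction <= 1))
    # spot-check one annotation against the map
    i <- 1
    len <- some_fr$end[i] - some_fr$start[i] + 1
    ov <- pmax(0, pmin(map$regions$end, some_fr$end[i]) -
                  pmax(map$regions$start, some_fr$start[i]) + 1)
    expect_equal(some_fr$intron_fraction[i],
                 sum(ov[map$regions$kind == "intron"]) / len,
                 tolerance = 1e-6)
  }
})
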