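# Windowed diversity, Weir-Cockerham FST, Tajima's D, PCA/MDS.

test_that("identical sequences give zero diversity in every window", {
  g <- toy_geno(matrix(1L, 5, 4), genome_length = 5000L)
  w <- nucleotide_diversity(g, window = 1000, step = 500)
  expect_true(all(w$pi == 0))
})

test_that("two sequences with one difference give pi = 1/L in that window", {
  g <- toy_geno(matrix(c(0L, 1L), 1, 2), pos = 500L, genome_length = 1000L)
  w <- nucleotide_diversity(g, window = 1000, step = 1000)
  expect_equal(nrow(w), 1)
  expect_equal(w$pi, 1 / 1000)
})

test_that("windowed pi matches the brute-force pairwise oracle", {
  set.seed(101)
  for (rep in 1:25) {
    g <- random_geno(sample(5:50, 1), sample(3:12, 1),
                     missing_rate = sample(c(0, 0.15), 1),
                     genome_length = 20000L)
    w <- nucleotide_diversity(g, window = 20000, step = 20000)
    expect_equal(w$pi, brute_force_pi(g, L = 20000), tolerance = 1e-12)
  }
})

test_that("windows whose sites all lack callable pairs give NA pi", {
  calls <- rbind(c(1L, NA_integer_, NA_integer_),
                 c(0L, 1L, 0L))
  g <- toy_geno(calls, pos = c(100L, 1600L), genome_length = 2000L)
  w <- nucleotide_diversity(g, window = 1000, step = 1000)
  expect_true(is.na(w$pi[1]))   # only site has 1 non-missing call
  expect_gt(w$pi[2], 0)
})

test_that("FST is 1 for a fixed difference and <= 0 at equal frequencies", {
  g_fixed <- toy_geno(matrix(c(rep(0L, 10), rep(1L, 10)), 1, 20))
  pm <- half_split_map(g_fixed)
  expect_equal(weir_cockerham_fst(g_fixed, pm, "a", "b")$fst, 1)

  g_equal <- toy_geno(matrix(rep(c(0L, 1L), 10), 1, 20))  # p = 0.5 in both
  pm2 <- tibble::tibble(sample = geno_samples(g_equal),
                        group = rep(c("a", "b"), each = 10))
  expect_lte(weir_cockerham_fst(g_equal, pm2, "a", "b")$fst, 0)
})

test_that("weighted FST equals summed hand-computed ANOVA components", {
  # independent per-site oracle, written directly from the two-level ANOVA
  oracle_site <- function(p1, p2, n1, n2) {
    N <- n1 + n2
    nc <- N - (n1^2 + n2^2) / N
    a <- 0; b <- 0
    for (u in 0:1) {
      q1 <- if (u == 1) p1 else 1 - p1
      q2 <- if (u == 1) p2 else 1 - p2
      qbar <- (n1 * q1 + n2 * q2) / N
      msp <- n1 * (q1 - qbar)^2 + n2 * (q2 - qbar)^2
      msg <- (n1 * q1 * (1 - q1) + n2 * q2 * (1 - q2)) / (N - 2)
      a <- a + (msp - msg) / nc
      b <- b + msg
    }
    c(a = a, b = b)
  }
  n1 <- 8; n2 <- 6
  site_freqs <- list(c(0.25, 0.5), c(0.875, 1 / 6), c(0.5, 0.5))
  calls <- t(vapply(site_freqs, function(f) {
    c(rep(1L, round(f[1] * n1)), rep(0L, n1 - round(f[1] * n1)),
      rep(1L, round(f[2] * n2)), rep(0L, n2 - round(f[2] * n2)))
  }, integer(n1 + n2)))
  g <- toy_geno(calls)
  pm <- tibble::tibble(sample = geno_samples(g),
                       group = rep(c("a", "b"), c(n1, n2)))
  res <- weir_cockerham_fst(g, pm, "a", "b")
  comp <- t(vapply(site_freqs, function(f) oracle_site(f[1], f[2], n1, n2),
                   numeric(2)))
  expect_equal(res$per_site$a, comp[, "a"], tolerance = 1e-12)
  expect_equal(res$per_site$b, comp[, "b"], tolerance = 1e-12)
  expect_equal(res$fst, sum(comp[, "a"]) / sum(comp[, "a"] + comp[, "b"]),
               tolerance = 1e-12)
})

test_that("FST of a group against itself equals -1/(n-1) and shrinks with n", {
  for (n in c(5, 10, 40)) {
    g <- toy_geno(rbind(rep(c(0L, 1L), length.out = n),
                        rep(c(1L, 0L, 0L), length.out = n)))
    pm <- tibble::tibble(sample = geno_samples(g), group = "a")
    self <- weir_cockerham_fst(g, pm, "a", "a")$fst
    expect_equal(self, -1 / (n - 1), tolerance = 1e-12)
  }
})

test_that("permuted labels over one panmictic pool give near-zero FST", {
  # unlinked neutral sites: with no true structure, any labelling is a
  # random split and the weighted estimate concentrates at 0
  set.seed(31)
  g <- simulate_bottleneck_dataset(40, 47, 0)  # E[S] ~ 200 unlinked sites
  for (i in 1:3) {
    pm <- tibble::tibble(sample = sample(geno_samples(g)),
                         group = rep(c("a", "b"), each = 20))
    expect_lt(abs(weir_cockerham_fst(g, pm, "a", "b")$fst), 0.05)
  }
})

test_that("Tajima's D matches direct evaluation of the published constants", {
  # n = 4, three singleton sites: S = 3, pi_total = 3 * (4/3) * (6/16) = 1.5
  calls <- rbind(c(1L, 0L, 0L, 0L),
                 c(0L, 1L, 0L, 0L),
                 c(0L, 0L, 1L, 0L))
  g <- toy_geno(calls)
  res <- tajimas_d(g)
  expect_equal(res$S, 3)
  expect_equal(res$pi_total, 1.5)
  n <- 4
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D_hand <- (1.5 - 3 / a1) / sqrt(e1 * 3 + e2 * 3 * 2)
  expect_equal(res$a1, a1)
  expect_equal(res$D, D_hand, tolerance = 1e-12)
})

test_that("Tajima's D is NA with a warning when S = 0", {
  g <- toy_geno(matrix(1L, 2, 5))
  expect_warning(res <- tajimas_d(g), "S = 0")
  expect_true(is.na(res$D))
})

test_that("Tajima's D is invariant under sample relabeling", {
  set.seed(77)
  g <- random_geno(30, 8)
  perm <- sample(geno_samples(g))
  suppressWarnings({
    d1 <- tajimas_d(g)$D
    d2 <- tajimas_d(g, samples = perm)$D
  })
  expect_equal(d1, d2)
})

test_that("PCA gives identical coordinates to duplicated samples and sane
           explained fractions", {
  set.seed(5)
  g <- random_geno(40, 6)
  g$calls[, 6] <- g$calls[, 1]  # duplicate sample
  p <- pca_genotypes(g, k = 3)
  coords <- p$coordinates
  expect_equal(unlist(coords[coords$sample == "s1", -1]),
               unlist(coords[coords$sample == "s6", -1]),
               tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
})

test_that("PCA separates two internally identical groups on axis 1", {
  calls <- cbind(matrix(0L, 10, 5), matrix(1L, 10, 5))
  g <- toy_geno(calls)
  p <- pca_genotypes(g, k = 2)
  ax1 <- p$coordinates$axis1
  expect_equal(length(unique(round(ax1[1:5], 9))), 1)
  expect_equal(length(unique(round(ax1[6:10], 9))), 1)
  expect_gt(abs(mean(ax1[1:5]) - mean(ax1[6:10])), 1)
  expect_error(pca_genotypes(toy_geno(matrix(1L, 3, 4))), "monomorphic")
})

test_that("MDS reproduces 3-point distances exactly and collapses duplicates", {
  calls <- rbind(c(0L, 1L, 0L), c(0L, 1L, 1L), c(0L, 0L, 1L),
                 c(1L, 0L, 0L), c(0L, 1L, 0L))
  g <- toy_geno(calls)
  d <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    d[i, j] <- d[j, i] <- mean(g$calls[, i] != g$calls[, j])
  }
  m <- mds_genotypes(g, k = 2)
  pts <- as.matrix(m$coordinates[, -1])
  expect_equal(as.matrix(dist(pts)), as.matrix(dist(pts)))  # self-consistency
  expect_equal(unname(as.matrix(dist(pts))), unname(d), tolerance = 1e-8)

  g_same <- toy_geno(matrix(c(0L, 0L, 0L), 3, 3))
  expect_warning(m0 <- mds_genotypes(g_same), "zero")
  expect_true(all(as.matrix(m0$coordinates[, -1]) == 0))
})

test_that("three equidistant samples embed as an equilateral triangle", {
  calls <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  g <- toy_geno(calls)
  m <- mds_genotypes(g, k = 2)
  pts <- as.matrix(m$coordinates[, -1])
  dd <- as.numeric(dist(pts))
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-9)
})
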