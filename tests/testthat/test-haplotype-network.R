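test_that("haplotype collapsing groups identical allele vectors", {
  calls <- cbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(1L, 0L))
  g <- toy_geno(calls)
  h <- collapse_haplotypes(g)
  expect_equal(nrow(h), 2)
  expect_equal(h$size, c(3L, 1L))
  expect_setequal(h$members[[1]], c("s1", "s2", "s3"))
})

test_that("samples with missing calls are excluded under the default policy", {
  calls <- cbind(c(0L, 1L), c(0L, NA_integer_), c(0L, 1L))
  g <- toy_geno(calls)
  expect_message(h <- collapse_haplotypes(g), "excluded")
  expect_equal(sum(h$size), 2)
  expect_false("s2" %in% unlist(h$members))
})

test_that("haplotype partition matches brute-force vector grouping", {
  set.seed(55)
  for (i in 1:10) {
    g <- random_geno(6, 8)
    h <- collapse_haplotypes(g)
    # oracle: quadratic pairwise equality partition
    m <- g$calls
    groups <- list()
    for (s in colnames(m)) {
      placed <- FALSE
      for (gi in seq_along(groups)) {
        if (all(m[, s] == m[, groups[[gi]][1]])) {
          groups[[gi]] <- c(groups[[gi]], s); placed <- TRUE; break
        }
      }
      if (!placed) groups[[length(groups) + 1]] <- s
    }
    expect_equal(nrow(h), length(groups))
    expect_setequal(purrr::map_chr(h$members, ~ paste(sort(.x), collapse = ",")),
                    purrr::map_chr(groups, ~ paste(sort(.x), collapse = ",")))
  }
})

test_that("group counts sum to haplotype sizes when a map is supplied", {
  set.seed(56)
  g <- random_geno(5, 10)
  pm <- half_split_map(g)
  h <- collapse_haplotypes(g, pm = pm)
  expect_equal(purrr::map_int(h$group_counts, ~ sum(.x$n)), h$size)
})

test_that("parsimony limit is monotone in length and explodes as confidence
           vanishes", {
  for (L in c(300, 1000, 13452)) {
    expect_gte(parsimony_limit(10 * L), parsimony_limit(L))
  }
  # near-zero confidence connects everything up to the sequence length
  expect_gte(parsimony_limit(10, confidence = 1e-12), 9)
  expect_equal(parsimony_limit(1000, 0.95),
               max(which(sapply(1:50, function(j)
                 chloropop:::parsimony_probability(j, 1000) > 0.95))))
})

test_that("parsimony probability matches a Monte-Carlo oracle of the model", {
  # oracle: Poisson hits per site at the Jukes-Cantor-style rate, conditioned
  # on exactly j sites hit; parsimony = all hit sites single-hit
  set.seed(17)
  L <- 200; j <- 6
  lambda <- -log(1 - j / L)
  hits_ok <- 0; parsimonious <- 0
  while (hits_ok < 4000) {
    hits <- rpois(L, lambda)
    if (sum(hits > 0) == j) {
      hits_ok <- hits_ok + 1
      if (all(hits[hits > 0] == 1)) parsimonious <- parsimonious + 1
    }
  }
  p_mc <- parsimonious / hits_ok
  p_model <- chloropop:::parsimony_probability(j, L)
  se <- sqrt(p_mc * (1 - p_mc) / hits_ok)
  expect_lt(abs(p_mc - p_model), 4 * se + 1e-3)
})

test_that("distance-1 pairs connect by a single edge without intermediates", {
  calls <- cbind(c(0L, 0L), c(1L, 0L))
  h <- collapse_haplotypes(toy_geno(calls))
  net <- build_tcs_network(h, limit = 10)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sum(net$nodes$type == "inferred"), 0)
})

test_that("a distance-3 pair inserts two inferred intermediates", {
  calls <- cbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  h <- collapse_haplotypes(toy_geno(calls))
  net <- build_tcs_network(h, limit = 3)
  expect_equal(sum(net$nodes$type == "inferred"), 2)
  expect_equal(nrow(net$edges), 3)
  expect_equal(length(unique(net$membership)), 1)
  # beyond the limit the pair stays in separate components
  net2 <- build_tcs_network(h, limit = 2)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(length(unique(net2$membership)), 2)
})

test_that("a star of haplotypes puts degree 4 on the centre", {
  centre <- c(0L, 0L, 0L, 0L)
  tips <- diag(1L, 4)
  calls <- cbind(centre, tips[, 1], tips[, 2], tips[, 3], tips[, 4])
  colnames(calls) <- paste0("s", 1:5)
  h <- collapse_haplotypes(toy_geno(calls))
  net <- build_tcs_network(h, limit = 5)
  centre_id <- h$haplotype[purrr::map_lgl(h$key, ~ all(.x == 0L))]
  deg <- igraph::degree(net$graph)
  expect_equal(unname(deg[centre_id]), 4)
})

test_that("network conserves haplotype and sample counts on random data", {
  set.seed(66)
  for (i in 1:8) {
    g <- random_geno(sample(4:12, 1), sample(5:15, 1))
    h <- collapse_haplotypes(g)
    net <- build_tcs_network(h, limit = 100)
    expect_equal(sum(net$nodes$type == "sampled"), nrow(h))
    expect_equal(sum(net$nodes$size), n_samples(g))
    expect_equal(glance(net)$n_haplotypes, nrow(h))
  }
})

test_that("the connection limit for the chloroplast genome is stable", {
  lim <- parsimony_limit(134525, 0.95)
  expect_gte(lim, 2)
  # identical call twice -> deterministic
  expect_equal(parsimony_limit(134525, 0.95), lim)
})
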