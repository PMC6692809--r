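#' Neutral infinite-sites coalescent sample
#'
#' Simulates a Kingman genealogy for `n` haploid sequences (exponential
#' coalescence times at rate `j(j-1)/2`), drops mutations on branches as a
#' Poisson process at rate `theta/2` per unit branch length, and places
#' each mutation at its own site (infinite sites). Sites are mapped to
#' unique integer coordinates drawn uniformly over the genome so windowed
#' statistics see realistic positions.
#'
#' @param n Number of sequences (>= 2).
#' @param theta Scaled mutation rate (> 0).
#' @param seed Optional integer seed.
#' @param genome_length Genome span for site placement (default 134525).
#' @param sample_prefix Prefix for generated sample ids.
#' @return A list of class `coalescent_sample`: `geno` (a [geno_matrix()]
#'   with 0/1 calls), `S` (segregating sites), `tree_length` (total branch
#'   length), `n`, `theta`.
#' @export
simulate_coalescent <- function(n, theta, seed = NULL,
                                genome_length = 134525L,
                                sample_prefix = "s") {
  stopifnot(n >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  branches <- kingman_branches(n)
  total_len <- sum(branches$length)
  n_mut <- stats::rpois(1, theta / 2 * total_len)
  samples <- paste0(sample_prefix, seq_len(n))
  if (n_mut == 0) {
    calls <- matrix(integer(0), nrow = 0, ncol = n,
                    dimnames = list(NULL, samples))
    sites <- tibble::tibble(pos = integer(0), ref = character(0),
                            alts = list())
  } else {
    which_branch <- sample.int(nrow(branches), n_mut, replace = TRUE,
                               prob = branches$length)
    pos <- sort(sample.int(genome_length, n_mut, replace = FALSE))
    calls <- matrix(0L, nrow = n_mut, ncol = n,
                    dimnames = list(NULL, samples))
    for (i in seq_len(n_mut)) {
      calls[i, branches$tips[[which_branch[i]]]] <- 1L
    }
    alleles <- draw_site_alleles(n_mut)
    sites <- tibble::tibble(pos = pos, ref = alleles$ref, alts = alleles$alts)
  }
  structure(
    list(geno = geno_matrix(sites, calls, genome_length = genome_length),
         S = n_mut, tree_length = total_len, n = n, theta = theta),
    class = "coalescent_sample"
  )
}

# internal: branches of a Kingman genealogy as (tip set, length) records
kingman_branches <- function(n) {
  tips <- as.list(seq_len(n))
  lens <- numeric(n)
  branches_tips <- list()
  branches_len <- numeric(0)
  k <- n
  while (k > 1) {
    t <- stats::rexp(1, k * (k - 1) / 2)
    lens <- lens + t
    pr <- sort(sample.int(k, 2))
    for (idx in pr) {  # the two coalescing lineages close their branches
      branches_tips[[length(branches_tips) + 1]] <- tips[[idx]]
      branches_len <- c(branches_len, lens[idx])
    }
    tips[[pr[1]]] <- c(tips[[pr[1]]], tips[[pr[2]]])
    lens[pr[1]] <- 0
    tips[[pr[2]]] <- NULL
    lens <- lens[-pr[2]]
    k <- k - 1L
  }
  tibble::tibble(tips = branches_tips, length = branches_len)
}

# internal: REF/ALT pairs with the study-like transition bias
draw_site_alleles <- function(n_sites, ts_prob = 0.637, indel_fraction = 0) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n_sites, replace = TRUE)
  alts <- vector("list", n_sites)
  n_indel <- round(indel_fraction * n_sites)
  indel_idx <- if (n_indel > 0) sample.int(n_sites, n_indel) else integer(0)
  for (i in seq_len(n_sites)) {
    if (i %in% indel_idx) {
      alts[[i]] <- paste0(ref[i], sample(bases, 1))
    } else if (stats::runif(1) < ts_prob) {
      alts[[i]] <- transition[[ref[i]]]
    } else {
      alts[[i]] <- sample(setdiff(bases, c(ref[i], transition[[ref[i]]])), 1)
    }
  }
  list(ref = ref, alts = alts)
}

#' Simulation configuration for structured chloroplast-like data
#'
#' Defaults mirror the study's 412-accession design: seven subgroups with
#' the published sample sizes, per-group diversity ordered wild >> indica >
#' japonica, planted fixed differences between indica and the japonica
#' pair, light missingness, the observed InDel share and transition bias.
#'
#' @param genome_length Genome length in bp.
#' @param groups Tibble with `group`, `n` (sample counts).
#' @param theta Named per-group scaled mutation rates.
#' @param n_fixed_diff Fixed differences planted between `fixed_pair_a`
#'   and `fixed_pair_b` samples.
#' @param fixed_pair_a,fixed_pair_b Group label vectors on each side of the
#'   planted divergence.
#' @param missing_rate Per-call missing probability.
#' @param indel_fraction Fraction of sites emitted as single-base
#'   insertions.
#' @param ts_prob Transition probability among emitted SNPs.
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 134525L,
                       groups = tibble::tibble(
                         group = c("indica", "temperate_japonica",
                                   "tropical_japonica", "aus", "aromatic",
                                   "admixture", "wild"),
                         n = c(66L, 253L, 25L, 9L, 2L, 3L, 54L)),
                       theta = c(indica = 4, temperate_japonica = 1.5,
                                 tropical_japonica = 1.5, aus = 5,
                                 aromatic = 0.5, admixture = 0.5, wild = 30),
                       n_fixed_diff = 10L,
                       fixed_pair_a = "indica",
                       fixed_pair_b = c("temperate_japonica",
                                        "tropical_japonica"),
                       missing_rate = 0.02,
                       indel_fraction = 0.122,
                       ts_prob = 0.637,
                       seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("group", "n") %in% names(groups)), all(groups$n >= 1),
            n_fixed_diff >= 0, missing_rate >= 0, missing_rate < 1,
            indel_fraction >= 0, indel_fraction <= 1)
  if (is.null(seed)) rlang::abort("a seed is mandatory for reproducibility")
  missing_theta <- setdiff(groups$group, names(theta))
  if (length(missing_theta)) {
    rlang::abort(paste0("no theta for group(s): ",
                        paste(missing_theta, collapse = ", ")))
  }
  structure(
    list(genome_length = as.integer(genome_length), groups = groups,
         theta = theta, n_fixed_diff = as.integer(n_fixed_diff),
         fixed_pair_a = fixed_pair_a, fixed_pair_b = fixed_pair_b,
         missing_rate = missing_rate, indel_fraction = indel_fraction,
         ts_prob = ts_prob, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a structured multi-group dataset
#'
#' Per group, within-group polymorphism comes from an independent neutral
#' coalescent at the group's theta (other groups carry the reference allele
#' at those sites). `n_fixed_diff` sites are planted fixed-derived in the
#' `fixed_pair_a` groups and fixed-ancestral everywhere else, emulating the
#' deep indica/japonica chloroplast divergence. Missing calls are sprinkled
#' uniformly; a fraction of sites is emitted as single-base insertions.
#'
#' @param cfg A [sim_config()].
#' @return List: `geno` (a `chloro_geno`), `pm` (population map tibble) and
#'   `truth` (planted parameters: fixed-difference positions, thetas, seed).
#' @export
simulate_structured <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- cfg$groups
  samples <- purrr::pmap(groups, function(group, n) {
    paste0(group, "_", seq_len(n))
  })
  pm <- tibble::tibble(sample = unlist(samples),
                       group = rep(groups$group, groups$n))
  blocks <- purrr::pmap(groups, function(group, n) {
    if (n < 2 || cfg$theta[[group]] <= 0) {
      return(matrix(integer(0), nrow = 0, ncol = n))
    }
    cs <- simulate_coalescent(n, cfg$theta[[group]],
                              genome_length = cfg$genome_length)
    cs$geno$calls
  })
  n_group_sites <- vapply(blocks, nrow, integer(1))
  n_total <- sum(n_group_sites) + cfg$n_fixed_diff
  if (n_total > cfg$genome_length) {
    rlang::abort("more sites requested than genome positions available")
  }
  pos_all <- sort(sample.int(cfg$genome_length, n_total))
  calls <- matrix(0L, nrow = n_total, ncol = nrow(pm),
                  dimnames = list(NULL, pm$sample))
  slot <- sample(seq_len(n_total))  # scatter block rows over positions
  row_at <- 0L
  for (b in seq_along(blocks)) {
    if (n_group_sites[b] == 0) next
    rows <- slot[row_at + seq_len(n_group_sites[b])]
    calls[rows, pm$sample[pm$group == groups$group[b]]] <- blocks[[b]]
    row_at <- row_at + n_group_sites[b]
  }
  fixed_rows <- integer(0)
  if (cfg$n_fixed_diff > 0) {
    fixed_rows <- slot[row_at + seq_len(cfg$n_fixed_diff)]
    side_a <- pm$sample[pm$group %in% cfg$fixed_pair_a]
    calls[fixed_rows, side_a] <- 1L
  }
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }
  alleles <- draw_site_alleles(n_total, ts_prob = cfg$ts_prob,
                               indel_fraction = cfg$indel_fraction)
  sites <- tibble::tibble(pos = pos_all, ref = alleles$ref,
                          alts = alleles$alts)
  list(
    geno = geno_matrix(sites, calls, genome_length = cfg$genome_length),
    pm = pm,
    truth = list(fixed_diff_pos = sort(pos_all[fixed_rows]),
                 theta = as.list(cfg$theta), seed = cfg$seed,
                 n_sites = n_total)
  )
}

#' Simulate a dataset with a bottleneck-distorted frequency spectrum
#'
#' Generates unlinked neutral sites — each from its own genealogy, so the
#' count of segregating sites is `Poisson(theta * a1)` and the derived
#' count of each site follows the neutral `1/i` spectrum — then prunes
#' rare variants: a site with minor allele frequency `maf` is removed with
#' probability `severity * (1 - 2 * maf)`. Losing rare alleles faster than
#' gene diversity is exactly the footprint of a recent contraction, so
#' increasing `severity` plants a heterozygosity-excess signal;
#' `severity = 0` leaves the neutral spectrum untouched.
#'
#' @param n Number of haploid samples.
#' @param theta Scaled mutation rate of the pre-bottleneck population.
#' @param severity Pruning strength in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param genome_length Genome span for site placement.
#' @return A `chloro_geno`; the pre-pruning site count is attached as
#'   attribute `"n_sites_neutral"`.
#' @export
simulate_bottleneck_dataset <- function(n, theta, severity, seed = NULL,
                                        genome_length = 134525L) {
  stopifnot(n >= 2, theta > 0, severity >= 0, severity <= 1)
  if (!is.null(seed)) set.seed(seed)
  a1 <- sum(1 / seq_len(n - 1))
  S <- stats::rpois(1, theta * a1)
  freq_weights <- 1 / seq_len(n - 1)
  derived <- sample.int(n - 1, S, replace = TRUE,
                        prob = freq_weights / sum(freq_weights))
  maf <- pmin(derived, n - derived) / n
  keep <- stats::runif(S) >= severity * (1 - 2 * maf)
  derived <- derived[keep]
  S_kept <- length(derived)
  samples <- paste0("s", seq_len(n))
  calls <- matrix(0L, nrow = S_kept, ncol = n,
                  dimnames = list(NULL, samples))
  for (i in seq_len(S_kept)) {
    calls[i, sample.int(n, derived[i])] <- 1L
  }
  pos <- sort(sample.int(genome_length, S_kept))
  alleles <- draw_site_alleles(S_kept)
  g <- geno_matrix(tibble::tibble(pos = pos, ref = alleles$ref,
                                  alts = alleles$alts),
                   calls, genome_length = genome_length)
  attr(g, "n_sites_neutral") <- S
  g
}

#' Write a simulated dataset to disk
#'
#' Emits a VCF v4.2, a two-column groups TSV and a truth JSON of planted
#' parameters, the trio downstream test harnesses key on.
#'
#' @param geno A `chloro_geno`.
#' @param pm Population map tibble (must be non-empty).
#' @param dir Output directory (created if needed).
#' @param truth Optional list of planted parameters.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(geno, pm, dir, truth = NULL) {
  pm <- pop_map(pm)
  if (nrow(pm) == 0) rlang::abort("empty population map")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(geno, paths[["vcf"]])
  utils::write.table(pm, paths[["groups"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(truth %||% list(), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
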