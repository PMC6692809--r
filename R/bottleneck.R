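#' Pre-filter loci for the bottleneck test
#'
#' The study removes loci with minor allele frequency below 0.05 before
#' testing (strict `<` removal), and only loci with at least two observed
#' alleles in the tested group are informative.
#'
#' @param g A `chloro_geno`.
#' @param pm,group Optional population map and group label; when given, MAF
#'   and allele counts are computed within that group only.
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return The filtered `chloro_geno` (full sample set, sites restricted).
#' @export
prefilter_loci <- function(g, pm = NULL, group = NULL, min_maf = 0.05) {
  gg <- g
  if (!is.null(pm) && !is.null(group)) {
    ids <- intersect(pop_samples(pop_map(pm), group), geno_samples(g))
    gg <- select_samples(g, ids)
  }
  keep <- site_maf(gg) >= min_maf & site_allele_number(gg) >= 2
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) rlang::abort("no loci survive the bottleneck pre-filter")
  slice_sites(g, which(keep))
}

#' Unbiased expected heterozygosity from allele counts
#'
#' Nei's gene diversity with the small-sample correction,
#' `n/(n-1) * (1 - sum(p^2))`, the quantity the heterozygosity-excess
#' bottleneck test compares against its simulated equilibrium
#' distribution.
#'
#' @param counts Integer vector of allele copy counts at one locus.
#' @return A number in `[0, 1]`.
#' @export
unbiased_heterozygosity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Simulate the equilibrium heterozygosity distribution given k alleles
#'
#' Draws coalescent samples of `n` genes under the chosen mutation model,
#' keeps replicates that show exactly `k` alleles (the observed allele
#' count), and summarises the unbiased heterozygosity of the accepted
#' replicates — the Cornuet & Luikart-style conditional equilibrium
#' distribution `Heq | k`.
#'
#' Models: `IAM` (every mutation creates a novel allele; simulated exactly
#' via the Ewens/Hoppe urn, with theta solved from the Ewens expected
#' allele count), `SMM` (strict one-step ladder walks on a genealogy) and
#' `TPM` (two-phase: single step with probability `p_ss`, otherwise a
#' geometric multi-step with variance `variance_geom`). For SMM/TPM, theta
#' is calibrated by stochastic bisection so the expected allele count
#' matches `k`, then rejection sampling conditions exactly.
#'
#' @param k Observed allele count (2 <= k <= n).
#' @param n Number of genes (haploid samples).
#' @param model `"IAM"`, `"SMM"` or `"TPM"`.
#' @param reps Accepted replicates to collect (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param p_ss TPM single-step probability (default 0.70).
#' @param variance_geom TPM geometric multi-step variance (default 30).
#' @param max_attempts Attempt budget before giving up (default `200 * reps`).
#' @return List: `heq_mean`, `heq_sd`, `samples` (accepted Heq values),
#'   `theta`, `acceptance` rate.
#' @export
simulate_heq <- function(k, n, model = c("IAM", "SMM", "TPM"), reps = 1000,
                         seed = NULL, p_ss = 0.70, variance_geom = 30,
                         max_attempts = 200 * reps) {
  model <- match.arg(model)
  stopifnot(k >= 2, k <= n, reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  p_geom <- (-1 + sqrt(1 + 4 * variance_geom)) / (2 * variance_geom)
  theta <- if (model == "IAM") ewens_theta(k, n) else {
    calibrate_theta(k, n, model, p_ss, p_geom)
  }
  draw <- function() {
    if (model == "IAM") sim_iam_partition(n, theta) else {
      tabulate_states(sim_stepwise_states(n, theta, model, p_ss, p_geom))
    }
  }
  samples <- numeric(0)
  attempts <- 0L
  while (length(samples) < reps && attempts < max_attempts) {
    counts <- draw()
    attempts <- attempts + 1L
    if (length(counts) == k) {
      samples <- c(samples, unbiased_heterozygosity(counts))
    }
  }
  acc <- length(samples) / attempts
  if (length(samples) < reps && acc < 0.01) {
    rlang::abort(sprintf(
      "acceptance rate %.3f%% for k = %d, n = %d under %s; widen the theta search or raise max_attempts",
      100 * acc, k, n, model))
  }
  list(heq_mean = mean(samples), heq_sd = stats::sd(samples),
       samples = samples, theta = theta, acceptance = acc)
}

# internal: solve Ewens E[K] = sum_{i=0}^{n-1} theta/(theta+i) for theta
ewens_theta <- function(k, n) {
  expected_k <- function(theta) sum(theta / (theta + 0:(n - 1)))
  if (k >= n) return(1e6)  # every gene its own allele
  stats::uniroot(function(lt) expected_k(exp(lt)) - k,
                 lower = log(1e-6), upper = log(1e6), tol = 1e-9)$root |> exp()
}

# internal: Hoppe-urn draw of an IAM allele configuration (Ewens sampling)
sim_iam_partition <- function(n, theta) {
  counts <- integer(0)
  for (i in seq_len(n)) {
    if (stats::runif(1) < theta / (theta + i - 1)) {
      counts <- c(counts, 1L)
    } else {
      j <- sample.int(length(counts), 1, prob = counts)
      counts[j] <- counts[j] + 1L
    }
  }
  counts
}

# internal: tip allele states on a Kingman genealogy with stepwise mutation
sim_stepwise_states <- function(n, theta, model, p_ss, p_geom) {
  state <- integer(n)
  groups <- as.list(seq_len(n))
  k <- n
  while (k > 1) {
    t <- stats::rexp(1, k * (k - 1) / 2)
    m <- stats::rpois(k, theta / 2 * t)
    for (i in which(m > 0)) {
      state[groups[[i]]] <- state[groups[[i]]] +
        mutation_steps(m[i], model, p_ss, p_geom)
    }
    pr <- sort(sample.int(k, 2))
    groups[[pr[1]]] <- c(groups[[pr[1]]], groups[[pr[2]]])
    groups[[pr[2]]] <- NULL
    k <- k - 1L
  }
  state
}

# internal: net ladder displacement of m mutations
mutation_steps <- function(m, model, p_ss, p_geom) {
  sizes <- if (model == "SMM") rep(1L, m) else {
    ifelse(stats::runif(m) < p_ss, 1L, 1L + stats::rgeom(m, p_geom))
  }
  sum(sample(c(-1L, 1L), m, replace = TRUE) * sizes)
}

tabulate_states <- function(states) as.integer(table(states))

# internal: stochastic bisection of theta so mean allele count matches k
calibrate_theta <- function(k, n, model, p_ss, p_geom, batch = 120,
                            iterations = 12) {
  mean_k <- function(theta) {
    mean(replicate(batch, length(unique(
      sim_stepwise_states(n, theta, model, p_ss, p_geom)))))
  }
  lo <- hi <- max(ewens_theta(min(k, n - 1L), n), 1e-4)
  while (mean_k(lo) > k && lo > 1e-6) lo <- lo / 4
  while (mean_k(hi) < k && hi < 1e5) hi <- hi * 4
  for (i in seq_len(iterations)) {
    mid <- sqrt(lo * hi)
    if (mean_k(mid) < k) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Heterozygosity-excess bottleneck test for one group
#'
#' For each testable locus (>= 2 alleles among the group's non-missing
#' calls), compares the observed unbiased heterozygosity with the
#' simulated equilibrium distribution conditioned on the observed allele
#' count ([simulate_heq()]), yielding a standardised difference
#' `DH = (He_obs - Heq_mean)/Heq_sd` and an excess flag. Two group-level
#' summaries follow the classic design: a sign test of the number of
#' excess loci against the simulation-estimated expected proportion, and
#' a one-tailed Wilcoxon signed-rank test of `DH > 0`. A recently
#' bottlenecked population loses alleles faster than gene diversity, so
#' heterozygosity excess across loci signals a contraction (or strong
#' selection on this non-recombining genome).
#'
#' Loci sharing an (allele count, sample size) pair reuse one simulation.
#'
#' @param g A `chloro_geno` (apply [prefilter_loci()] first to mirror the
#'   study's MAF >= 0.05 rule).
#' @param pm,group Optional population map and group label restricting the
#'   samples tested.
#' @param model `"IAM"`, `"SMM"` or `"TPM"`.
#' @param reps Accepted simulation replicates per locus class (default 1000).
#' @param seed Integer seed (default 1).
#' @param ... Passed to [simulate_heq()] (`p_ss`, `variance_geom`, ...).
#' @return A `cp_bottleneck` object: `loci` tibble (`pos`, `k`, `n`,
#'   `He_obs`, `Heq_mean`, `Heq_sd`, `DH`, `excess`), `model`, `group`,
#'   `reps`, `p_sign`, `p_wilcoxon`, `prop_excess_expected`.
#' @export
het_excess_test <- function(g, pm = NULL, group = NULL,
                            model = c("IAM", "SMM", "TPM"), reps = 1000,
                            seed = 1, ...) {
  model <- match.arg(model)
  if (!is.null(pm) && !is.null(group)) {
    ids <- intersect(pop_samples(pop_map(pm), group), geno_samples(g))
    g <- select_samples(g, ids)
  }
  tabs <- site_allele_counts(g$calls)
  loci <- tibble::tibble(
    pos = g$sites$pos,
    k = vapply(tabs, length, integer(1)),
    n = vapply(tabs, sum, numeric(1)),
    He_obs = vapply(tabs, function(tt) unbiased_heterozygosity(as.integer(tt)),
                    numeric(1))
  )
  loci <- loci[loci$k >= 2 & loci$n >= 2, , drop = FALSE]
  if (nrow(loci) < 2) rlang::abort("fewer than 2 testable loci")
  set.seed(seed)
  combos <- unique(loci[, c("k", "n")])
  combos <- combos[order(combos$k, combos$n), , drop = FALSE]
  sims <- purrr::pmap(combos, function(k, n) {
    simulate_heq(k, n, model = model, reps = reps, seed = NULL, ...)
  })
  key <- paste(combos$k, combos$n)
  sim_of <- sims[match(paste(loci$k, loci$n), key)]
  loci$Heq_mean <- purrr::map_dbl(sim_of, "heq_mean")
  loci$Heq_sd <- purrr::map_dbl(sim_of, "heq_sd")
  loci$DH <- (loci$He_obs - loci$Heq_mean) / loci$Heq_sd
  loci$DH[!is.finite(loci$DH)] <- NA_real_
  loci$excess <- loci$He_obs > loci$Heq_mean
  # expected proportion of excess loci under equilibrium, from the same sims
  p_exc <- purrr::map_dbl(sim_of, function(s) mean(s$samples > mean(s$samples)))
  p_ref <- mean(p_exc[match(paste(loci$k, loci$n), key)])
  p_sign <- stats::binom.test(sum(loci$excess), nrow(loci), p = p_ref,
                              alternative = "greater")$p.value
  dh <- loci$DH[!is.na(loci$DH)]
  p_wilcoxon <- if (length(dh) >= 2) {
    suppressWarnings(stats::wilcox.test(dh, mu = 0,
                                        alternative = "greater")$p.value)
  } else NA_real_
  structure(
    list(loci = loci, model = model,
         group = if (is.null(group)) "all" else paste(group, collapse = "+"),
         reps = reps, p_sign = p_sign, p_wilcoxon = p_wilcoxon,
         prop_excess_expected = p_ref),
    class = "cp_bottleneck"
  )
}

#' @export
print.cp_bottleneck <- function(x, ...) {
  cat(sprintf("<cp_bottleneck> group %s, model %s, %d loci\n",
              x$group, x$model, nrow(x$loci)))
  cat(sprintf("  excess loci: %d/%d (expected prop %.2f)\n",
              sum(x$loci$excess), nrow(x$loci), x$prop_excess_expected))
  cat(sprintf("  sign test p = %.4g; Wilcoxon (excess) p = %.4g\n",
              x$p_sign, x$p_wilcoxon))
  invisible(x)
}

#' Tidy per-locus bottleneck summaries
#' @param x A `cp_bottleneck`.
#' @param ... Unused.
#' @return The per-locus tibble.
#' @method tidy cp_bottleneck
#' @export
tidy.cp_bottleneck <- function(x, ...) x$loci

#' One-row bottleneck test summary
#' @param x A `cp_bottleneck`.
#' @param ... Unused.
#' @return Tibble with `group`, `model`, `n_loci`, `n_excess`, `p_sign`,
#'   `p_wilcoxon`.
#' @method glance cp_bottleneck
#' @export
glance.cp_bottleneck <- function(x, ...) {
  tibble::tibble(group = x$group, model = x$model, n_loci = nrow(x$loci),
                 n_excess = sum(x$loci$excess), p_sign = x$p_sign,
                 p_wilcoxon = x$p_wilcoxon)
}
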