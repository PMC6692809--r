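#' Windowed nucleotide diversity (pi)
#'
#' Sliding-window nucleotide diversity per site. For each window, pi is the
#' sum over variant sites of the unbiased per-site heterozygosity
#' `n_i/(n_i - 1) * (1 - sum(p_a^2))` (with `n_i` the non-missing calls at
#' site `i`), divided by the window length `L` — i.e. diversity per bp,
#' invariant positions included in the denominator. Windows are anchored at
#' position 1 and tile the genome; the final partial window keeps its true
#' length. This matches the vcftools-style windowed pi the study used
#' (1000-bp windows, 500-bp steps).
#'
#' @param g A `chloro_geno`.
#' @param samples Sample subset (default: all samples).
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default 500).
#' @return A tibble with columns `start`, `end`, `L`, `n_variants`, `pi`.
#'   `pi` is `NA` for windows whose every site has fewer than 2 non-missing
#'   calls; windows without variant sites have `pi = 0`.
#' @export
nucleotide_diversity <- function(g, samples = NULL, window = 1000, step = 500) {
  stopifnot(window >= step, step >= 1)
  if (!is.null(samples)) g <- select_samples(g, samples)
  if (n_samples(g) < 2) rlang::abort("need at least 2 samples for diversity")
  het <- site_heterozygosity(g)
  pos <- g$sites$pos
  starts <- seq(1L, g$genome_length, by = as.integer(step))
  ends <- pmin(starts + as.integer(window) - 1L, g$genome_length)
  purrr::map2_dfr(starts, ends, function(s, e) {
    idx <- which(pos >= s & pos <= e)
    L <- e - s + 1L
    h <- het[idx]
    if (length(idx) > 0 && all(is.na(h))) {
      pi <- NA_real_
    } else {
      pi <- sum(h, na.rm = TRUE) / L
    }
    tibble::tibble(start = s, end = e, L = L, n_variants = length(idx), pi = pi)
  })
}

# internal: unbiased per-site heterozygosity n/(n-1)(1 - sum p^2); NA if n < 2
site_heterozygosity <- function(g) {
  vapply(site_allele_counts(g$calls), function(tab) {
    n <- sum(tab)
    if (n < 2) return(NA_real_)
    p <- as.numeric(tab) / n
    n / (n - 1) * (1 - sum(p^2))
  }, numeric(1))
}

#' Whole-region nucleotide diversity
#'
#' Mean pairwise diversity per site over the whole genome: the sum of
#' per-site unbiased heterozygosities divided by `genome_length`.
#'
#' @inheritParams nucleotide_diversity
#' @return A single number.
#' @export
pi_per_site <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- select_samples(g, samples)
  if (n_samples(g) < 2) rlang::abort("need at least 2 samples for diversity")
  sum(site_heterozygosity(g), na.rm = TRUE) / g$genome_length
}

#' Windowed diversity for every group of a population map
#'
#' @param g A `chloro_geno`.
#' @param pm Population map tibble (`sample`, `group`).
#' @param ... Passed to [nucleotide_diversity()].
#' @return A tibble like [nucleotide_diversity()] with a leading `group`
#'   column. Groups with fewer than 2 samples are skipped with a message.
#' @export
diversity_by_group <- function(g, pm, ...) {
  pm <- pop_map(pm)
  purrr::map_dfr(pop_groups(pm), function(grp) {
    ids <- intersect(pop_samples(pm, grp), geno_samples(g))
    if (length(ids) < 2) {
      rlang::inform(sprintf("group '%s' has < 2 samples; skipped", grp))
      return(NULL)
    }
    dplyr::mutate(nucleotide_diversity(g, samples = ids, ...),
                  group = grp, .before = 1)
  })
}
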