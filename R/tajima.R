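#' Tajima's D
#'
#' Standardised difference between the pairwise-diversity and
#' segregating-sites estimators of the population mutation rate, after
#' Tajima (1989):
#' \deqn{D = \frac{\hat\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S - 1)}}}
#' with the usual constants derived from the sample size `n`
#' (`a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`, etc.).
#' `pi_total` here is the mean number of pairwise differences (sum of
#' unbiased per-site heterozygosities, per-site non-missing denominators).
#'
#' The default is one whole-genome value for the sample subset; passing
#' `window` switches to the sliding-window grid used elsewhere in the
#' package.
#'
#' @param g A `chloro_geno`.
#' @param samples Sample subset (default: all).
#' @param window Optional window size in bp; `NULL` (default) = whole genome.
#' @param step Step size in bp when windowed (default 500).
#' @return A tibble with columns `start`, `end` (absent for whole-genome),
#'   `n`, `S`, `pi_total`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`,
#'   `D`. `D` is `NA` (with a warning) when `S = 0`.
#' @export
tajimas_d <- function(g, samples = NULL, window = NULL, step = 500) {
  if (!is.null(samples)) g <- select_samples(g, samples)
  n <- n_samples(g)
  if (n < 2) rlang::abort("need at least 2 samples")
  if (n < 4) rlang::warn("Tajima's D with n < 4 is poorly behaved")
  het <- site_heterozygosity(g)
  seg <- site_allele_number(g) >= 2
  if (is.null(window)) {
    out <- tajima_row(n, S = sum(seg), pi_total = sum(het[seg], na.rm = TRUE))
  } else {
    pos <- g$sites$pos
    starts <- seq(1L, g$genome_length, by = as.integer(step))
    ends <- pmin(starts + as.integer(window) - 1L, g$genome_length)
    out <- purrr::map2_dfr(starts, ends, function(s, e) {
      idx <- which(pos >= s & pos <= e & seg)
      dplyr::mutate(
        tajima_row(n, S = length(idx), pi_total = sum(het[idx], na.rm = TRUE),
                   warn = FALSE),
        start = s, end = e, .before = 1)
    })
  }
  if (any(out$S == 0)) {
    rlang::warn("S = 0 in at least one interval; D undefined there")
  }
  out
}

# internal: Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajima_row <- function(n, S, pi_total, warn = TRUE) {
  k <- tajima_constants(n)
  D <- if (S == 0) NA_real_ else {
    (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  tibble::tibble(n = n, S = S, pi_total = pi_total,
                 a1 = k$a1, a2 = k$a2, b1 = k$b1, b2 = k$b2,
                 c1 = k$c1, c2 = k$c2, e1 = k$e1, e2 = k$e2, D = D)
}

#' Tajima's D for every group of a population map
#'
#' @param g A `chloro_geno`.
#' @param pm Population map tibble.
#' @param ... Passed on to [tajimas_d()].
#' @return Tibble like [tajimas_d()] with a leading `group` column.
#' @export
tajima_by_group <- function(g, pm, ...) {
  pm <- pop_map(pm)
  purrr::map_dfr(pop_groups(pm), function(grp) {
    ids <- intersect(pop_samples(pm, grp), geno_samples(g))
    if (length(ids) < 2) return(NULL)
    dplyr::mutate(tajimas_d(g, samples = ids, ...), group = grp, .before = 1)
  })
}
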