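#' Weir-Cockerham weighted FST between two groups
#'
#' The Weir & Cockerham (1984) ANOVA estimator specialised to haploid data:
#' each chloroplast call is a single allele, so only two variance components
#' remain — among groups (`a`) and within groups (`b`). Per site and per
#' allele `u`:
#' \deqn{MSP_u = \sum_i n_i (p_{iu} - \bar p_u)^2 / (r - 1), \quad
#'       MSG_u = \sum_i n_i p_{iu}(1 - p_{iu}) / \sum_i (n_i - 1)}
#' with \eqn{n_c = (N - \sum n_i^2 / N)/(r - 1)}, giving
#' \eqn{a_u = (MSP_u - MSG_u)/n_c} and \eqn{b_u = MSG_u}; the site components
#' sum over alleles. The "weighted" genome-wide estimate is the ratio of
#' summed components, \eqn{\hat\theta = \sum a / \sum (a + b)}, over all
#' sites polymorphic in the pooled pair. Sample sizes `n_i` are the
#' non-missing calls of each group at that site.
#'
#' @param g A `chloro_geno`.
#' @param pm Population map tibble.
#' @param group_a,group_b Group labels (vectors allowed; pooled).
#' @return An object of class `cp_fst`: list with `fst` (weighted estimate),
#'   `per_site` tibble (`pos`, `a`, `b`, `fst_site`), and the group labels.
#' @export
weir_cockerham_fst <- function(g, pm, group_a, group_b) {
  pm <- pop_map(pm)
  ids_a <- intersect(pop_samples(pm, group_a), geno_samples(g))
  ids_b <- intersect(pop_samples(pm, group_b), geno_samples(g))
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    rlang::abort("both groups need at least 2 samples present in the matrix")
  }
  comp <- purrr::map_dfr(seq_len(n_sites(g)), function(i) {
    fst_site_components(g$calls[i, ids_a], g$calls[i, ids_b], g$sites$pos[i])
  })
  comp <- comp[!is.na(comp$a), , drop = FALSE]
  denom <- sum(comp$a + comp$b)
  fst <- if (nrow(comp) == 0 || denom == 0) NA_real_ else sum(comp$a) / denom
  structure(
    list(fst = fst, per_site = comp,
         group_a = paste(group_a, collapse = "+"),
         group_b = paste(group_b, collapse = "+"),
         n_a = length(ids_a), n_b = length(ids_b)),
    class = "cp_fst"
  )
}

# internal: WC haploid variance components at one site (NA row when the site
# is monomorphic across both groups or a group has < 2 calls)
fst_site_components <- function(calls_a, calls_b, pos) {
  calls_a <- calls_a[!is.na(calls_a)]
  calls_b <- calls_b[!is.na(calls_b)]
  n <- c(length(calls_a), length(calls_b))
  na_row <- tibble::tibble(pos = pos, a = NA_real_, b = NA_real_,
                           fst_site = NA_real_)
  if (any(n < 2)) return(na_row)
  alleles <- sort(unique(c(calls_a, calls_b)))
  if (length(alleles) < 2) return(na_row)
  N <- sum(n)
  r <- 2
  n_c <- (N - sum(n^2) / N) / (r - 1)
  a_tot <- 0
  b_tot <- 0
  for (u in alleles) {
    p <- c(mean(calls_a == u), mean(calls_b == u))
    pbar <- sum(n * p) / N
    msp <- sum(n * (p - pbar)^2) / (r - 1)
    msg <- sum(n * p * (1 - p)) / sum(n - 1)
    a_tot <- a_tot + (msp - msg) / n_c
    b_tot <- b_tot + msg
  }
  tibble::tibble(
    pos = pos, a = a_tot, b = b_tot,
    fst_site = if (a_tot + b_tot == 0) NA_real_ else a_tot / (a_tot + b_tot)
  )
}

#' @export
print.cp_fst <- function(x, ...) {
  cat(sprintf("<cp_fst> %s vs %s (n = %d, %d)\n", x$group_a, x$group_b,
              x$n_a, x$n_b))
  cat(sprintf("  weighted FST = %.4f over %d site(s)\n", x$fst, nrow(x$per_site)))
  invisible(x)
}

#' Tidy per-site FST components
#' @param x A `cp_fst`.
#' @param ... Unused.
#' @return Tibble with `pos`, `a`, `b`, `fst_site`.
#' @method tidy cp_fst
#' @export
tidy.cp_fst <- function(x, ...) x$per_site

#' One-row FST summary
#' @param x A `cp_fst`.
#' @param ... Unused.
#' @return Tibble with `group_a`, `group_b`, `fst`, `n_sites`.
#' @method glance cp_fst
#' @export
glance.cp_fst <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 fst = x$fst, n_sites = nrow(x$per_site))
}

#' Pairwise weighted FST across all groups of a map
#'
#' @param g A `chloro_geno`.
#' @param pm Population map tibble.
#' @param min_n Minimum samples per group to include it (default 2).
#' @return Tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, `fst`, `n_sites`.
#' @export
fst_matrix <- function(g, pm, min_n = 2) {
  pm <- pop_map(pm)
  grps <- pop_groups(pm)
  grps <- grps[vapply(grps, function(x)
    length(intersect(pop_samples(pm, x), geno_samples(g))) >= min_n, logical(1))]
  if (length(grps) < 2) rlang::abort("need at least two groups with enough samples")
  pairs <- utils::combn(grps, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    glance.cp_fst(weir_cockerham_fst(g, pm, p[1], p[2]))
  })
}
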