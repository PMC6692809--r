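#' Construct a haploid genotype matrix
#'
#' The central container of the package: an ordered table of variant sites on
#' a (circular, effectively haploid) chloroplast genome together with an
#' integer matrix of per-sample allele calls. Allele index 0 is the reference
#' allele, 1..k index the alternate alleles, and `NA` marks a missing call.
#'
#' @param sites A data frame with one row per variant, containing at least
#'   `pos` (1-based position), `ref` (reference allele string) and `alts`
#'   (list-column of alternate allele strings). `chrom` defaults to `"chloroplast"`.
#'   Variant class (`vclass`), substitution type (`subst`) and `region`
#'   annotations are filled by [classify_variants()] / [annotate_regions()]
#'   when absent.
#' @param calls Integer matrix, sites in rows and samples in columns
#'   (column names are sample ids). Values index alleles; `NA` = missing.
#' @param genome_length Reference genome length in bp. Defaults to 134525,
#'   the Nipponbare chloroplast (GenBank NC_001320).
#' @return An object of class `chloro_geno`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   sites = tibble::tibble(pos = c(10L, 20L), ref = c("A", "T"),
#'                          alts = list("G", "TA")),
#'   calls = matrix(c(0L, 1L, 1L, 0L), nrow = 2,
#'                  dimnames = list(NULL, c("s1", "s2")))
#' )
#' g
geno_matrix <- function(sites, calls, genome_length = 134525L) {
  sites <- tibble::as_tibble(sites)
  stopifnot(is.matrix(calls))
  if (nrow(sites) != nrow(calls)) {
    rlang::abort("`sites` and `calls` must have the same number of rows")
  }
  if (is.null(colnames(calls)) && ncol(calls) > 0) {
    colnames(calls) <- paste0("sample_", seq_len(ncol(calls)))
  }
  if (!"chrom" %in% names(sites)) sites$chrom <- "chloroplast"
  if (!"alts" %in% names(sites)) rlang::abort("`sites` needs an `alts` list-column")
  if (!is.list(sites$alts)) sites$alts <- as.list(sites$alts)
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0)) {
    ord <- order(sites$pos)
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    if (any(diff(sites$pos) == 0)) {
      rlang::warn("duplicated positions present; site order may be ambiguous")
    }
  }
  if (any(sites$pos < 1)) rlang::abort("positions must be >= 1")
  storage.mode(calls) <- "integer"
  n_alleles <- 1L + lengths(sites$alts)
  mx <- suppressWarnings(apply(calls, 1, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0L
  if (any(mx > n_alleles - 1L)) {
    rlang::abort("call indexes an allele beyond REF/ALT list")
  }
  if (!"vclass" %in% names(sites) || !"subst" %in% names(sites)) {
    cls <- classify_variants(sites$ref, sites$alts)
    sites$vclass <- cls$vclass
    sites$subst <- cls$subst
  }
  if (!"region" %in% names(sites)) sites$region <- NA_character_
  structure(
    list(sites = sites, calls = calls,
         genome_length = as.integer(genome_length)),
    class = "chloro_geno"
  )
}

#' @export
print.chloro_geno <- function(x, ...) {
  cat(sprintf(
    "<chloro_geno> %d sites x %d samples over %s bp\n",
    n_sites(x), n_samples(x), format(x$genome_length, big.mark = ",")
  ))
  tab <- table(x$sites$vclass)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of variant sites / samples
#' @param g A `chloro_geno`.
#' @return Integer count.
#' @export
n_sites <- function(g) nrow(g$calls)

#' @rdname n_sites
#' @export
n_samples <- function(g) ncol(g$calls)

#' Sample ids of a genotype matrix
#' @param g A `chloro_geno`.
#' @return Character vector of sample ids.
#' @export
geno_samples <- function(g) colnames(g$calls)

#' Restrict a genotype matrix to a sample subset
#' @param g A `chloro_geno`.
#' @param samples Character vector of sample ids (order preserved as given).
#' @return A `chloro_geno` containing only those samples.
#' @export
select_samples <- function(g, samples) {
  missing_ids <- setdiff(samples, geno_samples(g))
  if (length(missing_ids)) {
    rlang::abort(paste0("unknown sample id(s): ",
                        paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  geno_matrix(g$sites, g$calls[, samples, drop = FALSE], g$genome_length)
}

# internal: row subset preserving structure
slice_sites <- function(g, idx) {
  geno_matrix(g$sites[idx, , drop = FALSE], g$calls[idx, , drop = FALSE],
              g$genome_length)
}

#' Per-site missing-call rate
#' @param g A `chloro_geno`.
#' @return Numeric vector, one value in `[0, 1]` per site.
#' @export
site_missing_rate <- function(g) {
  if (n_samples(g) == 0) return(rep(NA_real_, n_sites(g)))
  rowMeans(is.na(g$calls))
}

# internal: list of per-site allele count tables (named by allele index)
site_allele_counts <- function(calls) {
  apply(calls, 1, function(x) table(x[!is.na(x)]), simplify = FALSE)
}

#' Per-site minor allele frequency
#'
#' Frequency of the second-most-common allele among non-missing calls
#' (0 for monomorphic sites; `NA` when no calls). For multiallelic sites this
#' is the second-ranked allele's frequency, so values stay in `[0, 0.5]`.
#'
#' @param g A `chloro_geno`.
#' @return Numeric vector per site.
#' @export
site_maf <- function(g) {
  vapply(site_allele_counts(g$calls), function(tab) {
    n <- sum(tab)
    if (n == 0) return(NA_real_)
    if (length(tab) < 2) return(0)
    sort(as.numeric(tab), decreasing = TRUE)[2] / n
  }, numeric(1))
}

#' Per-site observed allele count (k)
#' @param g A `chloro_geno`.
#' @return Integer vector: distinct alleles seen among non-missing calls.
#' @export
site_allele_number <- function(g) {
  vapply(site_allele_counts(g$calls), length, integer(1))
}

#' Long tibble view of the calls
#'
#' @param x A `chloro_geno`.
#' @param ... Unused.
#' @return A tibble with columns `pos`, `sample`, `allele` (integer index,
#'   `NA` = missing).
#' @method tidy chloro_geno
#' @export
tidy.chloro_geno <- function(x, ...) {
  tibble::tibble(
    pos = rep(x$sites$pos, times = n_samples(x)),
    sample = rep(geno_samples(x), each = n_sites(x)),
    allele = as.integer(x$calls)
  )
}

#' One-row summary of a genotype matrix
#' @param x A `chloro_geno`.
#' @param ... Unused.
#' @return A one-row tibble: site/sample counts, SNP and InDel counts,
#'   overall missing rate.
#' @method glance chloro_geno
#' @export
glance.chloro_geno <- function(x, ...) {
  tibble::tibble(
    n_sites = n_sites(x),
    n_samples = n_samples(x),
    n_snp = sum(x$sites$vclass == "SNP", na.rm = TRUE),
    n_indel = sum(x$sites$vclass == "InDel", na.rm = TRUE),
    missing_rate = mean(is.na(x$calls)),
    genome_length = x$genome_length
  )
}

#' Population map helpers
#'
#' A population map is a plain tibble with columns `sample` and `group`.
#' `pop_map()` validates one; `pop_samples()` extracts the sample ids of a
#' group and errors on unknown labels, `pop_groups()` lists labels.
#'
#' @param x A data frame with columns `sample`, `group`.
#' @return `pop_map()`: the validated tibble. `pop_samples()`: character
#'   vector of sample ids. `pop_groups()`: character vector of labels.
#' @export
pop_map <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("sample", "group") %in% names(x))) {
    rlang::abort("a population map needs `sample` and `group` columns")
  }
  if (anyDuplicated(x$sample)) rlang::abort("duplicated sample ids in population map")
  x
}

#' @rdname pop_map
#' @param pm A population map tibble.
#' @param group A group label (or vector of labels, pooled).
#' @export
pop_samples <- function(pm, group) {
  pm <- pop_map(pm)
  unknown <- setdiff(group, pm$group)
  if (length(unknown)) {
    rlang::abort(paste0("unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  pm$sample[pm$group %in% group]
}

#' @rdname pop_map
#' @export
pop_groups <- function(pm) unique(pop_map(pm)$group)
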