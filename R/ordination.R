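#' Principal component analysis of a genotype matrix
#'
#' Eigen-decomposition of the covariance of the mean-centred allele-count
#' matrix (samples x sites, allele indexes as counts). Missing calls are
#' imputed to the site mean before centring. Axes are ordered by explained
#' variance.
#'
#' @param g A `chloro_geno`.
#' @param samples Sample subset (default: all).
#' @param k Number of axes to keep (default 2).
#' @return A `cp_ordination` object: `method = "PCA"`, `coordinates` tibble
#'   (`sample`, `axis1`, ..., `axisk`), `explained` variance fractions.
#' @export
pca_genotypes <- function(g, samples = NULL, k = 2) {
  if (!is.null(samples)) g <- select_samples(g, samples)
  if (n_samples(g) < k + 1) rlang::abort("need at least k + 1 samples")
  X <- impute_site_means(t(g$calls))
  if (all(apply(X, 2, stats::var) == 0)) {
    rlang::abort("all sites monomorphic; PCA undefined")
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(p$x))
  expl <- p$sdev^2 / sum(p$sdev^2)
  coords <- tibble::as_tibble(p$x[, seq_len(k), drop = FALSE],
                              .name_repair = ~ paste0("axis", seq_len(k)))
  coords <- dplyr::mutate(coords, sample = rownames(X), .before = 1)
  new_ordination("PCA", coords, explained = expl[seq_len(k)])
}

#' Classical multidimensional scaling of a genotype matrix
#'
#' Metric MDS (`cmdscale`) on normalised pairwise allele-mismatch (Hamming)
#' distances; sites where either member of a pair is missing are excluded
#' from that pair's comparison, and the mismatch count is divided by the
#' number of compared sites.
#'
#' @inheritParams pca_genotypes
#' @param k Number of axes (default 2).
#' @return A `cp_ordination` object (`method = "MDS"`, no `explained`).
#' @export
mds_genotypes <- function(g, samples = NULL, k = 2) {
  if (!is.null(samples)) g <- select_samples(g, samples)
  if (n_samples(g) < 3) rlang::abort("need at least 3 samples for MDS")
  d <- hamming_distances(g)
  if (all(d == 0)) {
    rlang::warn("all pairwise distances are zero; samples collapse to one point")
    coords <- tibble::as_tibble(
      matrix(0, n_samples(g), k, dimnames = list(NULL, paste0("axis", seq_len(k)))))
    coords <- dplyr::mutate(coords, sample = geno_samples(g), .before = 1)
    return(new_ordination("MDS", coords, eig = rep(0, n_samples(g))))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n_samples(g) - 1),
                         eig = TRUE)
  pts <- fit$points
  coords <- tibble::as_tibble(pts, .name_repair = ~ paste0("axis", seq_len(ncol(pts))))
  coords <- dplyr::mutate(coords, sample = geno_samples(g), .before = 1)
  new_ordination("MDS", coords, eig = fit$eig)
}

# internal: normalised pairwise mismatch matrix among samples
hamming_distances <- function(g) {
  m <- g$calls
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      d[i, j] <- d[j, i] <- if (any(ok)) mean(m[ok, i] != m[ok, j]) else 0
    }
  }
  d
}

# internal: samples x sites matrix with NAs replaced by column means
impute_site_means <- function(X) {
  X <- apply(X, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col[is.nan(col)] <- 0
    col
  })
  storage.mode(X) <- "double"
  X
}

new_ordination <- function(method, coordinates, explained = NULL, eig = NULL) {
  structure(list(method = method, coordinates = coordinates,
                 explained = explained, eig = eig),
            class = "cp_ordination")
}

#' @export
print.cp_ordination <- function(x, ...) {
  cat(sprintf("<cp_ordination> %s, %d samples, %d axes\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates) - 1))
  if (!is.null(x$explained)) {
    cat("  explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy ordination coordinates
#' @param x A `cp_ordination`.
#' @param ... Unused.
#' @return The coordinates tibble (`sample`, `axis1`, ...).
#' @method tidy cp_ordination
#' @export
tidy.cp_ordination <- function(x, ...) x$coordinates

#' One-row ordination summary
#' @param x A `cp_ordination`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_samples`, `k`, and `explained_1`
#'   (first-axis variance fraction, PCA only).
#' @method glance cp_ordination
#' @export
glance.cp_ordination <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = nrow(x$coordinates),
    k = ncol(x$coordinates) - 1,
    explained_1 = if (is.null(x$explained)) NA_real_ else x$explained[1]
  )
}
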