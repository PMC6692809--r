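#' Collapse samples into haplotypes
#'
#' Samples with identical allele vectors over the retained sites share a
#' haplotype. On the non-recombining chloroplast the variant alleles travel
#' as a unit, so this partition is the natural sequence-class summary.
#' By default samples with any missing call at a retained site are excluded
#' (and reported), because missing-tolerant matching can make haplotype
#' identity non-transitive.
#'
#' @param g A `chloro_geno`.
#' @param samples Sample subset (default: all).
#' @param pm Optional population map; when given, per-group member counts
#'   are added as a nested `group_counts` tibble column.
#' @param snp_only Drop InDel sites before collapsing (default `FALSE`;
#'   the study built haplotypes from its full high-quality variant set).
#' @return Tibble sorted by decreasing size: `haplotype` ("H1", ...),
#'   `size`, `members` (list of sample ids), `key` (list of allele
#'   vectors), and optionally `group_counts`.
#' @export
collapse_haplotypes <- function(g, samples = NULL, pm = NULL, snp_only = FALSE) {
  if (!is.null(samples)) g <- select_samples(g, samples)
  if (n_samples(g) < 1) rlang::abort("need at least 1 sample")
  if (snp_only) g <- slice_sites(g, which(g$sites$vclass == "SNP"))
  if (n_sites(g) == 0) rlang::abort("no retained sites to collapse over")
  complete <- !apply(g$calls, 2, anyNA)
  if (any(!complete)) {
    rlang::inform(sprintf("%d sample(s) with missing calls excluded from haplotyping",
                          sum(!complete)))
  }
  m <- g$calls[, complete, drop = FALSE]
  if (ncol(m) == 0) rlang::abort("no complete samples left to collapse")
  keys <- apply(m, 2, paste, collapse = ",")
  split_members <- split(colnames(m), keys)
  ord <- order(-lengths(split_members), names(split_members))
  split_members <- split_members[ord]
  out <- tibble::tibble(
    haplotype = paste0("H", seq_along(split_members)),
    size = unname(lengths(split_members)),
    members = unname(split_members),
    key = purrr::map(names(split_members),
                     ~ as.integer(strsplit(.x, ",", fixed = TRUE)[[1]]))
  )
  if (!is.null(pm)) {
    pm <- pop_map(pm)
    out$group_counts <- purrr::map(out$members, function(ids) {
      dplyr::count(dplyr::filter(pm, .data$sample %in% ids), .data$group,
                   name = "n")
    })
  }
  out
}

#' Statistical-parsimony connection limit
#'
#' The largest number of observed differences `j` between two sequences of
#' length `seq_length` that can still be accepted as a parsimonious
#' (single-hit-per-site) connection with probability above `confidence`.
#'
#' The model: mutations hit each site as an independent Poisson process.
#' For a pair differing at `j` of `L` sites the per-site hit rate is
#' estimated Jukes-Cantor-style as `lambda = -log(1 - j/L)`; given a site
#' shows a difference (>= 1 hit), the chance it received exactly one hit is
#' `r = lambda * exp(-lambda) / (1 - exp(-lambda))`, and the probability
#' that the whole connection is free of superimposed changes is `r^j`.
#' The limit is the largest `j` with `r^j > confidence`; it grows roughly
#' like `sqrt(L)` and is monotone in `L`.
#'
#' @param seq_length Sequence length in bp (>= 1).
#' @param confidence Parsimony confidence (default 0.95).
#' @return Integer number of mutational steps.
#' @export
parsimony_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  limit <- 0L
  for (j in seq_len(seq_length)) {
    if (parsimony_probability(j, seq_length) > confidence) limit <- j else break
  }
  limit
}

# internal: P(no superimposed changes | j of L sites differ)
parsimony_probability <- function(j, L) {
  q <- j / L
  if (q >= 1) return(0)
  lambda <- -log(1 - q)
  r <- lambda * (1 - q) / q
  r^j
}

#' Build a TCS-style statistical-parsimony network
#'
#' Agglomerative construction over the haplotype set: candidate pairs are
#' visited in increasing Hamming distance (ties broken towards pairs
#' containing the higher-frequency haplotype, then lower node index), and a
#' pair is connected when it does not exceed the parsimony `limit` and its
#' members are not yet in the same component. A connection of `d` steps
#' inserts `d - 1` inferred intermediate nodes so that every edge spans
#' exactly one mutational step.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param limit Maximum parsimonious connection length in steps; computed
#'   from `seq_length` via [parsimony_limit()] when `NULL`.
#' @param seq_length Sequence length used when `limit` is `NULL`.
#' @param confidence Confidence for the computed limit (default 0.95).
#' @return A `tcs_network` object: `nodes` tibble (`node`, `type`
#'   sampled/inferred, `size`), `edges` tibble (`from`, `to`), `limit`,
#'   `membership` (component id per node) and the underlying `igraph`.
#' @export
build_tcs_network <- function(haps, limit = NULL, seq_length = NULL,
                              confidence = 0.95) {
  if (nrow(haps) < 1) rlang::abort("need at least 1 haplotype")
  if (is.null(limit)) {
    if (is.null(seq_length)) {
      rlang::abort("supply `limit` or `seq_length` to derive it")
    }
    limit <- parsimony_limit(seq_length, confidence)
  }
  nh <- nrow(haps)
  nodes <- tibble::tibble(node = haps$haplotype, type = "sampled",
                          size = haps$size)
  edges <- tibble::tibble(from = character(), to = character())
  if (nh > 1) {
    pairs <- utils::combn(nh, 2)
    d <- apply(pairs, 2, function(p)
      sum(haps$key[[p[1]]] != haps$key[[p[2]]]))
    ord <- order(d,
                 -pmax(haps$size[pairs[1, ]], haps$size[pairs[2, ]]),
                 -pmin(haps$size[pairs[1, ]], haps$size[pairs[2, ]]),
                 pairs[1, ], pairs[2, ])
    comp <- seq_len(nh)  # union-find by relabel
    n_inferred <- 0L
    for (idx in ord) {
      if (d[idx] > limit) break
      i <- pairs[1, idx]; j <- pairs[2, idx]
      if (comp[i] == comp[j]) next
      chain <- haps$haplotype[i]
      if (d[idx] > 1) {
        mids <- paste0("I", n_inferred + seq_len(d[idx] - 1L))
        n_inferred <- n_inferred + d[idx] - 1L
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          node = mids, type = "inferred", size = 0L))
        chain <- c(chain, mids)
      }
      chain <- c(chain, haps$haplotype[j])
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = chain[-length(chain)], to = chain[-1]))
      comp[comp == comp[j]] <- comp[i]
    }
  }
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = nodes)
  membership <- igraph::components(gr)$membership[nodes$node]
  structure(
    list(nodes = nodes, edges = edges, limit = limit,
         membership = membership, graph = gr),
    class = "tcs_network"
  )
}

#' @export
print.tcs_network <- function(x, ...) {
  cat(sprintf(
    "<tcs_network> %d sampled + %d inferred nodes, %d edges, limit %d step(s), %d component(s)\n",
    sum(x$nodes$type == "sampled"), sum(x$nodes$type == "inferred"),
    nrow(x$edges), x$limit, length(unique(x$membership))))
  invisible(x)
}

#' Tidy network edge list
#' @param x A `tcs_network`.
#' @param ... Unused.
#' @return Tibble of single-step edges (`from`, `to`).
#' @method tidy tcs_network
#' @export
tidy.tcs_network <- function(x, ...) x$edges

#' One-row network summary
#' @param x A `tcs_network`.
#' @param ... Unused.
#' @return Tibble with node/edge/component counts and the limit.
#' @method glance tcs_network
#' @export
glance.tcs_network <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = sum(x$nodes$type == "sampled"),
    n_inferred = sum(x$nodes$type == "inferred"),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$membership)),
    limit = x$limit
  )
}
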