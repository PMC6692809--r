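#' Synonymous/nonsynonymous site counts for one codon
#'
#' Nei-Gojobori (1986) site counting: at each codon position the
#' synonymous fraction is the share of the three possible single-nucleotide
#' changes that leave the encoded amino acid unchanged (changes to stop
#' codons count as nonsynonymous), so `n + s = 3` for every sense codon.
#'
#' @param codon A 3-letter string over `{A,C,G,T}`; must not be a stop.
#' @param code Genetic code table (default `Biostrings::GENETIC_CODE`,
#'   the standard code used by chloroplast protein genes).
#' @return Named numeric vector `c(n = ..., s = ...)`.
#' @export
#' @examples
#' count_sites("TTT")  # Phe: s = 1/3
#' count_sites("ATG")  # Met: s = 0
count_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) rlang::abort("codon must be 3 bases over {A,C,G,T}")
  aa <- code[[codon]]
  if (aa == "*") rlang::abort("stop codon has no site counts")
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == aa) s <- s + 1 / 3  # fraction of the 3 changes at p
    }
  }
  c(n = 3 - s, s = s)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences, then applies the Jukes-Cantor multiple-hit
#' correction `K = -3/4 * log(1 - 4/3 * p)`. Codons differing at several
#' positions average the step classification over all orderings of single
#' changes, excluding pathways through stop codons (all orderings are used
#' only when every pathway is blocked). Codons containing gaps or ambiguous
#' bases in either sequence are skipped; a shared terminal stop codon is
#' trimmed; an internal stop is an error.
#'
#' @param a,b Equal-length codon-aligned nucleotide strings.
#' @param gene Optional gene id carried into the result.
#' @param code Genetic code table.
#' @return A one-row tibble: `gene`, `codons` compared, `N`, `S`, `Nd`,
#'   `Sd`, `pN`, `pS`, `Ka`, `Ks`, `omega`, `classification`. `omega` is
#'   `NA` when `Ks = 0`; `pN` or `pS >= 3/4` makes the correction
#'   undefined (`NA`, classification `"undefined"`).
#' @export
pairwise_kaks <- function(a, b, gene = NA_character_,
                          code = Biostrings::GENETIC_CODE) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) rlang::abort("sequences must be aligned to equal length")
  if (nchar(a) %% 3 != 0) rlang::abort("alignment length must be a multiple of 3")
  nc <- nchar(a) / 3
  ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  is_stop <- function(x) vapply(
    x, function(cd) grepl("^[ACGT]{3}$", cd) && code[[cd]] == "*", logical(1))
  stop_a <- is_stop(ca); stop_b <- is_stop(cb)
  if (nc > 0 && stop_a[nc] && stop_b[nc]) {  # shared terminal stop
    ok[nc] <- FALSE
    stop_a[nc] <- stop_b[nc] <- FALSE
  }
  if (any(stop_a[ok]) || any(stop_b[ok])) {
    rlang::abort("internal stop codon in alignment")
  }
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) rlang::abort("no comparable codons")
  sites_a <- vapply(ca, function(cd) count_sites(cd, code), numeric(2))
  sites_b <- vapply(cb, function(cd) count_sites(cd, code), numeric(2))
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  diffs <- purrr::map2(ca, cb, codon_path_differences, code = code)
  Nd <- sum(purrr::map_dbl(diffs, "nd"))
  Sd <- sum(purrr::map_dbl(diffs, "sd"))
  pN <- Nd / N
  pS <- Sd / S
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  Ka <- jc(pN); Ks <- jc(pS)
  omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  cls <- if (is.na(Ka) || is.na(Ks)) "undefined" else classify_selection(omega)
  tibble::tibble(gene = gene, codons = length(ca), N = N, S = S,
                 Nd = Nd, Sd = Sd, pN = pN, pS = pS, Ka = Ka, Ks = Ks,
                 omega = omega, classification = cls)
}

# internal: average syn/nonsyn step counts over mutational pathways
codon_path_differences <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(list(nd = 0, sd = 0))
  perms <- permutations_of(pos)
  count_path <- function(order_pos) {
    cur <- c1
    nd <- 0; sd <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") return(NULL)  # pathway through a stop: excluded
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  paths <- purrr::compact(purrr::map(perms, count_path))
  if (length(paths) == 0) {  # every ordering blocked; fall back to all
    paths <- purrr::map(perms, function(order_pos) {
      cur <- c1; nd <- 0; sd <- 0
      for (p in order_pos) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- code[[cur]]; aa2 <- code[[nxt]]
        if (!identical(aa1, aa2)) nd <- nd + 1 else sd <- sd + 1
        cur <- nxt
      }
      c(nd = nd, sd = sd)
    })
  }
  mat <- do.call(rbind, paths)
  list(nd = mean(mat[, "nd"]), sd = mean(mat[, "sd"]))
}

# internal: all orderings of a short position vector
permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Classify selection from an omega (Ka/Ks) value
#'
#' `omega > 1` accelerated (positive) selection, `< 1` purifying, `= 1`
#' neutral; `omega > 5` is treated as an outlier (as in the study's removal
#' rule) and overrides; `NA` is `"undefined"`.
#'
#' @param omega Ka/Ks ratio (scalar or vector), `NA` allowed.
#' @return Character vector of classifications.
#' @export
classify_selection <- function(omega) {
  dplyr::case_when(
    is.na(omega) ~ "undefined",
    omega > 5 ~ "outlier",
    omega > 1 ~ "accelerated",
    omega < 1 ~ "purifying",
    TRUE ~ "neutral"
  )
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @return Named character vector of equal-length sequences (length a
#'   multiple of 3).
#' @export
read_codon_alignment <- function(path) {
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  if (length(unique(nchar(seqs))) != 1) {
    rlang::abort("alignment sequences have unequal lengths")
  }
  if (nchar(seqs[1]) %% 3 != 0) {
    rlang::abort("alignment length is not a multiple of 3")
  }
  seqs
}

#' Per-gene Ka/Ks table over a set of codon alignments
#'
#' Runs [pairwise_kaks()] between two chosen taxa for every gene
#' alignment.
#'
#' @param alignments Named list of codon alignments (named character
#'   vectors, e.g. from [read_codon_alignment()]); names are gene ids.
#' @param seq_a,seq_b Names (or indexes) of the two sequences to compare
#'   in each alignment (defaults: first and second).
#' @return Tibble with one row per gene, columns as in
#'   [pairwise_kaks()].
#' @export
kaks_table <- function(alignments, seq_a = 1, seq_b = 2) {
  purrr::imap_dfr(alignments, function(aln, gene) {
    pairwise_kaks(aln[[seq_a]], aln[[seq_b]], gene = gene)
  })
}
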