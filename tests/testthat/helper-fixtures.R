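# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# Quick genotype matrix from a calls matrix (rows = sites). SNP alleles by
# default; positions spread evenly unless given.
toy_geno <- function(calls, pos = NULL, genome_length = 134525L,
                     ref = NULL, alts = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ns <- nrow(calls)
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  }
  if (is.null(pos)) pos <- as.integer(seq(100, by = 100, length.out = ns))
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alts)) {
    alts <- lapply(seq_len(ns), function(i) {
      mx <- suppressWarnings(max(calls[i, ], na.rm = TRUE))
      nalt <- if (is.finite(mx)) max(1L, mx) else 1L
      c("G", "C", "T")[seq_len(nalt)]
    })
  }
  geno_matrix(tibble::tibble(pos = pos, ref = ref, alts = alts), calls,
              genome_length = genome_length)
}

# Random biallelic matrix with optional missingness (0/1 calls)
random_geno <- function(n_sites, n_samples, missing_rate = 0,
                        genome_length = 134525L) {
  calls <- matrix(rbinom(n_sites * n_samples, 1, runif(1, 0.2, 0.8)),
                  nrow = n_sites)
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  }
  pos <- sort(sample.int(genome_length, n_sites))
  toy_geno(calls, pos = pos, genome_length = genome_length)
}

# Independent oracle: nucleotide diversity as the average over sample pairs
# of per-site mismatch indicators, complete pairs only, divided by L.
brute_force_pi <- function(g, L = g$genome_length) {
  m <- g$calls
  n <- ncol(m)
  total <- 0
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        if (!is.na(x[a]) && !is.na(x[b])) {
          pairs <- pairs + 1
          if (x[a] != x[b]) diffs <- diffs + 1
        }
      }
    }
    if (pairs > 0) total <- total + diffs / pairs
  }
  total / L
}

# A two-group map over a geno's samples, split in half
half_split_map <- function(g, labels = c("a", "b")) {
  ids <- geno_samples(g)
  n <- length(ids)
  tibble::tibble(sample = ids,
                 group = rep(labels, c(ceiling(n / 2), floor(n / 2))))
}

# Write a small VCF text fixture and return its path
write_vcf_fixture <- function(lines, samples = c("s1", "s2")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chloroplast,length=134525>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}
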