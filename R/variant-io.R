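#' Read a multi-sample VCF into a haploid genotype matrix
#'
#' Parses a VCF (v4.x) of chloroplast variants. The chloroplast is effectively
#' haploid, but organelle variants are often diploid-coded by the caller:
#' homozygous diploid calls (`1/1`, `0|0`, ...) collapse to a single haploid
#' allele; heterozygous calls are treated as artifacts and become missing
#' (default) or the first-listed allele under `het = "major"`.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param genome_length Reference length in bp (default Nipponbare
#'   chloroplast, 134525).
#' @param het How to handle heterozygous diploid calls: `"missing"` (default)
#'   or `"major"` (keep the first allele of the genotype).
#' @return A [geno_matrix()] object.
#' @export
read_vcf <- function(path, genome_length = 134525L,
                     het = c("missing", "major")) {
  het <- match.arg(het)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) rlang::abort(paste0("VCF parse error: ", conditionMessage(e)))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) rlang::abort("VCF contains no variant records")
  if (ncol(v@gt) <= 1) rlang::abort("VCF contains zero samples")
  if (length(unique(fix[, "CHROM"])) > 1) {
    rlang::warn("VCF spans multiple reference sequences; expected a single chloroplast")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- parse_gt_calls(gt, het = het)
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alts = strsplit(fix[, "ALT"], ",", fixed = TRUE)
  )
  geno_matrix(sites, calls, genome_length = genome_length)
}

# internal: GT strings -> integer haploid allele matrix
parse_gt_calls <- function(gt, het = "missing") {
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  first <- sub(":.*$", "", gt)
  parts <- strsplit(first, "[/|]")
  n_het <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) == 0 || any(p == ".") || any(is.na(p))) next
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) next
    if (length(unique(a)) == 1L) {
      out[i] <- a[1]
    } else {
      n_het <- n_het + 1L
      if (het == "major") out[i] <- a[1]
    }
  }
  if (n_het > 0 && het == "missing") {
    rlang::inform(sprintf("%d heterozygous diploid call(s) set to missing", n_het))
  }
  out
}

#' Classify variants as SNP/InDel and transition/transversion
#'
#' A site is a SNP iff the reference and every alternate allele are single
#' nucleotides; anything else is an InDel. Substitution type is defined for
#' biallelic SNPs only: a transition swaps within purines `{A,G}` or
#' pyrimidines `{C,T}`, a transversion crosses the two classes.
#'
#' @param ref Character vector of reference alleles.
#' @param alts List of character vectors of alternate alleles (a plain
#'   character vector is treated as one alt per site).
#' @return A tibble with columns `vclass` (`"SNP"`/`"InDel"`) and `subst`
#'   (`"transition"`/`"transversion"`/`NA`).
#' @export
#' @examples
#' classify_variants(c("A", "A", "T"), list("G", "T", "TA"))
classify_variants <- function(ref, alts) {
  if (!is.list(alts)) alts <- as.list(alts)
  all_alleles <- c(ref, unlist(alts))
  if (any(!grepl("^[ACGT]+$", all_alleles))) {
    rlang::abort("alleles must be non-empty strings over {A,C,G,T}")
  }
  purines <- c("A", "G")
  out <- purrr::map2(ref, alts, function(r, a) {
    snp <- nchar(r) == 1 && all(nchar(a) == 1)
    subst <- NA_character_
    if (snp && length(a) == 1) {
      subst <- if ((r %in% purines) == (a %in% purines)) "transition" else "transversion"
    }
    list(vclass = if (snp) "SNP" else "InDel", subst = subst)
  })
  tibble::tibble(
    vclass = purrr::map_chr(out, "vclass"),
    subst = purrr::map_chr(out, "subst")
  )
}

#' Filter variants on missingness and minor allele frequency
#'
#' Applies the study's high-quality filter: a site is removed when its
#' missing-call fraction is strictly greater than `max_missing` or its minor
#' allele frequency is strictly below `min_maf` (MAF computed among
#' non-missing calls only). Site order is preserved; retained/removed counts
#' are attached as the `"filter_counts"` attribute and messaged.
#'
#' @param g A `chloro_geno`.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return The filtered `chloro_geno`.
#' @export
filter_variants <- function(g, max_missing = 0.20, min_maf = 0.01) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  if (n_sites(g) == 0) rlang::abort("empty genotype matrix")
  keep <- site_missing_rate(g) <= max_missing & site_maf(g) >= min_maf
  keep[is.na(keep)] <- FALSE
  out <- slice_sites(g, which(keep))
  counts <- c(retained = sum(keep), removed = sum(!keep))
  attr(out, "filter_counts") <- counts
  rlang::inform(sprintf("retained %d site(s), removed %d", counts[1], counts[2]))
  out
}

#' Transition/transversion ratio
#'
#' Counts transitions and transversions among biallelic SNPs. Returns `Inf`
#' when no transversions are present.
#'
#' @param g A `chloro_geno`.
#' @return A single number, `#transitions / #transversions`.
#' @export
tstv_ratio <- function(g) {
  subst <- g$sites$subst[g$sites$vclass == "SNP"]
  subst <- subst[!is.na(subst)]
  if (length(subst) == 0) rlang::abort("no biallelic SNPs to compute Ts/Tv")
  ts <- sum(subst == "transition")
  tv <- sum(subst == "transversion")
  if (tv == 0) return(Inf)
  ts / tv
}

#' Annotate variants as coding or noncoding
#'
#' Marks each site `coding` when its position falls inside any gene interval
#' (1-based inclusive), `noncoding` otherwise.
#'
#' @param g A `chloro_geno`.
#' @param genes Either a data frame with columns `start`, `end`, or the path
#'   to a GFF3 file (rows with `type == "gene"` are used).
#' @return The `chloro_geno` with its `region` column filled.
#' @export
annotate_regions <- function(g, genes) {
  if (is.character(genes) && length(genes) == 1) {
    gff <- ape::read.gff(genes)
    genes <- gff[gff$type == "gene", c("start", "end")]
  }
  genes <- tibble::as_tibble(genes)
  if (any(genes$end < genes$start)) rlang::abort("gene interval with end < start")
  inside <- vapply(g$sites$pos, function(p) {
    any(p >= genes$start & p <= genes$end)
  }, logical(1))
  g$sites$region <- ifelse(inside, "coding", "noncoding")
  g
}

#' Variant density per kilobase
#'
#' Number of sites polymorphic within a sample subset (two or more distinct
#' non-missing alleles), per kb of genome.
#'
#' @param g A `chloro_geno`.
#' @param samples Sample ids to consider (default: all).
#' @return Variants per kb.
#' @export
variant_density <- function(g, samples = NULL) {
  if (g$genome_length <= 0) rlang::abort("genome_length must be positive")
  if (!is.null(samples)) {
    if (length(samples) == 0) rlang::abort("empty sample subset")
    g <- select_samples(g, samples)
  }
  if (n_samples(g) == 0) rlang::abort("empty sample subset")
  poly <- sum(site_allele_number(g) >= 2)
  poly / (g$genome_length / 1000)
}

#' Write a genotype matrix to a VCF v4.2 file
#'
#' Emits haploid GT calls (`0`, `1`, ..., `.` for missing), suitable for
#' round-tripping through [read_vcf()].
#'
#' @param g A `chloro_geno`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", g$sites$chrom[1] %||% "chloroplast",
            g$genome_length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno_samples(g)), collapse = "\t")
  )
  gt <- g$calls
  gt_chr <- matrix(as.character(gt), nrow = nrow(gt))
  gt_chr[is.na(gt)] <- "."
  body <- vapply(seq_len(n_sites(g)), function(i) {
    paste(c(g$sites$chrom[i], g$sites$pos[i], ".", g$sites$ref[i],
            paste(g$sites$alts[[i]], collapse = ","), ".", "PASS", ".",
            "GT", gt_chr[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-site summary table
#'
#' @param g A `chloro_geno`.
#' @return A tibble with one row per site: `pos`, `ref`, `alt` (comma-joined),
#'   `vclass`, `subst`, `region`, `missing_rate`, `maf`, `k` (allele count).
#' @export
site_summary <- function(g) {
  tibble::tibble(
    pos = g$sites$pos,
    ref = g$sites$ref,
    alt = purrr::map_chr(g$sites$alts, paste, collapse = ","),
    vclass = g$sites$vclass,
    subst = g$sites$subst,
    region = g$sites$region,
    missing_rate = site_missing_rate(g),
    maf = site_maf(g),
    k = site_allele_number(g)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
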