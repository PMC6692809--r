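#' Per-site derived-allele frequency within a group
#'
#' Frequency of the non-reference (derived) allele among the group's
#' non-missing calls; with no outgroup polarisation described for the
#' chloroplast data, "derived" means any allele other than the reference
#' (Nipponbare NC_001320).
#'
#' @param g A `chloro_geno`.
#' @param pm Population map tibble.
#' @param group Group label (vectors allowed; pooled).
#' @return Tibble with `pos` and `freq` (`NA` when the group has no
#'   non-missing call at the site).
#' @export
group_allele_freq <- function(g, pm, group) {
  pm <- pop_map(pm)
  ids <- intersect(pop_samples(pm, group), geno_samples(g))
  if (length(ids) == 0) rlang::abort("group has no samples present in the matrix")
  m <- g$calls[, ids, drop = FALSE]
  freq <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x != 0)
  })
  tibble::tibble(pos = g$sites$pos, freq = freq)
}

#' Classify group-specific (potentially introgressed) sites
#'
#' A site is `japonica_specific` when its derived-allele frequency is
#' strictly above `high` in japonica and strictly below `low` in indica;
#' `indica_specific` by the mirrored rule; `shared` when above `high` in
#' both; `none` otherwise. Wild-rice presence of the derived allele is
#' recorded as a flag (the study restricts to alleles undetected in wild
#' rice); `exclude_wild` applies that restriction strictly.
#'
#' @param freq_i,freq_j Frequency tibbles from [group_allele_freq()] for
#'   indica and japonica (aligned site lists).
#' @param freq_wild Optional frequency tibble for wild rice.
#' @param high,low Frequency thresholds (defaults 0.95 / 0.05, strict
#'   inequalities).
#' @param exclude_wild Demote sites whose derived allele occurs in wild
#'   rice to `none` (default `FALSE`: flag only).
#' @return Tibble with `pos`, `freq_indica`, `freq_japonica`, `freq_wild`,
#'   `wild_presence`, `status`.
#' @export
classify_specific_sites <- function(freq_i, freq_j, freq_wild = NULL,
                                    high = 0.95, low = 0.05,
                                    exclude_wild = FALSE) {
  if (nrow(freq_i) != nrow(freq_j) || any(freq_i$pos != freq_j$pos)) {
    rlang::abort("site lists of the two groups are not aligned")
  }
  fw <- if (is.null(freq_wild)) rep(NA_real_, nrow(freq_i)) else {
    if (any(freq_wild$pos != freq_i$pos)) rlang::abort("wild site list not aligned")
    freq_wild$freq
  }
  fi <- freq_i$freq
  fj <- freq_j$freq
  status <- dplyr::case_when(
    is.na(fi) | is.na(fj) ~ NA_character_,
    fj > high & fi < low ~ "japonica_specific",
    fi > high & fj < low ~ "indica_specific",
    fi > high & fj > high ~ "shared",
    TRUE ~ "none"
  )
  wild_presence <- !is.na(fw) & fw > 0
  if (exclude_wild) {
    status[wild_presence & status %in% c("indica_specific", "japonica_specific")] <- "none"
  }
  tibble::tibble(
    pos = freq_i$pos, freq_indica = fi, freq_japonica = fj, freq_wild = fw,
    wild_presence = wild_presence, status = status
  )
}

#' Joint allele-frequency table for two groups
#'
#' Counts sites per pair of frequency bins, the two-dimensional spectrum
#' used to visualise whether the groups share intermediate-frequency
#' alleles. Bin edges are `[0, 1/bins), ..., [1 - 1/bins, 1]` (last bin
#' closed).
#'
#' @param freq_i,freq_j Frequency tibbles from [group_allele_freq()].
#' @param bins Number of bins per axis (default 10).
#' @return Tibble with `bin_i`, `bin_j` (interval labels), `n`. Sites with
#'   either frequency missing are dropped.
#' @export
joint_frequency_table <- function(freq_i, freq_j, bins = 10) {
  stopifnot(bins >= 2)
  ok <- !is.na(freq_i$freq) & !is.na(freq_j$freq)
  edges <- seq(0, 1, length.out = bins + 1)
  cut_bin <- function(x) cut(x, breaks = edges, include.lowest = TRUE,
                             right = FALSE)
  # right = FALSE makes [a, b) bins; values of exactly 1 fall in the last
  # bin thanks to include.lowest on the reversed side, so patch them in:
  bin_of <- function(x) {
    b <- as.integer(cut_bin(pmin(x, 1 - 1e-12)))
    b[x >= 1] <- bins
    b
  }
  labs <- sprintf("[%.2g,%.2g%s", edges[-length(edges)], edges[-1],
                  c(rep(")", bins - 1), "]"))
  bi <- factor(labs[bin_of(freq_i$freq[ok])], levels = labs)
  bj <- factor(labs[bin_of(freq_j$freq[ok])], levels = labs)
  out <- tibble::as_tibble(as.data.frame(table(bin_i = bi, bin_j = bj),
                                         stringsAsFactors = FALSE))
  names(out)[3] <- "n"
  out$n <- as.integer(out$n)
  out
}

#' Per-accession profile of group-specific alleles
#'
#' For every accession, counts how many classified indica-specific and
#' japonica-specific derived alleles it carries, and flags accessions of
#' the indica or japonica groups that carry the *opposite* group's
#' specific alleles above a threshold fraction as candidate
#' introgressants.
#'
#' @param g A `chloro_geno`.
#' @param sites Classified site tibble from [classify_specific_sites()].
#' @param pm Population map tibble.
#' @param indica_groups,japonica_groups Labels making up the two sides
#'   (defaults `"indica"` and the two japonica subgroups).
#' @param threshold Opposite-type carried fraction above which an
#'   accession becomes a `candidate_introgressant` (default 0.10).
#' @return Tibble with `sample`, `group`, `n_indica_specific_carried`,
#'   `n_japonica_specific_carried`, `opposite_fraction`, `verdict`
#'   (`"none"` / `"candidate_introgressant"`, `NA` for accessions outside
#'   both sides).
#' @export
accession_allele_profile <- function(g, sites, pm,
                                     indica_groups = "indica",
                                     japonica_groups = c("temperate_japonica",
                                                         "tropical_japonica"),
                                     threshold = 0.10) {
  cls <- sites[!is.na(sites$status) &
                 sites$status %in% c("indica_specific", "japonica_specific"), ,
               drop = FALSE]
  if (nrow(cls) == 0) rlang::abort("no classified group-specific sites")
  pm <- pop_map(pm)
  idx <- match(cls$pos, g$sites$pos)
  if (anyNA(idx)) rlang::abort("classified sites missing from the genotype matrix")
  carried <- g$calls[idx, , drop = FALSE] != 0  # derived carried (NA kept)
  is_ind <- cls$status == "indica_specific"
  n_ind <- colSums(carried[is_ind, , drop = FALSE], na.rm = TRUE)
  n_jap <- colSums(carried[!is_ind, , drop = FALSE], na.rm = TRUE)
  seen_ind <- colSums(!is.na(carried[is_ind, , drop = FALSE]))
  seen_jap <- colSums(!is.na(carried[!is_ind, , drop = FALSE]))
  out <- tibble::tibble(sample = geno_samples(g)) |>
    dplyr::left_join(pm, by = "sample")
  side <- dplyr::case_when(
    out$group %in% indica_groups ~ "indica",
    out$group %in% japonica_groups ~ "japonica",
    TRUE ~ NA_character_
  )
  opp_n <- ifelse(side == "indica", n_jap, n_ind)
  opp_seen <- ifelse(side == "indica", seen_jap, seen_ind)
  opp_frac <- ifelse(is.na(side) | opp_seen == 0, NA_real_, opp_n / opp_seen)
  out$n_indica_specific_carried <- as.integer(n_ind)
  out$n_japonica_specific_carried <- as.integer(n_jap)
  out$opposite_fraction <- opp_frac
  out$verdict <- dplyr::case_when(
    is.na(side) ~ NA_character_,
    !is.na(opp_frac) & opp_frac > threshold ~ "candidate_introgressant",
    TRUE ~ "none"
  )
  out
}
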