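#' Windowed diversity-reduction ratio
#'
#' Per-window ratio of nucleotide diversity in a reference group (typically
#' wild rice) to diversity in a focal cultivated group, the classic
#' domestication-sweep signal: windows where the cultivated group has lost
#' most of the reference diversity show large `pi_w / pi_c`.
#'
#' @param wild_windows,cult_windows Window tibbles from
#'   [nucleotide_diversity()] on the *same* grid.
#' @param floor Denominator floor: windows with `pi_c < floor` get `NA`
#'   ratios (default `1e-9`), keeping monomorphic windows out of the
#'   percentile ranking.
#' @return Tibble with `start`, `end`, `pi_w`, `pi_c`, `ratio`.
#' @export
diversity_ratio_scan <- function(wild_windows, cult_windows, floor = 1e-9) {
  if (nrow(wild_windows) != nrow(cult_windows) ||
      any(wild_windows$start != cult_windows$start) ||
      any(wild_windows$end != cult_windows$end)) {
    rlang::abort("window grids differ between the two scans")
  }
  tibble::tibble(
    start = wild_windows$start,
    end = wild_windows$end,
    pi_w = wild_windows$pi,
    pi_c = cult_windows$pi,
    ratio = dplyr::if_else(
      is.na(wild_windows$pi) | is.na(cult_windows$pi) | cult_windows$pi < floor,
      NA_real_,
      wild_windows$pi / cult_windows$pi
    )
  )
}

#' Call candidate selection regions from a ratio scan
#'
#' Ranks the defined (non-`NA`) window ratios, takes the
#' `(100 - percentile)`-th percentile (linear interpolation) as cutoff,
#' selects every window with `ratio >= cutoff` (ties at the cutoff
#' included), and merges adjacent or overlapping selected windows into
#' regions.
#'
#' @param ratios Tibble from [diversity_ratio_scan()].
#' @param percentile Top tail size in percent (default 2.5).
#' @return Tibble with one row per merged region: `region`, `start`, `end`,
#'   `n_windows`, `peak_ratio`. The cutoff value and the selected-window
#'   count are attached as attributes `"cutoff"` and `"n_selected"`.
#' @export
candidate_regions <- function(ratios, percentile = 2.5) {
  defined <- ratios[!is.na(ratios$ratio), , drop = FALSE]
  if (nrow(defined) == 0) rlang::abort("all window ratios are NA")
  cutoff <- stats::quantile(defined$ratio, probs = 1 - percentile / 100,
                            names = FALSE, type = 7)
  sel <- defined[defined$ratio >= cutoff, , drop = FALSE]
  sel <- dplyr::arrange(sel, .data$start)
  regions <- merge_windows(sel)
  regions <- dplyr::mutate(regions, region = dplyr::row_number(), .before = 1)
  attr(regions, "cutoff") <- cutoff
  attr(regions, "n_selected") <- nrow(sel)
  regions
}

# internal: merge sorted windows that touch or overlap
merge_windows <- function(w) {
  if (nrow(w) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_windows = integer(), peak_ratio = numeric()))
  }
  out <- list()
  cur_start <- w$start[1]; cur_end <- w$end[1]
  cur_n <- 1L; cur_peak <- w$ratio[1]
  if (nrow(w) > 1) {
    for (i in seq(2, nrow(w))) {
      if (w$start[i] <= cur_end + 1) {
        cur_end <- max(cur_end, w$end[i])
        cur_n <- cur_n + 1L
        cur_peak <- max(cur_peak, w$ratio[i])
      } else {
        out[[length(out) + 1]] <- tibble::tibble(
          start = cur_start, end = cur_end, n_windows = cur_n,
          peak_ratio = cur_peak)
        cur_start <- w$start[i]; cur_end <- w$end[i]
        cur_n <- 1L; cur_peak <- w$ratio[i]
      }
    }
  }
  out[[length(out) + 1]] <- tibble::tibble(
    start = cur_start, end = cur_end, n_windows = cur_n, peak_ratio = cur_peak)
  dplyr::bind_rows(out)
}
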