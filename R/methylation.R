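# Cytosine-context DNA methylation levels.
#
# The per-site level is mc / (mc + umc); sites with zero coverage are
# undefined and excluded from aggregates (they are never counted as 0).
# Region levels are read-weighted: sum(mc) / sum(mc + umc) over covered
# sites of a context inside the region, both strands pooled. The weighted
# form is additive in the numerator and denominator, so splitting a region
# and recombining counts is exact.

METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Per-site methylation level
#'
#' Adds a `level` column, `mc / (mc + umc)`, `NA` at zero coverage.
#'
#' @param cx Cytosine tibble from [read_cx_report()].
#' @return `cx` with a `level` column.
#' @export
site_level <- function(cx) {
  stopifnot(all(c("mc", "umc") %in% names(cx)))
  tot <- cx$mc + cx$umc
  dplyr::mutate(cx, level = ifelse(tot > 0, .data$mc / tot, NA_real_))
}

#' Read-weighted methylation level of regions, by context
#'
#' For each region and cytosine context, computes
#' `sum(mc) / sum(mc + umc)` over the covered sites falling inside the
#' region (strand ignored; both strands pooled). Regions or contexts with
#' no covered sites are reported with `level = NA` and `covered_sites = 0`.
#'
#' @param cx Cytosine tibble.
#' @param regions Interval tibble with a `region_id` column (or `id`, which
#'   is renamed).
#' @param contexts Contexts to report (default all three).
#' @param min_coverage Minimum reads for a site to count as covered
#'   (default 1, i.e. no filter beyond non-zero coverage).
#' @return Tibble `region_id`, `context`, `level`, `covered_sites`,
#'   `total_reads`.
#' @export
region_methylation <- function(cx, regions, contexts = METH_CONTEXTS,
                               min_coverage = 1L) {
  if (!"region_id" %in% names(regions)) {
    if ("id" %in% names(regions)) {
      regions <- dplyr::rename(regions, region_id = "id")
    } else {
      regions$region_id <- paste0("region_", seq_len(nrow(regions)))
    }
  }
  grid <- tidyr::expand_grid(region_id = regions$region_id, context = contexts)
  sites <- cx %>% dplyr::filter(.data$mc + .data$umc >= min_coverage,
                                .data$context %in% contexts)
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    return(grid %>% dplyr::mutate(level = NA_real_, covered_sites = 0L,
                                  total_reads = 0))
  }
  prs <- overlap_pairs(sites, regions, stranded = FALSE)
  agg <- tibble(
    region_id = regions$region_id[prs$subject_row],
    context = sites$context[prs$query_row],
    mc = sites$mc[prs$query_row],
    tot = sites$mc[prs$query_row] + sites$umc[prs$query_row]
  ) %>%
    dplyr::group_by(.data$region_id, .data$context) %>%
    dplyr::summarise(level = sum(.data$mc) / sum(.data$tot),
                     covered_sites = dplyr::n(),
                     total_reads = sum(.data$tot), .groups = "drop")
  grid %>%
    dplyr::left_join(agg, by = c("region_id", "context")) %>%
    dplyr::mutate(covered_sites = tidyr::replace_na(.data$covered_sites, 0L),
                  total_reads = tidyr::replace_na(.data$total_reads, 0))
}
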