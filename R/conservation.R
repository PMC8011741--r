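# Cross-species homology: HSP chaining, query coverage, and RT-PCR band
# matrix summaries.
#
# Tabular BLAST HSPs are chained per (query, target genome): within each
# (query, subject sequence, subject strand) group, dynamic programming over
# HSPs sorted by query start selects the highest-total-bitscore chain that
# is colinear in both query and subject with inter-HSP subject gaps of at
# most max_gap. The best-scoring group across subjects yields the
# representative homologous region; query coverage is the merged length of
# the chained query intervals divided by the query length, so overlapping
# HSPs are never double-counted.

#' Chain HSPs into one representative homology call per query and genome
#'
#' @param hsps HSP tibble ([read_hsp_table()]); rows above the e-value
#'   cutoff are dropped, and fully duplicated rows are de-duplicated.
#' @param query_lengths Tibble `query_id`, `query_length` (nt), or a model
#'   tibble with `id` + `length` columns.
#' @param max_gap Maximum subject-side gap between chained HSPs, in bases
#'   (default 10000).
#' @param evalue_cutoff Keep HSPs with `evalue <= cutoff` (default 1e-10).
#' @return Tibble `query_id`, `genome`, `subject_id`, `strand`, `n_hsps`,
#'   `total_score`, `aligned_length`, `query_length`, `coverage`. Queries
#'   with no surviving HSP for a genome in `hsps` get `coverage = 0` rows
#'   for that genome.
#' @export
chain_hsps <- function(hsps, query_lengths, max_gap = 10000, evalue_cutoff = 1e-10) {
  if ("id" %in% names(query_lengths) && !"query_id" %in% names(query_lengths)) {
    query_lengths <- dplyr::transmute(query_lengths, query_id = .data$id,
                                      query_length = .data$length)
  }
  stopifnot(all(c("query_id", "query_length") %in% names(query_lengths)))
  genomes <- unique(hsps$genome)
  keep <- hsps %>%
    dplyr::filter(.data$evalue <= evalue_cutoff) %>%
    dplyr::distinct()
  grid <- tidyr::expand_grid(query_id = unique(query_lengths$query_id),
                             genome = genomes)
  calls <- if (nrow(keep)) {
    keep %>%
      dplyr::group_by(.data$query_id, .data$genome, .data$subject_id,
                      .data$subject_strand) %>%
      dplyr::group_modify(~ chain_one_group(.x, .y, max_gap)) %>%
      dplyr::ungroup() %>%
      dplyr::group_by(.data$query_id, .data$genome) %>%
      dplyr::slice_max(.data$total_score, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup()
  } else {
    tibble(query_id = character(), genome = character(),
           subject_id = character(), subject_strand = character(),
           n_hsps = integer(), total_score = numeric(),
           aligned_length = numeric())
  }
  grid %>%
    dplyr::left_join(calls, by = c("query_id", "genome")) %>%
    dplyr::left_join(query_lengths, by = "query_id") %>%
    dplyr::mutate(
      n_hsps = tidyr::replace_na(.data$n_hsps, 0L),
      total_score = tidyr::replace_na(.data$total_score, 0),
      aligned_length = tidyr::replace_na(.data$aligned_length, 0),
      coverage = pmin(1, .data$aligned_length / .data$query_length)
    ) %>%
    dplyr::rename(strand = "subject_strand")
}

# DP over the HSPs of one (query, subject, strand) group. Successor j of i
# must satisfy query colinearity (query_start_j >= query_start_i) and
# subject colinearity in the strand direction with a subject gap <= max_gap
# (negative gaps, i.e. subject overlap, always allowed).
chain_one_group <- function(g, key, max_gap) {
  minus <- key$subject_strand == "-"
  s_lo <- pmin(g$subject_start, g$subject_end)
  s_hi <- pmax(g$subject_start, g$subject_end)
  ord <- order(g$query_start, g$query_end, s_lo)
  g <- g[ord, ]; s_lo <- s_lo[ord]; s_hi <- s_hi[ord]
  n <- nrow(g)
  score <- g$bitscore
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)[-1]) {
    for (i in seq_len(j - 1)) {
      ok_q <- g$query_start[j] >= g$query_start[i] &&
        g$query_end[j] >= g$query_end[i]
      gap_s <- if (minus) s_lo[i] - s_hi[j] else s_lo[j] - s_hi[i]
      ok_s <- if (minus) s_hi[j] <= s_hi[i] && s_lo[j] <= s_lo[i]
              else s_lo[j] >= s_lo[i] && s_hi[j] >= s_hi[i]
      if (ok_q && ok_s && gap_s <= max_gap && score[i] + g$bitscore[j] > score[j]) {
        score[j] <- score[i] + g$bitscore[j]
        prev[j] <- i
      }
    }
  }
  best <- which.max(score)
  chain <- best
  while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
  # merged query footprint (1-based inclusive BLAST coordinates)
  qiv <- IRanges::reduce(IRanges::IRanges(g$query_start[chain], g$query_end[chain]))
  tibble(
    n_hsps = length(chain),
    total_score = score[best],
    aligned_length = sum(IRanges::width(qiv))
  )
}

#' Per-class, per-genome coverage summary
#'
#' @param calls Output of [chain_hsps()].
#' @param classes Tibble `transcript_id`/`query_id` + `class` (a classified
#'   model tibble with `id` also works).
#' @param thresholds Coverage thresholds for the `frac_ge_*` columns.
#' @return Tibble per class x genome: `n`, quartiles, `mean_coverage` and
#'   the fraction of queries at or above each threshold.
#' @export
coverage_summary <- function(calls, classes, thresholds = c(0.5, 0.8)) {
  if ("id" %in% names(classes)) {
    classes <- dplyr::transmute(classes, query_id = .data$id, class = .data$class)
  }
  if ("transcript_id" %in% names(classes)) {
    classes <- dplyr::rename(classes, query_id = "transcript_id")
  }
  d <- dplyr::inner_join(calls, classes[, c("query_id", "class")], by = "query_id")
  base <- d %>%
    dplyr::group_by(.data$class, .data$genome) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_coverage = mean(.data$coverage),
      q25 = quantile(.data$coverage, 0.25),
      median_coverage = median(.data$coverage),
      q75 = quantile(.data$coverage, 0.75),
      .groups = "drop"
    )
  for (th in thresholds) {
    col <- paste0("frac_ge_", format(th, trim = TRUE))
    fr <- d %>%
      dplyr::group_by(.data$class, .data$genome) %>%
      dplyr::summarise(!!col := mean(.data$coverage >= th), .groups = "drop")
    base <- dplyr::left_join(base, fr, by = c("class", "genome"))
  }
  base
}

#' Summarise an RT-PCR band matrix by line group
#'
#' "Expressed" means a strong band (`+++`); weak (`+`) and absent (`-`)
#' bands do not count. For each named group of lines the distribution of
#' rows by the number of lines with a strong band is returned.
#'
#' @param matrix_tbl Band matrix ([read_band_matrix()]): first column ids,
#'   remaining columns one per line.
#' @param line_groups Named list of character vectors of line columns.
#' @return Tibble `line_group`, `n_lines`, `n_strong` (0..n_lines),
#'   `n_rows`; rows with `n_strong = n_lines` are expressed in all lines,
#'   rows with `n_strong = 0` are not (or only slightly) expressed.
#' @export
band_summary <- function(matrix_tbl, line_groups) {
  cells <- unlist(matrix_tbl[, -1])
  if (!all(cells %in% c("+++", "+", "-"))) stop("unknown band symbol(s)")
  purrr::imap_dfr(line_groups, function(cols, grp) {
    miss <- setdiff(cols, names(matrix_tbl))
    if (length(miss)) stop("line(s) not in matrix: ", paste(miss, collapse = ", "))
    strong <- rowSums(matrix_tbl[, cols, drop = FALSE] == "+++")
    tibble(line_group = grp, n_lines = length(cols),
           n_strong = 0:length(cols)) %>%
      dplyr::mutate(n_rows = vapply(.data$n_strong,
                                    function(k) sum(strong == k), numeric(1)))
  })
}
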