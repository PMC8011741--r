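# Per-transcript chromatin-mark status and stratification tables.
#
# A transcript is IRR-positive (inverted repeat region, RepeatMasker-style
# annotation) or H3K27me3-positive when its span shares >= 1 bp with any
# mark interval (threshold configurable in bases or as a fraction of the
# transcript). The stratification table is the headline summary: counts and
# one-decimal percentages of each class with (+) and without (-) each mark.

#' One-decimal percentage, rounded half away from zero
#'
#' `100 * n / d` rounded to one decimal with ties going away from zero —
#' the convention used when reporting "k of n (xx.x%)" style counts.
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @return Numeric percentage(s) with one decimal.
#' @export
#' @examples
#' percent1(66, 92) # 71.7
percent1 <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

# span or exon-level overlap of transcripts with mark intervals
mark_overlap_status <- function(transcripts, marks, stranded = FALSE,
                                exon_only = FALSE, min_overlap = 1L,
                                min_fraction = 0) {
  if (nrow(transcripts) == 0) return(logical(0))
  if (is.null(marks) || nrow(marks) == 0) return(rep(FALSE, nrow(transcripts)))
  qry <- if (exon_only) model_exons(transcripts) else transcripts
  prs <- overlap_pairs(qry, marks, stranded = stranded, min_overlap = min_overlap)
  if (min_fraction > 0) {
    key <- if (exon_only) qry$id[prs$query_row] else transcripts$id[prs$query_row]
    ov <- tibble(id = key, overlap = prs$overlap) %>%
      dplyr::group_by(.data$id) %>%
      dplyr::summarise(overlap = sum(.data$overlap), .groups = "drop")
    len <- transcripts$length
    m <- match(transcripts$id, ov$id)
    frac <- ifelse(is.na(m), 0, ov$overlap[m] / (transcripts$end - transcripts$start))
    return(frac >= min_fraction)
  }
  hit_ids <- if (exon_only) unique(qry$id[prs$query_row]) else unique(transcripts$id[prs$query_row])
  transcripts$id %in% hit_ids
}

#' Per-transcript IRR overlap status
#'
#' @param transcripts Model tibble.
#' @param irrs Interval tibble of inverted repeat regions (BED-derived).
#' @param stranded Strand-aware overlap? Default `FALSE` (repeat
#'   annotations are typically unstranded).
#' @param exon_only Score overlap against exons only instead of the span.
#' @param min_overlap Minimum shared bases (default 1).
#' @return Tibble `transcript_id`, `irr` (logical).
#' @export
irr_status <- function(transcripts, irrs, stranded = FALSE, exon_only = FALSE,
                       min_overlap = 1L) {
  tibble(transcript_id = transcripts$id,
         irr = mark_overlap_status(transcripts, irrs, stranded = stranded,
                                   exon_only = exon_only,
                                   min_overlap = min_overlap))
}

#' Per-transcript H3K27me3 status
#'
#' @param transcripts Model tibble.
#' @param domains Interval tibble of H3K27me3 domains.
#' @param min_overlap Minimum shared bases (default 1).
#' @param min_fraction Alternatively require this fraction of the span to
#'   be covered (0 disables).
#' @param exon_only Score overlap against exons only.
#' @return Tibble `transcript_id`, `k27` (logical).
#' @export
k27_status <- function(transcripts, domains, min_overlap = 1L,
                       min_fraction = 0, exon_only = FALSE) {
  tibble(transcript_id = transcripts$id,
         k27 = mark_overlap_status(transcripts, domains, exon_only = exon_only,
                                   min_overlap = min_overlap,
                                   min_fraction = min_fraction))
}

#' Combined per-transcript mark status
#'
#' Convenience wrapper computing IRR, siRNA (containment) and H3K27me3
#' status for classified transcripts in one call.
#'
#' @param transcripts Classified model tibble (column `class`).
#' @param irrs,domains Mark interval tibbles (either may be `NULL`).
#' @param reads24 24-nt unique read tibble (may be `NULL`).
#' @param ... Passed to [sirna_overlap_status()].
#' @return Tibble `transcript_id`, `class`, `irr`, `sirna`, `k27`.
#' @export
mark_status <- function(transcripts, irrs = NULL, reads24 = NULL,
                        domains = NULL, ...) {
  out <- tibble(transcript_id = transcripts$id, class = transcripts$class)
  out$irr <- mark_overlap_status(transcripts, irrs)
  out$sirna <- if (is.null(reads24)) rep(FALSE, nrow(out)) else {
    sirna_overlap_status(transcripts, reads24 = reads24, ...)$sirna
  }
  out$k27 <- mark_overlap_status(transcripts, domains)
  out
}

#' Stratification table: class x mark x status
#'
#' Counts and one-decimal percentages of transcripts with (+) and without
#' (-) each mark, per class — the headline "k of n (xx.x%)" numbers.
#'
#' @param statuses Tibble from [mark_status()] (columns `class` plus one
#'   logical column per mark).
#' @param marks Mark columns to tabulate.
#' @param classes Classes to report, in order; empty ones are dropped with
#'   a warning.
#' @return Tibble `class`, `mark`, `status` (`"+"`/`"-"`), `count`,
#'   `class_total`, `percent`.
#' @export
stratify <- function(statuses, marks = c("irr", "sirna", "k27"),
                     classes = LNC_CLASSES) {
  marks <- intersect(marks, names(statuses))
  present <- intersect(classes, unique(statuses$class))
  absent <- setdiff(classes, present)
  if (length(absent)) warning("empty class(es) omitted: ", paste(absent, collapse = ", "))
  long <- statuses %>%
    dplyr::filter(.data$class %in% present) %>%
    tidyr::pivot_longer(dplyr::all_of(marks), names_to = "mark",
                        values_to = "positive")
  grid <- tidyr::expand_grid(class = present, mark = marks,
                             status = c("+", "-"))
  counts <- long %>%
    dplyr::mutate(status = ifelse(.data$positive, "+", "-")) %>%
    dplyr::count(.data$class, .data$mark, .data$status, name = "count")
  grid %>%
    dplyr::left_join(counts, by = c("class", "mark", "status")) %>%
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    dplyr::group_by(.data$class, .data$mark) %>%
    dplyr::mutate(class_total = sum(.data$count),
                  percent = percent1(.data$count, .data$class_total)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(class = factor(.data$class, levels = present)) %>%
    dplyr::arrange(.data$mark, .data$class, dplyr::desc(.data$status))
}

#' Joint IRR x siRNA table
#'
#' Cross-tabulation of IRR and siRNA status per class, from which the
#' conditional fraction "of siRNA-overlapping transcripts, how many also
#' harbour IRRs" is read off.
#'
#' @inheritParams stratify
#' @return Tibble `class`, `irr`, `sirna`, `count` plus per-class
#'   `sirna_total` and `frac_irr_given_sirna` on the `sirna = TRUE` rows.
#' @export
joint_irr_sirna <- function(statuses, classes = LNC_CLASSES) {
  present <- intersect(classes, unique(statuses$class))
  tab <- statuses %>%
    dplyr::filter(.data$class %in% present) %>%
    dplyr::count(.data$class, .data$irr, .data$sirna, name = "count") %>%
    tidyr::complete(class = present, irr = c(TRUE, FALSE),
                    sirna = c(TRUE, FALSE), fill = list(count = 0L))
  cond <- tab %>%
    dplyr::filter(.data$sirna) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(sirna_total = sum(.data$count),
                  frac_irr_given_sirna = ifelse(.data$sirna_total > 0,
                                                .data$count / .data$sirna_total,
                                                NA_real_)) %>%
    dplyr::ungroup()
  dplyr::left_join(
    tab,
    cond %>% dplyr::select("class", "irr", "sirna", "sirna_total",
                           "frac_irr_given_sirna"),
    by = c("class", "irr", "sirna")
  )
}

#' Derive H3K27me3 domains from a bedGraph coverage track
#'
#' A labelled convenience for when only per-base coverage is available:
#' positions with coverage `>= min_value` are thresholded, merged across
#' gaps of at most `gap` bases, and merged intervals shorter than
#' `min_width` are dropped. This is a simple threshold deriver, not a
#' ChIP-seq peak caller with a background model.
#'
#' @param bg bedGraph tibble ([read_bedgraph()]).
#' @param min_value Coverage threshold.
#' @param min_width Minimum domain width in bases.
#' @param gap Merge gap in bases (default 0).
#' @return Interval tibble of domains.
#' @export
domains_from_bedgraph <- function(bg, min_value, min_width = 100L, gap = 0L) {
  hi <- bg %>% dplyr::filter(.data$value >= min_value)
  if (nrow(hi) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character()))
  }
  reduce_intervals(hi %>% dplyr::mutate(strand = "."), gap = gap) %>%
    dplyr::filter(.data$end - .data$start >= min_width)
}
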