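# Positional classification of assembled transcripts.
#
# The classes follow the standard positional taxonomy of plant lncRNAs:
#   NAT      - natural antisense transcript, exon-overlapping a gene on the
#              opposite strand;
#   incRNA   - intronic noncoding RNA, span fully inside a single intron;
#   putative_mRNA - intergenic transcript with a protein-database hit;
#   lincRNA  - intergenic, no hit, longer than the lncRNA length floor;
#   unclassified - anything failing all rules (e.g. sense-overlapping,
#              non-intronic transcripts, or short intergenic fragments).
# Precedence NAT > incRNA > intergenic rules; every transcript receives
# exactly one label.

LNC_CLASSES <- c("lincRNA", "NAT", "incRNA", "putative_mRNA")

#' Default distance bins to the nearest gene
#'
#' Breakpoints in bp; the first must be 0 and the last is unbounded.
#' @param breaks Strictly increasing numeric breakpoints starting at 0.
#' @return Object of class `distance_bins`: the breakpoints plus labels.
#' @export
distance_bins <- function(breaks = c(0, 2000, 5000, 10000, 20000)) {
  stopifnot(breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE))
  labs <- c(
    paste0("[", format(breaks[-length(breaks)], scientific = FALSE, trim = TRUE),
           ",", format(breaks[-1], scientific = FALSE, trim = TRUE), ")"),
    paste0(">=", format(breaks[length(breaks)], scientific = FALSE, trim = TRUE))
  )
  structure(list(breaks = breaks, labels = labs), class = "distance_bins")
}

#' Classify transcripts by genomic position and coding-hit status
#'
#' @param transcripts Model tibble of assembled transcripts
#'   ([transcript_models()] / [read_gff()]).
#' @param genes Model tibble of annotated genes.
#' @param hits Optional coding-hit table with columns `transcript_id` and
#'   `evalue` (best protein-database hit per transcript); absent or missing
#'   transcripts are treated as hit-free.
#' @param evalue_cutoff Hits at or below this e-value count as coding
#'   evidence (default `1e-10`).
#' @param min_nat_overlap Minimum exon-vs-exon antisense overlap, in bases,
#'   required for the NAT call.
#' @param incrna_same_strand Require intron-contained transcripts to match
#'   the host gene strand? Default `FALSE` (either strand).
#' @param min_lnc_length lncRNA length floor in nt (default 200; lincRNA
#'   calls require `length > min_lnc_length`).
#' @return `transcripts` with a `class` column added.
#' @export
classify_transcripts <- function(transcripts, genes, hits = NULL,
                                 evalue_cutoff = 1e-10,
                                 min_nat_overlap = 1L,
                                 incrna_same_strand = FALSE,
                                 min_lnc_length = 200L) {
  tx <- transcripts
  if (nrow(tx) == 0) return(dplyr::mutate(tx, class = character(0)))
  known_chroms <- unique(genes$chrom)
  unknown <- !(tx$chrom %in% known_chroms)
  if (any(unknown)) {
    warning(sum(unknown), " transcript(s) on chromosomes absent from the gene ",
            "annotation; labelled unclassified")
  }

  tx_ex <- model_exons(tx)
  g_ex <- model_exons(genes)
  g_introns <- model_introns(genes)

  # NAT: >=1 transcript exon overlaps >=1 gene exon on the opposite strand
  is_nat <- rep(FALSE, nrow(tx))
  if (nrow(tx_ex) && nrow(g_ex)) {
    prs <- overlap_pairs(tx_ex, g_ex, stranded = FALSE,
                         min_overlap = min_nat_overlap)
    anti <- prs[tx_ex$strand[prs$query_row] != g_ex$strand[prs$subject_row] &
                  tx_ex$strand[prs$query_row] %in% c("+", "-") &
                  g_ex$strand[prs$subject_row] %in% c("+", "-"), ]
    nat_ids <- unique(tx_ex$id[anti$query_row])
    is_nat <- tx$id %in% nat_ids
  }

  # incRNA: span fully contained in a single intron
  is_inc <- rep(FALSE, nrow(tx))
  if (nrow(g_introns)) {
    is_inc <- overlaps_any(tx, g_introns, stranded = incrna_same_strand,
                           contained = TRUE)
  }

  # genic overlap at the span level (either strand)
  genic <- overlaps_any(tx, genes, stranded = FALSE)

  best_e <- rep(Inf, nrow(tx))
  if (!is.null(hits) && nrow(hits)) {
    stopifnot(all(c("transcript_id", "evalue") %in% names(hits)))
    hb <- hits %>%
      dplyr::group_by(.data$transcript_id) %>%
      dplyr::summarise(evalue = min(.data$evalue), .groups = "drop")
    m <- match(tx$id, hb$transcript_id)
    best_e[!is.na(m)] <- hb$evalue[m[!is.na(m)]]
  }

  class <- dplyr::case_when(
    unknown ~ "unclassified",
    is_nat ~ "NAT",
    is_inc ~ "incRNA",
    !genic & best_e <= evalue_cutoff ~ "putative_mRNA",
    !genic & tx$length > min_lnc_length ~ "lincRNA",
    TRUE ~ "unclassified"
  )
  dplyr::mutate(tx, class = class)
}

#' Per-class exon-count distribution
#'
#' Fractions of transcripts with 1, 2, 3 and >= 4 exons in each class
#' (the standard single-exon-dominance summary for plant lncRNAs).
#'
#' @param transcripts Classified model tibble (column `class`).
#' @param classes Classes to report; empty classes are dropped with a
#'   warning.
#' @return Tibble `class`, `exon_bin`, `count`, `fraction` (fractions sum to
#'   1 within each class).
#' @export
exon_count_distribution <- function(transcripts, classes = LNC_CLASSES) {
  present <- intersect(classes, unique(transcripts$class))
  absent <- setdiff(classes, present)
  if (length(absent)) warning("empty class(es) omitted: ", paste(absent, collapse = ", "))
  transcripts %>%
    dplyr::filter(.data$class %in% present) %>%
    dplyr::mutate(exon_bin = factor(
      ifelse(.data$n_exons >= 4, ">=4", as.character(.data$n_exons)),
      levels = c("1", "2", "3", ">=4")
    )) %>%
    dplyr::count(.data$class, .data$exon_bin, name = "count", .drop = FALSE) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(fraction = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$class %in% present)
}

#' Per-class transcript length summary
#'
#' Transcript length is the sum of exon lengths (spliced length).
#'
#' @inheritParams exon_count_distribution
#' @return Tibble `class`, `n`, `mean_length`, `median_length`, `sd_length`.
#' @export
length_summary <- function(transcripts, classes = unique(transcripts$class)) {
  transcripts %>%
    dplyr::filter(.data$class %in% classes) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(.data$length),
      median_length = median(.data$length),
      sd_length = sd(.data$length),
      .groups = "drop"
    )
}

#' Distance from each transcript to its nearest gene
#'
#' Distance is 0 for transcripts overlapping a gene span, otherwise the
#' smallest end-to-start gap to any gene (strand ignored). Transcripts on
#' chromosomes without genes get distance `Inf`.
#'
#' @param transcripts Model tibble.
#' @param genes Gene model tibble.
#' @param bins A [distance_bins()] spec used to label each distance.
#' @return `transcripts` with `distance` and `distance_bin` columns.
#' @export
distance_to_nearest_gene <- function(transcripts, genes, bins = distance_bins()) {
  stopifnot(inherits(bins, "distance_bins"))
  if (nrow(genes) == 0) stop("no genes supplied")
  d <- rep(Inf, nrow(transcripts))
  if (nrow(transcripts)) {
    qry <- as_granges0(transcripts)
    sbj <- as_granges0(genes)
    hits <- suppressWarnings(
      GenomicRanges::distanceToNearest(qry, sbj, ignore.strand = TRUE))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  idx <- findInterval(d, c(bins$breaks[-1]), left.open = FALSE) + 1L
  transcripts %>%
    dplyr::mutate(distance = d, distance_bin = factor(bins$labels[idx],
                                                      levels = bins$labels))
}

#' Binned distance-to-gene proportions per class
#'
#' @param dist_tbl Output of [distance_to_nearest_gene()] with a `class`
#'   column.
#' @param classes Classes to report.
#' @return Tibble `class`, `distance_bin`, `count`, `fraction`.
#' @export
distance_bin_proportions <- function(dist_tbl, classes = LNC_CLASSES) {
  dist_tbl %>%
    dplyr::filter(.data$class %in% classes) %>%
    dplyr::count(.data$class, .data$distance_bin, name = "count", .drop = FALSE) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(fraction = .data$count / sum(.data$count)) %>%
    dplyr::ungroup()
}
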