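# 24-nt siRNA extraction, RPM normalisation, cluster calling and
# transcript overlap status.
#
# 24-nt siRNAs are the RdDM-pathway effector size class; the analyses here
# keep uniquely mapped 24-nt reads, normalise counts to reads per million
# mapped reads, and score a transcript as siRNA-overlapping when at least
# one such read lies fully within its genomic span (the "containment"
# criterion), or alternatively when a called cluster overlaps it.

#' Keep reads of one length class
#'
#' @param reads Small-RNA read tibble ([read_srna_table()]).
#' @param length_nt Read length to keep (default 24).
#' @param unique_only Keep uniquely mapped reads only? Default `TRUE`.
#' @return Filtered read tibble.
#' @export
filter_24nt <- function(reads, length_nt = 24L, unique_only = TRUE) {
  out <- dplyr::filter(reads, .data$read_length == length_nt)
  if (unique_only) out <- dplyr::filter(out, .data$unique)
  out
}

#' Reads per million mapped reads
#'
#' @param count Read count(s).
#' @param library_size Total mapped reads in the library (> 0).
#' @return `count * 1e6 / library_size`.
#' @export
#' @examples
#' rpm(7, 3.5e6)
rpm <- function(count, library_size) {
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  count * 1e6 / library_size
}

#' Call siRNA clusters from 24-nt reads
#'
#' Read intervals separated by at most `gap` bases are merged per
#' chromosome; merged intervals supported by at least `min_reads` member
#' reads become clusters. The cluster definition (100-bp gap, >= 3 reads)
#' is a package convention, configurable.
#'
#' @param reads24 Read tibble already filtered to 24-nt unique reads.
#' @param gap Maximum merge gap in bases (default 100).
#' @param min_reads Minimum member reads per cluster (default 3).
#' @param library_size Optional library size for the cluster `rpm` column
#'   (defaults to `nrow(reads24)`).
#' @return Tibble `chrom`, `start`, `end`, `strand`, `read_count`, `rpm`.
#' @export
call_clusters <- function(reads24, gap = 100L, min_reads = 3L,
                          library_size = NULL) {
  if (is.null(library_size)) library_size <- max(nrow(reads24), 1L)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), read_count = integer(), rpm = numeric())
  if (nrow(reads24) == 0) return(empty)
  validate_intervals(reads24)
  out <- reads24 %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
      red <- IRanges::reduce(ir, min.gapwidth = gap + 1, with.revmap = TRUE)
      tibble(
        start = IRanges::start(red) - 1,
        end = as.numeric(IRanges::end(red)),
        strand = ".",
        read_count = lengths(S4Vectors::mcols(red)$revmap)
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$read_count >= min_reads) %>%
    dplyr::mutate(rpm = rpm(.data$read_count, library_size)) %>%
    dplyr::arrange(.data$chrom, .data$start)
  out
}

#' Per-transcript siRNA overlap status
#'
#' Mode `"containment"` (default): a transcript is siRNA-positive when at
#' least one uniquely mapped 24-nt read interval lies fully within its
#' genomic span — genomic containment of a uniquely mapped read implies
#' perfect sequence identity of the siRNA to the locus. Mode `"cluster"`:
#' positive when >= 1 called cluster overlaps the span by >= 1 bp.
#'
#' @param transcripts Model tibble.
#' @param reads24 24-nt unique read tibble (containment mode).
#' @param clusters Cluster tibble from [call_clusters()] (cluster mode).
#' @param mode `"containment"` or `"cluster"`.
#' @param stranded Require the read/cluster strand to match the transcript?
#'   Default `FALSE`.
#' @return Tibble `transcript_id`, `sirna` (logical).
#' @export
sirna_overlap_status <- function(transcripts, reads24 = NULL, clusters = NULL,
                                 mode = c("containment", "cluster"),
                                 stranded = FALSE) {
  mode <- match.arg(mode)
  if (mode == "containment") {
    stopifnot(!is.null(reads24))
    # containment of a read in a span == the read, as query, lies within
    status <- if (nrow(reads24) == 0) rep(FALSE, nrow(transcripts)) else {
      hits <- suppressWarnings(GenomicRanges::findOverlaps(
        as_granges0(reads24), as_granges0(transcripts),
        type = "within", ignore.strand = !stranded
      ))
      seq_len(nrow(transcripts)) %in% S4Vectors::subjectHits(hits)
    }
  } else {
    stopifnot(!is.null(clusters))
    status <- overlaps_any(transcripts, clusters, stranded = stranded)
  }
  tibble(transcript_id = transcripts$id, sirna = status)
}
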