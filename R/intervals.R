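# Interval algebra on 0-based half-open coordinates.
#
# Every function in the package represents a genomic interval as a row of a
# data frame with columns chrom, start, end, strand.  start is 0-based
# inclusive, end is exclusive, so length = end - start.  GFF and CX-report
# inputs (1-based) are converted at the I/O boundary; BED is consumed as-is.

#' Construct a tibble of genomic intervals
#'
#' The package-wide coordinate convention is 0-based half-open
#' (`start` inclusive, `end` exclusive), as in BED. Strand is one of
#' `"+"`, `"-"` or `"."`; `"."` matches either strand in stranded queries.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer coordinates, `0 <= start < end`.
#' @param strand Strand characters, recycled.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
#' @examples
#' genomic_intervals("A01", 100, 200)
genomic_intervals <- function(chrom, start, end, strand = ".") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the package invariants: non-empty `chrom`, `0 <= start < end`,
#' strand in `+`/`-`/`.`. Returns the input invisibly, or errors.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval table has empty chrom values")
  }
  if (any(x$start < 0)) stop("negative start coordinate")
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop("interval with end <= start at row ", bad)
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

# Convert an interval tibble to GRanges (1-based closed internally).
# "." is mapped to "*" so unstranded features match either strand.
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Convert GRanges back to the 0-based tibble convention.
granges_to_tbl <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = strand
  )
}

#' Merge intervals separated by at most a gap
#'
#' Collapses runs of intervals on a single chromosome whose successive gaps
#' are `<= gap` bases into maximal merged intervals. Strand is ignored; the
#' output is sorted, disjoint and carries strand `"."`.
#'
#' @param x Interval tibble, all rows on one chromosome.
#' @param gap Maximum separation, in bases, that is still bridged
#'   (`gap = 0` merges only touching or overlapping intervals).
#' @return Tibble of merged intervals.
#' @export
#' @examples
#' merge_intervals(genomic_intervals("c", c(100, 250), c(200, 300)), gap = 50)
merge_intervals <- function(x, gap = 0) {
  validate_intervals(x)
  stopifnot(gap >= 0)
  if (nrow(x) == 0) return(x[0, c("chrom", "start", "end", "strand")])
  if (length(unique(x$chrom)) > 1) {
    stop("merge_intervals expects a single chromosome; use reduce_intervals() for many")
  }
  ir <- IRanges::IRanges(start = x$start + 1L, end = x$end)
  red <- IRanges::reduce(ir, min.gapwidth = gap + 1)
  tibble(
    chrom = x$chrom[1],
    start = IRanges::start(red) - 1,
    end = as.numeric(IRanges::end(red)),
    strand = "."
  )
}

#' Merge intervals chromosome by chromosome
#'
#' Grouped convenience wrapper around [merge_intervals()].
#'
#' @inheritParams merge_intervals
#' @return Tibble of merged intervals, sorted by chrom then start.
#' @export
reduce_intervals <- function(x, gap = 0) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[0, c("chrom", "start", "end", "strand")])
  x %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(~ merge_intervals(.x %>% dplyr::mutate(chrom = .y$chrom), gap = gap) %>%
      dplyr::select(-"chrom")) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Number of bases shared by two intervals
#'
#' Vectorised over rows: `a` and `b` must have the same number of rows (or
#' one of them a single row, which is recycled). Returns 0 when chromosomes
#' differ, and when `stranded = TRUE` and the strands are `+` vs `-`
#' (strand `"."` matches any).
#'
#' @param a,b Interval tibbles.
#' @param stranded Require strand compatibility?
#' @return Numeric vector of overlap lengths in bases.
#' @export
#' @examples
#' overlap_length(genomic_intervals("c", 0, 10), genomic_intervals("c", 5, 15))
overlap_length <- function(a, b, stranded = FALSE) {
  validate_intervals(a)
  validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  if (stranded) {
    sa <- if ("strand" %in% names(a)) a$strand else "."
    sb <- if ("strand" %in% names(b)) b$strand else "."
    clash <- sa != "." & sb != "." & sa != sb
    ov[clash] <- 0
  }
  ov
}

# For each row of x, TRUE iff it overlaps (or is contained in) any subject
# interval. contained = TRUE requires the x interval to lie fully within a
# single subject interval. min_overlap is in bases.
overlaps_any <- function(x, subject, stranded = FALSE, contained = FALSE,
                         min_overlap = 1L) {
  validate_intervals(x)
  validate_intervals(subject)
  if (nrow(x) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(x)))
  qry <- as_granges0(x)
  sbj <- as_granges0(subject)
  type <- if (contained) "within" else "any"
  # findOverlaps warns when the two sides share no sequence levels; for
  # status queries that is simply "no overlap"
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    qry, sbj,
    type = type,
    minoverlap = as.integer(min_overlap),
    ignore.strand = !stranded
  ))
  out <- rep(FALSE, nrow(x))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# Overlap join: rows (query_row, subject_row, overlap) for every pair with
# >= min_overlap shared bases.
overlap_pairs <- function(x, subject, stranded = FALSE, min_overlap = 1L) {
  validate_intervals(x)
  validate_intervals(subject)
  if (nrow(x) == 0 || nrow(subject) == 0) {
    return(tibble(query_row = integer(), subject_row = integer(), overlap = numeric()))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges0(x), as_granges0(subject),
    minoverlap = as.integer(min_overlap), ignore.strand = !stranded
  ))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tibble(
    query_row = qi,
    subject_row = si,
    overlap = pmax(0, pmin(x$end[qi], subject$end[si]) - pmax(x$start[qi], subject$start[si]))
  )
}
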