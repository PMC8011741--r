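# Readers and writers for the external formats the pipeline touches.
#
# All coordinate-bearing inputs end up in the internal 0-based half-open
# convention: GFF3 and CX reports (1-based) are shifted at this boundary,
# BED and bedGraph pass through unchanged. Plain or gzip-compressed paths
# are accepted everywhere (readr and rtracklayer decompress transparently).

CONTEXT_DIALECT <- c(
  "CG" = "CG", "CpG" = "CG", "cpg" = "CG", "cg" = "CG",
  "CHG" = "CHG", "chg" = "CHG",
  "CHH" = "CHH", "chh" = "CHH"
)

#' Build transcript/gene models from an exon table
#'
#' Assembles a model table (one row per transcript or gene, exon chain in a
#' list-column) from a flat exon table. Exons are sorted by start and checked
#' to be non-overlapping and on a single chromosome and strand per model.
#'
#' @param exons Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param type Model type recorded for every row (`"transcript"` or
#'   `"gene"`), recycled.
#' @return A model tibble with columns `id`, `type`, `chrom`, `start`,
#'   `end`, `strand`, `n_exons`, `length` and list-column `exons`.
#' @export
transcript_models <- function(exons, type = "transcript") {
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in% names(exons)))
  validate_intervals(exons)
  out <- exons %>%
    dplyr::group_by(.data$id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      span_start = min(.data$start),
      span_end = max(.data$end),
      strand = dplyr::first(.data$strand),
      n_exons = dplyr::n(),
      length = sum(.data$end - .data$start),
      exons = list(tibble(start = start, end = end)),
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      .groups = "drop"
    )
  if (any(out$n_chrom > 1)) {
    stop("model(s) with exons on multiple chromosomes: ",
         paste(out$id[out$n_chrom > 1], collapse = ", "))
  }
  if (any(out$n_strand > 1)) {
    stop("model(s) with exons on multiple strands: ",
         paste(out$id[out$n_strand > 1], collapse = ", "))
  }
  bad <- purrr::map_lgl(out$exons, function(e) {
    nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])
  })
  if (any(bad)) {
    stop("model(s) with overlapping exons: ", paste(out$id[bad], collapse = ", "))
  }
  out %>%
    dplyr::transmute(
      id = .data$id, type = rep_len(type, dplyr::n()),
      chrom = .data$chrom, start = .data$span_start, end = .data$span_end,
      strand = .data$strand, n_exons = .data$n_exons, length = .data$length,
      exons = .data$exons
    )
}

#' Flatten model exon chains
#'
#' @param models Model tibble from [transcript_models()] or [read_gff()].
#' @return Tibble with one row per exon: `id`, `chrom`, `start`, `end`,
#'   `strand`, `exon_rank`.
#' @export
model_exons <- function(models) {
  if (nrow(models) == 0) {
    return(tibble(id = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), exon_rank = integer()))
  }
  models %>%
    dplyr::select("id", "chrom", "strand", "exons") %>%
    dplyr::mutate(exons = purrr::map(.data$exons, ~ dplyr::mutate(.x, exon_rank = dplyr::row_number()))) %>%
    tidyr::unnest("exons") %>%
    dplyr::select("id", "chrom", "start", "end", "strand", "exon_rank")
}

#' Derive introns from model exon chains
#'
#' Introns are the complement of the exons within each model span; models
#' with a single exon contribute no rows.
#'
#' @inheritParams model_exons
#' @return Tibble `id`, `chrom`, `start`, `end`, `strand`, `intron_rank`.
#' @export
model_introns <- function(models) {
  ex <- model_exons(models)
  if (nrow(ex) == 0) {
    return(tibble(id = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), intron_rank = integer()))
  }
  ex %>%
    dplyr::group_by(.data$id, .data$chrom, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe(istart = .data$end[-dplyr::n()], iend = .data$start[-1]) %>%
    dplyr::rename(start = "istart", end = "iend") %>%
    dplyr::filter(.data$end > .data$start) %>%
    dplyr::group_by(.data$id) %>%
    dplyr::mutate(intron_rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("id", "chrom", "start", "end", "strand", "intron_rank")
}

#' Read gene and transcript models from GFF3/GTF
#'
#' Parses the file with rtracklayer, links exons to their parents (directly,
#' or through an mRNA/transcript layer under a gene) and converts 1-based
#' inclusive GFF coordinates to the internal 0-based half-open convention.
#' Features without exon children are given a single exon equal to their
#' span.
#'
#' @param path GFF3 or GTF file, optionally gzipped.
#' @param transcript_types Feature types treated as transcripts.
#' @return Model tibble (see [transcript_models()]) with `type` `"gene"` or
#'   `"transcript"`.
#' @export
read_gff <- function(path, transcript_types = c("mRNA", "transcript", "lnc_RNA", "ncRNA")) {
  lines <- readr::read_lines(path, n_max = 50L)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    warning("no features in ", path)
    return(tibble(id = character(), type = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  n_exons = integer(), length = numeric(), exons = list()))
  }
  gr <- rtracklayer::import(path)
  feat <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    ftype = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) {
      vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
    } else rep(NA_character_, length(gr))
  )
  # GTF dialect: transcript_id/gene_id instead of ID/Parent
  if (all(is.na(feat$id)) && !is.null(gr$transcript_id)) {
    feat$id <- ifelse(feat$ftype %in% transcript_types, as.character(gr$transcript_id),
                      as.character(gr$gene_id))
    feat$parent <- ifelse(feat$ftype == "exon", as.character(gr$transcript_id), NA_character_)
  }
  genes <- feat %>% dplyr::filter(.data$ftype == "gene")
  txs <- feat %>% dplyr::filter(.data$ftype %in% transcript_types)
  exf <- feat %>% dplyr::filter(.data$ftype == "exon")

  assemble <- function(parents, type) {
    if (nrow(parents) == 0) return(NULL)
    ex <- exf %>%
      dplyr::filter(.data$parent %in% parents$id) %>%
      dplyr::transmute(id = .data$parent, chrom = .data$chrom,
                       start = .data$start, end = .data$end, strand = .data$strand)
    noex <- setdiff(parents$id, unique(ex$id))
    if (length(noex)) {
      ex <- dplyr::bind_rows(ex, parents %>%
        dplyr::filter(.data$id %in% noex) %>%
        dplyr::transmute(id = .data$id, chrom = .data$chrom,
                         start = .data$start, end = .data$end, strand = .data$strand))
    }
    m <- transcript_models(ex, type = type)
    chk <- m %>% dplyr::inner_join(parents %>% dplyr::select("id", pstart = "start", pend = "end"),
                                   by = "id")
    if (any(chk$start < chk$pstart | chk$end > chk$pend)) {
      off <- chk$id[chk$start < chk$pstart | chk$end > chk$pend]
      stop("exon(s) outside parent span for: ", paste(off, collapse = ", "))
    }
    m
  }

  # gene exon chains come from their first child transcript when one exists
  gene_models <- NULL
  if (nrow(genes)) {
    child <- txs %>%
      dplyr::filter(.data$parent %in% genes$id) %>%
      dplyr::distinct(.data$parent, .keep_all = TRUE)
    gene_as_parent <- genes
    if (nrow(child)) {
      # substitute the child's exons under the gene id
      exf <- dplyr::bind_rows(
        exf,
        exf %>%
          dplyr::inner_join(child %>% dplyr::select(tx_id = "id", gene_id = "parent"),
                            by = c(parent = "tx_id")) %>%
          dplyr::mutate(parent = .data$gene_id) %>%
          dplyr::select(-"gene_id")
      )
    }
    gene_models <- assemble(gene_as_parent, "gene")
  }
  # standalone transcripts: those not acting as the exon source of a gene
  tx_standalone <- txs %>% dplyr::filter(is.na(.data$parent) | !(.data$parent %in% genes$id))
  tx_models <- assemble(tx_standalone, "transcript")
  out <- dplyr::bind_rows(gene_models, tx_models)
  if (is.null(out) || nrow(out) == 0) {
    warning("no gene or transcript features in ", path)
    out <- tibble(id = character(), type = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  n_exons = integer(), length = numeric(), exons = list())
  }
  out
}

#' Write models to GFF3
#'
#' Genes are written as `gene` + `mRNA` + `exon` rows; transcripts as
#' `transcript` + `exon` rows. Coordinates are converted back to 1-based
#' inclusive. Round-trips through [read_gff()].
#'
#' @param models Model tibble.
#' @param path Output path.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path, source = "lncmarks") {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    g1 <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, source, if (m$type == "gene") "gene" else "transcript",
                  m$start + 1, m$end, m$strand, paste0("ID=", m$id))
    ex <- m$exons[[1]]
    parent <- m$id
    if (m$type == "gene") {
      tx_id <- paste0(m$id, ".t1")
      g1 <- c(g1, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                          m$chrom, source, m$start + 1, m$end, m$strand, tx_id, m$id))
      parent <- tx_id
    }
    exl <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                   m$chrom, source, ex$start + 1, ex$end, m$strand, parent)
    lines <- c(lines, g1, exl)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED3/4/6 file (0-based half-open), optionally gzipped.
#' @return Interval tibble with `name` and `score` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl(gr)
  if (!is.null(gr$name)) out$name <- as.character(gr$name)
  if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
  out
}

#' Write intervals to BED
#'
#' @param x Interval tibble (optionally with `name`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else paste0("feat_", seq_len(nrow(x)))
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE), name, score, strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Expected columns (no header): chrom, 1-based position, strand, methylated
#' read count, unmethylated read count, context, with an optional trailing
#' trinucleotide column. Context dialects (`CpG` for `CG`, case variants)
#' are normalised to `CG`/`CHG`/`CHH`.
#'
#' @param path TSV file, optionally gzipped.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based, length-1),
#'   `strand`, `context`, `mc`, `umc`, `zero_coverage`.
#' @export
read_cx_report <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (nrow(x) == 0) {
    warning("empty CX report: ", path)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), context = character(), mc = integer(),
                  umc = integer(), zero_coverage = logical()))
  }
  if (ncol(x) < 6) stop("CX report needs >= 6 columns, got ", ncol(x))
  ctx_raw <- as.character(x[[6]])
  ctx <- unname(CONTEXT_DIALECT[ctx_raw])
  if (anyNA(ctx)) {
    stop("unknown cytosine context(s): ",
         paste(unique(ctx_raw[is.na(ctx)]), collapse = ", "))
  }
  mc <- as.integer(x[[4]]); umc <- as.integer(x[[5]])
  if (any(mc < 0) || any(umc < 0)) stop("negative read count in CX report")
  pos <- as.numeric(x[[2]])
  if (any(pos < 1)) stop("CX report position must be 1-based (>= 1)")
  tibble(
    chrom = as.character(x[[1]]), start = pos - 1, end = pos,
    strand = as.character(x[[3]]), context = ctx, mc = mc, umc = umc,
    zero_coverage = (mc + umc) == 0L
  )
}

#' Write a cytosine report
#'
#' Inverse of [read_cx_report()] (1-based positions, no header).
#' @param cx Cytosine tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(cx, path) {
  df <- data.frame(cx$chrom, format(cx$start + 1, scientific = FALSE, trim = TRUE),
                   cx$strand, cx$mc, cx$umc, cx$context)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read aligned small-RNA reads
#'
#' Primary format: headered TSV with columns `chrom`, `start`, `end`,
#' `strand`, `read_length`, `unique` (0-based half-open). A headerless BED6
#' is also accepted: read length is inferred from the coordinates and a
#' positive score marks a uniquely mapped read.
#'
#' @param path TSV/BED file, optionally gzipped.
#' @return Tibble `chrom`, `start`, `end`, `strand`, `read_length`,
#'   `unique`.
#' @export
read_srna_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) && startsWith(first, "chrom")) {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    x$unique <- as.logical(x$unique)
  } else {
    b <- read_bed(path)
    x <- b %>% dplyr::mutate(read_length = .data$end - .data$start,
                             unique = .data$score > 0) %>%
      dplyr::select("chrom", "start", "end", "strand", "read_length", "unique")
  }
  bad <- x$read_length != x$end - x$start
  if (any(bad)) stop(sum(bad), " read(s) whose length != end - start")
  if (any(x$read_length < 18 | x$read_length > 30)) {
    stop("read length outside the small-RNA range [18, 30]")
  }
  as_tibble(x)
}

#' Write aligned small-RNA reads
#' @param reads Read tibble (see [read_srna_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srna_table <- function(reads, path) {
  readr::write_tsv(reads %>% dplyr::mutate(unique = as.integer(.data$unique)), path)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph (0-based half-open), optionally gzipped.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       show_col_types = FALSE, progress = FALSE, comment = "#")
  as_tibble(x)
}

#' Write a bedGraph file
#' @param x Tibble `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path, col_names = FALSE)
  invisible(path)
}

HSP_COLS <- c("query_id", "subject_id", "pident", "align_length", "mismatch",
              "gapopen", "query_start", "query_end", "subject_start",
              "subject_end", "evalue", "bitscore")

#' Read BLAST tabular (outfmt 6) HSPs
#'
#' Standard 12-column outfmt-6 layout; an optional 13th column names the
#' target genome (otherwise the `genome` argument is used for all rows).
#' Query/subject coordinates stay 1-based inclusive, the BLAST convention;
#' subject strand is inferred from the coordinate order.
#'
#' @param path TSV file (no header), optionally gzipped.
#' @param genome Genome label applied when the file has 12 columns.
#' @return Tibble of HSP records with a `genome` and `subject_strand` column.
#' @export
read_hsp_table <- function(path, genome = "target") {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (nrow(x) == 0) {
    return(tibble::as_tibble(setNames(rep(list(character(0)), 12), HSP_COLS)) %>%
             dplyr::mutate(genome = character(0), subject_strand = character(0)))
  }
  if (ncol(x) < 12) stop("HSP table needs >= 12 columns, got ", ncol(x))
  names(x)[1:12] <- HSP_COLS
  x$genome <- if (ncol(x) >= 13) as.character(x[[13]]) else genome
  x <- x[, c(HSP_COLS, "genome")]
  num <- c("pident", "align_length", "mismatch", "gapopen", "query_start",
           "query_end", "subject_start", "subject_end", "evalue", "bitscore")
  x[num] <- lapply(x[num], as.numeric)
  if (any(x$query_start > x$query_end)) stop("HSP with query_start > query_end")
  if (any(x$evalue < 0)) stop("HSP with negative e-value")
  x$subject_strand <- ifelse(x$subject_start <= x$subject_end, "+", "-")
  as_tibble(x)
}

#' Write HSPs as BLAST outfmt 6 (+ genome column)
#' @param hsps HSP tibble from [read_hsp_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hsp_table <- function(hsps, path) {
  readr::write_tsv(hsps[, c(HSP_COLS, "genome")], path, col_names = FALSE)
  invisible(path)
}

#' Read a transcript-by-replicate FPKM table
#'
#' @param path Headered TSV: `transcript_id` then one numeric column per
#'   replicate.
#' @return Long tibble `transcript_id`, `replicate`, `fpkm`.
#' @export
read_fpkm_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(names(x)[1] == "transcript_id", ncol(x) >= 2)
  long <- tidyr::pivot_longer(x, -"transcript_id", names_to = "replicate",
                              values_to = "fpkm")
  if (any(!is.finite(long$fpkm)) || any(long$fpkm < 0)) {
    stop("FPKM values must be finite and non-negative")
  }
  long
}

#' Read a gene-to-GO-term map
#' @param path Headered TSV with columns `gene` and `term`.
#' @return Tibble `gene`, `term`.
#' @export
read_go_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "term") %in% names(x)))
  as_tibble(x[, c("gene", "term")])
}

#' Read an RT-PCR band matrix
#'
#' First column transcript ids, remaining columns one per line, cells in
#' `{+++, +, -}` (strong band, weak band, no band).
#'
#' @param path Headered TSV.
#' @return Tibble, first column `lncRNA`, then one character column per line.
#' @export
read_band_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "lncRNA"
  cells <- unlist(x[, -1])
  if (!all(cells %in% c("+++", "+", "-"))) {
    stop("band matrix cells must be one of '+++', '+', '-'; saw: ",
         paste(setdiff(unique(cells), c("+++", "+", "-")), collapse = ", "))
  }
  as_tibble(x)
}
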