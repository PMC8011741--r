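# Small in-text tables used as worked inputs: the RT-PCR band matrix of
# twelve conserved lncRNAs across six B. rapa lines and three B. oleracea
# cultivars, and the published class x mark count pairs ("k of n").
# These are inputs to the summarisation functions, built in code so the
# package carries no binary fixtures.

RAPA_LINES <- c("RJKB-T24", "Homei", "Harunosaiten", "BRA2209", "Osome",
                "Yellow Sarson")
OLERACEA_LINES <- c("Reiho", "Matsunami", "Kinkei 201")

#' RT-PCR band matrix of twelve conserved lncRNAs
#'
#' Expression of twelve B. rapa lncRNAs assayed by RT-PCR across six
#' B. rapa lines and three B. oleracea cabbage cultivars. Cells:
#' `+++` strong band, `+` weak band, `-` no band.
#'
#' @return Tibble: `lncRNA` id column plus one column per line.
#' @export
worked_band_matrix <- function() {
  m <- tibble::tribble(
    ~lncRNA, ~`RJKB-T24`, ~Homei, ~Harunosaiten, ~BRA2209, ~Osome,
    ~`Yellow Sarson`, ~Reiho, ~Matsunami, ~`Kinkei 201`,
    "M15784", "+++", "-",   "+++", "-",   "+++", "+++", "-",   "-",   "-",
    "M26919", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++",
    "M3316",  "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "-",
    "M491",   "+++", "-",   "+++", "+++", "+++", "-",   "+",   "+",   "-",
    "M17356", "+++", "+",   "-",   "-",   "-",   "-",   "-",   "-",   "-",
    "M17153", "+++", "-",   "-",   "-",   "-",   "+",   "+++", "+++", "+++",
    "M25534", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++",
    "M259",   "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++",
    "M4317",  "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++",
    "M26796", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++", "+++",
    "M4921",  "+++", "+++", "+",   "+",   "+++", "+++", "-",   "+++", "-",
    "M24531", "+++", "+++", "+++", "+++", "+++", "+++", "-",   "+",   "-"
  )
  m
}

#' Default line groups for the band matrix
#'
#' @return Named list: the six B. rapa lines and the three B. oleracea
#'   cultivars.
#' @export
worked_line_groups <- function() {
  list(B_rapa = RAPA_LINES, B_oleracea = OLERACEA_LINES)
}

#' Published class x mark count pairs
#'
#' The "k of n" counts of transcripts per class overlapping each mark on
#' chromosomes A01-A10: inverted repeat regions (irr), unique-mapped 24-nt
#' siRNA loci (sirna) and H3K27me3 domains (k27).
#'
#' @return Tibble `class`, `mark`, `k` (overlapping), `n` (class size).
#' @export
worked_count_pairs <- function() {
  tibble::tribble(
    ~class,          ~mark,   ~k,   ~n,
    "lincRNA",       "irr",   763, 1173,
    "NAT",           "irr",   291,  529,
    "incRNA",        "irr",    66,   92,
    "putative_mRNA", "irr",   314,  490,
    "lincRNA",       "sirna", 219, 1173,
    "NAT",           "sirna",  74,  529,
    "incRNA",        "sirna",  16,   92,
    "lincRNA",       "k27",   127, 1173,
    "NAT",           "k27",    83,  529,
    "incRNA",        "k27",    15,   92,
    "putative_mRNA", "k27",    53,  490
  )
}

#' Write the worked tables to files
#'
#' Emits the band matrix and the count pairs as TSV fixtures.
#'
#' @param outdir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
emit_worked_tables <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  band_path <- file.path(outdir, "band_matrix.tsv")
  counts_path <- file.path(outdir, "count_pairs.tsv")
  readr::write_tsv(worked_band_matrix(), band_path)
  readr::write_tsv(worked_count_pairs(), counts_path)
  invisible(list(band_matrix = band_path, count_pairs = counts_path))
}
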