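# Shared fixtures: one small synthetic dataset generated once per test run
# and cached, plus tiny hand-built tables used across files.

.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42) {
  sim_config(
    seed = seed, n_chroms = 2, chrom_length = 300000,
    n_genes = 40, n_lincRNA = 50, n_NAT = 25, n_incRNA = 10,
    n_putative_mRNA = 20, cytosine_density = 0.02, gap_mean = 800
  )
}

sim_fixture <- function() {
  if (is.null(.fixture_env$out)) {
    dir <- file.path(tempdir(), "lncmarks-fixture")
    .fixture_env$out <- generate_dataset(small_sim_config(), dir)
  }
  .fixture_env$out
}

# all inputs of the fixture parsed through the package readers
sim_loaded <- function() {
  if (is.null(.fixture_env$loaded)) {
    out <- sim_fixture()
    p <- out$paths
    genes <- read_gff(p$genes_gff)
    tx <- read_gff(p$transcripts_gff)
    hits <- readr::read_tsv(p$coding_hits, show_col_types = FALSE)
    reads <- read_srna_table(p$srna)
    .fixture_env$loaded <- list(
      genes = genes, transcripts = tx, hits = hits,
      classified = classify_transcripts(tx, genes, hits),
      irr = read_bed(p$irr_bed), k27 = read_bed(p$k27_bed),
      reads = reads, reads24 = filter_24nt(reads),
      cx = read_cx_report(p$cx_report),
      fpkm = read_fpkm_table(p$fpkm),
      hsps = read_hsp_table(p$hsp),
      go = read_go_map(p$go_map),
      manifest = out$manifest, regions = out$regions
    )
  }
  .fixture_env$loaded
}

# single-exon transcript model helper
mk_tx <- function(id, chrom, start, end, strand = "+") {
  transcript_models(tibble::tibble(id = id, chrom = chrom, start = start,
                                   end = end, strand = strand))
}

# random interval table on one chromosome
rand_intervals <- function(n, span = 10000, max_w = 400) {
  s <- sample.int(span - max_w, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  genomic_intervals("c1", s, s + w)
}
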