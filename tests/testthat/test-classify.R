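# Positional classification and Fig-1-style descriptive statistics.

# one gene with two exons [1000,1400) + [2000,2400) on "+", on chrom c1
fixture_gene <- function() {
  transcript_models(tibble::tibble(
    id = "g1", chrom = "c1", start = c(1000, 2000), end = c(1400, 2400),
    strand = "+"), type = "gene")
}

test_that("each definition case gets its class", {
  genes <- fixture_gene()
  tx <- dplyr::bind_rows(
    mk_tx("linc", "c1", 5000, 5725, "+"),         # intergenic, no hit, 725 nt
    mk_tx("nat", "c1", 1200, 2600, "-"),          # exon overlaps gene exon, antisense
    mk_tx("pmr", "c1", 8000, 8400, "+"),          # intergenic with strong hit
    mk_tx("inc", "c1", 1500, 1900, "+"),          # wholly inside the intron
    mk_tx("short", "c1", 12000, 12180, "+"),      # intergenic, no hit, 180 nt
    mk_tx("sense", "c1", 1200, 2600, "+")         # sense overlap, not intronic
  )
  hits <- tibble::tibble(transcript_id = c("pmr", "linc"),
                         evalue = c(1e-12, 1e-4)) # linc hit above cutoff
  got <- classify_transcripts(tx, genes, hits)
  expect_equal(setNames(got$class, got$id),
               c(linc = "lincRNA", nat = "NAT", pmr = "putative_mRNA",
                 inc = "incRNA", short = "unclassified",
                 sense = "unclassified"))
})

test_that("precedence is total and NAT outranks incRNA", {
  genes <- fixture_gene()
  # antisense transcript that also exon-overlaps: NAT wins
  tx <- mk_tx("t", "c1", 1100, 1450, "-")
  expect_equal(classify_transcripts(tx, genes)$class, "NAT")
  # antisense but wholly intronic: no exon-exon overlap, so incRNA
  tx2 <- mk_tx("t2", "c1", 1500, 1900, "-")
  expect_equal(classify_transcripts(tx2, genes)$class, "incRNA")
  # same-strand containment only, when requested
  expect_equal(classify_transcripts(tx2, genes, incrna_same_strand = TRUE)$class,
               "unclassified")
})

test_that("transcripts on unknown chromosomes are unclassified with warning", {
  expect_warning(
    got <- classify_transcripts(mk_tx("t", "cZ", 0, 500), fixture_gene()),
    "absent from the gene"
  )
  expect_equal(got$class, "unclassified")
})

test_that("every synthetic transcript is labelled and matches its truth", {
  l <- sim_loaded()
  cmp <- dplyr::inner_join(
    dplyr::select(l$classified, id, class),
    dplyr::select(l$manifest, id = transcript_id, true = class), by = "id")
  expect_equal(nrow(cmp), nrow(l$manifest))
  expect_true(all(cmp$class == cmp$true))
  expect_true(all(!is.na(l$classified$class)))
})

test_that("exon-count distribution sums to one and matches direct counting", {
  l <- sim_loaded()
  d <- exon_count_distribution(l$classified)
  sums <- tapply(d$fraction, d$class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  linc <- l$classified[l$classified$class == "lincRNA", ]
  expect_equal(d$fraction[d$class == "lincRNA" & d$exon_bin == "1"],
               mean(linc$n_exons == 1))
  tx3 <- dplyr::bind_rows(mk_tx("a", "c", 0, 100), mk_tx("b", "c", 200, 300),
                          transcript_models(tibble::tibble(
                            id = "c", chrom = "c", start = c(400, 600),
                            end = c(500, 700), strand = "+")))
  tx3$class <- "lincRNA"
  expect_warning(d3 <- exon_count_distribution(tx3), "omitted")
  expect_equal(d3$fraction[d3$exon_bin == "1"], 2 / 3)
})

test_that("length summary is the arithmetic mean of spliced lengths", {
  tx <- dplyr::bind_rows(mk_tx("a", "c", 0, 100), mk_tx("b", "c", 200, 500))
  tx$class <- "lincRNA"
  s <- length_summary(tx)
  expect_equal(s$mean_length, 200)
  expect_equal(s$n, 2L)
  one <- length_summary(dplyr::mutate(mk_tx("x", "c", 0, 321), class = "NAT"))
  expect_equal(one$mean_length, 321)
})

test_that("distance to nearest gene matches examples and a quadratic oracle", {
  genes <- fixture_gene()
  t1 <- distance_to_nearest_gene(mk_tx("t", "c1", 3000, 3200), genes)
  expect_equal(t1$distance, 600) # gap from 2400 to 3000
  near <- distance_to_nearest_gene(mk_tx("t", "c1", 1000, 1200), genes)
  expect_equal(near$distance, 0) # overlapping
  far_genes <- transcript_models(
    tibble::tibble(id = "g", chrom = "c1", start = 30000, end = 32000,
                   strand = "+"), type = "gene")
  far <- distance_to_nearest_gene(mk_tx("t", "c1", 1000, 1200), far_genes)
  expect_equal(as.character(far$distance_bin), ">=20000")

  # quadratic all-pairs oracle on random features
  set.seed(11)
  g <- transcript_models(tibble::tibble(
    id = paste0("g", 1:20), chrom = "c1",
    start = (s <- sort(sample.int(90000, 20)) * 1), end = s + 500,
    strand = "+"), type = "gene")
  tx <- transcript_models(tibble::tibble(
    id = paste0("t", 1:30), chrom = "c1",
    start = (ts <- sample.int(95000, 30)), end = ts + 200, strand = "+"))
  got <- distance_to_nearest_gene(tx, g)$distance
  want <- vapply(seq_len(nrow(tx)), function(i) {
    gaps <- pmax(0, pmax(g$start - tx$end[i], tx$start[i] - g$end))
    ov <- g$start < tx$end[i] & g$end > tx$start[i]
    if (any(ov)) 0 else min(gaps)
  }, numeric(1))
  expect_equal(got, want)
})

test_that("distance is symmetric under coordinate mirroring", {
  set.seed(12)
  L <- 100000
  g <- transcript_models(tibble::tibble(
    id = paste0("g", 1:10), chrom = "c1",
    start = (s <- sample.int(L - 600, 10)), end = s + 500, strand = "+"),
    type = "gene")
  tx <- transcript_models(tibble::tibble(
    id = paste0("t", 1:10), chrom = "c1",
    start = (ts <- sample.int(L - 300, 10)), end = ts + 200, strand = "+"))
  mirror <- function(m) {
    transcript_models(
      model_exons(m) %>%
        dplyr::transmute(id, chrom, mstart = L - end, mend = L - start,
                         strand = strand) %>%
        dplyr::rename(start = mstart, end = mend),
      type = m$type[1])
  }
  d1 <- distance_to_nearest_gene(tx, g)
  d2 <- distance_to_nearest_gene(mirror(tx), mirror(g))
  expect_equal(sort(d1$distance), sort(d2$distance))
})

test_that("distance bins follow the breakpoint spec", {
  b <- distance_bins()
  expect_equal(b$breaks, c(0, 2000, 5000, 10000, 20000))
  expect_error(distance_bins(c(100, 200)), "breaks")
  genes <- fixture_gene()
  tx <- mk_tx("t", "c1", 2500, 2700) # 100 bp from gene end at 2400
  got <- distance_to_nearest_gene(tx, genes)
  expect_equal(as.character(got$distance_bin), "[0,2000)")
})
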