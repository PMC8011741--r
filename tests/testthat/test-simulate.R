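# Synthetic-data generator: determinism, planted structure, round-trips.

test_that("the same seed produces byte-identical outputs", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 200000,
                    n_genes = 15, n_lincRNA = 15, n_NAT = 8, n_incRNA = 4,
                    n_putative_mRNA = 6, cytosine_density = 0.01,
                    gap_mean = 800)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})

test_that("an overlap fraction of 1 forces every member positive", {
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_length = 200000,
                    n_genes = 12, n_lincRNA = 20, n_NAT = 6, n_incRNA = 3,
                    n_putative_mRNA = 5, cytosine_density = 0.005,
                    gap_mean = 800,
                    irr_overlap_fraction = c(lincRNA = 1, NAT = 0.5,
                                             incRNA = 0.5,
                                             putative_mRNA = 0.5))
  out <- generate_dataset(cfg, withr::local_tempdir())
  linc <- out$manifest[out$manifest$class == "lincRNA", ]
  expect_true(all(linc$irr))
  # verify against the emitted BED, not just the manifest
  irr <- read_bed(out$paths$irr_bed)
  tx <- read_gff(out$paths$transcripts_gff)
  st <- irr_status(tx[tx$id %in% linc$transcript_id, ], irr)
  expect_true(all(st$irr))
})

test_that("infeasible placement errors with advice", {
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 20000,
                    n_genes = 40, n_lincRNA = 60, n_NAT = 20, n_incRNA = 10,
                    n_putative_mRNA = 10)
  expect_error(generate_dataset(cfg, withr::local_tempdir()), "chrom_length")
})

test_that("emitted files parse cleanly through every reader", {
  l <- sim_loaded()
  expect_gt(nrow(l$genes), 0)
  expect_gt(nrow(l$transcripts), 0)
  expect_gt(nrow(l$cx), 0)
  expect_gt(nrow(l$reads), 0)
  expect_gt(nrow(l$hsps), 0)
  expect_gt(nrow(l$irr), 0)
  expect_gt(nrow(l$k27), 0)
  expect_true(all(l$cx$context %in% c("CG", "CHG", "CHH")))
  expect_true(all(l$reads$read_length >= 18 & l$reads$read_length <= 30))
})

test_that("manifest statuses equal statuses recomputed from the files", {
  l <- sim_loaded()
  st <- mark_status(l$classified, irrs = l$irr, reads24 = l$reads24,
                    domains = l$k27)
  cmp <- dplyr::inner_join(st, l$manifest, by = "transcript_id",
                           suffix = c("", ".t"))
  expect_equal(nrow(cmp), nrow(l$manifest))
  expect_true(all(cmp$irr == cmp$irr.t))
  expect_true(all(cmp$sirna == cmp$sirna.t))
  expect_true(all(cmp$k27 == cmp$k27.t))
})

test_that("realized overlap fractions track the configured targets", {
  l <- sim_loaded()
  cfg <- sim_fixture()$config
  for (cls in c("lincRNA", "NAT")) {
    m <- l$manifest[l$manifest$class == cls, ]
    n <- nrow(m)
    for (mark in c("irr", "sirna", "k27")) {
      target <- switch(mark, irr = cfg$irr_overlap_fraction[[cls]],
                       sirna = cfg$sirna_overlap_fraction[[cls]],
                       k27 = cfg$h3k27_fraction[[cls]])
      se <- sqrt(target * (1 - target) / n)
      # planted by exact count, so only rounding separates them
      expect_lt(abs(mean(m[[mark]]) - target), max(3 * se, 1 / n + 1e-9))
    }
  }
})

test_that("zero methylation boost leaves regions at background level", {
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 250000,
                    n_genes = 15, n_lincRNA = 25, n_NAT = 8, n_incRNA = 4,
                    n_putative_mRNA = 6, cytosine_density = 0.03,
                    gap_mean = 800, methylation_boost = 0)
  out <- generate_dataset(cfg, withr::local_tempdir())
  cx <- read_cx_report(out$paths$cx_report)
  irr <- read_bed(out$paths$irr_bed)
  chh <- cx[cx$context == "CHH" & !cx$zero_coverage, ]
  inside <- rep(FALSE, nrow(chh))
  for (i in seq_len(nrow(irr))) {
    inside <- inside | (chh$start >= irr$start[i] & chh$end <= irr$end[i])
  }
  lv_in <- chh$mc[inside] / (chh$mc[inside] + chh$umc[inside])
  lv_out <- chh$mc[!inside] / (chh$mc[!inside] + chh$umc[!inside])
  reads_in <- sum(chh$mc[inside] + chh$umc[inside])
  p0 <- cfg$methylation_base[["CHH"]]
  se <- sqrt(p0 * (1 - p0) * (1 / reads_in +
                                1 / sum(chh$mc[!inside] + chh$umc[!inside])))
  m_in <- sum(chh$mc[inside]) / reads_in
  m_out <- sum(chh$mc[!inside]) / sum(chh$mc[!inside] + chh$umc[!inside])
  expect_lt(abs(m_in - m_out), 3 * se)
})

test_that("worked tables are emitted as parseable fixtures", {
  d <- withr::local_tempdir()
  paths <- emit_worked_tables(d)
  bm <- read_band_matrix(paths$band_matrix)
  expect_equal(nrow(bm), 12)
  expect_equal(ncol(bm), 10)
  expect_equal(bm$lncRNA[2], "M26919")
  expect_true(all(bm[bm$lncRNA == "M26919", -1] == "+++"))
  cp <- readr::read_tsv(paths$count_pairs, show_col_types = FALSE)
  expect_equal(cp$k[cp$class == "lincRNA" & cp$mark == "irr"], 763)
  expect_equal(cp$n[cp$class == "lincRNA" & cp$mark == "irr"], 1173)
  expect_equal(cp$k[cp$class == "incRNA" & cp$mark == "irr"], 66)
})
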