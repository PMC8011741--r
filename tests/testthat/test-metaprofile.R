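# Metagene profiles: binning, strand handling, aggregation, conservation.

test_that("uniform coverage gives 1.0 in every bin", {
  f <- genomic_intervals("c1", 10000, 12000, "+")
  sig <- signal_coverage(genomic_intervals("c1", 0, 50000))
  pr <- feature_profile(f, sig, body_bins = 10, flank_bp = 1000,
                        flank_bins = 5)
  expect_equal(nrow(pr), 20)
  expect_true(all(abs(pr$value - 1) < 1e-12))
})

test_that("signal confined to flanks leaves body bins at zero", {
  f <- genomic_intervals("c1", 10000, 12000, "+")
  sig <- signal_coverage(genomic_intervals("c1", c(9000, 12000),
                                           c(10000, 13000)))
  pr <- feature_profile(f, sig, body_bins = 10, flank_bp = 1000,
                        flank_bins = 5)
  expect_true(all(pr$value[pr$segment == "body"] == 0))
  expect_true(all(pr$value[pr$segment != "body"] > 0))
})

test_that("minus-strand profiles mirror plus-strand ones", {
  # ascending per-base signal: value v on [10000+100*(v-1), 10000+100*v)
  steps <- genomic_intervals("c1", 10000 + 100 * (0:19), 10000 + 100 * (1:20))
  sig <- signal_coverage(steps, value = 1:20)
  fp <- feature_profile(genomic_intervals("c1", 10000, 12000, "+"), sig,
                        body_bins = 20, flank_bp = 0, flank_bins = 1)
  fm <- feature_profile(genomic_intervals("c1", 10000, 12000, "-"), sig,
                        body_bins = 20, flank_bp = 0, flank_bins = 1)
  bp <- fp$value[fp$segment == "body"]
  bm <- fm$value[fm$segment == "body"]
  expect_equal(bp, 1:20)
  expect_equal(bm, rev(bp))
})

test_that("per-bin values match a brute-force per-base oracle", {
  set.seed(51)
  for (rep in 1:8) {
    L <- sample(200:900, 1)
    s0 <- sample(3000:5000, 1)
    f <- genomic_intervals("c1", s0, s0 + L,
                           sample(c("+", "-"), 1))
    reads <- rand_intervals(30, span = 10000, max_w = 60)
    sig <- signal_coverage(reads)
    bb <- sample(3:12, 1)
    pr <- feature_profile(f, sig, body_bins = bb, flank_bp = 200,
                          flank_bins = 2)
    # per-base coverage then mean per bin, bins re-derived independently
    cov <- rep(0, 12000)
    for (i in seq_len(nrow(reads))) {
      cov[(reads$start[i] + 1):reads$end[i]] <-
        cov[(reads$start[i] + 1):reads$end[i]] + 1
    }
    edges_body <- s0 + floor((0:bb) * L / bb)
    edges <- c(seq(s0 - 200, s0, by = 100)[1:2], edges_body[-1],
               s0 + L + c(100, 200))
    starts <- c(seq(s0 - 200, s0 - 100, by = 100), edges_body[-(bb + 1)],
                s0 + L, s0 + L + 100)
    ends <- c(starts[1:2] + 100, edges_body[-1], s0 + L + 100, s0 + L + 200)
    want <- vapply(seq_along(starts), function(i) {
      if (ends[i] <= starts[i]) return(NA_real_)
      mean(cov[(starts[i] + 1):ends[i]])
    }, numeric(1))
    if (f$strand == "-") want <- rev(want)
    expect_equal(pr$value, want, tolerance = 1e-12)
  }
})

test_that("binning conserves total signal over the body", {
  set.seed(52)
  f <- genomic_intervals("c1", 5000, 6000, "+")
  reads <- rand_intervals(40, span = 8000, max_w = 50)
  # clip reads to the body so all their signal lands inside it
  reads <- reads[reads$start >= 5000 & reads$end <= 6000, ]
  if (nrow(reads) >= 1) {
    sig <- signal_coverage(reads)
    pr <- feature_profile(f, sig, body_bins = 10, flank_bp = 0,
                          flank_bins = 1)
    body <- pr[pr$segment == "body", ]
    total <- sum(body$value * 100) # each bin is 100 bp wide
    expect_equal(total, sum(reads$end - reads$start), tolerance = 1e-9)
  }
})

test_that("methylation bins are read-weighted and undefined without sites", {
  cx <- tibble::tibble(chrom = "c1", start = c(150, 160, 450), end = start + 1,
                       strand = "+", context = "CHH",
                       mc = c(2, 8, 5), umc = c(8, 2, 5),
                       zero_coverage = FALSE)
  sig <- signal_methylation(cx, "CHH")
  f <- genomic_intervals("c1", 100, 500, "+")
  pr <- feature_profile(f, sig, body_bins = 4, flank_bp = 0, flank_bins = 1)
  body <- pr$value[pr$segment == "body"]
  expect_equal(body[1], 10 / 20) # two sites pooled by reads
  expect_true(is.na(body[2]))
  expect_equal(body[4], 0.5)
})

test_that("aggregation averages features and keeps single features intact", {
  f2 <- genomic_intervals("c1", c(1000, 3000), c(2000, 4000), "+")
  sig <- signal_coverage(genomic_intervals("c1", c(0, 2500), c(2500, 10000)),
                         value = c(1, 3))
  ag <- aggregate_profiles(f2, sig, body_bins = 5, flank_bp = 0,
                           flank_bins = 1)
  expect_true(all(ag$value[ag$segment == "body"] == 2))
  single <- aggregate_profiles(f2[1, ], sig, body_bins = 5, flank_bp = 0,
                               flank_bins = 1)
  indiv <- feature_profile(f2[1, ], sig, body_bins = 5, flank_bp = 0,
                           flank_bins = 1)
  expect_equal(single$value, indiv$value)
  expect_equal(attr(ag, "n_features"), 2)
})

test_that("flanks truncated at the chromosome origin are flagged", {
  f <- genomic_intervals("c1", 50, 500, "+")
  sig <- signal_coverage(genomic_intervals("c1", 0, 1000))
  pr <- feature_profile(f, sig, body_bins = 2, flank_bp = 200, flank_bins = 2)
  expect_true(any(pr$truncated))
  expect_true(is.na(pr$value[1])) # fully off-chromosome bin undefined
})

test_that("boosted IRR methylation shows up in the IRR profile on synthetic data", {
  l <- sim_loaded()
  sig <- signal_methylation(l$cx, "CHH")
  irr_pr <- aggregate_profiles(l$irr %>% dplyr::mutate(strand = "."),
                               sig, body_bins = 5, flank_bp = 500,
                               flank_bins = 3)
  set.seed(53)
  rand <- tibble::tibble(chrom = "A02",
                         start = (s <- sample.int(150000, 80)), end = s + 300,
                         strand = ".")
  rand_pr <- aggregate_profiles(rand, sig, body_bins = 5, flank_bp = 500,
                                flank_bins = 3)
  body_irr <- irr_pr$value[irr_pr$segment == "body"]
  body_rand <- rand_pr$value[rand_pr$segment == "body"]
  expect_true(all(body_irr > body_rand))
})
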