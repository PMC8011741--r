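# HSP chaining, coverage and band-matrix summaries.

mk_hsp <- function(qs, qe, ss, se, bits, query = "q1", subject = "s1",
                   genome = "g", evalue = 1e-30) {
  tibble::tibble(
    query_id = query, subject_id = subject, pident = 95,
    align_length = qe - qs + 1, mismatch = 0, gapopen = 0,
    query_start = qs, query_end = qe, subject_start = ss, subject_end = se,
    evalue = evalue, bitscore = bits, genome = genome,
    subject_strand = ifelse(ss <= se, "+", "-")
  )
}
qlen <- function(id = "q1", len = 400) {
  tibble::tibble(query_id = id, query_length = len)
}

test_that("single and overlapping HSPs give merged coverage", {
  one <- mk_hsp(1, 200, 1000, 1199, 300)
  got <- chain_hsps(one, qlen())
  expect_equal(got$coverage, 0.5)
  two <- dplyr::bind_rows(mk_hsp(1, 100, 1000, 1099, 150),
                          mk_hsp(51, 200, 1050, 1199, 200))
  got2 <- chain_hsps(two, qlen())
  expect_equal(got2$n_hsps, 2L)
  expect_equal(got2$coverage, 0.5) # merged 1..200, no double counting
})

test_that("queries with no passing HSP get coverage 0", {
  weak <- mk_hsp(1, 200, 1000, 1199, 300, evalue = 1e-3)
  got <- chain_hsps(weak, qlen())
  expect_equal(got$coverage, 0)
  expect_equal(got$n_hsps, 0L)
})

test_that("coverage is invariant to row order and duplication", {
  set.seed(71)
  h <- dplyr::bind_rows(
    mk_hsp(1, 100, 1000, 1099, 150),
    mk_hsp(150, 260, 1200, 1310, 180),
    mk_hsp(300, 380, 1500, 1580, 120)
  )
  a <- chain_hsps(h, qlen())
  b <- chain_hsps(h[sample(3), ], qlen())
  d <- chain_hsps(dplyr::bind_rows(h, h), qlen())
  expect_equal(a$coverage, b$coverage)
  expect_equal(a$coverage, d$coverage)
  expect_equal(a$total_score, d$total_score)
})

# exhaustive oracle over all subsets respecting the colinearity predicate
best_chain_oracle <- function(h, max_gap) {
  n <- nrow(h)
  minus <- h$subject_start[1] > h$subject_end[1]
  s_lo <- pmin(h$subject_start, h$subject_end)
  s_hi <- pmax(h$subject_start, h$subject_end)
  ok_pair <- function(i, j) {
    if (!(h$query_start[j] >= h$query_start[i] &&
          h$query_end[j] >= h$query_end[i])) return(FALSE)
    if (minus) {
      s_hi[j] <= s_hi[i] && s_lo[j] <= s_lo[i] && (s_lo[i] - s_hi[j]) <= max_gap
    } else {
      s_lo[j] >= s_lo[i] && s_hi[j] >= s_hi[i] && (s_lo[j] - s_hi[i]) <= max_gap
    }
  }
  best <- 0
  for (m in 1:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    idx <- idx[order(h$query_start[idx], h$query_end[idx], s_lo[idx])]
    valid <- TRUE
    if (length(idx) > 1) {
      for (t in 2:length(idx)) {
        if (!ok_pair(idx[t - 1], idx[t])) { valid <- FALSE; break }
      }
    }
    if (valid) best <- max(best, sum(h$bitscore[idx]))
  }
  best
}

test_that("DP chain score equals exhaustive subset enumeration", {
  set.seed(72)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    minus <- runif(1) < 0.5
    qs <- sort(sample.int(900, n))
    qe <- qs + sample.int(120, n)
    w <- qe - qs
    base <- sample.int(5000, n)  # deliberately unordered on the subject
    h <- if (minus) {
      mk_hsp(qs, qe, ss = 9000 - base, se = 9000 - base - w,
             bits = sample.int(200, n))
    } else {
      mk_hsp(qs, qe, ss = base, se = base + w, bits = sample.int(200, n))
    }
    max_gap <- sample(c(100, 1000, 10000), 1)
    got <- chain_hsps(h, qlen(len = 1200), max_gap = max_gap)
    expect_equal(got$total_score, best_chain_oracle(h, max_gap))
  }
})

test_that("the best-scoring subject group is chosen as representative", {
  h <- dplyr::bind_rows(
    mk_hsp(1, 100, 1000, 1099, 150, subject = "sA"),
    mk_hsp(120, 300, 2000, 2180, 280, subject = "sB")
  )
  got <- chain_hsps(h, qlen())
  expect_equal(got$subject_id, "sB")
  expect_equal(got$coverage, 181 / 400)
})

test_that("planted per-genome conservation ordering is recovered", {
  l <- sim_loaded()
  calls <- chain_hsps(l$hsps, l$classified)
  cs <- coverage_summary(calls, l$classified)
  means <- cs %>%
    dplyr::group_by(genome) %>%
    dplyr::summarise(m = mean(mean_coverage), .groups = "drop")
  m <- setNames(means$m, means$genome)
  expect_gt(m[["B_oleracea"]], m[["B_nigra"]])
  expect_gt(m[["B_nigra"]], m[["B_juncea"]])
  expect_gt(m[["B_napus"]], m[["B_juncea"]])
})

test_that("band summary of the worked matrix matches the published counts", {
  bm <- worked_band_matrix()
  got <- band_summary(bm, worked_line_groups())
  rapa <- got[got$line_group == "B_rapa", ]
  oler <- got[got$line_group == "B_oleracea", ]
  expect_equal(rapa$n_rows[rapa$n_strong == 6], 7)   # expressed in all six lines
  expect_equal(oler$n_rows[oler$n_strong == 3], 6)   # all three cultivars
  expect_equal(oler$n_rows[oler$n_strong == 2], 1)
  expect_equal(oler$n_rows[oler$n_strong == 1], 1)
  expect_equal(oler$n_rows[oler$n_strong == 0], 4)   # not/slightly expressed
  # categories are exhaustive
  expect_equal(sum(rapa$n_rows), nrow(bm))
  expect_equal(sum(oler$n_rows), nrow(bm))
})

test_that("an all-absent matrix has zero strong counts everywhere", {
  m <- worked_band_matrix()
  m[, -1] <- "-"
  got <- band_summary(m, worked_line_groups())
  expect_true(all(got$n_rows[got$n_strong > 0] == 0))
  expect_true(all(got$n_rows[got$n_strong == 0] == nrow(m)))
})

test_that("unknown band symbols are rejected", {
  m <- worked_band_matrix()
  m[1, 2] <- "++"
  expect_error(band_summary(m, worked_line_groups()), "unknown band symbol")
})
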