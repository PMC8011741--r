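# Stratified expression t-tests and length ANOVA.

mk_status <- function(ids, class, flag) {
  tibble::tibble(transcript_id = ids, class = class, sirna = flag,
                 irr = FALSE, k27 = FALSE)
}
mk_fpkm <- function(ids, values) {
  tibble::tibble(transcript_id = ids, replicate = "rep1", fpkm = values)
}

test_that("identical strata give t = 0, p = 1, no stars", {
  ids <- paste0("t", 1:6)
  st <- mk_status(ids, "lincRNA", rep(c(TRUE, FALSE), each = 3))
  fp <- mk_fpkm(ids, c(1, 2, 3, 1, 2, 3))
  got <- strata_compare(fp, st, mark = "sirna", classes = "lincRNA")
  expect_equal(got$t, 0)
  expect_equal(got$p_value, 1)
  expect_equal(got$stars, "")
})

test_that("well-separated strata reach p < 0.001, checked in closed form", {
  pos <- c(10, 11, 12, 13); neg <- c(1, 2, 2, 3)
  ids <- paste0("t", 1:8)
  st <- mk_status(ids, "NAT", rep(c(TRUE, FALSE), each = 4))
  fp <- mk_fpkm(ids, c(pos, neg))
  got <- strata_compare(fp, st, mark = "sirna", classes = "NAT")
  # pooled-variance t with 6 df, computed from first principles
  sp2 <- (3 * var(pos) + 3 * var(neg)) / 6
  t_manual <- (mean(pos) - mean(neg)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$t, t_manual)
  expect_equal(got$df, 6)
  # 5.959 is the two-sided 0.001 critical value of t with 6 df
  expect_gt(got$t, 5.959)
  expect_lt(got$p_value, 0.001)
  expect_equal(got$stars, "***")
})

test_that("t is antisymmetric under swapping strata; p invariant", {
  set.seed(61)
  ids <- paste0("t", 1:20)
  flag <- rep(c(TRUE, FALSE), 10)
  vals <- rlnorm(20)
  a <- strata_compare(mk_fpkm(ids, vals), mk_status(ids, "lincRNA", flag),
                      mark = "sirna", classes = "lincRNA")
  b <- strata_compare(mk_fpkm(ids, vals), mk_status(ids, "lincRNA", !flag),
                      mark = "sirna", classes = "lincRNA")
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
})

test_that("tiny strata are skipped as NA", {
  ids <- paste0("t", 1:4)
  st <- mk_status(ids, "incRNA", c(TRUE, FALSE, FALSE, FALSE))
  got <- strata_compare(mk_fpkm(ids, 1:4), st, mark = "sirna",
                        classes = "incRNA")
  expect_true(is.na(got$p_value))
  expect_equal(got$n_pos, 1L)
})

test_that("replicates are averaged per transcript before testing", {
  ids <- c("a", "b", "c", "d")
  st <- mk_status(ids, "lincRNA", c(TRUE, TRUE, FALSE, FALSE))
  wide <- tibble::tibble(transcript_id = ids, rep1 = c(10, 13, 1, 3),
                         rep2 = c(14, 11, 3, 3))
  got <- strata_compare(wide, st, mark = "sirna", classes = "lincRNA")
  expect_equal(got$mean_pos, 12)
  expect_equal(got$mean_neg, 2.5)
  expect_equal(got$n_pos, 2L) # transcripts, not replicates
})

test_that("pooled t-test agrees with a permutation test on a small fixture", {
  set.seed(62)
  pos <- c(4.1, 5.2, 6.3, 4.8, 5.5)
  neg <- c(3.0, 3.9, 4.4, 3.2, 4.0)
  ids <- paste0("t", 1:10)
  st <- mk_status(ids, "NAT", rep(c(TRUE, FALSE), each = 5))
  got <- strata_compare(mk_fpkm(ids, c(pos, neg)), st, mark = "sirna",
                        classes = "NAT")
  all_v <- c(pos, neg)
  obs <- abs(mean(pos) - mean(neg))
  perm <- replicate(10000, {
    idx <- sample(10, 5)
    abs(mean(all_v[idx]) - mean(all_v[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(got$p_value - p_perm), 0.02)
})

test_that("the planted siRNA expression effect is detected on synthetic data", {
  l <- sim_loaded()
  st <- mark_status(l$classified, irrs = l$irr, reads24 = l$reads24,
                    domains = l$k27)
  got <- strata_compare(l$fpkm, st, mark = "sirna", classes = "lincRNA")
  expect_gt(got$mean_pos, got$mean_neg)
  # at this small n the direction is the reliable signal; the log2 scale
  # stabilises the heavy-tailed FPKM and the full-size suite asserts
  # significance
  lg <- strata_compare(l$fpkm, st, mark = "sirna", classes = "lincRNA",
                       log2 = TRUE)
  expect_gt(lg$mean_pos, lg$mean_neg)
})

test_that("ANOVA letter groups separate well-separated classes", {
  set.seed(63)
  d <- tibble::tibble(
    class = rep(c("lincRNA", "NAT"), each = 20),
    length = c(rnorm(20, 700, 50), rnorm(20, 1300, 50))
  )
  fit <- anova_lengths(d)
  expect_lt(fit$p_value, 1e-6)
  expect_equal(unname(nchar(fit$table$letters)), c(1, 1))
  expect_false(fit$table$letters[1] == fit$table$letters[2])
  # overlapping classes share a letter
  d2 <- tibble::tibble(class = rep(c("a", "b"), each = 20),
                       length = rnorm(40, 700, 100))
  fit2 <- anova_lengths(d2)
  expect_equal(fit2$table$letters, c("a", "a"))
})

test_that("constant equal classes give F = 0", {
  d <- tibble::tibble(class = rep(c("a", "b"), each = 3), length = 1)
  fit <- anova_lengths(d)
  expect_equal(fit$f_statistic, 0)
})

test_that("tidy and glance return the broom-style tables", {
  set.seed(64)
  d <- tibble::tibble(class = rep(c("a", "b", "c"), each = 10),
                      length = rnorm(30, rep(c(500, 800, 1200), each = 10), 80))
  fit <- anova_lengths(d)
  td <- tidy(fit)
  expect_true(all(c("class", "n", "mean_length", "letters") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$p_value < 0.001)
})

test_that("type-I error is near nominal under the null", {
  set.seed(65)
  n_rep <- 1000
  ids <- paste0("t", 1:40)
  flag <- rep(c(TRUE, FALSE), each = 20)
  st <- mk_status(ids, "lincRNA", flag)
  rej <- vapply(seq_len(n_rep), function(i) {
    fp <- mk_fpkm(ids, rnorm(40, 10, 2))
    strata_compare(fp, st, mark = "sirna", classes = "lincRNA")$p_value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})
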