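# Stratified expression comparisons and class-wise length ANOVA.
#
# Expression tests compare transcripts with (+) and without (-) a mark
# within each class by a two-sided pooled-variance (Student) t-test on
# per-transcript mean FPKM; replicates are averaged per transcript first,
# because the transcript, not the replicate, is the sampling unit.
# Class-wise length differences use one-way ANOVA with Bonferroni-corrected
# pairwise t-tests for the compact letter display.

stars_for <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Mean expression per transcript
#'
#' @param fpkm Long FPKM tibble ([read_fpkm_table()]) or a wide table with a
#'   `transcript_id` column.
#' @return Tibble `transcript_id`, `fpkm` (replicate mean).
#' @export
mean_fpkm <- function(fpkm) {
  if (!"fpkm" %in% names(fpkm)) {
    fpkm <- tidyr::pivot_longer(fpkm, -"transcript_id",
                                names_to = "replicate", values_to = "fpkm")
  }
  fpkm %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(fpkm = mean(.data$fpkm), .groups = "drop")
}

#' Compare expression of mark-positive vs mark-negative transcripts
#'
#' For each class, runs a two-sided equal-variance Student t-test of mean
#' FPKM between transcripts with and without the mark, and assigns
#' significance stars at 0.05 / 0.01 / 0.001. A stratum with fewer than two
#' members yields `NA` statistics.
#'
#' @param fpkm Long or wide FPKM table.
#' @param statuses Tibble from [mark_status()] (columns `transcript_id`,
#'   `class` and the mark columns).
#' @param mark Name of the logical status column to stratify on
#'   (`"irr"`, `"sirna"` or `"k27"`).
#' @param classes Classes to test.
#' @param log2 Test on `log2(FPKM + 1)` instead of raw FPKM.
#' @return Tibble `class`, `mark`, `n_pos`, `n_neg`, `mean_pos`,
#'   `mean_neg`, `t`, `df`, `p_value`, `stars`.
#' @export
strata_compare <- function(fpkm, statuses, mark = "sirna",
                           classes = LNC_CLASSES, log2 = FALSE) {
  stopifnot(mark %in% names(statuses))
  expr <- mean_fpkm(fpkm)
  if (log2) expr$fpkm <- log2(expr$fpkm + 1)
  d <- statuses %>%
    dplyr::inner_join(expr, by = "transcript_id") %>%
    dplyr::filter(.data$class %in% classes)
  purrr::map_dfr(intersect(classes, unique(d$class)), function(cl) {
    dc <- d[d$class == cl, ]
    pos <- dc$fpkm[dc[[mark]]]
    neg <- dc$fpkm[!dc[[mark]]]
    base <- tibble(class = cl, mark = mark,
                   n_pos = length(pos), n_neg = length(neg),
                   mean_pos = if (length(pos)) mean(pos) else NA_real_,
                   mean_neg = if (length(neg)) mean(neg) else NA_real_)
    if (length(pos) < 2 || length(neg) < 2) {
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_,
                           p_value = NA_real_, stars = NA_character_))
    }
    if (sd(pos) == 0 && sd(neg) == 0) {
      # degenerate strata: no within-group variance for the t-test
      same <- isTRUE(all.equal(mean(pos), mean(neg)))
      return(dplyr::mutate(base, t = if (same) 0 else sign(mean(pos) - mean(neg)) * Inf,
                           df = length(pos) + length(neg) - 2,
                           p_value = if (same) 1 else 0,
                           stars = stars_for(if (same) 1 else 0)))
    }
    tt <- t.test(pos, neg, var.equal = TRUE)
    dplyr::mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, stars = stars_for(tt$p.value))
  })
}

#' One-way ANOVA of transcript lengths across classes
#'
#' Fits `length ~ class`, then derives a compact letter display from
#' Bonferroni-corrected pairwise pooled-variance t-tests: classes sharing a
#' letter are not significantly different at `alpha`.
#'
#' @param transcripts Classified model tibble, or any tibble with `class`
#'   and `length` columns.
#' @param classes Classes to include; classes with < 2 members are dropped
#'   with a warning.
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @return An object of class `lnc_anova` with `tidy()` and `glance()`
#'   methods; `$letters` maps class to letter group.
#' @export
anova_lengths <- function(transcripts, classes = unique(transcripts$class),
                          alpha = 0.05) {
  d <- transcripts %>%
    dplyr::filter(.data$class %in% classes) %>%
    dplyr::select("class", "length")
  sizes <- table(d$class)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("class(es) with < 2 members excluded: ", paste(small, collapse = ", "))
    d <- d[!(d$class %in% small), ]
  }
  if (dplyr::n_distinct(d$class) < 2) stop("need >= 2 classes with >= 2 members")
  d$class <- factor(d$class)
  if (sd(d$length) == 0) {
    # all lengths identical: zero between- and within-group variance
    lv <- levels(d$class)
    return(structure(list(
      table = tibble(class = lv, n = as.integer(table(d$class)[lv]),
                     mean_length = rep(d$length[1], length(lv)),
                     letters = rep("a", length(lv))),
      f_statistic = 0, p_value = 1,
      df_between = length(lv) - 1, df_within = nrow(d) - length(lv),
      pairwise_p = NULL, alpha = alpha), class = "lnc_anova"))
  }
  fit <- aov(length ~ class, data = d)
  sm <- summary(fit)[[1]]
  fstat <- sm[["F value"]][1]
  pval <- sm[["Pr(>F)"]][1]
  if (is.nan(fstat) && sm[["Sum Sq"]][1] == 0) {
    # all group means identical and zero residual variance
    fstat <- 0; pval <- 1
  }

  lv <- levels(d$class)
  pw <- stats::pairwise.t.test(d$length, d$class, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  # symmetric matrix of "not significantly different" relations
  ns <- matrix(TRUE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in rownames(pw$p.value)) {
    for (j in colnames(pw$p.value)) {
      pij <- pw$p.value[i, j]
      if (!is.na(pij)) ns[i, j] <- ns[j, i] <- pij >= alpha
    }
  }
  letters_map <- letter_groups(ns, order(-tapply(d$length, d$class, mean)))

  structure(
    list(
      table = tibble(class = lv,
                     n = as.integer(table(d$class)[lv]),
                     mean_length = as.numeric(tapply(d$length, d$class, mean)[lv]),
                     letters = unname(letters_map[lv])),
      f_statistic = fstat, p_value = pval,
      df_between = sm$Df[1], df_within = sm$Df[2],
      pairwise_p = pw$p.value, alpha = alpha
    ),
    class = "lnc_anova"
  )
}

# Compact letter display from a logical "not different" matrix: enumerate
# maximal cliques (feasible for the handful of classes at play), order them
# by the supplied class ranking, letter them a, b, c, ...
letter_groups <- function(ns, rank_order) {
  lv <- rownames(ns)
  k <- length(lv)
  subsets <- lapply(seq_len(2^k) - 1, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) > 0 && all(ns[s, s, drop = FALSE])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) length(setdiff(cliques[[i]], o)) == 0 &&
                  length(o) > length(cliques[[i]]), logical(1)))
  }, logical(1))]
  # order cliques by the best-ranked member so 'a' goes to the top group
  pos <- vapply(maximal, function(s) min(match(s, rank_order)), numeric(1))
  maximal <- maximal[order(pos)]
  out <- setNames(rep("", k), lv)
  for (i in seq_along(maximal)) {
    mem <- lv[maximal[[i]]]
    out[mem] <- paste0(out[mem], letters[i])
  }
  out
}

#' @export
print.lnc_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$table)
  invisible(x)
}

#' @export
tidy.lnc_anova <- function(x, ...) x$table

#' @export
glance.lnc_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}
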