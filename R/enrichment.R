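# GO-term over-representation by hypergeometric test with BH-FDR control.
#
# For each term with at least one study hit: k = study genes annotated with
# the term, n = study size, K = population genes with the term, N =
# population size; the p-value is the upper tail P(X >= k) of
# hypergeometric(N, K, n). The background population is an explicit input
# (all supplied annotated genes), and terms are tested as given — no
# GO-graph propagation to ancestor terms.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ hypergeometric(N, K, n)`, evaluated in log space by
#' the underlying distribution function for numerical stability.
#'
#' @param k Study hits (successes drawn).
#' @param n Study size (draws).
#' @param K Population hits (successes in the urn).
#' @param N Population size.
#' @return P(X >= k); 1 when `k = 0`.
#' @export
#' @examples
#' hypergeom_upper(3, 5, 5, 20) # 1126/15504
hypergeom_upper <- function(k, n, K, N) {
  bad <- K > N | n > N | k > pmin(n, K) | k < 0 | K < 0 | n < 0 | N < 0
  if (any(bad)) stop("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; q-values are monotone non-decreasing in p-value
#' rank and capped at 1. Empty input yields empty output.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' GO-term enrichment of a study gene set
#'
#' @param study_genes Character vector of study gene ids (deduplicated);
#'   must be a subset of the population.
#' @param population_genes Character vector, the explicit background.
#' @param go_map Tibble `gene`, `term` ([read_go_map()]).
#' @param alpha_fdr FDR level for the `significant` flag (default 0.01).
#' @param term_names Optional tibble `term`, `name`.
#' @return Tibble sorted by `q_value`: `term`, (`name`,) `k`, `n`, `K`,
#'   `N`, `p_value`, `q_value`, `stars` (0.05/0.01/0.001 coding of the raw
#'   p-value), `significant` (`q_value <= alpha_fdr`). Only terms with at
#'   least one study hit are tested.
#' @export
enrich <- function(study_genes, population_genes, go_map, alpha_fdr = 0.01,
                   term_names = NULL) {
  study <- unique(study_genes)
  pop <- unique(population_genes)
  out_of_pop <- setdiff(study, pop)
  if (length(out_of_pop)) {
    stop("study gene(s) missing from population: ",
         paste(head(out_of_pop, 10), collapse = ", "),
         if (length(out_of_pop) > 10) " ..." else "")
  }
  gm <- go_map %>%
    dplyr::filter(.data$gene %in% pop) %>%
    dplyr::distinct(.data$gene, .data$term)
  N <- length(pop)
  n <- length(study)
  tab <- gm %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(K = dplyr::n(),
                     k = sum(.data$gene %in% study), .groups = "drop") %>%
    dplyr::filter(.data$k >= 1)
  if (nrow(tab) == 0) {
    return(tibble(term = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p_value = numeric(),
                  q_value = numeric(), stars = character(),
                  significant = logical()))
  }
  tab <- tab %>%
    dplyr::mutate(n = n, N = N,
                  p_value = hypergeom_upper(.data$k, n, .data$K, N)) %>%
    dplyr::mutate(q_value = bh_fdr(.data$p_value),
                  stars = stars_for(.data$p_value),
                  significant = .data$q_value <= alpha_fdr) %>%
    dplyr::select("term", "k", "n", "K", "N", "p_value", "q_value",
                  "stars", "significant") %>%
    dplyr::arrange(.data$q_value, .data$p_value, .data$term)
  if (!is.null(term_names)) {
    tab <- tab %>%
      dplyr::left_join(term_names, by = "term") %>%
      dplyr::relocate("name", .after = "term")
  }
  tab
}
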