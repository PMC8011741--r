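# Metagene profiles: scaled feature body plus fixed-width flanks.
#
# The body of each feature is divided into body_bins near-equal windows
# (floor arithmetic, remainder spread over the leading bins), each flank
# into flank_bins fixed-width windows. Minus-strand features are reversed
# so bin 1 is always at the 5' end. For coverage-type signals (reads,
# bedGraph) a record contributes to every bin it overlaps, weighted by
# overlap length, and the bin value is mean per-base signal — this
# conserves total signal under binning. For methylation the bin value is
# the read-weighted level sum(mc)/sum(mc+umc) over sites in the bin.

#' Coverage-type signal from intervals
#'
#' @param x Interval tibble; each row contributes `value` per base.
#' @param value Per-base value of each record (scalar or per-row).
#' @return Signal object for [feature_profile()] / [aggregate_profiles()].
#' @export
signal_coverage <- function(x, value = 1) {
  validate_intervals(x)
  structure(list(kind = "coverage",
                 data = tibble(chrom = x$chrom, start = x$start, end = x$end,
                               value = rep_len(value, nrow(x)))),
            class = "lnc_signal")
}

#' 24-nt siRNA RPM signal
#'
#' Each read contributes `1e6 / library_size` per base, so bin values are
#' mean per-base RPM.
#'
#' @param reads24 24-nt read tibble (already filtered).
#' @param library_size Total mapped reads in the library.
#' @return Signal object.
#' @export
signal_sirna <- function(reads24, library_size) {
  signal_coverage(reads24, value = rpm(1, library_size))
}

#' bedGraph signal
#' @param bg bedGraph tibble ([read_bedgraph()]).
#' @return Signal object.
#' @export
signal_bedgraph <- function(bg) {
  signal_coverage(bg, value = bg$value)
}

#' Cytosine methylation signal for one context
#' @param cx Cytosine tibble.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return Signal object.
#' @export
signal_methylation <- function(cx, context = "CHH") {
  stopifnot(context %in% METH_CONTEXTS)
  d <- cx %>% dplyr::filter(.data$context == !!context, .data$mc + .data$umc > 0)
  structure(list(kind = "methylation",
                 data = tibble(chrom = d$chrom, start = d$start, end = d$end,
                               mc = d$mc, tot = d$mc + d$umc)),
            class = "lnc_signal")
}

# Per-feature bin table: one row per (feature, bin), 0-based half-open bin
# coordinates, bin_index running 5' -> 3' on the feature's own strand.
profile_bins <- function(features, body_bins = 40L, flank_bp = 2000L,
                         flank_bins = 20L) {
  stopifnot(body_bins >= 1, flank_bins >= 1, flank_bp >= 0)
  n_bins <- 2L * flank_bins + body_bins
  rows <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    L <- f$end - f$start
    body_edges <- f$start + floor((0:body_bins) * L / body_bins)
    lf_edges <- f$start - flank_bp + floor((0:flank_bins) * flank_bp / flank_bins)
    rf_edges <- f$end + floor((0:flank_bins) * flank_bp / flank_bins)
    b <- tibble(
      start = c(lf_edges[-(flank_bins + 1)], body_edges[-(body_bins + 1)],
                rf_edges[-(flank_bins + 1)]),
      end = c(lf_edges[-1], body_edges[-1], rf_edges[-1]),
      side = rep(c("left", "body", "right"),
                 c(flank_bins, body_bins, flank_bins))
    )
    # clip flanks at the chromosome origin; fully off-chrom bins are NA
    b$truncated <- b$start < 0 & b$end > 0
    b$valid <- b$end > 0
    b$start <- pmax(b$start, 0)
    minus <- identical(f$strand, "-")
    b$bin_index <- if (minus) rev(seq_len(n_bins)) else seq_len(n_bins)
    b$segment <- dplyr::case_when(
      b$side == "body" ~ "body",
      (b$side == "left") != minus ~ "5'flank",
      TRUE ~ "3'flank"
    )
    b$feature_row <- i
    b$chrom <- f$chrom
    b
  })
  rows$width <- rows$end - rows$start
  rows$valid <- rows$valid & rows$width > 0
  rows
}

bin_values <- function(bins, signal) {
  stopifnot(inherits(signal, "lnc_signal"))
  bt <- bins %>% dplyr::mutate(strand = ".", row = dplyr::row_number())
  value <- rep(NA_real_, nrow(bt))
  ok <- bt$valid
  sd_ <- signal$data
  if (any(ok) && nrow(sd_) > 0) {
    prs <- overlap_pairs(bt[ok, ], sd_ %>% dplyr::mutate(strand = "."))
    if (signal$kind == "coverage") {
      agg <- tibble(row = bt$row[ok][prs$query_row],
                    v = prs$overlap * sd_$value[prs$subject_row]) %>%
        dplyr::group_by(.data$row) %>%
        dplyr::summarise(v = sum(.data$v), .groups = "drop")
      value[ok] <- 0 # covered genome, no signal record -> 0 per base
      value[agg$row] <- agg$v
      value[ok] <- value[ok] / bt$width[ok]
    } else {
      agg <- tibble(row = bt$row[ok][prs$query_row],
                    mc = sd_$mc[prs$subject_row],
                    tot = sd_$tot[prs$subject_row]) %>%
        dplyr::group_by(.data$row) %>%
        dplyr::summarise(level = sum(.data$mc) / sum(.data$tot),
                         .groups = "drop")
      value[agg$row] <- agg$level
    }
  } else if (any(ok) && signal$kind == "coverage") {
    value[ok] <- 0
  }
  value
}

#' Profile a single feature
#'
#' @param feature One-row interval tibble.
#' @param signal Signal object (`signal_*()` constructors).
#' @param body_bins Number of scaled body windows (default 40).
#' @param flank_bp Flank width in bases on each side (default 2000).
#' @param flank_bins Number of fixed-width windows per flank (default 20).
#' @return Tibble `bin_index`, `segment`, `value` ordered 5' to 3';
#'   `value` is `NA` for bins with no defined signal (methylation) or that
#'   fall off the chromosome start.
#' @export
feature_profile <- function(feature, signal, body_bins = 40L,
                            flank_bp = 2000L, flank_bins = 20L) {
  stopifnot(nrow(feature) == 1)
  bins <- profile_bins(feature, body_bins, flank_bp, flank_bins)
  bins$value <- bin_values(bins, signal)
  bins %>%
    dplyr::arrange(.data$bin_index) %>%
    dplyr::select("bin_index", "segment", "value", "truncated")
}

#' Aggregate profile over a feature set
#'
#' Per-bin mean over features, ignoring undefined bins.
#'
#' @param features Interval tibble (>= 1 row).
#' @param signal Signal object.
#' @inheritParams feature_profile
#' @return A `lnc_metaprofile` tibble: `bin_index`, `segment`, `value`,
#'   `n` (features contributing to the bin), with the spec recorded in
#'   attributes.
#' @export
aggregate_profiles <- function(features, signal, body_bins = 40L,
                               flank_bp = 2000L, flank_bins = 20L) {
  stopifnot(nrow(features) >= 1)
  bins <- profile_bins(features, body_bins, flank_bp, flank_bins)
  bins$value <- bin_values(bins, signal)
  out <- bins %>%
    dplyr::group_by(.data$bin_index) %>%
    dplyr::summarise(segment = dplyr::first(.data$segment),
                     value = if (all(is.na(.data$value))) NA_real_
                             else mean(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop") %>%
    dplyr::arrange(.data$bin_index)
  if (all(is.na(out$value))) stop("no defined signal in any bin")
  attr(out, "n_features") <- nrow(features)
  attr(out, "spec") <- list(body_bins = body_bins, flank_bp = flank_bp,
                            flank_bins = flank_bins, kind = signal$kind)
  class(out) <- c("lnc_metaprofile", class(out))
  out
}
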