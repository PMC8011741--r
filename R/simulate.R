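# Synthetic dataset generator with a ground-truth manifest.
#
# The generator lays out a toy genome of A01-style chromosomes in which
# every transcript's class is guaranteed by construction: lincRNAs and
# putative mRNAs are placed in intergenic space, NATs start inside the
# first exon of a host gene on the opposite strand, and incRNAs sit wholly
# inside one intron of a host gene. Marks are planted per transcript:
# IRR intervals and H3K27me3 domains are drawn inside the spans of
# transcripts selected as positive (and in guaranteed-free intergenic
# zones as background), so a transcript's true status is unambiguous and
# exactly recoverable from the emitted files. 24-nt siRNA source windows
# are contained in the selected transcripts; off-length (21/22-nt) and
# multi-mapping background reads make the length/uniqueness filters
# non-trivial. Per-site methylated counts are binomial at a per-context
# base level, with beta-distributed region means elevated by a configured
# boost inside IRRs and siRNA windows. FPKM is log-normal with a
# multiplicative effect for siRNA-positive transcripts. Each file type is
# generated under its own RNG stream derived from the master seed, so
# adding one file type never perturbs the others.

#' Simulation configuration
#'
#' Defaults emulate the study conditions this package targets: ten
#' chromosomes, about one thousand noncoding/putative transcripts, the
#' published per-class IRR/siRNA/H3K27me3 overlap fractions, plant-typical
#' CG/CHG/CHH base methylation with an RdDM-style boost inside IRRs and
#' siRNA loci at 20x depth, and a two-fold expression effect for
#' siRNA-overlapping transcripts.
#'
#' @param seed Master RNG seed.
#' @param n_chroms,chrom_length Genome shape (chromosomes named A01, ...).
#' @param n_genes Number of annotated genes.
#' @param n_lincRNA,n_NAT,n_incRNA,n_putative_mRNA Transcript counts per
#'   class; `n_NAT + n_incRNA` must not exceed `n_genes` (each NAT and each
#'   incRNA gets its own host gene).
#' @param irr_overlap_fraction,sirna_overlap_fraction,h3k27_fraction Named
#'   per-class target overlap fractions in `[0, 1]`.
#' @param sirna_in_irr Fraction of siRNA-positive transcripts drawn from
#'   the IRR-positive subset (plants the nested siRNA-in-IRR structure).
#' @param methylation_base Named per-context mean levels (CG, CHG, CHH).
#' @param methylation_boost Additive elevation of region means inside IRRs
#'   and siRNA source windows.
#' @param read_depth Mean reads per cytosine (Poisson).
#' @param cytosine_density Cytosine sites per bp (all contexts combined).
#' @param expression_lognormal `c(mu, sigma)` of log FPKM.
#' @param sirna_expression_effect Multiplicative FPKM effect for
#'   siRNA-positive transcripts.
#' @param n_replicates FPKM replicates.
#' @param exon1_fraction Named per-class single-exon fractions.
#' @param mean_length Named per-class mean transcript lengths (nt).
#' @param conservation Named per-genome presence probability of a homolog.
#' @param conservation_coverage Named per-genome mean query coverage of
#'   present homologs.
#' @return A `lnc_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 10L, chrom_length = 800000L,
                       n_genes = 350L,
                       n_lincRNA = 500L, n_NAT = 230L, n_incRNA = 90L,
                       n_putative_mRNA = 180L,
                       irr_overlap_fraction = c(lincRNA = 0.650, NAT = 0.550,
                                                incRNA = 0.717,
                                                putative_mRNA = 0.641),
                       sirna_overlap_fraction = c(lincRNA = 0.187, NAT = 0.140,
                                                  incRNA = 0.174,
                                                  putative_mRNA = 0.150),
                       h3k27_fraction = c(lincRNA = 0.108, NAT = 0.157,
                                          incRNA = 0.163,
                                          putative_mRNA = 0.108),
                       sirna_in_irr = 0.85,
                       methylation_base = c(CG = 0.40, CHG = 0.20, CHH = 0.08),
                       methylation_boost = 0.20,
                       read_depth = 20,
                       cytosine_density = 0.06,
                       expression_lognormal = c(mu = 1, sigma = 1),
                       sirna_expression_effect = 2,
                       n_replicates = 2L,
                       exon1_fraction = c(lincRNA = 0.657, NAT = 0.724,
                                          incRNA = 0.710,
                                          putative_mRNA = 0.350),
                       mean_length = c(lincRNA = 725, NAT = 1271,
                                       incRNA = 779, putative_mRNA = 1305),
                       conservation = c(B_oleracea = 0.80, B_nigra = 0.55,
                                        B_napus = 0.55, B_juncea = 0.30),
                       conservation_coverage = c(B_oleracea = 0.75,
                                                 B_nigra = 0.60,
                                                 B_napus = 0.60,
                                                 B_juncea = 0.45),
                       gap_mean = 2500) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = n_chroms, chrom_length = chrom_length,
    n_genes = n_genes, n_lincRNA = n_lincRNA, n_NAT = n_NAT,
    n_incRNA = n_incRNA, n_putative_mRNA = n_putative_mRNA,
    irr_overlap_fraction = irr_overlap_fraction,
    sirna_overlap_fraction = sirna_overlap_fraction,
    h3k27_fraction = h3k27_fraction, sirna_in_irr = sirna_in_irr,
    methylation_base = methylation_base, methylation_boost = methylation_boost,
    read_depth = read_depth, cytosine_density = cytosine_density,
    expression_lognormal = expression_lognormal,
    sirna_expression_effect = sirna_expression_effect,
    n_replicates = as.integer(n_replicates),
    exon1_fraction = exon1_fraction, mean_length = mean_length,
    conservation = conservation,
    conservation_coverage = conservation_coverage,
    gap_mean = gap_mean
  )
  fracs <- c(cfg$irr_overlap_fraction, cfg$sirna_overlap_fraction,
             cfg$h3k27_fraction, cfg$sirna_in_irr, cfg$exon1_fraction)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            all(cfg$methylation_base >= 0 & cfg$methylation_base <= 1),
            cfg$read_depth >= 1,
            cfg$n_NAT + cfg$n_incRNA <= cfg$n_genes)
  structure(cfg, class = "lnc_sim_config")
}

# independent RNG stream per file type
stream_seed <- function(seed, k) (as.integer(seed) * 7L + k * 1009L) %% 2147483647L

rlen <- function(n, mean, sdlog = 0.45, lo = 250, hi = 4000) {
  pmin(pmax(round(rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)), lo), hi)
}

# split a total length into k parts, each at least lo (shrunk when the
# total is too small to honour it)
split_len <- function(total, k, lo = 60) {
  if (k == 1) return(total)
  lo <- max(1, min(lo, floor(total / (2 * k))))
  as.numeric(stats::rmultinom(1, total - k * lo, rep(1, k))) + lo
}

#' Generate the complete synthetic dataset
#'
#' Writes every input file the pipeline consumes plus a ground-truth
#' manifest; the same config (including its seed) always produces
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (per-transcript truth),
#'   `regions` (per-region true methylation means), `paths` (named file
#'   paths) and `config`.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "lnc_sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lay <- sim_layout(config)                       # stream 1
  meth <- sim_methylation(config, lay)            # stream 2
  reads <- sim_srna_reads(config, lay)            # stream 3
  fpkm <- sim_expression(config, lay)             # stream 4
  hsps <- sim_hsps(config, lay)                   # stream 5
  go <- sim_go_map(config, lay)                   # stream 6

  p <- list(
    genes_gff = file.path(outdir, "genes.gff3"),
    transcripts_gff = file.path(outdir, "transcripts.gff3"),
    coding_hits = file.path(outdir, "coding_hits.tsv"),
    irr_bed = file.path(outdir, "irr.bed"),
    cx_report = file.path(outdir, "cx_report.tsv"),
    srna = file.path(outdir, "srna_reads.tsv"),
    k27_bed = file.path(outdir, "k27_domains.bed"),
    k27_bedgraph = file.path(outdir, "k27_coverage.bedgraph"),
    fpkm = file.path(outdir, "fpkm.tsv"),
    hsp = file.path(outdir, "hsp_hits.tsv"),
    go_map = file.path(outdir, "go_map.tsv"),
    manifest = file.path(outdir, "manifest.tsv"),
    regions = file.path(outdir, "manifest_regions.tsv"),
    manifest_json = file.path(outdir, "manifest.json")
  )
  write_gff(lay$genes, p$genes_gff)
  write_gff(lay$transcripts, p$transcripts_gff)
  readr::write_tsv(lay$hits, p$coding_hits)
  write_bed(lay$irr %>% dplyr::mutate(strand = "."), p$irr_bed)
  write_cx_report(meth$cx, p$cx_report)
  write_srna_table(reads, p$srna)
  write_bed(lay$k27 %>% dplyr::mutate(strand = "."), p$k27_bed)
  write_bedgraph(lay$bedgraph, p$k27_bedgraph)
  readr::write_tsv(fpkm, p$fpkm)
  write_hsp_table(hsps$hsps, p$hsp)
  readr::write_tsv(go$map, p$go_map)

  manifest <- lay$truth %>%
    dplyr::left_join(hsps$truth, by = "transcript_id")
  readr::write_tsv(manifest, p$manifest)
  readr::write_tsv(meth$regions, p$regions)
  jsonlite::write_json(
    list(config = unclass(config),
         class_counts = as.list(table(manifest$class)),
         conservation_presence = as.list(config$conservation),
         enriched_term = go$enriched_term,
         n_srna_reads = nrow(reads)),
    p$manifest_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(manifest = manifest, regions = meth$regions, paths = p,
                 config = config))
}

# ---- stream 1: genome layout ------------------------------------------------

sim_layout <- function(cfg) {
  set.seed(stream_seed(cfg$seed, 1L))
  chroms <- sprintf("A%02d", seq_len(cfg$n_chroms))

  # host-gene assignment: each NAT and each incRNA gets a distinct gene
  gene_host <- rep("none", cfg$n_genes)
  gene_host[seq_len(cfg$n_NAT)] <- "NAT"
  gene_host[cfg$n_NAT + seq_len(cfg$n_incRNA)] <- "incRNA"
  gene_host <- sample(gene_host)

  units <- c(
    purrr::map(seq_len(cfg$n_genes), ~ list(kind = "gene", host = gene_host[.x])),
    purrr::map(seq_len(cfg$n_lincRNA), ~ list(kind = "lincRNA")),
    purrr::map(seq_len(cfg$n_putative_mRNA), ~ list(kind = "putative_mRNA"))
  )
  units <- sample(units)
  unit_chrom <- rep_len(seq_len(cfg$n_chroms), length(units))

  gene_rows <- list(); tx_rows <- list()
  irr_rows <- list(); sirna_win <- list(); k27_rows <- list()
  free_zones <- list()
  cursor <- setNames(rep(0, cfg$n_chroms), chroms)
  gi <- ti <- 0L

  rgap <- function() min(max(round(rlnorm(1, log(cfg$gap_mean), 1.1)), 150),
                         max(12 * cfg$gap_mean, 1000))

  exon_tbl <- function(id, chrom, strand, starts, ends) {
    tibble(id = id, chrom = chrom, start = starts, end = ends, strand = strand)
  }

  for (u in seq_along(units)) {
    unit <- units[[u]]
    chrom <- chroms[unit_chrom[u]]
    at <- cursor[chrom] + rgap()
    strand <- sample(c("+", "-"), 1)

    if (unit$kind == "gene") {
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      n_ex <- sample(1:6, 1, prob = c(0.151, 0.25, 0.25, 0.2, 0.1, 0.049))
      if (unit$host == "incRNA" && n_ex < 2) n_ex <- 2L
      ex_len <- round(runif(n_ex, 150, 400))
      in_len <- if (n_ex > 1) round(runif(n_ex - 1, 200, 800)) else numeric(0)

      inc_len <- NA
      if (unit$host == "incRNA") {
        inc_len <- rlen(1, cfg$mean_length[["incRNA"]], lo = 250, hi = 2000)
        j <- sample(n_ex - 1, 1)
        in_len[j] <- inc_len + round(runif(1, 120, 400))
        host_intron <- j
      }
      widths <- as.numeric(rbind(ex_len, c(in_len, 0))[seq_len(2 * n_ex - 1)])
      edges <- at + c(0, cumsum(widths))
      ex_idx <- seq(1, 2 * n_ex - 1, by = 2)
      ex_start <- edges[ex_idx]; ex_end <- edges[ex_idx + 1]
      gene_rows[[length(gene_rows) + 1]] <-
        exon_tbl(gid, chrom, strand, ex_start, ex_end)
      unit_end <- edges[length(edges)]

      if (unit$host == "NAT") {
        ti <- ti + 1L
        tid <- sprintf("T%04d", ti)
        nat_len <- rlen(1, cfg$mean_length[["NAT"]], lo = 300)
        nat_strand <- if (strand == "+") "-" else "+"
        nat_start <- ex_start[1] + floor(ex_len[1] / 3)
        single <- runif(1) < cfg$exon1_fraction[["NAT"]]
        if (single) {
          st <- nat_start; en <- nat_start + nat_len
        } else {
          k <- sample(2:3, 1)
          lens <- split_len(nat_len, k, lo = 80)
          gaps <- round(runif(k - 1, 80, 300))
          st <- nat_start + c(0, cumsum(lens[-k] + gaps))
          en <- st + lens
        }
        tx_rows[[length(tx_rows) + 1]] <-
          exon_tbl(tid, chrom, nat_strand, st, en) %>%
          dplyr::mutate(class = "NAT")
        unit_end <- max(unit_end, max(en))
      }
      if (unit$host == "incRNA") {
        ti <- ti + 1L
        tid <- sprintf("T%04d", ti)
        intron_start <- ex_end[host_intron]
        intron_end <- ex_start[host_intron + 1]
        pad <- intron_end - intron_start - inc_len
        off <- round(runif(1, 30, pad - 30))
        single <- runif(1) < cfg$exon1_fraction[["incRNA"]]
        if (single) {
          st <- intron_start + off; en <- st + inc_len
        } else {
          lens <- split_len(inc_len, 2, lo = 80)
          gap2 <- min(round(runif(1, 40, 120)), pad - off - 40)
          st <- intron_start + off + c(0, lens[1] + max(gap2, 10))
          en <- st + lens
          en[2] <- min(en[2], intron_end - 5)
          st[2] <- min(st[2], en[2] - 30)
        }
        tx_rows[[length(tx_rows) + 1]] <-
          exon_tbl(tid, chrom, strand, st, en) %>%
          dplyr::mutate(class = "incRNA")
      }
    } else {
      ti <- ti + 1L
      tid <- sprintf("T%04d", ti)
      cls <- unit$kind
      len <- rlen(1, cfg$mean_length[[cls]], lo = 250)
      single <- runif(1) < cfg$exon1_fraction[[cls]]
      if (single) {
        st <- at; en <- at + len
      } else {
        k <- sample(2:4, 1)
        lens <- split_len(len, k, lo = 80)
        gaps <- round(runif(k - 1, 80, 300))
        st <- at + c(0, cumsum(lens[-k] + gaps))
        en <- st + lens
      }
      tx_rows[[length(tx_rows) + 1]] <-
        exon_tbl(tid, chrom, strand, st, en) %>%
        dplyr::mutate(class = cls)
      unit_end <- max(en)
    }
    free_zones[[length(free_zones) + 1]] <-
      tibble(chrom = chrom, start = cursor[chrom] + 20, end = at - 20)
    cursor[chrom] <- unit_end
    if (cursor[chrom] > cfg$chrom_length) {
      stop("features do not fit on ", chrom,
           "; increase chrom_length or reduce counts")
    }
  }

  gene_ex <- dplyr::bind_rows(gene_rows)
  tx_ex <- dplyr::bind_rows(tx_rows)
  genes <- transcript_models(gene_ex, type = "gene")
  transcripts <- transcript_models(tx_ex %>% dplyr::select(-"class"),
                                   type = "transcript") %>%
    dplyr::left_join(dplyr::distinct(tx_ex, .data$id, .data$class), by = "id")

  free <- dplyr::bind_rows(free_zones) %>%
    dplyr::filter(.data$end - .data$start >= 100)

  # planted mark statuses: exact per-class counts, siRNA nested inside IRR
  truth <- transcripts %>%
    dplyr::select(transcript_id = "id", "class", "chrom", "start", "end",
                  "strand", "length", "n_exons")
  truth$irr <- truth$sirna <- truth$k27 <- FALSE
  for (cls in LNC_CLASSES) {
    idx <- which(truth$class == cls)
    n <- length(idx)
    if (n == 0) next
    irr_pos <- sample(idx, round(cfg$irr_overlap_fraction[[cls]] * n))
    truth$irr[irr_pos] <- TRUE
    m_s <- round(cfg$sirna_overlap_fraction[[cls]] * n)
    from_irr <- min(round(cfg$sirna_in_irr * m_s), length(irr_pos))
    irr_neg <- setdiff(idx, irr_pos)
    n_neg <- min(m_s - from_irr, length(irr_neg))
    s_pos <- c(sample(irr_pos, from_irr),
               if (n_neg > 0) sample(irr_neg, n_neg))
    truth$sirna[s_pos] <- TRUE
    truth$k27[sample(idx, round(cfg$h3k27_fraction[[cls]] * n))] <- TRUE
  }

  place_inside <- function(row, w_lo, w_hi) {
    span <- row$end - row$start
    w <- min(round(runif(1, w_lo, w_hi)), span)
    s <- row$start + sample.int(span - w + 1, 1) - 1
    tibble(chrom = row$chrom, start = s, end = s + w)
  }
  place_free <- function(n, w_lo, w_hi) {
    zones <- free %>% dplyr::filter(.data$end - .data$start >= w_hi + 40)
    pick <- sample.int(nrow(zones), n, replace = TRUE,
                       prob = zones$end - zones$start)
    purrr::map_dfr(pick, function(z) {
      w <- round(runif(1, w_lo, w_hi))
      lo <- zones$start[z] + 20
      s <- lo + sample.int(zones$end[z] - 20 - w - lo + 1, 1) - 1
      tibble(chrom = zones$chrom[z], start = s, end = s + w)
    })
  }

  irr <- dplyr::bind_rows(
    purrr::map_dfr(which(truth$irr), ~ place_inside(truth[.x, ], 80, 400)),
    place_free(150, 100, 1000)
  )
  sirna_windows <- purrr::map_dfr(which(truth$sirna), function(i) {
    place_inside(truth[i, ], 100, 300) %>%
      dplyr::mutate(transcript_id = truth$transcript_id[i])
  })
  k27 <- dplyr::bind_rows(
    purrr::map_dfr(which(truth$k27), function(i) {
      row <- truth[i, ]
      span <- row$end - row$start
      place_inside(row, max(200, 0.4 * span), 0.9 * span)
    }),
    place_free(80, 500, 2000)
  )
  bedgraph <- dplyr::bind_rows(
    k27 %>% dplyr::mutate(value = round(runif(dplyr::n(), 10, 20), 2)),
    place_free(400, 100, 400) %>%
      dplyr::mutate(value = round(runif(dplyr::n(), 0.5, 3), 2))
  ) %>% dplyr::arrange(.data$chrom, .data$start)

  # coding hits: every putative mRNA, plus sub-threshold decoys on lincRNAs
  put <- truth$transcript_id[truth$class == "putative_mRNA"]
  linc <- truth$transcript_id[truth$class == "lincRNA"]
  decoy <- sample(linc, round(0.1 * length(linc)))
  hits <- dplyr::bind_rows(
    tibble(transcript_id = put,
           subject_id = sprintf("sp|Q%05d", sample.int(99999, length(put))),
           evalue = 10^-runif(length(put), 12, 50)),
    tibble(transcript_id = decoy,
           subject_id = sprintf("sp|P%05d", sample.int(99999, length(decoy))),
           evalue = 10^-runif(length(decoy), 2, 8))
  )

  list(genes = genes, transcripts = transcripts, truth = truth, irr = irr,
       sirna_windows = sirna_windows, k27 = k27, bedgraph = bedgraph,
       hits = hits, free = free, chroms = chroms)
}

# ---- stream 2: methylation --------------------------------------------------

sim_methylation <- function(cfg, lay) {
  set.seed(stream_seed(cfg$seed, 2L))
  base <- cfg$methylation_base
  boost <- cfg$methylation_boost
  regions <- dplyr::bind_rows(
    lay$irr %>% dplyr::mutate(kind = "irr"),
    lay$sirna_windows %>% dplyr::select("chrom", "start", "end") %>%
      dplyr::mutate(kind = "sirna_window")
  ) %>%
    dplyr::mutate(region_id = sprintf("R%05d", dplyr::row_number()))
  m <- pmin(base + boost, 0.90)
  conc <- 100
  if (boost > 0) {
    # elevated regions carry beta-distributed means around base + boost
    regions$p_CG <- rbeta(nrow(regions), m[["CG"]] * conc, (1 - m[["CG"]]) * conc)
    regions$p_CHG <- rbeta(nrow(regions), m[["CHG"]] * conc, (1 - m[["CHG"]]) * conc)
    regions$p_CHH <- rbeta(nrow(regions), m[["CHH"]] * conc, (1 - m[["CHH"]]) * conc)
  } else {
    # nothing to elevate: regions sit exactly at the background level
    regions$p_CG <- rep(m[["CG"]], nrow(regions))
    regions$p_CHG <- rep(m[["CHG"]], nrow(regions))
    regions$p_CHH <- rep(m[["CHH"]], nrow(regions))
  }

  cx <- purrr::map_dfr(lay$chroms, function(ch) {
    extent <- max(c(lay$transcripts$end[lay$transcripts$chrom == ch],
                    lay$genes$end[lay$genes$chrom == ch], 10000)) + 2500
    n <- round(cfg$cytosine_density * extent)
    pos <- sort(sample.int(extent, n)) - 1
    tibble(chrom = ch, start = pos, end = pos + 1,
           strand = sample(c("+", "-"), n, replace = TRUE),
           context = sample(METH_CONTEXTS, n, replace = TRUE,
                            prob = c(0.3, 0.3, 0.4)))
  })
  p <- unname(base[cx$context])
  prs <- overlap_pairs(cx, regions %>% dplyr::mutate(strand = "."))
  if (nrow(prs)) {
    prs <- prs[!duplicated(prs$query_row), ]   # first region wins
    pm <- as.matrix(regions[, c("p_CG", "p_CHG", "p_CHH")])
    p[prs$query_row] <- pm[cbind(prs$subject_row,
                                 match(cx$context[prs$query_row], METH_CONTEXTS))]
  }
  depth <- rpois(nrow(cx), cfg$read_depth)
  mc <- rbinom(nrow(cx), depth, p)
  cx$mc <- mc
  cx$umc <- depth - mc
  cx$zero_coverage <- depth == 0L
  list(cx = cx, regions = regions %>%
         dplyr::select("region_id", "kind", "chrom", "start", "end",
                       "p_CG", "p_CHG", "p_CHH"))
}

# ---- stream 3: small-RNA reads ----------------------------------------------

sim_srna_reads <- function(cfg, lay) {
  set.seed(stream_seed(cfg$seed, 3L))
  win <- lay$sirna_windows
  planted <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
    w <- win[i, ]
    k <- 3 + rpois(1, 8)
    s <- w$start + sample.int(w$end - w$start - 24 + 1, k, replace = TRUE) - 1
    tibble(chrom = w$chrom, start = s, end = s + 24,
           strand = sample(c("+", "-"), k, replace = TRUE),
           read_length = 24L, unique = TRUE)
  })
  n24 <- nrow(planted)
  # uniquely mapped 24-nt background confined to free intergenic zones
  zones <- lay$free %>% dplyr::filter(.data$end - .data$start >= 120)
  nbg <- round(0.15 * n24)
  zi <- sample.int(nrow(zones), nbg, replace = TRUE,
                   prob = zones$end - zones$start)
  s <- zones$start[zi] + 20 +
    floor(runif(nbg) * (zones$end[zi] - zones$start[zi] - 64))
  bg24 <- tibble(chrom = zones$chrom[zi], start = s, end = s + 24,
                 strand = sample(c("+", "-"), nbg, replace = TRUE),
                 read_length = 24L, unique = TRUE)
  # off-length and multi-mapping background anywhere on the genome
  rand_reads <- function(n, lens, uniq) {
    ch <- sample(lay$chroms, n, replace = TRUE)
    len <- lens[sample.int(length(lens), n, replace = TRUE)]
    s <- floor(runif(n) * (cfg$chrom_length - 40))
    tibble(chrom = ch, start = s, end = s + len,
           strand = sample(c("+", "-"), n, replace = TRUE),
           read_length = as.integer(len), unique = uniq)
  }
  offlen <- rand_reads(round(1.5 * n24), c(21L, 22L), TRUE)
  multi <- rand_reads(round(0.3 * n24), 24L, FALSE)
  dplyr::bind_rows(planted, bg24, offlen, multi) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

# ---- stream 4: expression ---------------------------------------------------

sim_expression <- function(cfg, lay) {
  set.seed(stream_seed(cfg$seed, 4L))
  tr <- lay$truth
  mu <- cfg$expression_lognormal[[1]]
  sigma <- cfg$expression_lognormal[[2]]
  base <- rlnorm(nrow(tr), mu, sigma) *
    ifelse(tr$sirna, cfg$sirna_expression_effect, 1)
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    round(base * exp(rnorm(nrow(tr), 0, 0.15)), 4)
  })
  out <- tibble(transcript_id = tr$transcript_id)
  for (r in seq_len(cfg$n_replicates)) out[[paste0("rep", r)]] <- reps[[r]]
  out
}

# ---- stream 5: HSPs against related genomes ---------------------------------

sim_hsps <- function(cfg, lay) {
  set.seed(stream_seed(cfg$seed, 5L))
  tr <- lay$truth
  genomes <- names(cfg$conservation)
  rows <- list(); truth_rows <- list()
  for (g in genomes) {
    pres <- runif(nrow(tr)) < cfg$conservation[[g]]
    covm <- cfg$conservation_coverage[[g]]
    cov <- rep(0, nrow(tr))
    for (i in which(pres)) {
      len <- tr$length[i]
      ci <- min(max(rbeta(1, covm * 8, (1 - covm) * 8), 0.05), 0.95)
      alen <- max(60, round(ci * len))
      if (alen > len) alen <- len
      k <- sample(1:3, 1)
      if (alen < k * 40) k <- 1
      lens <- split_len(alen, k, lo = 30)
      qs <- sample.int(len - alen + 1, 1)
      q_start <- qs + c(0, cumsum(lens[-k]))
      q_end <- q_start + lens - 1
      minus <- runif(1) < 0.3
      sbj <- sprintf("%s_scf%04d", g, sample.int(9999, 1))
      s0 <- sample.int(900000, 1)
      gaps <- if (k > 1) round(runif(k - 1, 0, 400)) else numeric(0)
      s_start <- s0 + c(0, cumsum(lens[-k] + gaps))
      s_end <- s_start + lens - 1
      if (minus) {
        # subject runs downhill as the query advances: start > end per HSP
        s_hi <- s0 + 500000 - c(0, cumsum(lens[-k] + gaps))
        s_lo <- s_hi - lens + 1
        s_start <- s_hi; s_end <- s_lo
      }
      rows[[length(rows) + 1]] <- tibble(
        query_id = tr$transcript_id[i], subject_id = sbj,
        pident = round(runif(k, 85, 99), 2), align_length = lens,
        mismatch = round(lens * 0.02), gapopen = 0,
        query_start = q_start, query_end = q_end,
        subject_start = s_start, subject_end = s_end,
        evalue = 1e-50, bitscore = round(1.8 * lens, 1), genome = g
      )
      # occasional weaker decoy hit on another subject
      if (runif(1) < 0.3) {
        dl <- round(runif(1, 30, 80))
        dq <- sample.int(max(len - dl, 1), 1)
        rows[[length(rows) + 1]] <- tibble(
          query_id = tr$transcript_id[i],
          subject_id = sprintf("%s_scf%04d", g, sample.int(9999, 1)),
          pident = round(runif(1, 75, 90), 2), align_length = dl,
          mismatch = round(dl * 0.1), gapopen = 0,
          query_start = dq, query_end = dq + dl - 1,
          subject_start = 1000, subject_end = 1000 + dl - 1,
          evalue = 1e-12, bitscore = round(0.9 * dl, 1), genome = g
        )
      }
      # sub-cutoff noise, dropped by the e-value filter
      if (runif(1) < 0.2) {
        rows[[length(rows) + 1]] <- tibble(
          query_id = tr$transcript_id[i],
          subject_id = sprintf("%s_scf%04d", g, sample.int(9999, 1)),
          pident = 80, align_length = 40, mismatch = 6, gapopen = 1,
          query_start = 1, query_end = 40,
          subject_start = 500, subject_end = 539,
          evalue = 1e-3, bitscore = 35, genome = g
        )
      }
      cov[i] <- alen / len
    }
    truth_rows[[g]] <- tibble(transcript_id = tr$transcript_id,
                              !!paste0("cov_", g) := cov)
  }
  hsps <- dplyr::bind_rows(rows)
  hsps$subject_strand <- ifelse(hsps$subject_start <= hsps$subject_end, "+", "-")
  truth <- purrr::reduce(truth_rows, dplyr::left_join, by = "transcript_id")
  list(hsps = hsps, truth = truth)
}

# ---- stream 6: GO map -------------------------------------------------------

sim_go_map <- function(cfg, lay) {
  set.seed(stream_seed(cfg$seed, 6L))
  genes <- lay$genes$id
  enriched_term <- "GO:0006355"
  generic <- sprintf("GO:%07d", 1000 + seq_len(29))
  # hosts of incRNAs: genes whose intron contains a transcript
  introns <- model_introns(lay$genes)
  inc <- lay$transcripts %>% dplyr::filter(.data$class == "incRNA")
  host_hit <- overlap_pairs(inc, introns)
  hosts <- unique(introns$id[host_hit$subject_row])
  rows <- purrr::map_dfr(genes, function(g) {
    k <- 1 + rpois(1, 1)
    tibble(gene = g, term = sample(generic, min(k, length(generic))))
  })
  p_enr <- ifelse(genes %in% hosts, 0.8, 0.1)
  extra <- tibble(gene = genes[runif(length(genes)) < p_enr],
                  term = enriched_term)
  list(map = dplyr::bind_rows(rows, extra) %>% dplyr::arrange(.data$gene),
       enriched_term = enriched_term)
}
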