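# End-to-end pipeline driver.
#
# run_pipeline() wires the stages together in the order a full analysis
# runs them: classification, mark statuses and stratification, regional
# methylation, metaprofiles, stratified expression tests, homology
# coverage, and GO enrichment. Inputs are validated before any computation
# starts (fail-fast), every stage is a pure function of its declared
# inputs plus the parameters, and a machine-readable run manifest records
# inputs, parameters and package version.

PIPELINE_STAGES <- c("classify", "marks", "methylation", "profile",
                     "expression", "conservation", "enrichment")

stage_requirements <- list(
  classify = c("genes_gff", "transcripts_gff"),
  marks = c("genes_gff", "transcripts_gff"),
  methylation = c("cx_report", "transcripts_gff", "genes_gff"),
  profile = c("transcripts_gff", "genes_gff"),
  expression = c("fpkm", "genes_gff", "transcripts_gff"),
  conservation = c("hsp", "genes_gff", "transcripts_gff"),
  enrichment = c("go_map", "genes_gff", "transcripts_gff")
)

#' Run the full analysis pipeline
#'
#' @param inputs Named list (or flat key=value config file path) of input
#'   files: `genes_gff`, `transcripts_gff`, and as needed per stage
#'   `coding_hits`, `irr_bed`, `srna`, `cx_report`, `k27_bed`, `fpkm`,
#'   `hsp`, `go_map` — the file set written by [generate_dataset()].
#' @param outdir Output directory for the result TSVs and run manifest.
#' @param stages Which stages to run (default all).
#' @param evalue_cutoff Coding-hit e-value cutoff for classification.
#' @param cluster_gap,cluster_min_reads siRNA cluster parameters.
#' @param profile_body_bins,profile_flank_bp,profile_flank_bins Metagene
#'   geometry.
#' @param alpha_fdr FDR level for enrichment.
#' @param seed Seed recorded in the run manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a named list of the computed tables.
#' @export
run_pipeline <- function(inputs, outdir, stages = PIPELINE_STAGES,
                         evalue_cutoff = 1e-10,
                         cluster_gap = 100L, cluster_min_reads = 3L,
                         profile_body_bins = 40L, profile_flank_bp = 2000L,
                         profile_flank_bins = 20L,
                         alpha_fdr = 0.01, seed = NULL) {
  if (is.character(inputs) && length(inputs) == 1) {
    inputs <- read_config_file(inputs)
  }
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)

  # fail fast: every requested stage must see its inputs before work starts
  needed <- unique(c(unlist(stage_requirements[stages]),
                     if ("marks" %in% stages) c("irr_bed", "srna", "k27_bed")))
  missing_keys <- setdiff(needed, names(inputs))
  if (length(missing_keys)) {
    stop("missing input(s) for requested stage(s): ",
         paste(missing_keys, collapse = ", "))
  }
  absent <- needed[!file.exists(unlist(inputs[needed]))]
  if (length(absent)) {
    stop("input file(s) not found: ",
         paste(unlist(inputs[absent]), collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  genes <- read_gff(inputs$genes_gff)
  transcripts <- read_gff(inputs$transcripts_gff)
  hits <- if (!is.null(inputs$coding_hits) && file.exists(inputs$coding_hits)) {
    readr::read_tsv(inputs$coding_hits, show_col_types = FALSE, progress = FALSE)
  } else NULL
  classed <- classify_transcripts(transcripts, genes, hits,
                                  evalue_cutoff = evalue_cutoff)
  res$classes <- classed %>% dplyr::select("id", "class")
  readr::write_tsv(res$classes, file.path(outdir, "classes.tsv"))

  if ("classify" %in% stages) {
    res$exon_counts <- exon_count_distribution(classed)
    res$lengths <- length_summary(classed)
    res$distances <- distance_bin_proportions(
      distance_to_nearest_gene(classed, genes))
    readr::write_tsv(res$exon_counts, file.path(outdir, "exon_counts.tsv"))
    readr::write_tsv(res$lengths, file.path(outdir, "length_summary.tsv"))
    readr::write_tsv(res$distances, file.path(outdir, "distance_bins.tsv"))
  }

  irrs <- if (!is.null(inputs$irr_bed)) read_bed(inputs$irr_bed) else NULL
  k27 <- if (!is.null(inputs$k27_bed)) read_bed(inputs$k27_bed) else NULL
  reads <- if (!is.null(inputs$srna)) read_srna_table(inputs$srna) else NULL
  reads24 <- if (!is.null(reads)) filter_24nt(reads) else NULL

  if ("marks" %in% stages) {
    res$status <- mark_status(classed, irrs = irrs, reads24 = reads24,
                              domains = k27)
    res$stratification <- stratify(res$status)
    res$joint <- joint_irr_sirna(res$status)
    res$clusters <- call_clusters(reads24, gap = cluster_gap,
                                  min_reads = cluster_min_reads,
                                  library_size = nrow(reads))
    readr::write_tsv(res$status, file.path(outdir, "mark_status.tsv"))
    readr::write_tsv(res$stratification, file.path(outdir, "stratification.tsv"))
    readr::write_tsv(res$joint, file.path(outdir, "joint_irr_sirna.tsv"))
    readr::write_tsv(res$clusters, file.path(outdir, "sirna_clusters.tsv"))
  }

  if ("methylation" %in% stages) {
    cx <- read_cx_report(inputs$cx_report)
    regions <- classed %>%
      dplyr::transmute(region_id = .data$id, chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand)
    res$methylation <- region_methylation(cx, regions) %>%
      dplyr::left_join(res$classes, by = c(region_id = "id"))
    readr::write_tsv(res$methylation, file.path(outdir, "region_methylation.tsv"))
  }

  if ("profile" %in% stages && !is.null(reads24)) {
    sig <- signal_sirna(reads24, library_size = nrow(reads))
    res$profiles <- purrr::map_dfr(
      intersect(LNC_CLASSES, unique(classed$class)),
      function(cl) {
        aggregate_profiles(classed %>% dplyr::filter(.data$class == cl), sig,
                           body_bins = profile_body_bins,
                           flank_bp = profile_flank_bp,
                           flank_bins = profile_flank_bins) %>%
          dplyr::mutate(feature_set = cl, signal = "sirna_rpm")
      })
    readr::write_tsv(res$profiles, file.path(outdir, "metaprofiles.tsv"))
  }

  if ("expression" %in% stages) {
    fpkm <- read_fpkm_table(inputs$fpkm)
    status <- res$status %||% mark_status(classed, irrs = irrs,
                                          reads24 = reads24, domains = k27)
    res$expression <- purrr::map_dfr(c("irr", "sirna", "k27"),
                                     ~ strata_compare(fpkm, status, mark = .x))
    res$length_anova <- anova_lengths(classed %>%
                                        dplyr::filter(.data$class %in% LNC_CLASSES))
    readr::write_tsv(res$expression, file.path(outdir, "expression_stats.tsv"))
    readr::write_tsv(tidy(res$length_anova), file.path(outdir, "length_anova.tsv"))
  }

  if ("conservation" %in% stages) {
    hsps <- read_hsp_table(inputs$hsp)
    res$homology <- chain_hsps(hsps, classed)
    res$coverage <- coverage_summary(res$homology, classed)
    readr::write_tsv(res$homology, file.path(outdir, "homology_coverage.tsv"))
    readr::write_tsv(res$coverage, file.path(outdir, "coverage_summary.tsv"))
  }

  if ("enrichment" %in% stages) {
    go <- read_go_map(inputs$go_map)
    introns <- model_introns(genes)
    host_inc <- overlap_pairs(classed %>% dplyr::filter(.data$class == "incRNA"),
                              introns)
    study <- unique(introns$id[host_inc$subject_row])
    if (length(study)) {
      res$enrichment <- enrich(study, genes$id, go, alpha_fdr = alpha_fdr)
      readr::write_tsv(res$enrichment, file.path(outdir, "enrichment_incRNA.tsv"))
    }
  }

  run_manifest <- list(
    package = "lncmarks",
    version = as.character(utils::packageVersion("lncmarks")),
    inputs = inputs[intersect(names(inputs), needed)],
    parameters = list(evalue_cutoff = evalue_cutoff,
                      cluster_gap = cluster_gap,
                      cluster_min_reads = cluster_min_reads,
                      profile_body_bins = profile_body_bins,
                      profile_flank_bp = profile_flank_bp,
                      profile_flank_bins = profile_flank_bins,
                      alpha_fdr = alpha_fdr),
    stages = stages, seed = seed
  )
  jsonlite::write_json(run_manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat key = value config file, one pair per line, '#' comments
read_config_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- stringr::str_split_fixed(lines, "\\s*=\\s*", 2)
  if (any(!nzchar(kv[, 2]))) stop("malformed config line: ",
                                  lines[!nzchar(kv[, 2])][1])
  setNames(as.list(trimws(kv[, 2])), trimws(kv[, 1]))
}
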