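#' Run the full QC and primary-analysis pipeline
#'
#' End-to-end driver: reads the three GenomeStudio exports (and optional
#' exclusion list), summarizes the internal control probes, computes the
#' detection summary and removes samples whose mean detection p-value is not
#' below the cutoff, lists systematically undetected CpGs, optionally drops
#' chromosome-X probes, diagnoses dye bias, quantile-normalizes the pooled
#' methylated/unmethylated intensities at the probe level, computes
#' M-values, assesses sample similarity by PCA and hierarchical clustering,
#' and writes the QC report (PDF + HTML), the statistics workbook with its
#' four tab-delimited mirrors, the M-value text export and the dendrogram
#' Newick tree into `out_dir`.
#'
#' @param sample_table,control_profile,avg_beta Paths to the three
#'   GenomeStudio exports.
#' @param exclude Optional exclusion-list path or character vector of sample
#'   IDs.
#' @param pval_cutoff Mean detection p-value cutoff for sample removal
#'   (strict; default 0.05).
#' @param detection_cutoffs Detection p-value cutoffs summarized per sample
#'   and used for the undetected-CpG lists.
#' @param sample_fraction Fraction-of-samples threshold for the
#'   undetected-CpG lists (strict; default 0.05).
#' @param drop_chrx Drop chromosome-X probes? Default `FALSE`.
#' @param chr_annotation Probe-to-chromosome annotation (path or data
#'   frame); required when `drop_chrx = TRUE`.
#' @param distance Clustering distance (`euclidean` default).
#' @param linkage Clustering linkage (`average` default).
#' @param panel `"27K"` or `"450K"` export dialect.
#' @param m_offset,beta_offset Intensity offsets for M- and Beta-values.
#' @param out_dir Output directory, created if absent; `NULL` skips all file
#'   output.
#' @return Invisibly, a list of class `methqc_run` with elements `dataset`
#'   (filtered, normalized), `control_qc`, `detection`, `removed`,
#'   `undetected`, `dye`, `m`, `similarity` and `paths`.
#' @export
run_methqc <- function(sample_table, control_profile, avg_beta,
                       exclude = NULL,
                       pval_cutoff = 0.05,
                       detection_cutoffs = c(0.01, 0.05),
                       sample_fraction = 0.05,
                       drop_chrx = FALSE, chr_annotation = NULL,
                       distance = "euclidean", linkage = "average",
                       panel = c("450K", "27K"),
                       m_offset = 1, beta_offset = 100,
                       out_dir = NULL) {
  panel <- match.arg(panel)

  samples <- read_sample_table(sample_table)
  betas <- read_avg_beta(avg_beta, panel = panel)
  controls <- read_control_profile(control_profile, panel = panel)
  dataset <- assemble_dataset(samples, betas, controls,
                              exclusion = exclude)

  control_qc <- control_summary(dataset)
  detection_all <- detection_summary(dataset, cutoffs = detection_cutoffs,
                                     pass_cutoff = pval_cutoff)
  flt <- filter_samples(dataset, detection_all, pass_cutoff = pval_cutoff)
  dataset <- flt$dataset
  dataset <- drop_chrX(dataset, annotation = chr_annotation,
                       enabled = drop_chrx)

  detection <- detection_summary(dataset, cutoffs = detection_cutoffs,
                                 pass_cutoff = pval_cutoff)
  undetected <- undetected_cpg_lists(dataset, cutoffs = detection_cutoffs,
                                     sample_fraction = sample_fraction)
  dye <- dye_bias_diagnostics(dataset)
  control_qc_retained <- dplyr::filter(
    control_qc, .data$sample_id %in% dataset$betas$samples)

  dataset <- normalize_intensities(dataset)
  m <- m_values(dataset, offset = m_offset)
  similarity <- sample_similarity(m, metric = distance,
                                  linkage_method = linkage)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    params <- list(panel = panel, pval_cutoff = pval_cutoff,
                   detection_cutoffs = detection_cutoffs,
                   sample_fraction = sample_fraction,
                   drop_chrx = drop_chrx, distance = distance,
                   linkage = linkage, m_offset = m_offset)
    colour_by <- NULL
    if ("sample_group" %in% names(dataset$samples)) {
      colour_by <- setNames(dataset$samples$sample_group,
                            dataset$samples$sample_id)
    }
    report_paths <- render_report(
      control_qc_retained, detection, dye, similarity,
      removed = flt$removed, params = params,
      out_path = file.path(out_dir, "report.pdf"), colour_by = colour_by)
    stat_paths <- export_statistics(control_qc_retained, detection,
                                    undetected, out_dir)
    m_path <- file.path(out_dir, "m_values.txt")
    export_m_values(m, m_path)
    nwk_path <- file.path(out_dir, "dendrogram.newick")
    dendrogram_newick(similarity$hclust, nwk_path)
    paths <- c(report_paths, stat_paths, m_values = m_path,
               dendrogram = nwk_path)
  }

  invisible(structure(
    list(dataset = dataset, control_qc = control_qc_retained,
         control_qc_all = control_qc, detection = detection,
         detection_all = detection_all, removed = flt$removed,
         undetected = undetected, dye = dye, m = m,
         similarity = similarity, paths = paths),
    class = "methqc_run"
  ))
}

#' @export
print.methqc_run <- function(x, ...) {
  cat("<methqc_run>\n")
  print(x$dataset)
  cat("  removed samples:",
      if (nrow(x$removed) > 0) paste(x$removed$sample_id, collapse = ", ")
      else "none", "\n")
  cat("  undetected CpGs listed:", nrow(x$undetected), "rows\n")
  if (!is.null(x$paths)) {
    cat("  outputs:\n")
    cat(paste0("    ", names(x$paths), ": ", x$paths, "\n"), sep = "")
  }
  invisible(x)
}
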