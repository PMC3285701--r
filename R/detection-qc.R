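#' Per-sample detection p-value summary
#'
#' For each retained sample, the percentage of probes not detectable (strict
#' `p > cutoff`) at each detection cutoff (defaults 0.01 and 0.05), the
#' arithmetic mean detection p-value, and a pass flag: a sample passes when
#' its mean detection p-value is strictly below `pass_cutoff`. Percentages
#' are computed over non-missing probes only, so missingness never
#' masquerades as detection failure.
#'
#' @param dataset A `meth_dataset`.
#' @param cutoffs Detection p-value cutoffs to summarize at.
#' @param pass_cutoff Mean-p-value threshold below which a sample passes.
#' @return A tibble with columns `sample_id`,
#'   `pct_undetected_<cutoff>` (one per cutoff, dots as underscores),
#'   `mean_detection_pval`, `passed`; attribute `pass_cutoff`.
#' @export
detection_summary <- function(dataset, cutoffs = c(0.01, 0.05),
                              pass_cutoff = 0.05) {
  pv <- dataset$betas$pval
  n_obs <- colSums(!is.na(pv))
  if (any(n_obs == 0)) {
    stop("all detection p-values missing for sample(s): ",
         paste(colnames(pv)[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(sample_id = colnames(pv))
  for (ct in sort(cutoffs)) {
    out[[pct_col_name(ct)]] <-
      unname(100 * colSums(pv > ct, na.rm = TRUE) / n_obs)
  }
  out$mean_detection_pval <- unname(colMeans(pv, na.rm = TRUE))
  out$passed <- out$mean_detection_pval < pass_cutoff
  attr(out, "pass_cutoff") <- pass_cutoff
  attr(out, "cutoffs") <- sort(cutoffs)
  out
}

pct_col_name <- function(cutoff) {
  paste0("pct_undetected_", gsub("\\.", "_", format(cutoff)))
}

#' Remove low-performance samples
#'
#' Drops every sample whose mean detection p-value is not strictly below the
#' cutoff (default 0.05), so downstream normalization, PCA and clustering
#' only see samples that passed.
#'
#' @param dataset A `meth_dataset`.
#' @param summary Optional precomputed [detection_summary()] on the same
#'   dataset; recomputed if `NULL`.
#' @param pass_cutoff Mean-p-value threshold (strict).
#' @return A list with `dataset` (filtered) and `removed` (tibble of removed
#'   samples with their failing statistics).
#' @export
filter_samples <- function(dataset, summary = NULL, pass_cutoff = 0.05) {
  if (is.null(summary)) {
    summary <- detection_summary(dataset, pass_cutoff = pass_cutoff)
  }
  if (!setequal(summary$sample_id, dataset$betas$samples)) {
    stop("detection summary was not computed on this dataset", call. = FALSE)
  }
  keep_ids <- summary$sample_id[summary$mean_detection_pval < pass_cutoff]
  if (length(keep_ids) == 0) {
    stop("no sample passes the detection cutoff of ", pass_cutoff,
         "; pipeline cannot proceed", call. = FALSE)
  }
  removed <- summary[!(summary$sample_id %in% keep_ids), , drop = FALSE]
  list(dataset = subset_samples(dataset, keep_ids), removed = removed)
}

#' Lists of systematically undetected CpGs
#'
#' A probe is listed at a cutoff when its detection p-value exceeds that
#' cutoff (strict) in strictly more than `sample_fraction` of the retained
#' samples. Run this on the sample-filtered dataset so failing arrays do not
#' inflate the lists.
#'
#' @param dataset A `meth_dataset` (already sample-filtered).
#' @param cutoffs Detection p-value cutoffs (defaults 0.01 and 0.05).
#' @param sample_fraction Fraction-of-samples threshold (strict; default
#'   0.05).
#' @return A tibble with columns `cutoff`, `probe_id`, `n_undetected`,
#'   `frac_samples`; attribute `sample_fraction`.
#' @export
undetected_cpg_lists <- function(dataset, cutoffs = c(0.01, 0.05),
                                 sample_fraction = 0.05) {
  pv <- dataset$betas$pval
  n <- ncol(pv)
  res <- purrr::map_dfr(sort(cutoffs), function(ct) {
    cnt <- rowSums(pv > ct, na.rm = TRUE)
    frac <- cnt / n
    sel <- frac > sample_fraction
    tibble::tibble(cutoff = ct, probe_id = rownames(pv)[sel],
                   n_undetected = as.integer(cnt[sel]),
                   frac_samples = frac[sel])
  })
  attr(res, "sample_fraction") <- sample_fraction
  attr(res, "n_samples") <- n
  res
}

#' Optionally drop probes on chromosome X
#'
#' Sex-chromosome probes can dominate clustering when samples mix sexes; the
#' pipeline can drop them given a probe-to-chromosome annotation. Disabled by
#' default.
#'
#' @param dataset A `meth_dataset`.
#' @param annotation Tibble/data frame with columns `probe_id` and
#'   `chromosome`, or a path to a tab-delimited file with those columns.
#'   Required when `enabled = TRUE`.
#' @param enabled Drop chrX probes? Default `FALSE` (identity).
#' @return The dataset, with chrX probes removed from every matrix when
#'   enabled. Probes absent from the annotation are retained with a warning.
#' @export
drop_chrX <- function(dataset, annotation = NULL, enabled = FALSE) {
  if (!enabled) return(dataset)
  if (is.null(annotation)) {
    stop("drop_chrX enabled but no probe-to-chromosome annotation supplied",
         call. = FALSE)
  }
  if (is.character(annotation)) {
    annotation <- read_probe_annotation(annotation)
  }
  probes <- dataset$betas$probes
  chr <- annotation$chromosome[match(probes, annotation$probe_id)]
  unannotated <- probes[is.na(chr)]
  if (length(unannotated) > 0) {
    warning(length(unannotated),
            " probe(s) absent from the annotation; retained", call. = FALSE)
  }
  is_x <- !is.na(chr) & toupper(sub("^chr", "", chr,
                                    ignore.case = TRUE)) == "X"
  subset_probes(dataset, probes[!is_x])
}

#' Read a probe-to-chromosome annotation file
#'
#' @param path Tab-delimited file with columns `probe_id` and `chromosome`
#'   (header required).
#' @return Tibble with those two columns.
#' @export
read_probe_annotation <- function(path) {
  tab <- read_gs_tsv(path)
  need <- c("probe_id", "chromosome")
  if (!all(need %in% tolower(names(tab)))) {
    stop("annotation must have columns 'probe_id' and 'chromosome'; found: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  names(tab) <- tolower(names(tab))
  tab[need]
}

# -- dataset subsetting ------------------------------------------------------

subset_samples <- function(dataset, keep) {
  b <- dataset$betas
  keep <- b$samples[b$samples %in% keep]  # preserve canonical order
  b$samples <- keep
  for (f in c("beta", "pval", "meth", "unmeth")) {
    b[[f]] <- b[[f]][, keep, drop = FALSE]
  }
  dataset$betas <- b
  dataset$samples <- dplyr::filter(dataset$samples,
                                   .data$sample_id %in% keep)
  dataset$controls <- dplyr::filter(dataset$controls,
                                    .data$sample_id %in% keep)
  dataset
}

subset_probes <- function(dataset, keep) {
  b <- dataset$betas
  keep <- b$probes[b$probes %in% keep]
  b$probes <- keep
  for (f in c("beta", "pval", "meth", "unmeth")) {
    b[[f]] <- b[[f]][keep, , drop = FALSE]
  }
  dataset$betas <- b
  dataset
}
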