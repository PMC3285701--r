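#' Read a GenomeStudio "Sample table" export
#'
#' Parses the tab-delimited sample sheet exported by the GenomeStudio
#' Methylation Module. The sample-identifier column is located by name
#' (`Sample ID`, `Sample Name`, `Sample_Name`, `sample_id`, case-insensitive);
#' any remaining columns (group, plate, Sentrix barcode/position, ...) are
#' kept as annotation.
#'
#' @param path Path to the tab-delimited sample table.
#' @return A tibble with one row per sample; the identifier column is renamed
#'   to `sample_id`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) {
    stop("sample table not found: ", path, call. = FALSE)
  }
  tab <- read_gs_tsv(path)
  id_candidates <- c("sample id", "sample name", "sample_name", "sample_id",
                     "sample.id", "sampleid", "id")
  hit <- which(tolower(names(tab)) %in% id_candidates)
  if (length(hit) == 0) {
    stop("no sample-identifier column found; headers present: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  names(tab)[hit[1]] <- "sample_id"
  tab$sample_id <- as.character(tab$sample_id)
  if (any(is.na(tab$sample_id) | tab$sample_id == "")) {
    stop("empty sample_id in sample table", call. = FALSE)
  }
  dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id in sample table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dplyr::relocate(tab, "sample_id")
}

#' Read a GenomeStudio "Average Beta table" export
#'
#' The export carries four column groups per sample: `<sample>.AVG_Beta`,
#' `<sample>.Detection Pval`, `<sample>.Signal_A` and `<sample>.Signal_B`.
#' The mapping of the two signal columns onto methylated/unmethylated
#' intensities depends on the BeadChip: on the 27K panel `Signal_A` is the
#' methylated and `Signal_B` the unmethylated signal, while the 450K export
#' swaps the two. The header names themselves are identical between panels,
#' so `panel` selects the mapping.
#'
#' Missing numeric cells (`NA`, `NaN`, empty) are stored as missing, never as
#' zero. Any other non-numeric cell is a parse error reported with its
#' row/column location.
#'
#' @param path Path to the tab-delimited Average Beta table.
#' @param panel `"27K"` or `"450K"`; decides the Signal_A/Signal_B mapping.
#' @return A `beta_matrix` object: list with character vectors `probes`,
#'   `samples` and numeric probe-by-sample matrices `beta`, `pval`, `meth`,
#'   `unmeth`.
#' @export
read_avg_beta <- function(path, panel = c("27K", "450K")) {
  panel <- match.arg(panel)
  if (!file.exists(path)) {
    stop("average beta table not found: ", path, call. = FALSE)
  }
  tab <- read_gs_tsv(path, all_character = TRUE)
  headers <- names(tab)

  groups <- list(
    beta   = "\\.AVG_Beta$",
    pval   = "\\.Detection Pval$",
    sig_a  = "\\.Signal_A$",
    sig_b  = "\\.Signal_B$"
  )
  cols <- lapply(groups, function(re) {
    hit <- grep(re, headers)
    setNames(headers[hit], sub(re, "", headers[hit]))
  })
  samples <- names(cols$beta)
  if (length(samples) == 0) {
    stop("no '<sample>.AVG_Beta' columns found; headers present: ",
         paste(head(headers, 20), collapse = ", "), call. = FALSE)
  }
  for (grp in c("pval", "sig_a", "sig_b")) {
    missing_for <- setdiff(samples, names(cols[[grp]]))
    if (length(missing_for) > 0) {
      nm <- c(pval = "Detection Pval", sig_a = "Signal_A",
              sig_b = "Signal_B")[[grp]]
      stop("column '", nm, "' absent for sample(s): ",
           paste(missing_for, collapse = ", "), call. = FALSE)
    }
  }

  probe_col <- headers[1]
  probes <- as.character(tab[[probe_col]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe identifiers in average beta table", call. = FALSE)
  }

  to_matrix <- function(group) {
    m <- vapply(samples, function(s) {
      parse_numeric_column(tab[[cols[[group]][[s]]]], cols[[group]][[s]])
    }, numeric(length(probes)))
    m <- matrix(m, nrow = length(probes), ncol = length(samples),
                dimnames = list(probes, samples))
    m
  }
  beta <- to_matrix("beta")
  pval <- to_matrix("pval")
  sig_a <- to_matrix("sig_a")
  sig_b <- to_matrix("sig_b")

  if (panel == "27K") {
    meth <- sig_a; unmeth <- sig_b
  } else {
    meth <- sig_b; unmeth <- sig_a
  }
  validate_beta_ranges(beta, pval, meth, unmeth)
  structure(
    list(probes = probes, samples = samples,
         beta = beta, pval = pval, meth = meth, unmeth = unmeth,
         panel = panel),
    class = "beta_matrix"
  )
}

validate_beta_ranges <- function(beta, pval, meth, unmeth) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("avg_beta values outside [0, 1]", call. = FALSE)
  }
  if (any(pval < 0 | pval > 1, na.rm = TRUE)) {
    stop("detection p-values outside [0, 1]", call. = FALSE)
  }
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("negative signal intensities", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a GenomeStudio "Control probe profile" export
#'
#' Rows carry a control-type text field that is classified onto the eight
#' internal control categories (staining, extension, target removal,
#' hybridization, bisulfite conversion, specificity, negative,
#' non-polymorphic). Hybridization rows are tagged with their synthetic-target
#' concentration level (low/medium/high), specificity rows with their
#' perfect-match/mismatch design (PM/MM), and extension/non-polymorphic rows
#' with the queried nucleotide. Rows whose type cannot be classified are kept
#' but flagged `recognized = FALSE` and excluded from all metrics; newer
#' panels carry control types the 27K did not.
#'
#' @param path Path to the tab-delimited control probe profile.
#' @param panel `"27K"` or `"450K"` (recorded; classification is shared).
#' @return A tibble in long form with columns `control_probe_id`,
#'   `control_type`, `category`, `subcategory`, `recognized`, `sample_id`,
#'   `channel` and `signal`.
#' @export
read_control_profile <- function(path, panel = c("27K", "450K")) {
  panel <- match.arg(panel)
  if (!file.exists(path)) {
    stop("control probe profile not found: ", path, call. = FALSE)
  }
  tab <- read_gs_tsv(path, all_character = TRUE)
  headers <- names(tab)

  grn <- grep("\\.Signal_Grn$", headers)
  red <- grep("\\.Signal_Red$", headers)
  if (length(grn) == 0 || length(red) == 0) {
    stop("no '<sample>.Signal_Grn'/'<sample>.Signal_Red' columns found; ",
         "headers present: ", paste(head(headers, 20), collapse = ", "),
         call. = FALSE)
  }
  samples_grn <- sub("\\.Signal_Grn$", "", headers[grn])
  samples_red <- sub("\\.Signal_Red$", "", headers[red])
  samples <- intersect(samples_grn, samples_red)
  if (length(samples) == 0) {
    stop("no sample has both green and red signal columns", call. = FALSE)
  }

  type_col <- headers[grepl("^TargetID$|^Target ID$|control.?type", headers,
                            ignore.case = TRUE)][1]
  if (is.na(type_col)) type_col <- headers[1]
  id_col <- headers[grepl("^ProbeID$|^Probe ID$|^Address", headers,
                          ignore.case = TRUE)][1]
  probe_id <- if (is.na(id_col)) {
    paste0("ctrl_", seq_len(nrow(tab)))
  } else {
    as.character(tab[[id_col]])
  }

  cls <- classify_control_type(as.character(tab[[type_col]]))
  if (!any(cls$recognized)) {
    stop("no recognizable control rows in ", path, call. = FALSE)
  }

  base <- tibble::tibble(
    control_probe_id = probe_id,
    control_type = as.character(tab[[type_col]]),
    category = cls$category,
    subcategory = cls$subcategory,
    recognized = cls$recognized
  )
  long <- purrr::map_dfr(samples, function(s) {
    g <- parse_numeric_column(tab[[paste0(s, ".Signal_Grn")]],
                              paste0(s, ".Signal_Grn"))
    r <- parse_numeric_column(tab[[paste0(s, ".Signal_Red")]],
                              paste0(s, ".Signal_Red"))
    dplyr::bind_rows(
      dplyr::mutate(base, sample_id = s, channel = "green", signal = g),
      dplyr::mutate(base, sample_id = s, channel = "red", signal = r)
    )
  })
  if (any(long$signal < 0, na.rm = TRUE)) {
    stop("negative control-probe intensities", call. = FALSE)
  }
  attr(long, "panel") <- panel
  long
}

#' Map GenomeStudio control-type labels onto the eight control categories
#'
#' @param type Character vector of control-type labels.
#' @return A list with `category`, `subcategory` and `recognized` vectors.
#' @keywords internal
classify_control_type <- function(type) {
  lt <- tolower(type)
  category <- rep(NA_character_, length(type))
  subcategory <- rep(NA_character_, length(type))

  category[grepl("stain", lt)] <- "staining"
  category[grepl("extension", lt)] <- "extension"
  category[grepl("target.?removal", lt)] <- "target_removal"
  category[grepl("^hyb", lt)] <- "hybridization"
  category[grepl("bisulfite", lt)] <- "bisulfite_conversion"
  category[grepl("specificity", lt)] <- "specificity"
  category[grepl("negative", lt)] <- "negative"
  category[grepl("non.?polymorphic|^np\\b", lt)] <- "non_polymorphic"

  nt <- stringr::str_match(type, "\\(([ATCG])\\)")[, 2]
  sel <- category %in% c("extension", "non_polymorphic") & !is.na(nt)
  subcategory[sel] <- nt[sel]

  lev <- stringr::str_match(lt, "\\b(low|medium|med|high)\\b")[, 2]
  lev[lev %in% "med"] <- "medium"
  sel <- category %in% "hybridization" & !is.na(lev)
  subcategory[sel] <- lev[sel]

  pm <- rep(NA_character_, length(type))
  pm[grepl("\\bmm\\b|mismatch", lt)] <- "MM"
  pm[grepl("\\bpm\\b|perfect", lt)] <- "PM"
  sel <- category %in% "specificity" & !is.na(pm)
  subcategory[sel] <- pm[sel]

  list(category = category, subcategory = subcategory,
       recognized = !is.na(category))
}

#' Read a sample-exclusion list (one sample ID per line)
#'
#' @param path Path to the exclusion file; blank lines and `#` comments are
#'   ignored.
#' @return Character vector of sample IDs (possibly empty).
#' @export
read_exclusion_list <- function(path) {
  if (is.null(path)) return(character(0))
  if (!file.exists(path)) {
    stop("exclusion list not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Assemble the three parsed tables into one methylation dataset
#'
#' Samples named in the optional exclusion list are dropped from every matrix
#' (an unknown name raises a warning, not an error), and the retained samples
#' are put in the Sample-table order everywhere. Sample sets of the beta and
#' control tables must agree after exclusion.
#'
#' @param samples Tibble from [read_sample_table()].
#' @param betas `beta_matrix` from [read_avg_beta()].
#' @param controls Control tibble from [read_control_profile()].
#' @param exclusion Optional path to an exclusion list, or a character vector
#'   of sample IDs to drop.
#' @return A `meth_dataset` object.
#' @export
assemble_dataset <- function(samples, betas, controls, exclusion = NULL) {
  excluded <- if (is.character(exclusion) && !all(file.exists(exclusion))) {
    exclusion
  } else if (!is.null(exclusion)) {
    read_exclusion_list(exclusion)
  } else {
    character(0)
  }
  unknown <- setdiff(excluded, samples$sample_id)
  if (length(unknown) > 0) {
    warning("exclusion list names unknown sample(s), ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    excluded <- setdiff(excluded, unknown)
  }

  keep <- setdiff(samples$sample_id, excluded)
  beta_samples <- setdiff(betas$samples, excluded)
  ctrl_samples <- setdiff(unique(controls$sample_id), excluded)
  if (!setequal(keep, beta_samples) || !setequal(keep, ctrl_samples)) {
    stop("sample sets disagree after exclusion; sample table: ",
         length(keep), ", beta table: ", length(beta_samples),
         ", control profile: ", length(ctrl_samples), call. = FALSE)
  }

  sub <- function(m) m[, keep, drop = FALSE]
  betas$samples <- keep
  betas$beta <- sub(betas$beta)
  betas$pval <- sub(betas$pval)
  betas$meth <- sub(betas$meth)
  betas$unmeth <- sub(betas$unmeth)

  controls <- dplyr::filter(controls, .data$sample_id %in% keep)
  controls$sample_id <- factor(controls$sample_id, levels = keep)
  controls <- dplyr::arrange(controls, .data$sample_id)
  controls$sample_id <- as.character(controls$sample_id)

  structure(
    list(
      samples = dplyr::filter(samples, .data$sample_id %in% keep),
      betas = betas,
      controls = controls,
      excluded = excluded,
      normalized = FALSE
    ),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("<meth_dataset> ", length(x$betas$probes), " probes x ",
      length(x$betas$samples), " samples (panel ", x$betas$panel, ")\n",
      sep = "")
  cat("  samples:", paste(head(x$betas$samples, 5), collapse = ", "),
      if (length(x$betas$samples) > 5) "..." else "", "\n")
  cat("  control rows:", nrow(x$controls),
      "| excluded samples:", length(x$excluded),
      "| intensities normalized:", x$normalized, "\n")
  invisible(x)
}

#' Number of samples / probes in a dataset
#' @param dataset A `meth_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) length(dataset$betas$samples)

#' @rdname n_samples
#' @export
n_probes <- function(dataset) length(dataset$betas$probes)

# -- low-level helpers -------------------------------------------------------

# Tab-delimited reader for GenomeStudio dialects: UTF-8 with optional BOM,
# "." decimal separator, header row first.
read_gs_tsv <- function(path, all_character = FALSE) {
  col_types <- if (all_character) readr::cols(.default = readr::col_character())
               else readr::cols()
  tab <- readr::read_tsv(
    path,
    col_types = col_types,
    locale = readr::locale(decimal_mark = ".", encoding = "UTF-8"),
    na = character(0),
    progress = FALSE,
    show_col_types = FALSE,
    name_repair = "minimal"
  )
  tibble::as_tibble(tab, .name_repair = "minimal")
}

# Strict numeric conversion: NA/NaN/empty -> NA, anything else non-numeric is
# a parse error located by row and column.
parse_numeric_column <- function(x, col_name) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | toupper(x) %in% c("NA", "NAN", "NULL")
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !miss)
  if (length(bad) > 0) {
    stop("non-numeric value '", x[bad[1]], "' in column '", col_name,
         "', data row ", bad[1], call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}
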