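#' Export an M-value matrix as tab-delimited text
#'
#' Probes in rows, samples in columns (in the retained-sample canonical
#' order), values at full precision so downstream differential-methylation
#' tools can consume them directly.
#'
#' @param m Probe-by-sample M-value matrix.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_m_values <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "TargetID")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read back an exported M-value file
#' @param path Path written by [export_m_values()].
#' @return Probe-by-sample numeric matrix.
#' @export
read_m_values <- function(path) {
  df <- read_gs_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Export the four statistics tables
#'
#' Writes one spreadsheet workbook (SpreadsheetML XML, openable by Excel and
#' LibreOffice) with four data sheets — internal-control summary, per-sample
#' detection summary, and the two systematically-undetected CpG lists — plus
#' a tab-delimited mirror of each sheet.
#'
#' @param control_qc Tibble from [control_summary()].
#' @param detection Tibble from [detection_summary()].
#' @param undetected Tibble from [undetected_cpg_lists()].
#' @param out_dir Output directory.
#' @param basename Stem for the workbook file.
#' @return Named character vector of the written paths.
#' @export
export_statistics <- function(control_qc, detection, undetected, out_dir,
                              basename = "statistics") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cutoffs <- sort(unique(undetected$cutoff))
  if (length(cutoffs) == 0) cutoffs <- c(0.01, 0.05)
  und_sheet <- function(ct) {
    dplyr::filter(undetected, .data$cutoff == ct) |>
      dplyr::select("probe_id", "n_undetected", "frac_samples")
  }
  sheets <- list(
    internal_controls = control_qc,
    detection_summary = detection,
    undetected_p0.01 = und_sheet(cutoffs[1]),
    undetected_p0.05 = und_sheet(cutoffs[length(cutoffs)])
  )
  wb_path <- file.path(out_dir, paste0(basename, ".xml"))
  write_spreadsheetml(sheets, wb_path)
  tsv_paths <- vapply(names(sheets), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".txt"))
    readr::write_tsv(sheets[[nm]], p)
    p
  }, character(1))
  c(workbook = wb_path, tsv_paths)
}

#' Write tables as a single-file SpreadsheetML workbook
#'
#' SpreadsheetML 2003 is a plain-XML workbook format readable by Excel and
#' LibreOffice; one `<Worksheet>` is written per table, with a header row
#' and typed (`Number`/`String`) cells.
#'
#' @param sheets Named list of data frames.
#' @param path Output `.xml` path.
#' @return The path, invisibly.
#' @export
write_spreadsheetml <- function(sheets, path) {
  stopifnot(length(names(sheets)) == length(sheets))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell <- function(value, type) {
    sprintf('<Cell><Data ss:Type="%s">%s</Data></Cell>', type, value)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">')
  for (nm in names(sheets)) {
    df <- as.data.frame(sheets[[nm]])
    w(sprintf('<Worksheet ss:Name="%s"><Table>', esc(nm)))
    w("<Row>", paste0(vapply(names(df), function(h) cell(esc(h), "String"),
                             character(1)), collapse = ""), "</Row>")
    if (nrow(df) > 0) {
      is_num <- vapply(df, is.numeric, logical(1))
      for (i in seq_len(nrow(df))) {
        cells <- vapply(seq_along(df), function(j) {
          v <- df[[j]][i]
          if (is.na(v)) return(cell("", "String"))
          if (is_num[j]) cell(formatC(as.numeric(v), format = "g",
                                      digits = 15), "Number")
          else cell(esc(as.character(v)), "String")
        }, character(1))
        w("<Row>", paste0(cells, collapse = ""), "</Row>")
      }
    }
    w("</Table></Worksheet>")
  }
  w("</Workbook>")
  invisible(path)
}

#' Read back a SpreadsheetML workbook written by [write_spreadsheetml()]
#'
#' @param path Workbook `.xml` path.
#' @return Named list of tibbles, one per sheet.
#' @export
read_spreadsheetml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(ss = "urn:schemas-microsoft-com:office:spreadsheet")
  sheets <- xml2::xml_find_all(doc, ".//ss:Worksheet", ns)
  out <- lapply(sheets, function(ws) {
    rows <- xml2::xml_find_all(ws, ".//ss:Row", ns)
    parsed <- lapply(rows, function(r) {
      cells <- xml2::xml_find_all(r, ".//ss:Data", ns)
      list(values = xml2::xml_text(cells),
           types = xml2::xml_attr(cells, "Type"))
    })
    header <- parsed[[1]]$values
    body <- parsed[-1]
    cols <- lapply(seq_along(header), function(j) {
      vals <- vapply(body, function(r) r$values[j], character(1))
      types <- vapply(body, function(r) r$types[j], character(1))
      if (length(vals) > 0 && all(types == "Number" | vals == "")) {
        as.numeric(ifelse(vals == "", NA, vals))
      } else {
        ifelse(vals == "", NA, vals)
      }
    })
    names(cols) <- header
    tibble::as_tibble(cols)
  })
  names(out) <- xml2::xml_attr(sheets, "Name")
  out
}

# -- QC plot builders --------------------------------------------------------

#' Bar plots of percentage of background on signal per control category
#'
#' One panel per control category/subcategory and channel, one bar per
#' sample. For the `low_good` categories a low percentage indicates good
#' performance; target-removal and mismatch-specificity panels are expected
#' near 100%.
#'
#' @param control_qc Tibble from [control_summary()].
#' @param sample_dependent `TRUE` for the sample-dependent section, `FALSE`
#'   for the sample-independent one.
#' @return A ggplot object.
#' @export
plot_controls <- function(control_qc, sample_dependent = FALSE) {
  df <- control_qc |>
    dplyr::filter(.data$sample_dependent == !!sample_dependent,
                  .data$category != "negative") |>
    dplyr::mutate(
      panel = paste0(.data$category,
                     ifelse(is.na(.data$subcategory), "",
                            paste0(" ", .data$subcategory)),
                     " [", .data$channel, "]"),
      sample_id = factor(.data$sample_id, levels = unique(.data$sample_id))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id,
                                   .data$pct_background_on_signal,
                                   fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(
      ok = "steelblue", very_high_ratio = "firebrick",
      undefined_high = "orange", background_level = "grey60")) +
    ggplot2::labs(
      x = NULL, y = "% background on signal",
      title = if (sample_dependent) "Sample-dependent internal controls"
              else "Sample-independent internal controls",
      subtitle = "Low % = good performance (target removal / MM: high expected)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Plot the negative-control background level per sample and channel
#' @param control_qc Tibble from [control_summary()].
#' @return A ggplot object.
#' @export
plot_background <- function(control_qc) {
  df <- dplyr::filter(control_qc, .data$category == "negative") |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = unique(.data$sample_id)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$mean_signal,
                                   fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(green = "darkgreen",
                                          red = "darkred")) +
    ggplot2::labs(x = NULL, y = "mean negative-control signal",
                  title = "System background (negative controls)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Plot per-sample detection statistics
#' @param detection Tibble from [detection_summary()].
#' @return A ggplot object.
#' @export
plot_detection <- function(detection) {
  pass_cutoff <- attr(detection, "pass_cutoff") %||% 0.05
  df <- detection |>
    tidyr::pivot_longer(dplyr::starts_with("pct_undetected"),
                        names_to = "cutoff", values_to = "pct") |>
    dplyr::mutate(
      cutoff = sub("pct_undetected_", "p > ", .data$cutoff),
      cutoff = gsub("_", ".", .data$cutoff),
      sample_id = factor(.data$sample_id, levels = unique(.data$sample_id))
    )
  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$pct,
                                         fill = .data$cutoff)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% CpGs not detected",
                  title = "Undetected CpGs per sample", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
  p2 <- ggplot2::ggplot(
    dplyr::mutate(detection,
                  sample_id = factor(.data$sample_id,
                                     levels = unique(.data$sample_id))),
    ggplot2::aes(.data$sample_id, .data$mean_detection_pval,
                 fill = .data$passed)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = pass_cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "mean detection p-value",
                  title = sprintf(
                    "Average detection p-value (cutoff %.2f)", pass_cutoff),
                  fill = "passed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
  list(undetected = p1, mean_pval = p2)
}

#' Plot dye-bias diagnostics
#' @param dye `methqc_dye` from [dye_bias_diagnostics()].
#' @return A ggplot object.
#' @export
plot_dye_bias <- function(dye) {
  df <- dye$summary |>
    tidyr::pivot_longer(dplyr::starts_with("q"), names_to = "quantile",
                        values_to = "intensity") |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = unique(.data$sample_id)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$intensity,
                                   colour = .data$channel,
                                   group = interaction(.data$channel,
                                                       .data$quantile))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(green = "darkgreen",
                                            red = "darkred")) +
    ggplot2::labs(x = NULL, y = "control intensity",
                  title = "Channel intensity distributions (dye bias)",
                  subtitle = "One line per distribution quantile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- report ------------------------------------------------------------------

#' Render the QC report
#'
#' Writes a multi-page PDF (and an HTML twin carrying the tables) with: a
#' header page of run parameters, the sample-independent and
#' sample-dependent control sections, the system-background section, the
#' detection summary, the dye-bias diagnostics, the PCA scatter and the
#' dendrogram, plus an exclusion section listing removed samples with their
#' failing statistic. All inputs must cover the same retained-sample set.
#'
#' @param control_qc Tibble from [control_summary()].
#' @param detection Tibble from [detection_summary()] on the retained
#'   samples.
#' @param dye `methqc_dye` from [dye_bias_diagnostics()].
#' @param similarity `methqc_similarity` from [sample_similarity()].
#' @param removed Tibble of removed samples (from [filter_samples()]), may
#'   be empty.
#' @param params Named list of run parameters printed in the header.
#' @param out_path Output PDF path; the HTML twin replaces the extension.
#' @param colour_by Optional named vector (by sample) colouring the PCA.
#' @return Named vector with the PDF and HTML paths.
#' @export
render_report <- function(control_qc, detection, dye, similarity,
                          removed = NULL, params = list(),
                          out_path = "report.pdf", colour_by = NULL) {
  sets <- list(
    control_qc = unique(control_qc$sample_id),
    detection = detection$sample_id,
    dye = unique(dye$summary$sample_id),
    similarity = rownames(similarity$pca$scores)
  )
  for (nm in names(sets)[-1]) {
    if (!setequal(sets[[1]], sets[[nm]])) {
      stop("sample sets disagree between report inputs ('control_qc' vs '",
           nm, "')", call. = FALSE)
    }
  }

  det_plots <- plot_detection(detection)
  grDevices::pdf(out_path, width = 10, height = 7.5, onefile = TRUE)
  ok <- try({
    print(report_header_page(params, sets[[1]], removed))
    print(plot_controls(control_qc, sample_dependent = FALSE))
    print(plot_controls(control_qc, sample_dependent = TRUE))
    print(plot_background(control_qc))
    print(det_plots$undetected)
    print(det_plots$mean_pval)
    print(plot_dye_bias(dye))
    print(autoplot(similarity$pca, colour_by = colour_by))
    plot(similarity$hclust$hclust,
         main = sprintf("Hierarchical clustering (%s distance, %s linkage)",
                        similarity$hclust$metric,
                        similarity$hclust$linkage_method),
         xlab = "", sub = "", cex = 0.8)
  }, silent = TRUE)
  grDevices::dev.off()
  if (inherits(ok, "try-error")) stop(ok)

  html_path <- paste0(tools::file_path_sans_ext(out_path), ".html")
  render_report_html(control_qc, detection, removed, params, html_path)
  c(pdf = out_path, html = html_path)
}

report_header_page <- function(params, retained, removed) {
  lines <- c(
    "Methylation array QC report",
    "",
    sprintf("Retained samples (%d): %s", length(retained),
            paste(retained, collapse = ", ")),
    if (!is.null(removed) && nrow(removed) > 0) {
      sprintf("Removed samples (%d): %s", nrow(removed),
              paste(sprintf("%s (mean detection p = %.3g)",
                            removed$sample_id,
                            removed$mean_detection_pval), collapse = ", "))
    } else "Removed samples: none",
    "",
    "Run parameters:",
    if (length(params) > 0) {
      paste0("  ", names(params), " = ",
             vapply(params, function(x) paste(format(x), collapse = " "),
                    character(1)))
    } else "  (defaults)"
  )
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 1,
                      label = paste(lines, collapse = "\n"),
                      hjust = 0, vjust = 1, size = 3.4, family = "mono") +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::theme_void()
}

render_report_html <- function(control_qc, detection, removed, params,
                               path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html_table <- function(df) {
    df <- as.data.frame(df)
    hdr <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                 collapse = ""), "</tr>")
    rows <- vapply(seq_len(nrow(df)), function(i) {
      cells <- vapply(seq_along(df), function(j) {
        v <- df[[j]][i]
        if (is.na(v)) ""
        else if (is.numeric(v)) formatC(v, format = "g", digits = 6)
        else esc(as.character(v))
      }, character(1))
      paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
    }, character(1))
    paste0("<table border='1' cellspacing='0' cellpadding='3'>", hdr,
           paste(rows, collapse = ""), "</table>")
  }
  param_txt <- if (length(params) > 0) {
    paste0("<li>", esc(names(params)), " = ",
           esc(vapply(params, function(x) paste(format(x), collapse = " "),
                      character(1))), "</li>", collapse = "")
  } else "<li>(defaults)</li>"
  removed_html <- if (!is.null(removed) && nrow(removed) > 0) {
    html_table(removed)
  } else "<p>none</p>"
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Methylation array QC report</title></head><body>",
    "<h1>Methylation array QC report</h1>",
    "<h2>Run parameters</h2><ul>", param_txt, "</ul>",
    "<h2>Removed samples</h2>", removed_html,
    "<h2>Detection summary</h2>", html_table(detection),
    "<h2>Internal control summary</h2>", html_table(control_qc),
    "</body></html>"
  ), path)
  invisible(path)
}
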