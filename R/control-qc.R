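#' System background from negative control probes
#'
#' The negative control probes carry randomly permuted sequences that should
#' not hybridize; the arithmetic mean of their signals defines the system
#' background for a sample and channel.
#'
#' @param controls Control tibble (see [read_control_profile()]) or a
#'   `meth_dataset`.
#' @param sample Sample identifier.
#' @param channel `"green"` or `"red"`.
#' @return Mean negative-control intensity (scalar).
#' @export
system_background <- function(controls, sample, channel = c("green", "red")) {
  channel <- match.arg(channel)
  controls <- as_controls(controls)
  sig <- controls$signal[controls$recognized &
                         controls$category == "negative" &
                         controls$sample_id == sample &
                         controls$channel == channel]
  sig <- sig[!is.na(sig)]
  if (length(sig) == 0) {
    stop("no negative control probes for sample '", sample, "' (", channel,
         " channel); system background undefined", call. = FALSE)
  }
  mean(sig)
}

#' Percentage of background on signal for one control category
#'
#' Defined as `100 * background / mean(category signal)` for a sample and
#' channel, where background is the mean negative-control signal
#' ([system_background()]). Low percentages indicate strong signal over
#' background; for target-removal controls the reading is inverted (the
#' stripping step should leave these probes near background, so a high
#' percentage is the good outcome). A non-positive category mean yields
#' `NA` with a warning (undefined-high) rather than an infinity.
#'
#' @inheritParams system_background
#' @param category One of the eight control categories.
#' @param subcategory Optional tag restricting the probes (nucleotide for
#'   extension/non-polymorphic, `low`/`medium`/`high` for hybridization,
#'   `PM`/`MM` for specificity).
#' @return Percentage (scalar), `NA` if undefined-high.
#' @export
background_on_signal_pct <- function(controls, sample, category,
                                     channel = c("green", "red"),
                                     subcategory = NULL) {
  channel <- match.arg(channel)
  controls <- as_controls(controls)
  bg <- system_background(controls, sample, channel)
  sel <- controls$recognized &
    controls$category == category &
    controls$sample_id == sample &
    controls$channel == channel
  if (!is.null(subcategory)) {
    sel <- sel & !is.na(controls$subcategory) &
      controls$subcategory == subcategory
  }
  sig <- controls$signal[sel]
  sig <- sig[!is.na(sig)]
  if (length(sig) == 0) {
    stop("no recognized '", category, "' control probes for sample '",
         sample, "' (", channel, " channel)", call. = FALSE)
  }
  m <- mean(sig)
  if (m <= 0) {
    warning("mean '", category, "' signal is non-positive for sample '",
            sample, "'; percentage undefined-high", call. = FALSE)
    return(NA_real_)
  }
  100 * bg / m
}

# Category semantics: which are sample-dependent, and the orientation of the
# quality reading ("low_good": low % of background on signal is good;
# "high_good": the probes are expected at background, so high % is good).
control_category_info <- function() {
  tibble::tibble(
    category = c("staining", "extension", "target_removal", "hybridization",
                 "bisulfite_conversion", "specificity", "negative",
                 "non_polymorphic"),
    sample_dependent = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    orientation = c("low_good", "low_good", "high_good", "low_good",
                    "low_good", "low_good", "background", "low_good")
  )
}

#' Per-sample summary of all internal control categories
#'
#' Computes, for every retained sample, channel, control category and
#' subcategory present in the data, the mean control signal, the system
#' background, and the percentage of background on signal. The
#' sample-independent set covers staining, extension (per nucleotide),
#' target removal and hybridization (per concentration level); the
#' sample-dependent set covers bisulfite conversion, specificity (PM and MM
#' separately), negative controls (reported as the background level itself)
#' and non-polymorphic controls (per queried base). Specificity mismatch
#' probes and target-removal probes are expected near background
#' (`orientation` records the reading); for the `low_good` categories a
#' percentage of 50 or more raises the `very_high_ratio` flag that marks
#' failing samples.
#'
#' @param dataset A `meth_dataset`.
#' @return A tibble with one row per sample x category x channel x
#'   subcategory: `sample_id`, `category`, `subcategory`, `channel`,
#'   `sample_dependent`, `orientation`, `background`, `mean_signal`,
#'   `pct_background_on_signal`, `flag`.
#' @export
control_summary <- function(dataset) {
  controls <- as_controls(dataset)
  info <- control_category_info()

  bg_tab <- controls |>
    dplyr::filter(.data$recognized, .data$category == "negative",
                  !is.na(.data$signal)) |>
    dplyr::group_by(.data$sample_id, .data$channel) |>
    dplyr::summarise(background = mean(.data$signal), .groups = "drop")
  all_pairs <- dplyr::distinct(controls, .data$sample_id, .data$channel)
  if (nrow(bg_tab) < nrow(all_pairs)) {
    miss <- dplyr::anti_join(all_pairs, bg_tab,
                             by = c("sample_id", "channel"))
    stop("no negative control probes for sample '", miss$sample_id[1],
         "' (", miss$channel[1], " channel); system background undefined",
         call. = FALSE)
  }

  out <- controls |>
    dplyr::filter(.data$recognized, !is.na(.data$signal)) |>
    dplyr::group_by(.data$sample_id, .data$category, .data$subcategory,
                    .data$channel) |>
    dplyr::summarise(mean_signal = mean(.data$signal),
                     n_probes = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(bg_tab, by = c("sample_id", "channel")) |>
    dplyr::left_join(info, by = "category") |>
    dplyr::mutate(
      # MM specificity probes are designed not to extend: near-background
      # signal is the good outcome, like target removal.
      orientation = dplyr::if_else(
        .data$category == "specificity" & .data$subcategory %in% "MM",
        "high_good", .data$orientation
      )
    ) |>
    dplyr::mutate(
      pct_background_on_signal = dplyr::case_when(
        .data$category == "negative" ~ NA_real_,
        .data$mean_signal <= 0 ~ NA_real_,
        TRUE ~ 100 * .data$background / .data$mean_signal
      ),
      flag = dplyr::case_when(
        .data$category == "negative" ~ "background_level",
        .data$mean_signal <= 0 ~ "undefined_high",
        .data$orientation == "low_good" &
          .data$pct_background_on_signal >= 50 ~ "very_high_ratio",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select("sample_id", "category", "subcategory", "channel",
                  "sample_dependent", "orientation", "background",
                  "mean_signal", "pct_background_on_signal", "flag") |>
    dplyr::arrange(factor(.data$sample_id,
                          levels = unique(controls$sample_id)),
                   .data$category, .data$channel, .data$subcategory)
  out
}

#' Target-removal signal relative to hybridization controls
#'
#' Target-removal probes test the stripping step after extension and should
#' sit near background, i.e. well below even the weakest hybridization
#' control. This secondary metric reports the ratio of the mean
#' target-removal signal to the mean low-concentration hybridization signal
#' per sample and channel; values well below 1 indicate efficient removal.
#'
#' @param dataset A `meth_dataset`.
#' @return Tibble with `sample_id`, `channel`, `target_removal_mean`,
#'   `hybridization_low_mean`, `ratio`.
#' @export
target_removal_ratio <- function(dataset) {
  controls <- as_controls(dataset)
  tr <- controls |>
    dplyr::filter(.data$recognized, .data$category == "target_removal",
                  !is.na(.data$signal)) |>
    dplyr::group_by(.data$sample_id, .data$channel) |>
    dplyr::summarise(target_removal_mean = mean(.data$signal),
                     .groups = "drop")
  hyb <- controls |>
    dplyr::filter(.data$recognized, .data$category == "hybridization",
                  .data$subcategory %in% "low", !is.na(.data$signal)) |>
    dplyr::group_by(.data$sample_id, .data$channel) |>
    dplyr::summarise(hybridization_low_mean = mean(.data$signal),
                     .groups = "drop")
  dplyr::inner_join(tr, hyb, by = c("sample_id", "channel")) |>
    dplyr::mutate(ratio = dplyr::if_else(
      .data$hybridization_low_mean > 0,
      .data$target_removal_mean / .data$hybridization_low_mean,
      NA_real_
    ))
}

as_controls <- function(x) {
  if (inherits(x, "meth_dataset")) x$controls else x
}
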