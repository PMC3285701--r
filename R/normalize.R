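#' Dye-bias diagnostics from channel-resolved control intensities
#'
#' Two-colour arrays commonly show a systematic intensity difference between
#' the green and red channels. This summarizes, per sample and channel, the
#' control-probe intensity distribution (quantiles, linear interpolation
#' between order statistics) and the number of probes above each intensity
#' cutoff, plus a per-sample bias score
#' `|median(green) - median(red)| / median(all)`.
#'
#' @param dataset A `meth_dataset`.
#' @param cutoffs Intensity cutoffs for the above-cutoff counts.
#' @param probs Quantile probabilities for the distribution summaries.
#' @return An object of class `methqc_dye`: list with `summary` (tibble per
#'   sample x channel: quantile columns `q<prob>` and count columns
#'   `n_above_<cutoff>`) and `bias` (tibble per sample with `bias_score`).
#' @export
dye_bias_diagnostics <- function(dataset,
                                 cutoffs = c(500, 1000, 5000),
                                 probs = c(0, 0.05, 0.25, 0.5, 0.75,
                                           0.95, 1)) {
  controls <- as_controls(dataset)
  controls <- dplyr::filter(controls, !is.na(.data$signal))
  if (nrow(controls) == 0) stop("no control intensities", call. = FALSE)
  chans <- dplyr::distinct(controls, .data$sample_id, .data$channel)
  if (length(unique(chans$channel)) < 2) {
    stop("empty channel: both green and red intensities are required",
         call. = FALSE)
  }

  summary <- controls |>
    dplyr::group_by(.data$sample_id, .data$channel) |>
    dplyr::summarise(
      stats = list({
        q <- quantile(.data$signal, probs = probs, type = 7, names = FALSE)
        cnt <- vapply(cutoffs, function(ct) sum(.data$signal > ct),
                      integer(1))
        setNames(c(as.list(q), as.list(cnt)),
                 c(sprintf("q%02d", round(100 * probs)),
                   sprintf("n_above_%g", cutoffs)))
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats")

  bias <- controls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      median_green = median(.data$signal[.data$channel == "green"]),
      median_red = median(.data$signal[.data$channel == "red"]),
      median_all = median(.data$signal),
      .groups = "drop"
    ) |>
    dplyr::mutate(bias_score = abs(.data$median_green - .data$median_red) /
                    .data$median_all)

  structure(list(summary = summary, bias = bias,
                 cutoffs = cutoffs, probs = probs),
            class = "methqc_dye")
}

#' @export
print.methqc_dye <- function(x, ...) {
  cat("<methqc_dye> dye-bias diagnostics,", nrow(x$bias), "samples\n")
  print(x$bias)
  invisible(x)
}

#' Probe-level quantile normalization of pooled intensities
#'
#' Equalizes intensity distributions across samples at the probe level: for
#' each sample the methylated and unmethylated intensities are pooled into a
#' single vector of length 2N, and each value is replaced by the cross-sample
#' mean of the order statistics at its rank. After normalization every
#' sample's sorted pooled vector is identical, which removes dye bias and
#' array-intensity effects while leaving the within-sample methylated vs
#' unmethylated contrast — and hence the methylation signal — intact.
#' Normalizing the pooled intensities, rather than summarized methylation
#' values, rests on the assumption that the pooled distribution is similar
#' across samples even when global methylation differs.
#'
#' Ties receive the mean of the tied order-statistic targets; missing values
#' are excluded from ranking and restored as missing (such samples are mapped
#' onto the reference distribution by linear interpolation of its quantile
#' function).
#'
#' @param meth,unmeth Probe-by-sample intensity matrices of identical shape.
#' @return A list with normalized `meth` and `unmeth` matrices.
#' @export
quantile_normalize <- function(meth, unmeth) {
  stopifnot(identical(dim(meth), dim(unmeth)))
  if (ncol(meth) < 2) {
    warning("fewer than 2 samples: quantile normalization is the identity",
            call. = FALSE)
    return(list(meth = meth, unmeth = unmeth))
  }
  pooled <- rbind(meth, unmeth)
  L <- nrow(pooled)

  # Reference distribution: per-sample quantile function evaluated on a
  # common grid of L points, averaged across samples. With no missing data
  # this is exactly the mean of order statistics.
  grid <- if (L == 1) 0 else (seq_len(L) - 1) / (L - 1)
  ref <- rowMeans(vapply(seq_len(ncol(pooled)), function(j) {
    x <- sort(pooled[, j][!is.na(pooled[, j])])
    if (length(x) == 0) {
      stop("sample '", colnames(pooled)[j], "' has no observed intensities",
           call. = FALSE)
    }
    if (length(x) == L) x else quantile(x, probs = grid, type = 7,
                                        names = FALSE)
  }, numeric(L)))

  norm <- apply(pooled, 2, function(x) {
    obs <- which(!is.na(x))
    n <- length(obs)
    targets <- if (n == L) ref else quantile_interp(ref, n)
    idx <- sort.list(x[obs], method = "radix")  # stable
    xs <- x[obs][idx]
    # ties: mean of the tied order-statistic targets
    if (anyDuplicated(xs)) {
      targets <- stats::ave(targets, match(xs, xs), FUN = mean)
    }
    assigned <- numeric(n)
    assigned[idx] <- targets
    out <- rep(NA_real_, L)
    out[obs] <- assigned
    out
  })
  dimnames(norm) <- dimnames(pooled)
  list(meth = norm[seq_len(nrow(meth)), , drop = FALSE],
       unmeth = norm[nrow(meth) + seq_len(nrow(unmeth)), , drop = FALSE])
}

# Quantile function of the reference (length-L sorted vector) evaluated at n
# equally spaced probabilities, by linear interpolation of order statistics.
quantile_interp <- function(ref, n) {
  quantile(ref, probs = if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1),
           type = 7, names = FALSE)
}

#' Quantile-normalize the intensities of a dataset
#'
#' Applies [quantile_normalize()] to the methylated/unmethylated matrices of
#' a `meth_dataset` and marks it normalized.
#'
#' @param dataset A `meth_dataset` (sample-filtered).
#' @return The dataset with normalized intensities.
#' @export
normalize_intensities <- function(dataset) {
  qn <- quantile_normalize(dataset$betas$meth, dataset$betas$unmeth)
  dataset$betas$meth <- qn$meth
  dataset$betas$unmeth <- qn$unmeth
  dataset$normalized <- TRUE
  dataset
}

#' M-values from methylated/unmethylated intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`. An M-value close to 0
#' means similar methylated and unmethylated intensity (about
#' half-methylated); positive values indicate hyper-methylation, negative
#' hypo-methylation. The offset (default 1 intensity unit) guards against
#' log of zero.
#'
#' @param meth Probe-by-sample methylated intensity matrix, or a
#'   `meth_dataset` (in which case `unmeth` is ignored).
#' @param unmeth Unmethylated intensity matrix.
#' @param offset Intensity offset added to both channels.
#' @return Probe-by-sample matrix of M-values (log2 units).
#' @export
m_values <- function(meth, unmeth = NULL, offset = 1) {
  if (inherits(meth, "meth_dataset")) {
    unmeth <- meth$betas$unmeth
    meth <- meth$betas$meth
  }
  stopifnot(identical(dim(meth), dim(unmeth)))
  if (offset <= 0 && (any(meth <= 0, na.rm = TRUE) ||
                      any(unmeth <= 0, na.rm = TRUE))) {
    stop("offset must be > 0 unless all intensities are positive",
         call. = FALSE)
  }
  log2((meth + offset) / (unmeth + offset))
}

#' Beta-values from methylated/unmethylated intensities
#'
#' `Beta = meth / (meth + unmeth + offset)`, a methylation fraction in
#' `[0, 1)`. The default offset of 100 matches the convention used when
#' summarizing raw intensities and regularizes low-intensity probes.
#'
#' @inheritParams m_values
#' @param offset Intensity offset added to the denominator.
#' @return Probe-by-sample matrix of Beta-values.
#' @export
beta_values <- function(meth, unmeth = NULL, offset = 100) {
  if (inherits(meth, "meth_dataset")) {
    unmeth <- meth$betas$unmeth
    meth <- meth$betas$meth
  }
  stopifnot(identical(dim(meth), dim(unmeth)))
  meth / (meth + unmeth + offset)
}
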