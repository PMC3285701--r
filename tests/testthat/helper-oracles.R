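# Independent brute-force oracles and in-code fixture builders.

# Mean-of-order-statistics quantile normalization on pooled matrices.
# Valid for tie-free, complete data only (asserted).
oracle_quantile_normalize <- function(meth, unmeth) {
  pooled <- rbind(meth, unmeth)
  stopifnot(!anyNA(pooled), all(apply(pooled, 2, anyDuplicated) == 0))
  ref <- rowMeans(apply(pooled, 2, sort))
  norm <- apply(pooled, 2, function(x) ref[rank(x)])
  dimnames(norm) <- dimnames(pooled)
  list(meth = norm[seq_len(nrow(meth)), , drop = FALSE],
       unmeth = norm[nrow(meth) + seq_len(nrow(unmeth)), , drop = FALSE])
}

# Naive double-loop detection statistics.
oracle_detection <- function(pv, cutoffs, pass_cutoff) {
  res <- list()
  for (s in colnames(pv)) {
    x <- pv[, s]
    x <- x[!is.na(x)]
    row <- list(sample_id = s)
    for (ct in sort(cutoffs)) {
      cnt <- 0
      for (v in x) if (v > ct) cnt <- cnt + 1
      row[[paste0("pct_", format(ct))]] <- 100 * cnt / length(x)
    }
    row$mean_pval <- sum(x) / length(x)
    row$passed <- row$mean_pval < pass_cutoff
    res[[s]] <- row
  }
  res
}

# Naive undetected-CpG lists (strict > on both thresholds).
oracle_undetected <- function(pv, cutoff, sample_fraction) {
  n <- ncol(pv)
  listed <- character(0)
  for (p in rownames(pv)) {
    cnt <- 0
    for (s in colnames(pv)) {
      v <- pv[p, s]
      if (!is.na(v) && v > cutoff) cnt <- cnt + 1
    }
    if (cnt / n > sample_fraction) listed <- c(listed, p)
  }
  listed
}

# Exhaustive O(n^3) agglomerative clustering; returns the cophenetic
# distance matrix and the sorted merge heights.
oracle_agglom <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  n <- nrow(dm)
  labs <- rownames(dm)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  heights <- numeric(0)
  cdist <- function(a, b) {
    dd <- dm[clusters[[a]], clusters[[b]], drop = FALSE]
    if (method == "average") mean(dd) else max(dd)
  }
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- cdist(i, j)
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- best
    coph[clusters[[bj]], clusters[[bi]]] <- best
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(cophenetic = coph, heights = sort(heights))
}

# -- fixture builders --------------------------------------------------------

# Control tibble with explicit per-sample signal values.
# rows: data.frame(category, subcategory, channel, signal is a function of
# sample index or a constant)
make_controls <- function(samples, rows) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    for (s_idx in seq_along(samples)) {
      sig <- rows$signal[[i]]
      out[[length(out) + 1]] <- tibble::tibble(
        control_probe_id = paste0("ctl", i),
        control_type = rows$category[i],
        category = rows$category[i],
        subcategory = rows$subcategory[i],
        recognized = !is.na(rows$category[i]),
        sample_id = samples[s_idx],
        channel = rows$channel[i],
        signal = if (is.function(sig)) sig(s_idx) else sig
      )
    }
  }
  dplyr::bind_rows(out)
}

# Assemble a meth_dataset directly from matrices (bypassing file IO).
make_dataset <- function(beta = NULL, pval = NULL, meth = NULL,
                         unmeth = NULL, controls = NULL,
                         samples = NULL, panel = "450K") {
  template <- Filter(Negate(is.null), list(beta, pval, meth, unmeth))[[1]]
  probes <- rownames(template)
  sample_ids <- colnames(template)
  blank <- matrix(NA_real_, length(probes), length(sample_ids),
                  dimnames = dimnames(template))
  if (is.null(controls)) {
    controls <- make_controls(sample_ids, tibble::tibble(
      category = "negative", subcategory = NA_character_,
      channel = rep(c("green", "red"), each = 1), signal = list(100, 100)))
  }
  structure(
    list(
      samples = samples %||% tibble::tibble(sample_id = sample_ids),
      betas = structure(
        list(probes = probes, samples = sample_ids,
             beta = beta %||% blank, pval = pval %||% blank,
             meth = meth %||% blank, unmeth = unmeth %||% blank,
             panel = panel),
        class = "beta_matrix"),
      controls = controls,
      excluded = character(0), normalized = FALSE),
    class = "meth_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

named_matrix <- function(data, n_probes, samples) {
  matrix(data, n_probes, length(samples),
         dimnames = list(paste0("cg", seq_len(n_probes)), samples))
}

# Small, fast simulation used across tests.
tiny_spec <- function(seed = 42, n_probes = 300, ...) {
  simulation_spec(n_probes = n_probes, seed = seed, ...)
}
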