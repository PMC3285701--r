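#' Principal component analysis of samples on M-values
#'
#' Samples are projected on the principal axes of the probe-centred M-value
#' matrix (probe-wise mean centring, no scaling: M-values already share a
#' log2 scale). Probes with any missing value are dropped (complete-case).
#' Component signs are fixed by forcing the largest-magnitude probe loading
#' of each component to be positive, so scores are reproducible across
#' platforms and sample orderings.
#'
#' @param m Probe-by-sample M-value matrix (see [m_values()]).
#' @param n_components Number of components to retain (default: all).
#' @return An object of class `methqc_pca`: list with `scores` (sample x
#'   component), `loadings`, `variance_explained` (fraction per retained
#'   component), `sdev`, `n_probes_used`.
#' @export
pca_m <- function(m, n_components = NULL) {
  if (ncol(m) < 2) {
    stop("PCA requires at least 2 samples", call. = FALSE)
  }
  keep <- complete.cases(m)
  if (!any(keep)) stop("no complete-case probes", call. = FALSE)
  x <- t(m[keep, , drop = FALSE])  # samples x probes
  fit <- prcomp(x, center = TRUE, scale. = FALSE)

  # deterministic sign: largest |loading| positive per component
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(n_components)) ncol(fit$x)
       else min(n_components, ncol(fit$x))
  structure(
    list(scores = fit$x[, seq_len(k), drop = FALSE],
         loadings = fit$rotation[, seq_len(k), drop = FALSE],
         variance_explained = ve[seq_len(k)],
         variance_explained_all = ve,
         sdev = fit$sdev,
         n_probes_used = sum(keep)),
    class = "methqc_pca"
  )
}

#' @export
print.methqc_pca <- function(x, ...) {
  cat("<methqc_pca>", nrow(x$scores), "samples,", x$n_probes_used,
      "complete-case probes\n")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(head(x$variance_explained, 4)),
                     100 * head(x$variance_explained, 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.methqc_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "score")
}

#' @export
glance.methqc_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_probes_used = x$n_probes_used,
    n_components = ncol(x$scores),
    pc1_variance = x$variance_explained[1],
    pc2_variance = if (length(x$variance_explained) >= 2)
      x$variance_explained[2] else NA_real_
  )
}

#' @param object A `methqc_pca` object.
#' @param components Two components to plot.
#' @param colour_by Optional named vector (by sample) used to colour points.
#' @param ... Unused.
#' @rdname pca_m
#' @export
autoplot.methqc_pca <- function(object, components = c(1, 2),
                                colour_by = NULL, ...) {
  k <- components
  df <- tibble::tibble(
    sample_id = rownames(object$scores),
    x = object$scores[, k[1]],
    y = object$scores[, k[2]]
  )
  if (!is.null(colour_by)) df$group <- colour_by[df$sample_id]
  lab <- function(i) sprintf("PC%d (%.1f%% variance)", k[i],
                             100 * object$variance_explained[k[i]])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(
      if (!is.null(colour_by)) ggplot2::aes(colour = .data$group),
      size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, size = 2.6, show.legend = FALSE) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL,
                  title = "PCA of normalized M-values") +
    ggplot2::theme_minimal()
  p
}

#' Agglomerative hierarchical clustering of samples on M-values
#'
#' Samples are clustered on complete-case probes using the chosen distance
#' (`euclidean` by default, the pipeline's standard; `manhattan`; or
#' `pearson`, i.e. 1 - Pearson correlation) and linkage (`average` by
#' default, `complete`, or `ward` via Ward's D2 criterion).
#'
#' @param m Probe-by-sample M-value matrix.
#' @param metric Distance metric between samples.
#' @param linkage_method Agglomeration criterion.
#' @return An object of class `methqc_hclust`: list wrapping the `hclust`
#'   tree plus `metric`, `linkage_method` and the sample distance matrix.
#' @export
hcluster_m <- function(m, metric = c("euclidean", "manhattan", "pearson"),
                       linkage_method = c("average", "complete", "ward")) {
  metric <- match.arg(metric)
  linkage_method <- match.arg(linkage_method)
  if (ncol(m) < 2) {
    stop("clustering requires at least 2 samples", call. = FALSE)
  }
  keep <- complete.cases(m)
  if (!any(keep)) stop("no complete-case probes", call. = FALSE)
  x <- m[keep, , drop = FALSE]
  d <- switch(metric,
    euclidean = dist(t(x), method = "euclidean"),
    manhattan = dist(t(x), method = "manhattan"),
    pearson = as.dist(1 - cor(x, use = "everything"))
  )
  if (any(!is.finite(d))) {
    dm <- as.matrix(d)
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
    stop("non-finite distance between samples '",
         rownames(dm)[bad[1]], "' and '", colnames(dm)[bad[2]], "'",
         call. = FALSE)
  }
  hc_method <- c(average = "average", complete = "complete",
                 ward = "ward.D2")[[linkage_method]]
  hc <- hclust(d, method = hc_method)
  structure(
    list(hclust = hc, metric = metric, linkage_method = linkage_method,
         dist = d, n_probes_used = sum(keep)),
    class = "methqc_hclust"
  )
}

#' @export
print.methqc_hclust <- function(x, ...) {
  cat("<methqc_hclust>", length(x$hclust$labels), "samples,",
      x$metric, "distance,", x$linkage_method, "linkage\n")
  invisible(x)
}

#' @export
tidy.methqc_hclust <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    merge_step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1],
    right = hc$merge[, 2],
    height = hc$height
  )
}

#' @export
glance.methqc_hclust <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$hclust$labels),
    metric = x$metric,
    linkage_method = x$linkage_method,
    max_height = max(x$hclust$height),
    n_probes_used = x$n_probes_used
  )
}

#' Export a clustering tree as a Newick string
#'
#' @param x A `methqc_hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(x$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Sample similarity on normalized M-values
#'
#' Convenience wrapper computing both [pca_m()] and [hcluster_m()] on the
#' same M-value matrix.
#'
#' @param m Probe-by-sample M-value matrix.
#' @inheritParams hcluster_m
#' @param n_components Components to retain in the PCA part.
#' @return An object of class `methqc_similarity`: list with `pca` and
#'   `hclust` parts.
#' @export
sample_similarity <- function(m, metric = "euclidean",
                              linkage_method = "average",
                              n_components = NULL) {
  structure(
    list(pca = pca_m(m, n_components = n_components),
         hclust = hcluster_m(m, metric = metric,
                             linkage_method = linkage_method)),
    class = "methqc_similarity"
  )
}

#' @export
print.methqc_similarity <- function(x, ...) {
  print(x$pca); print(x$hclust)
  invisible(x)
}
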