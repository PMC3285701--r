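#' Specification for a simulated methylation experiment
#'
#' Describes a synthetic Infinium-style experiment with known ground truth:
#' sample groups with target methylation levels, optional batch (bisulfite
#' kit) intensity effects, planted poor-quality samples, a green/red dye
#' bias on the control channels, and the intensity levels of the eight
#' internal control categories. The default design mirrors a three-group
#' control experiment — native Jurkat DNA (`JUR`, target Beta 0.50),
#' artificially methylated Jurkat (`JUR MET`, 0.85) and whole-genome
#' amplified unmethylated DNA (`UNMET`, 0.05) — each group processed with
#' two bisulfite kits in two biological replicates (12 samples), plus one
#' poor-quality brain sample (`PD3 AMYG`) whose arrays largely failed.
#'
#' The intensity model is `meth = background + beta * dynamic_range + noise`
#' and `unmeth = background + (1 - beta) * dynamic_range + noise`, truncated
#' at 0, with per-probe true Betas drawn once per group around the target
#' (sd `probe_beta_sd`) and shared by the group's samples — this is what
#' makes biological replicates correlate. Poor samples have a fraction
#' `failure_fraction` of probes at background intensity with detection
#' p-values uniform on \[0, 1\] (mean detection p about half, i.e. ten times
#' a 0.05 cutoff, and >90% undetected probes); good samples have detection
#' p-values uniform on \[0, 0.005\].
#'
#' @param n_probes Number of CpG probes.
#' @param groups Data frame with columns `label`, `n_samples`, `mean_beta`.
#' @param batches Character vector of batch labels cycled over the samples
#'   of each group (e.g. bisulfite kits).
#' @param batch_effect Multiplicative intensity factor applied to the second
#'   and following batches.
#' @param poor_samples Data frame with columns `sample_id`,
#'   `failure_fraction`, appended after the group samples.
#' @param dye_bias Multiplicative factor applied to the green control
#'   channel.
#' @param background Mean negative-control (system background) intensity.
#' @param dynamic_range Intensity span between fully unmethylated and fully
#'   methylated probes.
#' @param noise_sd Gaussian intensity noise sd per probe and sample.
#' @param probe_beta_sd Sd of per-probe true Beta around the group target.
#' @param control_levels Named list overriding control-category mean
#'   intensities.
#' @param n_negative Number of negative control probes.
#' @param seed Integer seed; a fixed seed makes the simulation (and the
#'   files written from it) reproducible.
#' @return A `simulation_spec` object (validated list).
#' @export
simulation_spec <- function(n_probes = 5000,
                            groups = default_groups(),
                            batches = c("KIT1", "KIT2"),
                            batch_effect = 1.1,
                            poor_samples = default_poor_samples(),
                            dye_bias = 1.2,
                            background = 100,
                            dynamic_range = 10000,
                            noise_sd = 80,
                            probe_beta_sd = 0.08,
                            control_levels = list(),
                            n_negative = 32,
                            seed = 20111219) {
  spec <- list(
    n_probes = as.integer(n_probes), groups = tibble::as_tibble(groups),
    batches = batches, batch_effect = batch_effect,
    poor_samples = tibble::as_tibble(poor_samples), dye_bias = dye_bias,
    background = background, dynamic_range = dynamic_range,
    noise_sd = noise_sd, probe_beta_sd = probe_beta_sd,
    control_levels = utils::modifyList(default_control_levels(),
                                       control_levels),
    n_negative = as.integer(n_negative), seed = as.integer(seed)
  )
  validate_spec(spec)
  structure(spec, class = "simulation_spec")
}

default_groups <- function() {
  tibble::tibble(
    label = c("JUR", "JUR MET", "UNMET"),
    n_samples = c(4L, 4L, 4L),
    mean_beta = c(0.50, 0.85, 0.05)
  )
}

default_poor_samples <- function() {
  tibble::tibble(sample_id = "PD3 AMYG", failure_fraction = 0.98)
}

default_control_levels <- function() {
  list(
    staining = 3000, extension = 4000, target_removal = 150,
    hybridization_low = 500, hybridization_medium = 1500,
    hybridization_high = 3000,
    bisulfite_conversion = 2000, specificity_pm = 3000,
    specificity_mm = 150, non_polymorphic = 3000
  )
}

validate_spec <- function(spec) {
  if (spec$n_probes < 1) {
    stop("n_probes must be >= 1", call. = FALSE)
  }
  g <- spec$groups
  if (!all(c("label", "n_samples", "mean_beta") %in% names(g)) ||
      nrow(g) == 0) {
    stop("groups must have columns label, n_samples, mean_beta",
         call. = FALSE)
  }
  if (any(g$n_samples < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(g$mean_beta < 0 | g$mean_beta > 1)) {
    stop("mean_beta targets must lie in [0, 1]", call. = FALSE)
  }
  p <- spec$poor_samples
  if (nrow(p) > 0 &&
      any(p$failure_fraction < 0 | p$failure_fraction > 1)) {
    stop("failure_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd < 0 || spec$background < 0 || spec$dynamic_range <= 0 ||
      spec$dye_bias <= 0) {
    stop("background/noise_sd must be >= 0; dynamic_range/dye_bias > 0",
         call. = FALSE)
  }
  invisible(spec)
}

#' Simulate a methylation dataset with known ground truth
#'
#' Draws a `meth_dataset` according to a [simulation_spec()]: group-wise
#' per-probe true Betas, intensity pairs under the additive
#' background/dynamic-range model, batch intensity factors, control probes
#' at the specified levels with negative controls defining the background,
#' a green-channel dye-bias factor, and planted poor-quality samples whose
#' failing probes sit at background with uniform detection p-values (the
#' poor sample's control probes are also drawn at background, reproducing
#' the very-high background-on-signal ratios a failing array shows).
#'
#' @param spec A [simulation_spec()].
#' @return A `meth_dataset`; attribute `truth` records the per-sample group,
#'   batch and quality assignments.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)

  roster <- simulation_roster(spec)
  n_s <- nrow(roster)
  probes <- sprintf("cg%08d", seq_len(spec$n_probes))

  # group-wise per-probe true Beta, shared by the group's samples
  group_beta <- lapply(seq_len(nrow(spec$groups)), function(i) {
    pmin(pmax(rnorm(spec$n_probes, spec$groups$mean_beta[i],
                    spec$probe_beta_sd), 0), 1)
  })
  names(group_beta) <- spec$groups$label
  # poor samples get an ordinary mid-methylation profile; their failure is
  # an intensity/detection failure, not a biology change
  poor_beta <- pmin(pmax(rnorm(spec$n_probes, 0.5, spec$probe_beta_sd),
                         0), 1)

  meth <- unmeth <- pval <- matrix(
    NA_real_, spec$n_probes, n_s, dimnames = list(probes, roster$sample_id))
  for (j in seq_len(n_s)) {
    b <- if (roster$poor[j]) poor_beta else group_beta[[roster$group[j]]]
    fac <- spec$batch_effect ^ (match(roster$batch[j], spec$batches) - 1)
    mu_m <- (spec$background + b * spec$dynamic_range) * fac
    mu_u <- (spec$background + (1 - b) * spec$dynamic_range) * fac
    m <- pmax(mu_m + rnorm(spec$n_probes, 0, spec$noise_sd), 0)
    u <- pmax(mu_u + rnorm(spec$n_probes, 0, spec$noise_sd), 0)
    p <- runif(spec$n_probes, 0, 0.005)
    if (roster$poor[j]) {
      n_fail <- round(roster$failure_fraction[j] * spec$n_probes)
      fail <- sample.int(spec$n_probes, n_fail)
      m[fail] <- pmax(rnorm(n_fail, spec$background, spec$noise_sd / 2), 0)
      u[fail] <- pmax(rnorm(n_fail, spec$background, spec$noise_sd / 2), 0)
      p[fail] <- runif(n_fail)
    }
    meth[, j] <- m
    unmeth[, j] <- u
    pval[, j] <- p
  }
  beta <- meth / (meth + unmeth)
  beta[!is.finite(beta)] <- NA_real_

  controls <- simulate_controls(spec, roster)

  betas <- structure(
    list(probes = probes, samples = roster$sample_id,
         beta = beta, pval = pval, meth = meth, unmeth = unmeth,
         panel = "450K"),
    class = "beta_matrix")
  samples <- tibble::tibble(
    sample_id = roster$sample_id,
    sample_group = roster$group,
    sample_batch = roster$batch
  )
  ds <- structure(
    list(samples = samples, betas = betas, controls = controls,
         excluded = character(0), normalized = FALSE),
    class = "meth_dataset")
  attr(ds, "truth") <- roster
  ds
}

simulation_roster <- function(spec) {
  g <- spec$groups
  rows <- purrr::pmap_dfr(g, function(label, n_samples, mean_beta) {
    batch <- rep(spec$batches, length.out = n_samples)
    rep_id <- stats::ave(seq_len(n_samples), batch, FUN = seq_along)
    tibble::tibble(
      sample_id = paste0(label, " ", batch, "_BIO", rep_id),
      group = label, batch = batch,
      poor = FALSE, failure_fraction = 0
    )
  })
  if (nrow(spec$poor_samples) > 0) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      sample_id = spec$poor_samples$sample_id,
      group = "POOR", batch = spec$batches[1],
      poor = TRUE, failure_fraction = spec$poor_samples$failure_fraction
    ))
  }
  rows
}

simulate_controls <- function(spec, roster) {
  lv <- spec$control_levels
  defs <- tibble::tibble(
    control_type = c(
      "Staining", paste0("Extension (", c("A", "T", "C", "G"), ")"),
      "Target Removal",
      paste0("Hybridization (", c("Low", "Medium", "High"), ")"),
      "Bisulfite Conversion I",
      "Specificity (PM)", "Specificity (MM)",
      rep("Negative", spec$n_negative),
      paste0("Non-Polymorphic (", c("A", "T", "C", "G"), ")")
    ),
    level = c(
      lv$staining, rep(lv$extension, 4), lv$target_removal,
      lv$hybridization_low, lv$hybridization_medium, lv$hybridization_high,
      lv$bisulfite_conversion, lv$specificity_pm, lv$specificity_mm,
      rep(spec$background, spec$n_negative), rep(lv$non_polymorphic, 4)
    )
  )
  defs$control_probe_id <- sprintf("ctl%05d", seq_len(nrow(defs)))
  cls <- classify_control_type(defs$control_type)
  rel_sd <- 0.08  # within-category probe noise, relative

  purrr::map_dfr(seq_len(nrow(roster)), function(j) {
    level <- if (roster$poor[j]) {
      rep(spec$background, nrow(defs))  # failing array: everything at bg
    } else {
      defs$level
    }
    draw <- function(chan_factor) {
      pmax(level * chan_factor *
             (1 + rnorm(nrow(defs), 0, rel_sd)), 0)
    }
    dplyr::bind_rows(
      tibble::tibble(
        control_probe_id = defs$control_probe_id,
        control_type = defs$control_type,
        category = cls$category, subcategory = cls$subcategory,
        recognized = cls$recognized,
        sample_id = roster$sample_id[j], channel = "green",
        signal = draw(spec$dye_bias)
      ),
      tibble::tibble(
        control_probe_id = defs$control_probe_id,
        control_type = defs$control_type,
        category = cls$category, subcategory = cls$subcategory,
        recognized = cls$recognized,
        sample_id = roster$sample_id[j], channel = "red",
        signal = draw(1)
      )
    )
  })
}

#' Write a dataset as the three GenomeStudio-dialect text files
#'
#' Produces `SampleTable.txt`, `ControlProbeProfile.txt` and
#' `AverageBeta.txt` in the chosen dialect, readable back by the
#' [read_sample_table()] / [read_control_profile()] / [read_avg_beta()]
#' readers with an exact round trip at the printed precision (6 significant
#' digits).
#'
#' @param dataset A `meth_dataset`.
#' @param out_dir Output directory (created if absent).
#' @param panel `"27K"` or `"450K"`; decides which signal column
#'   (`Signal_A`/`Signal_B`) carries the methylated intensity.
#' @return Named character vector of the three file paths.
#' @export
write_genomestudio_files <- function(dataset, out_dir,
                                     panel = c("450K", "27K")) {
  panel <- match.arg(panel)
  if (n_probes(dataset) == 0) {
    stop("dataset has 0 probes; nothing to write", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  b <- dataset$betas
  fmt <- function(m) ifelse(is.na(m), "NA", formatC(m, format = "g",
                                                    digits = 6))

  sample_path <- file.path(out_dir, "SampleTable.txt")
  st <- dataset$samples
  names(st)[names(st) == "sample_id"] <- "Sample ID"
  readr::write_tsv(st, sample_path)

  beta_path <- file.path(out_dir, "AverageBeta.txt")
  cols <- list(TargetID = b$probes)
  for (s in b$samples) {
    cols[[paste0(s, ".AVG_Beta")]] <- fmt(b$beta[, s])
    cols[[paste0(s, ".Detection Pval")]] <- fmt(b$pval[, s])
    if (panel == "27K") {
      cols[[paste0(s, ".Signal_A")]] <- fmt(b$meth[, s])
      cols[[paste0(s, ".Signal_B")]] <- fmt(b$unmeth[, s])
    } else {
      cols[[paste0(s, ".Signal_A")]] <- fmt(b$unmeth[, s])
      cols[[paste0(s, ".Signal_B")]] <- fmt(b$meth[, s])
    }
  }
  readr::write_tsv(tibble::as_tibble(cols), beta_path)

  ctrl_path <- file.path(out_dir, "ControlProbeProfile.txt")
  wide <- dataset$controls |>
    dplyr::mutate(channel = dplyr::if_else(.data$channel == "green",
                                           "Signal_Grn", "Signal_Red"),
                  signal = fmt(.data$signal)) |>
    tidyr::pivot_wider(
      id_cols = c("control_probe_id", "control_type"),
      names_from = c("sample_id", "channel"),
      names_glue = "{sample_id}.{channel}",
      values_from = "signal"
    ) |>
    dplyr::rename(TargetID = "control_type",
                  ProbeID = "control_probe_id") |>
    dplyr::relocate("TargetID", "ProbeID")
  readr::write_tsv(wide, ctrl_path)

  c(sample_table = sample_path, control_profile = ctrl_path,
    avg_beta = beta_path)
}

#' Simulate and write GenomeStudio fixture files in one step
#'
#' @inheritParams simulate_dataset
#' @inheritParams write_genomestudio_files
#' @return Named character vector of the three file paths; the simulated
#'   dataset is attached as attribute `dataset`.
#' @export
simulate_genomestudio_files <- function(spec = simulation_spec(), out_dir,
                                        panel = "450K") {
  ds <- simulate_dataset(spec)
  paths <- write_genomestudio_files(ds, out_dir, panel = panel)
  attr(paths, "dataset") <- ds
  paths
}
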