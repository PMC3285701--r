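write_sample_table <- function(ids, path = withr::local_tempfile(
                                 fileext = ".txt",
                                 .local_envir = parent.frame())) {
  readr::write_tsv(tibble::tibble(`Sample ID` = ids), path)
  path
}

table1_roster <- c(
  "JUR KIT2_BIO1", "JUR KIT2_BIO2", "JUR KIT1_BIO1", "JUR KIT1_BIO2",
  "JUR MET KIT2_BIO1", "JUR MET KIT2_BIO2", "JUR MET KIT1_BIO1",
  "JUR MET KIT1_BIO2", "UNMET KIT2_BIO1", "UNMET KIT2_BIO2",
  "UNMET KIT1_BIO1", "UNMET KIT1_BIO2", "PD3 AMYG")

test_that("sample table reader enforces identifier presence and uniqueness", {
  p <- write_sample_table(c("A", "B", "C"))
  tab <- read_sample_table(p)
  expect_equal(tab$sample_id, c("A", "B", "C"))

  p2 <- write_sample_table(c("A", "B", "A"))
  expect_error(read_sample_table(p2), "duplicate sample_id.*A")

  p3 <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(tibble::tibble(foo = 1:3, bar = letters[1:3]), p3)
  expect_error(read_sample_table(p3), "foo, bar")

  expect_error(read_sample_table(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("the 13-sample bisulfite-experiment roster reads as 13 samples", {
  p <- write_sample_table(table1_roster)
  tab <- read_sample_table(p)
  expect_equal(nrow(tab), 13)
  expect_setequal(tab$sample_id, table1_roster)
})

write_beta_fixture <- function(path, probes, samples, beta, pval, meth,
                               unmeth, panel = "27K", drop_cols = NULL) {
  cols <- list(TargetID = probes)
  for (j in seq_along(samples)) {
    s <- samples[j]
    cols[[paste0(s, ".AVG_Beta")]] <- beta[, j]
    cols[[paste0(s, ".Detection Pval")]] <- pval[, j]
    if (panel == "27K") {
      cols[[paste0(s, ".Signal_A")]] <- meth[, j]
      cols[[paste0(s, ".Signal_B")]] <- unmeth[, j]
    } else {
      cols[[paste0(s, ".Signal_A")]] <- unmeth[, j]
      cols[[paste0(s, ".Signal_B")]] <- meth[, j]
    }
  }
  cols[drop_cols] <- NULL
  readr::write_tsv(tibble::as_tibble(cols), path)
  path
}

test_that("average beta reader builds the four matrices in both dialects", {
  probes <- paste0("cg", 1:5)
  samples <- c("S1", "S2")
  set.seed(7)
  beta <- matrix(round(runif(10), 4), 5)
  pval <- matrix(round(runif(10), 4), 5)
  meth <- matrix(round(runif(10, 100, 900), 1), 5)
  unmeth <- matrix(round(runif(10, 100, 900), 1), 5)

  for (panel in c("27K", "450K")) {
    p <- withr::local_tempfile(fileext = ".txt")
    write_beta_fixture(p, probes, samples, beta, pval, meth, unmeth,
                       panel = panel)
    bm <- read_avg_beta(p, panel = panel)
    expect_equal(bm$samples, samples)
    expect_equal(dim(bm$beta), c(5, 2))
    expect_equal(unname(bm$beta), beta)
    expect_equal(unname(bm$pval), pval)
    expect_equal(unname(bm$meth), meth, info = panel)
    expect_equal(unname(bm$unmeth), unmeth, info = panel)
  }
})

test_that("missing cells stay missing and bad cells are located", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "TargetID\tS1.AVG_Beta\tS1.Detection Pval\tS1.Signal_A\tS1.Signal_B\tS2.AVG_Beta\tS2.Detection Pval\tS2.Signal_A\tS2.Signal_B",
    "cg1\tNaN\t0.01\t10\t20\t0.5\t0.02\t30\t40",
    "cg2\t0.4\t0.03\t50\t60\t0.6\t0.04\t70\t80"), p)
  bm <- read_avg_beta(p, panel = "27K")
  expect_true(is.na(bm$beta["cg1", "S1"]))
  expect_equal(bm$pval["cg1", "S1"], 0.01)  # detection still usable

  writeLines(c(
    "TargetID\tS1.AVG_Beta\tS1.Detection Pval\tS1.Signal_A\tS1.Signal_B",
    "cg1\t0.5\t0.01\toops\t20"), p)
  expect_error(read_avg_beta(p, panel = "27K"),
               "non-numeric value 'oops'.*Signal_A.*row 1")
})

test_that("a sample missing one column group is a format error naming it", {
  p <- withr::local_tempfile(fileext = ".txt")
  probes <- paste0("cg", 1:3)
  m <- matrix(1, 3, 2)
  write_beta_fixture(p, probes, c("A", "B"), m, m, m, m,
                     drop_cols = "B.Detection Pval")
  expect_error(read_avg_beta(p), "Detection Pval.*absent.*B")
})

write_control_fixture <- function(path, samples,
                                  types = c("Staining",
                                            "Extension (A)",
                                            "Target Removal",
                                            "Hybridization (Low)",
                                            "Hybridization (Medium)",
                                            "Hybridization (High)",
                                            "Bisulfite Conversion I",
                                            "Specificity (PM)",
                                            "Specificity (MM)",
                                            "Negative",
                                            "Non-Polymorphic (G)"),
                                  value = 500) {
  cols <- list(TargetID = types, ProbeID = paste0("c", seq_along(types)))
  for (s in samples) {
    cols[[paste0(s, ".Signal_Grn")]] <- rep(value, length(types))
    cols[[paste0(s, ".Signal_Red")]] <- rep(value, length(types))
  }
  readr::write_tsv(tibble::as_tibble(cols), path)
  path
}

test_that("control reader classifies the eight categories and their tags", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_control_fixture(p, c("S1", "S2"))
  ctl <- read_control_profile(p)
  expect_setequal(
    unique(ctl$category[ctl$recognized]),
    c("staining", "extension", "target_removal", "hybridization",
      "bisulfite_conversion", "specificity", "negative", "non_polymorphic"))
  hyb <- dplyr::filter(ctl, category == "hybridization")
  expect_setequal(unique(hyb$subcategory), c("low", "medium", "high"))
  spc <- dplyr::filter(ctl, category == "specificity")
  expect_setequal(unique(spc$subcategory), c("PM", "MM"))
  expect_equal(
    unique(ctl$subcategory[ctl$category %in% "non_polymorphic"]), "G")
  expect_setequal(unique(ctl$channel), c("green", "red"))
})

test_that("unrecognized control rows are kept, flagged, and ignored by metrics", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_control_fixture(p, "S1",
                        types = c("Negative", "Hybridization (High)",
                                  "MYSTERY CONTROL"))
  ctl <- read_control_profile(p)
  expect_true(all(!ctl$recognized[ctl$control_type == "MYSTERY CONTROL"]))
  expect_equal(sum(!ctl$recognized), 2)  # one row x two channels
  # metric unaffected: mean hybridization signal excludes the mystery row
  expect_equal(background_on_signal_pct(ctl, "S1", "hybridization", "green"),
               100)

  p2 <- withr::local_tempfile(fileext = ".txt")
  write_control_fixture(p2, "S1", types = c("MYSTERY", "UNKNOWN"))
  expect_error(read_control_profile(p2), "no recognizable control rows")
})

test_that("assembly applies exclusions, canonical order, and consistency checks", {
  spec <- tiny_spec(n_probes = 50)
  dir <- withr::local_tempdir()
  paths <- simulate_genomestudio_files(spec, dir)
  samples <- read_sample_table(paths["sample_table"])
  betas <- read_avg_beta(paths["avg_beta"], panel = "450K")
  controls <- read_control_profile(paths["control_profile"])

  ds <- assemble_dataset(samples, betas, controls,
                         exclusion = "PD3 AMYG")
  expect_equal(n_samples(ds), 12)
  expect_false("PD3 AMYG" %in% ds$betas$samples)
  expect_false("PD3 AMYG" %in% ds$controls$sample_id)
  expect_equal(ds$betas$samples, ds$samples$sample_id)

  # empty exclusion file is the identity
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  ds2 <- assemble_dataset(samples, betas, controls, exclusion = empty)
  expect_equal(n_samples(ds2), 13)

  # unknown name: warning, nothing dropped
  expect_warning(
    ds3 <- assemble_dataset(samples, betas, controls, exclusion = "GHOST"),
    "GHOST")
  expect_equal(n_samples(ds3), 13)

  # sample mismatch after exclusion is an error
  samples_extra <- dplyr::bind_rows(samples,
                                    tibble::tibble(sample_id = "EXTRA"))
  expect_error(assemble_dataset(samples_extra, betas, controls),
               "sample sets disagree")
})

test_that("reader output is invariant to input row order", {
  spec <- tiny_spec(n_probes = 40)
  dir <- withr::local_tempdir()
  paths <- simulate_genomestudio_files(spec, dir)

  lines <- readLines(paths["avg_beta"])
  shuffled <- c(lines[1], sample(lines[-1]))
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(shuffled, p2)

  a <- read_avg_beta(paths["avg_beta"], panel = "450K")
  b <- read_avg_beta(p2, panel = "450K")
  ord <- a$probes
  expect_equal(a$beta, b$beta[ord, ])
  expect_equal(a$meth, b$meth[ord, ])
  expect_equal(a$pval, b$pval[ord, ])
})

test_that("write -> read round trips both dialects at printed precision", {
  spec <- tiny_spec(n_probes = 60)
  ds <- simulate_dataset(spec)
  for (panel in c("27K", "450K")) {
    dir <- withr::local_tempdir()
    paths <- write_genomestudio_files(ds, dir, panel = panel)
    betas <- read_avg_beta(paths["avg_beta"], panel = panel)
    expect_equal(betas$meth, ds$betas$meth, tolerance = 1e-5)
    expect_equal(betas$unmeth, ds$betas$unmeth, tolerance = 1e-5)
    expect_equal(betas$beta, ds$betas$beta, tolerance = 1e-5)
    expect_equal(betas$pval, ds$betas$pval, tolerance = 1e-5)
    ctl <- read_control_profile(paths["control_profile"])
    merged <- dplyr::inner_join(
      ctl, ds$controls,
      by = c("control_probe_id", "sample_id", "channel"),
      suffix = c("_rt", "_orig"))
    expect_equal(nrow(merged), nrow(ds$controls))
    expect_equal(merged$signal_rt, merged$signal_orig, tolerance = 1e-5)
    expect_equal(merged$category_rt, merged$category_orig)
  }
})
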