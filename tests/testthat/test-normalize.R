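random_pair <- function(n_probes, samples, seed = 1) {
  set.seed(seed)
  list(
    meth = named_matrix(runif(n_probes * length(samples), 50, 5000),
                        n_probes, samples),
    unmeth = named_matrix(runif(n_probes * length(samples), 50, 5000),
                          n_probes, samples)
  )
}

test_that("pooled quantile normalization matches the worked 2-sample case", {
  meth <- named_matrix(c(1, 2, 2, 4), 2, c("A", "B"))
  unmeth <- named_matrix(c(3, 4, 6, 8), 2, c("A", "B"))
  # pooled columns: A = {1,2,3,4}, B = {2,4,6,8}; order-statistic means
  # {1.5, 3, 4.5, 6} assigned back at matching ranks
  qn <- quantile_normalize(meth, unmeth)
  expect_equal(unname(qn$meth[, "A"]), c(1.5, 3))
  expect_equal(unname(qn$unmeth[, "A"]), c(4.5, 6))
  expect_equal(unname(qn$meth[, "B"]), c(1.5, 3))
  expect_equal(unname(qn$unmeth[, "B"]), c(4.5, 6))
})

test_that("normalization equalizes sorted pooled vectors exactly", {
  pr <- random_pair(200, sprintf("S%d", 1:10))
  qn <- quantile_normalize(pr$meth, pr$unmeth)
  pooled <- rbind(qn$meth, qn$unmeth)
  sorted <- apply(pooled, 2, sort)
  for (j in 2:ncol(sorted)) {
    expect_identical(sorted[, j], sorted[, 1])  # bit-identical
  }
  # and equals the brute-force mean-of-order-statistics oracle
  o <- oracle_quantile_normalize(pr$meth, pr$unmeth)
  expect_equal(qn$meth, o$meth, tolerance = 1e-9)
  expect_equal(qn$unmeth, o$unmeth, tolerance = 1e-9)
})

test_that("normalization agrees with an established reference implementation", {
  skip_if_not_installed("limma")
  pr <- random_pair(80, c("A", "B", "C"), seed = 5)
  pooled <- rbind(pr$meth, pr$unmeth)
  ref <- limma::normalizeQuantiles(pooled, ties = TRUE)
  qn <- quantile_normalize(pr$meth, pr$unmeth)
  expect_equal(unname(rbind(qn$meth, qn$unmeth)), unname(ref),
               tolerance = 1e-9)
})

test_that("identical pooled distributions are a fixed point", {
  base <- seq(100, 1000, length.out = 40)
  set.seed(3)
  meth <- named_matrix(NA_real_, 20, c("A", "B", "C"))
  unmeth <- named_matrix(NA_real_, 20, c("A", "B", "C"))
  for (j in 1:3) {
    perm <- sample(base)  # same values, different probe assignment
    meth[, j] <- perm[1:20]
    unmeth[, j] <- perm[21:40]
  }
  qn <- quantile_normalize(meth, unmeth)
  expect_equal(qn$meth, meth, tolerance = 1e-12)
  expect_equal(qn$unmeth, unmeth, tolerance = 1e-12)
})

test_that("ties receive the mean of the tied order-statistic targets", {
  meth <- named_matrix(c(5, 5, 1, 9), 2, c("A", "B"))
  unmeth <- named_matrix(c(1, 9, 5, 13), 2, c("A", "B"))
  # pooled A = {5,5,1,9}, B = {1,9,5,13}; sorted A {1,5,5,9}, B {1,5,9,13}
  # targets = {1, 5, 7, 11}; A's tied 5s share mean(5, 7) = 6
  qn <- quantile_normalize(meth, unmeth)
  expect_equal(unname(qn$meth[, "A"]), c(6, 6))
  expect_equal(unname(qn$unmeth[, "A"]), c(1, 11))
  expect_equal(unname(qn$meth[, "B"]), c(1, 7))
  expect_equal(unname(qn$unmeth[, "B"]), c(5, 11))
})

test_that("missing intensities are excluded from ranking and restored", {
  pr <- random_pair(50, c("A", "B", "C"), seed = 9)
  pr$meth[c(3, 10), "A"] <- NA
  pr$unmeth[7, "B"] <- NA
  qn <- quantile_normalize(pr$meth, pr$unmeth)
  expect_true(all(is.na(qn$meth[c(3, 10), "A"])))
  expect_true(is.na(qn$unmeth[7, "B"]))
  expect_false(anyNA(qn$meth[-c(3, 10), "A"]))
  # observed values keep their within-sample ranks
  obs <- !is.na(pr$meth[, "A"])
  expect_equal(rank(qn$meth[obs, "A"]), rank(pr$meth[obs, "A"]))
})

test_that("within-sample ranks are preserved and a lone sample passes through", {
  pr <- random_pair(100, c("A", "B"), seed = 21)
  qn <- quantile_normalize(pr$meth, pr$unmeth)
  for (s in c("A", "B")) {
    pooled_in <- c(pr$meth[, s], pr$unmeth[, s])
    pooled_out <- c(qn$meth[, s], qn$unmeth[, s])
    expect_equal(rank(pooled_out), rank(pooled_in))
  }
  single <- lapply(pr, function(m) m[, "A", drop = FALSE])
  expect_warning(qn1 <- quantile_normalize(single$meth, single$unmeth),
                 "identity")
  expect_identical(qn1$meth, single$meth)
})

test_that("M-values follow log2((meth+o)/(unmeth+o)) with its sign meaning", {
  m <- m_values(named_matrix(100, 1, "S"), named_matrix(100, 1, "S"),
                offset = 0)
  expect_identical(unname(m[1, 1]), 0)  # half-methylated: M exactly 0
  expect_equal(unname(m_values(named_matrix(400, 1, "S"),
                               named_matrix(100, 1, "S"), offset = 0)[1, 1]),
               2)
  # hyper-methylated probes are positive, hypo negative
  expect_gt(m_values(matrix(300), matrix(100), offset = 1)[1, 1], 0)
  expect_lt(m_values(matrix(100), matrix(300), offset = 1)[1, 1], 0)
  # strictly increasing in meth, decreasing in unmeth
  expect_true(all(diff(m_values(matrix(1:10 * 100, 10), matrix(500, 10),
                                offset = 1)[, 1]) > 0))
  expect_true(all(diff(m_values(matrix(500, 10), matrix(1:10 * 100, 10),
                                offset = 1)[, 1]) < 0))
  expect_error(m_values(matrix(0), matrix(10), offset = 0), "offset")
})

test_that("Beta and M satisfy the logit identity at zero offset", {
  pr <- random_pair(10, sprintf("S%d", 1:4), seed = 13)
  beta <- beta_values(pr$meth, pr$unmeth, offset = 0)
  m <- m_values(pr$meth, pr$unmeth, offset = 0)
  expect_equal(m, log2(beta / (1 - beta)), tolerance = 1e-9)
  # Beta 0.8 realized as 80/20 gives M = 2
  expect_equal(unname(m_values(matrix(80), matrix(20), offset = 0)[1, 1]),
               2, tolerance = 1e-12)
  # beta boundaries
  expect_equal(beta_values(matrix(100), matrix(0), offset = 0)[1, 1], 1)
  expect_equal(beta_values(matrix(70), matrix(70), offset = 0)[1, 1], 0.5)
})

test_that("normalizing permuted samples yields permuted M-values", {
  set.seed(31)
  m0 <- named_matrix(runif(60, 100, 4000), 30, c("A", "B"))
  u0 <- named_matrix(runif(60, 100, 4000), 30, c("A", "B"))
  perm <- sample(30)
  meth <- cbind(m0, C = m0[perm, "A"])
  unmeth <- cbind(u0, C = u0[perm, "A"])
  qn <- quantile_normalize(meth, unmeth)
  mv <- m_values(qn$meth, qn$unmeth)
  expect_equal(unname(mv[perm, "A"]), unname(mv[, "C"]), tolerance = 1e-12)
})

test_that("dye-bias diagnostics report quantiles, counts and bias score", {
  ds <- simulate_dataset(tiny_spec(n_probes = 20))
  dye <- dye_bias_diagnostics(ds, cutoffs = c(200, 1000))
  expect_setequal(unique(dye$summary$channel), c("green", "red"))
  qcols <- grep("^q", names(dye$summary), value = TRUE)
  qs <- as.matrix(dye$summary[, qcols])
  expect_true(all(apply(qs, 1, function(r) all(diff(r) >= 0))))

  # direct formula recomputation per sample
  for (s in ds$betas$samples[c(1, 13)]) {
    sig <- ds$controls[ds$controls$sample_id == s, ]
    expected <- abs(median(sig$signal[sig$channel == "green"]) -
                    median(sig$signal[sig$channel == "red"])) /
      median(sig$signal)
    expect_equal(dye$bias$bias_score[dye$bias$sample_id == s], expected,
                 tolerance = 1e-12)
  }

  # symmetric channels give zero bias; doubling green gives the formula value
  ctl <- make_controls(c("S1"), tibble::tibble(
    category = "negative", subcategory = NA_character_,
    channel = c("green", "green", "red", "red"),
    signal = list(100, 300, 100, 300)))
  ds_sym <- make_dataset(beta = named_matrix(0.5, 2, "S1"), controls = ctl)
  expect_equal(dye_bias_diagnostics(ds_sym)$bias$bias_score, 0)
  ctl2 <- ctl
  ctl2$signal[ctl2$channel == "green"] <- c(200, 600)
  ds_2x <- make_dataset(beta = named_matrix(0.5, 2, "S1"), controls = ctl2)
  expect_equal(dye_bias_diagnostics(ds_2x)$bias$bias_score,
               abs(400 - 200) / median(c(200, 600, 100, 300)))

  # stated interpolation rule: quantiles of {1,2,3,4} at {0, .5, 1}
  ctl3 <- make_controls("S1", tibble::tibble(
    category = "negative", subcategory = NA_character_,
    channel = c("green", "green", "green", "green", "red"),
    signal = list(1, 2, 3, 4, 1)))
  ds3 <- make_dataset(beta = named_matrix(0.5, 2, "S1"), controls = ctl3)
  d3 <- dye_bias_diagnostics(ds3, probs = c(0, 0.5, 1))
  grn <- d3$summary[d3$summary$channel == "green", ]
  expect_equal(unname(unlist(grn[, c("q00", "q50", "q100")])), c(1, 2.5, 4))
})
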