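test_that("mirror_baf folds onto [0.5, 1] symmetrically", {
  expect_equal(mirror_baf(0.5), 0.5)
  expect_equal(mirror_baf(0.2), 0.8)
  set.seed(101)
  b <- runif(200)
  expect_equal(mirror_baf(b), mirror_baf(1 - b))
  expect_true(all(mirror_baf(b) >= 0.5 & mirror_baf(b) <= 1))
  expect_error(mirror_baf(1.2), "\\[0, 1\\]")
})

test_that("segments classify as neutral / gain / loss / cnn by thresholds", {
  expect_equal(call_imbalance(0.52, 0.30), "neutral")
  expect_equal(call_imbalance(0.70, 0.20), "gain")
  expect_equal(call_imbalance(0.70, -0.30), "loss")
  expect_equal(call_imbalance(0.70, 0.00), "cnn_imbalance")
  # boundaries: the gain cutoff is strict
  expect_equal(call_imbalance(0.70, 0.073), "cnn_imbalance")
  # the printed positive loss cutoff remains available via configuration
  lit <- clonality_thresholds(log2_loss = 0.080, log2_gain = 0.081)
  expect_equal(call_imbalance(0.70, 0.02, lit), "loss")
})

test_that("segment fusion merges close, similar neighbours re-testingly", {
  segs <- baf_segments(data.frame(
    chromosome = "3",
    start = c(1e6, 20.5e6, 42.5e6),
    end   = c(20e6, 42e6, 60e6),
    mbaf = c(0.70, 0.66, 0.62),
    mbaf_min = c(0.68, 0.64, 0.60),
    mbaf_max = c(0.72, 0.69, 0.64),
    log2ratio = c(0.2, 0.2, 0.2),
    n_markers = c(100L, 300L, 100L)))
  # gaps are 0.5 Mb and successive mBAF differences 0.04: the first merge
  # (weighted mBAF 0.67) re-tests against the third and merges again
  fused <- fuse_segments(segs)
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$n_markers, 500L)
  expect_equal(fused$mbaf_min, 0.60)
  expect_equal(fused$mbaf_max, 0.72)
  expect_equal(fused$mbaf,
               weighted.mean(c(weighted.mean(c(0.70, 0.66), c(100, 300)),
                               0.62), c(400, 100)))
  expect_equal(fused$start, 1e6)
  expect_equal(fused$end, 60e6)

  # a 2 Mb gap or a 0.15 mBAF difference blocks fusion
  far <- segs; far$start[2] <- 22e6  # 2 Mb gap after the first segment
  expect_equal(nrow(fuse_segments(far)), 2L)  # 2nd+3rd still fuse
  diff <- segs; diff$mbaf[2] <- 0.85; diff$mbaf_max[2] <- 0.88
  expect_equal(nrow(fuse_segments(diff)), 3L)
})

test_that("fusion never increases segment count and conserves markers", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    # inter-segment gaps of 0.2/0.5/1.5/4 Mb: some fusable, some not
    starts <- 1e6 + cumsum(sample(c(8.2e6, 8.5e6, 9.5e6, 1.2e7), n,
                                  replace = TRUE))
    m <- pmin(0.99, 0.5 + abs(rnorm(n, 0.1, 0.08)))
    segs <- baf_segments(data.frame(
      chromosome = sample(c("1", "2"), n, replace = TRUE),
      start = starts, end = starts + 8e6,
      mbaf = m, mbaf_min = m - 0.01, mbaf_max = m + 0.005,
      log2ratio = rnorm(n, 0, 0.2),
      n_markers = sample(50:500, n, replace = TRUE)))
    fused <- fuse_segments(segs)
    expect_lte(nrow(fused), nrow(segs))
    expect_equal(sum(fused$n_markers), sum(segs$n_markers))
  }
})

test_that("expected mBAF follows the allele-mixture model", {
  expect_equal(expected_mbaf(c(1, 0), 0), 0.5)
  expect_equal(expected_mbaf(c(3, 1), 0), 0.5)
  expect_equal(expected_mbaf(c(1, 0), 1), 1.0)
  expect_equal(expected_mbaf(c(2, 1), 0.5), 0.6)  # (1+0.5)/(2+0.5)
  # strictly increasing in f for unbalanced genotypes
  f <- seq(0, 1, by = 0.05)
  for (g in list(c(1, 0), c(2, 1), c(2, 0), c(3, 1))) {
    m <- expected_mbaf(g, f)
    expect_true(all(diff(m) > 0))
    expect_true(all(m >= 0.5 & m <= 1))
  }
  # balanced genotypes stay at 0.5
  expect_equal(expected_mbaf(c(2, 2), 0.7), 0.5)
  expect_error(expected_mbaf(c(0, 0), 1), "no DNA")
  expect_error(expected_mbaf(c(1, 2), 0.5), "nA >= nB")
})

test_that("AC estimation inverts the mixture model exactly", {
  # closed-form anchors at the 0.56 calling threshold
  expect_equal(estimate_ac(0.56, call_type = "loss")$ac_mean, 2 - 1 / 0.56,
               tolerance = 1e-12)
  expect_equal(estimate_ac(0.56, call_type = "gain")$ac_mean,
               (2 * 0.56 - 1) / (1 - 0.56), tolerance = 1e-12)

  # estimate_ac(expected_mbaf(g, f)) == f to 1e-9 above the detection limit
  cases <- list(loss = seq(0.25, 1, by = 0.025),
                gain = seq(0.28, 1, by = 0.025),
                cnn_imbalance = seq(0.15, 1, by = 0.025))
  for (ct in names(cases)) {
    for (f in cases[[ct]]) {
      m <- expected_mbaf(.karyolute_genotype(ct), f)
      expect_equal(estimate_ac(m, call_type = ct)$ac_mean, f,
                   tolerance = 1e-9)
    }
  }

  # min/max mBAF produce the confidence interval, clipped to [0, 1]
  est <- estimate_ac(0.70, 0.58, 0.99, call_type = "loss")
  expect_lte(est$ac_min, est$ac_mean)
  expect_lte(est$ac_mean, est$ac_max)
  expect_lte(est$ac_max, 1)

  # refusals: below the calling threshold, and amplified genotypes
  expect_error(estimate_ac(0.555, call_type = "loss"), "not quantifiable")
  expect_error(estimate_ac(0.9, genotype = c(4, 2)), "[Aa]mplified")
})

test_that("AC inversion works on a tetraploid background", {
  for (ct in c("loss", "gain")) {
    for (f in seq(0.4, 1, by = 0.1)) {
      g <- .karyolute_genotype(ct, background = 4)
      m <- expected_mbaf(g, f, background_ploidy = 4)
      if (m < 0.56) next
      est <- estimate_ac(m, call_type = ct, background_ploidy = 4)
      expect_equal(est$ac_mean, f, tolerance = 1e-9)
    }
  }
})

test_that("detection limits match the analytic inversions and are monotone", {
  expect_equal(detection_limit("loss", 0.56), 3 / 14, tolerance = 1e-12)
  expect_equal(detection_limit("gain", 0.56), 3 / 11, tolerance = 1e-12)
  expect_lt(detection_limit("loss", 0.5001), 1e-3)
  th <- seq(0.52, 0.9, by = 0.02)
  for (ct in c("loss", "gain", "cnn_imbalance"))
    expect_true(all(diff(vapply(th, function(t)
      detection_limit(ct, t), numeric(1))) > 0))
})

test_that("case summaries compute prevalence spans per class", {
  one <- data.frame(ac_mean = 0.8, ac_min = 0.75, ac_max = 0.85,
                    aberration_class = "numerical")
  s1 <- summarize_case(one, "solo")
  expect_equal(s1$span_total, 0)
  expect_equal(s1$span_numerical, 0)
  expect_true(is.na(s1$span_structural))

  calls <- data.frame(
    ac_mean = c(0.80, 0.60, 0.35),
    ac_min = c(0.78, 0.55, 0.30), ac_max = c(0.85, 0.65, 0.40),
    aberration_class = c("numerical", "numerical", "structural"))
  s <- summarize_case(calls, "trio")
  expect_equal(s$span_total, 45)
  expect_equal(s$span_numerical, 20)
  expect_equal(s$span_structural, 0)
  expect_lte(s$span_numerical, s$span_total)
  expect_lte(s$span_structural, s$span_total)
})

test_that("majority-clone membership uses band overlap", {
  calls <- data.frame(
    ac_mean = c(0.80, 0.78, 0.75, 0.30),
    ac_min = c(0.76, 0.74, 0.72, 0.25),
    ac_max = c(0.84, 0.82, 0.78, 0.35),
    aberration_class = c("numerical", "numerical", "numerical",
                         "structural"))
  cons <- majority_clone_consistency(calls)
  expect_equal(unname(cons["numerical"]), 1)
  expect_equal(unname(cons["structural"]), 0)
  expect_equal(unname(cons["overall"]), 0.75)
})

test_that("the call pipeline quantifies aberrant segments end to end", {
  segs <- toy_segments()
  calls <- call_segments(segs, aberration_class = c("structural",
                                                    "numerical",
                                                    "numerical"))
  # third segment (mBAF 0.55) is neutral and absent
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$call_type, c("loss", "gain"))
  expect_equal(calls$ac_mean[1],
               estimate_ac(0.82, call_type = "loss")$ac_mean)
})
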