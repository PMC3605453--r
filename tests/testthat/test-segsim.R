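test_that("model construction enforces start-ploidy constraints", {
  expect_error(segregation_model("loss_tetraploid", "diploid"),
               "tetraploid")
  m <- segregation_model("seq_nondisjunction")
  expect_equal(m$start_ploidy, "diploid")
  expect_equal(segregation_model("tripolar_random",
                                 "tetraploid")$start_ploidy, "tetraploid")
})

test_that("forced-outcome targets give deterministic profiles", {
  loss <- segregation_model("loss_tetraploid")
  s92 <- evolve_to_target(loss, 92, sim_config(500, seed = 1))
  expect_true(all(s92$copies == 4L))
  expect_equal(expected_prevalence(cn_profile(counts = c(`4` = 23)), s92),
               1)
  s91 <- evolve_to_target(loss, 91, sim_config(500, seed = 1))
  expect_equal(expected_prevalence(
    cn_profile(counts = c(`3` = 1, `4` = 22)), s91), 1)
  expect_error(evolve_to_target(loss, 93, sim_config(10)), "above")
  expect_error(evolve_to_target(loss, 20, sim_config(10)), "nullisomy")
})

test_that("two chromatid losses hit the same chromosome with P = 3/91", {
  s90 <- evolve_to_target(segregation_model("loss_tetraploid"), 90,
                          sim_config(20000, seed = 42))
  p_same <- expected_prevalence(cn_profile(counts = c(`2` = 1, `4` = 22)),
                                s90)
  expect_lt(abs(p_same - 3 / 91), 4 * mc_se(3 / 91, 20000))
  p_diff <- expected_prevalence(cn_profile(counts = c(`3` = 2, `4` = 21)),
                                s90)
  expect_equal(p_same + p_diff, 1)
})

test_that("simulated prevalence matches exhaustive enumeration (<=3 losses)", {
  loss <- segregation_model("loss_tetraploid")
  for (k in 2:3) {
    oracle <- enum_loss_profiles(k)
    sims <- evolve_to_target(loss, 92 - k, sim_config(20000, seed = k))
    for (key in names(oracle)) {
      counts <- strsplit(sub("^23\\|", "", key), ",")[[1]]
      kv <- do.call(rbind, strsplit(counts, ":"))
      prof <- cn_profile(counts = stats::setNames(as.integer(kv[, 2]),
                                                  kv[, 1]))
      p_hat <- expected_prevalence(prof, sims)
      expect_lt(abs(p_hat - oracle[[key]]),
                4 * mc_se(oracle[[key]], 20000) + 1e-9)
    }
  }
})

test_that("every emitted profile hits the target with no nullisomy", {
  models <- list(
    segregation_model("loss_tetraploid"),
    segregation_model("seq_nondisjunction"),
    segregation_model("seq_nondisjunction", "tetraploid"),
    segregation_model("tripolar_random", "tetraploid"),
    segregation_model("tripolar_cytofail", "tetraploid"))
  targets <- list(c(55, 70, 88), c(50, 60, 75), c(70, 85), c(58, 64),
                  c(55, 64, 70))
  for (i in seq_along(models)) {
    for (tN in targets[[i]]) {
      s <- evolve_to_target(models[[i]], tN, sim_config(300, seed = i))
      expect_true(all(rowSums(s$copies) == tN))
      expect_true(all(s$copies >= 1L))
    }
  }
  # monosomy selection removes all monosomies from the finished set
  s <- evolve_to_target(segregation_model("loss_tetraploid"), 60,
                        sim_config(2000, monosomy_selection = TRUE,
                                   seed = 9))
  expect_true(all(s$copies >= 2L))
})

test_that("downward non-disjunction follows the monosomic daughter", {
  s <- evolve_to_target(segregation_model("seq_nondisjunction",
                                          "tetraploid"), 85,
                        sim_config(300, seed = 3))
  expect_true(all(rowSums(s$copies) == 85))
  expect_true(all(s$copies <= 4L))
})

test_that("cytokinetic-failure daughters carry only gains or only losses", {
  gains <- evolve_to_target(segregation_model("tripolar_cytofail"), 55,
                            sim_config(300, seed = 5))
  expect_true(all(gains$copies >= 2L))   # gains daughter from diploid
  expect_true(all(gains$copies <= 4L))   # at most double per chromosome
  losses <- evolve_to_target(segregation_model("tripolar_cytofail",
                                               "tetraploid"), 72,
                             sim_config(300, seed = 5))
  expect_true(all(losses$copies <= 4L))
})

test_that("seeded runs are bit-reproducible", {
  for (kind in c("loss_tetraploid", "tripolar_cytofail")) {
    m <- segregation_model(kind, "tetraploid")
    a <- evolve_to_target(m, 70, sim_config(500, seed = 77))
    b <- evolve_to_target(m, 70, sim_config(500, seed = 77))
    expect_identical(a$copies, b$copies)
  }
})

test_that("expected_prevalence validates its inputs", {
  s <- evolve_to_target(segregation_model("loss_tetraploid"), 91,
                        sim_config(100, seed = 1))
  expect_error(expected_prevalence(cn_profile(copies = rep(4, 23)), s),
               "mismatch")
  empty <- s
  empty$copies <- s$copies[0, , drop = FALSE]
  expect_error(expected_prevalence(
    cn_profile(counts = c(`3` = 1, `4` = 22)), empty), "empty")
})

test_that("pooled class distributions are frequency-normalised", {
  expect_equal(pooled_cn_distribution(cn_profile(copies = rep(2, 23))),
               c(`2` = 1))
  two <- list(cn_profile(copies = rep(2, 23)),
              cn_profile(copies = rep(3, 23)))
  expect_equal(pooled_cn_distribution(two), c(`2` = 0.5, `3` = 0.5))
  # pooling equals the chromosome-type weighted mean of per-case
  # distributions
  mix <- list(cn_profile(counts = c(`1` = 1, `2` = 19, `3` = 2, `4` = 1)),
              cn_profile(copies = rep(4, 23)))
  pooled <- pooled_cn_distribution(mix)
  manual <- (c(`1` = 1, `2` = 19, `3` = 2, `4` = 1) +
               c(`1` = 0, `2` = 0, `3` = 0, `4` = 23)) / 46
  expect_equal(pooled, manual[manual > 0])
})

test_that("chi-square comparison matches the Pearson formula and pools", {
  # observed proportional to expected: statistic 0, p 1
  r0 <- chisq_compare(c(`2` = 10, `3` = 10), c(`2` = 0.5, `3` = 0.5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # 4-category case against the hand-computed statistic and chisq.test
  obs <- c(`1` = 12, `2` = 30, `3` = 40, `4` = 18)
  ef <- c(`1` = 0.1, `2` = 0.3, `3` = 0.4, `4` = 0.2)
  r <- chisq_compare(obs, ef)
  hand <- sum((obs - 100 * ef)^2 / (100 * ef))
  expect_equal(r$statistic, hand)
  expect_equal(r$df, 3L)
  ct <- suppressWarnings(stats::chisq.test(obs, p = ef))
  expect_equal(r$statistic, unname(ct$statistic))
  expect_equal(r$p_value, ct$p.value)

  # sparse classes pool into the adjacent class, reducing df
  obs2 <- c(`1` = 2, `2` = 50, `3` = 48)
  ef2 <- c(`1` = 0.02, `2` = 0.49, `3` = 0.49)
  r2 <- chisq_compare(obs2, ef2)
  expect_equal(r2$df, 1L)
  expect_equal(sum(r2$table$observed), 100)

  expect_error(chisq_compare(c(`2` = 0, `3` = 0), c(`2` = 0.5, `3` = 0.5)),
               "zero")
})

test_that("cohort evaluation aggregates cases and flags unreachable ones", {
  rec <- karyotype_record("one", cn_profile(counts = c(`3` = 1, `4` = 22)))
  r <- run_cohort_evaluation(list(rec), segregation_model("loss_tetraploid"),
                             sim_config(200, seed = 1))
  expect_equal(r$mean_prevalence, 1)
  expect_equal(r$n_evaluated, 1L)
  expect_equal(r$chisq$statistic, 0)

  # an unreachable tripolar target becomes a flagged row, not an abort
  far <- karyotype_record("far", cn_profile(copies = rep(4, 23)))
  r2 <- run_cohort_evaluation(
    list(rec, far), segregation_model("tripolar_random", "tetraploid"),
    sim_config(200, seed = 1, max_attempts = 2L))
  expect_equal(sum(is.na(r2$per_case$expected_prevalence)), 2L)
  expect_match(r2$per_case$note[r2$per_case$case_id == "far"],
               "unreachable")
})
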