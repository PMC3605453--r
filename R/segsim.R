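#' A mitotic segregation-error model
#'
#' Four stochastic models of how a balanced pre-neoplastic cell can evolve
#' an aneuploid stem line, each driven by one error type:
#'
#' * `loss_tetraploid` — sequential random loss of single chromatids from a
#'   tetraploid complement. Each loss removes one chromatid drawn uniformly
#'   over all chromatids (i.e. proportional to current copy number).
#' * `seq_nondisjunction` — sequential sister-chromatid non-disjunction:
#'   each step one chromosome type (uniform) gains or loses one copy, the
#'   followed daughter being the one moving towards the target chromosome
#'   number.
#' * `tripolar_random` — a single tripolar mitosis with failed sister
#'   separation: after replication every chromatid is assigned to one of
#'   three poles with equal probability, and one daughter is followed.
#'   Divisions are re-run (rejection) until the daughter hits the target.
#' * `tripolar_cytofail` — a single tripolar mitosis with amphitelic
#'   segregation and cytokinetic failure between two poles: per chromosome
#'   copy, the sister pair goes to one of the three pole pairs uniformly,
#'   and the two fused poles form a daughter with gains while the third
#'   collects the losses; one of the two daughters is followed, re-running
#'   the division until the target is hit.
#'
#' @param kind model kind (see above)
#' @param start_ploidy `"diploid"` or `"tetraploid"`; `loss_tetraploid`
#'   requires a tetraploid start
#' @return an object of class `segregation_model`
#' @export
segregation_model <- function(kind = c("loss_tetraploid",
                                       "seq_nondisjunction",
                                       "tripolar_random",
                                       "tripolar_cytofail"),
                              start_ploidy = NULL) {
  kind <- match.arg(kind)
  if (is.null(start_ploidy))
    start_ploidy <- if (kind == "loss_tetraploid") "tetraploid" else "diploid"
  start_ploidy <- match.arg(start_ploidy, c("diploid", "tetraploid"))
  if (kind == "loss_tetraploid" && start_ploidy != "tetraploid")
    stop("loss_tetraploid starts from a tetraploid complement")
  structure(list(kind = kind, start_ploidy = start_ploidy),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat(sprintf("<segregation_model %s from %s>\n", x$kind, x$start_ploidy))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_virtual number of virtual tumours per case (study default 10000)
#' @param monosomy_selection replace finished tumours carrying a monosomy by
#'   resampling from the monosomy-free members of the set (models negative
#'   selection against monosomic cells)
#' @param seed optional integer seed; runs are bit-reproducible
#' @param n_types chromosome types per genome
#' @param max_attempts rejection-sampling budget (batches) for the tripolar
#'   models before a target is declared unreachable
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_virtual = 10000L, monosomy_selection = FALSE,
                       seed = NULL, n_types = 23L, max_attempts = 200L) {
  stopifnot(n_virtual >= 1L, n_types >= 1L, max_attempts >= 1L)
  structure(list(n_virtual = as.integer(n_virtual),
                 monosomy_selection = isTRUE(monosomy_selection),
                 seed = seed, n_types = as.integer(n_types),
                 max_attempts = as.integer(max_attempts)),
            class = "sim_config")
}

start_copies <- function(model) {
  if (model$start_ploidy == "tetraploid") 4L else 2L
}

#' Evolve virtual tumours to a target chromosome number
#'
#' Expands `config$n_virtual` balanced virtual cells under a segregation
#' error model until each reaches exactly `targetN` chromosomes. Cells that
#' acquire a nullisomy during evolution are eliminated and replaced by
#' random sampling from the remaining population; with
#' `config$monosomy_selection`, finished tumours carrying a monosomy are
#' likewise replaced from the monosomy-free remainder.
#'
#' @param model a [segregation_model()]
#' @param targetN target total chromosome number (must be reachable: at most
#'   the start chromosome number for the loss model, at least `n_types` for
#'   all models since nullisomies are non-viable)
#' @param config a [sim_config()]
#' @return an object of class `cn_profile_set`: a list with `copies`
#'   (`n_virtual` x `n_types` integer matrix), `model` and `targetN`
#' @examples
#' s <- evolve_to_target(segregation_model("loss_tetraploid"), 91,
#'                       sim_config(100, seed = 1))
#' table(apply(s$copies, 1, min))  # every tumour is 4:22 + 3:1
#' @export
evolve_to_target <- function(model, targetN, config = sim_config()) {
  stopifnot(inherits(model, "segregation_model"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nt <- config$n_types
  b <- start_copies(model)
  startN <- b * nt
  targetN <- as.integer(targetN)
  if (targetN < nt)
    stop("targetN ", targetN, " implies a nullisomy (fewer chromosomes ",
         "than chromosome types)")
  copies <- switch(
    model$kind,
    loss_tetraploid = {
      if (targetN > startN)
        stop("loss model cannot reach targetN ", targetN, " above the ",
             "tetraploid count ", startN)
      sim_loss(config$n_virtual, nt, b, startN - targetN)
    },
    seq_nondisjunction = sim_seq_nondisjunction(
      config$n_virtual, nt, b, targetN - startN),
    tripolar_random = sim_tripolar(
      config$n_virtual, nt, b, targetN, config$max_attempts,
      randomized = TRUE),
    tripolar_cytofail = sim_tripolar(
      config$n_virtual, nt, b, targetN, config$max_attempts,
      randomized = FALSE)
  )
  copies <- replace_nonviable(copies, apply(copies, 1L, min) == 0L,
                              "nullisomy")
  if (config$monosomy_selection)
    copies <- replace_nonviable(copies, apply(copies, 1L, min) == 1L,
                                "monosomy")
  structure(list(copies = copies, model = model, targetN = targetN),
            class = "cn_profile_set")
}

# replace flagged rows by sampling (with replacement) from the remainder
replace_nonviable <- function(copies, bad, what) {
  if (!any(bad)) return(copies)
  if (all(bad))
    stop("every virtual tumour carries a ", what,
         ": replacement pool is empty")
  good <- which(!bad)
  copies[bad, ] <- copies[good[sample.int(length(good), sum(bad),
                                          replace = TRUE)], , drop = FALSE]
  copies
}

# Sequential chromatid loss, one uniformly chosen chromatid at a time, is
# distributionally a uniform draw of k chromatids without replacement
# (multivariate hypergeometric over chromosome types).
sim_loss <- function(n, nt, b, k) {
  startN <- b * nt
  stopifnot(k >= 0L, k <= startN - nt)
  copies <- matrix(b, nrow = n, ncol = nt)
  if (k == 0L) return(copies)
  for (i in seq_len(n)) {
    idx <- sample.int(startN, k)
    copies[i, ] <- b - tabulate((idx - 1L) %/% b + 1L, nt)
  }
  copies
}

# each step: uniform chromosome type, one copy towards the target
sim_seq_nondisjunction <- function(n, nt, b, delta) {
  k <- abs(delta)
  s <- sign(delta)
  if (k == 0L) return(matrix(b, nrow = n, ncol = nt))
  m <- stats::rmultinom(n, k, rep(1, nt))  # nt x n
  copies <- t(b + s * m)
  # downward runs can overshoot to negative counts in rejected cells only;
  # clamp so the nullisomy replacement sees them as nullisomic
  if (s < 0L) copies[copies < 0L] <- 0L
  copies
}

# single tripolar division, rejection-sampled until N == targetN
sim_tripolar <- function(n, nt, b, targetN, max_attempts, randomized) {
  acc <- matrix(0L, nrow = 0L, ncol = nt)
  batch <- max(n, 2000L)
  for (attempt in seq_len(max_attempts)) {
    if (randomized) {
      # 2b chromatids per chromosome, multinomial over 3 poles; followed
      # daughter uniform == pole 1 by symmetry
      draw <- matrix(stats::rbinom(batch * nt, 2L * b, 1 / 3),
                     nrow = batch, ncol = nt)
    } else {
      # amphitelic: per copy the sister pair hits pole pair AB, AC or BC
      # uniformly; cytokinesis fails between A and B. The fused daughter
      # gains Binomial(b, 1/3) copies, the third pole loses as many; the
      # followed daughter is drawn uniformly.
      x <- matrix(stats::rbinom(batch * nt, b, 1 / 3),
                  nrow = batch, ncol = nt)
      side <- sample(c(-1L, 1L), batch, replace = TRUE)
      draw <- b + side * x
    }
    ok <- rowSums(draw) == targetN & apply(draw, 1L, min) >= 1L
    if (any(ok)) acc <- rbind(acc, draw[ok, , drop = FALSE])
    if (nrow(acc) >= n) return(acc[seq_len(n), , drop = FALSE])
  }
  stop("tripolar model did not reach targetN ", targetN, " within ",
       max_attempts, " attempts: target unreachable in a single division")
}

#' Expected prevalence of an observed copy-number profile
#'
#' The fraction of simulated virtual tumours whose copy-number profile
#' (counts of chromosome types per copy-number class; chromosome identity
#' ignored) equals the observed profile. Both must have the same total
#' chromosome number.
#'
#' @param observed a [cn_profile()] or [karyotype_record()]
#' @param simulated a `cn_profile_set` from [evolve_to_target()]
#' @return a fraction in `[0, 1]`
#' @export
expected_prevalence <- function(observed, simulated) {
  if (inherits(observed, "karyotype_record")) observed <- observed$profile
  stopifnot(inherits(observed, "cn_profile"),
            inherits(simulated, "cn_profile_set"))
  if (!nrow(simulated$copies)) stop("empty simulation set")
  if (observed$N != simulated$targetN)
    stop("chromosome number mismatch: observed N = ", observed$N,
         ", simulated targetN = ", simulated$targetN)
  key <- profile_key(observed)
  keys <- apply(simulated$copies, 1L, copies_key)
  mean(keys == key)
}

#' Pooled copy-number class distribution
#'
#' Relative frequencies of copy-number classes pooled over all chromosome
#' types of all profiles (simulated tumours or cohort records).
#'
#' @param x a `cn_profile_set`, a list of [cn_profile()]s /
#'   [karyotype_record()]s, or a single profile
#' @return named numeric vector of class frequencies summing to 1
#' @export
pooled_cn_distribution <- function(x) {
  counts <- pooled_cn_counts(x)
  counts / sum(counts)
}

pooled_cn_counts <- function(x) {
  if (inherits(x, "cn_profile_set")) {
    tab <- tabulate(x$copies + 1L)
    return(stats::setNames(tab, seq_along(tab) - 1L)[tab > 0])
  }
  if (inherits(x, c("cn_profile", "karyotype_record"))) x <- list(x)
  if (!length(x)) stop("nothing to pool")
  acc <- numeric(0)
  for (p in x) {
    if (inherits(p, "karyotype_record")) p <- p$profile
    stopifnot(inherits(p, "cn_profile"))
    for (cl in names(p$counts))
      acc[cl] <- (if (cl %in% names(acc)) acc[cl] else 0) + p$counts[cl]
  }
  acc[order(as.integer(names(acc)))]
}

#' Chi-square comparison of copy-number class distributions
#'
#' Pearson goodness-of-fit of observed class counts against expected class
#' frequencies, with classes whose expected count falls below
#' `min_expected` pooled into the adjacent class (degrees of freedom
#' reduced accordingly).
#'
#' @param observed_counts named integer vector of observed counts per
#'   copy-number class
#' @param expected_freqs named numeric vector of expected class frequencies
#'   (renormalised to sum to 1 after alignment)
#' @param min_expected pooling threshold for sparse classes
#' @return list: `statistic`, `df`, `p_value`, and the pooled
#'   observed/expected `table`
#' @export
chisq_compare <- function(observed_counts, expected_freqs,
                          min_expected = 5) {
  if (sum(observed_counts) == 0) stop("all observed counts are zero")
  cls <- sort(unique(as.integer(c(names(observed_counts),
                                  names(expected_freqs)))))
  key <- as.character(cls)
  o <- stats::setNames(rep(0, length(cls)), key)
  e <- o
  o[names(observed_counts)] <- observed_counts
  e[names(expected_freqs)] <- expected_freqs
  e <- e / sum(e)
  n <- sum(o)
  labels <- key
  # pool sparse classes into the adjacent class with the larger expectation
  repeat {
    exp_counts <- e * n
    if (length(e) <= 1L || all(exp_counts >= min_expected)) break
    i <- which(exp_counts < min_expected)[1L]
    j <- if (i == 1L) 2L
         else if (i == length(e)) i - 1L
         else if (exp_counts[i - 1L] >= exp_counts[i + 1L]) i - 1L
         else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    labels[lo] <- paste(labels[lo], labels[hi], sep = "+")
    o[lo] <- o[lo] + o[hi]; e[lo] <- e[lo] + e[hi]
    labels <- labels[-hi]; o <- o[-hi]; e <- e[-hi]
  }
  exp_counts <- e * n
  stat <- sum((o - exp_counts)^2 / exp_counts)
  df <- length(o) - 1L
  list(statistic = stat, df = df,
       p_value = if (df >= 1L)
         stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_,
       table = data.frame(class = labels, observed = as.numeric(o),
                          expected = as.numeric(exp_counts)))
}

#' Evaluate a cohort against a segregation-error model
#'
#' For every karyotype record, simulates `config$n_virtual` virtual tumours
#' at the case's chromosome number under `model`, computes the expected
#' prevalence of the case's copy-number profile, pools the simulated class
#' distribution over all cases, and compares it with the observed pooled
#' distribution by chi-square. Cases whose target is unreachable under the
#' model are returned as flagged rows with `NA` prevalence rather than
#' aborting the run.
#'
#' @param cohort list of [karyotype_record()]s
#' @param model a [segregation_model()]
#' @param config a [sim_config()]
#' @param by_subtype also compute mean prevalence per clinical-genetic
#'   subtype
#' @details A model that cannot reach a case's chromosome number assigns
#'   zero probability to that case, so flagged cases enter
#'   `mean_prevalence` as 0; `per_case` keeps them as `NA` with the reason,
#'   and `n_evaluated` counts the cases actually simulated.
#' @return list: `per_case` data frame (case_id, subtype, N,
#'   expected_prevalence, note), `mean_prevalence` (unreachable cases
#'   counted as prevalence 0), `n_evaluated`, `pooled_observed`,
#'   `pooled_expected`, `chisq`, and optionally `by_subtype`
#' @export
run_cohort_evaluation <- function(cohort, model, config = sim_config(),
                                  by_subtype = FALSE) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, TRUE, "karyotype_record")))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # one stream for the whole cohort
  exp_counts <- numeric(0)
  rows <- lapply(cohort, function(rec) {
    res <- tryCatch({
      sims <- evolve_to_target(model, rec$profile$N, cfg)
      cnt <- pooled_cn_counts(sims)
      for (cl in names(cnt))
        exp_counts[cl] <<- (if (cl %in% names(exp_counts))
          exp_counts[cl] else 0) + cnt[cl]
      list(prev = expected_prevalence(rec$profile, sims), note = "")
    }, error = function(e) list(prev = NA_real_, note = conditionMessage(e)))
    data.frame(case_id = rec$case_id, subtype = rec$subtype,
               N = rec$profile$N, expected_prevalence = res$prev,
               note = res$note, stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  obs <- pooled_cn_counts(cohort)
  prev0 <- per_case$expected_prevalence
  prev0[is.na(prev0)] <- 0  # unreachable: the model predicts the case never
  out <- list(
    per_case = per_case,
    mean_prevalence = mean(prev0),
    n_evaluated = sum(!is.na(per_case$expected_prevalence)),
    pooled_observed = obs,
    pooled_expected = if (length(exp_counts))
      exp_counts[order(as.integer(names(exp_counts)))] / sum(exp_counts)
      else NULL)
  out$chisq <- if (!is.null(out$pooled_expected))
    chisq_compare(obs, out$pooled_expected) else NULL
  if (by_subtype)
    out$by_subtype <- vapply(split(prev0, per_case$subtype), mean,
                             numeric(1))
  out
}
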