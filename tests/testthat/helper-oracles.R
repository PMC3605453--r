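# Independent oracles, deliberately implemented by a different route than
# the package internals.

# Exhaustive enumeration of the chromatid-loss process: every ordered loss
# sequence of length k, each step removing one chromatid with probability
# proportional to the current copy number; paths reaching a nullisomy are
# eliminated. Returns probabilities per profile key, conditioned on survival.
enum_loss_profiles <- function(k, n_types = 23L, start = 4L) {
  acc <- new.env(parent = emptyenv())
  recurse <- function(copies, prob, steps) {
    if (any(copies == 0L)) return()
    if (steps == 0L) {
      key <- profile_key(cn_profile(copies = copies))
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return()
    }
    tot <- sum(copies)
    for (i in seq_len(n_types)) if (copies[i] > 0L) {
      c2 <- copies
      c2[i] <- c2[i] - 1L
      recurse(c2, prob * copies[i] / tot, steps - 1L)
    }
  }
  recurse(rep(start, n_types), 1, k)
  v <- unlist(as.list(acc))
  v / sum(v)
}

# default genotype models, restated independently of the package internals
.karyolute_genotype <- function(call_type, background = 2) {
  half <- background / 2
  switch(call_type,
         loss = c(half, half - 1),
         gain = c(half + 1, half),
         cnn_imbalance = c(half + 1, half - 1))
}

# Monte-Carlo standard error of an estimated proportion
mc_se <- function(p, n) sqrt(p * (1 - p) / n)

# a small well-formed segment table for IO tests
toy_segments <- function() {
  baf_segments(data.frame(
    chromosome = c("1", "1", "2"),
    start = c(1e6, 2.5e7, 5e6),
    end = c(2e7, 4e7, 3e7),
    mbaf = c(0.82, 0.60, 0.55),
    mbaf_min = c(0.80, 0.58, 0.53),
    mbaf_max = c(0.85, 0.63, 0.56),
    log2ratio = c(-0.32, 0.12, 0.01),
    n_markers = c(420L, 150L, 300L)))
}
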