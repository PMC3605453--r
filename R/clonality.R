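#' Mirror a B-allele frequency
#'
#' Folds a BAF onto `[0.5, 1]`: `max(baf, 1 - baf)`. A balanced heterozygous
#' locus gives 0.5; allelic imbalance pushes the value towards 1.
#'
#' @param baf numeric vector in `[0, 1]`
#' @return numeric vector in `[0.5, 1]`
#' @export
mirror_baf <- function(baf) {
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("BAF values must lie in [0, 1]")
  pmax(baf, 1 - baf)
}

#' Classification thresholds for segment calling
#'
#' Defaults: segments with mBAF above `mbaf_imbalance` (0.55) are in allelic
#' imbalance; among those, log2 ratio above `log2_gain` (0.073) is a genomic
#' gain, below `log2_loss` (-0.080) a loss, and in between a copy-number
#' neutral imbalance. Abnormality-content quantification additionally
#' requires mBAF at or above `mbaf_call` (0.56).
#'
#' @param mbaf_imbalance mBAF cutoff for calling allelic imbalance
#' @param mbaf_call mBAF threshold below which AC is not quantifiable
#' @param log2_gain,log2_loss log2-ratio cutoffs for gain / loss
#' @param max_copies genotypes with more total copies are refused
#'   (amplifications cannot be quantified from mBAF)
#' @return a list of thresholds
#' @export
clonality_thresholds <- function(mbaf_imbalance = 0.55, mbaf_call = 0.56,
                                 log2_gain = 0.073, log2_loss = -0.080,
                                 max_copies = 5L) {
  stopifnot(mbaf_imbalance >= 0.5, mbaf_call > 0.5,
            log2_loss < log2_gain)
  list(mbaf_imbalance = mbaf_imbalance, mbaf_call = mbaf_call,
       log2_gain = log2_gain, log2_loss = log2_loss,
       max_copies = as.integer(max_copies))
}

#' Call the imbalance type of a segment
#'
#' @param mbaf segment mirrored BAF (vectorised)
#' @param log2ratio segment log2 copy-number ratio (vectorised)
#' @param thresholds see [clonality_thresholds()]
#' @return character vector: `"neutral"`, `"gain"`, `"loss"` or
#'   `"cnn_imbalance"`
#' @examples
#' call_imbalance(0.70, 0.20)   # gain
#' call_imbalance(0.70, 0.00)   # cnn_imbalance
#' call_imbalance(0.52, 0.30)   # neutral (mBAF below imbalance cutoff)
#' @export
call_imbalance <- function(mbaf, log2ratio,
                           thresholds = clonality_thresholds()) {
  out <- rep("neutral", length(mbaf))
  imb <- mbaf > thresholds$mbaf_imbalance
  out[imb & log2ratio > thresholds$log2_gain] <- "gain"
  out[imb & log2ratio < thresholds$log2_loss] <- "loss"
  out[imb & log2ratio <= thresholds$log2_gain &
        log2ratio >= thresholds$log2_loss] <- "cnn_imbalance"
  out
}

#' Fuse adjacent segments
#'
#' Merges same-chromosome neighbours whose interspersed genomic distance is
#' below `max_gap` (1 Mb) and whose mBAF values differ by less than
#' `max_dmbaf` (0.1). Fusion runs left-to-right and re-tests after every
#' merge. The fused mBAF (and log2 ratio) is the marker-count-weighted mean,
#' falling back to length weighting when marker counts are absent; the
#' mBAF min/max are the union extrema and marker counts are summed.
#'
#' @param segments a segment data frame ([baf_segments()])
#' @param max_gap maximal distance (bp) between segments to fuse
#' @param max_dmbaf maximal absolute mBAF difference to fuse
#' @return a segment data frame with at most as many rows
#' @export
fuse_segments <- function(segments, max_gap = 1e6, max_dmbaf = 0.1) {
  segments <- baf_segments(segments)
  pieces <- split(segments, segments$chromosome)
  fused <- lapply(pieces, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    i <- 1L
    while (i < nrow(df)) {
      gap <- df$start[i + 1L] - df$end[i]
      if (gap < max_gap && abs(df$mbaf[i + 1L] - df$mbaf[i]) < max_dmbaf) {
        w <- df$n_markers[i:(i + 1L)]
        if (anyNA(w)) w <- df$end[i:(i + 1L)] - df$start[i:(i + 1L)] + 1
        w <- w / sum(w)
        df$mbaf[i] <- sum(w * df$mbaf[i:(i + 1L)])
        df$log2ratio[i] <- sum(w * df$log2ratio[i:(i + 1L)])
        df$mbaf_min[i] <- min(df$mbaf_min[i:(i + 1L)])
        df$mbaf_max[i] <- max(df$mbaf_max[i:(i + 1L)])
        df$end[i] <- max(df$end[i:(i + 1L)])
        df$n_markers[i] <- sum(df$n_markers[i:(i + 1L)])
        df <- df[-(i + 1L), , drop = FALSE]
        # stay on i: the merged segment may now fuse with the next one
      } else {
        i <- i + 1L
      }
    }
    df
  })
  out <- do.call(rbind, fused)
  rownames(out) <- NULL
  out
}

#' Expected mirrored BAF of an allele mixture
#'
#' The allele-mixture model behind abnormality-content estimation: a clone
#' carrying `genotype = c(nA, nB)` copies of the two parental alleles
#' (major allele first) makes up a fraction `f` of the sampled DNA, the
#' remainder being a balanced background of ploidy `background_ploidy`
#' (equal allele split). The expected segment mBAF is
#' \deqn{m(f) = \frac{f\,n_A + (1-f)\,\pi/2}{f\,(n_A+n_B) + (1-f)\,\pi}}
#' with \eqn{\pi} the background ploidy. It equals 0.5 at `f = 0` and is
#' strictly increasing in `f` for any unbalanced genotype.
#'
#' @param genotype integer pair `c(nA, nB)` with `nA >= nB >= 0`
#' @param f clone DNA fraction(s) in `[0, 1]` (vectorised)
#' @param background_ploidy total copies in the non-aberrant background
#'   (2 = diploid, 4 = tetraploid)
#' @return expected mBAF in `[0.5, 1]`
#' @examples
#' expected_mbaf(c(1, 0), 1)    # pure hemizygous deletion -> 1
#' expected_mbaf(c(2, 1), 0.5)  # half-clonal trisomy -> 0.6
#' @export
expected_mbaf <- function(genotype, f, background_ploidy = 2L) {
  check_genotype(genotype)
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  nA <- genotype[1L]; nB <- genotype[2L]; p <- background_ploidy
  tot <- f * (nA + nB) + (1 - f) * p
  if (any(tot == 0))
    stop("mixture contains no DNA (nA + nB = 0 at f = 1)")
  (f * nA + (1 - f) * p / 2) / tot
}

check_genotype <- function(genotype) {
  if (length(genotype) != 2L || any(genotype < 0) ||
      genotype[1L] < genotype[2L] ||
      any(genotype != as.integer(genotype)))
    stop("genotype must be an integer pair c(nA, nB) with nA >= nB >= 0")
  invisible(genotype)
}

# closed-form inverse of expected_mbaf in f; derived by solving the mixture
# equation for f. Specialises to f = 2 - 1/m (deletion), (2m-1)/(1-m)
# (single-copy gain) and 2m - 1 (CNN-LOH) on a diploid background.
invert_mbaf <- function(mbaf, genotype, background_ploidy = 2L) {
  nA <- genotype[1L]; nB <- genotype[2L]; p <- background_ploidy
  denom <- mbaf * (nA + nB - p) - nA + p / 2
  if (any(abs(denom) < .Machine$double.eps * 4))
    stop("genotype is indistinguishable from the background at this mBAF")
  (p / 2 - mbaf * p) / denom
}

.default_genotypes <- function(call_type, background_ploidy = 2L) {
  half <- background_ploidy / 2
  switch(call_type,
         loss = c(half, half - 1),
         gain = c(half + 1, half),
         cnn_imbalance = c(half + 1, half - 1),
         stop("no genotype model for call type '", call_type, "'"))
}

#' Estimate the abnormality content (AC) of a segment
#'
#' Inverts the allele-mixture model ([expected_mbaf()]) at the segment's
#' median, minimum and maximum mBAF to obtain the mean and confidence
#' interval of the fraction of sampled DNA carrying the aberration.
#' Default genotype models on a diploid background: loss `(1,0)`, gain
#' `(2,1)`, copy-number neutral imbalance `(2,0)`; on other background
#' ploidies the single-copy analogues are used. Estimates are clipped to
#' `[0, 1]`.
#'
#' Refuses segments whose mBAF is below the calling threshold (the
#' aberration is then not quantifiable) and genotypes with more than
#' `thresholds$max_copies` total copies (amplified sequences cannot be
#' quantified from allelic ratios).
#'
#' @param mbaf,mbaf_min,mbaf_max segment mBAF summary values
#' @param call_type `"loss"`, `"gain"` or `"cnn_imbalance"` (ignored when
#'   `genotype` is given)
#' @param genotype optional explicit allele pair `c(nA, nB)`
#' @param background_ploidy background ploidy (2 or 4)
#' @param thresholds see [clonality_thresholds()]
#' @return list with `ac_mean`, `ac_min`, `ac_max` (fractions), the
#'   genotype used and the call type
#' @examples
#' estimate_ac(0.56, call_type = "loss")$ac_mean   # ~0.214
#' estimate_ac(0.56, call_type = "gain")$ac_mean   # ~0.273
#' @export
estimate_ac <- function(mbaf, mbaf_min = mbaf, mbaf_max = mbaf,
                        call_type = c("loss", "gain", "cnn_imbalance"),
                        genotype = NULL, background_ploidy = 2L,
                        thresholds = clonality_thresholds()) {
  if (is.null(genotype)) {
    call_type <- match.arg(call_type)
    genotype <- .default_genotypes(call_type, background_ploidy)
  } else {
    call_type <- if (is.character(call_type)) call_type[1L] else NA_character_
  }
  check_genotype(genotype)
  if (sum(genotype) > thresholds$max_copies)
    stop("amplified sequences (>", thresholds$max_copies,
         " copies) cannot be quantified from mBAF")
  if (mbaf < thresholds$mbaf_call)
    stop("segment mBAF ", mbaf, " is below the calling threshold ",
         thresholds$mbaf_call, ": abnormality content not quantifiable")
  clip <- function(x) pmin(1, pmax(0, x))
  list(ac_mean = clip(invert_mbaf(mbaf, genotype, background_ploidy)),
       ac_min = clip(invert_mbaf(max(mbaf_min, 0.5), genotype,
                                 background_ploidy)),
       ac_max = clip(invert_mbaf(mbaf_max, genotype, background_ploidy)),
       genotype = genotype, call_type = call_type)
}

#' Minimal detectable clone fraction at an mBAF threshold
#'
#' The clone DNA fraction at which an aberration's expected mBAF reaches the
#' calling threshold: smaller clones are invisible. Monotone increasing in
#' the threshold. At the default threshold of 0.56, hemizygous losses are
#' detectable above ~21% of sampled DNA and single-copy gains above ~27%.
#'
#' @param call_type `"loss"`, `"gain"` or `"cnn_imbalance"`
#' @param mbaf_threshold calling threshold in `(0.5, 1)`
#' @param background_ploidy background ploidy
#' @return minimal detectable clone DNA fraction
#' @export
detection_limit <- function(call_type = c("loss", "gain", "cnn_imbalance"),
                            mbaf_threshold = 0.56,
                            background_ploidy = 2L) {
  call_type <- match.arg(call_type)
  stopifnot(mbaf_threshold > 0.5, mbaf_threshold < 1)
  invert_mbaf(mbaf_threshold,
              .default_genotypes(call_type, background_ploidy),
              background_ploidy)
}

#' Call and quantify all aberrant segments of a case
#'
#' Convenience pipeline: classifies each segment ([call_imbalance()]) and,
#' for non-neutral segments that are quantifiable, estimates the
#' abnormality content ([estimate_ac()]). Segments refused by the AC model
#' (mBAF below the calling threshold) are kept with `NA` estimates.
#'
#' @param segments a segment data frame ([baf_segments()])
#' @param aberration_class `"numerical"` or `"structural"` per segment
#'   (recycled); whole-chromosome segments are numerical
#' @param background_ploidy background ploidy for the mixture model
#' @param thresholds see [clonality_thresholds()]
#' @return a calls data frame: label, aberration_class, call_type, nA, nB,
#'   ac_mean, ac_min, ac_max
#' @export
call_segments <- function(segments, aberration_class = "structural",
                          background_ploidy = 2L,
                          thresholds = clonality_thresholds()) {
  segments <- baf_segments(segments)
  types <- call_imbalance(segments$mbaf, segments$log2ratio, thresholds)
  keep <- which(types != "neutral")
  klass <- rep_len(aberration_class, nrow(segments))
  rows <- lapply(keep, function(i) {
    sign <- switch(types[i], gain = "+", loss = "-", "cnn ")
    est <- tryCatch(
      estimate_ac(segments$mbaf[i], segments$mbaf_min[i],
                  segments$mbaf_max[i], call_type = types[i],
                  background_ploidy = background_ploidy,
                  thresholds = thresholds),
      error = function(e) NULL)
    data.frame(label = paste0(sign, segments$chromosome[i]),
               aberration_class = klass[i], call_type = types[i],
               nA = if (is.null(est)) NA_integer_ else est$genotype[1L],
               nB = if (is.null(est)) NA_integer_ else est$genotype[2L],
               ac_mean = if (is.null(est)) NA_real_ else est$ac_mean,
               ac_min = if (is.null(est)) NA_real_ else est$ac_min,
               ac_max = if (is.null(est)) NA_real_ else est$ac_max,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(label = character(), aberration_class = character(),
                      call_type = character(), nA = integer(),
                      nB = integer(), ac_mean = numeric(),
                      ac_min = numeric(), ac_max = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-case prevalence-span summary
#'
#' The case's clone-size diversity metric: the span is the difference in
#' abnormality content between the most and the least prevalent aberration,
#' computed over all calls and within the numerical and structural classes.
#' Spans are in percentage points of sampled DNA.
#'
#' @param calls a calls data frame (see [call_segments()]) with columns
#'   `ac_mean`, `ac_min`, `ac_max`, `aberration_class`
#' @param case_id identifier carried into the summary
#' @param ploidy free-text ploidy annotation
#' @return a one-row data frame: case_id, ploidy, n_segments, n_numerical,
#'   n_structural, span_total, span_numerical, span_structural
#' @export
summarize_case <- function(calls, case_id = NA_character_,
                           ploidy = NA_character_) {
  calls <- calls[!is.na(calls$ac_mean), , drop = FALSE]
  if (!nrow(calls)) stop("no quantified calls to summarise")
  span <- function(x) if (length(x)) 100 * (max(x) - min(x)) else NA_real_
  num <- calls$ac_mean[calls$aberration_class == "numerical"]
  str <- calls$ac_mean[calls$aberration_class == "structural"]
  data.frame(case_id = case_id, ploidy = ploidy,
             n_segments = nrow(calls),
             n_numerical = length(num), n_structural = length(str),
             span_total = span(calls$ac_mean),
             span_numerical = span(num), span_structural = span(str),
             stringsAsFactors = FALSE)
}

#' Fraction of calls consistent with the majority clone
#'
#' Operationalises "within the same DNA content level as the majority of
#' aberrations" as interval overlap: each call occupies the band
#' `[ac_min, ac_max]`; the majority band is the call interval overlapping
#' the largest number of call intervals (ties broken towards the widest
#' band). Per aberration class, returns the fraction of calls whose band
#' overlaps the majority band.
#'
#' @param calls a calls data frame with `ac_min`, `ac_max`,
#'   `aberration_class`
#' @return named numeric vector: fractions for `overall`, `numerical`,
#'   `structural` (NA when a class has no calls), plus attribute
#'   `majority_band`
#' @export
majority_clone_consistency <- function(calls) {
  calls <- calls[!is.na(calls$ac_min) & !is.na(calls$ac_max), ,
                 drop = FALSE]
  if (!nrow(calls)) stop("no quantified calls")
  lo <- calls$ac_min; hi <- calls$ac_max
  overlaps <- function(i) lo <= hi[i] & hi >= lo[i]
  n_over <- vapply(seq_len(nrow(calls)), function(i) sum(overlaps(i)),
                   integer(1))
  best <- which(n_over == max(n_over))
  best <- best[which.max(hi[best] - lo[best])]
  inband <- overlaps(best)
  frac <- function(sel) if (any(sel)) mean(inband[sel]) else NA_real_
  out <- c(overall = mean(inband),
           numerical = frac(calls$aberration_class == "numerical"),
           structural = frac(calls$aberration_class == "structural"))
  attr(out, "majority_band") <- c(lo[best], hi[best])
  out
}
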