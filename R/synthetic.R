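#' Ground truth for synthetic subclone mixtures
#'
#' Describes a tumour sample as a mixture of subclones at known DNA
#' fractions, each carrying a set of aberrations with explicit allele
#' genotypes, on a balanced background with optional normal-cell
#' contamination. Used by the synthetic generators so that every estimator
#' can be benchmarked against known truth.
#'
#' @param clones list of clones; each clone is a list with elements
#'   `fraction` (DNA fraction) and `aberrations` — a list of aberrations,
#'   each with `chromosome` (label), `genotype` (`c(nA, nB)`), and an
#'   optional `label`
#' @param normal_contamination DNA fraction of non-neoplastic cells
#' @param background_ploidy total copies of the balanced background
#' @return an object of class `clonal_truth`
#' @export
clonal_truth <- function(clones, normal_contamination = 0,
                         background_ploidy = 2L) {
  fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (any(fr < 0) || normal_contamination < 0)
    stop("fractions must be non-negative")
  if (abs(sum(fr) + normal_contamination - 1) > 1e-8)
    stop("clone fractions plus contamination must sum to 1 (got ",
         sum(fr) + normal_contamination, ")")
  for (cl in clones)
    for (ab in cl$aberrations) check_genotype(ab$genotype)
  structure(list(clones = clones,
                 normal_contamination = normal_contamination,
                 background_ploidy = as.integer(background_ploidy)),
            class = "clonal_truth")
}

#' Generate a synthetic mBAF segment table from known clonal truth
#'
#' Each aberration of each clone becomes one genomic segment whose marker
#' mBAF values are drawn from a Gaussian around the allele-mixture
#' expectation ([expected_mbaf()]) at the clone's DNA fraction, truncated
#' to `[0.5, 1]`; the segment mBAF is the marker median and the min/max
#' are the marker extremes. The log2 ratio follows the total-copy mixture,
#' `log2(total/background)`, plus noise. Neutral filler segments are added
#' to reach `n_segments`.
#'
#' @param truth a [clonal_truth()]
#' @param n_segments total number of segments to emit (at least the number
#'   of aberrations)
#' @param markers_per_segment integer scalar or range `c(lo, hi)` to draw
#'   marker counts from (uniform)
#' @param noise_sd per-marker mBAF standard deviation
#' @param seed optional integer seed
#' @return list: `segments` (a [baf_segments()] data frame) and `truth`
#'   (per-segment data frame with the generating clone fraction and
#'   genotype; `NA` rows are neutral fillers)
#' @export
gen_baf_segments <- function(truth, n_segments = NULL,
                             markers_per_segment = c(50L, 500L),
                             noise_sd = 0.005, seed = NULL) {
  stopifnot(inherits(truth, "clonal_truth"))
  if (!is.null(seed)) set.seed(seed)
  ab_rows <- list()
  for (ci in seq_along(truth$clones)) {
    cl <- truth$clones[[ci]]
    for (ab in cl$aberrations)
      ab_rows[[length(ab_rows) + 1L]] <-
        list(clone = ci, fraction = cl$fraction,
             chromosome = as.character(ab$chromosome),
             nA = ab$genotype[1L], nB = ab$genotype[2L],
             label = if (is.null(ab$label)) NA_character_ else ab$label)
  }
  if (is.null(n_segments)) n_segments <- length(ab_rows)
  if (n_segments < length(ab_rows))
    stop("n_segments smaller than the number of aberrations in the truth")
  pi0 <- truth$background_ploidy
  n_fill <- n_segments - length(ab_rows)
  draw_markers <- function() {
    if (length(markers_per_segment) == 1L) as.integer(markers_per_segment)
    else sample(markers_per_segment[1L]:markers_per_segment[2L], 1L)
  }
  seg <- vector("list", n_segments)
  tr <- vector("list", n_segments)
  fill_chroms <- rep(as.character(1:22), length.out = max(n_fill, 1L))
  pos <- new.env(parent = emptyenv())  # per-chromosome layout cursor
  next_span <- function(chrom) {
    cur <- if (is.null(pos[[chrom]])) 1e6 else pos[[chrom]]
    len <- 2e7
    pos[[chrom]] <- cur + len + 5e6  # gaps > 1 Mb: no accidental fusion
    c(cur, cur + len - 1)
  }
  emit <- function(i, chrom, m_expect, total_copies, clone, fraction,
                   nA, nB, label) {
    mk <- draw_markers()
    vals <- pmin(1, pmax(0.5, stats::rnorm(mk, m_expect, noise_sd)))
    span <- next_span(chrom)
    seg[[i]] <<- data.frame(
      chromosome = chrom, start = span[1L], end = span[2L],
      mbaf = stats::median(vals), mbaf_min = min(vals),
      mbaf_max = max(vals),
      log2ratio = log2(total_copies / pi0) + stats::rnorm(1, 0, noise_sd),
      n_markers = mk)
    tr[[i]] <<- data.frame(
      chromosome = chrom, start = span[1L], end = span[2L],
      clone = clone, fraction = fraction, nA = nA, nB = nB,
      label = label, stringsAsFactors = FALSE)
  }
  for (i in seq_along(ab_rows)) {
    r <- ab_rows[[i]]
    m <- expected_mbaf(c(r$nA, r$nB), r$fraction, pi0)
    tot <- r$fraction * (r$nA + r$nB) + (1 - r$fraction) * pi0
    emit(i, r$chromosome, m, tot, r$clone, r$fraction, r$nA, r$nB, r$label)
  }
  for (j in seq_len(n_fill))
    emit(length(ab_rows) + j, fill_chroms[j], 0.5, pi0,
         NA_integer_, NA_real_, NA_integer_, NA_integer_, NA_character_)
  segments <- baf_segments(do.call(rbind, seg))
  list(segments = segments, truth = do.call(rbind, tr))
}

#' Generate synthetic FISH count tables from known clonal truth
#'
#' Cells are drawn from the clones (plus normal contamination, treated as a
#' clone at background ploidy) according to their fractions; each cell's
#' true probe copy number is mis-scored by one signal (up or down with
#' equal probability) with probability `epsilon`, emulating imperfect
#' hybridisation/scoring.
#'
#' @param truth a [clonal_truth()]
#' @param probe_map matrix of true copy numbers, probes in rows (rownames =
#'   probe labels), one column per clone in `truth$clones` order
#' @param n_cells nuclei scored per probe
#' @param epsilon per-cell mis-scoring probability (at most 0.1)
#' @param sample_id sample label for the emitted tables
#' @param seed optional integer seed
#' @return list of [fish_counts()], one per probe, plus attribute `truth`
#' @export
gen_fish_counts <- function(truth, probe_map, n_cells = 200L,
                            epsilon = 0, sample_id = "synthetic",
                            seed = NULL) {
  stopifnot(inherits(truth, "clonal_truth"), n_cells >= 1L,
            epsilon >= 0, epsilon <= 0.1)
  probe_map <- as.matrix(probe_map)
  if (ncol(probe_map) != length(truth$clones))
    stop("probe_map needs one column per clone")
  if (!is.null(seed)) set.seed(seed)
  fr <- vapply(truth$clones, function(cl) cl$fraction, numeric(1))
  if (truth$normal_contamination > 0) {
    fr <- c(fr, truth$normal_contamination)
    probe_map <- cbind(probe_map, truth$background_ploidy)
  }
  out <- lapply(seq_len(nrow(probe_map)), function(pi) {
    clone <- sample.int(length(fr), n_cells, replace = TRUE, prob = fr)
    copies <- probe_map[pi, clone]
    err <- stats::runif(n_cells) < epsilon
    copies[err] <- pmax(0L, copies[err] +
                          sample(c(-1L, 1L), sum(err), replace = TRUE))
    fish_counts(table(copies), sample_id = sample_id,
                probe = rownames(probe_map)[pi], min_cells = 1L)
  })
  names(out) <- rownames(probe_map)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic karyotype cohort under a segregation-error model
#'
#' Each case is a single virtual tumour evolved under `model` to a target
#' chromosome number drawn uniformly from `targetN_range`; the generating
#' model is recorded as truth metadata, enabling model-recovery benchmarks
#' of [run_cohort_evaluation()]. Cases whose target is unreachable under
#' the model are skipped and listed in the `skipped` attribute.
#'
#' @param model a [segregation_model()]
#' @param n_cases number of cases to generate
#' @param targetN_range integer range `c(lo, hi)` (or scalar) of target
#'   chromosome numbers
#' @param config a [sim_config()]; `n_virtual` here is the small pool used
#'   to draw each case's single stem line
#' @param seed optional integer seed
#' @return list of [karyotype_record()]s with attributes `truth` (data
#'   frame: case_id, model, start_ploidy, targetN) and `skipped`
#' @export
gen_cohort <- function(model, n_cases, targetN_range,
                       config = sim_config(n_virtual = 25L), seed = NULL) {
  stopifnot(inherits(model, "segregation_model"), n_cases >= 1L)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$seed <- NULL
  lo <- min(targetN_range); hi <- max(targetN_range)
  span <- lo:hi
  records <- list()
  truth <- list()
  skipped <- character()
  for (i in seq_len(n_cases)) {
    targetN <- span[sample.int(length(span), 1L)]
    case_id <- sprintf("synth%03d", i)
    sims <- tryCatch(evolve_to_target(model, targetN, cfg),
                     error = function(e) e)
    if (inherits(sims, "error")) {
      skipped <- c(skipped, sprintf("%s (N=%d): %s", case_id, targetN,
                                    conditionMessage(sims)))
      next
    }
    copies <- sims$copies[sample.int(nrow(sims$copies), 1L), ]
    records[[length(records) + 1L]] <- karyotype_record(
      case_id, cn_profile(copies = copies), source = "snp_array")
    truth[[length(truth) + 1L]] <- data.frame(
      case_id = case_id, model = model$kind,
      start_ploidy = model$start_ploidy, targetN = targetN,
      stringsAsFactors = FALSE)
  }
  if (!length(records))
    stop("no case target in [", lo, ", ", hi, "] was reachable under ",
         model$kind)
  attr(records, "truth") <- do.call(rbind, truth)
  attr(records, "skipped") <- skipped
  records
}
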