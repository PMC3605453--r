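#' Bundled neuroblastoma reference tables
#'
#' Two small curated tables distributed with the package, used in examples
#' and as published anchors for the diversity statistics:
#'
#' * `nb_prevalence_spans()` — per-case clone-prevalence spans from
#'   SNP-array (mBAF) analysis of a 30-case neuroblastoma cohort (10 cases
#'   per clinical-genetic subtype: 1, 2A, 2B): case identifier, subtype,
#'   ploidy annotation, the number of quantified aberrant segments split
#'   into numerical and structural changes, and the prevalence span in
#'   percentage points of sampled DNA.
#' * `nb_clone_nonmodal()` — FISH non-modal cell percentages for two
#'   neuroblastoma cell lines (GI-MEN, SK-N-AS), three single-cell clones
#'   each, their mother lines, and a normal-fibroblast technical control,
#'   for centromere probes CEP11/CEP17/CEP18 and locus probes 1p/17q, with
#'   the modal signal count per probe.
#'
#' @return a data frame
#' @examples
#' spans <- nb_prevalence_spans()
#' tapply(spans$prevalence_span, spans$subtype, mean)  # 21 / 50 / 39
#' @export
nb_prevalence_spans <- function() {
  utils::read.delim(system.file("extdata", "nb_prevalence_spans.tsv",
                                package = "karyolute"),
                    stringsAsFactors = FALSE)
}

#' @rdname nb_prevalence_spans
#' @export
nb_clone_nonmodal <- function() {
  utils::read.delim(system.file("extdata", "nb_clone_nonmodal.tsv",
                                package = "karyolute"),
                    stringsAsFactors = FALSE)
}
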