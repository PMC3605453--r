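#' A FISH signal-count table
#'
#' Per-cell signal counts for one probe in one sample: how many nuclei
#' showed each copy number. Analysis-grade tables should score at least 200
#' nuclei; smaller tables are accepted with a warning.
#'
#' @param counts named integer vector mapping copy number (0, 1, 2, ...) to
#'   the number of cells with that signal count
#' @param sample_id,probe labels (e.g. probe `"CEP11"`, `"1p36"`, `"17q"`)
#' @param min_cells warn below this many scored nuclei
#' @return an object of class `fish_counts`
#' @export
fish_counts <- function(counts, sample_id = NA_character_,
                        probe = NA_character_, min_cells = 200L) {
  if (is.null(names(counts)))
    stop("`counts` must be named by copy number")
  cls <- suppressWarnings(as.integer(names(counts)))
  if (anyNA(cls) || any(cls < 0))
    stop("copy-number names must be non-negative integers")
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("cell counts must be non-negative integers")
  n_cells <- sum(counts)
  if (n_cells < 1L) stop("empty FISH table")
  if (n_cells < min_cells)
    warning("only ", n_cells, " nuclei scored for ", sample_id, "/", probe,
            " (at least ", min_cells, " recommended)")
  o <- order(cls)
  structure(list(counts = stats::setNames(counts[o], cls[o]),
                 sample_id = sample_id, probe = probe,
                 n_cells = n_cells),
            class = "fish_counts")
}

#' @export
print.fish_counts <- function(x, ...) {
  cat(sprintf("<fish_counts %s/%s: %d nuclei, modal %d, non-modal %.1f%%>\n",
              x$sample_id, x$probe, x$n_cells, modal_number(x),
              nonmodal_fraction(x)))
  invisible(x)
}

#' Modal copy number of a FISH table
#'
#' The copy-number class with the largest cell count. Ties are broken
#' towards the class nearest `expected_ploidy` (when given), then towards
#' the lower class; tied tables carry a `tied` attribute.
#'
#' @param table a [fish_counts()]
#' @param expected_ploidy optional expected copy number used for
#'   tie-breaking
#' @return the modal copy number (integer), with attribute `tied`
#' @export
modal_number <- function(table, expected_ploidy = NULL) {
  stopifnot(inherits(table, "fish_counts"))
  counts <- table$counts
  cls <- as.integer(names(counts))
  top <- cls[counts == max(counts)]
  tied <- length(top) > 1L
  if (tied && !is.null(expected_ploidy))
    top <- top[order(abs(top - expected_ploidy), top)]
  # ties without an expected ploidy resolve to the lower class (top is
  # sorted ascending by construction)
  structure(top[1L], tied = tied)
}

#' Fraction of nuclei outside the modal copy number
#'
#' @param table a [fish_counts()]
#' @param expected_ploidy passed to [modal_number()] for tie-breaking
#' @return percentage in `[0, 100]`
#' @examples
#' nonmodal_fraction(fish_counts(c(`2` = 150, `3` = 30, `1` = 20)))  # 25
#' @export
nonmodal_fraction <- function(table, expected_ploidy = NULL) {
  stopifnot(inherits(table, "fish_counts"))
  modal <- as.character(modal_number(table, expected_ploidy))
  100 * (1 - table$counts[[modal]] / table$n_cells)
}

#' Control-derived significance threshold for non-modal fractions
#'
#' Mean of the control (e.g. normal fibroblast) non-modal fractions plus
#' three sample standard deviations (n-1 denominator). Samples above the
#' threshold show a significant prevalence of cells with non-modal copy
#' number.
#'
#' @param control_values numeric vector of control non-modal percentages,
#'   one per probe (at least 2)
#' @return threshold percentage
#' @examples
#' control_threshold(c(0.5, 0, 0, 0, 0))  # 0.77
#' @export
control_threshold <- function(control_values) {
  if (length(control_values) < 2L)
    stop("need at least 2 control values to estimate a threshold")
  mean(control_values) + 3 * stats::sd(control_values)
}

#' Compare copy-number diversity between two groups
#'
#' Two-tailed Student's t-test on groups of non-modal fractions
#' (normal-like averages), or a two-tailed Fisher exact test when given a
#' 2x2 contingency matrix. Degenerate variance in both groups falls back to
#' the exact test on modal/non-modal cell counts when those are supplied.
#'
#' @param group_a,group_b numeric vectors of non-modal fractions, or a
#'   single 2x2 matrix in `group_a` (then `group_b` is ignored)
#' @return list: `test` (`"t"` or `"fisher"`), `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `p_value`, `note`
#' @export
compare_diversity <- function(group_a, group_b = NULL) {
  if (is.matrix(group_a)) {
    stopifnot(all(dim(group_a) == 2L))
    ft <- stats::fisher.test(group_a, alternative = "two.sided")
    return(list(test = "fisher", n_a = sum(group_a[, 1L]),
                n_b = sum(group_a[, 2L]), mean_a = NA_real_,
                mean_b = NA_real_, p_value = ft$p.value, note = ""))
  }
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    p <- if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else NA_real_
    return(list(test = "degenerate", n_a = length(group_a),
                n_b = length(group_b), mean_a = mean(group_a),
                mean_b = mean(group_b), p_value = p,
                note = "zero variance in both groups; no t-test possible"))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE,
                      alternative = "two.sided")
  list(test = "t", n_a = length(group_a), n_b = length(group_b),
       mean_a = mean(group_a), mean_b = mean(group_b),
       p_value = tt$p.value, note = "")
}

#' Read / write FISH count tables
#'
#' Tab-delimited long format: columns `sample`, `probe`, `copy_number`,
#' `cells`; one [fish_counts()] object per sample/probe pair.
#'
#' @param path file path
#' @param min_cells passed to [fish_counts()]
#' @return `read_fish_table()`: a list of [fish_counts()] objects named
#'   `"sample/probe"`
#' @export
read_fish_table <- function(path, min_cells = 200L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "probe", "copy_number", "cells")
  if (!all(need %in% names(df)))
    stop("FISH table needs columns: ", paste(need, collapse = ", "))
  pieces <- split(df, paste(df$sample, df$probe, sep = "/"))
  lapply(pieces, function(d)
    fish_counts(stats::setNames(d$cells, d$copy_number),
                sample_id = d$sample[1L], probe = d$probe[1L],
                min_cells = min_cells))
}

#' @rdname read_fish_table
#' @param tables list of [fish_counts()] objects
#' @export
write_fish_table <- function(tables, path) {
  rows <- lapply(tables, function(tb)
    data.frame(sample = tb$sample_id, probe = tb$probe,
               copy_number = as.integer(names(tb$counts)),
               cells = as.integer(tb$counts)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
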