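#' Validate a table of mBAF segments
#'
#' Canonicalises a data frame of genomic segments carrying mirrored B-allele
#' frequencies (mBAF) and log2 copy-number ratios, as produced by BAF
#' segmentation of SNP-array data. Coordinates are 1-based inclusive on
#' GRCh37. Enforced invariants: `0.5 <= mbaf <= 1`,
#' `mbaf_min <= mbaf <= mbaf_max`, `start <= end`.
#'
#' @param df data frame with columns `chromosome`, `start`, `end`, `mbaf`,
#'   `log2ratio`, and optionally `mbaf_min`, `mbaf_max` (default to `mbaf`)
#'   and `n_markers`
#' @return a validated data frame with canonical column order
#' @export
baf_segments <- function(df) {
  need <- c("chromosome", "start", "end", "mbaf", "log2ratio")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing segment column(s): ", paste(missing, collapse = ", "))
  if (is.null(df$mbaf_min)) df$mbaf_min <- df$mbaf
  if (is.null(df$mbaf_max)) df$mbaf_max <- df$mbaf
  if (is.null(df$n_markers)) df$n_markers <- NA_integer_
  df <- df[, c("chromosome", "start", "end", "mbaf", "mbaf_min", "mbaf_max",
               "log2ratio", "n_markers")]
  probs <- segment_row_problems(df)
  if (nrow(probs))
    stop("invalid segment row(s):\n",
         paste(sprintf("  row %d: %s", probs$row, probs$reason),
               collapse = "\n"))
  df$chromosome <- as.character(df$chromosome)
  rownames(df) <- NULL
  df
}

segment_row_problems <- function(df) {
  reasons <- character(nrow(df))
  num <- c("start", "end", "mbaf", "mbaf_min", "mbaf_max", "log2ratio")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    vals <- suppressWarnings(vapply(num, function(cn) as.numeric(r[[cn]]),
                                    numeric(1)))
    if (anyNA(vals[c("start", "end", "mbaf", "log2ratio")])) {
      bad <- num[is.na(vals)]
      reasons[i] <- paste0("non-numeric value in ",
                           paste(bad, collapse = ", "))
    } else if (vals["start"] > vals["end"]) {
      reasons[i] <- "start > end"
    } else if (vals["mbaf"] < 0.5 || vals["mbaf"] > 1) {
      reasons[i] <- sprintf("mBAF %.4g outside [0.5, 1] (must be mirrored)",
                            vals["mbaf"])
    } else if (!is.na(vals["mbaf_min"]) && !is.na(vals["mbaf_max"]) &&
               (vals["mbaf_min"] > vals["mbaf"] ||
                vals["mbaf"] > vals["mbaf_max"])) {
      reasons[i] <- "mbaf_min <= mbaf <= mbaf_max violated"
    }
  }
  data.frame(row = which(nzchar(reasons)),
             reason = reasons[nzchar(reasons)])
}

.seg_aliases <- list(
  chromosome = c("chromosome", "chrom", "chr"),
  start      = c("start", "begin", "pos_start"),
  end        = c("end", "stop", "pos_end"),
  mbaf       = c("mbaf", "mbaf_median", "segment_mbaf"),
  mbaf_min   = c("mbaf_min", "min_mbaf", "mbafmin"),
  mbaf_max   = c("mbaf_max", "max_mbaf", "mbafmax"),
  log2ratio  = c("log2ratio", "log2_ratio", "logr", "log2r", "logratio"),
  n_markers  = c("n_markers", "markers", "nmarkers", "n_snps", "snps")
)

#' Read / write an mBAF segment table
#'
#' Tab-delimited, UTF-8, with a header row. Column names are matched
#' case-insensitively against common aliases (`Chromosome`/`chrom`/`chr`,
#' `Log2ratio`/`logR`, ...). Rows violating the segment invariants are
#' dropped with a warning giving their line numbers; missing required
#' columns are an error.
#'
#' @param path file path
#' @return `read_segment_table()`: a validated segment data frame (see
#'   [baf_segments()]) with a `rejected` attribute listing dropped rows.
#' @export
read_segment_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  lower <- tolower(gsub("[ .]", "_", names(raw)))
  out <- list()
  for (canon in names(.seg_aliases)) {
    hit <- which(lower %in% .seg_aliases[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1L]]]
  }
  need <- c("chromosome", "start", "end", "mbaf", "log2ratio")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("segment table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (is.null(df$mbaf_min)) df$mbaf_min <- df$mbaf
  if (is.null(df$mbaf_max)) df$mbaf_max <- df$mbaf
  if (is.null(df$n_markers)) df$n_markers <- NA_integer_
  num <- c("start", "end", "mbaf", "mbaf_min", "mbaf_max", "log2ratio",
           "n_markers")
  for (cn in num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  probs <- segment_row_problems(df)
  if (nrow(probs)) {
    # +1 for the header: report physical line numbers
    warning("dropping ", nrow(probs), " invalid segment row(s) in ", path,
            ":\n", paste(sprintf("  line %d: %s", probs$row + 1L,
                                 probs$reason), collapse = "\n"))
    df <- df[-probs$row, , drop = FALSE]
  }
  df <- baf_segments(df)
  attr(df, "rejected") <- probs
  df
}

#' @rdname read_segment_table
#' @param segments a segment data frame as returned by [baf_segments()]
#' @export
write_segment_table <- function(segments, path) {
  segments <- baf_segments(segments)
  out <- segments
  names(out) <- c("Chromosome", "Start", "End", "mBAF", "mBAF_min",
                  "mBAF_max", "Log2ratio", "n_markers")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a whole-chromosome copy-number profile table
#'
#' One row per case: identifier, total chromosome number `N`, the number of
#' chromosome types in each copy-number class (columns `cn0`, `cn1`, ...,
#' kept exact however high the class), subtype, source, flags and optional
#' metadata. The round trip through `write_profile_table()` and
#' `read_profile_table()` is lossless.
#'
#' @param path file path
#' @param n_types expected chromosome types per case (row check)
#' @return `read_profile_table()`: a list of [karyotype_record()]s
#' @export
read_profile_table <- function(path, n_types = 23L) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cn_cols <- grep("^cn[0-9]+$", names(df), value = TRUE)
  if (!length(cn_cols) || !all(c("case_id", "N") %in% names(df)))
    stop("profile table needs case_id, N and cn<k> columns")
  cls <- as.integer(sub("^cn", "", cn_cols))
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    counts <- as.integer(df[i, cn_cols])
    counts[is.na(counts)] <- 0L
    if (sum(counts) != n_types)
      stop("row ", i, " (", df$case_id[i], "): class counts sum to ",
           sum(counts), ", expected ", n_types)
    prof <- cn_profile(counts = stats::setNames(counts, cls))
    if (prof$N != df$N[i])
      stop("row ", i, " (", df$case_id[i], "): N column is ", df$N[i],
           " but classes imply ", prof$N)
    flags <- if (!is.null(df$flags) && nzchar(df$flags[i]) &&
                 !is.na(df$flags[i]))
      strsplit(df$flags[i], ";", fixed = TRUE)[[1L]] else character()
    records[[i]] <- karyotype_record(
      df$case_id[i], prof,
      subtype = if (is.null(df$subtype)) "unknown" else df$subtype[i],
      source = if (is.null(df$source)) "cytogenetics" else df$source[i],
      flags = flags,
      age_years = if (is.null(df$age_years)) NA_real_ else df$age_years[i],
      karyotype = if (is.null(df$karyotype)) NA_character_
                  else df$karyotype[i])
  }
  records
}

#' @rdname read_profile_table
#' @param records list of [karyotype_record()]s
#' @export
write_profile_table <- function(records, path) {
  stopifnot(all(vapply(records, inherits, TRUE, "karyotype_record")))
  max_cls <- max(vapply(records, function(r)
    max(as.integer(names(r$profile$counts))), integer(1)))
  cls <- 0:max_cls
  rows <- lapply(records, function(r) {
    counts <- vapply(cls, function(k) class_count(r$profile, k), integer(1))
    cbind(data.frame(case_id = r$case_id, N = r$profile$N),
          as.data.frame(as.list(stats::setNames(counts,
                                                paste0("cn", cls)))),
          data.frame(subtype = r$subtype, source = r$source,
                     flags = paste(r$flags, collapse = ";"),
                     age_years = r$age_years,
                     karyotype = ifelse(is.na(r$karyotype), "",
                                        r$karyotype)))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
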