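#' Whole-chromosome copy-number profile
#'
#' A `cn_profile` summarises a tumour stem line as the number of chromosome
#' types present at each copy-number class (monosomies, disomies, trisomies,
#' ...). Chromosome identity is deliberately discarded: two stem lines with
#' trisomy 2 and trisomy 7 respectively have the same profile. The genome is
#' modelled as `n_types` chromosome types (default 23: the 22 autosome pairs
#' plus one sex-chromosome slot), so a normal diploid has N = 46 and a
#' tetraploid N = 92.
#'
#' Internally every copy-number class is kept exact, however high; pooling of
#' high polysomies ("5+") is a display concern only (see [format.cn_profile()]),
#' so the total chromosome number N is always exact.
#'
#' @param copies integer vector of per-chromosome-type copy numbers
#'   (length `n_types`), all >= 0. Mutually exclusive with `counts`.
#' @param counts named integer vector mapping copy-number class (name,
#'   coercible to integer >= 0) to the number of chromosome types in that
#'   class. Mutually exclusive with `copies`.
#' @param n_types number of chromosome types; required with `counts` only if
#'   it cannot be inferred (it is checked against `sum(counts)`).
#'
#' @return an object of class `cn_profile` with elements `counts` (named
#'   integer vector over classes present), `n_types`, and `N` (total
#'   chromosome number, `sum(class * count)`).
#' @examples
#' cn_profile(counts = c(`1` = 1, `2` = 19, `3` = 2, `4` = 1))  # N = 49
#' cn_profile(copies = rep(2, 23))                              # diploid
#' @export
cn_profile <- function(copies = NULL, counts = NULL, n_types = NULL) {
  if (is.null(copies) == is.null(counts))
    stop("supply exactly one of `copies` or `counts`")
  if (!is.null(copies)) {
    copies <- as.integer(copies)
    if (anyNA(copies) || any(copies < 0))
      stop("`copies` must be non-negative integers")
    tab <- table(copies)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    n_types <- length(copies)
  } else {
    if (is.null(names(counts)))
      stop("`counts` must be named by copy-number class")
    cls <- suppressWarnings(as.integer(names(counts)))
    if (anyNA(cls) || any(cls < 0))
      stop("class names must be non-negative integers")
    counts <- as.integer(counts)
    if (anyNA(counts) || any(counts < 0))
      stop("counts must be non-negative integers")
    keep <- counts > 0
    counts <- counts[keep]
    names(counts) <- cls[keep]
    if (is.null(n_types)) n_types <- sum(counts)
    if (sum(counts) != n_types)
      stop("counts sum to ", sum(counts), ", expected n_types = ", n_types)
  }
  cls <- as.integer(names(counts))
  o <- order(cls)
  counts <- counts[o]
  structure(
    list(counts = counts, n_types = as.integer(n_types),
         N = sum(as.integer(names(counts)) * counts)),
    class = "cn_profile"
  )
}

#' @export
format.cn_profile <- function(x, pool_cap = 5L, ...) {
  cls <- as.integer(names(x$counts))
  lo <- cls < pool_cap
  parts <- sprintf("%d:%d", cls[lo], x$counts[lo])
  if (any(!lo))
    parts <- c(parts, sprintf("%d+:%d", pool_cap, sum(x$counts[!lo])))
  sprintf("<cn_profile N=%d (%s) over %d chromosome types>",
          x$N, paste(parts, collapse = " "), x$n_types)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Canonical key identifying a copy-number profile
#'
#' Two profiles compare equal (for expected-prevalence counting) iff they
#' have identical per-class counts and the same number of chromosome types.
#'
#' @param x a `cn_profile`
#' @return a character scalar
#' @keywords internal
#' @export
profile_key <- function(x) {
  stopifnot(inherits(x, "cn_profile"))
  paste0(x$n_types, "|",
         paste(names(x$counts), x$counts, sep = ":", collapse = ","))
}

# key for a raw copies vector; avoids building cn_profile objects in hot loops
copies_key <- function(copies, n_types = length(copies)) {
  tab <- tabulate(copies + 1L)  # class 0 at index 1
  nz <- which(tab > 0L)
  paste0(n_types, "|", paste(nz - 1L, tab[nz], sep = ":", collapse = ","))
}

#' Count of chromosome types in one copy-number class
#'
#' @param x a `cn_profile`
#' @param class integer copy-number class (0 = nullisomy, 1 = monosomy, ...)
#' @return integer count (0 if the class is absent)
#' @export
class_count <- function(x, class) {
  stopifnot(inherits(x, "cn_profile"))
  n <- x$counts[as.character(as.integer(class))]
  if (is.na(n)) 0L else unname(n)
}

#' A karyotype record: one case with its copy-number profile
#'
#' Bundles a case's whole-chromosome copy-number profile with the clinical
#' and parsing metadata that drive cohort filtering: the clinical-genetic
#' subtype (1 = hyperdiploid/near-triploid numerical tumours, 2A = structural
#' without MYCN amplification, 2B = MYCN amplified), the data source, and
#' exclusion flags (`recurrent`, `adult`, `incomplete`, `marker`, `ring`,
#' `no_numerical_change`).
#'
#' @param case_id character identifier
#' @param profile a [cn_profile()]
#' @param subtype one of `"1"`, `"2A"`, `"2B"`, `"unknown"`
#' @param source `"cytogenetics"` or `"snp_array"`
#' @param flags character vector drawn from the flag vocabulary
#' @param age_years numeric age at diagnosis, or `NA`
#' @param karyotype original ISCN-like string, if any
#' @return an object of class `karyotype_record`
#' @export
karyotype_record <- function(case_id, profile,
                             subtype = "unknown",
                             source = c("cytogenetics", "snp_array"),
                             flags = character(),
                             age_years = NA_real_,
                             karyotype = NA_character_) {
  stopifnot(inherits(profile, "cn_profile"))
  subtype <- match.arg(as.character(subtype), c("1", "2A", "2B", "unknown"))
  source <- match.arg(source)
  known <- c("recurrent", "adult", "incomplete", "marker", "ring",
             "no_numerical_change", "inconsistent_count")
  bad <- setdiff(flags, known)
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "))
  structure(
    list(case_id = as.character(case_id), subtype = subtype,
         profile = profile, source = source,
         flags = unique(as.character(flags)),
         age_years = as.numeric(age_years), karyotype = karyotype),
    class = "karyotype_record"
  )
}

#' @export
print.karyotype_record <- function(x, ...) {
  cat(sprintf("<karyotype_record %s [type %s, %s] %s%s>\n",
              x$case_id, x$subtype, x$source, format(x$profile),
              if (length(x$flags))
                paste0(" flags=", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}
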