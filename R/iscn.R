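#' Parse a numerical ISCN-style karyotype into a copy-number profile
#'
#' Interprets a single-clone karyotype string of the form
#' `"49,XX,-1,+2,+3,+4,+4"`: a leading modal chromosome count, a sex
#' chromosome field, then comma-separated aberration tokens. Only numerical
#' tokens change whole-chromosome counts; structural tokens (`del`, `dup`,
#' `t`, `add`, `i`, `inv`, `der`, ...) are ignored for counting, while a few
#' are recognised for flagging: `inc` (incomplete), `mar` (marker), `r`
#' (ring), and `dmin`/`hsr`, whose presence assigns clinical-genetic subtype
#' 2B (taken as equivalent to MYCN amplification in cytogenetic records).
#'
#' The baseline ploidy is the multiple of 23 nearest to the modal count
#' (configurable via `baseline`): every chromosome type starts at that many
#' copies, the sex slot is set from the sex field (number of X/Y letters),
#' and each `+chr` / `-chr` token then adds or removes one copy. A karyotype
#' whose resulting profile is the normal diploid complement is flagged
#' `no_numerical_change`. If the computed total disagrees with the declared
#' modal count by more than `slack` (markers and rings are credited to the
#' declared count for this check only), the record is flagged
#' `inconsistent_count` rather than rejected.
#'
#' @param karyotype character scalar, ISCN-like
#' @param case_id identifier for the resulting record
#' @param source data source label for the record
#' @param age_years optional age at diagnosis (drives the adult filter)
#' @param recurrent logical; flags the record as from a recurrent tumour
#' @param baseline `"nearest"` (multiple of 23 nearest the modal count) or an
#'   explicit integer ploidy level (copies per chromosome type)
#' @param slack allowed absolute difference between declared and computed
#'   chromosome number before flagging
#' @param n_types number of chromosome types (23: autosomes + one sex slot)
#' @return a [karyotype_record()]
#' @examples
#' parse_iscn_numerical("49,XX,-1,+2,+3,+4,+4")$profile  # {1:1,2:19,3:2,4:1}
#' parse_iscn_numerical("46,XX")$flags                   # no_numerical_change
#' @export
parse_iscn_numerical <- function(karyotype, case_id = karyotype,
                                 source = "cytogenetics",
                                 age_years = NA_real_, recurrent = FALSE,
                                 baseline = "nearest", slack = 0L,
                                 n_types = 23L) {
  stopifnot(is.character(karyotype), length(karyotype) == 1L)
  tokens <- split_iscn(karyotype)
  if (!length(tokens)) stop("empty karyotype string")

  count_tok <- tokens[[1L]]
  m <- regmatches(count_tok, regexpr("^[0-9]+", count_tok))
  if (!length(m))
    stop("unparseable chromosome count field: '", count_tok, "'")
  declared <- as.integer(m)

  if (identical(baseline, "nearest")) {
    lev <- seq_len(8L)
    b <- lev[which.min(abs(declared - n_types * lev))]
  } else {
    b <- as.integer(baseline)
    stopifnot(b >= 1L)
  }
  copies <- rep(b, n_types)
  sex_slot <- n_types  # last slot holds the sex chromosomes

  rest <- tokens[-1L]
  flags <- character()
  subtype <- "unknown"
  if (recurrent) flags <- c(flags, "recurrent")
  if (!is.na(age_years) && age_years > 18) flags <- c(flags, "adult")
  declared_extra <- 0L  # markers/rings credited to the declared count

  # sex field, when present, overrides the baseline for the sex slot
  if (length(rest) && grepl("^[XxYy?]+$", rest[[1L]])) {
    sex <- rest[[1L]]
    copies[sex_slot] <- nchar(gsub("[^XxYy]", "", sex))
    rest <- rest[-1L]
  }

  for (tok in rest) {
    tok <- trimws(tok)
    if (!nchar(tok)) next
    if (grepl("dmin", tok, ignore.case = TRUE) ||
        grepl("hsr", tok, ignore.case = TRUE)) {
      subtype <- "2B"
      next
    }
    if (grepl("^\\+?inc$", tok, ignore.case = TRUE)) {
      flags <- c(flags, "incomplete"); next
    }
    if (grepl("^[+~]?[0-9]*mar", tok, ignore.case = TRUE)) {
      flags <- c(flags, "marker")
      if (startsWith(tok, "+")) declared_extra <- declared_extra + 1L
      next
    }
    if (grepl("^\\+?r([(]|$)", tok)) {
      flags <- c(flags, "ring")
      if (startsWith(tok, "+")) declared_extra <- declared_extra + 1L
      next
    }
    gm <- regmatches(tok, regexec("^([+−-])([0-9]+|[XY])$", tok))[[1L]]
    if (length(gm)) {
      delta <- if (gm[2L] == "+") 1L else -1L
      idx <- if (gm[3L] %in% c("X", "Y")) sex_slot else as.integer(gm[3L])
      if (idx < 1L || idx > n_types)
        stop("chromosome out of range in token '", tok, "'")
      copies[idx] <- copies[idx] + delta
      if (copies[idx] < 0L)
        stop("token '", tok, "' drives chromosome ", gm[3L],
             " below zero copies")
      next
    }
    # anything else (del, dup, t, add, i, inv, der, ins, ...) is structural:
    # no effect on whole-chromosome counts
  }

  if (all(copies == 2L)) flags <- c(flags, "no_numerical_change")
  if (abs(sum(copies) + declared_extra - declared) > slack)
    flags <- c(flags, "inconsistent_count")

  karyotype_record(case_id, cn_profile(copies = copies),
                   subtype = subtype, source = source, flags = flags,
                   age_years = age_years, karyotype = karyotype)
}

# split on top-level commas only (commas inside parentheses stay put)
split_iscn <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- chars == "," & depth == 0L
  grp <- cumsum(cut)
  toks <- vapply(split(chars[!cut], grp[!cut]), paste, "", collapse = "")
  trimws(unname(toks))
}

#' Filter a karyotype cohort by exclusion rules
#'
#' Removes records matching any enabled rule, mirroring the curation used to
#' assemble high-quality aneuploid cohorts: recurrent tumours, adults
#' (age > 18 years), incomplete karyotypes (`inc`), karyotypes with marker
#' (`mar`) or ring (`r`) chromosomes, and karyotypes without numerical
#' changes. Filtering is idempotent.
#'
#' @param records list of [karyotype_record()] objects
#' @param rules character vector of rules to apply; any of `"recurrent"`,
#'   `"adult"`, `"incomplete"`, `"marker"`, `"ring"`,
#'   `"no_numerical_change"`, `"inconsistent_count"`
#' @param adult_age age threshold in years for the adult rule
#' @return the retained records, with an `excluded_counts` attribute giving
#'   the number of records matching each rule (a record may match several)
#' @export
filter_cohort <- function(records,
                          rules = c("recurrent", "adult", "incomplete",
                                    "marker", "ring",
                                    "no_numerical_change"),
                          adult_age = 18) {
  stopifnot(all(vapply(records, inherits, TRUE, "karyotype_record")))
  rules <- match.arg(rules, several.ok = TRUE,
                     choices = c("recurrent", "adult", "incomplete",
                                 "marker", "ring", "no_numerical_change",
                                 "inconsistent_count"))
  hit <- function(r, rule) {
    if (rule == "adult")
      return("adult" %in% r$flags ||
               (!is.na(r$age_years) && r$age_years > adult_age))
    rule %in% r$flags
  }
  counts <- vapply(rules, function(rule)
    sum(vapply(records, hit, TRUE, rule = rule)), integer(1))
  drop <- vapply(records, function(r)
    any(vapply(rules, hit, TRUE, r = r)), TRUE)
  out <- records[!drop]
  attr(out, "excluded_counts") <- counts
  out
}
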