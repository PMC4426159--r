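# Amenable-mortality classification: a machine-readable cause list
# (ICD-10 code ranges with age windows, split by place and timing of the
# health-care intervention) and a matcher over (code, age) pairs.
#
# Range semantics are the conventional ICD-10 prefix-interval ones on the
# dot-stripped code: "A00-09" matches any code with letter A and two-digit
# block 00..09 including decimal subcodes; "A48.1" matches that subcode and
# its children but not A48.0; ranges never cross the letter boundary unless
# written with two letters ("B99-C10").

#' Parse an ICD-10 code pattern
#'
#' Accepted forms: a single block (`"A37"`), a subcode (`"A48.1"`,
#' matching itself and its children), a same-letter range (`"I60-69"`) and
#' a two-letter range (`"B99-C10"`).  En-dashes are treated as hyphens.
#'
#' @param pattern a single non-empty pattern string.
#' @return An object of class `icd_matcher`.
#' @examples
#' m <- parse_icd_range("I60-69")
#' icd_matches(m, "I63.9")
#' @export
parse_icd_range <- function(pattern) {
  raw <- pattern
  pattern <- toupper(gsub("–", "-", trimws(pattern)))
  if (!nzchar(pattern)) stop("empty ICD-10 pattern")
  fail <- function(pos) {
    stop(sprintf("malformed ICD-10 pattern '%s' (at position %d)", raw, pos))
  }
  m <- list(pattern = pattern)
  if (grepl("^[A-Z][0-9]{2}$", pattern)) {
    m$letter <- m$letter2 <- substr(pattern, 1, 1)
    m$lo <- m$hi <- as.integer(substr(pattern, 2, 3))
    m$sub <- NA_character_
  } else if (grepl("^[A-Z][0-9]{2}\\.[0-9]+$", pattern)) {
    m$letter <- m$letter2 <- substr(pattern, 1, 1)
    m$lo <- m$hi <- as.integer(substr(pattern, 2, 3))
    m$sub <- sub("^[A-Z][0-9]{2}\\.", "", pattern)
  } else if (grepl("^[A-Z][0-9]{2}-[0-9]{2}$", pattern)) {
    m$letter <- m$letter2 <- substr(pattern, 1, 1)
    m$lo <- as.integer(substr(pattern, 2, 3))
    m$hi <- as.integer(substr(pattern, 5, 6))
    m$sub <- NA_character_
    if (m$hi < m$lo) fail(5L)
  } else if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", pattern)) {
    m$letter <- substr(pattern, 1, 1)
    m$lo <- as.integer(substr(pattern, 2, 3))
    m$letter2 <- substr(pattern, 5, 5)
    m$hi <- as.integer(substr(pattern, 6, 7))
    m$sub <- NA_character_
    if (m$letter2 < m$letter) fail(5L)
  } else {
    # report the first character where the pattern stops looking like a code
    ok <- regmatches(pattern,
                     regexpr("^[A-Z]?[0-9]{0,2}[.-]?", pattern))[[1]]
    fail(nchar(ok) + 1L)
  }
  class(m) <- "icd_matcher"
  m
}

#' @export
print.icd_matcher <- function(x, ...) {
  cat("ICD-10 matcher:", x$pattern, "\n")
  invisible(x)
}

# normalize a code to (letter, 2-digit block, subcode digits); NULL if it
# does not look like an ICD-10 code
parse_icd_code <- function(code) {
  code <- toupper(gsub("[. ]", "", trimws(code)))
  if (!grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", code)) return(NULL)
  list(letter = substr(code, 1, 1),
       block = as.integer(substr(code, 2, 3)),
       sub = substring(code, 4))
}

#' Test a code against a matcher
#'
#' @param matcher an [parse_icd_range()] result.
#' @param code an ICD-10 code such as `"I63.9"`; the dot is ignored.
#' @return `TRUE`/`FALSE`; `NA` if `code` is not a well-formed ICD-10 code.
#' @export
icd_matches <- function(matcher, code) {
  stopifnot(inherits(matcher, "icd_matcher"))
  pc <- parse_icd_code(code)
  if (is.null(pc)) return(NA)
  if (matcher$letter == matcher$letter2) {
    if (pc$letter != matcher$letter) return(FALSE)
    if (pc$block < matcher$lo || pc$block > matcher$hi) return(FALSE)
  } else {
    lo_key <- paste0(matcher$letter, sprintf("%02d", matcher$lo))
    hi_key <- paste0(matcher$letter2, sprintf("%02d", matcher$hi))
    key <- paste0(pc$letter, sprintf("%02d", pc$block))
    if (key < lo_key || key > hi_key) return(FALSE)
  }
  if (!is.na(matcher$sub) && !startsWith(pc$sub, matcher$sub)) return(FALSE)
  TRUE
}

split_patterns <- function(field) {
  if (is.na(field) || !nzchar(trimws(field))) return(character(0))
  trimws(strsplit(field, ";", fixed = TRUE)[[1]])
}

#' Load the amenable-cause rule set
#'
#' Reads a rule file — by default the packaged list of causes of death
#' considered amenable to health care — and compiles each row's ICD-10
#' patterns and exclusions into matchers.
#'
#' @param path rule CSV with columns `cause_label,place,timing,age_min,
#'   age_max,icd_patterns,exclusions` (patterns `;`-separated); defaults to
#'   the packaged file.
#' @return A data frame of class `amenable_rules` with list-columns
#'   `matchers` and `excl_matchers`.
#' @export
amenable_rules <- function(path = system.file("extdata",
                                              "amenable_rules.csv",
                                              package = "concsim")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cause_label", "place", "timing", "age_min", "age_max",
              "icd_patterns", "exclusions")
  if (!all(needed %in% names(df)))
    stop("rule file is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  df$matchers <- lapply(df$icd_patterns,
                        function(s) lapply(split_patterns(s), parse_icd_range))
  df$excl_matchers <- lapply(df$exclusions,
                             function(s) lapply(split_patterns(s),
                                                parse_icd_range))
  stopifnot(all(df$age_min <= df$age_max))
  class(df) <- c("amenable_rules", "data.frame")
  df
}

#' Write a rule set back to CSV
#'
#' Serializes the plain columns of an [amenable_rules()] object; re-reading
#' the file yields identical matchers (round-trip property).
#'
#' @param rules an `amenable_rules` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_amenable_rules <- function(rules, path) {
  utils::write.csv(rules[, c("cause_label", "place", "timing", "age_min",
                             "age_max", "icd_patterns", "exclusions")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify a death as amenable to health care
#'
#' Returns every rule whose ICD-10 pattern matches the code, whose
#' exclusion list does not, and whose age window contains the age.  An
#' empty result means "not amenable".  Overlapping rules all match; the
#' classifier does not rank them.
#'
#' @param icd ICD-10 code of the underlying cause (e.g. `"I63.9"`).
#' @param age age at death in whole years.
#' @param rules rule set, defaulting to the packaged list.
#' @return The matching rows of `rules` (zero rows if not amenable).
#'   An unparseable code yields zero rows with a warning.
#' @examples
#' rules <- amenable_rules()
#' classify_amenable("A37", 10, rules)$cause_label   # whooping cough
#' nrow(classify_amenable("A37", 20, rules))         # 0: outside age window
#' @export
classify_amenable <- function(icd, age, rules = amenable_rules()) {
  stopifnot(inherits(rules, "amenable_rules"), age >= 0)
  if (is.null(parse_icd_code(icd))) {
    warning(sprintf("'%s' is not a well-formed ICD-10 code", icd))
    return(rules[0L, ])
  }
  hit <- vapply(seq_len(nrow(rules)), function(r) {
    if (age < rules$age_min[r] || age > rules$age_max[r]) return(FALSE)
    inc <- any(vapply(rules$matchers[[r]], icd_matches, logical(1),
                      code = icd))
    if (!inc) return(FALSE)
    exc <- rules$excl_matchers[[r]]
    !(length(exc) && any(vapply(exc, icd_matches, logical(1), code = icd)))
  }, logical(1))
  rules[hit, ]
}

#' Is a (code, age) pair amenable?
#'
#' @inheritParams classify_amenable
#' @return Single logical.
#' @export
is_amenable <- function(icd, age, rules = amenable_rules()) {
  nrow(classify_amenable(icd, age, rules)) > 0L
}
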