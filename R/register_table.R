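#' Aggregated register count table
#'
#' Container for death counts and person-years cross-classified by age group
#' and socioeconomic group (SEG).  The SEG ordering is an explicit attribute
#' of the object, running from the least to the most advantaged group; it is
#' never inferred from the group labels.  The table must be dense: every
#' (age group, SEG) cell is present, deaths are non-negative integers and
#' person-years are strictly positive.
#'
#' @param deaths integer matrix of death counts, age groups in rows, SEGs in
#'   columns (ordered least to most advantaged).
#' @param person_years numeric matrix of person-years at risk, same shape and
#'   dimnames as `deaths`.
#' @param age_groups,seg_groups optional character labels; default to the
#'   dimnames of `deaths`.
#' @return An object of class `register_table` with elements `deaths`,
#'   `person_years`, `age_groups`, `seg_groups`.
#' @examples
#' d <- matrix(c(5, 3, 2, 1), 2, 2,
#'             dimnames = list(c("1-39", "40-74"), c("low", "high")))
#' p <- matrix(1e4, 2, 2, dimnames = dimnames(d))
#' register_table(d, p)
#' @export
register_table <- function(deaths, person_years,
                           age_groups = rownames(deaths),
                           seg_groups = colnames(deaths)) {
  deaths <- as.matrix(deaths)
  person_years <- as.matrix(person_years)
  if (is.null(age_groups)) age_groups <- paste0("age", seq_len(nrow(deaths)))
  if (is.null(seg_groups)) seg_groups <- paste0("seg", seq_len(ncol(deaths)))
  age_groups <- as.character(age_groups)
  seg_groups <- as.character(seg_groups)
  if (!all(dim(deaths) == dim(person_years)))
    stop("`deaths` and `person_years` must have identical dimensions")
  if (nrow(deaths) != length(age_groups) || ncol(deaths) != length(seg_groups))
    stop("label lengths do not match the count matrices")
  if (ncol(deaths) < 2L)
    stop("at least two socioeconomic groups are required (G >= 2)")
  if (nrow(deaths) < 1L)
    stop("at least one age group is required (I >= 1)")
  if (anyNA(deaths) || anyNA(person_years))
    stop("missing cells: the table must be dense")
  if (any(deaths < 0) || any(deaths != round(deaths)))
    stop("`deaths` must be non-negative integer counts")
  if (any(person_years <= 0)) {
    bad <- which(person_years <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive person-years in cell (age '%s', seg '%s')",
                 age_groups[bad[1L]], seg_groups[bad[2L]]))
  }
  storage.mode(deaths) <- "double"       # one storage mode, whatever the input
  storage.mode(person_years) <- "double"
  dimnames(deaths) <- dimnames(person_years) <- list(age_groups, seg_groups)
  structure(list(deaths = deaths, person_years = person_years,
                 age_groups = age_groups, seg_groups = seg_groups),
            class = "register_table")
}

#' @export
print.register_table <- function(x, ...) {
  cat(sprintf("Aggregated register table: %d age groups x %d SEGs\n",
              length(x$age_groups), length(x$seg_groups)))
  cat(sprintf("  total deaths %d, total person-years %.0f\n",
              sum(x$deaths), sum(x$person_years)))
  cat("  SEG order (least -> most advantaged): ",
      paste(x$seg_groups, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Reverse the socioeconomic ordering of a register table
#'
#' Utility mainly for sign-convention checks: the concentration index of the
#' reversed table is the negative of the original.
#' @param table a [register_table()].
#' @return A `register_table` with SEG columns in reversed order.
#' @export
reverse_seg_order <- function(table) {
  stopifnot(inherits(table, "register_table"))
  idx <- rev(seq_along(table$seg_groups))
  register_table(table$deaths[, idx, drop = FALSE],
                 table$person_years[, idx, drop = FALSE])
}

#' Standard population weights
#'
#' Age-group weights for direct standardization.  Whatever the scale of the
#' input, the weights are normalized at construction so that they sum to
#' exactly 100,000, the convention under which standardized rates are read
#' as events per 100,000 person-years.
#'
#' @param weights positive numeric vector of age-group weights.
#' @param age_groups labels, defaulting to `names(weights)`.
#' @return An object of class `standard_population` with elements `weights`
#'   (summing to 100,000) and `age_groups`.
#' @export
standard_population <- function(weights, age_groups = names(weights)) {
  force(age_groups)
  weights <- as.numeric(weights)
  if (is.null(age_groups)) age_groups <- paste0("age", seq_along(weights))
  age_groups <- as.character(age_groups)
  if (length(weights) != length(age_groups))
    stop("weights and age-group labels differ in length")
  if (anyNA(weights) || any(weights <= 0))
    stop("standard-population weights must be positive")
  w <- weights / sum(weights) * 1e5
  # floating-point sum after rescaling can miss 100,000 by a few ulp;
  # absorb the discrepancy into the largest weight so the sum is exact
  for (k in 1:5) {
    delta <- 1e5 - sum(w)
    if (delta == 0) break
    i <- which.max(w)
    w[i] <- w[i] + delta
  }
  names(w) <- age_groups
  structure(list(weights = w, age_groups = age_groups),
            class = "standard_population")
}

#' @export
print.standard_population <- function(x, ...) {
  cat(sprintf("Standard population: %d age groups, weights sum to %.0f\n",
              length(x$weights), sum(x$weights)))
  invisible(x)
}

# Align a standard population to a table's age groups; labeled error on
# mismatch so callers never silently standardize against the wrong bands.
align_stdpop <- function(table, stdpop) {
  stopifnot(inherits(table, "register_table"),
            inherits(stdpop, "standard_population"))
  if (!setequal(table$age_groups, stdpop$age_groups) ||
      length(table$age_groups) != length(stdpop$age_groups)) {
    missing_w <- setdiff(table$age_groups, stdpop$age_groups)
    extra_w <- setdiff(stdpop$age_groups, table$age_groups)
    stop(sprintf(paste0(
      "age-group labels of the table and standard population do not match",
      " (missing weights: %s; unused weights: %s)"),
      if (length(missing_w)) paste(missing_w, collapse = ", ") else "none",
      if (length(extra_w)) paste(extra_w, collapse = ", ") else "none"))
  }
  stdpop$weights[table$age_groups]
}
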