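# CSV readers/writers for the documented file dialects and the
# method-comparison driver.

#' Read an aggregated count table from CSV
#'
#' Long-format dialect with header
#' `age_group,seg,seg_order,deaths,person_years`; `seg_order` is the
#' explicit socioeconomic ordering (integer 1..G, 1 = least advantaged) —
#' it is required, never inferred from the labels.  The table must be
#' dense; validation errors name the offending rows or cells.
#'
#' @param path CSV file path.
#' @return A [register_table()]; age groups keep their order of first
#'   appearance in the file.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("age_group", "seg", "seg_order", "deaths", "person_years")
  if (!all(needed %in% names(df)))
    stop("counts file must have columns ", paste(needed, collapse = ","),
         "; missing: ", paste(setdiff(needed, names(df)), collapse = ", "))
  bad <- which(df$deaths < 0 | df$deaths != round(df$deaths))
  if (length(bad))
    stop("non-integer or negative deaths in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!(df$person_years > 0))
  if (length(bad))
    stop("non-positive person-years in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  ord <- unique(df[, c("seg", "seg_order")])
  if (anyDuplicated(ord$seg) || anyDuplicated(ord$seg_order))
    stop("inconsistent seg_order: each seg needs exactly one order value")
  G <- nrow(ord)
  if (!setequal(ord$seg_order, seq_len(G)))
    stop("seg_order must be the integers 1..G; got: ",
         paste(sort(ord$seg_order), collapse = ", "))
  segs <- ord$seg[order(ord$seg_order)]
  ages <- unique(df$age_group)
  key <- paste(df$age_group, df$seg, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate cell (age '%s', seg '%s')",
                 dup$age_group, dup$seg))
  }
  full <- expand.grid(age_group = ages, seg = segs,
                      stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$age_group, full$seg, sep = "\r"), key)
  if (length(missing)) {
    cell <- strsplit(missing[1L], "\r", fixed = TRUE)[[1]]
    stop(sprintf("missing cell (age '%s', seg '%s'): the table must be dense",
                 cell[1L], cell[2L]))
  }
  d <- matrix(NA_real_, length(ages), G, dimnames = list(ages, segs))
  p <- d
  d[cbind(df$age_group, df$seg)] <- df$deaths
  p[cbind(df$age_group, df$seg)] <- df$person_years
  register_table(d, p)
}

#' Write an aggregated count table to CSV
#'
#' Inverse of [read_counts_csv()]: a write-then-read round trip reproduces
#' the table exactly.
#'
#' @param table a [register_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(table, path) {
  stopifnot(inherits(table, "register_table"))
  df <- data.frame(
    age_group = rep(table$age_groups, times = length(table$seg_groups)),
    seg = rep(table$seg_groups, each = length(table$age_groups)),
    seg_order = rep(seq_along(table$seg_groups),
                    each = length(table$age_groups)),
    deaths = as.vector(table$deaths),
    # full precision so the write -> read round trip is bit-exact
    person_years = sprintf("%.17g", as.vector(table$person_years)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read standard-population weights from CSV
#'
#' Dialect `age_group,weight`; weights are normalized to sum to 100,000 at
#' load regardless of the file's scale.
#'
#' @param path CSV file path.
#' @return A [standard_population()].
#' @export
read_stdpop_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_group", "weight") %in% names(df)))
    stop("standard-population file must have columns age_group,weight")
  standard_population(stats::setNames(df$weight, df$age_group))
}

#' Write standard-population weights to CSV
#' @param stdpop a [standard_population()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stdpop_csv <- function(stdpop, path) {
  stopifnot(inherits(stdpop, "standard_population"))
  utils::write.csv(data.frame(age_group = stdpop$age_groups,
                              weight = unname(stdpop$weights)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Compare interval methods on one dataset
#'
#' Runs any subset of the seven interval procedures (REG, KWV, MC, MC_RATE,
#' BIN, POIS, MN) on the same table and returns one row per method with the
#' shared observed-data point estimate, the bounds and the interval length
#' (upper minus lower).  Each simulation method draws from an independent
#' substream derived from the master seed and the method's position in the
#' canonical method list, so adding or removing a method never perturbs the
#' others' results.
#'
#' @param table a [register_table()].
#' @param stdpop a matching [standard_population()].
#' @param methods character vector of method names (case-insensitive;
#'   `"all"` for all seven).
#' @param n_replicates,seed,alpha,estimator passed into [sim_config()] for
#'   the simulation methods; `alpha` also sets the analytic intervals.
#' @param kwv_n_obs optional KWV denominator override (default: G).
#' @return A data frame, one row per requested method, with attribute
#'   `"intervals"` holding the full `interval_estimate` objects.
#' @export
run_compare <- function(table, stdpop, methods = "all",
                        n_replicates = 10000L, seed = 1L, alpha = 0.05,
                        estimator = "formula", kwv_n_obs = NULL) {
  if (identical(methods, "all")) methods <- ALL_METHODS
  methods <- vapply(methods, normalize_method, character(1),
                    USE.NAMES = FALSE)
  if (!length(methods)) stop("at least one method must be requested")
  profile <- build_seg_profile(table, stdpop)
  ests <- lapply(methods, function(m) {
    if (m == "REG")
      return(reg_interval(concentration_index_wls(profile), alpha = alpha))
    if (m == "KWV")
      return(kwv_interval(profile, alpha = alpha, n_obs = kwv_n_obs))
    sub_seed <- (as.integer(seed) + 7919L * match(m, ALL_METHODS)) %%
      2147483647L
    cfg <- sim_config(method = m,
                      estimator = if (m == "MC") "wls" else estimator,
                      n_replicates = n_replicates, seed = sub_seed,
                      alpha = alpha)
    run_interval(table, stdpop, cfg)
  })
  out <- do.call(rbind, lapply(ests, as.data.frame))
  attr(out, "intervals") <- stats::setNames(ests, methods)
  out
}
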