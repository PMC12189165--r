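#' @keywords internal
"_PACKAGE"

# Known osteological collections. "other" is a catch-all so the pipeline
# generalizes beyond the four study collections.
.known_collections <- c("Vienna", "Graz", "Terzer", "NMDID", "other")

.cohort_columns <- c("specimen_id", "collection", "sex", "age_years",
                     "lateral_angle_deg", "aub_mm", "excluded_flag",
                     "exclusion_reason")

#' Construct and validate a cohort table
#'
#' A cohort table is a data frame with one row per specimen and columns
#' `specimen_id`, `collection`, `sex` (`"F"`/`"M"`), `age_years` (decimal
#' years), `lateral_angle_deg` (degrees, strictly inside (0, 90), may be
#' `NA`), `aub_mm` (biauricular breadth in mm, strictly inside (40, 180),
#' may be `NA`), `excluded_flag` (logical) and `exclusion_reason` (text).
#' Missing measurement columns are added as all-`NA`; missing flags default
#' to `FALSE`. Rows failing validation raise errors that name the offending
#' row.
#'
#' @param x a data frame with at least `specimen_id`, `collection`, `sex`
#'   and `age_years`.
#' @param line_offset integer added to row indices in error messages (used
#'   by [read_cohort_table()] so messages cite file line numbers).
#' @return a data frame of class `"cohort_table"`.
#' @export
as_cohort_table <- function(x, line_offset = 0L) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("specimen_id", "collection", "sex", "age_years")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L)
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  if (!"lateral_angle_deg" %in% names(x)) x$lateral_angle_deg <- NA_real_
  if (!"aub_mm" %in% names(x)) x$aub_mm <- NA_real_
  if (!"excluded_flag" %in% names(x)) x$excluded_flag <- FALSE
  if (!"exclusion_reason" %in% names(x)) x$exclusion_reason <- ""

  x$specimen_id <- as.character(x$specimen_id)
  x$collection <- as.character(x$collection)
  x$sex <- as.character(x$sex)
  x$age_years <- as.numeric(x$age_years)
  x$lateral_angle_deg <- as.numeric(x$lateral_angle_deg)
  x$aub_mm <- as.numeric(x$aub_mm)
  x$excluded_flag <- .as_flag(x$excluded_flag)
  x$exclusion_reason[is.na(x$exclusion_reason)] <- ""
  x$exclusion_reason <- as.character(x$exclusion_reason)

  where <- function(i) paste0("row ", i + line_offset,
                              " (specimen_id '", x$specimen_id[i], "')")

  bad <- which(is.na(x$sex) | !(x$sex %in% c("F", "M")))
  if (length(bad) > 0L)
    stop("unknown sex code '", x$sex[bad[1L]], "' in ", where(bad[1L]),
         "; sex must be 'F' or 'M'", call. = FALSE)

  bad <- which(is.na(x$age_years) | x$age_years < 0)
  if (length(bad) > 0L)
    stop("missing or negative age_years in ", where(bad[1L]), call. = FALSE)

  unknown <- !(x$collection %in% .known_collections)
  if (any(unknown)) {
    warning("unknown collection(s) ",
            paste(sQuote(unique(x$collection[unknown])), collapse = ", "),
            " mapped to 'other'", call. = FALSE)
    x$collection[unknown] <- "other"
  }

  # Strict physiological ranges; sentinels like -1 for "missing" are
  # rejected rather than silently treated as data.
  bad <- which(!is.na(x$lateral_angle_deg) &
                 (x$lateral_angle_deg <= 0 | x$lateral_angle_deg >= 90))
  if (length(bad) > 0L)
    stop("lateral_angle_deg out of (0, 90) in ", where(bad[1L]),
         "; encode missing values as empty cells, not sentinels",
         call. = FALSE)

  bad <- which(!is.na(x$aub_mm) & (x$aub_mm <= 40 | x$aub_mm >= 180))
  if (length(bad) > 0L)
    stop("aub_mm out of (40, 180) in ", where(bad[1L]),
         "; encode missing values as empty cells, not sentinels",
         call. = FALSE)

  x <- x[, .cohort_columns]
  rownames(x) <- NULL
  class(x) <- c("cohort_table", "data.frame")
  x
}

.as_flag <- function(v) {
  if (is.logical(v)) {
    v[is.na(v)] <- FALSE
    return(v)
  }
  out <- tolower(trimws(as.character(v))) %in% c("true", "t", "1", "yes")
  out
}

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 delimited text file with a header row and validates it
#' with [as_cohort_table()]. Empty cells are missing values; malformed rows
#' are reported with their file line number.
#'
#' @param path path to the file (or a connection).
#' @param sep field separator; comma by default, tab accepted.
#' @param dec decimal mark.
#' @return a `cohort_table`.
#' @export
read_cohort_table <- function(path, sep = ",", dec = ".") {
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", encoding = "UTF-8",
                          quote = "\"", comment.char = "")
  # header is line 1, so data row i sits on file line i + 1
  as_cohort_table(df, line_offset = 1L)
}

#' Write a cohort table as delimited text
#'
#' Missing measurements are written as empty cells so that
#' `read_cohort_table(write_cohort_table(x, f))` round-trips.
#'
#' @param x a `cohort_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort_table"))
  out <- as.data.frame(x)
  for (col in c("age_years", "lateral_angle_deg", "aub_mm")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.12g", v))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", nrow(x), " specimens (",
      sum(x$sex == "F"), " F / ", sum(x$sex == "M"), " M), ",
      sum(!is.na(x$lateral_angle_deg)), " with lateral angle, ",
      sum(!is.na(x$aub_mm)), " with biauricular breadth\n", sep = "")
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Exclusion rules for a cohort
#'
#' Rules mirror the study design: a global age cap (inclusion up to 30
#' years), per-collection age caps (the Graz collection is capped at 21
#' years because its older subjects formed a deviating cluster), and
#' removal of rows flagged for trauma/pathology.
#'
#' @param max_age_years global maximum age in years.
#' @param collection_age_caps named numeric vector mapping collection to
#'   its maximum age.
#' @param drop_flagged drop rows whose `excluded_flag` is `TRUE`?
#' @return an object of class `"exclusion_rules"`.
#' @export
exclusion_rules <- function(max_age_years = 30,
                            collection_age_caps = c(Graz = 21),
                            drop_flagged = TRUE) {
  if (length(collection_age_caps) > 0L) {
    if (is.null(names(collection_age_caps)) ||
        any(!nzchar(names(collection_age_caps))))
      stop("collection_age_caps must be a named vector", call. = FALSE)
    unknown <- setdiff(names(collection_age_caps), .known_collections)
    if (length(unknown) > 0L)
      stop("collection_age_caps names unknown collection(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(collection_age_caps < 0)) stop("age caps must be >= 0")
  }
  if (max_age_years < 0) stop("max_age_years must be >= 0")
  structure(list(max_age_years = max_age_years,
                 collection_age_caps = collection_age_caps,
                 drop_flagged = isTRUE(drop_flagged)),
            class = "exclusion_rules")
}

#' Apply exclusion rules to a cohort table
#'
#' Removes rows violating any rule and logs, for each removed row, the
#' first rule it violated (checked in the order: global age cap,
#' per-collection age cap, trauma/pathology flag). Filtering is
#' order-independent and idempotent; an empty result is legal.
#'
#' @param table a `cohort_table`.
#' @param rules an [exclusion_rules()] object.
#' @return a list with components `table` (the retained `cohort_table`) and
#'   `log` (a data frame with columns `specimen_id`, `collection`,
#'   `age_years`, `rule`).
#' @export
apply_exclusions <- function(table, rules = exclusion_rules()) {
  stopifnot(inherits(table, "cohort_table"), inherits(rules, "exclusion_rules"))
  rule_hit <- rep(NA_character_, nrow(table))

  over_max <- table$age_years > rules$max_age_years
  rule_hit[over_max & is.na(rule_hit)] <- "max_age"

  caps <- rules$collection_age_caps
  if (length(caps) > 0L) {
    cap <- caps[table$collection]
    over_cap <- !is.na(cap) & table$age_years > cap
    rule_hit[over_cap & is.na(rule_hit)] <- "collection_age_cap"
  }

  if (rules$drop_flagged)
    rule_hit[table$excluded_flag & is.na(rule_hit)] <- "flagged"

  drop <- !is.na(rule_hit)
  log <- data.frame(specimen_id = table$specimen_id[drop],
                    collection = table$collection[drop],
                    age_years = table$age_years[drop],
                    rule = rule_hit[drop],
                    stringsAsFactors = FALSE)
  kept <- table[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("cohort_table", "data.frame")
  list(table = kept, log = log)
}

#' Descriptive summary by collection and sex
#'
#' One row per (collection, sex, variable) with the count of non-missing
#' values and their mean, n-1 sample standard deviation, median, min and
#' max, in a fixed deterministic order (collections in their canonical
#' order, then sex). A stratum with a single observation reports `NA` for
#' the standard deviation (the n-1 denominator is undefined); an empty
#' stratum reports `n = 0` and missing statistics.
#'
#' @param table a `cohort_table`.
#' @param variables measurement columns to summarize.
#' @return a data frame of class `"cohort_summary"`.
#' @export
summarize_cohort <- function(table,
                             variables = c("age_years", "lateral_angle_deg",
                                           "aub_mm")) {
  stopifnot(inherits(table, "cohort_table"), nrow(table) > 0L)
  stopifnot(all(variables %in% names(table)))
  colls <- intersect(.known_collections, unique(table$collection))
  sexes <- c("M", "F")
  rows <- list()
  for (v in variables) for (cl in colls) for (sx in sexes) {
    vals <- table[[v]][table$collection == cl & table$sex == sx]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    rows[[length(rows) + 1L]] <- data.frame(
      collection = cl, sex = sx, variable = v, n = n,
      mean = if (n > 0L) mean(vals) else NA_real_,
      sd = if (n > 1L) stats::sd(vals) else NA_real_,
      median = if (n > 0L) stats::median(vals) else NA_real_,
      min = if (n > 0L) min(vals) else NA_real_,
      max = if (n > 0L) max(vals) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$variable, variables),
                   match(out$collection, .known_collections),
                   match(out$sex, sexes)), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
summary.cohort_table <- function(object, ...) summarize_cohort(object, ...)

#' Published lateral-angle literature values
#'
#' Reference fixture of published lateral-angle means, standard deviations
#' and sex-classification accuracies across populations and measurement
#' methods (casts vs CT), illustrating the inter-population and
#' inter-method variability that motivates population-specific cut-offs.
#'
#' @return a data frame.
#' @export
lateral_angle_literature <- function() {
  utils::read.csv(system.file("extdata", "lateral_angle_literature.csv",
                              package = "petrousgrowth"),
                  stringsAsFactors = FALSE)
}

#' Published descriptive statistics of the four reference collections
#'
#' Reference fixture of the published per-collection, per-sex summary cells
#' (n, mean, sd, median, min, max) for age, lateral angle and biauricular
#' breadth in the Vienna, Graz and Terzer historical collections and the
#' NMDID sample. These are published summary statistics, not raw data; the
#' synthetic cohort generator is calibrated against them.
#'
#' @return a data frame in the same layout as [summarize_cohort()] output.
#' @export
reference_collection_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_collection_summary.csv",
                              package = "petrousgrowth"),
                  stringsAsFactors = FALSE)
}
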