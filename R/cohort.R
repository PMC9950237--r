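#' Grouped cohort tables
#'
#' A cohort table is a tibble with one row per stratum cell of a grouped
#' cohort (the unit of the grouped Poisson likelihood). Required columns:
#'
#' * `city`: `"hiroshima"` or `"nagasaki"`
#' * `nic`: logical, not-in-city group
#' * `sex`: `"male"` or `"female"`
#' * `age_at_exposure`: years (cell representative value, e)
#' * `attained_age`: years (cell representative value, a)
#' * `birth_year`: calendar year (byr)
#' * `dose`: weighted colon dose in Gy (gamma + 10 x neutron absorbed dose)
#' * `kerma_gt4`: logical, total shielded kerma above 4 Gy
#' * `pyr`: person-years at risk
#' * `cases`: solid-cancer case count
#'
#' Cells with `pyr == 0` are retained (so record counts match the source
#' file) but flagged in the `likelihood` column and excluded from fitting.
#'
#' @param x a data frame with the columns above.
#' @param provenance free-text origin of the table (file path or generator
#'   digest); stored as an attribute.
#' @return a validated `cohort_tbl` tibble.
#' @export
cohort_table <- function(x, provenance = "in-memory") {
  x <- tibble::as_tibble(x)
  missing <- setdiff(cohort_columns(), names(x))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::select(x, dplyr::all_of(cohort_columns()), dplyr::any_of("likelihood"))
  x$city <- validate_level(x$city, c("hiroshima", "nagasaki"), "city")
  x$sex <- validate_level(x$sex, c("male", "female"), "sex")
  x$nic <- as.logical(x$nic)
  x$kerma_gt4 <- as.logical(x$kerma_gt4)
  for (col in c("age_at_exposure", "attained_age", "birth_year", "dose", "pyr")) {
    x[[col]] <- validate_numeric(x[[col]], col)
  }
  x$cases <- validate_numeric(x$cases, "cases")
  validate_cohort(x)
  x$likelihood <- x$pyr > 0
  attr(x, "provenance") <- provenance
  class(x) <- c("cohort_tbl", class(tibble::tibble()))
  x
}

cohort_columns <- function() {
  c("city", "nic", "sex", "age_at_exposure", "attained_age", "birth_year",
    "dose", "kerma_gt4", "pyr", "cases")
}

validate_level <- function(x, levels, name) {
  x <- tolower(as.character(x))
  bad <- !x %in% levels
  if (any(bad)) {
    stop(sprintf("column '%s' has value(s) outside {%s} at row(s) %s", name,
                 paste(levels, collapse = ", "),
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  x
}

validate_numeric <- function(x, name) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- is.na(xn) & !is.na(x)
  if (any(bad) || anyNA(xn)) {
    stop(sprintf("column '%s' is non-numeric or missing at row(s) %s", name,
                 paste(utils::head(which(bad | is.na(xn)), 5), collapse = ", ")),
         call. = FALSE)
  }
  xn
}

validate_cohort <- function(x) {
  if (nrow(x) == 0) stop("cohort table is empty", call. = FALSE)
  check_rows <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("invalid cohort cell(s): %s at row(s) %s", what,
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  check_rows(x$pyr < 0, "pyr < 0")
  check_rows(x$cases < 0 | x$cases != round(x$cases), "cases not a non-negative integer")
  check_rows(x$dose < 0, "dose < 0")
  check_rows(x$attained_age < x$age_at_exposure, "attained_age < age_at_exposure")
  check_rows(x$pyr == 0 & x$cases > 0, "cases > 0 with pyr = 0")
  key <- do.call(paste, c(x[setdiff(cohort_columns(), c("pyr", "cases"))], sep = "\r"))
  check_rows(duplicated(key), "duplicate covariate combination")
  if (!all(is.finite(c(sum(x$pyr), sum(x$cases))))) {
    stop("pyr/cases totals are not finite", call. = FALSE)
  }
  invisible(x)
}

#' Default column mapping for the RERF lssinc07 grouped incidence file
#'
#' Best-effort mapping from the package's standard cohort fields to the
#' column names of the publicly distributed LSS solid-cancer incidence file
#' (lssinc07). The file's dialect is not under the package's control:
#' verify every entry against the downloaded file before use. Entries may
#' be a source column name (character) or a constant default (any other
#' type) used for fields the file does not carry.
#'
#' @return named list mapping standard field -> source column or constant.
#' @export
lss_column_map <- function() {
  list(
    city = "city",
    nic = "nic",
    sex = "sex",
    age_at_exposure = "agex",
    attained_age = "age",
    birth_year = 1945,          # derived: exposure year minus age at exposure
    dose = "colon10",           # weighted colon dose (neutron RBE 10), Gy
    kerma_gt4 = "over4gy",
    pyr = "pyr",
    cases = "solid"
  )
}

#' Read a grouped cohort table from a delimited text file
#'
#' Reads a CSV or TSV file (delimiter sniffed from the header line) and maps
#' its columns onto the standard cohort fields via `column_map`. Unknown
#' source columns are ignored. City and sex codings `0/1` are accepted
#' (`0 = hiroshima/male`, `1 = nagasaki/female`) alongside the literal
#' labels.
#'
#' @param path file path.
#' @param column_map named list mapping each standard field to a source
#'   column name (character) or to a constant default; see
#'   [lss_column_map()].
#' @param dose_unit_scale multiplier applied to the source dose column to
#'   obtain Gy (e.g. `0.001` for a file in mGy).
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, column_map = lss_column_map(), dose_unit_scale = 1) {
  stopifnot(is.numeric(dose_unit_scale), dose_unit_scale > 0)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  out <- list()
  for (field in cohort_columns()) {
    spec <- column_map[[field]]
    if (is.null(spec)) {
      stop("column_map does not cover field '", field, "'", call. = FALSE)
    }
    if (is.character(spec)) {
      if (!spec %in% names(raw)) {
        stop("mapped column '", spec, "' (field '", field,
             "') not found in ", path, call. = FALSE)
      }
      out[[field]] <- raw[[spec]]
    } else {
      out[[field]] <- rep(spec, nrow(raw))
    }
  }
  out <- tibble::as_tibble(out)
  out$city <- decode_binary(out$city, c("hiroshima", "nagasaki"))
  out$sex <- decode_binary(out$sex, c("male", "female"))
  out$dose <- validate_numeric(out$dose, "dose") * dose_unit_scale
  cohort_table(out, provenance = path)
}

decode_binary <- function(x, levels) {
  if (is.numeric(x) || all(as.character(x) %in% c("0", "1"))) {
    levels[as.integer(as.character(x)) + 1L]
  } else {
    x
  }
}

#' Write a cohort table as canonical CSV
#'
#' Fixed column order
#' `city,nic,sex,age_at_exposure,attained_age,birth_year,dose,kerma_gt4,pyr,cases`;
#' logicals written as 0/1 so the file round-trips through [read_cohort()].
#'
#' @param table a [cohort_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- tibble::as_tibble(table)[cohort_columns()]
  out$nic <- as.integer(out$nic)
  out$kerma_gt4 <- as.integer(out$kerma_gt4)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Cap doses at a maximum value
#'
#' Replaces every cell dose by `min(dose, cap)`. Used for model variants
#' that restrict the analysed dose range (survivors with estimated exposure
#' above the cap are assigned the cap).
#'
#' @param table a [cohort_table()].
#' @param cap dose cap in Gy; must be positive.
#' @return a new cohort table; the input is unmodified.
#' @export
truncate_dose <- function(table, cap = 4) {
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("cap must be a single positive dose in Gy", call. = FALSE)
  }
  out <- table
  out$dose <- pmin(out$dose, cap)
  out
}

#' Summarize a cohort table
#'
#' @param table a [cohort_table()].
#' @return one-row tibble with total person-years, total cases, cell count,
#'   dose range and the realized stratum counts of the two stratification
#'   schemes used by the stratified-baseline models (sex x city x age at
#'   exposure x attained age; sex x city x birth year x attained age).
#' @export
summarize_cohort <- function(table) {
  tibble::tibble(
    n_cells = nrow(table),
    total_pyr = sum(table$pyr),
    total_cases = sum(table$cases),
    dose_min = min(table$dose),
    dose_max = max(table$dose),
    n_strata_exposure_age = dplyr::n_distinct(
      paste(table$sex, table$city, table$age_at_exposure, table$attained_age)),
    n_strata_birth_year = dplyr::n_distinct(
      paste(table$sex, table$city, table$birth_year, table$attained_age))
  )
}
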