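#' Read a daily stage series
#'
#' Parses a CSV of daily river stage records with columns `date` (ISO 8601
#' calendar date) and `level_m` (stage in metres above the gauge datum).
#' Missing days are recorded, never interpolated: the series keeps only the
#' rows present in the file and the count of interior calendar gaps is stored
#' in the `n_gap_days` attribute.
#'
#' @param path Path to the CSV file.
#' @return A `"stage_series"` data frame with columns `date` (`Date`) and
#'   `level_m` (numeric), and attribute `n_gap_days`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("date,level_m", "2000-01-01,19.0", "2000-01-02,20.1"), f)
#' read_stage_series(f)
#' @export
read_stage_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty stage file: ", path, call. = FALSE)
  req <- c("date", "level_m")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("stage file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dates <- as.Date(tab$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable date at row ", which(is.na(dates))[1L], call. = FALSE)
  lev <- suppressWarnings(as.numeric(tab$level_m))
  if (anyNA(lev))
    stop("non-numeric level at row ", which(is.na(lev))[1L], call. = FALSE)
  if (anyDuplicated(dates))
    stop("duplicate date: ", format(dates[duplicated(dates)][1L]),
         call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing", call. = FALSE)
  out <- data.frame(date = dates, level_m = lev)
  attr(out, "n_gap_days") <-
    as.integer(as.numeric(dates[length(dates)] - dates[1L]) + 1L - nrow(out))
  class(out) <- c("stage_series", "data.frame")
  out
}

# shared schema checker: required columns error, extras warn
check_schema <- function(tab, required, what) {
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(what, " table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(tab), required)
  if (length(extra))
    warning(what, " table has unknown columns (ignored): ",
            paste(extra, collapse = ", "), call. = FALSE)
  tab[required]
}

#' Read fish survey tables
#'
#' Readers for the tabular survey inputs. Schemas:
#' \describe{
#'   \item{catch}{`date,species_id,count` — one row per species per sampling
#'     date; counts are individuals caught.}
#'   \item{effort}{`cycle_id,effort_m2` — total gillnet area fished per
#'     flood-pulse cycle.}
#'   \item{trait}{`species_id,max_sl_mm,maturation_sl_mm,fecundity,
#'     oocyte_diam_mm,parental_care_score` — the five life-history traits.}
#'   \item{diet}{`species_id,item_category,volume_prop` with categories in
#'     detritus, algae, plant, invertebrate, plankton, fish, other. Per
#'     species proportions are renormalised to sum to one (with a warning
#'     when the raw sum is off by more than 1e-6).}
#'   \item{labels}{`species_id,life_history,trophic_level` — expert
#'     functional-group assignments.}
#' }
#' Required columns missing is an error; unknown columns warn and are
#' dropped.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_catch_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty catch file: ", path, call. = FALSE)
  tab <- check_schema(tab, c("date", "species_id", "count"), "catch")
  tab$date <- as.Date(tab$date, format = "%Y-%m-%d")
  if (anyNA(tab$date)) stop("unparseable date in catch table", call. = FALSE)
  tab$count <- as.numeric(tab$count)
  if (anyNA(tab$count) || any(tab$count < 0))
    stop("catch counts must be non-negative numbers", call. = FALSE)
  tab
}

#' @rdname read_tables
#' @export
read_effort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty effort file: ", path, call. = FALSE)
  tab <- check_schema(tab, c("cycle_id", "effort_m2"), "effort")
  tab$effort_m2 <- as.numeric(tab$effort_m2)
  if (anyNA(tab$effort_m2) || any(tab$effort_m2 <= 0))
    stop("effort must be positive", call. = FALSE)
  if (anyDuplicated(tab$cycle_id))
    stop("duplicate cycle_id in effort table", call. = FALSE)
  tab
}

#' @rdname read_tables
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty trait file: ", path, call. = FALSE)
  req <- c("species_id", "max_sl_mm", "maturation_sl_mm", "fecundity",
           "oocyte_diam_mm", "parental_care_score")
  tab <- check_schema(tab, req, "trait")
  num <- req[-1L]
  tab[num] <- lapply(tab[num], as.numeric)
  if (anyNA(tab[num]) || any(as.matrix(tab[num]) <= 0))
    stop("trait values must be positive numbers", call. = FALSE)
  bad <- tab$maturation_sl_mm > tab$max_sl_mm
  if (any(bad))
    stop("maturation size exceeds maximum size for: ",
         paste(tab$species_id[bad], collapse = ", "), call. = FALSE)
  tab
}

diet_categories <- c("detritus", "algae", "plant", "invertebrate",
                     "plankton", "fish", "other")

#' @rdname read_tables
#' @export
read_diet_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty diet file: ", path, call. = FALSE)
  tab <- check_schema(tab, c("species_id", "item_category", "volume_prop"),
                      "diet")
  bad <- !tab$item_category %in% diet_categories
  if (any(bad))
    stop("unknown diet category: ",
         paste(unique(tab$item_category[bad]), collapse = ", "),
         call. = FALSE)
  tab$volume_prop <- as.numeric(tab$volume_prop)
  if (anyNA(tab$volume_prop) || any(tab$volume_prop < 0))
    stop("diet proportions must be non-negative", call. = FALSE)
  sums <- tapply(tab$volume_prop, tab$species_id, sum)
  if (any(sums == 0))
    stop("empty diet (all-zero proportions) for: ",
         paste(names(sums)[sums == 0], collapse = ", "), call. = FALSE)
  off <- abs(sums - 1) > 1e-6
  if (any(off))
    warning("diet proportions renormalised for: ",
            paste(names(sums)[off], collapse = ", "), call. = FALSE)
  tab$volume_prop <- as.numeric(tab$volume_prop / sums[tab$species_id])
  tab
}

#' @rdname read_tables
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty label file: ", path, call. = FALSE)
  tab <- check_schema(tab, c("species_id", "life_history", "trophic_level"),
                      "label")
  bad <- !tab$life_history %in% c("ES", "EL", "IS", "PL", "PS")
  if (any(bad))
    stop("unknown life-history label: ",
         paste(unique(tab$life_history[bad]), collapse = ", "),
         call. = FALSE)
  tab$trophic_level <- as.numeric(tab$trophic_level)
  bad <- !tab$trophic_level %in% c(1, 1.5, 2, 3)
  if (any(bad))
    stop("trophic level must be one of 1, 1.5, 2, 3", call. = FALSE)
  if (anyDuplicated(tab$species_id))
    stop("duplicate species_id in label table", call. = FALSE)
  tab
}

#' Write a result table as plain CSV
#'
#' Plain-text output so downstream tools need no custom parser; numbers are
#' written with full precision and round-trip through [utils::read.csv()].
#'
#' @param tab A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
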