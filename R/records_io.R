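# Data model, validation, CSV IO and championship scoring arithmetic.

CANONICAL_LINES <- c("Gurgul", "Goral", "Hroby", "Ousor", "Pietrosu", "Polan", "Prislop")

ROSTER_COLUMNS <- c("horse_id", "name", "sex", "year_of_birth", "coat",
                    "sire_line", "dam_family", "breeder", "owner_kind")
START_COLUMNS <- c("horse_id", "championship_year", "exterior", "hucul_path",
                   "rally", "position")
MARK_COLUMNS <- c("mark_type", "mark_conformation", "mark_walk", "mark_trot",
                  "mark_overall")
CSV_COLUMNS <- c("horse_id", "name", "sex", "year_of_birth", "coat",
                 "sire_line", "dam_family", "breeder", "owner_kind",
                 "championship_year", "exterior", "hucul_path", "rally",
                 "position")

#' Championship scoring rules
#'
#' The national Hucul performance championship scores three elements --
#' exterior evaluation (max 50 points), the Hucul path obstacle course
#' (max 80) and the endurance rally (max 80) -- and combines them with
#' fixed conversion factors 0.8, 1.25 and 0.75, so that a perfect pair
#' earns 200 points.
#'
#' @param weights Numeric length-3 conversion factors for
#'   (exterior, hucul_path, rally).
#' @param maxima Numeric length-3 per-element score ceilings.
#' @return An object of class `scoring_rules`.
#' @export
#' @examples
#' max_total_score(scoring_rules())  # 200
scoring_rules <- function(weights = c(exterior = 0.8, hucul_path = 1.25, rally = 0.75),
                          maxima = c(exterior = 50, hucul_path = 80, rally = 80)) {
  stopifnot(length(weights) == 3, length(maxima) == 3,
            all(is.finite(weights)), all(is.finite(maxima)), all(maxima >= 0))
  structure(list(weights = unname(weights), maxima = unname(maxima)),
            class = "scoring_rules")
}

#' Weighted championship total for one start
#'
#' @param exterior,hucul_path,rally Component scores, each within its
#'   ceiling under `rules`. Vectorised.
#' @param rules A [scoring_rules()] object.
#' @return Weighted total points.
#' @export
weighted_total_score <- function(exterior, hucul_path, rally, rules = scoring_rules()) {
  scores <- cbind(exterior, hucul_path, rally)
  if (any(!is.finite(scores))) stop("component scores must be finite", call. = FALSE)
  if (any(scores < 0) || any(t(t(scores) - rules$maxima) > 1e-9)) {
    stop("component score outside [0, maximum] for its element", call. = FALSE)
  }
  as.numeric(scores %*% rules$weights)
}

#' Maximum attainable championship total
#'
#' @param rules A [scoring_rules()] object.
#' @return The weighted total at the component ceilings.
#' @export
max_total_score <- function(rules = scoring_rules()) {
  sum(rules$weights * rules$maxima)
}

#' Construct a validated start-record dataset
#'
#' A dataset couples a horse roster (one row per horse: identity, sex,
#' year of birth, coat, sire line, dam family, breeder, ownership) with
#' start records (one row per horse-start: championship year, component
#' scores, finishing position). Horses become eligible at age 4 and may
#' start in several years.
#'
#' @param roster Data frame with columns horse_id, name, sex,
#'   year_of_birth, coat, sire_line, dam_family, breeder, owner_kind.
#' @param starts Data frame with columns horse_id, championship_year,
#'   exterior, hucul_path, rally, position (optional mark_* columns for
#'   the five expert evaluations, carried but never used as predictors).
#' @param validate If `FALSE`, skip invariant checks (used internally
#'   for null-model datasets whose positions are arbitrary labels).
#' @return An object of class `hucul_dataset`: list with `roster` and
#'   `starts` tibbles; `starts` gains a derived `age` column.
#' @export
hucul_dataset <- function(roster, starts, validate = TRUE) {
  roster <- tibble::as_tibble(roster)
  starts <- tibble::as_tibble(starts)
  missing_r <- setdiff(ROSTER_COLUMNS, names(roster))
  missing_s <- setdiff(START_COLUMNS, names(starts))
  if (length(missing_r) || length(missing_s)) {
    stop("schema error: missing columns: ",
         paste(c(missing_r, missing_s), collapse = ", "), call. = FALSE)
  }
  yob <- roster$year_of_birth[match(starts$horse_id, roster$horse_id)]
  starts$age <- as.integer(starts$championship_year - yob)
  ds <- structure(list(roster = roster, starts = starts), class = "hucul_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' Validate dataset invariants
#'
#' Checks: unique horse ids; non-empty sire lines; every start resolves
#' to a roster entry; ages >= 4; positions a strict permutation of
#' 1..n within each championship year; no duplicate (horse, year);
#' component scores within their ceilings. Violations are reported with
#' the offending row numbers.
#'
#' @param dataset A `hucul_dataset`.
#' @param rules Scoring rules for the component ceilings.
#' @return The dataset, invisibly, if valid; otherwise an error listing
#'   every violation.
#' @export
validate_dataset <- function(dataset, rules = scoring_rules()) {
  roster <- dataset$roster
  starts <- dataset$starts
  problems <- character()
  dup <- duplicated(roster$horse_id)
  if (any(dup)) {
    problems <- c(problems, paste0("roster row ", which(dup),
                                   ": duplicate horse_id '", roster$horse_id[dup], "'"))
  }
  bad_line <- !nzchar(trimws(as.character(roster$sire_line))) | is.na(roster$sire_line)
  if (any(bad_line)) {
    problems <- c(problems, paste0("roster row ", which(bad_line), ": empty sire_line"))
  }
  unknown <- !(starts$horse_id %in% roster$horse_id)
  if (any(unknown)) {
    problems <- c(problems, paste0("start row ", which(unknown),
                                   ": horse_id '", starts$horse_id[unknown],
                                   "' not in roster"))
  }
  under <- !is.na(starts$age) & starts$age < 4L
  if (any(under)) {
    problems <- c(problems, paste0("start row ", which(under), ": age ",
                                   starts$age[under], " < 4 (minimum eligible age)"))
  }
  key <- paste(starts$horse_id, starts$championship_year)
  dup2 <- duplicated(key)
  if (any(dup2)) {
    problems <- c(problems, paste0("start row ", which(dup2),
                                   ": duplicate (horse_id, year) ", key[dup2]))
  }
  for (yr in sort(unique(starts$championship_year))) {
    idx <- which(starts$championship_year == yr)
    pos <- starts$position[idx]
    if (anyNA(pos) || any(pos < 1) || any(pos != round(pos)) ||
        anyDuplicated(pos) || !setequal(pos, seq_along(pos))) {
      problems <- c(problems,
                    paste0("year ", yr, " (start rows ", paste(idx, collapse = ","),
                           "): positions are not a permutation of 1..", length(idx)))
    }
  }
  sc <- as.matrix(starts[, c("exterior", "hucul_path", "rally")])
  present <- stats::complete.cases(sc)
  if (any(present)) {
    over <- which(present)[rowSums(t(t(sc[present, , drop = FALSE]) - rules$maxima) > 1e-9) > 0 |
                             rowSums(sc[present, , drop = FALSE] < 0) > 0]
    if (length(over)) {
      problems <- c(problems, paste0("start row ", over,
                                     ": component score outside its [0, max] range"))
    }
  }
  if (length(problems)) {
    stop("integrity error:\n", paste("  -", problems, collapse = "\n"), call. = FALSE)
  }
  invisible(dataset)
}

#' @export
print.hucul_dataset <- function(x, ...) {
  cat("<hucul_dataset> ", nrow(x$roster), " horses, ", nrow(x$starts),
      " starts, years ", min(x$starts$championship_year), "-",
      max(x$starts$championship_year), "\n", sep = "")
  invisible(x)
}

# Accept both "12.9" and Polish-style "12,9" in numeric fields.
parse_flexible_number <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
}

#' Read a start-record dataset from CSV
#'
#' One row per horse-start with the flat columns listed under
#' [hucul_dataset()] (roster traits repeated on every row). Numeric
#' fields accept both the decimal point and the Polish decimal comma.
#' The roster is reconstructed from the distinct horses; conflicting
#' trait values for the same horse_id are an error.
#'
#' @param path CSV file with a header row.
#' @return A validated `hucul_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(CSV_COLUMNS, names(raw))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("year_of_birth", "championship_year", "exterior", "hucul_path",
                "rally", "position", intersect(MARK_COLUMNS, names(raw)))) {
    raw[[col]] <- parse_flexible_number(raw[[col]])
  }
  raw$sire_line <- canonicalize_category(raw$sire_line, CANONICAL_LINES)
  roster <- dplyr::distinct(raw[, ROSTER_COLUMNS])
  clash <- roster$horse_id[duplicated(roster$horse_id)]
  if (length(clash)) {
    stop("integrity error: conflicting roster traits for horse_id ",
         paste(unique(clash), collapse = ", "), call. = FALSE)
  }
  starts <- raw[, c(START_COLUMNS, intersect(MARK_COLUMNS, names(raw)))]
  starts$championship_year <- as.integer(starts$championship_year)
  starts$position <- as.integer(starts$position)
  roster$year_of_birth <- as.integer(roster$year_of_birth)
  hucul_dataset(roster, starts)
}

# Case-insensitive, trimmed matching against a preferred spelling list;
# unmatched values keep their trimmed form (vocabulary is open).
canonicalize_category <- function(x, preferred) {
  x <- trimws(as.character(x))
  hit <- match(tolower(x), tolower(preferred))
  ifelse(is.na(hit), x, preferred[hit])
}

#' Write a dataset to CSV
#'
#' Emits the flat one-row-per-start layout read by [read_dataset()],
#' always with the decimal point. `read_dataset(write_dataset(d))`
#' reproduces `d` field for field; roster entries of horses without any
#' start are not representable in the flat layout and are dropped.
#'
#' @param dataset A `hucul_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  starts <- dataset$starts
  flat <- dplyr::left_join(starts, dataset$roster, by = "horse_id")
  cols <- c(CSV_COLUMNS, intersect(MARK_COLUMNS, names(flat)))
  readr::write_csv(flat[, cols], path, progress = FALSE)
  invisible(path)
}
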