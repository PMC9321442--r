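# Pedigree-line start-efficiency coefficients and descriptive
# aggregations of championship results.

#' Start-efficiency coefficient of a line in one championship
#'
#' SR = 1/(n * m), where n is the number of horses from the line that
#' started in the championship and m the position credited to the line.
#' It attains its maximum, 1, when a single horse from the line starts
#' and finishes first; more starters or worse positions lower it.
#'
#' @param n Integer >= 1, the line's starter count. Vectorised.
#' @param m Integer >= 1, the position credited to the line.
#' @return SR in (0, 1].
#' @export
#' @examples
#' sr_coefficient(1, 1)  # 1
#' sr_coefficient(2, 2)  # 0.25
sr_coefficient <- function(n, m) {
  if (any(n < 1) || any(m < 1) || any(n != round(n)) || any(m != round(m))) {
    stop("n and m must be integers >= 1", call. = FALSE)
  }
  1 / (n * m)
}

#' Average start-efficiency coefficient of a line
#'
#' The plain arithmetic mean of a line's SR values over the k
#' championships it entered; championships without a starter from the
#' line contribute no term.
#'
#' @param srs Non-empty numeric vector of SR values in (0, 1].
#' @return ASR in (0, 1].
#' @export
asr_coefficient <- function(srs) {
  if (length(srs) == 0) stop("asr_coefficient: empty SR sequence", call. = FALSE)
  if (any(srs <= 0) || any(srs > 1)) {
    stop("SR values must lie in (0, 1]", call. = FALSE)
  }
  mean(srs)
}

#' Per-line, per-year competition statistics
#'
#' For every (sire line, championship year) with at least one starter:
#' n, the line's starter count that year; m, the position credited to
#' the line; and sr = 1/(n*m). When a line fields several horses, `m`
#' follows `m_rule`: `"best"` (default) uses the line's best (minimum)
#' position, giving one SR per line and competition;
#' `"per_horse_mean"` instead averages 1/(n*m_h) over the line's
#' individual starters.
#'
#' @param dataset A `hucul_dataset`.
#' @param m_rule `"best"` or `"per_horse_mean"`.
#' @return Tibble with columns line, year, n, m, sr (for
#'   `"per_horse_mean"`, `m` is the best position but `sr` the
#'   per-starter mean).
#' @export
line_competition_stats <- function(dataset, m_rule = c("best", "per_horse_mean")) {
  m_rule <- match.arg(m_rule)
  joined <- dplyr::left_join(dataset$starts, dataset$roster[, c("horse_id", "sire_line")],
                             by = "horse_id")
  out <- joined |>
    dplyr::group_by(line = .data$sire_line, year = .data$championship_year) |>
    dplyr::summarise(
      n = dplyr::n(),
      m = min(.data$position),
      sr = if (m_rule == "best") 1 / (dplyr::n() * min(.data$position))
           else mean(1 / (dplyr::n() * .data$position)),
      .groups = "drop") |>
    dplyr::arrange(.data$line, .data$year)
  out
}

#' Per-line summaries: ASR, wins, mean positions
#'
#' @param dataset A `hucul_dataset`.
#' @param m_rule Passed to [line_competition_stats()].
#' @return Tibble with one row per line: `k` championships entered,
#'   `asr`, `wins`, `win_fraction` (wins over championships entered),
#'   and `mean_position_by_year`, a list-column of named vectors
#'   (year -> mean finishing position of the line's starters).
#' @export
line_summary <- function(dataset, m_rule = "best") {
  stats_ly <- line_competition_stats(dataset, m_rule)
  joined <- dplyr::left_join(dataset$starts, dataset$roster[, c("horse_id", "sire_line")],
                             by = "horse_id")
  mp <- joined |>
    dplyr::group_by(line = .data$sire_line, year = .data$championship_year) |>
    dplyr::summarise(mean_pos = mean(.data$position), .groups = "drop")
  wins <- joined |>
    dplyr::group_by(line = .data$sire_line) |>
    dplyr::summarise(wins = sum(.data$position == 1L), .groups = "drop")
  stats_ly |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(k = dplyr::n(), asr = asr_coefficient(.data$sr),
                     .groups = "drop") |>
    dplyr::left_join(wins, by = "line") |>
    dplyr::mutate(win_fraction = .data$wins / .data$k,
                  mean_position_by_year = lapply(.data$line, function(l) {
                    sub <- mp[mp$line == l, ]
                    stats::setNames(sub$mean_pos, sub$year)
                  })) |>
    dplyr::arrange(dplyr::desc(.data$asr))
}

#' Finishing positions tabulated by age
#'
#' One row per age observed in the data: counts of places 1-6, their
#' total, the mean finishing position over all the age's starts (not
#' only the top six), and the number of starts.
#'
#' @param dataset A `hucul_dataset`.
#' @return Tibble with columns age, place_1..place_6, top6_total,
#'   mean_position, n_starts.
#' @export
age_position_table <- function(dataset) {
  starts <- dataset$starts
  ages <- sort(unique(starts$age))
  out <- lapply(ages, function(a) {
    pos <- starts$position[starts$age == a]
    counts <- vapply(1:6, function(p) sum(pos == p), integer(1))
    tibble::tibble(age = a,
                   place_1 = counts[1], place_2 = counts[2], place_3 = counts[3],
                   place_4 = counts[4], place_5 = counts[5], place_6 = counts[6],
                   top6_total = sum(counts),
                   mean_position = mean(pos),
                   n_starts = length(pos))
  })
  dplyr::bind_rows(out)
}

#' Wins and win fractions by a categorical trait
#'
#' For each level of the chosen trait: the number of victories
#' (position 1), the number of starts, the number of championships in
#' which the group had at least one starter, and the win fraction
#' (victories over championships entered).
#'
#' @param dataset A `hucul_dataset`.
#' @param group_by One of sire_line, dam_family, sex, coat, breeder,
#'   owner_kind.
#' @return Tibble with columns group, wins, n_starts, n_competitions,
#'   win_fraction; groups with no starts are absent.
#' @export
wins_by_group <- function(dataset, group_by = "sire_line") {
  allowed <- c("sire_line", "dam_family", "sex", "coat", "breeder", "owner_kind")
  if (!group_by %in% allowed) {
    stop("unknown trait '", group_by, "'; expected one of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(dataset$starts,
                             dataset$roster[, c("horse_id", group_by)],
                             by = "horse_id")
  joined |>
    dplyr::group_by(group = .data[[group_by]]) |>
    dplyr::summarise(wins = sum(.data$position == 1L),
                     n_starts = dplyr::n(),
                     n_competitions = dplyr::n_distinct(.data$championship_year),
                     .groups = "drop") |>
    dplyr::mutate(win_fraction = .data$wins / .data$n_competitions) |>
    dplyr::arrange(dplyr::desc(.data$wins))
}
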