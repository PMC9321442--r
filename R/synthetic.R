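# Synthetic championship generator with planted, recoverable ability
# structure: line effect + dam-family effect + age curve + per-horse
# baseline + per-start noise. Within-year positions are the descending
# ranks of realized ability, so every downstream statistic has a known
# ground truth.

#' Default age-ability curve
#'
#' Ability offset by age, peaking around ages 10-11 (the ages with the
#' best average placings in the study population) and falling off toward
#' the eligibility age of 4 and late teens.
#'
#' @param ages Integer ages to tabulate.
#' @param amplitude Peak offset in ability units.
#' @return Named numeric vector, age -> offset.
#' @export
default_age_curve <- function(ages = 4:18, amplitude = 1) {
  stats::setNames(amplitude * (1 - ((ages - 10.5) / 6.5)^2), ages)
}

#' Configuration for the synthetic championship generator
#'
#' Defaults are sized to the studied population: 184 horses starting 374
#' times over the 11 championships of 2009-2019 (about 34 starters per
#' year, half of a year's field returning the next year), seven paternal
#' founder lines with Hroby the most numerous, and line effects ordered
#' Goral > Gurgul > Hroby > Ousor > Pietrosu > Prislop > Polan.
#'
#' @param n_horses Roster size.
#' @param years Integer vector of championship years.
#' @param starters_per_year Field size (scalar, or length-2 range to
#'   sample uniformly per year).
#' @param line_probs Named sampling probabilities over sire lines.
#' @param line_effects Named ability offsets per line (same names).
#' @param family_count Number of dam families.
#' @param family_effect_sd SD of dam-family ability offsets.
#' @param horse_sd SD of the per-horse latent baseline.
#' @param age_curve Named numeric vector, age -> ability offset; ages
#'   outside its range use the nearest tabulated age.
#' @param noise_sd SD of per-start noise.
#' @param restart_prob Probability that a horse that started this year
#'   re-enters the next year's championship.
#' @param balanced_lines If `TRUE`, sire lines are assigned by
#'   stratified (largest-remainder) allocation of `line_probs` instead
#'   of multinomial sampling, so roster line counts are deterministic.
#'   Used by recovery studies: SR = 1/(n m) carries heavy-tailed 1/n
#'   noise under multinomial assignment, so exact rank recovery needs
#'   balanced line representation.
#' @param cohort `"staggered"` (default) spreads births so the
#'   population turns over across the year range; `"contemporary"`
#'   draws births from the window in which every horse is aged 4-18 in
#'   every championship year (requires a year span of at most 14), so
#'   the whole roster is eligible throughout.
#' @param seed Integer seed; the generator is deterministic given the
#'   full configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_horses = 184,
                             years = 2009:2019,
                             starters_per_year = 34,
                             line_probs = c(Gurgul = 0.12, Goral = 0.16, Hroby = 0.30,
                                            Ousor = 0.08, Pietrosu = 0.10, Polan = 0.10,
                                            Prislop = 0.14),
                             line_effects = c(Gurgul = 1.0, Goral = 1.2, Hroby = 0.8,
                                              Ousor = 0.6, Pietrosu = 0.4, Polan = 0.0,
                                              Prislop = 0.2),
                             family_count = 30,
                             family_effect_sd = 0.5,
                             horse_sd = 0.7,
                             age_curve = default_age_curve(),
                             noise_sd = 1.0,
                             restart_prob = 0.5,
                             balanced_lines = FALSE,
                             cohort = c("staggered", "contemporary"),
                             seed = 1L) {
  cohort <- match.arg(cohort)
  if (any(line_probs < 0) || sum(line_probs) <= 0) {
    stop("config error: line_probs must be nonnegative with positive sum", call. = FALSE)
  }
  if (is.null(names(line_probs)) || !setequal(names(line_probs), names(line_effects))) {
    stop("config error: line_probs and line_effects must share names", call. = FALSE)
  }
  if (noise_sd < 0 || family_effect_sd < 0 || horse_sd < 0) {
    stop("config error: standard deviations must be >= 0", call. = FALSE)
  }
  if (n_horses < max(starters_per_year)) {
    stop("config error: n_horses must be >= starters_per_year", call. = FALSE)
  }
  if (restart_prob < 0 || restart_prob > 1) {
    stop("config error: restart_prob must be in [0, 1]", call. = FALSE)
  }
  if (cohort == "contemporary" && diff(range(years)) > 14) {
    stop("config error: contemporary cohort needs a year span <= 14", call. = FALSE)
  }
  structure(list(n_horses = as.integer(n_horses), years = as.integer(years),
                 starters_per_year = starters_per_year,
                 line_probs = line_probs / sum(line_probs),
                 line_effects = line_effects, family_count = as.integer(family_count),
                 family_effect_sd = family_effect_sd, horse_sd = horse_sd,
                 age_curve = age_curve, noise_sd = noise_sd,
                 restart_prob = restart_prob, balanced_lines = balanced_lines,
                 cohort = cohort, seed = as.integer(seed)),
            class = "synthetic_config")
}

age_curve_lookup <- function(curve, ages) {
  tab_ages <- as.integer(names(curve))
  idx <- pmin(pmax(ages, min(tab_ages)), max(tab_ages))
  unname(curve[match(idx, tab_ages)])
}

#' Generate a synthetic roster with planted ability structure
#'
#' @param config A [synthetic_config()].
#' @return List with `roster` (a tibble of horse profiles) and `truth`,
#'   a `planted_truth` object holding per-horse baseline, line and
#'   family effects.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_horses
    horse_id <- sprintf("H%03d", seq_len(n))
    lines <- if (config$balanced_lines) {
      quota <- floor(config$line_probs * n)
      frac <- config$line_probs * n - quota
      short <- n - sum(quota)
      if (short > 0) {
        top_up <- order(frac, decreasing = TRUE)[seq_len(short)]
        quota[top_up] <- quota[top_up] + 1
      }
      sample(rep(names(config$line_probs), quota))
    } else {
      sample(names(config$line_probs), n, replace = TRUE,
             prob = config$line_probs)
    }
    families <- sprintf("F%02d", seq_len(config$family_count))
    family_effects <- stats::setNames(
      stats::rnorm(config$family_count, 0, config$family_effect_sd), families)
    fam <- sample(families, n, replace = TRUE)
    # births spread so every championship year has a comfortable pool of
    # age-4..18 eligibles; a contemporary cohort is eligible throughout
    yob_window <- if (config$cohort == "contemporary") {
      (max(config$years) - 18L):(min(config$years) - 4L)
    } else {
      (min(config$years) - 12L):(max(config$years) - 4L)
    }
    yob <- sample(yob_window, n, replace = TRUE)
    coats <- c("bay", "black", "gray", "dun", "tarpan")
    roster <- tibble::tibble(
      horse_id = horse_id,
      name = paste0("Syn", horse_id),
      sex = sample(c("stallion", "mare", "gelding"), n, replace = TRUE,
                   prob = c(0.35, 0.50, 0.15)),
      year_of_birth = as.integer(yob),
      coat = sample(coats, n, replace = TRUE, prob = c(0.45, 0.15, 0.15, 0.15, 0.10)),
      sire_line = lines,
      dam_family = fam,
      breeder = sprintf("B%02d", sample.int(40, n, replace = TRUE)),
      owner_kind = sample(c("private", "public"), n, replace = TRUE, prob = c(0.8, 0.2))
    )
    truth <- structure(list(
      horses = tibble::tibble(
        horse_id = horse_id, sire_line = lines, dam_family = fam,
        baseline = stats::rnorm(n, 0, config$horse_sd),
        line_effect = unname(config$line_effects[lines]),
        family_effect = unname(family_effects[fam])),
      line_effects = config$line_effects,
      family_effects = family_effects,
      start_abilities = NULL), class = "planted_truth")
    list(roster = roster, truth = truth)
  })
}

# Decompose a weighted total into component scores honouring the
# ceilings exactly: each component at the common fraction of its
# maximum, with a small transfer between path and rally that leaves the
# total unchanged. Scores are cosmetic; only positions feed the models.
decompose_total <- function(total, rules = scoring_rules()) {
  cap <- max_total_score(rules)
  f <- pmin(pmax(total / cap, 0), 1)
  ext <- f * rules$maxima[1]
  path <- f * rules$maxima[2]
  rally <- f * rules$maxima[3]
  shift <- pmin(3, path, rules$maxima[3] - rally, (rules$maxima[2] - path)) *
    stats::runif(length(total), -1, 1)
  path2 <- path + shift
  rally2 <- rally - shift * rules$weights[2] / rules$weights[3]
  ok <- path2 >= 0 & path2 <= rules$maxima[2] & rally2 >= 0 & rally2 <= rules$maxima[3]
  tibble::tibble(exterior = round(ext, 2),
                 hucul_path = round(ifelse(ok, path2, path), 2),
                 rally = round(ifelse(ok, rally2, rally), 2))
}

#' Simulate multi-year championships from a roster
#'
#' Each year a field of starters is drawn: last year's participants
#' re-enter with probability `restart_prob`, topped up with debutants.
#' Each start realizes ability = baseline + line effect + family effect
#' + age_curve(age) + Normal(0, noise_sd); finishing positions are the
#' descending-ability ranks 1..n, and component scores are generated so
#' that higher ability gives a higher weighted total.
#'
#' @param roster Roster tibble from [generate_roster()].
#' @param truth Matching `planted_truth`.
#' @param config The same [synthetic_config()].
#' @return A validated `hucul_dataset`; per-start abilities are attached
#'   as attribute `"planted_ability"` (tibble horse_id,
#'   championship_year, ability = noise-free latent part, realized =
#'   latent + per-start noise, the quantity actually ranked) for
#'   recovery tests.
#' @export
simulate_championships <- function(roster, truth, config) {
  stopifnot(inherits(config, "synthetic_config"), nrow(roster) > 0)
  withr::with_seed(config$seed + 1L, {
    spy <- config$starters_per_year
    prev <- character()
    started <- character()
    rows <- vector("list", length(config$years))
    for (i in seq_along(config$years)) {
      yr <- config$years[i]
      eligible <- roster$horse_id[yr - roster$year_of_birth >= 4 &
                                    yr - roster$year_of_birth <= 18]
      n_target <- if (length(spy) == 2) sample(spy[1]:spy[2], 1) else spy
      if (n_target > length(eligible)) {
        stop("config error: starters_per_year (", n_target,
             ") exceeds eligible horses (", length(eligible), ") in ", yr,
             call. = FALSE)
      }
      returning <- intersect(prev, eligible)
      returning <- returning[stats::runif(length(returning)) < config$restart_prob]
      need <- n_target - length(returning)
      newcomers <- setdiff(eligible, c(returning, started))
      lapsed <- setdiff(eligible, c(returning, newcomers))
      fill <- c(sample(newcomers, min(need, length(newcomers))),
                if (need > length(newcomers))
                  sample(lapsed, need - length(newcomers)))
      field <- if (need > 0) c(returning, fill) else sample(returning, n_target)
      h <- truth$horses[match(field, truth$horses$horse_id), ]
      age <- yr - roster$year_of_birth[match(field, roster$horse_id)]
      ability <- h$baseline + h$line_effect + h$family_effect +
        age_curve_lookup(config$age_curve, age)
      realized <- ability +
        if (config$noise_sd > 0) stats::rnorm(length(field), 0, config$noise_sd) else 0
      pos <- rank(-realized, ties.method = "first")
      nf <- length(field)
      total <- 195 - 75 * (pos - 1) / max(nf - 1, 1)
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(horse_id = field, championship_year = yr,
                       position = as.integer(pos), ability = ability,
                       realized = realized),
        decompose_total(total))
      prev <- field
      started <- union(started, field)
    }
    all <- dplyr::bind_rows(rows)
    ds <- hucul_dataset(roster,
                        all[, c("horse_id", "championship_year", "exterior",
                                "hucul_path", "rally", "position")])
    attr(ds, "planted_ability") <-
      all[, c("horse_id", "championship_year", "ability", "realized")]
    ds
  })
}

#' Generate a complete synthetic dataset in one call
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `hucul_dataset`) and `truth` (the
#'   `planted_truth`, with `start_abilities` filled in).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  r <- generate_roster(config)
  ds <- simulate_championships(r$roster, r$truth, config)
  r$truth$start_abilities <- attr(ds, "planted_ability")
  list(dataset = ds, truth = r$truth)
}

#' Randomize finishing positions (null-model datasets)
#'
#' Severs any link between a horse's traits and its label, for
#' chance-level calibration of classifiers. Two schemes:
#' `"within_year"` permutes the true positions within each championship
#' (field sizes and the 1..n structure are preserved, so decoded-group
#' frequencies keep their natural, unbalanced shares);
#' `"balanced_groups"` redraws each start's position stratified
#' uniformly over the three decoded groups (strong 1-8, medium 9-28,
#' weak 29-44), which makes the expected efficiency of any classifier
#' that ignores the labels exactly 1/3. Balanced positions are
#' arbitrary labels, not ranks, so that scheme skips the within-year
#' permutation check.
#'
#' @param dataset A `hucul_dataset`.
#' @param seed Integer seed.
#' @param scheme `"balanced_groups"` or `"within_year"`.
#' @return A `hucul_dataset` with randomized positions.
#' @export
scramble_positions <- function(dataset, seed,
                               scheme = c("balanced_groups", "within_year")) {
  scheme <- match.arg(scheme)
  starts <- dataset$starts
  withr::with_seed(as.integer(seed), {
    if (scheme == "within_year") {
      starts$position <- stats::ave(starts$position, starts$championship_year,
                                    FUN = sample)
      starts$position <- as.integer(starts$position)
    } else {
      n <- nrow(starts)
      grp <- sample(rep_len(1:3, n))
      lo <- c(1L, 9L, 29L)[grp]
      hi <- c(8L, 28L, 44L)[grp]
      starts$position <- as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
    }
  })
  hucul_dataset(dataset$roster, starts[, setdiff(names(starts), "age")],
                validate = scheme == "within_year")
}
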