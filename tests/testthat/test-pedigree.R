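test_that("SR coefficient matches its closed form and bounds", {
  expect_identical(sr_coefficient(1, 1), 1)
  expect_identical(sr_coefficient(2, 1), 0.5)
  expect_identical(sr_coefficient(4, 5), 0.05)
  expect_error(sr_coefficient(0, 1), "integers >= 1")
  for (n in 2:6) {
    for (m in 2:6) {
      sr <- sr_coefficient(n, m)
      expect_gt(sr, 0); expect_lte(sr, 1)
      expect_lt(sr, sr_coefficient(n - 1, m))
      expect_lt(sr, sr_coefficient(n, m - 1))
    }
  }
})

test_that("ASR is the arithmetic mean of the line's SR values", {
  expect_identical(asr_coefficient(1.0), 1.0)
  expect_identical(asr_coefficient(c(0.5, 0.25, 0.75)), 0.5)
  expect_identical(asr_coefficient(rep(0.2, 7)), 0.2)
  expect_error(asr_coefficient(numeric(0)), "empty")
})

test_that("per-line competition stats follow the m rule", {
  ds <- tiny_dataset()
  best <- line_competition_stats(ds, m_rule = "best")
  goral <- best[best$line == "Goral" & best$year == 2015, ]
  expect_identical(goral$n, 1L)
  expect_identical(goral$m, 1L)
  expect_identical(goral$sr, 1)
  hroby <- best[best$line == "Hroby" & best$year == 2015, ]
  expect_identical(hroby$n, 2L)
  expect_identical(hroby$sr, 0.25)  # 1/(2*2), best position 2
  phm <- line_competition_stats(ds, m_rule = "per_horse_mean")
  expect_equal(phm$sr[phm$line == "Hroby" & phm$year == 2015],
               mean(c(1 / (2 * 2), 1 / (2 * 6))))
})

test_that("line summaries aggregate SR, wins and k entered competitions", {
  ds <- tiny_dataset()
  ls <- line_summary(ds)
  goral <- ls[ls$line == "Goral", ]
  expect_identical(goral$k, 2L)      # entered both years
  expect_identical(goral$asr, 1)     # won both as sole starter
  expect_identical(goral$wins, 2L)
  expect_identical(goral$win_fraction, 1)
  polan <- ls[ls$line == "Polan", ]
  expect_identical(polan$k, 1L)      # no Polan starter in 2016
  expect_equal(goral$mean_position_by_year[[1]],
               c("2015" = 1, "2016" = 1))
})

test_that("age table equals a brute-force tally", {
  one <- hucul_dataset(tiny_dataset()$roster,
                       tibble::tibble(horse_id = "A", championship_year = 2015L,
                                      exterior = 40, hucul_path = 70, rally = 60,
                                      position = 1L))
  tab1 <- age_position_table(one)
  expect_identical(tab1$age, 7L)
  expect_identical(tab1$place_1, 1L)
  expect_identical(tab1$top6_total, 1L)
  expect_identical(tab1$mean_position, 1)

  ds <- simulate_dataset(synthetic_config(n_horses = 80, years = 2013:2018,
                                          starters_per_year = 20, seed = 14L))$dataset
  tab <- age_position_table(ds)
  expect_setequal(tab$age, unique(ds$starts$age))
  for (i in seq_len(nrow(tab))) {
    pos <- ds$starts$position[ds$starts$age == tab$age[i]]
    for (p in 1:6) {
      expect_identical(tab[[paste0("place_", p)]][i], sum(pos == p))
    }
    expect_identical(tab$top6_total[i], sum(pos <= 6))
    expect_equal(tab$mean_position[i], mean(pos))
    expect_identical(tab$n_starts[i], length(pos))
  }
})

test_that("wins by trait equal a brute-force tally and sum to the championships", {
  ds <- simulate_dataset(synthetic_config(n_horses = 80, years = 2013:2018,
                                          starters_per_year = 20, seed = 15L))$dataset
  joined <- dplyr::left_join(ds$starts, ds$roster, by = "horse_id")
  wb <- wins_by_group(ds, "sire_line")
  expect_identical(sum(wb$wins), length(unique(ds$starts$championship_year)))
  for (i in seq_len(nrow(wb))) {
    sub <- joined[joined$sire_line == wb$group[i], ]
    expect_identical(wb$wins[i], sum(sub$position == 1))
    expect_identical(wb$n_competitions[i], length(unique(sub$championship_year)))
    expect_equal(wb$win_fraction[i],
                 sum(sub$position == 1) / length(unique(sub$championship_year)))
  }
  expect_error(wins_by_group(ds, "name"), "unknown trait")
})

test_that("ASR ranking recovers planted line effects", {
  # zero noise + balanced contemporary design: exact recovery
  ls <- line_summary(simulate_dataset(recovery_config(31L))$dataset)
  expect_identical(stats::cor(ls$asr, strong_effects[ls$line],
                              method = "kendall"), 1)
  # moderate noise (half the SD of the line effects): tau >= 0.8 on average
  taus <- sapply(1:20, function(s) {
    ls <- line_summary(simulate_dataset(
      recovery_config(200L + s, noise_sd = stats::sd(strong_effects) / 2))$dataset)
    stats::cor(ls$asr, strong_effects[ls$line], method = "kendall")
  })
  expect_gte(mean(taus), 0.8)
})
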