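# Independent re-derivation of the three piecewise membership formulas,
# used as the oracle for decode checks.
oracle_memberships <- function(x) {
  strong <- if (x <= 3) 1 else if (x <= 12) 1 - (x - 3) / 10 else 0
  medium <- if (x > 3 && x <= 12) 1 - (13 - x) / 10
            else if (x > 12 && x <= 23) 1
            else if (x > 23 && x <= 32) 1 - (x - 23) / 10 else 0
  weak <- if (x > 23 && x <= 32) 1 - (33 - x) / 10 else if (x > 32) 1 else 0
  c(strong = strong, medium = medium, weak = weak)
}

test_that("memberships form a partition of unity on positions 1..200", {
  m <- fuzzy_memberships(1:200)
  expect_lt(max(abs(rowSums(m) - 1)), 1e-12)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("membership values match hand evaluation at key positions", {
  expect_equal(membership_vector(2), c(strong = 1, medium = 0, weak = 0))
  expect_equal(membership_vector(8), c(strong = 0.5, medium = 0.5, weak = 0))
  expect_equal(membership_vector(18), c(strong = 0, medium = 1, weak = 0))
  expect_equal(membership_vector(40), c(strong = 0, medium = 0, weak = 1))
  expect_error(membership_vector(0), "integer >= 1")
})

test_that("memberships are continuous at the breakpoints and match the oracle", {
  for (x in 1:60) {
    expect_equal(membership_vector(x), oracle_memberships(x))
  }
  # ramps take one 0.1 step per position off each plateau
  expect_equal(unname(membership_vector(4)["strong"]), 0.9)
  expect_equal(unname(membership_vector(12)["strong"]), 0.1)
  expect_equal(unname(membership_vector(12)["medium"]), 0.9)
  expect_equal(unname(membership_vector(23)["medium"]), 1)
  expect_equal(unname(membership_vector(24)["medium"]), 0.9)
  expect_equal(unname(membership_vector(24)["weak"]), 0.1)
  expect_equal(unname(membership_vector(32)["weak"]), 0.9)
})

test_that("group decoding is arg-max with ties toward the stronger group", {
  expect_identical(as.character(decode_group(c(0.9, 0.3, 0.1))), "strong")
  expect_identical(as.character(decode_group(c(0.5, 0.5, 0))), "strong")
  expect_identical(as.character(decode_group(c(0.1, 0.4, 0.4))), "medium")
  expect_error(decode_group(c(1, NA, 0)), "finite")
  for (x in 1:50) {
    o <- oracle_memberships(x)
    expect_identical(as.character(position_group(x)),
                     names(o)[which.max(o)])
  }
})

test_that("position targets round-trip through the affine map", {
  for (cap in c(2L, 7L, 34L)) {
    expect_identical(position_target(1, cap), -1)
    expect_identical(position_target(cap, cap), 1)
    expect_identical(target_position(position_target(1:cap, cap), cap), 1:cap)
  }
  expect_identical(target_position(5, 10), 10L)  # clamped
  expect_error(position_target(1, 0), "field_cap")
})

test_that("one-hot encoding expands observed categories", {
  ds <- tiny_dataset()
  X <- encode_features(ds, feature_spec(c(sex = "one_hot")))
  expect_setequal(colnames(X), paste0("sex.", sort(unique(ds$roster$sex))))
  expect_true(all(X %in% c(0, 1)))
  expect_equal(unname(rowSums(X)), rep(1, nrow(ds$starts)))
})

test_that("performance-ordinal encoding uses fit-row means with fallback", {
  ds <- tiny_dataset()
  fit <- which(ds$starts$championship_year == 2016L)
  X <- encode_features(ds, feature_spec(c(sire_line = "performance_ordinal")),
                       fit_rows = fit)
  cap <- max(ds$starts$position[fit])
  start_line <- ds$roster$sire_line[match(ds$starts$horse_id, ds$roster$horse_id)]
  # Goral won its only fit start -> extreme best end of the scale
  expect_equal(unname(X[which(start_line == "Goral"), 1]),
               rep(position_target(1, cap), 2))
  # Polan has no 2016 start: its rows get the global fit mean
  expect_equal(unname(X[which(start_line == "Polan"), 1]),
               position_target(mean(ds$starts$position[fit]), cap))
})

test_that("test-row positions cannot leak into the encoding", {
  ds <- simulate_dataset(synthetic_config(n_horses = 60, years = 2015:2018,
                                          starters_per_year = 15, seed = 19L))$dataset
  fit <- which(ds$starts$championship_year <= 2016L)
  test_rows <- setdiff(seq_len(nrow(ds$starts)), fit)
  X1 <- encode_features(ds, feature_spec(), fit_rows = fit)
  shuffled <- ds$starts
  shuffled$position[test_rows] <- rev(shuffled$position[test_rows])
  ds2 <- structure(list(roster = ds$roster, starts = shuffled),
                   class = "hucul_dataset")
  X2 <- encode_features(ds2, feature_spec(), fit_rows = fit)
  expect_identical(X1, X2)
})

test_that("excluded-by-design traits are rejected", {
  expect_error(feature_spec(c(name = "one_hot")), "inadmissible")
  expect_error(feature_spec(c(year_of_birth = "numeric")), "inadmissible")
  expect_error(feature_spec(c(age = "one_hot")), "numeric")
})
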