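# Shared fixtures: planted-effect configurations and a tiny hand-built
# dataset.

strong_effects <- c(Goral = 30, Gurgul = 25, Hroby = 20, Ousor = 15,
                    Pietrosu = 10, Prislop = 5, Polan = 0)
uniform_lines <- stats::setNames(rep(1 / 7, 7), names(strong_effects))

# Recovery configuration: balanced stratified line assignment, fully
# contemporary cohort, full participation -> identical line counts in
# every year's field, so the planted feature-to-position map is
# deterministic at zero noise.
recovery_config <- function(seed, noise_sd = 0) {
  synthetic_config(
    n_horses = 56, years = 2010:2019, starters_per_year = 56,
    line_probs = uniform_lines, line_effects = strong_effects,
    family_count = 14, family_effect_sd = 0.2, horse_sd = 0.2,
    age_curve = stats::setNames(rep(0, 15), 4:18),
    noise_sd = noise_sd, restart_prob = 1,
    balanced_lines = TRUE, cohort = "contemporary", seed = seed)
}

# Fast Levenberg-Marquardt settings for test-sized problems.
test_training <- function(seed, ...) {
  training_config(seed = seed, max_epochs = 100, n_restarts = 2, ...)
}

# Two championships, hand-enumerable: year 2015 has a lone Goral winner
# and two Hroby horses at 2 and 6 (plus fillers), year 2016 reuses
# three horses.
tiny_dataset <- function() {
  roster <- tibble::tibble(
    horse_id = c("A", "B", "C", "D", "E", "F"),
    name = paste0("N", 1:6),
    sex = c("mare", "stallion", "mare", "gelding", "mare", "stallion"),
    year_of_birth = c(2008L, 2009L, 2007L, 2010L, 2008L, 2009L),
    coat = c("bay", "bay", "gray", "dun", "bay", "black"),
    sire_line = c("Goral", "Hroby", "Hroby", "Polan", "Prislop", "Gurgul"),
    dam_family = c("F1", "F2", "F1", "F3", "F2", "F3"),
    breeder = c("B1", "B1", "B2", "B2", "B3", "B3"),
    owner_kind = c("private", "public", "private", "private", "public", "private"))
  starts <- tibble::tibble(
    horse_id = c("A", "B", "D", "E", "F", "C", "A", "B", "C"),
    championship_year = c(rep(2015L, 6), rep(2016L, 3)),
    exterior = c(48, 45, 40, 38, 36, 34, 47, 44, 41),
    hucul_path = c(78, 74, 70, 66, 60, 55, 77, 72, 68),
    rally = c(76, 72, 68, 62, 58, 50, 75, 70, 64),
    position = c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 2L, 3L))
  hucul_dataset(roster, starts)
}
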