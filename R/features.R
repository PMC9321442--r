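# Fuzzy strong/medium/weak labelling of finishing positions and
# leakage-safe numeric encoding of descriptive traits.

GROUP_LEVELS <- c("strong", "medium", "weak")

#' Fuzzy membership of a finishing position
#'
#' Piecewise-linear memberships of the groups "strong", "medium" and
#' "weak" as functions of the absolute finishing position x:
#' strong is 1 up to position 3 and ramps down to 0 over 3 < x <= 12;
#' medium ramps up over the same span (1 - (13 - x)/10), plateaus at 1
#' for 12 < x <= 23 and ramps down over 23 < x <= 32; weak ramps up
#' over 23 < x <= 32 and is 1 beyond 32. Outside each formula's stated
#' span the membership is 0. The three memberships sum to 1 at every
#' integer position (partition of unity).
#'
#' @param position Integer position(s) >= 1.
#' @return For one position, a named numeric (strong, medium, weak);
#'   see [fuzzy_memberships()] for the matrix form.
#' @export
#' @examples
#' membership_vector(8)  # 0.5 strong, 0.5 medium
membership_vector <- function(position) {
  m <- fuzzy_memberships(position)
  if (nrow(m) == 1) m[1, ] else m
}

#' @rdname membership_vector
#' @return `fuzzy_memberships()` returns an n x 3 matrix with columns
#'   strong, medium, weak.
#' @export
fuzzy_memberships <- function(position) {
  x <- as.numeric(position)
  if (any(!is.finite(x)) || any(x < 1) || any(x != round(x))) {
    stop("position must be an integer >= 1", call. = FALSE)
  }
  strong <- ifelse(x <= 3, 1, ifelse(x <= 12, 1 - (x - 3) / 10, 0))
  medium <- ifelse(x > 3 & x <= 12, 1 - (13 - x) / 10,
                   ifelse(x > 12 & x <= 23, 1,
                          ifelse(x > 23 & x <= 32, 1 - (x - 23) / 10, 0)))
  weak <- ifelse(x > 23 & x <= 32, 1 - (33 - x) / 10, ifelse(x > 32, 1, 0))
  cbind(strong = strong, medium = medium, weak = weak)
}

#' Decode a membership triple to its group
#'
#' Arg-max of the (strong, medium, weak) triple; exact ties break
#' toward the stronger group (strong over medium over weak).
#'
#' @param label A length-3 numeric, or an n x 3 matrix of triples
#'   (e.g. network outputs).
#' @return Factor with levels strong, medium, weak.
#' @export
decode_group <- function(label) {
  m <- if (is.matrix(label)) label else matrix(label, nrow = 1)
  if (ncol(m) != 3 || any(!is.finite(m))) {
    stop("label must be three finite values per row", call. = FALSE)
  }
  factor(GROUP_LEVELS[max.col(m, ties.method = "first")], levels = GROUP_LEVELS)
}

#' Decoded group of an actual finishing position
#'
#' @param position Integer position(s) >= 1.
#' @return Factor with levels strong, medium, weak.
#' @export
position_group <- function(position) {
  decode_group(fuzzy_memberships(position))
}

#' Scale a finishing position to a tanh-friendly target
#'
#' Affine map of min(position, field_cap) from [1, field_cap] onto
#' [-1, 1]; [target_position()] inverts it, rounding to the nearest
#' integer position.
#'
#' @param position Position(s) >= 1 (reals allowed, e.g. category mean
#'   positions).
#' @param field_cap Largest position of interest (>= 1).
#' @return Real target(s) in [-1, 1].
#' @export
position_target <- function(position, field_cap) {
  if (field_cap < 1) stop("field_cap must be >= 1", call. = FALSE)
  if (any(position < 1)) stop("position must be >= 1", call. = FALSE)
  if (field_cap == 1) return(rep(0, length(position)))
  p <- pmin(position, field_cap)
  2 * (p - 1) / (field_cap - 1) - 1
}

#' @rdname position_target
#' @param target Real value(s), clamped to [-1, 1].
#' @return `target_position()` returns integer positions in
#'   [1, field_cap].
#' @export
target_position <- function(target, field_cap) {
  if (field_cap < 1) stop("field_cap must be >= 1", call. = FALSE)
  t <- pmin(pmax(target, -1), 1)
  as.integer(pmin(pmax(round((t + 1) / 2 * (field_cap - 1) + 1), 1), field_cap))
}

#' Feature specification for model inputs
#'
#' Declares which descriptive traits enter the model and how each is
#' encoded. `one_hot` expands a trait into indicator columns;
#' `performance_ordinal` replaces each category by the mean finishing
#' position of that category in the training rows, rescaled to
#' [-1, 1] (categories unseen in training fall back to the training
#' global mean); `numeric` (age only) is scaled to [-1, 1]. Name,
#' year of birth and the sire/dam names are never admissible: the
#' analysis uses only descriptive traits of demonstrated relevance.
#'
#' @param traits Named character vector, trait -> encoding. Admissible
#'   traits: age, sire_line, dam_family, sex, coat, breeder,
#'   owner_kind.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(traits = c(age = "numeric",
                                    sex = "one_hot",
                                    owner_kind = "one_hot",
                                    sire_line = "performance_ordinal",
                                    dam_family = "performance_ordinal",
                                    coat = "performance_ordinal",
                                    breeder = "performance_ordinal")) {
  admissible <- c("age", "sire_line", "dam_family", "sex", "coat", "breeder",
                  "owner_kind")
  bad <- setdiff(names(traits), admissible)
  if (length(bad)) {
    stop("inadmissible trait(s): ", paste(bad, collapse = ", "),
         " (only ", paste(admissible, collapse = ", "), " may be used)",
         call. = FALSE)
  }
  ok_enc <- traits %in% c("numeric", "one_hot", "performance_ordinal")
  if (!all(ok_enc)) stop("unknown encoding: ", paste(traits[!ok_enc], collapse = ", "),
                         call. = FALSE)
  if (!is.null(traits["age"]) && !is.na(traits["age"]) && traits[["age"]] != "numeric") {
    stop("age must use the numeric encoding", call. = FALSE)
  }
  structure(list(traits = traits), class = "feature_spec")
}

#' Encode descriptive traits into a numeric model matrix
#'
#' Builds one row per start record. All statistics that depend on
#' finishing positions (performance-ordinal category means, the
#' position cap, age range) are computed on `fit_rows` only, so test
#' rows never leak their labels into the encoding.
#'
#' @param dataset A `hucul_dataset`.
#' @param spec A [feature_spec()].
#' @param fit_rows Integer indices into `dataset$starts` used to fit
#'   the encoding (default: all rows).
#' @return Numeric matrix with unique column names, entries in
#'   [-1, 1], no missing values; attribute `"field_cap"` carries the
#'   largest position seen in `fit_rows`.
#' @export
encode_features <- function(dataset, spec = feature_spec(),
                            fit_rows = seq_len(nrow(dataset$starts))) {
  stopifnot(inherits(spec, "feature_spec"), length(fit_rows) > 0)
  starts <- dataset$starts
  joined <- dplyr::left_join(starts, dataset$roster, by = "horse_id")
  fit <- joined[fit_rows, ]
  cap <- max(fit$position)
  global_mean <- mean(fit$position)
  blocks <- list()
  for (trait in names(spec$traits)) {
    enc <- spec$traits[[trait]]
    if (!trait %in% names(joined)) {
      stop("schema error: trait '", trait, "' absent from dataset", call. = FALSE)
    }
    v <- joined[[trait]]
    if (enc == "numeric") {
      lo <- min(fit[[trait]]); hi <- max(fit[[trait]])
      col <- if (hi > lo) 2 * (pmin(pmax(v, lo), hi) - lo) / (hi - lo) - 1 else rep(0, length(v))
      blocks[[trait]] <- matrix(col, ncol = 1, dimnames = list(NULL, trait))
    } else if (enc == "one_hot") {
      levs <- sort(unique(as.character(fit[[trait]])))
      m <- vapply(levs, function(l) as.numeric(v == l), numeric(length(v)))
      colnames(m) <- paste(trait, levs, sep = ".")
      blocks[[trait]] <- m
    } else {
      means <- tapply(fit$position, as.character(fit[[trait]]), mean)
      val <- means[as.character(v)]
      val[is.na(val)] <- global_mean
      blocks[[trait]] <- matrix(position_target(val, cap), ncol = 1,
                                dimnames = list(NULL, trait))
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  stopifnot(!anyNA(out), !anyDuplicated(colnames(out)))
  attr(out, "field_cap") <- cap
  out
}
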