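#' silencescreen: pooled silencing-loss longevity screen, simulated end to end
#'
#' The package models a genome-scale positive-selection screen for long-lived
#' yeast deletion mutants.  Every strain in a barcoded pool carries a URA3
#' reporter at a transcriptionally silenced locus; silencing decays late in a
#' mother cell's replicative life, URA3 turns on, and 5-fluoroorotic acid
#' (5-FOA) kills the derepressed cells.  Long-lived mutants therefore persist
#' longer under 5-FOA, and their barcodes are overrepresented in the selected
#' culture relative to an unselected one.  The package provides synthetic
#' library generators ([make_library()]), the pooled-culture simulator
#' ([run_screen()]), the two-channel barcode-array readout and classifier
#' ([simulate_hybridization()], [classify_long_lived()], [control_filter()]),
#' and the single-strain validation statistics ([mann_whitney_u()],
#' [logrank_test()], [summarize_rls()], [build_repro_curve()]).
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain types: StrainSpec, Library, DissectionSet, ReproSet
# ---------------------------------------------------------------------------

#' Describe one barcoded deletion strain
#'
#' A strain specification holds the phenomenological parameters that drive the
#' simulator: the mean replicative lifespan (number of daughters a mother
#' produces), its dispersion, and the silencing-loss window.  Loss of
#' reporter silencing happens at a division drawn uniformly between
#' `loss_frac_lo` and `loss_frac_hi` of the mother's own lifespan; strains
#' flagged `silencing_defect` instead lose silencing at any division with a
#' constant per-division probability, the age-independent false positives
#' that the control library is designed to catch.
#'
#' @param barcode_id Unique TAG identifier (character scalar).
#' @param mean_lifespan Mean replicative lifespan in generations (> 0).
#' @param lifespan_cv Coefficient of variation of per-mother lifespan (>= 0).
#' @param loss_frac_lo,loss_frac_hi Earliest/latest silencing-loss point as a
#'   fraction of the mother's lifespan, both in (0, 1],
#'   `loss_frac_lo <= loss_frac_hi`.
#' @param silencing_defect Logical; if `TRUE` silencing is lost with constant
#'   per-division probability irrespective of age.
#' @param defect_rate Per-division silencing-loss probability used when
#'   `silencing_defect` is `TRUE`.
#' @param label Planted ground-truth label, one of `"wildtype_like"`,
#'   `"long_lived"`, `"short_lived"`, `"silencing_defective"`.
#'
#' @return A one-row `data.frame` of class `"strain_spec"`.
#' @seealso [make_library()]
#' @export
#' @examples
#' strain_spec("TAG0001", mean_lifespan = 30)
strain_spec <- function(barcode_id, mean_lifespan, lifespan_cv = 0.35,
                        loss_frac_lo = 0.70, loss_frac_hi = 1.00,
                        silencing_defect = FALSE, defect_rate = 0.2,
                        label = c("wildtype_like", "long_lived",
                                  "short_lived", "silencing_defective")) {
  label <- match.arg(label)
  stopifnot(is.character(barcode_id), length(barcode_id) == 1L)
  if (!is.finite(mean_lifespan) || mean_lifespan <= 0)
    stop("'mean_lifespan' must be a positive finite number")
  if (!is.finite(lifespan_cv) || lifespan_cv < 0)
    stop("'lifespan_cv' must be a nonnegative finite number")
  if (!is.finite(loss_frac_lo) || loss_frac_lo <= 0 || loss_frac_lo > 1 ||
      !is.finite(loss_frac_hi) || loss_frac_hi <= 0 || loss_frac_hi > 1)
    stop("loss fractions must lie in (0, 1]")
  if (loss_frac_lo > loss_frac_hi)
    stop("'loss_frac_lo' must not exceed 'loss_frac_hi'")
  if (!is.finite(defect_rate) || defect_rate <= 0 || defect_rate > 1)
    stop("'defect_rate' must lie in (0, 1]")
  out <- data.frame(barcode_id = barcode_id,
                    mean_lifespan = mean_lifespan,
                    lifespan_cv = lifespan_cv,
                    loss_frac_lo = loss_frac_lo,
                    loss_frac_hi = loss_frac_hi,
                    silencing_defect = isTRUE(silencing_defect),
                    defect_rate = defect_rate,
                    label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_spec", "data.frame")
  out
}

#' Assemble a barcoded deletion library with planted lifespan effects
#'
#' Builds a library of `n_strains` strains: a fraction `frac_long` receive
#' mean lifespan `base_lifespan * (1 + long_effect)` and the label
#' `"long_lived"`, a fraction `frac_defective` are flagged as
#' age-independent silencing-defective, and the remainder are wild-type-like.
#' Which barcodes carry the planted effects is a seeded random draw, so the
#' same call always returns the identical library.
#'
#' @param n_strains Number of strains (>= 2).
#' @param frac_long Fraction of strains planted as long-lived.
#' @param long_effect Relative lifespan extension of planted long-lived
#'   strains (e.g. `0.4` for +40 percent).
#' @param frac_defective Fraction of strains with stochastic silencing
#'   defects.
#' @param base_lifespan Mean lifespan of wild-type-like strains, generations.
#' @param seed Integer seed; the library is a pure function of its arguments.
#' @param lifespan_cv,loss_frac_lo,loss_frac_hi,defect_rate Shared strain
#'   parameters, see [strain_spec()].
#'
#' @return A `data.frame` of class `"strain_library"` with one row per strain
#'   and a `seed` attribute.
#' @export
#' @examples
#' lib <- make_library(n_strains = 20, frac_long = 0.1, long_effect = 0.4,
#'                     frac_defective = 0.1, base_lifespan = 30, seed = 1)
#' table(lib$label)
make_library <- function(n_strains, frac_long = 0, long_effect = 0.4,
                         frac_defective = 0, base_lifespan = 30, seed = 1,
                         lifespan_cv = 0.35, loss_frac_lo = 0.70,
                         loss_frac_hi = 1.00, defect_rate = 0.2) {
  if (!is.finite(n_strains) || n_strains < 2)
    stop("'n_strains' must be at least 2")
  if (!is.finite(frac_long) || frac_long < 0 || !is.finite(frac_defective) ||
      frac_defective < 0 || frac_long + frac_defective > 1)
    stop("fractions must be nonnegative and sum to at most 1")
  if (!is.finite(long_effect) || long_effect <= 0)
    stop("'long_effect' must be positive")
  n_strains <- as.integer(n_strains)
  n_long <- as.integer(round(frac_long * n_strains))
  n_def <- as.integer(round(frac_defective * n_strains))

  lib <- with_seed(seed, {
    idx <- sample.int(n_strains, n_long + n_def)
    lib <- data.frame(
      barcode_id = sprintf("TAG%05d", seq_len(n_strains)),
      mean_lifespan = base_lifespan,
      lifespan_cv = lifespan_cv,
      loss_frac_lo = loss_frac_lo,
      loss_frac_hi = loss_frac_hi,
      silencing_defect = FALSE,
      defect_rate = defect_rate,
      label = "wildtype_like",
      stringsAsFactors = FALSE
    )
    if (n_long > 0) {
      long_idx <- idx[seq_len(n_long)]
      lib$mean_lifespan[long_idx] <- base_lifespan * (1 + long_effect)
      lib$label[long_idx] <- "long_lived"
    }
    if (n_def > 0) {
      def_idx <- idx[n_long + seq_len(n_def)]
      lib$silencing_defect[def_idx] <- TRUE
      lib$label[def_idx] <- "silencing_defective"
    }
    lib
  })
  attr(lib, "seed") <- as.integer(seed)
  class(lib) <- c("strain_library", "data.frame")
  validate_library(lib)
}

#' @export
print.strain_library <- function(x, ...) {
  cat(sprintf("Barcoded deletion library: %d strains (seed %s)\n",
              nrow(x), format(attr(x, "seed"))))
  print(table(label = x$label))
  invisible(x)
}

validate_library <- function(lib) {
  stopifnot(is.data.frame(lib), nrow(lib) >= 1L)
  need <- c("barcode_id", "mean_lifespan", "lifespan_cv", "loss_frac_lo",
            "loss_frac_hi", "silencing_defect", "label")
  missing <- setdiff(need, names(lib))
  if (length(missing))
    stop("library is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(lib$barcode_id))
    stop("barcodes must be unique within a library")
  if (any(lib$mean_lifespan <= 0)) stop("mean lifespans must be positive")
  if (any(lib$loss_frac_lo > lib$loss_frac_hi))
    stop("loss_frac_lo must not exceed loss_frac_hi")
  if (is.null(lib$defect_rate)) lib$defect_rate <- 0.2
  lib
}

# ---------------------------------------------------------------------------
# Lifespan and silencing-loss sampling
# ---------------------------------------------------------------------------

#' Draw per-mother replicative lifespans
#'
#' Lifespans are drawn from a gamma distribution with the strain's mean and
#' coefficient of variation and rounded to the nearest integer (a mother
#' completes a whole number of divisions).  `lifespan_cv = 0` returns
#' `round(mean_lifespan)` deterministically.  Uses the current RNG state;
#' seed upstream with `set.seed()` or use the seeded generators.
#'
#' @param strain A one-row strain specification ([strain_spec()] or a library
#'   row).
#' @param n Number of mothers to draw.
#' @return Integer vector of nonnegative lifespans.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_mother_lifespan(strain_spec("t", 30, lifespan_cv = 0.35), 1e4))
sample_mother_lifespan <- function(strain, n = 1L) {
  mu <- strain$mean_lifespan
  cv <- strain$lifespan_cv
  stopifnot(is.finite(mu), mu > 0, is.finite(cv), cv >= 0)
  if (cv == 0) return(rep.int(as.integer(round(mu)), n))
  shape <- 1 / cv^2
  as.integer(round(stats::rgamma(n, shape = shape, rate = shape / mu)))
}

#' Draw the division at which a mother loses reporter silencing
#'
#' For ordinary strains the loss division is uniform on the integers from
#' `ceiling(loss_frac_lo * lifespan)` to `ceiling(loss_frac_hi * lifespan)`
#' (the latter equals `lifespan` for the default window upper edge of 1), so
#' a mother with lifespan 30 and the default `[0.7, 1]` window derepresses
#' between divisions 21 and 30.  Silencing-defective strains return the first
#' success of a constant per-division Bernoulli trial, which may precede the
#' window or exceed the lifespan (in which case the mother dies silenced).
#'
#' @inheritParams sample_mother_lifespan
#' @param lifespan Integer lifespan(s) of the mother(s); recycled against `n`.
#' @param n Number of draws.
#' @return Integer vector of loss divisions (>= 1), bounded above by
#'   `lifespan` for non-defective strains.
#' @export
sample_loss_generation <- function(strain, lifespan, n = length(lifespan)) {
  stopifnot(all(lifespan >= 0))
  lifespan <- rep_len(as.integer(lifespan), n)
  if (isTRUE(strain$silencing_defect)) {
    return(as.integer(stats::rgeom(n, prob = strain$defect_rate)) + 1L)
  }
  lo <- pmax(1L, as.integer(ceiling(strain$loss_frac_lo * lifespan)))
  hi <- pmax(lo, as.integer(ceiling(strain$loss_frac_hi * lifespan)))
  lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
}

# ---------------------------------------------------------------------------
# Dissection and reproduction datasets
# ---------------------------------------------------------------------------

#' Generate a micro-dissection lifespan dataset for one genotype
#'
#' Emulates the mother-daughter dissection assay: `n_mothers` founding cells
#' are followed until each stops dividing, recording the number of daughters
#' produced.  Assays below 40 founders trigger a warning, mirroring the
#' conventional minimum starting population.
#'
#' @inheritParams sample_mother_lifespan
#' @param n_mothers Number of founding mothers (>= 1; warning below 40).
#' @param seed Integer seed.
#' @param genotype Genotype name recorded in the result.
#' @return An object of class `"dissection_set"`: a list with `genotype` and
#'   integer `lifespans`.
#' @export
#' @examples
#' d <- make_dissection_set(strain_spec("t", 17.5), n_mothers = 40, seed = 2)
#' summarize_rls(d)
make_dissection_set <- function(strain, n_mothers = 40L, seed = 1L,
                                genotype = strain$barcode_id) {
  if (!is.finite(n_mothers) || n_mothers < 1)
    stop("'n_mothers' must be at least 1")
  if (n_mothers < 40)
    warning("fewer than 40 founding mothers; lifespan estimates will be noisy")
  lifespans <- with_seed(seed,
                         sample_mother_lifespan(strain, as.integer(n_mothers)))
  structure(list(genotype = genotype, lifespans = lifespans),
            class = "dissection_set")
}

#' @export
print.dissection_set <- function(x, ...) {
  cat(sprintf("Dissection set '%s': %d mothers, mean lifespan %.2f\n",
              x$genotype, length(x$lifespans), mean(x$lifespans)))
  invisible(x)
}

#' Default daily matricide hazard
#'
#' Zero before the onset day, then a constant daily probability: matricide
#' ("bagging") is rare early in reproductive life and rises sharply in aged
#' hermaphrodites.
#'
#' @param days Number of days covered.
#' @param rate Constant daily hazard from `onset` onwards.
#' @param onset First day with nonzero hazard.
#' @return Numeric vector of per-day matricide probabilities.
#' @export
matricide_hazard <- function(days = 14L, rate = 0.05, onset = 5L) {
  h <- numeric(days)
  if (onset <= days) h[onset:days] <- rate
  h
}

#' Generate a reproductive-span dataset for one worm genotype
#'
#' Each hermaphrodite receives a reproductive-cessation day drawn from a
#' discretised gamma distribution with the given mean (minimum 1 day).  While
#' a worm is still reproducing it can die of matricide with the given daily
#' hazard, in which case it is recorded with outcome `"matricide"` on that
#' day; worms still reproducing at the end of the observation window are
#' `"alive_at_end"`.  A `sterile_frac` fraction of worms are flagged sterile
#' and carry no cessation day.
#'
#' @param mean_span Mean reproductive span in days of adulthood (day 1 is the
#'   first egg-laying day).
#' @param matricide_day_hazard Numeric vector of per-day matricide
#'   probabilities (see [matricide_hazard()]); `NULL` for none.
#' @param sterile_frac Fraction of sterile worms, in `[0, 1)`.
#' @param n_worms Number of worms.
#' @param seed Integer seed.
#' @param span_cv Coefficient of variation of the cessation-day distribution.
#' @param max_day Observation window in days.
#' @param genotype Genotype name recorded in the result.
#' @return An object of class `"repro_set"`: a `data.frame` with columns
#'   `worm_id`, `last_progeny_day`, `outcome`, `sterile` and a `genotype`
#'   attribute.
#' @export
#' @examples
#' r <- make_repro_set(mean_span = 4, n_worms = 25, seed = 3)
#' table(r$outcome)
make_repro_set <- function(mean_span, matricide_day_hazard = NULL,
                           sterile_frac = 0, n_worms = 25L, seed = 1L,
                           span_cv = 0.25, max_day = 14L,
                           genotype = "strain") {
  stopifnot(is.finite(mean_span), mean_span >= 1)
  if (!is.finite(sterile_frac) || sterile_frac < 0 || sterile_frac >= 1)
    stop("'sterile_frac' must lie in [0, 1)")
  if (!is.null(matricide_day_hazard) &&
      (any(!is.finite(matricide_day_hazard)) ||
       any(matricide_day_hazard < 0) || any(matricide_day_hazard > 1)))
    stop("matricide hazards must be probabilities in [0, 1]")
  n_worms <- as.integer(n_worms)
  haz <- if (is.null(matricide_day_hazard)) numeric(0) else matricide_day_hazard

  out <- with_seed(seed, {
    sterile <- stats::runif(n_worms) < sterile_frac
    cess <- if (span_cv == 0) rep.int(as.integer(round(mean_span)), n_worms)
    else {
      shape <- 1 / span_cv^2
      pmax(1L, as.integer(round(
        stats::rgamma(n_worms, shape = shape, rate = shape / mean_span))))
    }
    last_day <- rep(NA_integer_, n_worms)
    outcome <- rep(NA_character_, n_worms)
    for (i in seq_len(n_worms)) {
      if (sterile[i]) next
      stop_day <- min(cess[i], max_day)
      died <- FALSE
      for (d in seq_len(stop_day)) {
        p <- if (d <= length(haz)) haz[d] else 0
        if (p > 0 && stats::runif(1) < p) {
          last_day[i] <- d
          outcome[i] <- "matricide"
          died <- TRUE
          break
        }
      }
      if (!died) {
        last_day[i] <- stop_day
        outcome[i] <- if (cess[i] > max_day) "alive_at_end" else "ceased"
      }
    }
    data.frame(worm_id = sprintf("worm%03d", seq_len(n_worms)),
               last_progeny_day = last_day,
               outcome = outcome,
               sterile = sterile,
               stringsAsFactors = FALSE)
  })
  attr(out, "genotype") <- genotype
  class(out) <- c("repro_set", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Seed handling
# ---------------------------------------------------------------------------

# Evaluate `expr` under a local seed, restoring the caller's RNG state.
# All generators route through this, so they are pure in (parameters, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a base seed; keeps values inside 32-bit range.
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + as.integer(stage) * 104729L) %% 2147483587L
}
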