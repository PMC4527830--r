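# Two-channel barcode-array layer: hybridization noise, log-ratio
# normalization, the long-lived classification rule and the control-library
# false-positive filter.
#
# Dye convention: the PCR product of the unselected (-5-FOA) culture carries
# Cy5 and the selected (+5-FOA) culture carries Cy3, so a strain enriched by
# counter-selection has Cy5:Cy3 < 1 and a NEGATIVE log2 ratio -- the sign
# under which long-lived hits appear in the classification rule.

#' Simulate the co-hybridization of paired cultures onto a barcode array
#'
#' Each barcode's channel intensity is `scale * abundance * exp(e)` with `e ~
#' Normal(0, (noise_sd_log2 * ln 2)^2)` drawn independently per channel and
#' barcode, i.e. log-normal multiplicative measurement noise expressed on the
#' log2 scale.  Intensities below `floor_frac` of the per-sample median are
#' floored so that fully depleted strains yield finite ratios.  Raw log2
#' Cy5:Cy3 ratios are then median-centred via [normalize_log_ratios()].
#'
#' @param traj_plus,traj_minus Abundance trajectories of the same library
#'   from the +5-FOA and -5-FOA cultures (see [run_screen()]); they must
#'   share barcodes and sampling days.
#' @param noise_sd_log2 Channel noise standard deviation in log2 units.
#' @param seed Integer seed.
#' @param scale Arbitrary intensity scale.
#' @param floor_frac Detection floor as a fraction of the per-sample median
#'   intensity.
#' @return A list of `"array_sample"` data frames (columns `day`,
#'   `barcode_id`, `cy5`, `cy3`, `log2_ratio`), one per sampling day, named
#'   by day.
#' @export
simulate_hybridization <- function(traj_plus, traj_minus, noise_sd_log2 = 0.25,
                                   seed = 1L, scale = 1e4,
                                   floor_frac = 1e-6) {
  stopifnot(is.finite(noise_sd_log2), noise_sd_log2 >= 0)
  days <- sort(unique(traj_plus$day))
  if (!setequal(days, unique(traj_minus$day)))
    stop("trajectories do not share sampling days")
  with_seed(seed, {
    out <- lapply(days, function(d) {
      plus <- traj_plus[traj_plus$day == d, ]
      minus <- traj_minus[traj_minus$day == d, ]
      if (!setequal(plus$barcode_id, minus$barcode_id))
        stop("trajectories do not share barcode sets")
      minus <- minus[match(plus$barcode_id, minus$barcode_id), ]
      n <- nrow(plus)
      sd_ln <- noise_sd_log2 * log(2)
      cy3 <- scale * plus$rel_abundance * exp(stats::rnorm(n, 0, sd_ln))
      cy5 <- scale * minus$rel_abundance * exp(stats::rnorm(n, 0, sd_ln))
      cy3 <- pmax(cy3, floor_frac * stats::median(cy3[cy3 > 0]))
      cy5 <- pmax(cy5, floor_frac * stats::median(cy5[cy5 > 0]))
      smp <- data.frame(day = d, barcode_id = plus$barcode_id,
                        cy5 = cy5, cy3 = cy3,
                        log2_ratio = log2(cy5 / cy3),
                        stringsAsFactors = FALSE)
      class(smp) <- c("array_sample", "data.frame")
      normalize_log_ratios(smp)
    })
    names(out) <- as.character(days)
    out
  })
}

#' Median-centre the log2 ratios of an array sample
#'
#' Centres `log2_ratio` so its median across barcodes is exactly zero,
#' preserving rank order; the standard single-array normalization when most
#' strains are unchanged between channels.
#'
#' @param sample An `"array_sample"` data frame.
#' @return The sample with centred `log2_ratio`.
#' @export
normalize_log_ratios <- function(sample) {
  if (nrow(sample) < 2L)
    stop("normalization needs at least 2 barcodes")
  sample$log2_ratio <- sample$log2_ratio - stats::median(sample$log2_ratio)
  sample
}

#' Classify potentially long-lived strains from day-6 and day-16 arrays
#'
#' A strain is called long-lived when its normalized log2 Cy5:Cy3 ratio is
#' negative at both sampling days and falls strictly below `threshold` at the
#' late day: persistent enrichment in the counter-selected culture.
#'
#' @param day6,day16 `"array_sample"` data frames for the two sampling days,
#'   sharing barcodes.
#' @param threshold Late-day log2 ratio cutoff (default -2.3); must be
#'   negative unless `allow_nonneg_threshold` is set.
#' @param allow_nonneg_threshold Override for deliberately degenerate
#'   thresholds.
#' @return A `data.frame` of class `"screen_calls"` with columns
#'   `barcode_id`, `ratio_day6`, `ratio_day16`, `classified_long_lived`,
#'   `control_flagged` (initialised `FALSE`).
#' @export
#' @examples
#' d6 <- data.frame(day = 6, barcode_id = c("a", "b"), cy5 = 1, cy3 = 1,
#'                  log2_ratio = c(-0.5, 0.2))
#' d16 <- data.frame(day = 16, barcode_id = c("a", "b"), cy5 = 1, cy3 = 1,
#'                   log2_ratio = c(-2.5, -3))
#' classify_long_lived(d6, d16)
classify_long_lived <- function(day6, day16, threshold = -2.3,
                                allow_nonneg_threshold = FALSE) {
  if (threshold >= 0 && !allow_nonneg_threshold)
    stop("'threshold' should be negative; set allow_nonneg_threshold = TRUE ",
         "to override")
  if (!setequal(day6$barcode_id, day16$barcode_id))
    stop("day-6 and day-16 samples do not share barcode sets")
  day16 <- day16[match(day6$barcode_id, day16$barcode_id), ]
  out <- data.frame(
    barcode_id = day6$barcode_id,
    ratio_day6 = day6$log2_ratio,
    ratio_day16 = day16$log2_ratio,
    stringsAsFactors = FALSE)
  out$classified_long_lived <- out$ratio_day6 < 0 & out$ratio_day16 < 0 &
    out$ratio_day16 < threshold
  out$control_flagged <- FALSE
  class(out) <- c("screen_calls", "data.frame")
  out
}

#' Remove stochastic silencing defects using the control-library array
#'
#' Strains whose day-16 log2 ratio in the control library (reporter at a
#' constitutively silent locus) deviates from zero by more than
#' `control_tolerance` are flagged as age-independent expression outliers and
#' stripped of any long-lived classification.  Barcodes missing from the
#' control sample are flagged by convention.
#'
#' @param query_calls A `"screen_calls"` data frame from
#'   [classify_long_lived()].
#' @param control_day16 Day-16 `"array_sample"` of the control library.
#' @param control_tolerance Absolute log2 tolerance (default 1.0).
#' @return The calls with `control_flagged` set and flagged strains
#'   declassified.
#' @export
control_filter <- function(query_calls, control_day16,
                           control_tolerance = 1.0) {
  stopifnot(is.finite(control_tolerance), control_tolerance >= 0)
  idx <- match(query_calls$barcode_id, control_day16$barcode_id)
  ctrl <- control_day16$log2_ratio[idx]
  flagged <- abs(ctrl) > control_tolerance
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " barcode(s) missing from the control sample; flagged")
    flagged[is.na(idx)] <- TRUE
  }
  query_calls$control_flagged <- flagged
  query_calls$classified_long_lived <-
    query_calls$classified_long_lived & !flagged
  query_calls
}

#' @export
print.screen_calls <- function(x, ...) {
  cat(sprintf("Screen calls: %d strains, %d classified long-lived, %d %s\n",
              nrow(x), sum(x$classified_long_lived), sum(x$control_flagged),
              "control-flagged"))
  invisible(x)
}

#' Recovery of planted truth by the classifier
#'
#' Compares final calls (classified and not control-flagged) against the
#' library's planted labels, treating `"long_lived"` as the positive class.
#'
#' @param calls A `"screen_calls"` data frame.
#' @param library The [make_library()] object carrying planted labels.
#' @return A list of class `"recovery_report"`: confusion table,
#'   `sensitivity`, `specificity`, `precision`, the hypergeometric
#'   enrichment p-value of planted long-lived strains in the hit set
#'   (`enrichment_p`), and the flag rate among planted silencing-defective
#'   strains (`defective_flag_rate`, `NA` when none are planted).
#' @export
recovery_report <- function(calls, library) {
  idx <- match(calls$barcode_id, library$barcode_id)
  if (anyNA(idx)) stop("calls contain barcodes absent from the library")
  truth <- library$label[idx] == "long_lived"
  hit <- calls$classified_long_lived
  tp <- sum(hit & truth); fp <- sum(hit & !truth)
  fn <- sum(!hit & truth); tn <- sum(!hit & !truth)
  n <- length(truth)
  # P(>= tp planted strains among |hits| draws from n with sum(truth) planted)
  enrich <- if (sum(hit) == 0) 1 else
    stats::phyper(tp - 1L, sum(truth), n - sum(truth), sum(hit),
                  lower.tail = FALSE)
  defective <- library$label[idx] == "silencing_defective"
  flag_rate <- if (any(defective)) mean(calls$control_flagged[defective])
  else NA_real_
  structure(list(
    confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                       dimnames = list(truth = c("long_lived", "other"),
                                       call = c("hit", "no_hit"))),
    n_strains = n,
    n_hits = sum(hit),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    enrichment_p = enrich,
    defective_flag_rate = flag_rate), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery: %d hits / %d strains\n", x$n_hits, x$n_strains))
  print(x$confusion)
  cat(sprintf("sensitivity %.3f  specificity %.3f  precision %.3f\n",
              x$sensitivity, x$specificity, x$precision))
  cat(sprintf("hypergeometric enrichment p = %.3g\n", x$enrichment_p))
  if (!is.na(x$defective_flag_rate))
    cat(sprintf("planted defective strains control-flagged: %.1f%%\n",
                100 * x$defective_flag_rate))
  invisible(x)
}
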