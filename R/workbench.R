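# End-to-end "paper run": library -> paired +/-5-FOA simulations for the
# query and control reporters -> arrays -> classification -> control filter
# -> recovery report, with every stage seeded from one base seed and all
# outputs written as TSV plus a manifest.

#' Configuration for an end-to-end screen run
#'
#' Bundles the library parameters, culture schedule, array noise and
#' classification settings.  Stage seeds are derived deterministically from
#' `seed`, so a configuration fully determines the run.
#'
#' @param n_strains Library size.
#' @param n_long Number of planted long-lived strains (converted to a
#'   fraction of `n_strains`).
#' @param long_effect Planted relative lifespan extension.
#' @param frac_defective Fraction of silencing-defective strains.
#' @param base_lifespan Wild-type mean lifespan, generations.
#' @param lifespan_cv Per-mother lifespan coefficient of variation.
#' @param schedule A [make_schedule()].
#' @param noise_sd_log2 Array channel noise (log2 units).
#' @param threshold Day-16 classification cutoff.
#' @param control_tolerance Control-library flag tolerance (log2 units).
#' @param clock Silencing-clock mode for the simulator (see [new_pool()]).
#' @param mode `"expected"` or `"multinomial"`.
#' @param seed Base seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_strains = 3762L, n_long = 52L, long_effect = 0.4,
                       frac_defective = 0.02, base_lifespan = 30,
                       lifespan_cv = 0.35, schedule = make_schedule(),
                       noise_sd_log2 = 0.25, threshold = -2.3,
                       control_tolerance = 1.0, clock = "inherit",
                       mode = "expected", seed = 1L) {
  stopifnot(threshold < 0, n_long >= 0, n_strains >= 2)
  structure(list(n_strains = as.integer(n_strains),
                 n_long = as.integer(n_long), long_effect = long_effect,
                 frac_defective = frac_defective,
                 base_lifespan = base_lifespan, lifespan_cv = lifespan_cv,
                 schedule = schedule, noise_sd_log2 = noise_sd_log2,
                 threshold = threshold,
                 control_tolerance = control_tolerance, clock = clock,
                 mode = mode, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pooled screen and write all outputs
#'
#' Chains the whole screen: builds the library, simulates the query library
#' with and without 5-FOA and the control library likewise, hybridizes the
#' paired cultures at each sampling day, classifies long-lived strains,
#' applies the control filter, and scores recovery against the planted
#' labels.  All tables are written to `out_dir` together with a
#' `manifest.txt` of parameters and stage seeds; rerunning the same
#' configuration reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param quiet Suppress per-stage log lines?
#' @return Invisibly, a list with `library`, `trajectories`, `arrays`,
#'   `calls`, `report` and `manifest`.
#' @export
#' @examples
#' cfg <- run_config(n_strains = 40, n_long = 4, frac_defective = 0.1,
#'                   seed = 7)
#' res <- run_paper_screen(cfg, out_dir = NULL, quiet = TRUE)
#' res$report$n_hits
run_paper_screen <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- c(library = derive_seed(config$seed, 1L),
             sim = derive_seed(config$seed, 2L),
             array_query = derive_seed(config$seed, 3L),
             array_control = derive_seed(config$seed, 4L))

  say("stage library: %d strains (%d long-lived, %.0f defective planted)",
      config$n_strains, config$n_long,
      round(config$frac_defective * config$n_strains))
  lib <- make_library(config$n_strains,
                      frac_long = config$n_long / config$n_strains,
                      long_effect = config$long_effect,
                      frac_defective = config$frac_defective,
                      base_lifespan = config$base_lifespan,
                      lifespan_cv = config$lifespan_cv,
                      seed = seeds[["library"]])

  sim <- function(foa, reporter)
    run_screen(lib, config$schedule, foa_on = foa, mode = config$mode,
               seed = seeds[["sim"]], clock = config$clock,
               reporter = reporter)
  say("stage simulate: query library +/-5-FOA, %d days, %d gen/day",
      config$schedule$total_days, config$schedule$generations_per_day)
  traj <- list(query_plus = sim(TRUE, "query"),
               query_minus = sim(FALSE, "query"),
               control_plus = sim(TRUE, "control"),
               control_minus = sim(FALSE, "control"))

  say("stage hybridize: noise sd %.2f log2 units", config$noise_sd_log2)
  arrays_query <- simulate_hybridization(traj$query_plus, traj$query_minus,
                                         config$noise_sd_log2,
                                         seed = seeds[["array_query"]])
  arrays_control <- simulate_hybridization(traj$control_plus,
                                           traj$control_minus,
                                           config$noise_sd_log2,
                                           seed = seeds[["array_control"]])

  sampling <- config$schedule$sampling_days
  early <- as.character(min(sampling))
  late <- as.character(max(sampling))
  calls <- classify_long_lived(arrays_query[[early]], arrays_query[[late]],
                               threshold = config$threshold)
  n_pre <- sum(calls$classified_long_lived)
  calls <- control_filter(calls, arrays_control[[late]],
                          config$control_tolerance)
  say("stage classify: %d hits before control filter, %d after",
      n_pre, sum(calls$classified_long_lived))
  report <- recovery_report(calls, lib)

  manifest <- c(
    sprintf("n_strains\t%d", config$n_strains),
    sprintf("n_long_planted\t%d", config$n_long),
    sprintf("long_effect\t%g", config$long_effect),
    sprintf("frac_defective\t%g", config$frac_defective),
    sprintf("base_lifespan\t%g", config$base_lifespan),
    sprintf("lifespan_cv\t%g", config$lifespan_cv),
    sprintf("generations_per_day\t%d", config$schedule$generations_per_day),
    sprintf("sampling_days\t%s", paste(sampling, collapse = ",")),
    sprintf("noise_sd_log2\t%g", config$noise_sd_log2),
    sprintf("threshold\t%g", config$threshold),
    sprintf("control_tolerance\t%g", config$control_tolerance),
    sprintf("clock\t%s", config$clock),
    sprintf("mode\t%s", config$mode),
    sprintf("seed\t%d", config$seed),
    sprintf("seed_library\t%d", seeds[["library"]]),
    sprintf("seed_sim\t%d", seeds[["sim"]]),
    sprintf("seed_array_query\t%d", seeds[["array_query"]]),
    sprintf("seed_array_control\t%d", seeds[["array_control"]]),
    sprintf("n_hits\t%d", report$n_hits),
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("silencescreen"))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_library_tsv(lib, file.path(out_dir, "library.tsv"))
    write_trajectory_tsv(do.call(rbind, c(
      list(cbind(reporter = "query", rbind(traj$query_plus,
                                           traj$query_minus))),
      list(cbind(reporter = "control", rbind(traj$control_plus,
                                             traj$control_minus))))),
      file.path(out_dir, "trajectories.tsv"))
    write_array_tsv(do.call(rbind, arrays_query),
                    file.path(out_dir, "arrays_query.tsv"))
    write_array_tsv(do.call(rbind, arrays_control),
                    file.path(out_dir, "arrays_control.tsv"))
    calls_out <- calls
    calls_out$label <- lib$label[match(calls$barcode_id, lib$barcode_id)]
    write_calls_tsv(calls_out, file.path(out_dir, "calls.tsv"))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  invisible(list(library = lib, trajectories = traj,
                 arrays = list(query = arrays_query,
                               control = arrays_control),
                 calls = calls, report = report, manifest = manifest))
}

#' Write the canonical small fixture files
#'
#' Produces the miniature datasets used by the test suite and examples: a
#' two-strain library, 40-mother dissection sets with mean lifespans 17.5
#' and 27.5 generations (a wild-type-like strain and a long-lived mutant),
#' and 25-worm reproductive-span sets for a wild-type-like and a long-lived
#' worm genotype.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed = 1L, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  lib <- make_library(2, frac_long = 0, long_effect = 0.4,
                      frac_defective = 0, base_lifespan = 30,
                      seed = derive_seed(seed, 1L))
  paths["library"] <- write_library_tsv(lib, file.path(dir, "pool2.tsv"))

  wt <- make_dissection_set(strain_spec("wild_type", 17.5, lifespan_cv = 0.3),
                            n_mothers = 40, seed = derive_seed(seed, 2L),
                            genotype = "wild_type")
  mut <- make_dissection_set(strain_spec("long_lived", 27.5,
                                         lifespan_cv = 0.3),
                             n_mothers = 40, seed = derive_seed(seed, 3L),
                             genotype = "long_lived")
  paths["dissection"] <- write_dissection_tsv(list(wt, mut),
                                              file.path(dir,
                                                        "dissection.tsv"))

  worms_wt <- make_repro_set(4, matricide_hazard(), sterile_frac = 0.04,
                             n_worms = 25, seed = derive_seed(seed, 4L),
                             genotype = "worm_wild_type")
  worms_mut <- make_repro_set(6.6, matricide_hazard(rate = 0.1),
                              sterile_frac = 0.04, n_worms = 25,
                              seed = derive_seed(seed, 5L),
                              genotype = "worm_long_lived")
  paths["repro"] <- write_repro_tsv(list(worms_wt, worms_mut),
                                    file.path(dir, "repro.tsv"))
  invisible(paths)
}
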