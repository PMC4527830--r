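# Tab-separated input/output for every domain table.  All files carry a
# header row and use the column layouts documented on the writers.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("file ", path, " lacks columns: ", paste(missing, collapse = ", "))
  x
}

#' Read and write library tables
#'
#' Libraries are stored as TSV with columns `barcode_id`, `mean_lifespan`,
#' `lifespan_cv`, `loss_frac_lo`, `loss_frac_hi`, `silencing_defect` (0/1),
#' `defect_rate`, `label`.
#'
#' @param library A `"strain_library"`.
#' @param path File path.
#' @return `read_library_tsv()` returns a validated `"strain_library"`;
#'   `write_library_tsv()` returns `path` invisibly.
#' @export
write_library_tsv <- function(library, path) {
  out <- as.data.frame(library)
  out$silencing_defect <- as.integer(out$silencing_defect)
  write_tsv(out, path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  x <- read_tsv(path, c("barcode_id", "mean_lifespan", "lifespan_cv",
                        "loss_frac_lo", "loss_frac_hi", "silencing_defect",
                        "label"))
  x$silencing_defect <- as.logical(x$silencing_defect)
  if (is.null(x$defect_rate)) x$defect_rate <- 0.2
  class(x) <- c("strain_library", "data.frame")
  validate_library(x)
}

#' Read and write dissection lifespan tables
#'
#' TSV columns: `genotype`, `mother_id`, `lifespan`.  One file may hold
#' several genotypes; `read_dissection_tsv()` returns a named list of
#' `"dissection_set"` objects.
#'
#' @param sets A `"dissection_set"` or list of them.
#' @param path File path.
#' @export
write_dissection_tsv <- function(sets, path) {
  if (inherits(sets, "dissection_set")) sets <- list(sets)
  rows <- lapply(sets, function(s)
    data.frame(genotype = s$genotype,
               mother_id = seq_along(s$lifespans),
               lifespan = s$lifespans, stringsAsFactors = FALSE))
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_dissection_tsv
#' @export
read_dissection_tsv <- function(path) {
  x <- read_tsv(path, c("genotype", "mother_id", "lifespan"))
  lapply(split(x, x$genotype), function(d)
    structure(list(genotype = d$genotype[1], lifespans = as.integer(d$lifespan)),
              class = "dissection_set"))
}

#' Read and write reproductive-span tables
#'
#' TSV columns: `genotype`, `worm_id`, `last_progeny_day` (empty for sterile
#' worms), `outcome`, `sterile` (0/1).  `read_repro_tsv()` returns a named
#' list of `"repro_set"` objects.
#'
#' @param sets A `"repro_set"` or list of them.
#' @param path File path.
#' @export
write_repro_tsv <- function(sets, path) {
  if (inherits(sets, "repro_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    out <- as.data.frame(s)
    out$sterile <- as.integer(out$sterile)
    cbind(genotype = attr(s, "genotype"), out, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_repro_tsv
#' @export
read_repro_tsv <- function(path) {
  x <- read_tsv(path, c("genotype", "worm_id", "last_progeny_day", "outcome",
                        "sterile"))
  x$sterile <- as.logical(x$sterile)
  sets <- split(x, x$genotype)
  lapply(sets, function(d) {
    out <- d[c("worm_id", "last_progeny_day", "outcome", "sterile")]
    rownames(out) <- NULL
    attr(out, "genotype") <- d$genotype[1]
    class(out) <- c("repro_set", "data.frame")
    out
  })
}

#' Read and write abundance trajectories and array samples
#'
#' Trajectory TSV columns: `day`, `condition`, `barcode_id`,
#' `rel_abundance`.  Array TSV columns: `day`, `barcode_id`, `cy5`, `cy3`,
#' `log2_ratio`.  Screen-call TSV columns: `barcode_id`, `ratio_day6`,
#' `ratio_day16`, `classified` (0/1), `control_flagged` (0/1).
#'
#' @param x The object to write.
#' @param path File path.
#' @export
write_trajectory_tsv <- function(x, path) write_tsv(as.data.frame(x), path)

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  x <- read_tsv(path, c("day", "condition", "barcode_id", "rel_abundance"))
  class(x) <- c("abundance_trajectory", "data.frame")
  x
}

#' @rdname write_trajectory_tsv
#' @export
write_array_tsv <- function(x, path) write_tsv(as.data.frame(x), path)

#' @rdname write_trajectory_tsv
#' @export
read_array_tsv <- function(path) {
  x <- read_tsv(path, c("day", "barcode_id", "cy5", "cy3", "log2_ratio"))
  class(x) <- c("array_sample", "data.frame")
  x
}

#' @rdname write_trajectory_tsv
#' @export
write_calls_tsv <- function(x, path) {
  out <- as.data.frame(x)
  out$classified <- as.integer(out$classified_long_lived)
  out$control_flagged <- as.integer(out$control_flagged)
  out$classified_long_lived <- NULL
  write_tsv(out, path)
}

#' @rdname write_trajectory_tsv
#' @export
read_calls_tsv <- function(path) {
  x <- read_tsv(path, c("barcode_id", "ratio_day6", "ratio_day16",
                        "classified", "control_flagged"))
  x$classified_long_lived <- as.logical(x$classified)
  x$classified <- NULL
  x$control_flagged <- as.logical(x$control_flagged)
  class(x) <- c("screen_calls", "data.frame")
  x
}
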