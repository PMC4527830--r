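# Independent oracles used across the suite.  These deliberately share no
# code with the package: the agent simulator follows the per-cell rules
# literally, the U enumeration works from first principles, and the log-rank
# oracle builds the O-E table by hand.

# Brute-force per-cell pool simulator with deterministic lifespan L and loss
# division g (reset clock).  Every cell is a row; division, silencing loss
# and 5-FOA removal follow the verbal rules one cell at a time.
agent_pool_counts <- function(L, g, foa_on, steps) {
  cells <- data.frame(age = 0L, silenced = TRUE)
  for (s in seq_len(steps)) {
    if (foa_on && nrow(cells))
      cells <- cells[cells$silenced, , drop = FALSE]
    if (!nrow(cells)) return(0L)
    dividers <- cells$age < L
    n_new <- sum(dividers)
    cells$age[dividers] <- cells$age[dividers] + 1L
    lost <- dividers & cells$silenced & cells$age >= g
    cells$silenced[lost] <- FALSE
    if (n_new)
      cells <- rbind(cells, data.frame(age = rep(0L, n_new),
                                       silenced = rep(TRUE, n_new)))
  }
  nrow(cells)
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# sample, computing U by pair counting (not ranks).
enumerate_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  ny <- length(y)
  u_pairs <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_pairs(x, y)
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(i) u_pairs(pooled[i], pooled[-i]))
  mid <- nx * ny / 2
  list(u = u_obs, p = mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9))
}

# Hand-built log-rank chi-square from explicit event/censor vectors.
oracle_logrank <- function(time, event, grp) {
  ome <- 0
  v <- 0
  for (tt in sort(unique(time[event]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 1)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & grp == 1)
    ome <- ome + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  ome^2 / v
}

# Tiny deterministic libraries for simulator tests.
toy_library <- function(L, cv = 0, lo = 1, hi = 1, n = 2, defect = FALSE) {
  lib <- data.frame(barcode_id = sprintf("s%02d", seq_len(n)),
                    mean_lifespan = L, lifespan_cv = cv,
                    loss_frac_lo = lo, loss_frac_hi = hi,
                    silencing_defect = defect, defect_rate = 0.2,
                    label = "wildtype_like", stringsAsFactors = FALSE)
  class(lib) <- c("strain_library", "data.frame")
  lib
}

repro_set_from <- function(days, outcome = "ceased", sterile = FALSE,
                           genotype = "g") {
  n <- length(days)
  out <- data.frame(worm_id = sprintf("w%02d", seq_len(n)),
                    last_progeny_day = ifelse(rep_len(sterile, n),
                                              NA_integer_, days),
                    outcome = ifelse(rep_len(sterile, n), NA_character_,
                                     rep_len(outcome, n)),
                    sterile = rep_len(sterile, n),
                    stringsAsFactors = FALSE)
  attr(out, "genotype") <- genotype
  class(out) <- c("repro_set", "data.frame")
  out
}
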