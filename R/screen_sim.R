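# Pooled +/-5-FOA culture simulator.
#
# Two observation-equivalent representations are used per strain, both
# aggregated over cohorts rather than individual cells:
#   clock = "reset"   per-mother silencing clock: each cell draws its own
#                     lifespan and loss division; daughters are born
#                     rejuvenated (age 0, silenced, fresh parameters).
#                     Cohorts are (age, dividing/doomed/stopped) classes with
#                     age-indexed transition probabilities derived from the
#                     joint (lifespan, loss) distribution.
#   clock = "inherit" heritable derepression: the silencing clock counts
#                     divisions since the founding lineage, so an entire
#                     clone derepresses together and is killed by 5-FOA as a
#                     unit.  This reproduces the clone envelope (2^g cells at
#                     the loss generation g) at the population level and is
#                     the regime the screen's day-6/day-16 contrast relies
#                     on.  See the methods vignette for why the fully
#                     rejuvenating clock cannot generate that contrast.

# ---------------------------------------------------------------------------
# Schedules and the clone envelope
# ---------------------------------------------------------------------------

#' Define the pooled-culture schedule
#'
#' @param generations_per_day Cell generations elapsed per day of culture.
#'   The default of 3 places the day-16 sample at 48 generations, just past
#'   the silencing-loss window of a 30-generation strain (21-30 divisions)
#'   and at the closing edge of a +40 percent strain's window (29-42), the
#'   regime in which the late sample discriminates lifespan; the day-6 sample
#'   (18 generations) falls before the window opens.
#' @param reseed_interval_days Days between serial reseeds into fresh medium.
#' @param reseed_target_size Population size restored at each reseed.
#' @param sampling_days Days at which relative abundances are recorded.
#' @param total_days Length of the experiment in days.
#' @return A list of class `"screen_schedule"`.
#' @export
make_schedule <- function(generations_per_day = 3L, reseed_interval_days = 1L,
                          reseed_target_size = 1e6,
                          sampling_days = c(6L, 16L), total_days = 16L) {
  stopifnot(generations_per_day >= 1, reseed_interval_days >= 1,
            reseed_target_size > 0, total_days >= 1)
  sampling_days <- as.integer(sort(unique(sampling_days)))
  if (any(sampling_days < 0) || any(sampling_days > total_days))
    stop("'sampling_days' must lie within [0, total_days]")
  structure(list(generations_per_day = as.integer(generations_per_day),
                 reseed_interval_days = as.integer(reseed_interval_days),
                 reseed_target_size = reseed_target_size,
                 sampling_days = sampling_days,
                 total_days = as.integer(total_days)),
            class = "screen_schedule")
}

#' Closed-form clone envelope under counter-selection
#'
#' The population a single founding clone reaches when every cell doubles
#' once per generation: without 5-FOA the clone attains `2^round(L)` cells by
#' the founder's mean lifespan `L`; with 5-FOA the clone is halted at the
#' earliest silencing-loss generation `g = ceiling(loss_fraction * round(L))`
#' and reaches `2^g` cells.  A 30-generation strain thus spans 2^21 to 2^30
#' daughters depending on where in the 70-100 percent loss window
#' derepression strikes.
#'
#' @param mean_lifespan Mean replicative lifespan `L` (> 0).
#' @param foa_on Logical; is the culture under 5-FOA counter-selection?
#' @param loss_fraction Fraction of the lifespan at which silencing is lost,
#'   in (0, 1]; only used when `foa_on` is `TRUE`.
#' @return The clone population size (a double; exact for `L <= 52`).
#' @export
#' @examples
#' clone_envelope(30, foa_on = FALSE)                  # 2^30
#' clone_envelope(30, foa_on = TRUE, loss_fraction = 0.7)  # 2^21
clone_envelope <- function(mean_lifespan, foa_on, loss_fraction = 0.7) {
  if (!is.finite(mean_lifespan) || mean_lifespan <= 0)
    stop("'mean_lifespan' must be positive")
  L <- round(mean_lifespan)
  if (!foa_on) return(2^L)
  if (!is.finite(loss_fraction) || loss_fraction <= 0 || loss_fraction > 1)
    stop("'loss_fraction' must lie in (0, 1]")
  2^ceiling(loss_fraction * L)
}

# ---------------------------------------------------------------------------
# Per-strain distributions
# ---------------------------------------------------------------------------

# Integer lifespan pmf: a gamma with the given mean and CV rounded to the
# nearest integer, truncated where the upper tail falls below ~1e-12.
lifespan_pmf <- function(mu, cv) {
  if (cv == 0) {
    L <- as.integer(round(mu))
    p <- numeric(L + 1L)
    p[L + 1L] <- 1
    return(p)  # index i+1 = P(lifespan == i)
  }
  shape <- 1 / cv^2
  rate <- shape / mu
  M <- as.integer(ceiling(stats::qgamma(1 - 1e-12, shape, rate))) + 1L
  i <- 0:M
  p <- stats::pgamma(i + 0.5, shape, rate) - stats::pgamma(i - 0.5, shape, rate)
  p[1] <- stats::pgamma(0.5, shape, rate)
  p / sum(p)
}

# Discrete-uniform silencing-loss window for a mother of lifespan l.
loss_window <- function(l, lo, hi) {
  a <- max(1L, as.integer(ceiling(lo * l)))
  b <- max(a, as.integer(ceiling(hi * l)))
  c(a, b)
}

# Joint distribution of (D, killed) for the per-mother ("reset") clock,
# where D is the number of divisions a cell completes and `killed` indicates
# removal by 5-FOA at age D + 1.  Returns fkill/fstop, each indexed d+1.
divloss_pmf <- function(strain, foa_on, reporter, foa_lag) {
  fl <- lifespan_pmf(strain$mean_lifespan, strain$lifespan_cv)
  M <- length(fl) - 1L
  fkill <- numeric(M + 1L)
  fstop <- numeric(M + 1L)
  defective <- isTRUE(strain$silencing_defect)
  loses <- foa_on && (defective || reporter == "query")
  if (!loses) {
    fstop <- fl
    return(list(fkill = fkill, fstop = fstop))
  }
  for (l in 0:M) {
    w <- fl[l + 1L]
    if (w == 0) next
    if (l == 0L) {
      fstop[1L] <- fstop[1L] + w  # never divides, never derepresses
    } else if (defective) {
      p <- strain$defect_rate
      pj <- p * (1 - p)^(seq_len(l) - 1L)
      d <- pmin(l, seq_len(l) + foa_lag)
      for (j in seq_len(l)) fkill[d[j] + 1L] <- fkill[d[j] + 1L] + w * pj[j]
      fstop[l + 1L] <- fstop[l + 1L] + w * (1 - p)^l  # dies silenced
    } else {
      ab <- loss_window(l, strain$loss_frac_lo, strain$loss_frac_hi)
      g <- ab[1]:ab[2]
      d <- pmin(l, g + foa_lag)
      wg <- w / length(g)
      for (j in seq_along(g)) fkill[d[j] + 1L] <- fkill[d[j] + 1L] + wg
    }
  }
  list(fkill = fkill, fstop = fstop)
}

# Age-indexed cohort transition probabilities for the reset clock.
reset_tables <- function(strain, foa_on, reporter, foa_lag) {
  pm <- divloss_pmf(strain, foa_on, reporter, foa_lag)
  fD <- pm$fkill + pm$fstop
  M <- length(fD) - 1L
  Tge <- rev(cumsum(rev(fD)))          # Tge[d+1] = P(D >= d)
  Tge <- c(Tge, 0)                     # P(D >= M+1) = 0
  pc <- pd <- ps <- numeric(M + 1L)
  for (a in 0:(M - 1L)) {              # from a dividing cell of age a
    denom <- Tge[a + 2L]               # P(D >= a+1)
    if (denom <= 0) next
    pc[a + 1L] <- Tge[a + 3L] / denom
    pd[a + 1L] <- pm$fkill[a + 2L] / denom
    ps[a + 1L] <- pm$fstop[a + 2L] / denom
  }
  list(pc = pc, pd = pd, ps = ps, M = M,
       newborn = c(div = Tge[2L], stop = fD[1L]))
}

# Presence survival G(t) for the heritable ("inherit") clock: the factor by
# which a clone's 2^t envelope is discounted at generation t.  NULL means no
# counter-selection applies (all clones persist).
inherit_survival <- function(strain, foa_on, reporter, foa_lag, t_max) {
  defective <- isTRUE(strain$silencing_defect)
  loses <- foa_on && (defective || reporter == "query")
  if (!loses) return(NULL)
  t <- 0:t_max
  if (defective) {
    # clone derepresses at the first per-division success, tolerated foa_lag
    # further divisions
    return((1 - strain$defect_rate)^pmax(0L, t - foa_lag - 1L))
  }
  fl <- lifespan_pmf(strain$mean_lifespan, strain$lifespan_cv)
  G <- numeric(t_max + 1L)
  for (l in seq_along(fl) - 1L) {
    w <- fl[l + 1L]
    if (w == 0) next
    if (l == 0L) { G <- G + w; next }  # clone of a non-divider never loses
    ab <- loss_window(l, strain$loss_frac_lo, strain$loss_frac_hi)
    # P(g + lag >= t) for g uniform on ab[1]:ab[2]
    surv <- pmin(1, pmax(0, (ab[2] + foa_lag - t + 1) / (ab[2] - ab[1] + 1)))
    G <- G + w * surv
  }
  G
}

# ---------------------------------------------------------------------------
# PoolState
# ---------------------------------------------------------------------------

group_key <- function(lib, reporter) {
  paste(lib$mean_lifespan, lib$lifespan_cv, lib$loss_frac_lo,
        lib$loss_frac_hi, lib$silencing_defect, lib$defect_rate,
        ifelse(lib$silencing_defect, "defect", reporter), sep = "|")
}

#' Initialize a pooled-culture state
#'
#' Creates the age-and-silencing-structured cohort state for a library, with
#' every strain starting as `init_per_strain` newborn silenced cells.
#' Stochastic initialisation (`mode = "multinomial"`) consumes the current
#' RNG stream; [run_screen()] wraps everything in a seed.
#'
#' @param library A [make_library()] object (or compatible data frame).
#' @param foa_on Logical; grow the pool under 5-FOA counter-selection?
#' @param mode `"expected"` for deterministic expected counts,
#'   `"multinomial"` for integer stochastic counts.
#' @param clock `"reset"` for the per-mother silencing clock with rejuvenated
#'   daughters, `"inherit"` for lineage-heritable derepression (see the
#'   methods vignette).
#' @param reporter `"query"` for the age-responsive reporter locus,
#'   `"control"` for the constitutively silent control locus (only
#'   silencing-defective strains ever derepress).
#' @param init_per_strain Founding cells per strain.
#' @param max_generations Horizon for precomputed survival tables.
#' @param foa_lag Divisions a derepressed cell is tolerated before removal.
#' @return An object of class `"pool_state"`.
#' @seealso [step_generation()], [reseed()], [pool_counts()], [run_screen()]
#' @export
new_pool <- function(library, foa_on, mode = c("expected", "multinomial"),
                     clock = c("reset", "inherit"),
                     reporter = c("query", "control"),
                     init_per_strain = 1, max_generations = 512L,
                     foa_lag = 0L) {
  mode <- match.arg(mode)
  clock <- match.arg(clock)
  reporter <- match.arg(reporter)
  library <- validate_library(library)
  n <- nrow(library)
  keys <- group_key(library, reporter)
  groups <- lapply(split(seq_len(n), keys), function(idx) {
    strain <- library[idx[1], , drop = FALSE]
    ng <- length(idx)
    if (clock == "reset") {
      tab <- reset_tables(strain, foa_on, reporter, foa_lag)
      V <- matrix(0, nrow = tab$M + 1L, ncol = ng)
      if (mode == "expected") {
        V[1, ] <- init_per_strain * tab$newborn["div"]
        stopped <- rep.int(init_per_strain * tab$newborn["stop"], ng)
      } else {
        n0 <- as.integer(round(init_per_strain))
        born <- stats::rmultinom(ng, n0, tab$newborn)
        V[1, ] <- born[1, ]
        stopped <- as.numeric(born[2, ])
      }
      list(strains = idx, tab = tab, V = V, doomed = numeric(ng),
           stopped = stopped)
    } else {
      G <- inherit_survival(strain, foa_on, reporter, foa_lag,
                            max_generations)
      if (mode == "expected") {
        list(strains = idx, G = G, base = rep.int(init_per_strain, ng))
      } else {
        t_max <- max_generations
        cls <- matrix(0, nrow = t_max + 1L, ncol = ng)
        n0 <- as.integer(round(init_per_strain))
        if (is.null(G)) {
          cls[t_max + 1L, ] <- n0
        } else {
          for (s in seq_len(ng)) {
            l <- sample_mother_lifespan(strain, n0)
            g <- sample_loss_generation(strain, pmax(l, 1L), n0) + foa_lag
            j <- pmin(g, t_max + 1L)
            cls[, s] <- tabulate(j, nbins = t_max + 1L)
          }
        }
        list(strains = idx, cls = cls)
      }
    }
  })
  structure(list(time_generations = 0L, foa_on = foa_on, mode = mode,
                 clock = clock, reporter = reporter, foa_lag = foa_lag,
                 library = library, groups = groups,
                 max_generations = as.integer(max_generations)),
            class = "pool_state")
}

#' Per-strain cell counts of a pool
#'
#' @param state A `"pool_state"`.
#' @return Named numeric vector of present-cell counts, one per barcode.
#' @export
pool_counts <- function(state) {
  n <- nrow(state$library)
  counts <- numeric(n)
  t <- state$time_generations
  for (gr in state$groups) {
    if (state$clock == "reset") {
      counts[gr$strains] <- colSums(gr$V) + gr$doomed + gr$stopped
    } else if (state$mode == "expected") {
      # gr$base tracks the unselected doubling (times reseed rescales);
      # gr$G discounts it by the clone-survival probability at time t
      surv <- if (is.null(gr$G)) 1 else gr$G[min(t, length(gr$G) - 1L) + 1L]
      counts[gr$strains] <- gr$base * surv
    } else {
      counts[gr$strains] <- colSums(gr$cls)
    }
  }
  names(counts) <- state$library$barcode_id
  counts
}

#' Advance the pool by one cell generation
#'
#' Every dividing cell divides: the mother advances one age unit, losing
#' silencing if this division reaches her loss generation, and a rejuvenated
#' silenced daughter is born (reset clock).  Cells past their lifespan stop
#' dividing but remain in the pool; under 5-FOA, cells that lost silencing
#' are removed at the following step.  Under the inherit clock the whole
#' clone shares one silencing clock and is removed together.
#'
#' @param state A `"pool_state"`.
#' @return The advanced `"pool_state"`.
#' @export
step_generation <- function(state) {
  t_new <- state$time_generations + 1L
  if (state$clock == "inherit" && t_new > state$max_generations)
    stop("pool stepped beyond 'max_generations'; rebuild with a larger horizon")
  for (k in seq_along(state$groups)) {
    gr <- state$groups[[k]]
    if (state$clock == "reset") {
      tab <- gr$tab
      M <- tab$M
      V <- gr$V
      if (state$foa_on) gr$doomed[] <- 0  # removed this step
      ndiv <- colSums(V)
      if (state$mode == "expected") {
        V2 <- matrix(0, nrow = M + 1L, ncol = ncol(V))
        if (M >= 1L)
          V2[2:(M + 1L), ] <- V[1:M, , drop = FALSE] * tab$pc[1:M]
        gr$doomed <- gr$doomed + colSums(V * tab$pd)
        gr$stopped <- gr$stopped + colSums(V * tab$ps)
        V2[1, ] <- V2[1, ] + ndiv * tab$newborn["div"]
        gr$stopped <- gr$stopped + ndiv * tab$newborn["stop"]
      } else {
        V2 <- matrix(0, nrow = M + 1L, ncol = ncol(V))
        for (a in which(rowSums(V) > 0) - 1L) {
          pr <- c(tab$pc[a + 1L], tab$pd[a + 1L], tab$ps[a + 1L])
          if (sum(pr) <= 0) next
          for (s in which(V[a + 1L, ] > 0)) {
            fate <- stats::rmultinom(1, V[a + 1L, s], pr)
            if (a + 2L <= M + 1L) V2[a + 2L, s] <- V2[a + 2L, s] + fate[1]
            gr$doomed[s] <- gr$doomed[s] + fate[2]
            gr$stopped[s] <- gr$stopped[s] + fate[3]
          }
        }
        for (s in which(ndiv > 0)) {
          b <- stats::rmultinom(1, ndiv[s], tab$newborn)
          V2[1, s] <- V2[1, s] + b[1]
          gr$stopped[s] <- gr$stopped[s] + b[2]
        }
      }
      gr$V <- V2
    } else if (state$mode == "expected") {
      gr$base <- gr$base * 2
    } else {
      # clones whose clock reads j are present through generation j and
      # removed at the following step
      cls <- gr$cls * 2
      if (state$foa_on && t_new >= 2L) cls[seq_len(t_new - 1L), ] <- 0
      gr$cls <- cls
    }
    state$groups[[k]] <- gr
  }
  state$time_generations <- t_new
  state
}

#' Reseed the pool into fresh medium
#'
#' Expected mode rescales every cohort by `target_size / total`, leaving
#' relative abundances untouched; multinomial mode draws a multinomial sample
#' of `round(target_size)` cells over all cohorts.
#'
#' @param state A `"pool_state"`.
#' @param target_size Population size after reseeding.
#' @param mode `"expected"` or `"multinomial"`; defaults to the pool's own
#'   mode.
#' @return The reseeded `"pool_state"`.
#' @export
reseed <- function(state, target_size, mode = state$mode) {
  mode <- match.arg(mode, c("expected", "multinomial"))
  total <- sum(pool_counts(state))
  if (total <= 0) stop("cannot reseed an empty pool")
  if (mode == "expected") {
    f <- target_size / total
    for (k in seq_along(state$groups)) {
      gr <- state$groups[[k]]
      if (state$clock == "reset") {
        gr$V <- gr$V * f
        gr$doomed <- gr$doomed * f
        gr$stopped <- gr$stopped * f
      } else if (state$mode == "expected") {
        gr$base <- gr$base * f
      } else {
        gr$cls <- gr$cls * f
      }
      state$groups[[k]] <- gr
    }
    return(state)
  }
  # multinomial subsampling over every cohort cell class
  pools <- list()
  for (k in seq_along(state$groups)) {
    gr <- state$groups[[k]]
    pools[[k]] <- if (state$clock == "reset")
      c(as.numeric(gr$V), gr$doomed, gr$stopped) else as.numeric(gr$cls)
  }
  lens <- vapply(pools, length, 1L)
  flat <- unlist(pools)
  draw <- as.numeric(stats::rmultinom(1, as.integer(round(target_size)),
                                      flat / sum(flat)))
  off <- 0L
  for (k in seq_along(state$groups)) {
    gr <- state$groups[[k]]
    piece <- draw[off + seq_len(lens[k])]
    off <- off + lens[k]
    if (state$clock == "reset") {
      nV <- length(gr$V)
      ng <- ncol(gr$V)
      gr$V <- matrix(piece[seq_len(nV)], nrow = nrow(gr$V))
      gr$doomed <- piece[nV + seq_len(ng)]
      gr$stopped <- piece[nV + ng + seq_len(ng)]
    } else {
      gr$cls <- matrix(piece, nrow = nrow(gr$cls))
    }
    state$groups[[k]] <- gr
  }
  state
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf(
    "Pool state: %d strains, generation %d, %s clock, %s mode, 5-FOA %s\n",
    nrow(x$library), x$time_generations, x$clock, x$mode,
    if (x$foa_on) "on" else "off"))
  cat(sprintf("  total cells: %.4g\n", sum(pool_counts(x))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# run_screen
# ---------------------------------------------------------------------------

#' Simulate one pooled culture over the full schedule
#'
#' Initializes equal per-strain abundance, iterates [step_generation()] with
#' serial reseeds, and records relative abundances at the sampling days.
#'
#' @inheritParams new_pool
#' @param schedule A [make_schedule()] object.
#' @param seed Integer seed (drives the multinomial mode; the expected mode
#'   is deterministic).
#' @return A `data.frame` of class `"abundance_trajectory"` with columns
#'   `day`, `condition`, `barcode_id`, `rel_abundance`; fractions sum to 1
#'   within each sampled day.
#' @export
#' @examples
#' lib <- make_library(4, frac_long = 0.25, long_effect = 0.4,
#'                     base_lifespan = 30, seed = 1)
#' tr <- run_screen(lib, make_schedule(), foa_on = TRUE, clock = "inherit")
#' subset(tr, day == 16)
run_screen <- function(library, schedule = make_schedule(), foa_on,
                       mode = c("expected", "multinomial"), seed = 1L,
                       clock = c("reset", "inherit"),
                       reporter = c("query", "control"), foa_lag = 0L,
                       init_per_strain = NULL) {
  mode <- match.arg(mode)
  clock <- match.arg(clock)
  reporter <- match.arg(reporter)
  stopifnot(inherits(schedule, "screen_schedule"))
  library <- validate_library(library)
  n <- nrow(library)
  if (is.null(init_per_strain))
    init_per_strain <- max(1, schedule$reseed_target_size / n)
  total_gens <- schedule$total_days * schedule$generations_per_day
  condition <- if (foa_on) "plus_foa" else "minus_foa"

  with_seed(seed, {
    state <- new_pool(library, foa_on, mode, clock, reporter,
                      init_per_strain = init_per_strain,
                      max_generations = total_gens, foa_lag = foa_lag)
    rows <- list()
    record <- function(day, state) {
      counts <- pool_counts(state)
      total <- sum(counts)
      if (total <= 0)
        stop(sprintf("pool extinct under 5-FOA on day %d", day))
      data.frame(day = day, condition = condition,
                 barcode_id = names(counts),
                 rel_abundance = as.numeric(counts) / total,
                 stringsAsFactors = FALSE)
    }
    if (0L %in% schedule$sampling_days) rows[["0"]] <- record(0L, state)
    for (day in seq_len(schedule$total_days)) {
      for (g in seq_len(schedule$generations_per_day)) {
        state <- step_generation(state)
        if (sum(pool_counts(state)) <= 0)
          stop(sprintf("pool extinct under 5-FOA on day %d", day))
      }
      if (day %in% schedule$sampling_days)
        rows[[as.character(day)]] <- record(day, state)
      if (day %% schedule$reseed_interval_days == 0L &&
          day < schedule$total_days)
        state <- reseed(state, schedule$reseed_target_size)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("abundance_trajectory", "data.frame")
    out
  })
}
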