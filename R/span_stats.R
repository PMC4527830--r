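# Replicative-lifespan and reproductive-span statistics used to validate
# screen hits strain by strain.

# ---------------------------------------------------------------------------
# Replicative lifespan (yeast dissection data)
# ---------------------------------------------------------------------------

#' Summarize a dissection lifespan dataset
#'
#' @param data A `"dissection_set"` (see [make_dissection_set()]), or any
#'   list with `genotype` and nonnegative integer `lifespans`.
#' @return A list of class `"rls_summary"`: `genotype`, `n_mothers`,
#'   `mean_lifespan`, `median_lifespan` (linear interpolation at the 50
#'   percent point for even sample sizes), `max_lifespan`, and
#'   `survival_curve`, a data frame giving the fraction of mothers still
#'   dividing at each generation (1 at generation 0, non-increasing to 0).
#' @export
#' @examples
#' summarize_rls(list(genotype = "wt", lifespans = c(10, 20, 30, 40)))
summarize_rls <- function(data) {
  x <- data$lifespans
  if (length(x) < 1L) stop("empty dissection set")
  stopifnot(all(x >= 0))
  gens <- 0:(max(x) + 1L)
  curve <- data.frame(generations = gens,
                      surviving = vapply(gens, function(g) mean(x >= g), 1))
  structure(list(genotype = data$genotype,
                 n_mothers = length(x),
                 mean_lifespan = mean(x),
                 median_lifespan = stats::median(x),
                 max_lifespan = max(x),
                 survival_curve = curve),
            class = "rls_summary")
}

#' @export
print.rls_summary <- function(x, ...) {
  cat(sprintf(
    "RLS '%s': n = %d, mean %.2f, median %.2f, max %d generations\n",
    x$genotype, x$n_mothers, x$mean_lifespan, x$median_lifespan,
    as.integer(x$max_lifespan)))
  invisible(x)
}

#' Select the eight data points flanking the 50 percent lifespan point
#'
#' Returns the four sorted lifespans immediately at-or-below the median
#' position and the four immediately above it (ties resolved by sorted
#' index, i.e. toward the median).  `method = "nearest"` instead picks the
#' eight values closest to the sample median by absolute distance, breaking
#' distance ties toward the median position.
#'
#' @param data A `"dissection_set"` with at least 8 mothers.
#' @param method `"position"` (default) or `"nearest"`.
#' @return Sorted numeric vector of length 8, a multiset subset of the data.
#' @export
#' @examples
#' flank8_select(list(genotype = "wt", lifespans = 1:40))  # positions 17-24
flank8_select <- function(data, method = c("position", "nearest")) {
  method <- match.arg(method)
  x <- sort(data$lifespans)
  n <- length(x)
  if (n < 8L) stop("need at least 8 mothers to flank the median")
  if (method == "nearest") {
    med <- stats::median(x)
    ord <- order(abs(x - med), abs(seq_len(n) - (n + 1) / 2))
    return(sort(x[ord[1:8]]))
  }
  m <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L  # median position
  lo <- m - 3L
  hi <- m + 4L
  if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
  if (hi > n) { lo <- lo - (hi - n); hi <- n }
  x[lo:hi]
}

# ---------------------------------------------------------------------------
# Mann-Whitney U
# ---------------------------------------------------------------------------

#' Mann-Whitney U test with exact enumeration or normal approximation
#'
#' The U statistic counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count
#' one half), so `U_x + U_y = n_x * n_y`.  The exact mode enumerates every
#' assignment of the pooled values to the two groups, which remains valid
#' under ties; the approximation uses the tie-corrected normal distribution
#' with continuity correction (as [stats::wilcox.test()] does).  `auto`
#' selects the exact mode whenever both groups have at most 10 observations.
#' P-values are two-sided.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A list of class `"span_test"` with `statistic` (U of `x`),
#'   `p_value`, `method` and `n_per_group`.
#' @export
#' @examples
#' mann_whitney_u(1:4, 5:8, mode = "exact")  # U = 0, p = 2/70
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  if (mode == "auto") mode <- if (nx <= 10L && ny <= 10L) "exact"
  else "normal_approx"
  u_stat <- function(xi, yi) {
    r <- rank(c(xi, yi))
    sum(r[seq_along(xi)]) - length(xi) * (length(xi) + 1) / 2
  }
  u <- u_stat(x, y)
  if (mode == "exact") {
    pooled <- c(x, y)
    splits <- utils::combn(nx + ny, nx)
    mid <- nx * ny / 2
    us <- apply(splits, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mid) >= abs(u - mid) - 1e-9)
    method <- "mann_whitney_exact"
  } else {
    mu <- nx * ny / 2
    ties <- table(c(x, y))
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "mann_whitney_normal"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n_per_group = c(nx, ny)), class = "span_test")
}

#' @export
print.span_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reproductive span (worm daily-progeny data)
# ---------------------------------------------------------------------------

#' End of reproduction from a daily progeny table
#'
#' The reproductive span ends on the last day with progeny that is followed
#' by two consecutive progeny-free days; later progeny production resets the
#' rule.  When the observation window closes before two empty days have been
#' seen, the worm is right-censored and `NA` is returned.
#'
#' @param daily_progeny Nonnegative integer vector of progeny counts indexed
#'   from day 1 of adulthood.
#' @return Integer cessation day, or `NA_integer_` if not yet ceased.
#' @export
#' @examples
#' repro_cessation_day(c(5, 8, 6, 0, 0))     # 3
#' repro_cessation_day(c(5, 0, 0, 2, 0, 0))  # 4
#' repro_cessation_day(c(5, 8, 6, 0))        # NA: censored
repro_cessation_day <- function(daily_progeny) {
  stopifnot(all(daily_progeny >= 0))
  pos <- which(daily_progeny > 0)
  if (!length(pos)) return(NA_integer_)
  d <- pos[length(pos)]
  if (d + 2L <= length(daily_progeny)) as.integer(d) else NA_integer_
}

#' Fraction of adults still reproducing, day by day
#'
#' Builds the reproduction curve from a [make_repro_set()] dataset: sterile
#' worms are excluded; each included worm reproduces through its
#' `last_progeny_day`; matricide worms are reproductively active when they
#' die, so by default they are right-censored at the matricide day
#' (Kaplan-Meier product-limit handling keeps the curve non-increasing);
#' `matricide = "drop"` excludes them entirely instead.  Worms alive at the
#' end of observation are always censored.
#'
#' @param data A `"repro_set"` data frame.
#' @param matricide `"censor"` (default) or `"drop"`.
#' @return A list of class `"repro_curve"`: `genotype`, `curve` (data frame
#'   of `day` and `fraction_reproducing`), `n_included`,
#'   `n_sterile_excluded`, `n_matricide`.
#' @export
build_repro_curve <- function(data, matricide = c("censor", "drop")) {
  matricide <- match.arg(matricide)
  sterile <- data$sterile
  keep <- !sterile
  n_mat <- sum(data$outcome[keep] == "matricide", na.rm = TRUE)
  if (matricide == "drop") keep <- keep & data$outcome != "matricide"
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no worms left after sterile exclusion")
  time <- d$last_progeny_day
  event <- d$outcome == "ceased"
  days <- seq_len(max(time))
  # product-limit survivor of the cessation time T; a worm reproduces on day
  # d iff T >= d, so fraction(d) = S(d - 1)
  S <- 1
  frac <- numeric(length(days))
  for (day in days) {
    frac[day] <- S
    at_risk <- sum(time >= day)
    events <- sum(event & time == day)
    if (at_risk > 0) S <- S * (1 - events / at_risk)
  }
  structure(list(genotype = attr(data, "genotype"),
                 curve = data.frame(day = days, fraction_reproducing = frac),
                 n_included = nrow(d),
                 n_sterile_excluded = sum(sterile),
                 n_matricide = n_mat),
            class = "repro_curve")
}

#' @export
print.repro_curve <- function(x, ...) {
  cat(sprintf(
    "Reproductive span '%s': %d worms (%d sterile excluded, %d matricide)\n",
    if (is.null(x$genotype)) "?" else x$genotype, x$n_included,
    x$n_sterile_excluded, x$n_matricide))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Mantel-Cox (log-rank) test between two reproductive-span groups
#'
#' Compares cessation-time distributions with the standard one-degree-of-
#' freedom log-rank chi-square.  Events are reproductive cessations;
#' matricide and end-of-observation are right-censoring (matricide worms may
#' alternatively be dropped).  Sterile worms are excluded.
#'
#' @param groupA,groupB `"repro_set"` data frames.
#' @param matricide `"censor"` (default) or `"drop"`.
#' @return A list of class `"span_test"` with the chi-square `statistic`,
#'   `p_value`, `method = "logrank"` and `n_per_group`.
#' @export
logrank_test <- function(groupA, groupB, matricide = c("censor", "drop")) {
  matricide <- match.arg(matricide)
  prep <- function(d) {
    d <- d[!d$sterile, , drop = FALSE]
    if (matricide == "drop") d <- d[d$outcome != "matricide", , drop = FALSE]
    data.frame(time = d$last_progeny_day, event = d$outcome == "ceased")
  }
  a <- prep(groupA); b <- prep(groupB)
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(0L, 1L), c(nrow(a), nrow(b)))
  if (!any(event)) stop("no cessation events in the pooled data")
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[event]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d_t <- sum(event & time == tt)
    d1 <- sum(event & time == tt & grp == 1L)
    o_minus_e <- o_minus_e + d1 - d_t * n1 / n
    if (n > 1)
      v <- v + d_t * (n1 / n) * (1 - n1 / n) * (n - d_t) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "logrank",
                 n_per_group = c(nrow(a), nrow(b))),
            class = "span_test")
}

#' Percent change between two lifespan summaries
#'
#' @param summary_a,summary_b `"rls_summary"` objects (baseline and
#'   comparison).
#' @param field `"mean"`, `"median"` or `"max"`.
#' @return `100 * (b - a) / a`.
#' @export
#' @examples
#' # mean lifespans 17.5 -> 27.5 give +57.1 percent
percent_change <- function(summary_a, summary_b,
                           field = c("mean", "median", "max")) {
  field <- match.arg(field)
  nm <- paste0(field, "_lifespan")
  a <- summary_a[[nm]]
  b <- summary_b[[nm]]
  if (!is.finite(a) || a <= 0) stop("baseline value must be positive")
  100 * (b - a) / a
}
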