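#' Irwin-Hall survival function
#'
#' Tail probability `P(S_K >= y)` for a sum `S_K` of `K` independent
#' Uniform(0,1) variables. The exact alternating-series form of the
#' Irwin-Hall CDF is used up to `k_switch` (evaluated with compensated
#' summation and reflected through the distribution's symmetry about `K/2`
#' so the alternating sum never suffers catastrophic cancellation in the
#' tail); beyond `k_switch` the normal approximation with mean `K/2` and
#' variance `K/12` is used.
#'
#' @param y numeric vector of observed sums.
#' @param k number of uniform summands (single positive integer).
#' @param k_switch order above which the normal approximation replaces the
#'   exact series. Default 30, where the two agree to well under 1e-3.
#' @return numeric vector of tail probabilities, `1` where `y < 0` and `0`
#'   where `y >= k`.
#' @export
irwin_hall_sf <- function(y, k, k_switch = 30L) {
  stopifnot(length(k) == 1L, k >= 1, k == as.integer(k))
  k <- as.integer(k)
  out <- numeric(length(y))
  out[y < 0] <- 1
  mid <- which(y >= 0 & y < k)
  if (length(mid)) {
    if (k > k_switch) {
      out[mid] <- pnorm(y[mid], mean = k / 2, sd = sqrt(k / 12),
                        lower.tail = FALSE)
    } else {
      yy <- y[mid]
      hi <- yy > k / 2
      v <- numeric(length(yy))
      # SF(y) = 1 - CDF(y); by symmetry SF(y) = CDF(k - y) for y > k/2
      if (any(hi))  v[hi]  <- ih_cdf_exact(k - yy[hi], k)
      if (any(!hi)) v[!hi] <- 1 - ih_cdf_exact(yy[!hi], k)
      out[mid] <- pmin(pmax(v, 0), 1)
    }
  }
  out
}

# Exact Irwin-Hall CDF at 0 <= x <= k/2 + 1 via the alternating series
#   CDF(x) = (1/k!) sum_{j=0}^{floor(x)} (-1)^j choose(k,j) (x-j)^k
# with Kahan-compensated accumulation of the signed terms.
ih_cdf_exact <- function(x, k) {
  res <- numeric(length(x))
  jmax <- floor(max(x))
  s <- numeric(length(x))
  comp <- numeric(length(x))
  for (j in 0:jmax) {
    act <- x >= j
    if (!any(act)) break
    term <- numeric(length(x))
    xm <- x[act] - j
    lt <- lchoose(k, j) + k * log(xm) - lfactorial(k)
    term[act] <- (-1)^j * exp(lt)
    term[act][xm == 0] <- 0
    # Kahan step
    yk <- term - comp
    tk <- s + yk
    comp <- (tk - s) - yk
    s <- tk
  }
  res <- s
  res[x <= 0] <- 0
  res
}

#' Poisson-mixture tail probability for the recurrence statistic
#'
#' Overall significance of an observed sum-of-residuals statistic `y` when
#' the number of contributing events `K` is itself Poisson with intensity
#' `lambda`: `p_raw = sum_{K>=1} IH_SF(y | K) * Pois(K | lambda)`, truncated
#' once the remaining Poisson tail mass falls below `tail_tol` (the
#' truncation error is bounded by that mass since the survival function is
#' at most 1). Because neither `y` nor the mixture is defined at `K = 0`,
#' only the conditional value `p_raw / P(K >= 1)` is uniform under the null;
#' both are returned and downstream ranking uses the conditional one.
#'
#' @param y numeric vector of observed statistics (>= 0).
#' @param lambda Poisson intensities, recycled against `y`. Must be > 0.
#' @param tail_tol truncation tolerance for the infinite mixture sum.
#' @param k_switch passed to [irwin_hall_sf()].
#' @return list with components `p_raw` and `p_conditional` (the latter
#'   clipped to at most 1).
#' @export
poisson_mixture_pvalue <- function(y, lambda, tail_tol = 1e-12,
                                   k_switch = 30L) {
  stopifnot(all(y >= 0), tail_tol > 0, tail_tol <= 1e-6)
  n <- max(length(y), length(lambda))
  y <- rep_len(y, n)
  lambda <- rep_len(lambda, n)
  if (any(lambda <= 0))
    stop("lambda must be positive wherever an event was observed")
  p_raw <- numeric(n)
  k <- 0L
  repeat {
    k <- k + 1L
    w <- dpois(k, lambda)
    # group y's by identical k so irwin_hall_sf vectorizes over y
    p_raw <- p_raw + w * irwin_hall_sf(y, k, k_switch = k_switch)
    if (all(ppois(k, lambda, lower.tail = FALSE) < tail_tol)) break
    if (k > 1e6) stop("Poisson mixture failed to truncate")
  }
  p_ge1 <- -expm1(-lambda)
  list(p_raw = p_raw, p_conditional = pmin(1, p_raw / p_ge1))
}

#' Cauchy combination of dependent p-values
#'
#' Combines p-values computed from the same data under different score
#' predictors into one: `T = mean(tan(pi * (0.5 - p)))`, returned as
#' `0.5 - atan(T) / pi`. Valid under arbitrary dependence between the
#' component tests, which is why it is used across correlated
#' deleteriousness predictors.
#'
#' @param pvals numeric vector of p-values in (0, 1); values at the
#'   boundaries are clamped to `[1e-15, 1 - 1e-15]` with a warning.
#' @return a single combined p-value.
#' @export
cauchy_combine <- function(pvals) {
  stopifnot(length(pvals) >= 1, all(is.finite(pvals)))
  eps <- 1e-15
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("p-values at 0 or 1 clamped before Cauchy combination")
    pvals <- pmin(pmax(pvals, eps), 1 - eps)
  }
  tstat <- mean(tan(pi * (0.5 - pvals)))
  if (tstat > 1e15) return(1 / (pi * tstat))  # atan precision floor
  0.5 - atan(tstat) / pi
}

#' Benjamini-Hochberg step-up adjustment, tolerant of weighted Q > 1
#'
#' Standard BH step-up with monotonicity enforcement. Unlike
#' `stats::p.adjust`, inputs above 1 are accepted (constraint-weighted
#' Q-values can exceed 1); adjusted values are capped at 1. With all-unit
#' weights this is exactly plain BH.
#'
#' @param values positive numeric vector of p- or Q-values.
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(values) {
  n <- length(values)
  if (n == 0L) return(numeric(0))
  stopifnot(all(values > 0))
  o <- order(values, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * values[o]))
  adj[order(o)]
}

#' One-sided Fisher exact upper-tail probability
#'
#' Hypergeometric tail probability that the top stratum of a 2x2 table is
#' at least as enriched for successes as observed (the enrichment
#' direction). Degenerate margins return 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts; rows are the two
#'   strata (e.g. top-k vs rest of a ranking), columns success/failure.
#' @return the one-sided enrichment p-value.
#' @export
fisher_exact_upper <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1, 1]
  m <- table[1, 1] + table[2, 1]   # total successes
  nn <- table[1, 2] + table[2, 2]  # total failures
  k <- table[1, 1] + table[1, 2]   # top stratum size
  if (m == 0 || nn == 0 || k == 0 || k == m + nn) return(1)
  phyper(a - 1, m, nn, k, lower.tail = FALSE)
}
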