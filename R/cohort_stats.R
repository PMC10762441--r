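#' Dive-weighted cohort proportions of dive types
#'
#' Computes each individual's dive-type proportions, then averages them
#' across individuals weighted by each individual's total number of dives,
#' \eqn{p_{type} = \sum_i w_i \, p_{i,type}} with \eqn{w_i = n_i / \sum_j n_j}.
#' Per-individual and cohort proportions each sum to 1. Individuals
#' contributing zero dives are excluded with a warning.
#'
#' @param typed a data frame with `individual_id` and `dive_type` columns
#'   (one row per dive), e.g. typed-dive tables of several animals bound
#'   together, optionally pre-filtered to one stratum (day or night).
#' @return list with `per_individual` (id, n_dives, one proportion column per
#'   type) and `cohort` (named numeric vector of weighted proportions).
#' @examples
#' df <- data.frame(individual_id = rep(c("a", "b"), c(100, 300)),
#'                  dive_type = c(rep(c("drift", "transit"), c(20, 80)),
#'                                rep(c("drift", "transit"), c(180, 120))))
#' weighted_proportions(df)$cohort[["drift"]]  # 0.5
#' @export
weighted_proportions <- function(typed) {
  stopifnot(all(c("individual_id", "dive_type") %in% names(typed)))
  ids <- unique(typed$individual_id)
  tab <- t(vapply(ids, function(id) {
    tabulate(factor(typed$dive_type[typed$individual_id == id],
                    levels = dive_types()), nbins = 4)
  }, numeric(4)))
  colnames(tab) <- dive_types()
  n <- rowSums(tab)
  if (any(n == 0)) {
    warning("individual(s) with zero dives excluded: ",
            paste(ids[n == 0], collapse = ", "))
    tab <- tab[n > 0, , drop = FALSE]
    ids <- ids[n > 0]
    n <- n[n > 0]
  }
  if (!length(n)) stop("no individual with any dives")
  props <- tab / n
  w <- n / sum(n)
  cohort <- colSums(props * w)
  per <- data.frame(individual_id = ids, n_dives = n, props,
                    row.names = NULL, check.names = FALSE)
  list(per_individual = per, cohort = cohort)
}

#' Two-sample z-test for proportions (no continuity correction)
#'
#' The pooled-variance z statistic for comparing two binomial proportions,
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},}
#' with \eqn{\hat p = (x_1+x_2)/(n_1+n_2)} and a two-sided p-value from the
#' standard normal. No continuity correction is applied. Swapping the samples
#' flips the sign of z and leaves p unchanged. When the pooled proportion is
#' 0 or 1 the statistic is undefined and `NA` is returned with a warning.
#'
#' @param x1,n1 successes and trials in the first sample.
#' @param x2,n2 successes and trials in the second sample.
#' @return an object of class `"htest"` with `statistic` (z), `p.value`, and
#'   `estimate` (the two proportions).
#' @examples
#' two_sample_z_prop(60, 100, 50, 100)  # z = 1.4213, p = 0.1553
#' @export
two_sample_z_prop <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is 0 or 1; z undefined")
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(prop1 = p1, prop2 = p2),
                 alternative = "two.sided",
                 method = "Two-sample z-test for proportions (no continuity correction)",
                 data.name = sprintf("%g/%g vs %g/%g", x1, n1, x2, n2)),
            class = "htest")
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two samples. The U
#' statistic is reported for the first sample, computed from midranks so that
#' ties are handled. The two-sided p-value comes from exact enumeration of
#' the null distribution (via the Wilcoxon count distribution) when
#' `n1 * n2 <= 400` and there are no ties, and otherwise from the normal
#' approximation with tie-corrected variance and a continuity correction.
#' `U1 + U2 = n1 * n2` always; identical samples give U near `n1 n2 / 2`;
#' two samples sharing a single constant value give p = 1 with a warning.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) decides by the rule above. Exact enumeration is not
#'   available with ties.
#' @return an object of class `"htest"` with `statistic` (U for `x`),
#'   `p.value`, and `method` recording which path produced p.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nt <- table(c(x, y))
  ties <- any(nt > 1)
  use_exact <- exact %||% (n1 * n2 <= 400 && !ties)
  if (use_exact && ties) {
    warning("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    mu <- n1 * n2 / 2
    p <- if (U > mu) 2 * (1 - stats::pwilcox(U - 1, n1, n2))
         else 2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    N <- n1 + n2
    tiesum <- sum(nt^3 - nt)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tiesum / (N * (N - 1)))
    if (sig2 <= 0) {
      warning("all values identical across both samples; p = 1")
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = U), p.value = p,
                 alternative = "two.sided", method = method,
                 data.name = sprintf("x (n=%d) vs y (n=%d)", n1, n2)),
            class = "htest")
}

#' Cohort comparison report
#'
#' Convenience wrapper producing the standard cohort comparisons for two
#' groups of typed dives: dive-weighted type proportions per group, a
#' z-test per dive type on the pooled day/night (or group) proportions, and
#' Mann-Whitney tests on the pooled per-dive maximum depth and duration.
#' Pooling dives across individuals treats dives as independent; with few
#' animals this is pseudo-replication, so the per-individual table is
#' returned alongside for inspection.
#'
#' @param typed_a,typed_b typed-dive tables for the two groups (each with
#'   `individual_id`, `dive_type`, `max_depth`, `duration`).
#' @param labels length-2 character names for the groups.
#' @return list with `proportions` (per group), `z_tests` (per dive type),
#'   `depth_test`, `duration_test`.
#' @export
compare_cohorts <- function(typed_a, typed_b, labels = c("A", "B")) {
  pa <- weighted_proportions(typed_a)
  pb <- weighted_proportions(typed_b)
  zt <- lapply(dive_types(), function(ty) {
    two_sample_z_prop(sum(typed_a$dive_type == ty), nrow(typed_a),
                      sum(typed_b$dive_type == ty), nrow(typed_b))
  })
  names(zt) <- dive_types()
  list(proportions = stats::setNames(list(pa, pb), labels),
       z_tests = zt,
       depth_test = mann_whitney_u(typed_a$max_depth, typed_b$max_depth),
       duration_test = mann_whitney_u(typed_a$duration, typed_b$duration))
}
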