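#' Binomial proportion confidence interval
#'
#' The four constructions compared by Brown, Cai & DasGupta: Wilson score,
#' Jeffreys (Beta(x + 1/2, n - x + 1/2) equal-tailed quantiles with the
#' boundary modifications lower = 0 at x = 0 and upper = 1 at x = n),
#' exact Clopper-Pearson (Beta inversion; lower = (alpha/2)^(1/n) when
#' x = n), and Agresti-Coull (adjusted Wald). The upper bound is 1 when
#' x = n for every method.
#'
#' @param x Successes (0..n).
#' @param n Trials (> 0).
#' @param method One of "clopper_pearson", "wilson", "jeffreys",
#'   "agresti_coull".
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' binomial_ci(505, 505)  # lower ~0.9927, the 99.26-100% interval
binomial_ci <- function(x, n, method = c("clopper_pearson", "wilson",
                                         "jeffreys", "agresti_coull"),
                        level = 0.95) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be > 0")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  z <- qnorm(1 - alpha / 2)
  ci <- switch(method,
    clopper_pearson = {
      lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
      hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
      c(lo, hi)
    },
    wilson = {
      center <- (x + z^2 / 2) / (n + z^2)
      hw <- z / (n + z^2) * sqrt(x * (n - x) / n + z^2 / 4)
      c(center - hw, center + hw)
    },
    jeffreys = {
      lo <- if (x == 0) 0 else qbeta(alpha / 2, x + 0.5, n - x + 0.5)
      hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 0.5, n - x + 0.5)
      c(lo, hi)
    },
    agresti_coull = {
      n_t <- n + z^2
      p_t <- (x + z^2 / 2) / n_t
      hw <- z * sqrt(p_t * (1 - p_t) / n_t)
      c(p_t - hw, p_t + hw)
    }
  )
  pmin(1, pmax(0, ci))
}

#' Confusion matrix for one abnormality class
#'
#' Reduces calls and truth labels to a binary task for one abnormality:
#' a sample is call-positive when its `call_class` equals the class (a
#' MOSAIC call counts as positive for its base class when
#' `count_mosaic = TRUE`), truth-positive when the expected call of its
#' true karyotype equals the class. INDETERMINATE calls count as
#' negative under policy "negative" or are dropped under "exclude".
#'
#' @param calls Data frame with `sample_id`, `call_class` (and
#'   `base_class` when mosaics are counted).
#' @param truth Data frame with `sample_id`, `true_karyotype` (ISCN-like
#'   strings) or `true_class` (pre-mapped classes).
#' @param abnormality Call class, e.g. "T21", "X0".
#' @param count_mosaic Count MOSAIC-of-this-class calls as positive.
#' @param indeterminate One of "negative", "exclude".
#' @return List with tp, fp, tn, fn (class `confusion_matrix`).
#' @export
confusion <- function(calls, truth, abnormality, count_mosaic = TRUE,
                      indeterminate = c("negative", "exclude")) {
  indeterminate <- match.arg(indeterminate)
  if (!abnormality %in% karyotype_classes) {
    stop("unknown abnormality class '", abnormality, "'")
  }
  if (!setequal(calls$sample_id, truth$sample_id)) {
    stop("sample_id sets of calls and truth do not match")
  }
  m <- merge(calls, truth, by = "sample_id")
  if (indeterminate == "exclude") {
    m <- m[m$call_class != "INDETERMINATE", , drop = FALSE]
  }
  if (is.null(m$true_class)) {
    kmap <- vapply(setNames(nm = unique(m$true_karyotype)), expected_call, "")
    m$true_class <- kmap[m$true_karyotype]
  }
  called_pos <- m$call_class == abnormality
  if (count_mosaic && "base_class" %in% names(m)) {
    called_pos <- called_pos |
      (m$call_class == "MOSAIC" & !is.na(m$base_class) &
         m$base_class == abnormality)
  }
  truth_pos <- m$true_class == abnormality
  structure(list(tp = sum(called_pos & truth_pos),
                 fp = sum(called_pos & !truth_pos),
                 tn = sum(!called_pos & !truth_pos),
                 fn = sum(!called_pos & truth_pos)),
            class = "confusion_matrix")
}

#' Sensitivity and specificity with confidence intervals
#'
#' sens = tp/(tp + fn), spec = tn/(tn + fp). Under the
#' "all_observations" denominator convention the CI for each proportion
#' is computed on the full cohort size n = tp + fp + tn + fn (the
#' convention under which a perfectly concordant cohort of 505 yields
#' the same 99.27-100% exact interval for every abnormality); under
#' "standard" the CI uses the respective denominator.
#'
#' @param cm A `confusion_matrix`.
#' @param method CI method, see [binomial_ci()].
#' @param denominator_convention "all_observations" or "standard".
#' @param level Confidence level.
#' @return List with sensitivity, specificity, their CIs, n used, and
#'   flags for undefined proportions.
#' @export
performance <- function(cm, method = "clopper_pearson",
                        denominator_convention = c("all_observations", "standard"),
                        level = 0.95) {
  denominator_convention <- match.arg(denominator_convention)
  stopifnot(inherits(cm, "confusion_matrix"))
  n_total <- cm$tp + cm$fp + cm$tn + cm$fn
  one <- function(x, n) {
    if (n == 0) {
      return(list(value = NA_real_, ci = c(NA_real_, NA_real_),
                  flag = "UNDEFINED"))
    }
    p <- x / n
    if (denominator_convention == "all_observations") {
      ci <- binomial_ci(round(p * n_total), n_total, method, level)
    } else {
      ci <- binomial_ci(x, n, method, level)
    }
    list(value = p, ci = ci, flag = "OK")
  }
  sens <- one(cm$tp, cm$tp + cm$fn)
  spec <- one(cm$tn, cm$tn + cm$fp)
  list(sensitivity = sens$value, sens_ci = sens$ci, sens_flag = sens$flag,
       specificity = spec$value, spec_ci = spec$ci, spec_flag = spec$flag,
       ci_method = method, denominator_convention = denominator_convention,
       n = if (denominator_convention == "all_observations") n_total else NA_integer_)
}

# exact null distribution of the Mann-Whitney U statistic: counts of
# arrangements with U = 0..m*n via the classic recurrence
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)
u_count_table <- function(m, n) {
  maxu <- m * n
  # tab[[mi+1]][u+1] = counts for group sizes (mi, n)
  tab <- matrix(0, nrow = m + 1, ncol = maxu + 1)
  tab[1, 1] <- 1
  for (mi in seq_len(m)) {
    # iterate the second recurrence dimension implicitly: build counts
    # for (mi, n) from (mi-1, n) using the generating-function identity
    # f_{mi,n}(q) = f_{mi-1,n}(q) * (1 - q^(n+mi)) / (1 - q^mi)
    prev <- tab[mi, ]
    cur <- numeric(maxu + 1)
    # multiply prev by 1/(1 - q^mi): cumulative sums with lag mi
    acc <- prev
    for (u in seq.int(mi, maxu)) acc[u + 1] <- acc[u + 1] + acc[u + 1 - mi]
    # multiply by (1 - q^(n+mi))
    cur <- acc
    if (n + mi <= maxu) {
      idx <- seq.int(n + mi, maxu)
      cur[idx + 1] <- cur[idx + 1] - acc[idx + 1 - (n + mi)]
    }
    tab[mi + 1, ] <- cur
  }
  tab[m + 1, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups of chromosomal ratios. The U
#' statistic is computed from midranks; the two-sided p-value uses the
#' exact null distribution of U (own dynamic-programming enumeration)
#' when there are no ties and n_a * n_b <= `exact_max`, and the normal
#' approximation with tie and continuity corrections otherwise.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param exact_max Largest n_a * n_b for the exact path.
#' @return List with `U` (for group_a), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(group_a, group_b, exact_max = 400) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  m <- length(group_a); n <- length(group_b)
  ranks <- rank(c(group_a, group_b))
  U <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (!has_ties && m * n <= exact_max) {
    counts <- u_count_table(m, n)
    total <- sum(counts)
    p_le <- sum(counts[seq_len(U + 1)]) / total
    p_ge <- sum(counts[seq.int(U + 1, m * n + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- m + n
  mu <- m * n / 2
  tie_tab <- table(ranks)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal")
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cohort percentage summary
#'
#' Percentages of labelled counts over a denominator, rounded half-up to
#' two decimals (65 of 125 -> 52.00).
#'
#' @param counts Named numeric vector of class counts.
#' @param denominator Total (> 0, >= every count).
#' @return Data frame with class, count, percent.
#' @export
#' @examples
#' cohort_summary(c(T21 = 65, T18 = 30), 125)
cohort_summary <- function(counts, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (any(counts > denominator)) stop("count exceeds denominator")
  data.frame(class = names(counts),
             count = as.numeric(counts),
             percent = round_half_up(100 * as.numeric(counts) / denominator, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Validate calls against truth across abnormality classes
#'
#' @param calls,truth As in [confusion()].
#' @param abnormalities Classes to score.
#' @param method,denominator_convention,level Passed to [performance()].
#' @return Data frame with one row per abnormality: tp/fp/tn/fn,
#'   sensitivity/specificity and their CI bounds.
#' @export
validate_calls <- function(calls, truth,
                           abnormalities = c("T13", "T18", "T21", "X0"),
                           method = "clopper_pearson",
                           denominator_convention = "all_observations",
                           level = 0.95) {
  rows <- lapply(abnormalities, function(ab) {
    cm <- confusion(calls, truth, ab)
    pf <- performance(cm, method, denominator_convention, level)
    data.frame(abnormality = ab, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn,
               sensitivity = pf$sensitivity,
               sens_lo = pf$sens_ci[1], sens_hi = pf$sens_ci[2],
               specificity = pf$specificity,
               spec_lo = pf$spec_ci[1], spec_hi = pf$spec_ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
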