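## Paired nonparametric statistics and population comparison tables.

#' Two-sided Wilcoxon matched-pair signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original method; the Pratt
#' variant, which ranks zeros before dropping them, is available via
#' `zero_method`). Ties receive mid-ranks. The null distribution of the
#' signed-rank sum is enumerated exactly (conditional on the observed
#' mid-ranks) for up to `exact_limit` non-zero differences; above that a
#' normal approximation with tie correction is used. The reported statistic
#' `W` is the smaller of the positive and negative rank sums.
#'
#' @param a,b paired numeric vectors (reference and comparator).
#' @param exact_limit maximum `n` for exact enumeration (default 15).
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @return object of class `wilcoxon_result`: `statistic` (W), `n_effective`,
#'   `p_two_sided`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 15,
                                 zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- b - a
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = 0, n_effective = 0L, p_two_sided = 1,
                          method = "degenerate"), class = "wilcoxon_result"))
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    # exact null: enumerate the distribution of W+ over all 2^n sign
    # assignments by convolution over doubled (integer) mid-ranks
    r2 <- round(2 * r)
    probs <- 1
    for (ri in r2) {
      probs <- c(probs, numeric(ri)) / 2 +
        c(numeric(ri), probs) / 2
    }
    support <- seq_along(probs) - 1  # values of 2*W+
    w2 <- round(2 * w_plus)
    p_lo <- sum(probs[support <= w2])
    p_hi <- sum(probs[support >= w2])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    # continuity correction toward the null mean
    z <- (w_plus - mu - 0.5 * sign(w_plus - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = w, n_effective = n, p_two_sided = p,
                 method = method), class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("wilcoxon_result: W = %g, n = %d, two-sided p = %.4g (%s)\n",
              x$statistic, x$n_effective, x$p_two_sided, x$method))
  invisible(x)
}

#' Percent reduction of a value relative to a reference
#'
#' `100 * (reference - new) / reference`; positive when the new value is
#' lower.
#'
#' @param reference,new numeric values, `reference != 0`.
#' @return percent reduction.
#' @export
reduction_percent <- function(reference, new) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (reference - new) / reference
}

#' Round half away from zero
#'
#' Report tables use 1-decimal half-up rounding (the convention of clinical
#' tables), which differs from R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Summarize paired per-case metrics for two techniques
#'
#' For each metric: mean (min-max) per technique, two-sided paired Wilcoxon
#' p-value, and the percent reduction of the comparator mean relative to the
#' reference mean.
#'
#' @param metrics data frame with columns `case`, `metric`, `reference`,
#'   `comparator` (one row per case and metric; rows for the same metric
#'   must be aligned by case).
#' @param digits decimal places for rounded report columns.
#' @return data frame with one row per metric: means, ranges, reduction
#'   percent, p-value (`NA` with a single case).
#' @export
summarize_population <- function(metrics, digits = 1) {
  stopifnot(all(c("case", "metric", "reference", "comparator") %in% names(metrics)))
  out <- lapply(split(metrics, metrics$metric), function(mm) {
    if (anyDuplicated(mm$case)) stop("misaligned cases: duplicate case per metric")
    p <- if (nrow(mm) > 1 && any(mm$reference != mm$comparator)) {
      wilcoxon_signed_rank(mm$reference, mm$comparator)$p_two_sided
    } else NA_real_
    data.frame(metric = mm$metric[1], n = nrow(mm),
               reference_mean = round_half_up(mean(mm$reference), digits),
               reference_min = min(mm$reference),
               reference_max = max(mm$reference),
               comparator_mean = round_half_up(mean(mm$comparator), digits),
               comparator_min = min(mm$comparator),
               comparator_max = max(mm$comparator),
               reduction_pct = round_half_up(
                 reduction_percent(mean(mm$reference), mean(mm$comparator)), digits),
               p_two_sided = p)
  })
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  rows
}

#' Summarize delivery tables (MU, time, gamma pass rates)
#'
#' Aggregates a per-plan delivery table into technique means and paired
#' tests. Delivery-time reduction is reported both as the mean of per-plan
#' reductions and as the reduction of mean times; the two aggregations
#' differ and neither is privileged.
#'
#' @param delivery data frame with columns `mu_reference`, `mu_comparator`,
#'   `time_s_reference`, `time_s_comparator`, `gamma_reference`,
#'   `gamma_comparator` (one row per plan).
#' @return list of summary components.
#' @export
summarize_delivery <- function(delivery) {
  list(
    gamma_mean_reference = round_half_up(mean(delivery$gamma_reference), 1),
    gamma_mean_comparator = round_half_up(mean(delivery$gamma_comparator), 1),
    gamma_p = wilcoxon_signed_rank(delivery$gamma_reference,
                                   delivery$gamma_comparator)$p_two_sided,
    mu_mean_reference = mean(delivery$mu_reference),
    mu_mean_comparator = mean(delivery$mu_comparator),
    mu_p = wilcoxon_signed_rank(delivery$mu_reference,
                                delivery$mu_comparator)$p_two_sided,
    time_reduction_mean_of_plans = round_half_up(mean(reduction_percent(
      delivery$time_s_reference, delivery$time_s_comparator)), 1),
    time_reduction_of_means = round_half_up(reduction_percent(
      mean(delivery$time_s_reference), mean(delivery$time_s_comparator)), 1),
    time_p = wilcoxon_signed_rank(delivery$time_s_reference,
                                  delivery$time_s_comparator)$p_two_sided)
}

#' Parse "m:ss" duration strings to seconds
#' @param x character vector like `"6:52"`.
#' @return numeric seconds.
#' @export
parse_min_sec <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

#' Load a bundled benchmark table
#'
#' The package ships, as plain CSV, per-patient benchmark tables from the
#' ten-patient adaptive head-and-neck dose-painting trial that this class
#' solution was developed against: quality factors, integral doses,
#' delivery statistics (MU, time, gamma pass rates) and population dose
#' levels. They let the reporting arithmetic be validated without any
#' patient images.
#'
#' @param name one of `"trial_qf"`, `"trial_integral_dose"`,
#'   `"trial_delivery"`, `"trial_population_dose"`.
#' @return data frame.
#' @export
load_benchmark_table <- function(name = c("trial_qf", "trial_integral_dose",
                                          "trial_delivery",
                                          "trial_population_dose")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "dosepaint",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
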