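#' Exact two-sided rank-sum test p-value by full enumeration
#'
#' Computes the exact null distribution of the Wilcoxon rank-sum statistic by
#' enumerating all `choose(n + m, n)` assignments of the pooled observations
#' to group A. Ties receive midranks (tied values share the average of the
#' ranks they span), so the enumeration remains exact in the presence of
#' ties, where the classical tables do not apply. The two-sided p-value
#' doubles the smaller tail probability of the observed rank sum and caps at
#' 1; with ties the null distribution need not be symmetric, which is why
#' tail doubling (rather than reflecting one tail) is used.
#'
#' For two groups of five with complete separation the smallest attainable
#' two-sided p-value is `2 / choose(10, 5) = 2/252 = 0.00794`.
#'
#' @param group_a,group_b Numeric vectors, both nonempty, with
#'   `choose(length(a) + length(b), length(a)) <= 1e6` (the exact
#'   enumeration regime; larger cohorts would need a normal approximation,
#'   which this function deliberately does not provide).
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' exact_ranksum_p(1:5, 6:10)  # 0.007936508 = 2/252
#' @export
exact_ranksum_p <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 1, length(group_b) >= 1,
            all(is.finite(group_a)), all(is.finite(group_b)))
  n <- length(group_a)
  m <- length(group_b)
  n_comb <- choose(n + m, n)
  if (n_comb > 1e6) {
    stop(sprintf(
      "choose(%d, %d) = %.3g assignments exceeds the exact enumeration bound (1e6); a normal approximation is out of scope",
      n + m, n, n_comb))
  }
  pooled <- c(group_a, group_b)
  r <- rank(pooled, ties.method = "average")
  w_obs <- sum(r[seq_len(n)])
  subsets <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[subsets], nrow = n))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Per-metric samples from two plan cohorts
#'
#' @param metric Canonical metric string or `metric_spec`.
#' @param structure Structure name the metric belongs to.
#' @param group_a,group_b Numeric metric values for the two cohorts.
#' @param labels Length-2 character vector naming the cohorts.
#' @return A `metric_samples` list.
#' @export
metric_samples <- function(metric, structure, group_a, group_b,
                           labels = c("A", "B")) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1, length(labels) == 2)
  if (length(group_a) > 20 || length(group_b) > 20) {
    stop("group sizes above 20 are outside the exact enumeration regime")
  }
  structure(list(metric = as_metric_spec(metric)$text, structure = structure,
                 group_a = as.numeric(group_a), group_b = as.numeric(group_b),
                 labels = as.character(labels)),
            class = "metric_samples")
}

#' Compare two plan cohorts metric by metric
#'
#' Produces the comparison table used when two planning techniques are
#' applied to the same cases: per metric, group means and medians plus the
#' exact two-sided rank-sum p-value.
#'
#' @param samples List of [metric_samples()] objects.
#' @return Data frame with columns `structure`, `metric`, `mean_a`, `mean_b`,
#'   `median_a`, `median_b`, `p_two_sided` (one row per metric; empty input
#'   gives an empty table). Writable as CSV.
#' @export
compare_cohorts <- function(samples) {
  if (length(samples) == 0) {
    return(data.frame(structure = character(0), metric = character(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      median_a = numeric(0), median_b = numeric(0),
                      p_two_sided = numeric(0)))
  }
  stopifnot(all(vapply(samples, inherits, TRUE, "metric_samples")))
  rows <- lapply(samples, function(s) {
    data.frame(structure = s$structure, metric = s$metric,
               mean_a = mean(s$group_a), mean_b = mean(s$group_b),
               median_a = stats::median(s$group_a),
               median_b = stats::median(s$group_b),
               p_two_sided = exact_ranksum_p(s$group_a, s$group_b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read cohort samples from a long-format CSV
#'
#' Expected columns: `structure`, `metric`, `group`, `value`; `group` must
#' take exactly two levels per metric.
#'
#' @param path CSV path.
#' @return List of `metric_samples`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "metric", "group", "value")
  if (!all(need %in% names(df))) {
    stop("cohort CSV needs columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(df[c("structure", "metric")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$structure == keys$structure[i] & df$metric == keys$metric[i], ]
    gl <- sort(unique(sub$group))
    if (length(gl) != 2) {
      stop(sprintf("metric %s/%s does not have exactly two groups",
                   keys$structure[i], keys$metric[i]))
    }
    metric_samples(keys$metric[i], keys$structure[i],
                   sub$value[sub$group == gl[1]],
                   sub$value[sub$group == gl[2]],
                   labels = gl)
  })
}
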