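## Culture assay module: growth-rate fitting, lag classification after
## washing, and the two statistical tests used on amendment experiments.

#' Exponential growth rate from a density time series
#'
#' Least-squares slope of `ln(density)` versus time inside the stated phase
#' window -- the standard log-linear fit for batch-culture exponential
#' growth. The window is an experimental input (read off the growth curve),
#' not inferred. The rate is invariant under rescaling densities by a
#' positive constant.
#'
#' @param times Time in days.
#' @param densities Cell densities (cells/mL), positive inside the window.
#' @param window Length-2 numeric `(t_start, t_end)` delimiting the fit;
#'   default: the full series.
#' @return Growth rate in 1/day.
#' @export
growth_rate <- function(times, densities, window = range(times)) {
  if (length(times) != length(densities)) {
    stop("`times` and `densities` must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3) {
    stop("need at least 3 points inside the phase window", call. = FALSE)
  }
  d <- densities[sel]
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("densities inside the phase window must be positive",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(d) ~ times[sel]))[2])
}

#' Classify a post-washing lag
#'
#' A washed culture counts as lagged when its density fails to rise at least
#' `resume_factor` above the post-wash starting density within `lag_days`
#' days of resuspension (time zero). The 50% default resumption threshold is
#' robust to counting noise while matching visual lag calls on growth
#' curves.
#'
#' @param times Days since resuspension (first entry is the baseline time).
#' @param densities Post-wash cell densities.
#' @param lag_days Days within which growth must resume (default 2).
#' @param resume_factor Required fractional rise above the baseline density
#'   (default 0.5).
#' @return `TRUE` if the culture lagged, `FALSE` otherwise.
#' @export
classify_lag <- function(times, densities, lag_days = 2,
                         resume_factor = 0.5) {
  if (!length(times) || length(times) != length(densities)) {
    stop("non-empty, equal-length `times` and `densities` required",
         call. = FALSE)
  }
  baseline <- densities[1]
  if (!is.finite(baseline) || baseline <= 0) {
    stop("post-wash baseline density must be positive", call. = FALSE)
  }
  inside <- times <= lag_days
  !any(densities[inside] >= (1 + resume_factor) * baseline)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value by hypergeometric enumeration: with the table's
#' margins fixed, the probabilities of all admissible tables are summed for
#' tables no more probable than the observed one (with a 1e-7 relative slack
#' on the comparison, the standard guard against floating-point ties). A
#' zero margin makes every table identical and returns p = 1.
#'
#' @param x 2x2 matrix (or object coercible to one) of non-negative integer
#'   counts.
#' @return Two-tailed p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(6, 0, 0, 6), 2)) # 2/924
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) stop("`x` must be 2x2", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m <- sum(x[1, ]) # row 1 margin
  n <- sum(x[2, ]) # row 2 margin
  k <- sum(x[, 1]) # column 1 margin
  if (m == 0 || n == 0 || k == 0 || sum(x[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-tailed two-sample t-test p-value
#'
#' Student's pooled-variance form by default (matching the conventional
#' "two-tailed Student's t test" on replicate summaries); set
#' `pooled = FALSE` for the Welch form. Two groups that are both constant
#' return p = 1 when their means agree (no evidence of a difference) and 0
#' otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance Student statistic (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return Two-tailed p-value.
#' @export
two_sample_t <- function(group_a, group_b, pooled = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = pooled)$p.value
}

#' Compare lag incidence between two conditions
#'
#' Builds the 2x2 lagged/not-lagged table for two treatment groups and
#' returns it with the two-tailed Fisher exact p-value.
#'
#' @param lagged_a,n_a Lagged replicate count and total replicates in
#'   condition A.
#' @param lagged_b,n_b Same for condition B.
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
compare_lag_counts <- function(lagged_a, n_a, lagged_b, n_b) {
  if (lagged_a > n_a || lagged_b > n_b) {
    stop("lagged counts cannot exceed totals", call. = FALSE)
  }
  tab <- matrix(c(lagged_a, n_a - lagged_a, lagged_b, n_b - lagged_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(condition = c("A", "B"),
                                outcome = c("lagged", "resumed")))
  list(table = tab, p_value = fisher_exact_2x2(tab))
}

#' Summarize growth rates across conditions
#'
#' Fits [growth_rate()] to each replicate curve of a long-format growth
#' table and reports per-condition means, SDs, and the Student t p-value of
#' each amended condition against its unamended control.
#'
#' @param curves data.frame with columns `time_days`, `density`, `condition`
#'   (medium label), `adenine_molar`, `replicate`.
#' @param window Phase window `(t_start, t_end)` passed to [growth_rate()].
#' @return data.frame with one row per condition x adenine level:
#'   `condition`, `adenine_molar`, `n`, `mean_rate`, `sd_rate`,
#'   `p_vs_control`.
#' @export
growth_rate_table <- function(curves, window) {
  req <- c("time_days", "density", "condition", "adenine_molar", "replicate")
  miss <- setdiff(req, names(curves))
  if (length(miss)) {
    stop("curves lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(curves$condition, curves$adenine_molar,
                     curves$replicate, drop = TRUE)
  fits <- lapply(split(seq_len(nrow(curves)), key), function(idx) {
    sub <- curves[idx, , drop = FALSE]
    sub <- sub[order(sub$time_days), , drop = FALSE]
    data.frame(condition = sub$condition[1],
               adenine_molar = sub$adenine_molar[1],
               replicate = sub$replicate[1],
               rate = growth_rate(sub$time_days, sub$density, window))
  })
  fits <- do.call(rbind, fits)
  key2 <- interaction(fits$condition, fits$adenine_molar, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(fits)), key2), function(idx) {
    sub <- fits[idx, , drop = FALSE]
    control <- fits$rate[fits$condition == sub$condition[1] &
                           fits$adenine_molar == 0]
    data.frame(
      condition = sub$condition[1], adenine_molar = sub$adenine_molar[1],
      n = nrow(sub), mean_rate = mean(sub$rate),
      sd_rate = stats::sd(sub$rate),
      p_vs_control = if (sub$adenine_molar[1] == 0 || length(control) < 2)
        NA_real_ else two_sample_t(sub$rate, control)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$adenine_molar), , drop = FALSE]
  rownames(out) <- NULL
  out
}
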