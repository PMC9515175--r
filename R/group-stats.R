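#' Two-sided pooled-variance Student's t-test
#'
#' Classic two-sample Student's t-test (equal variances pooled, two-sided,
#' `n_a + n_b - 2` degrees of freedom), with a Welch variant behind a flag.
#' When the pooled variance is zero and the means are equal, `t = 0, p = 1`
#' by convention; zero variance with different means is an error.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the unequal-variance (Welch) test instead (default FALSE).
#' @return List with `t`, `p`, `df`, `n_a`, `n_b`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  degenerate <- function() {
    if (isTRUE(all.equal(mean(a), mean(b))))
      list(t = 0, p = 1, df = length(a) + length(b) - 2L,
           n_a = length(a), n_b = length(b))
    else stop("degenerate samples: zero variance with different means",
              call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) return(degenerate())
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = !welch, alternative = "two.sided"),
    error = function(e) {
      if (grepl("essentially constant", conditionMessage(e)))
        return(NULL)
      stop(e)
    })
  if (is.null(ht)) return(degenerate())
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), n_a = length(a), n_b = length(b))
}

#' Compare every treatment group to control, per metric and day
#'
#' Aggregates per-colony measurement records and runs a two-sided Student's
#' t-test of each non-control group against the control group within each
#' `(metric, day)` cell, mirroring a distance-by-day comparison matrix.
#' P-values are reported raw (no multiple-testing correction), and
#' significance is called at p < 0.05.
#'
#' @param records Records data frame (see [measurement_records()]).
#' @param metrics Metric name(s) to compare; default all present.
#' @param control_label Group label of the control (default `"control"`).
#' @param welch Use Welch's t-test (default FALSE, pooled variance).
#' @return Data frame with columns `metric, day, group_a, group_b, n_a, n_b,
#'   t_statistic, p_value, significant`.
#' @export
compare_to_control <- function(records, metrics = NULL,
                               control_label = "control", welch = FALSE) {
  stopifnot(all(records_columns %in% names(records)))
  if (is.null(metrics)) metrics <- unique(records$metric)
  if (!control_label %in% records$group)
    stop(sprintf("control group '%s' not found in records", control_label),
         call. = FALSE)
  out <- list()
  for (m in metrics) {
    rm_ <- records[records$metric == m, ]
    for (d in sort(unique(rm_$day))) {
      rd <- rm_[rm_$day == d, ]
      ctrl <- rd$value[rd$group == control_label]
      # metrics undefined for controls (e.g. edge regression) are skipped
      if (length(ctrl) < 2L) next
      for (g in setdiff(unique(rd$group), control_label)) {
        trt <- rd$value[rd$group == g]
        if (length(trt) < 2L) next
        tt <- two_sample_ttest(trt, ctrl, welch = welch)
        out[[length(out) + 1L]] <- data.frame(
          metric = m, day = d, group_a = g, group_b = control_label,
          n_a = tt$n_a, n_b = tt$n_b, t_statistic = tt$t, p_value = tt$p,
          significant = tt$p < 0.05, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(metric = character(0), day = integer(0),
                      group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      t_statistic = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  do.call(rbind, out)
}
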