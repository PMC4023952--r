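#' Mixed between-within ANOVA
#'
#' Fits the standard mixed-design ANOVA used throughout the analysis: a
#' between-subjects factor (condition) crossed with a within-subjects
#' factor (task, measurement type, or test time), one observation per
#' participant and within-level. The between effect is tested against
#' the subjects-within-groups error and the within and interaction
#' effects against the subject-by-within error, via `stats::aov` with an
#' `Error(id/within)` stratum. When the within factor has a single level
#' the design reduces to a one-way between-subjects ANOVA and only the
#' between row is returned.
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param between name of the between-subjects factor column.
#' @param within name of the within-subjects factor column.
#' @param id name of the participant identifier column.
#' @return tibble with columns `effect` (`"between"`, `"within"`,
#'   `"interaction"`), `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data, dv, between, within, id = "participant_id") {
  stopifnot(all(c(dv, between, within, id) %in% names(data)))
  d <- data.frame(
    y = data[[dv]],
    b = factor(data[[between]]),
    w = factor(data[[within]]),
    s = factor(data[[id]])
  )
  if (anyNA(d$y)) stop("missing values in the dependent variable", call. = FALSE)
  cells <- table(d$b, d$w)
  if (any(cells == 0)) {
    stop("empty design cell(s): every condition must observe every within level",
         call. = FALSE)
  }
  per <- table(d$s, d$w)
  if (any(per[per > 0] != 1)) {
    stop("expected exactly one observation per participant and within level",
         call. = FALSE)
  }
  if (nlevels(d$w) == 1L) {
    fit <- stats::aov(y ~ b, data = d)
    tab <- summary(fit)[[1]]
    res <- zero_ss_rule(tab$`Sum Sq`[1], tab$`F value`[1], tab$`Pr(>F)`[1])
    return(tibble::tibble(
      effect = "between", F = res$F,
      df1 = tab$Df[1], df2 = tab$Df[2], p = res$p
    ))
  }
  fit <- stats::aov(y ~ b * w + Error(s / w), data = d)
  sm <- summary(fit)
  row_of <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    res <- zero_ss_rule(tab$`Sum Sq`[i], tab$`F value`[i], tab$`Pr(>F)`[i])
    list(F = res$F, df1 = tab$Df[i],
         df2 = tab$Df[match("Residuals", trimws(rownames(tab)))],
         p = res$p)
  }
  btw <- row_of("Error: s", "b")
  wth <- row_of("Error: s:w", "w")
  int <- row_of("Error: s:w", "b:w")
  tibble::tibble(
    effect = c("between", "within", "interaction"),
    F = c(btw$F, wth$F, int$F),
    df1 = c(btw$df1, wth$df1, int$df1),
    df2 = c(btw$df2, wth$df2, int$df2),
    p = c(btw$p, wth$p, int$p)
  )
}

# An effect with zero sum of squares carries no evidence regardless of the
# error term; report F = 0, p = 1 instead of the 0/0 NaN that arises when
# the dv is constant.
zero_ss_rule <- function(ss, F, p) {
  if (!is.na(ss) && ss <= .Machine$double.eps^0.75) list(F = 0, p = 1) else list(F = F, p = p)
}

#' Power of the between-subjects F test
#'
#' Noncentral-F power for a one-way between-subjects comparison of
#' `k_groups` groups of `n_per_group` participants at standardized
#' effect size RMSSE (root-mean-square standardized effect). The
#' noncentrality parameter is lambda = n (k - 1) RMSSE^2, the convention
#' under which RMSSE = 0.5 with k = 3 and n = 16 yields power close
#' to .7 at alpha = .05.
#'
#' @param k_groups number of groups (>= 2).
#' @param n_per_group participants per group (>= 2).
#' @param rmsse root-mean-square standardized effect (>= 0).
#' @param alpha type-I error rate, in (0, 1).
#' @return power, a probability.
#' @export
#' @examples
#' anova_power_between(3, 16, 0.5)  # ~ 0.69
anova_power_between <- function(k_groups, n_per_group, rmsse, alpha = 0.05) {
  if (k_groups < 2 || n_per_group < 2) stop("need k >= 2 groups of n >= 2", call. = FALSE)
  if (rmsse < 0) stop("rmsse must be non-negative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df1 <- k_groups - 1
  df2 <- k_groups * (n_per_group - 1)
  lambda <- n_per_group * (k_groups - 1) * rmsse^2
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}

#' Serial-order error analysis of mean estimates
#'
#' For each participant, compares the mean estimate with the mean of the
#' values actually experienced early on, late, and overall: it returns
#' the absolute error against the first-`quarter` trials, the
#' last-`quarter` trials, and all trials. Under random (order-blind)
#' sampling the total-mean error is expected to be smallest; a recency
#' (primacy) process shrinks the last- (first-) quarter error instead.
#' Other partitions are supported through `quarter`.
#'
#' @param responses data frame with columns `participant_id` and
#'   `est_mean`.
#' @param stimuli long data frame of the presented sequences with
#'   columns `participant_id`, `order_index`, `value`.
#' @param quarter number of leading/trailing trials per window; at most
#'   half the sequence length.
#' @return tibble with one row per participant: `participant_id`,
#'   `err_first`, `err_last`, `err_total`.
#' @export
quarter_order_analysis <- function(responses, stimuli, quarter = 30) {
  stopifnot(all(c("participant_id", "est_mean") %in% names(responses)),
            all(c("participant_id", "order_index", "value") %in% names(stimuli)))
  out <- lapply(seq_len(nrow(responses)), function(i) {
    pid <- responses$participant_id[i]
    est <- responses$est_mean[i]
    seq_i <- stimuli[stimuli$participant_id == pid, ]
    seq_i <- seq_i[order(seq_i$order_index), ]
    n <- nrow(seq_i)
    if (quarter > n / 2) {
      stop("quarter window larger than half the sequence", call. = FALSE)
    }
    v <- seq_i$value
    tibble::tibble(
      participant_id = pid,
      err_first = abs(est - mean(v[seq_len(quarter)])),
      err_last = abs(est - mean(v[(n - quarter + 1):n])),
      err_total = abs(est - mean(v))
    )
  })
  do.call(rbind, out)
}

#' Collapse mean and median deviations into one central-tendency measure
#'
#' Mean and median estimates carry the same information about central
#' tendency and are averaged into a single measure: signed deviations
#' are averaged, and absolute deviations are averaged separately (not
#' recomputed from the collapsed signed value).
#'
#' @param dev_mean,dev_median [deviation()] results, each computed
#'   against its own normative value.
#' @return a `deviation` with `measurement = "central_tendency"`.
#' @export
collapse_central_tendency <- function(dev_mean, dev_median) {
  stopifnot(inherits(dev_mean, "deviation"), inherits(dev_median, "deviation"))
  structure(list(
    signed = (dev_mean$signed + dev_median$signed) / 2,
    absolute = (dev_mean$absolute + dev_median$absolute) / 2,
    measurement = "central_tendency"
  ), class = "deviation")
}

#' Optional outlier screen on deviation scores
#'
#' Flags participants whose absolute deviation exceeds
#' `c_iqr` interquartile ranges above the third quartile. Off by default
#' in all analyses; provided because extreme estimates occasionally
#' occur and some analysts exclude them.
#'
#' @param absolute numeric vector of absolute deviations.
#' @param c_iqr IQR multiplier for the cutoff.
#' @return logical vector, TRUE for flagged (outlying) entries.
#' @export
flag_outliers <- function(absolute, c_iqr = 3) {
  q <- stats::quantile(absolute, c(0.25, 0.75), names = FALSE)
  absolute > q[2] + c_iqr * (q[2] - q[1])
}
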