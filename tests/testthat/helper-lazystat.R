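# Independent naive-loop Shape Index: explicit summation, no vectorization,
# kept deliberately separate from the package implementation.
naive_si <- function(x, p, config = si_config()) {
  s <- config$sign_vector
  total <- 0
  for (i in 1:10) {
    total <- total + s[i] * (x[i] - p[i])
  }
  total
}

# Random decile profile (proportions summing to 1).
random_profile <- function() {
  r <- runif(10)
  r / sum(r)
}

# Random profile guaranteed to stay in [0, 0.2] per bin, so its reflection
# 0.2 - x is also a valid profile.
reflectable_profile <- function() {
  e <- runif(10, -0.05, 0.05)
  e <- e - mean(e)
  0.1 + e
}

# Hand sums-of-squares decomposition for a balanced two-factor mixed design:
# between factor b, within factor w, subject s nested in b.
hand_mixed_anova <- function(y, b, w, s) {
  b <- factor(b); w <- factor(w); s <- factor(s)
  a <- nlevels(b); nl <- nlevels(w); n <- nlevels(s) / a
  grand <- mean(y)
  m_g <- tapply(y, b, mean)
  m_w <- tapply(y, w, mean)
  m_s <- tapply(y, s, mean)
  m_gw <- tapply(y, list(b, w), mean)
  group_of_subject <- tapply(as.character(b), s, function(z) z[1])
  ss_between <- nl * n * sum((m_g - grand)^2)
  ss_subjects <- nl * sum((m_s - m_g[group_of_subject])^2)
  ss_within <- a * n * sum((m_w - grand)^2)
  ss_inter <- n * sum((m_gw -
                         outer(m_g, rep(1, nl)) -
                         outer(rep(1, a), m_w) + grand)^2)
  fitted_cell <- m_gw[cbind(as.character(b), as.character(w))]
  ss_error <- sum((y - fitted_cell - m_s[as.character(s)] + m_g[as.character(b)])^2)
  df_b <- a - 1; df_sub <- a * (n - 1)
  df_w <- nl - 1; df_int <- df_b * df_w; df_err <- df_sub * df_w
  tibble::tibble(
    effect = c("between", "within", "interaction"),
    F = c((ss_between / df_b) / (ss_subjects / df_sub),
          (ss_within / df_w) / (ss_error / df_err),
          (ss_inter / df_int) / (ss_error / df_err)),
    df1 = c(df_b, df_w, df_int),
    df2 = c(df_sub, df_err, df_err)
  )
}

# Long table of one dv value per participant x within level, balanced.
random_mixed_table <- function(n_per_group = 5, groups = c("g1", "g2", "g3"),
                               within_levels = c("w1", "w2")) {
  ids <- sprintf("s%02d", seq_len(n_per_group * length(groups)))
  grid <- expand.grid(participant_id = ids, within = within_levels,
                      stringsAsFactors = FALSE)
  grid$between <- rep(rep(groups, each = n_per_group), times = length(within_levels))
  grid$dv <- rnorm(nrow(grid))
  grid
}
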