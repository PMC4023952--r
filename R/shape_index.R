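#' Shape Index configuration
#'
#' The Shape Index scores a 10-bin decile profile as a signed sum of
#' deviations from the normative profile. Two bins are excluded as
#' uninformative for the unimodal/bimodal distinction; by default these
#' are bins 4 (301--400) and 9 (801--900). A documented symmetric
#' variant uses bins 4 and 7 (301--400 and 601--700) instead. The sign
#' vector carries +1 on the non-excluded bins where the symmetric
#' Beta(`alpha`, `alpha`) reference profile exceeds the uniform 0.1
#' (the central bins), -1 on the remaining non-excluded (extreme) bins
#' and 0 on the excluded bins, so that unimodal-leaning judgments score
#' positive and bimodal-leaning ones negative.
#'
#' @param excluded_bins integer bin indices set to zero weight; default
#'   `c(4, 9)`, with `c(4, 7)` as the symmetric alternative.
#' @param sign_vector optional explicit 10-vector over `{-1, 0, 1}`; must
#'   be 0 exactly on the excluded bins. Overrides the Beta-derived default.
#' @param alpha shape parameter of the reference Beta used to orient the
#'   default sign vector.
#' @return list of class `si_config` with elements `excluded_bins` and
#'   `sign_vector`.
#' @export
#' @examples
#' si_config()$sign_vector
si_config <- function(excluded_bins = c(4L, 9L), sign_vector = NULL, alpha = 2.4) {
  excluded_bins <- as.integer(excluded_bins)
  stopifnot(all(excluded_bins %in% 1:10))
  if (is.null(sign_vector)) {
    sign_vector <- ifelse(beta_decile_probabilities(alpha, alpha) > 0.1, 1, -1)
    sign_vector[excluded_bins] <- 0
  } else {
    stopifnot(length(sign_vector) == 10, all(sign_vector %in% c(-1, 0, 1)))
    if (any(sign_vector[excluded_bins] != 0) ||
        any(sign_vector[setdiff(1:10, excluded_bins)] == 0)) {
      stop("sign_vector must be zero exactly on the excluded bins", call. = FALSE)
    }
  }
  structure(list(excluded_bins = excluded_bins, sign_vector = sign_vector),
            class = "si_config")
}

#' Shape Index of a decile profile
#'
#' Computes SI = sum over non-excluded bins of s_i (x_i - p_i), where x
#' is the judged proportion profile, p the normative profile (uniform,
#' all 0.1, in the standard design) and s the configured sign vector. SI
#' is 0 for uniform judgments, positive for unimodal-leaning and
#' negative for bimodal-leaning profiles.
#'
#' @param x judged profile: 10 proportions summing to 1 (tolerance 1e-6).
#' @param p normative profile; defaults to the uniform profile.
#' @param config an [si_config()].
#' @return a single numeric SI value (dimensionless).
#' @export
#' @examples
#' shape_index(rep(0.1, 10))                     # 0: uniform judgment
#' shape_index(beta_decile_probabilities(2.4))   # > 0: unimodal-leaning
shape_index <- function(x, p = rep(0.1, 10), config = si_config()) {
  stopifnot(inherits(config, "si_config"))
  if (length(x) != 10 || length(p) != 10) {
    stop("profiles must have 10 bins", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-6) {
    stop("judged proportions must sum to 1", call. = FALSE)
  }
  sum(config$sign_vector * (x - p))
}

si_result <- function(si, task, config) {
  structure(list(si = si, task = task, config = config), class = "si_result")
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("Shape Index (%s task): %.4f\n", x$task, x$si))
  invisible(x)
}

#' Shape Index from a production-task response
#'
#' The production task asks for the frequency of values in each decile
#' interval, with frequencies required to sum to the exposed total
#' (120 in the standard design); x_i is the stated frequency divided by
#' that total.
#'
#' @param freqs 10 non-negative counts.
#' @param total required sum of `freqs`.
#' @inheritParams shape_index
#' @return an `si_result` with `task = "production"`.
#' @export
si_from_production <- function(freqs, total = 120, config = si_config()) {
  if (length(freqs) != 10 || any(freqs < 0)) {
    stop("freqs must be 10 non-negative counts", call. = FALSE)
  }
  if (sum(freqs) != total) {
    stop("frequencies must sum to ", total, call. = FALSE)
  }
  si_result(shape_index(freqs / total, config = config), "production", config)
}

#' Shape Index from an identification-task choice
#'
#' Scores the decile profile of the chosen histogram prototype.
#'
#' @param choice prototype index, 1--7.
#' @param prototypes a [generate_prototypes()] list.
#' @inheritParams shape_index
#' @return an `si_result` with `task = "identification"`.
#' @export
si_from_identification <- function(choice, prototypes = generate_prototypes(),
                                   config = si_config()) {
  if (!(length(choice) == 1 && choice %in% seq_along(prototypes))) {
    stop("choice must index one of the ", length(prototypes), " prototypes", call. = FALSE)
  }
  si_result(shape_index(prototypes[[choice]]$profile, config = config),
            "identification", config)
}

#' Shape Index from sampling-task selections
#'
#' Bins the selected values into the ten decile intervals and scores the
#' empirical proportion profile.
#'
#' @param selected values in \[1, 1000\]; typically the 10 picks from one
#'   matrix, or the 40 pooled picks from the four same-provenance matrices.
#' @inheritParams shape_index
#' @return an `si_result` with `task = "sample"`.
#' @export
si_from_sample <- function(selected, config = si_config()) {
  if (length(selected) == 0) stop("empty selection", call. = FALSE)
  si_result(shape_index(decile_proportions(selected), config = config),
            "sample", config)
}

#' Deviation of an estimate from its normative value
#'
#' The accuracy and bias currency for the descriptive task: the signed
#' deviation is estimate minus normative value and the absolute deviation
#' its magnitude, both in rating units.
#'
#' @param e_s the participant's (or simulant's) estimate.
#' @param n_s the normative value of the statistic; must be finite.
#' @param measurement label, `"central_tendency"` or `"variability"`.
#' @return list of class `deviation` with `signed`, `absolute`,
#'   `measurement`.
#' @export
#' @examples
#' deviation(450, 500)  # signed -50, absolute 50
deviation <- function(e_s, n_s, measurement = c("central_tendency", "variability")) {
  measurement <- match.arg(measurement)
  if (!is.finite(n_s)) stop("normative value must be finite", call. = FALSE)
  structure(list(signed = e_s - n_s, absolute = abs(e_s - n_s),
                 measurement = measurement), class = "deviation")
}
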