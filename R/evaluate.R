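#' Pearson correlation coefficient
#'
#' Implemented as the mean (with `n - 1` normalisation) of the products of
#' the standardized deviations, using sample standard deviations:
#' `r = 1/(n-1) * sum(((x - mean(x))/S_x) * ((y - mean(y))/S_y))`.
#'
#' @param x,y Equal-length numeric series, `n >= 2`.
#' @return `r` in `[-1, 1]`, or `NA` (with attribute `undefined = TRUE`)
#'   when either series has zero variance.
#' @export
correlation_coefficient <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
}

#' Root-mean-square error
#'
#' `sqrt(mean((x - y)^2))`, in the units of the inputs.
#'
#' @param x,y Equal-length numeric series.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least 1 sample")
  sqrt(mean((x - y)^2))
}

#' Paired t-test
#'
#' Classical paired two-sided t-test on the differences `a - b` with
#' `n - 1` degrees of freedom, used to compare the per-(subject, finger)
#' correlation of the IC-based and channel-based decoders.
#'
#' @param a,b Equal-length numeric series, `n >= 2`.
#' @return List with `t`, `df`, `p_two_sided` and `undefined` (TRUE when
#'   the differences have zero variance, in which case `t` and `p` are NA).
#' @export
paired_ttest <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("a and b must have equal length")
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = n - 1L, p_two_sided = NA_real_,
                undefined = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, undefined = FALSE)
}

#' Aggregate an evaluation table across subjects
#'
#' @param tab An EvalTable data.frame from [run_protocol()].
#' @return data.frame with mean and sd of CC and RMSE per
#'   (finger, method, protocol).
#' @export
summarize_eval <- function(tab) {
  dt <- data.table::as.data.table(tab)
  out <- dt[, list(cc_mean = mean(cc, na.rm = TRUE),
                   cc_sd = stats::sd(cc, na.rm = TRUE),
                   rmse_mean = mean(rmse_deg, na.rm = TRUE),
                   rmse_sd = stats::sd(rmse_deg, na.rm = TRUE),
                   n_subjects = length(unique(subject))),
            by = c("protocol", "method", "finger")]
  as.data.frame(out)
}

#' Compare IC-based and channel-based decoding with a paired t-test
#'
#' Pairs the per-(subject, finger) CC values of the ICA and EMG variants of
#' the same model and applies a two-sided paired t-test.
#'
#' @param tab An EvalTable data.frame from [run_protocol()].
#' @param model `"MSM"` or `"LRM"`.
#' @return The [paired_ttest()] result plus the mean CC difference
#'   (`ica - emg`).
#' @export
compare_ic_emg <- function(tab, model = c("MSM", "LRM")) {
  model <- match.arg(model)
  key <- c("protocol", "subject", "finger")
  ica <- tab[tab$method == paste0(model, "-ICA"), c(key, "cc")]
  emg <- tab[tab$method == paste0(model, "-EMG"), c(key, "cc")]
  m <- merge(ica, emg, by = key, suffixes = c("_ica", "_emg"))
  if (nrow(m) < 2L) stop("not enough paired rows for ", model)
  res <- paired_ttest(m$cc_ica, m$cc_emg)
  res$mean_diff <- mean(m$cc_ica - m$cc_emg)
  res$n_pairs <- nrow(m)
  res
}
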