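## Method-agreement statistics: intraclass correlation and Bland-Altman.
##
## Manual and automated readings of the same eyes are treated as two raters
## in a two-way random-effects model with absolute agreement: ICC(2,1) for a
## single reading and ICC(2,k) for the average of the k = 2 methods, with
## exact F-based 95% confidence intervals (McGraw & Wong). Bland-Altman
## limits of agreement are bias +/- 1.96 x sample SD of the paired
## differences.

#' Paired manual/algorithm readings
#'
#' @param subject subject identifiers.
#' @param manual,algorithm readings in percent, one per subject.
#' @param measure label, e.g. `"arteriolar"`, `"venular"`, `"avsd"`.
#' @return data frame of class `paired_readings` with complete pairs only
#'   (rows with missing values are dropped); at least 3 complete pairs are
#'   required.
#' @export
paired_readings <- function(subject, manual, algorithm, measure = "measure") {
  stopifnot(length(manual) == length(subject),
            length(algorithm) == length(subject))
  df <- data.frame(subject = subject, manual = as.numeric(manual),
                   algorithm = as.numeric(algorithm),
                   measure = measure, stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df[, c("manual", "algorithm")]), ]
  if (nrow(df) < 3L) {
    stop("at least 3 complete pairs are required", call. = FALSE)
  }
  class(df) <- c("paired_readings", "data.frame")
  df
}

#' Intraclass correlation for two-method agreement
#'
#' Two-way random-effects, absolute-agreement ICC from the mean-squares
#' decomposition of the subject x rater ANOVA:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` and
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`, with exact
#' F-distribution confidence bounds (Satterthwaite degrees of freedom for
#' the single-measure form; the average-measure bounds are the
#' Spearman-Brown transform of the single-measure bounds).
#'
#' @param readings [paired_readings()].
#' @param conf_level confidence level for the intervals.
#' @return object of class `icc_result`: `icc_single`, `icc_average`, each
#'   with `ci` (lower, upper), the mean squares, `n`, `k`, and `degenerate`
#'   (`TRUE` when the between-subject variance is zero).
#' @export
icc <- function(readings, conf_level = 0.95) {
  stopifnot(inherits(readings, "paired_readings"))
  Y <- cbind(readings$manual, readings$algorithm)
  n <- nrow(Y); k <- ncol(Y)
  long <- data.frame(y = as.vector(Y),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used, so anova's F-test warning on a perfect
  # fit (identical raters) is irrelevant here
  ms <- suppressWarnings(
    anova(stats::lm(y ~ subject + rater, data = long))[["Mean Sq"]]
  )
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]

  degenerate <- MSR <= MSE + 1e-12 * max(MSR, MSE, 1)
  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icck <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  alpha <- 1 - conf_level
  # McGraw-Wong exact bounds for ICC(A,1)
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi1 <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  sb <- function(r) k * r / (1 + (k - 1) * r)

  structure(list(icc_single = icc1,
                 ci_single = c(lower = lo1, upper = hi1),
                 icc_average = icck,
                 ci_average = c(lower = sb(lo1), upper = sb(hi1)),
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 n = n, k = k,
                 conf_level = conf_level,
                 model = "two-way random, absolute agreement (ICC(2,1) / ICC(2,k))",
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC, %s (n = %d, k = %d)%s\n", x$model, x$n, x$k,
              if (x$degenerate) " [degenerate: no between-subject variance]" else ""))
  cat(sprintf("  single  %.3f (%.0f%% CI: %.3f to %.3f)\n", x$icc_single,
              100 * x$conf_level, x$ci_single[1], x$ci_single[2]))
  cat(sprintf("  average %.3f (%.0f%% CI: %.3f to %.3f)\n", x$icc_average,
              100 * x$conf_level, x$ci_average[1], x$ci_average[2]))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `manual - algorithm`; the limits of agreement are
#' `bias +/- 1.96 sd(d)` with the sample (n-1) standard deviation.
#'
#' @param readings [paired_readings()].
#' @return object of class `bland_altman`: `bias`, `loa` (lower, upper),
#'   `sd_diff`, `n_outside_loa`, `n`, per-rater `means` and `sds`, plus the
#'   paired `averages` and `differences` for plotting. `collapsed` is `TRUE`
#'   when the differences are constant (zero-width limits).
#' @export
bland_altman <- function(readings) {
  stopifnot(inherits(readings, "paired_readings"))
  d <- readings$manual - readings$algorithm
  m <- (readings$manual + readings$algorithm) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  collapsed <- !is.finite(s) || s < 1e-12
  if (collapsed) {
    warning("constant differences: limits of agreement collapse to the bias",
            call. = FALSE)
  }
  structure(list(bias = bias, sd_diff = s, loa = loa,
                 n_outside_loa = sum(abs(d - bias) > 1.96 * s),
                 n = length(d),
                 means = c(manual = mean(readings$manual),
                           algorithm = mean(readings$algorithm)),
                 sds = c(manual = stats::sd(readings$manual),
                         algorithm = stats::sd(readings$algorithm)),
                 averages = m, differences = d,
                 collapsed = collapsed),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f], %d outside\n",
              x$n, x$bias, x$loa[1], x$loa[2], x$n_outside_loa))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods (%)",
                              ylab = "manual - algorithm (%)", ...) {
  plot(x$averages, x$differences, xlab = xlab, ylab = ylab, ...)
  abline(h = x$bias)
  abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Agreement analysis of a paired-readings table
#'
#' Accepts a CSV path or data frame with columns `subject`, `manual`,
#' `algorithm` and optionally `measure`; computes [icc()] and
#' [bland_altman()] per measure.
#'
#' @param readings CSV path or data frame.
#' @param conf_level confidence level for the ICC intervals.
#' @return object of class `agreement_report`: a list with one
#'   `list(icc, bland_altman, n)` entry per measure.
#' @export
run_agreement <- function(readings, conf_level = 0.95) {
  if (is.character(readings)) {
    if (!file.exists(readings)) stop("file not found: ", readings, call. = FALSE)
    readings <- read.csv(readings, stringsAsFactors = FALSE)
  }
  required <- c("subject", "manual", "algorithm")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0) {
    stop_oxi("oxiring_schema",
             paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(readings$measure)) readings$measure <- "measure"
  out <- lapply(split(readings, readings$measure), function(df) {
    pr <- paired_readings(df$subject, df$manual, df$algorithm, df$measure[1])
    list(icc = icc(pr, conf_level), bland_altman = bland_altman(pr), n = nrow(pr))
  })
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]]$icc)
    print(x[[nm]]$bland_altman)
  }
  invisible(x)
}
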