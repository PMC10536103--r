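#' Generate a synthetic molecular-descriptor table
#'
#' Draws `n_samples` proteinoid-like samples with a molecular weight and
#' peptide length, and a mean firing rate following the affine law
#' \deqn{rate = b_0 + b_1 \cdot MW + b_2 \cdot length + \epsilon,\quad
#'       \epsilon \sim N(0, noise\_sd^2).}
#' With `noise_sd = 0` the rates are exactly affine in the descriptors,
#' so a downstream least-squares fit must recover `(b0, b1, b2)` to
#' machine precision; with noise the table is a parameter-recovery
#' benchmark for the QSAR fitter.
#'
#' Descriptor ranges default to molecular weights uniform on
#' \[100, 2000\] g/mol and peptide lengths uniform on 1..20 residues,
#' spanning short peptides through small thermal proteins.
#'
#' @param n_samples Number of samples (>= 3, the minimum for a
#'   two-predictor fit with intercept).
#' @param b0 Intercept, Hz.
#' @param b1 Slope on molecular weight, Hz per g/mol.
#' @param b2 Slope on peptide length, Hz per residue.
#' @param noise_sd Standard deviation of the rate noise, Hz.
#' @param seed Integer seed.
#' @param mw_range Length-2 molecular weight range, g/mol.
#' @param length_range Length-2 integer peptide-length range, residues.
#' @return A `data.frame` with columns `sample_id`, `molecular_weight`,
#'   `peptide_length`, `firing_rate`; the true coefficients are attached
#'   as attribute `"true_coefficients"`.
#' @examples
#' d <- generate_descriptor_table(10, b0 = 100, b1 = 0.5, b2 = 10,
#'                                noise_sd = 0, seed = 1)
#' head(d)
#' @export
generate_descriptor_table <- function(n_samples, b0 = 100, b1 = 0.5, b2 = 10,
                                      noise_sd = 5, seed = 1L,
                                      mw_range = c(100, 2000),
                                      length_range = c(1L, 20L)) {
  check_scalar(n_samples, "n_samples", positive = TRUE)
  if (n_samples < 3) stopf("`n_samples` must be >= 3 for a two-predictor fit")
  n <- as.integer(n_samples)
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (length(mw_range) != 2L || mw_range[1L] <= 0 || diff(mw_range) < 0) {
    stopf("`mw_range` must be a positive, nondecreasing length-2 range")
  }
  if (length(length_range) != 2L || length_range[1L] < 1) {
    stopf("`length_range` must be a length-2 range with minimum >= 1")
  }
  with_seed(seed, {
    mw <- stats::runif(n, mw_range[1L], mw_range[2L])
    len <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
    rate <- b0 + b1 * mw + b2 * len +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    out <- data.frame(sample_id = sprintf("synthetic-%03d", seq_len(n)),
                      molecular_weight = mw, peptide_length = len,
                      firing_rate = rate, stringsAsFactors = FALSE)
    attr(out, "true_coefficients") <- c(b0 = b0, b1 = b1, b2 = b2)
    out
  })
}

#' Fit the QSAR linear model of firing rate on molecular descriptors
#'
#' Ordinary least squares of mean firing rate (Hz) on molecular weight
#' (g/mol) and peptide length (residues), with intercept. 95% confidence
#' bounds come from the t distribution with `n - 3` degrees of freedom.
#'
#' @param rates Numeric vector of mean firing rates, Hz.
#' @param descriptors A `data.frame` with columns `molecular_weight` and
#'   `peptide_length` (e.g. from [generate_descriptor_table()]).
#' @return An object of class `qsar_model`: list with `coefficients`
#'   (named: `(Intercept)`, `molecular_weight`, `peptide_length`), `ci95`
#'   (3 x 2 matrix of bounds), `r_squared`, `fit` (the underlying `lm`),
#'   and the fitted descriptor ranges used to flag extrapolation.
#' @examples
#' d <- generate_descriptor_table(30, noise_sd = 0, seed = 1)
#' m <- fit_qsar(d$firing_rate, d)
#' coef(m)
#' @export
fit_qsar <- function(rates, descriptors) {
  if (!is.data.frame(descriptors) ||
      !all(c("molecular_weight", "peptide_length") %in% names(descriptors))) {
    stopf("`descriptors` needs columns molecular_weight and peptide_length")
  }
  rates <- as.numeric(rates)
  if (length(rates) != nrow(descriptors)) {
    stopf("length(rates) (%d) must equal nrow(descriptors) (%d)",
          length(rates), nrow(descriptors))
  }
  if (length(rates) < 3L) stopf("need >= 3 samples to fit two slopes")
  df <- data.frame(rate = rates,
                   molecular_weight = descriptors$molecular_weight,
                   peptide_length = descriptors$peptide_length)
  X <- cbind(1, df$molecular_weight, df$peptide_length)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    cols <- c("(Intercept)", "molecular_weight", "peptide_length")
    dropped <- cols[setdiff(seq_len(3L), qrX$pivot[seq_len(qrX$rank)])]
    stopf("rank-deficient design: collinear column(s) %s",
          paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(rate ~ molecular_weight + peptide_length, data = df)
  # noiseless designs fit exactly by construction; the stock lm warning
  # about a perfect fit is expected there and muffled
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  ci <- quiet_perfect(stats::confint(fit, level = 0.95))
  structure(
    list(coefficients = stats::coef(fit),
         ci95 = ci,
         r_squared = quiet_perfect(summary(fit)$r.squared),
         fit = fit,
         mw_range = range(df$molecular_weight),
         length_range = range(df$peptide_length)),
    class = "qsar_model"
  )
}

#' @export
coef.qsar_model <- function(object, ...) object$coefficients

#' @export
print.qsar_model <- function(x, ...) {
  b <- x$coefficients
  cat("<qsar_model> rate = b0 + b1 * MW + b2 * length\n")
  cat(sprintf("  b0 = %.6g Hz  [%.6g, %.6g]\n", b[1L], x$ci95[1L, 1L], x$ci95[1L, 2L]))
  cat(sprintf("  b1 = %.6g Hz/(g/mol)  [%.6g, %.6g]\n", b[2L], x$ci95[2L, 1L], x$ci95[2L, 2L]))
  cat(sprintf("  b2 = %.6g Hz/residue  [%.6g, %.6g]\n", b[3L], x$ci95[3L, 1L], x$ci95[3L, 2L]))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Predict firing rates from a fitted QSAR model
#'
#' Affine evaluation `b0 + b1 * MW + b2 * length`. Extrapolation outside
#' the fitted descriptor ranges is permitted — linear QSAR models
#' extrapolated far outside their calibration range can produce physically
#' impossible values such as negative rates — but is flagged in the
#' `"extrapolated"` attribute.
#'
#' @param object A `qsar_model`.
#' @param newdata `data.frame` with columns `molecular_weight`,
#'   `peptide_length`.
#' @param ... Unused.
#' @return Numeric vector of predicted rates (Hz) with logical attribute
#'   `"extrapolated"` marking rows outside the fitted ranges.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (!all(c("molecular_weight", "peptide_length") %in% names(newdata))) {
    stopf("`newdata` needs columns molecular_weight and peptide_length")
  }
  b <- object$coefficients
  pred <- b[1L] + b[2L] * newdata$molecular_weight +
    b[3L] * newdata$peptide_length
  extrap <- newdata$molecular_weight < object$mw_range[1L] |
    newdata$molecular_weight > object$mw_range[2L] |
    newdata$peptide_length < object$length_range[1L] |
    newdata$peptide_length > object$length_range[2L]
  structure(as.numeric(pred), extrapolated = extrap)
}

#' Percent deviation between predicted and observed rates
#'
#' Signed deviation `100 * (predicted - observed) / observed`; undefined
#' (`NA`) where the observed rate is 0.
#'
#' @param predicted,observed Numeric vectors, Hz.
#' @return Numeric vector of percent deviations.
#' @export
percent_deviation <- function(predicted, observed) {
  out <- 100 * (predicted - observed) / observed
  out[observed == 0] <- NA_real_
  out
}

#' Summarise the embedded firing-rate table
#'
#' Reports the samples with the maximal and minimal mean firing rate and
#' the per-row percent deviation between the tabulated QSAR prediction
#' and the observed rate.
#'
#' @param rates Optional `data.frame` as returned by
#'   [load_firing_rates()]; defaults to the embedded fixture.
#' @return List with `max_sample`, `max_rate`, `min_sample`, `min_rate`,
#'   and `table` (the input plus a `percent_deviation` column).
#' @examples
#' s <- summarize_firing_rates()
#' s$max_sample
#' @export
summarize_firing_rates <- function(rates = load_firing_rates()) {
  stopifnot(is.data.frame(rates),
            all(c("sample", "mean_firing_rate_hz", "predicted_qsar_hz") %in%
                  names(rates)))
  i_max <- which.max(rates$mean_firing_rate_hz)
  i_min <- which.min(rates$mean_firing_rate_hz)
  rates$percent_deviation <- percent_deviation(rates$predicted_qsar_hz,
                                               rates$mean_firing_rate_hz)
  list(max_sample = rates$sample[i_max],
       max_rate = rates$mean_firing_rate_hz[i_max],
       min_sample = rates$sample[i_min],
       min_rate = rates$mean_firing_rate_hz[i_min],
       table = rates)
}
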