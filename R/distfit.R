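# AIC/AICc bookkeeping shared by both fitters
aic_from_ll <- function(ll, k, n) {
  aic <- 2 * k - 2 * ll
  if (n - k - 1 <= 0)
    stop("AICc undefined: n <= k + 1", call. = FALSE)
  list(aic = aic, aicc = aic + (2 * k * (k + 1)) / (n - k - 1))
}

check_distfit_data <- function(data, xmin) {
  if (!is.numeric(xmin) || length(xmin) != 1L || !is.finite(xmin) || xmin <= 0)
    stop("xmin must be a single positive number", call. = FALSE)
  data <- data[is.finite(data)]
  if (length(data) < 2L) stop("need n >= 2 finite observations", call. = FALSE)
  if (any(data < xmin))
    stop("all data must be >= xmin", call. = FALSE)
  data
}

#' Maximum-likelihood fit of a shifted exponential distribution
#'
#' Density f(x) = lambda * exp(-lambda * (x - xmin)) for x >= xmin. The MLE
#' is lambda = 1 / (mean(data) - xmin); log-likelihood
#' n*log(lambda) - lambda * sum(x - xmin). One free parameter (k = 1).
#'
#' @param data Numeric vector, all values >= `xmin`.
#' @param xmin Lower support bound (e.g. the 100 mm field truncation
#'   threshold for lengths).
#' @return list of class `"dist_fit"`: `model`, `xmin`, `params` (named:
#'   `lambda`), `log_likelihood`, `k`, `n`, `aic`, `aicc`.
#' @export
fit_exponential <- function(data, xmin) {
  data <- check_distfit_data(data, xmin)
  n <- length(data)
  spread <- mean(data) - xmin
  if (spread <= 0)
    stop("mean(data) equals xmin: exponential rate undefined", call. = FALSE)
  lambda <- 1 / spread
  ll <- n * log(lambda) - lambda * sum(data - xmin)
  ic <- aic_from_ll(ll, 1L, n)
  structure(list(model = "exponential", xmin = xmin,
                 params = c(lambda = lambda), log_likelihood = ll,
                 k = 1L, n = n, aic = ic$aic, aicc = ic$aicc),
            class = "dist_fit")
}

#' Maximum-likelihood fit of a continuous power law (Pareto)
#'
#' Density f(x) = ((beta - 1)/xmin) * (x/xmin)^(-beta) for x >= xmin. The MLE
#' is beta = 1 + n / sum(log(x/xmin)); log-likelihood
#' n*log((beta-1)/xmin) - beta * sum(log(x/xmin)).
#'
#' The parameter count defaults to the convention in which xmin is treated
#' as a fitted parameter (k = 2); `k_convention = "conventional"` counts only
#' beta (k = 1) for a fixed, known xmin.
#'
#' @inheritParams fit_exponential
#' @param k_convention `"paper"` (k = 2, default) or `"conventional"` (k = 1).
#' @return list of class `"dist_fit"` (`params` named: `beta`).
#' @export
fit_power_law <- function(data, xmin, k_convention = c("paper", "conventional")) {
  k_convention <- match.arg(k_convention)
  data <- check_distfit_data(data, xmin)
  n <- length(data)
  slog <- sum(log(data / xmin))
  if (slog <= 0)
    stop("all data equal xmin: power-law exponent diverges", call. = FALSE)
  beta <- 1 + n / slog
  ll <- n * log((beta - 1) / xmin) - beta * slog
  k <- if (k_convention == "paper") 2L else 1L
  ic <- aic_from_ll(ll, k, n)
  structure(list(model = "power_law", xmin = xmin, params = c(beta = beta),
                 log_likelihood = ll, k = k, n = n,
                 aic = ic$aic, aicc = ic$aicc),
            class = "dist_fit")
}

#' AICc competition between two fitted distributions
#'
#' The winner has the lower AICc; the loser's relative likelihood is
#' exp(-delta_AICc / 2), also reported as log10 to survive underflow (a
#' delta above ~1420 underflows double precision).
#'
#' @param fit_a,fit_b Two `"dist_fit"` objects on the same data array
#'   (same `n` and `xmin`).
#' @return list of class `"model_comparison"`: `winner`, `loser`,
#'   `delta_aicc`, `relative_likelihood`, `log10_relative_likelihood`, `tie`.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dist_fit"), inherits(fit_b, "dist_fit"))
  if (fit_a$n != fit_b$n || fit_a$xmin != fit_b$xmin)
    stop("fits are not on the same data array (n or xmin differ)",
         call. = FALSE)
  delta <- fit_a$aicc - fit_b$aicc
  winner <- if (delta <= 0) fit_a else fit_b
  loser <- if (delta <= 0) fit_b else fit_a
  d <- abs(delta)
  structure(list(winner = winner$model, loser = loser$model, delta_aicc = d,
                 relative_likelihood = exp(-d / 2),
                 log10_relative_likelihood = -d / (2 * log(10)),
                 tie = d == 0),
            class = "model_comparison")
}

#' Relative likelihood from a pair of AICc scores
#'
#' Convenience for reproducing published AICc competitions without refitting:
#' exp(-|AICc_a - AICc_b| / 2).
#'
#' @param aicc_a,aicc_b Two AICc scores for the same data array.
#' @return list: `winner` (`"a"` or `"b"`), `delta_aicc`,
#'   `relative_likelihood`, `log10_relative_likelihood`.
#' @export
relative_likelihood <- function(aicc_a, aicc_b) {
  d <- abs(aicc_a - aicc_b)
  list(winner = if (aicc_a <= aicc_b) "a" else "b", delta_aicc = d,
       relative_likelihood = exp(-d / 2),
       log10_relative_likelihood = -d / (2 * log(10)))
}

#' Exponential vs power-law competition for one data array
#'
#' Fits both families above a common `xmin` and compares them by AICc.
#'
#' @inheritParams fit_power_law
#' @return data.frame row: `n`, `xmin`, `lambda`, `beta`, `aicc_exponential`,
#'   `aicc_power_law`, `winner`, `delta_aicc`, `relative_likelihood`,
#'   `log10_relative_likelihood`.
#' @export
size_distribution_competition <- function(data, xmin,
                                          k_convention = c("paper", "conventional")) {
  k_convention <- match.arg(k_convention)
  fe <- fit_exponential(data, xmin)
  fp <- fit_power_law(data, xmin, k_convention)
  cmp <- compare_models(fp, fe)
  data.frame(n = fe$n, xmin = xmin, lambda = unname(fe$params["lambda"]),
             beta = unname(fp$params["beta"]),
             aicc_exponential = fe$aicc, aicc_power_law = fp$aicc,
             winner = cmp$winner, delta_aicc = cmp$delta_aicc,
             relative_likelihood = cmp$relative_likelihood,
             log10_relative_likelihood = cmp$log10_relative_likelihood,
             stringsAsFactors = FALSE)
}
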