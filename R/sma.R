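#' The six variable pairs of the branch-allometry analysis
#'
#' Ordered pairs of the four cylinder dimensions (length L, diameter D,
#' surface area SA, volume V) whose log-log scaling exponents are all
#' determined by the single length-diameter exponent alpha.
#'
#' @return data.frame with columns `pair`, `y`, `x` in the canonical row
#'   order: SA~V, L~D, D~V, L~V, D~SA, L~SA.
#' @export
variable_pairs <- function() {
  data.frame(
    pair = c("SA~V", "L~D", "D~V", "L~V", "D~SA", "L~SA"),
    y = c("surface_area", "length", "diameter", "length", "diameter", "length"),
    x = c("volume", "diameter", "volume", "volume", "surface_area", "surface_area"),
    stringsAsFactors = FALSE)
}

#' Predicted scaling exponents implied by alpha
#'
#' For cylinders coupled by L = c * D^alpha, every pairwise log-log exponent
#' follows in closed form:
#' SA~V: (alpha+1)/(alpha+2); L~D: alpha; D~V: 1/(alpha+2);
#' L~V: alpha/(alpha+2); D~SA: 1/(alpha+1); L~SA: alpha/(alpha+1).
#' `alpha = 2` gives the constrained flow-similarity (CFS) column
#' (3/4, 2, 1/4, 1/2, 1/3, 2/3); `alpha = 2/3` the elastic-similarity (WBE)
#' column (5/8, 2/3, 3/8, 1/4, 3/5, 2/5).
#'
#' @param alpha Positive scaling exponent of length on diameter.
#' @param model_name Optional label (e.g. `"CFS"`, `"WBE"`).
#' @return list of class `"model_prediction"` with `model_name`, `alpha`, and
#'   `exponents` (named numeric over the six pairs).
#' @export
predict_exponents <- function(alpha, model_name = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  e <- c("SA~V" = (alpha + 1) / (alpha + 2),
         "L~D" = alpha,
         "D~V" = 1 / (alpha + 2),
         "L~V" = alpha / (alpha + 2),
         "D~SA" = 1 / (alpha + 1),
         "L~SA" = alpha / (alpha + 1))
  if (is.null(model_name))
    model_name <- if (isTRUE(all.equal(alpha, 2))) "CFS"
      else if (isTRUE(all.equal(alpha, 2 / 3))) "WBE" else sprintf("alpha=%g", alpha)
  structure(list(model_name = model_name, alpha = alpha, exponents = e),
            class = "model_prediction")
}

#' Standardized major axis regression on log10-log10 axes
#'
#' SMA (reduced major axis) fit for allometric data with error in both
#' variables. Both inputs are log10-transformed; the slope is
#' sign(r) * sd(y)/sd(x), the intercept mean(y) - slope * mean(x). The 95%
#' slope interval uses the standard construction
#' B = F(ci_level; 1, n-2) * (1 - r^2)/(n - 2), CI = b * (sqrt(B+1) +/- sqrt(B)),
#' and the intercept interval is propagated from the slope interval through
#' the means (documented, not guaranteed to match any particular software's
#' intercept interval).
#'
#' @param x,y Positive numeric vectors of equal length, n >= 3 (raw scale;
#'   logs are taken internally).
#' @param ci_level Confidence level, default 0.95.
#' @param pair Optional pair label carried into the result.
#' @param group Optional group label (tree id or "all").
#' @return list of class `"sma_fit"`: `pair`, `group`, `n`, `r_squared`,
#'   `slope`, `slope_ci_low`, `slope_ci_high`, `intercept`,
#'   `intercept_ci_low`, `intercept_ci_high`.
#' @export
sma_fit <- function(x, y, ci_level = 0.95, pair = NA_character_,
                    group = "all") {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("SMA fit needs n >= 3", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad))
    stop("non-positive values at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  sx <- stats::sd(lx); sy <- stats::sd(ly)
  if (sx == 0 || sy == 0)
    stop("zero variance in x or y on log axes", call. = FALSE)
  r <- stats::cor(lx, ly)
  b <- sign(r) * sy / sx
  if (b == 0) b <- sy / sx  # r exactly 0: orientation undefined, report +
  B <- stats::qf(ci_level, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  a <- mean(ly) - b * mean(lx)
  a_ci <- sort(mean(ly) - ci * mean(lx))
  structure(list(pair = pair, group = group, n = n, r_squared = r^2,
                 slope = b, slope_ci_low = ci[1], slope_ci_high = ci[2],
                 intercept = a, intercept_ci_low = a_ci[1],
                 intercept_ci_high = a_ci[2]),
            class = "sma_fit")
}

#' Compare one SMA fit against one model prediction
#'
#' For a single fitted slope the root mean squared error reduces to the
#' absolute deviation |slope - predicted exponent|. Use [model_rmse()] to
#' pool deviations across several fits.
#'
#' @param fit An [sma_fit()] with a `pair` label.
#' @param prediction A [predict_exponents()] result.
#' @return list of class `"model_evaluation"`: `pair`, `group`, `model_name`,
#'   `predicted`, `slope`, `rmse`.
#' @export
evaluate_model <- function(fit, prediction) {
  stopifnot(inherits(fit, "sma_fit"), inherits(prediction, "model_prediction"))
  if (is.na(fit$pair) || !(fit$pair %in% names(prediction$exponents)))
    stop("fit and prediction do not share a variable pair: ", fit$pair,
         call. = FALSE)
  p <- unname(prediction$exponents[fit$pair])
  structure(list(pair = fit$pair, group = fit$group,
                 model_name = prediction$model_name, predicted = p,
                 slope = fit$slope, rmse = abs(fit$slope - p)),
            class = "model_evaluation")
}

#' Root mean squared error of a set of slopes against one predicted exponent
#'
#' `sqrt(mean((slopes - predicted)^2))`. With a single slope this is the
#' absolute deviation reported by [evaluate_model()].
#'
#' @param slopes Numeric vector of fitted slopes.
#' @param predicted Single predicted exponent.
#' @return Non-negative scalar.
#' @export
model_rmse <- function(slopes, predicted) {
  stopifnot(is.numeric(slopes), length(slopes) >= 1L,
            is.numeric(predicted), length(predicted) == 1L)
  sqrt(mean((slopes - predicted)^2))
}

#' Build the SMA results table for a set of internodes
#'
#' One row per group x variable pair, mirroring the published table layout:
#' n, R^2, SMA slope with CI, predicted CFS and WBE exponents, intercept with
#' CI, and the per-fit RMSE against each model. Groups are the individual
#' trees, the pooled "all" set, or both.
#'
#' @param internodes Internode table with derived `surface_area` and `volume`
#'   columns (see [derive_dimensions()]).
#' @param groups `"both"` (default), `"per_tree"` or `"pooled"`.
#' @param ci_level Confidence level for intervals.
#' @return data.frame, pairs in canonical order, "all" rows first.
#' @export
sma_table <- function(internodes, groups = c("both", "per_tree", "pooled"),
                      ci_level = 0.95) {
  groups <- match.arg(groups)
  vp <- variable_pairs()
  cfs <- predict_exponents(2)
  wbe <- predict_exponents(2 / 3)
  grp <- character(0)
  if (groups %in% c("both", "pooled")) grp <- "all"
  if (groups %in% c("both", "per_tree"))
    grp <- c(grp, sort(unique(internodes$tree_id)))
  rows <- list()
  for (i in seq_len(nrow(vp))) {
    for (g in grp) {
      sub <- if (g == "all") internodes else
        internodes[internodes$tree_id == g, , drop = FALSE]
      f <- sma_fit(sub[[vp$x[i]]], sub[[vp$y[i]]], ci_level = ci_level,
                   pair = vp$pair[i], group = g)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = vp$pair[i], y = vp$y[i], x = vp$x[i], group = g, n = f$n,
        r_squared = f$r_squared, slope = f$slope,
        slope_ci_low = f$slope_ci_low, slope_ci_high = f$slope_ci_high,
        cfs_pred = unname(cfs$exponents[vp$pair[i]]),
        wbe_pred = unname(wbe$exponents[vp$pair[i]]),
        intercept = f$intercept, intercept_ci_low = f$intercept_ci_low,
        intercept_ci_high = f$intercept_ci_high,
        rmse_cfs = evaluate_model(f, cfs)$rmse,
        rmse_wbe = evaluate_model(f, wbe)$rmse,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
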