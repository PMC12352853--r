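#' Expected curvature of each log-log relationship
#'
#' Under the full flow-similarity picture (distal branches near alpha = 2,
#' basal branches shifting toward elastic similarity) relationships with
#' length in the numerator are concave on log-log axes and the two
#' diameter-on-size relationships are convex.
#'
#' @return Named character vector over the six pairs.
#' @export
expected_curvature <- function() {
  c("SA~V" = "concave", "L~D" = "concave", "D~V" = "convex",
    "L~V" = "concave", "L~SA" = "concave", "D~SA" = "convex")
}

# least-squares quadratic y = a*x^2 + b*x + c via the normal equations,
# solved on centred/scaled x for conditioning; returns coefficient a.
quad_coefficient <- function(x, y) {
  mx <- mean(x); sx <- stats::sd(x)
  if (sx == 0) stop("zero variance in x", call. = FALSE)
  z <- (x - mx) / sx
  X <- cbind(1, z, z^2)
  coef <- solve(crossprod(X), crossprod(X, y))
  coef[3L] / sx^2
}

#' Classify log-log curvature of a bivariate relationship
#'
#' Fits an ordinary least-squares quadratic on log10 axes and classifies by
#' the sign of the quadratic coefficient `a` (second derivative 2a): negative
#' is concave, positive convex. An `a` indistinguishable from 0 (exactly
#' linear data) is flagged degenerate with no classification. Only the sign
#' is used; no significance test is attached.
#'
#' @param x,y Positive numeric vectors (raw scale; logs taken internally),
#'   n >= 4.
#' @param pair Optional pair label; when it matches a name in
#'   [expected_curvature()] and `predicted` is NULL, the expectation is
#'   looked up automatically.
#' @param predicted Optional `"concave"`/`"convex"` expectation to compare
#'   against.
#' @param group Optional group label.
#' @return list of class `"curvature_result"`: `pair`, `group`, `quad_coeff`,
#'   `classification` (`NA` when degenerate), `degenerate`, `predicted`,
#'   `matches_prediction`.
#' @export
classify_curvature <- function(x, y, pair = NA_character_, predicted = NULL,
                               group = "all") {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4L) stop("curvature fit needs n >= 4", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad))
    stop("non-positive values at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  a <- quad_coefficient(lx, ly)
  # scale-aware zero test: 'a' has units of y-spread per x-spread^2
  tol <- 1e-10 * max(stats::sd(ly), .Machine$double.eps) /
    max(stats::sd(lx), .Machine$double.eps)^2
  degenerate <- abs(a) < tol
  cls <- if (degenerate) NA_character_ else if (a < 0) "concave" else "convex"
  if (is.null(predicted) && !is.na(pair) && pair %in% names(expected_curvature()))
    predicted <- unname(expected_curvature()[pair])
  structure(list(pair = pair, group = group, quad_coeff = a,
                 classification = cls, degenerate = degenerate,
                 predicted = if (is.null(predicted)) NA_character_ else predicted,
                 matches_prediction = if (is.null(predicted) || degenerate)
                   NA else identical(cls, predicted)),
            class = "curvature_result")
}

#' Bootstrap stability of the curvature sign (diagnostic)
#'
#' Resamples rows with replacement and reports the fraction of resamples in
#' which the quadratic coefficient keeps the full-data sign. Diagnostic only;
#' the headline classification never depends on it.
#'
#' @param x,y Positive numeric vectors, n >= 4.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Fraction in \[0, 1\].
#' @export
curvature_sign_stability <- function(x, y, n_boot = 200L, seed = 1L) {
  full <- classify_curvature(x, y)
  set.seed(seed)
  lx <- log10(x); ly <- log10(y)
  same <- 0L
  for (b in seq_len(n_boot)) {
    i <- sample.int(length(x), replace = TRUE)
    a <- tryCatch(quad_coefficient(lx[i], ly[i]), error = function(e) NA_real_)
    if (!is.na(a) && sign(a) == sign(full$quad_coeff)) same <- same + 1L
  }
  same / n_boot
}

#' Build the curvature results table
#'
#' One row per group x variable pair: quadratic coefficient, classification,
#' expectation, and match flag.
#'
#' @inheritParams sma_table
#' @return data.frame.
#' @export
curvature_table <- function(internodes, groups = c("both", "per_tree", "pooled")) {
  groups <- match.arg(groups)
  vp <- variable_pairs()
  grp <- character(0)
  if (groups %in% c("both", "pooled")) grp <- "all"
  if (groups %in% c("both", "per_tree"))
    grp <- c(grp, sort(unique(internodes$tree_id)))
  rows <- list()
  for (i in seq_len(nrow(vp))) {
    for (g in grp) {
      sub <- if (g == "all") internodes else
        internodes[internodes$tree_id == g, , drop = FALSE]
      cr <- classify_curvature(sub[[vp$x[i]]], sub[[vp$y[i]]],
                               pair = vp$pair[i], group = g)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = vp$pair[i], group = g, quad_coeff = cr$quad_coeff,
        classification = ifelse(is.na(cr$classification), "degenerate",
                                cr$classification),
        predicted = cr$predicted,
        matches_prediction = cr$matches_prediction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
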