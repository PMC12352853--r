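#' Cylinder surface area and volume of an internode
#'
#' Each internode is treated as a circular cylinder. Surface area is the
#' lateral area pi * D * L (no end caps, the usual convention in branch
#' allometry); volume is pi * (D/2)^2 * L. Both arguments recycle and the
#' self-consistency identity SA^2 / (V * L) = 4 * pi holds exactly.
#'
#' @param length,diameter Positive numeric vectors, mm.
#' @return data.frame with columns `surface_area` (mm^2) and `volume` (mm^3).
#' @examples
#' cylinder_dimensions(10, 2)  # SA = 20*pi, V = 10*pi
#' @export
cylinder_dimensions <- function(length, diameter) {
  bad <- which(!is.finite(length) | !is.finite(diameter) |
                 length <= 0 | diameter <= 0)
  if (length(bad))
    stop("non-positive or non-finite length/diameter at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  data.frame(surface_area = pi * diameter * length,
             volume = pi * (diameter / 2)^2 * length)
}

#' Extract bifurcations and their area ratios
#'
#' One row per internode having at least one child in the table. The area
#' ratio is sum(daughter_radius^2) / parent_radius^2 (the pi factors cancel);
#' under exact area-preserving branching it equals 1. Nodes with a single
#' measured child (the other daughter lost to field truncation) are retained
#' as degree-1 bifurcations unless `degree2_only = TRUE`.
#'
#' @param internodes Internode data.frame (`tree_id`, `internode_id`,
#'   `parent_id`, `diameter_mm`, ...).
#' @param degree2_only Keep only nodes with exactly two measured daughters.
#' @return data.frame: `tree_id`, `parent_id`, `parent_radius`, `n_daughters`,
#'   `area_ratio`.
#' @export
extract_bifurcations <- function(internodes, degree2_only = FALSE) {
  stopifnot(is.data.frame(internodes))
  key <- function(tree, id) paste(tree, id, sep = "\r")
  node_key <- key(internodes$tree_id, internodes$internode_id)
  child <- !is.na(internodes$parent_id) & internodes$parent_id != ""
  parent_key <- key(internodes$tree_id[child], internodes$parent_id[child])
  orphan <- !(parent_key %in% node_key)
  if (any(orphan))
    stop("children reference missing parents: ",
         paste(utils::head(internodes$internode_id[child][orphan], 5L),
               collapse = ", "), call. = FALSE)
  if (!any(child))
    return(data.frame(tree_id = character(), parent_id = character(),
                      parent_radius = numeric(), n_daughters = integer(),
                      area_ratio = numeric(), stringsAsFactors = FALSE))
  r_child <- internodes$diameter_mm[child] / 2
  sum_a <- rowsum(r_child^2, group = parent_key)
  n_d <- rowsum(rep(1L, sum(child)), group = parent_key)
  idx <- match(rownames(sum_a), node_key)
  rp <- internodes$diameter_mm[idx] / 2
  out <- data.frame(tree_id = internodes$tree_id[idx],
                    parent_id = internodes$internode_id[idx],
                    parent_radius = rp,
                    n_daughters = as.integer(n_d[, 1L]),
                    area_ratio = sum_a[, 1L] / rp^2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$tree_id, out$parent_id), , drop = FALSE]
  rownames(out) <- NULL
  if (degree2_only) out <- out[out$n_daughters == 2L, , drop = FALSE]
  out
}

#' Raw (Pearson) kurtosis
#'
#' Fourth standardized central moment m4 / m2^2, so a Gaussian scores 3 and
#' "leptokurtic" means a value above 3. Returns `NA` when the variance is 0.
#'
#' @param x Numeric vector, length >= 2.
#' @return A single number (or `NA_real_` for zero spread).
#' @export
raw_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("kurtosis needs n >= 2", call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

#' Summarise area ratios across bifurcations
#'
#' Ordinary mean and sd, raw kurtosis (Gaussian reference = 3), and the
#' per-parent-radius-bin variance that exposes how ratio scatter grows as
#' branches get smaller.
#'
#' @param bifurcations Output of [extract_bifurcations()], n >= 2.
#' @param n_bins Number of equal-width bins in log parent radius.
#' @return list with `n`, `mean`, `sd`, `kurtosis` (NA and flagged when sd is
#'   0), `degenerate` flag, and `by_radius` (data.frame: bin midpoint radius,
#'   n, variance of ratios in bin).
#' @export
area_ratio_summary <- function(bifurcations, n_bins = 8L) {
  stopifnot(is.data.frame(bifurcations))
  r <- bifurcations$area_ratio
  if (length(r) < 2L)
    stop("area_ratio_summary needs at least 2 bifurcations", call. = FALSE)
  s <- stats::sd(r)
  degenerate <- s == 0
  lr <- log10(bifurcations$parent_radius)
  brk <- seq(min(lr), max(lr), length.out = n_bins + 1L)
  if (length(unique(brk)) < 2L) brk <- c(min(lr) - 0.5, max(lr) + 0.5)
  bin <- cut(lr, breaks = brk, include.lowest = TRUE)
  by_radius <- data.frame(
    radius_mid = tapply(bifurcations$parent_radius, bin, mean),
    n = as.integer(tapply(r, bin, length)),
    variance = tapply(r, bin, function(v) if (length(v) >= 2L) stats::var(v) else NA_real_)
  )
  by_radius <- by_radius[!is.na(by_radius$n), , drop = FALSE]
  rownames(by_radius) <- NULL
  list(n = length(r), mean = mean(r), sd = s,
       kurtosis = if (degenerate) NA_real_ else raw_kurtosis(r),
       degenerate = degenerate, by_radius = by_radius)
}
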