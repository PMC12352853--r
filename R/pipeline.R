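#' Analysis configuration
#'
#' Collects pipeline settings with the field-protocol defaults: internodes
#' shorter than 100 mm or thinner than 1.5 mm were not measured, so those
#' thresholds drive both the truncation filter and the default lower support
#' bounds of the size-distribution fits.
#'
#' @param input_path CSV internode table (see [read_internode_table()]).
#' @param output_dir Directory for report files; created if absent.
#' @param ci_level Confidence level for SMA intervals.
#' @param length_min,diameter_min Truncation thresholds, mm (inclusive:
#'   values equal to the threshold are kept).
#' @param xmin_lengths,xmin_diameters Lower support bounds for the
#'   distribution fits; default to the truncation thresholds.
#' @param k_convention Power-law parameter counting, see [fit_power_law()].
#' @param groups `"both"`, `"per_tree"` or `"pooled"`.
#' @param prune_subtrees Allow the truncation filter to drop whole subtrees
#'   rooted at filtered internodes (otherwise dropping a non-leaf errors).
#' @param degree2_only_ratios Restrict the area-ratio summary to bifurcations
#'   with both daughters measured (default TRUE; see the vignette).
#' @param seed Seed for bootstrap diagnostics.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(input_path, output_dir = NULL, ci_level = 0.95,
                            length_min = 100, diameter_min = 1.5,
                            xmin_lengths = length_min,
                            xmin_diameters = diameter_min,
                            k_convention = c("paper", "conventional"),
                            groups = c("both", "per_tree", "pooled"),
                            prune_subtrees = FALSE,
                            degree2_only_ratios = TRUE,
                            seed = 1L) {
  k_convention <- match.arg(k_convention)
  groups <- match.arg(groups)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  if (length_min < 0 || diameter_min < 0)
    stop("truncation thresholds must be >= 0", call. = FALSE)
  structure(list(input_path = input_path, output_dir = output_dir,
                 ci_level = ci_level, length_min = length_min,
                 diameter_min = diameter_min, xmin_lengths = xmin_lengths,
                 xmin_diameters = xmin_diameters, k_convention = k_convention,
                 groups = groups, prune_subtrees = prune_subtrees,
                 degree2_only_ratios = degree2_only_ratios,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read and validate an internode table
#'
#' Expects columns `tree_id`, `internode_id`, `parent_id`, `length_mm`,
#' `diameter_mm`. Empty `parent_id` marks a tree base. Validation: numeric,
#' finite, positive dimensions (errors name the offending rows); unique
#' internode ids within each tree; every parent reference resolves within
#' the same tree; topology is acyclic.
#'
#' @param path CSV file path.
#' @return Internode data.frame.
#' @export
read_internode_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  req <- c("tree_id", "internode_id", "parent_id", "length_mm", "diameter_mm")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(raw$length_mm))
  dia <- suppressWarnings(as.numeric(raw$diameter_mm))
  bad <- which(is.na(len) | is.na(dia) | !is.finite(len) | !is.finite(dia) |
                 len <= 0 | dia <= 0)
  if (length(bad))
    stop("non-numeric or non-positive dimensions at data rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  out <- data.frame(tree_id = raw$tree_id, internode_id = raw$internode_id,
                    parent_id = ifelse(raw$parent_id == "", NA_character_,
                                       raw$parent_id),
                    length_mm = len, diameter_mm = dia,
                    stringsAsFactors = FALSE)
  validate_topology(out)
  out
}

validate_topology <- function(internodes) {
  key <- paste(internodes$tree_id, internodes$internode_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate internode ids within a tree: ",
         paste(utils::head(internodes$internode_id[dup], 5L), collapse = ", "),
         call. = FALSE)
  has_parent <- !is.na(internodes$parent_id)
  pkey <- paste(internodes$tree_id[has_parent],
                internodes$parent_id[has_parent], sep = "\r")
  orphan <- !(pkey %in% key)
  if (any(orphan))
    stop("parent ids not found in the same tree: ",
         paste(utils::head(unique(internodes$parent_id[has_parent][orphan]), 5L),
               collapse = ", "), call. = FALSE)
  # acyclicity: follow parent pointers; a walk longer than n implies a cycle
  parent_idx <- rep(NA_integer_, nrow(internodes))
  parent_idx[has_parent] <- match(pkey, key)
  n <- nrow(internodes)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    steps <- 0L; j <- i
    while (!is.na(j)) {
      if (!is.na(depth[j])) { steps <- steps + depth[j]; break }
      steps <- steps + 1L
      if (steps > n)
        stop("cyclic topology involving internode ",
             internodes$internode_id[i], call. = FALSE)
      j <- parent_idx[j]
    }
    depth[i] <- steps
  }
  invisible(TRUE)
}

#' Apply the field truncation filter
#'
#' Keeps internodes with `length_mm >= length_min` and
#' `diameter_mm >= diameter_min` (thresholds inclusive, since the field
#' protocol excluded branches *less than* the thresholds). By default a
#' filtered internode must be a leaf — dropping an internal node would
#' orphan its descendants and the call errors; with `prune_subtrees = TRUE`
#' every subtree rooted at a filtered internode is dropped as well.
#'
#' @param internodes Internode data.frame.
#' @param length_min,diameter_min Thresholds, mm.
#' @param prune_subtrees Drop whole subtrees below filtered internodes.
#' @return list: `kept` (data.frame), `dropped_count`.
#' @export
apply_truncation_filter <- function(internodes, length_min = 100,
                                    diameter_min = 1.5,
                                    prune_subtrees = FALSE) {
  stopifnot(is.data.frame(internodes))
  keep <- internodes$length_mm >= length_min &
    internodes$diameter_mm >= diameter_min
  if (prune_subtrees || !all(keep)) {
    key <- paste(internodes$tree_id, internodes$internode_id, sep = "\r")
    pkey <- paste(internodes$tree_id, internodes$parent_id, sep = "\r")
    parent_idx <- match(pkey, key)
    # propagate drops downward: a node whose ancestor is dropped is dropped
    repeat {
      orphaned <- !keep[parent_idx] & keep
      orphaned[is.na(orphaned)] <- FALSE
      if (!any(orphaned)) break
      if (!prune_subtrees)
        stop("truncation would drop non-leaf internodes (descendants of: ",
             paste(utils::head(unique(internodes$parent_id[orphaned]), 5L),
                   collapse = ", "),
             "); rerun with prune_subtrees = TRUE", call. = FALSE)
      keep[orphaned] <- FALSE
    }
  }
  list(kept = internodes[keep, , drop = FALSE],
       dropped_count = sum(!keep))
}

#' Attach cylinder surface area and volume to an internode table
#'
#' @param internodes Internode data.frame.
#' @return The table with `length`, `diameter`, `surface_area`, `volume`
#'   columns added (mm, mm, mm^2, mm^3).
#' @export
derive_dimensions <- function(internodes) {
  dd <- cylinder_dimensions(internodes$length_mm, internodes$diameter_mm)
  internodes$length <- internodes$length_mm
  internodes$diameter <- internodes$diameter_mm
  internodes$surface_area <- dd$surface_area
  internodes$volume <- dd$volume
  internodes
}

#' Run the full branch-allometry analysis
#'
#' Read -> truncation filter -> derived dimensions -> per group and pooled:
#' SMA fits with CFS/WBE model competition, curvature classification,
#' area-ratio summary, and the exponential vs power-law competition on
#' lengths and diameters per tree (and pooled). When `config$output_dir` is
#' set, writes `sma_table.csv`, `curvature_table.csv`, `distfit_table.csv`,
#' `area_ratio_summary.csv` and `report.json` there.
#'
#' @param config An [analysis_config()], or a path to its JSON serialization.
#' @param internodes Optional pre-loaded internode table (skips reading
#'   `config$input_path`).
#' @return list of class `"analysis_report"`: `sma_table`,
#'   `curvature_table`, `area_ratio_table`, `distfit_table`, `provenance`.
#' @export
run_analysis <- function(config, internodes = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(internodes)) internodes <- read_internode_table(config$input_path)
  n_read <- nrow(internodes)
  filt <- apply_truncation_filter(internodes, config$length_min,
                                  config$diameter_min, config$prune_subtrees)
  if (nrow(filt$kept) < 4L)
    stop("fewer than 4 internodes remain after truncation; no analysis run",
         call. = FALSE)
  dat <- derive_dimensions(filt$kept)
  message(sprintf("read %d internodes, dropped %d by truncation, analysing %d",
                  n_read, filt$dropped_count, nrow(dat)))

  smat <- sma_table(dat, groups = config$groups, ci_level = config$ci_level)
  curv <- curvature_table(dat, groups = config$groups)

  grp <- unique(smat$group)
  ar_rows <- list()
  for (g in grp) {
    sub <- if (g == "all") dat else dat[dat$tree_id == g, , drop = FALSE]
    bif <- extract_bifurcations(sub, degree2_only = config$degree2_only_ratios)
    if (nrow(bif) >= 2L) {
      s <- area_ratio_summary(bif)
      ar_rows[[length(ar_rows) + 1L]] <- data.frame(
        group = g, n = s$n, mean = s$mean, sd = s$sd, kurtosis = s$kurtosis,
        stringsAsFactors = FALSE)
    }
  }
  ar <- if (length(ar_rows)) do.call(rbind, ar_rows) else NULL

  df_rows <- list()
  for (g in grp) {
    sub <- if (g == "all") dat else dat[dat$tree_id == g, , drop = FALSE]
    for (measure in c("lengths", "diameters")) {
      vals <- if (measure == "lengths") sub$length_mm else sub$diameter_mm
      xmin <- if (measure == "lengths") config$xmin_lengths else config$xmin_diameters
      row <- tryCatch(
        size_distribution_competition(vals, xmin, config$k_convention),
        error = function(e) NULL)
      if (!is.null(row))
        df_rows[[length(df_rows) + 1L]] <- cbind(
          data.frame(group = g, measure = measure, stringsAsFactors = FALSE), row)
    }
  }
  dft <- if (length(df_rows)) do.call(rbind, df_rows) else NULL

  report <- structure(list(
    sma_table = smat, curvature_table = curv, area_ratio_table = ar,
    distfit_table = dft,
    provenance = list(
      package_version = as.character(utils::packageVersion("allomflow")),
      config = unclass(config),
      n_read = n_read, n_dropped = filt$dropped_count,
      n_analysed = nrow(dat),
      input_md5 = if (!is.null(config$input_path) &&
                        is.character(config$input_path) &&
                        file.exists(config$input_path))
        unname(tools::md5sum(config$input_path)) else NA_character_)),
    class = "analysis_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write an analysis report to disk
#'
#' @param report An `"analysis_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written))
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  wr(report$sma_table, "sma_table.csv")
  wr(report$curvature_table, "curvature_table.csv")
  wr(report$area_ratio_table, "area_ratio_summary.csv")
  wr(report$distfit_table, "distfit_table.csv")
  p <- file.path(dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE, pretty = TRUE)
  written <- c(written, p)
  ok <- TRUE
  invisible(dir)
}

#' Read an analysis configuration from JSON
#'
#' The JSON object mirrors the [analysis_config()] argument names. (YAML is
#' not supported: no YAML parser is available in the target environment.)
#'
#' @param path JSON file.
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals)
}

#' Read a simulation configuration from JSON
#'
#' JSON field names mirror [simulation_config()].
#'
#' @param path JSON file.
#' @return A `"simulation_config"`.
#' @export
read_simulation_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_config, vals)
}
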