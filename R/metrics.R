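#' Region-of-interest specification
#'
#' Two ROI kinds mirror the analysis protocol: a small central
#' `metric_roi` used to average parametric maps with minimal partial
#' volume, and a larger `whole_nerve_roi` covering the entire nerve
#' cross-section, from which nerve volume (and hence axon volume) is
#' computed. The two are always distinct inputs; neither is inferred
#' from the other.
#'
#' @param voxel_indices integer matrix (n x 3) of 0-based voxel
#'   coordinates, or a 3-D mask array (values > 0 are in the ROI).
#' @param voxel_volume voxel volume in mm^3.
#' @param kind `"metric_roi"` or `"whole_nerve_roi"`.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(voxel_indices, voxel_volume,
                     kind = c("metric_roi", "whole_nerve_roi")) {
  kind <- match.arg(kind)
  if (is.array(voxel_indices) && length(dim(voxel_indices)) == 3L)
    voxel_indices <- which(voxel_indices > 0, arr.ind = TRUE) - 1L
  voxel_indices <- as.matrix(voxel_indices)
  if (ncol(voxel_indices) != 3L)
    stop("voxel_indices must be an n x 3 matrix of 0-based coordinates")
  if (anyDuplicated(voxel_indices))
    stop("duplicate voxel indices in ROI")
  if (!(voxel_volume > 0)) stop("voxel_volume must be positive")
  structure(list(voxel_indices = voxel_indices, voxel_volume = voxel_volume,
                 kind = kind),
            class = "roi_spec")
}

#' Mean of a parametric map over an ROI
#'
#' Arithmetic mean of the map values at the ROI voxels, ignoring
#' flagged-invalid (`NA`) voxels; the number of dropped voxels is
#' reported as a warning.
#'
#' @param map 3-D numeric array.
#' @param roi an [roi_spec()] of kind `metric_roi`.
#' @return scalar mean.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$kind != "metric_roi")
    stop("roi_mean expects a metric_roi, got ", roi$kind)
  idx <- roi$voxel_indices + 1L
  if (nrow(idx) == 0L) stop("empty ROI")
  d <- dim(map)
  if (any(idx < 1L) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3]))
    stop("ROI voxel outside map bounds")
  vals <- map[idx]
  n_bad <- sum(is.na(vals))
  if (n_bad == length(vals)) stop("all ROI voxels are flagged invalid")
  if (n_bad > 0)
    warning("roi_mean: ignoring ", n_bad, " invalid voxel(s) of ",
            length(vals))
  mean(vals, na.rm = TRUE)
}

#' Nerve volume from a whole-nerve ROI
#'
#' Voxel count times voxel volume (mm^3).
#'
#' @param roi an [roi_spec()] of kind `whole_nerve_roi`.
#' @return volume in mm^3.
#' @export
nerve_volume <- function(roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$kind != "whole_nerve_roi")
    stop("nerve_volume expects a whole_nerve_roi, got ", roi$kind)
  n <- nrow(roi$voxel_indices)
  if (n == 0L) stop("empty whole-nerve ROI")
  n * roi$voxel_volume
}

#' Axon volume
#'
#' Nerve volume multiplied by the fiber fraction of the same
#' whole-nerve ROI: an axonal-content marker robust to nerve swelling,
#' since swelling inflates the volume while diluting the fraction.
#'
#' @param nerve_volume nerve volume (mm^3), non-negative.
#' @param fiber_fraction fiber signal fraction in \[0, 1\].
#' @return axon volume in mm^3 (exact product, no rounding).
#' @examples
#' axon_volume(0.15, 0.76)  # 0.114
#' @export
axon_volume <- function(nerve_volume, fiber_fraction) {
  if (any(nerve_volume < 0)) stop("nerve_volume must be >= 0")
  if (any(fiber_fraction < 0 | fiber_fraction > 1))
    stop("fiber_fraction must lie in [0, 1]")
  nerve_volume * fiber_fraction
}

#' Signed percent change between two group means
#'
#' `100 * (comparison - reference) / denominator`. The denominator
#' convention is explicit because published percent-change statements
#' alternate between normalizing by the reference (sham) mean and by
#' the comparison mean; `"larger"` picks whichever mean is larger.
#'
#' @param reference_mean reference (e.g. sham) group mean.
#' @param comparison_mean comparison (e.g. TBI) group mean.
#' @param denominator `"reference"`, `"comparison"` or `"larger"`.
#' @return signed percent change (not rounded; see [round()] for
#'   report-style integer percentages).
#' @examples
#' percent_change(0.03, 0.12)              # +300
#' percent_change(1.89, 1.47)              # -22.2
#' percent_change(0.10, 0.19, "comparison") # +47.4
#' @export
percent_change <- function(reference_mean, comparison_mean,
                           denominator = c("reference", "comparison",
                                           "larger")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                reference = reference_mean,
                comparison = comparison_mean,
                larger = pmax(reference_mean, comparison_mean))
  if (any(den == 0)) stop("chosen percent-change denominator is zero")
  100 * (comparison_mean - reference_mean) / den
}

#' Round a percent change for report output
#'
#' Nearest integer percent with halves rounded away from zero, the
#' convention used in narrative results (e.g. -12.5 becomes -13),
#' unlike [round()]'s round-half-to-even.
#'
#' @param x signed percent change(s).
#' @return integer percent(s).
#' @examples
#' report_percent(percent_change(1.84, 1.61))  # -13
#' @export
report_percent <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Pearson correlation with r-squared and p-value
#'
#' Sample Pearson correlation with the two-sided p-value from the
#' t transform on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (n >= 3, non-constant).
#' @return list with `r`, `r2`, `p`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Fixed-effects two-way ANOVA on a cohort table
#'
#' Type II sums of squares for group, day and their interaction, on the
#' per-eye records of one metric. This is a fixed-effects simplification
#' of a mixed design (eyes nested in animals are treated as independent
#' observations); the simplification is noted in the returned object.
#'
#' @param table tidy cohort data.frame with columns `group`, `day`,
#'   `metric`, `value` (as produced by [simulate_cohort()] or
#'   [summarize_cohort()]).
#' @param metric metric name to analyze.
#' @return data.frame with rows `group`, `day`, `group:day` and columns
#'   `F`, `p`, plus attribute `note` recording the fixed-effects
#'   simplification.
#' @export
two_way_anova <- function(table, metric) {
  d <- table[table$metric == metric, ]
  if (nrow(d) == 0L) stop("no records for metric '", metric, "'")
  d$group <- factor(d$group)
  d$day <- factor(d$day)
  if (nlevels(d$group) < 2L || nlevels(d$day) < 2L)
    stop("two_way_anova needs at least 2 levels per factor")
  cells <- table(d$group, d$day)
  if (any(cells < 2L)) {
    empty <- which(cells < 2L, arr.ind = TRUE)
    stop("cells with fewer than 2 observations: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  fit <- stats::lm(value ~ group * day, data = d)
  aov2 <- car::Anova(fit, type = 2)
  out <- data.frame(term = c("group", "day", "group:day"),
                    F = aov2[["F value"]][1:3],
                    p = aov2[["Pr(>F)"]][1:3],
                    row.names = NULL)
  attr(out, "note") <-
    "fixed-effects two-way ANOVA; eyes treated as independent observations"
  out
}

#' Summarize fitted maps of a simulated cohort into a tidy table
#'
#' Fits every nerve of a cohort ([fit_volume()] over the metric-ROI
#' voxels), averages each parametric map over the metric ROI, computes
#' nerve volume from the whole-nerve ROI and axon volume from the
#' whole-ROI fiber fraction, and returns one tidy record per
#' animal x eye x day x metric.
#'
#' Fitting is restricted to the voxels actually summarized (metric ROI
#' for map means; whole-nerve ROI voxels are fitted only for the fiber
#' fraction entering axon volume when `fit_whole = TRUE`, otherwise the
#' metric-ROI fiber fraction is reused).
#'
#' @param cohort result of [simulate_cohort()].
#' @param cfg a [dbsi_fit_config()]; defaults to the cohort's mode.
#' @param fit_whole fit all whole-nerve voxels for the axon-volume
#'   fiber fraction (slower); default reuses the central-ROI fraction.
#' @param verbose print one line per nerve.
#' @return tidy data.frame (animal, group, eye, day, metric, value).
#' @export
summarize_cohort <- function(cohort, cfg = NULL, fit_whole = FALSE,
                             verbose = FALSE) {
  if (is.null(cfg))
    cfg <- dbsi_fit_config(partition = partition_config(cohort$spec$mode))
  out <- vector("list", length(cohort$nerves))
  for (n in seq_along(cohort$nerves)) {
    nerve <- cohort$nerves[[n]]
    maps <- fit_volume(nerve$dwi, cohort$scheme, nerve$mask_metric, cfg)
    roi_m <- roi_spec(nerve$mask_metric, nerve$voxel_volume, "metric_roi")
    roi_w <- roi_spec(nerve$mask_whole, nerve$voxel_volume, "whole_nerve_roi")
    vals <- vapply(.metric_names, function(nm) roi_mean(maps[[nm]], roi_m), 0)
    nv <- nerve_volume(roi_w)
    ff_whole <- if (fit_whole) {
      maps_w <- fit_volume(nerve$dwi, cohort$scheme, nerve$mask_whole, cfg)
      roi_mean(maps_w$fiber_fraction,
               roi_spec(nerve$mask_whole, nerve$voxel_volume, "metric_roi"))
    } else vals[["fiber_fraction"]]
    vals <- c(vals, nerve_volume = nv, axon_volume = axon_volume(nv, ff_whole))
    out[[n]] <- data.frame(animal = nerve$animal, group = nerve$group,
                           eye = nerve$eye, day = nerve$day,
                           metric = names(vals), value = unname(vals),
                           row.names = NULL)
    if (verbose)
      message("summarize_cohort: nerve ", n, "/", length(cohort$nerves))
  }
  do.call(rbind, out)
}

#' Group summary table (mean +/- SD per group and day)
#'
#' @param table tidy cohort data.frame (animal, group, eye, day, metric,
#'   value).
#' @return data.frame with group, day, metric, n, mean, sd.
#' @export
group_summary <- function(table) {
  agg <- aggregate(value ~ group + day + metric, data = table,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  out <- data.frame(group = agg$group, day = agg$day, metric = agg$metric,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"])
  out[order(out$metric, out$day, out$group), ]
}
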