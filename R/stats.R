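#' Percent change between group means
#'
#' Reported as a loss relative to control:
#' `(control - disease) / control * 100`.
#'
#' @param control_mean positive control-group mean.
#' @param disease_mean disease-group mean.
#' @return Percent change (positive = reduction in disease).
#' @export
percent_change <- function(control_mean, disease_mean) {
  nc_check(is.numeric(control_mean) && all(is.finite(control_mean)) &&
             all(control_mean > 0), "control_mean must be positive")
  (control_mean - disease_mean) / control_mean * 100
}

.group_levels <- c("control", "disease")

.mean_sem <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
}

#' Nested two-group comparison of a per-cell metric
#'
#' Fits a linear mixed effects model with a fixed group effect and a
#' random intercept per animal (REML), honouring the nesting of cells
#' within animals: the cell is the observation unit, the animal the
#' grouping unit. Group means and SEMs are reported over cells. Cells
#' with a missing metric value (e.g. NND in a single-cluster cell) are
#' dropped.
#'
#' @param records data.frame with columns `animal_id`, `group` (levels
#'   "control"/"disease"), `cell_id`, and the metric column.
#' @param metric name of the metric column to compare.
#' @return A `group_comparison`: group means +/- SEM, fixed-effect
#'   estimate (disease minus control), two-sided p-value, percent change,
#'   and a model descriptor.
#' @export
compare_groups <- function(records, metric) {
  records <- as.data.frame(records)
  nc_check(all(c("animal_id", "group", "cell_id", metric) %in% names(records)),
           sprintf("records must contain animal_id, group, cell_id and '%s'", metric))
  nc_check(all(records$group %in% .group_levels),
           "group must be 'control' or 'disease'")
  d <- data.frame(animal_id = factor(records$animal_id),
                  group = factor(records$group, levels = .group_levels),
                  value = as.numeric(records[[metric]]))
  d <- d[is.finite(d$value), ]
  n_animals <- tapply(d$animal_id, d$group, function(a) length(unique(a)))
  if (any(is.na(n_animals)) || any(n_animals < 2))
    nc_stop("each group needs at least two animals with data",
            "nc_inference_error")
  ms <- lapply(split(d$value, d$group), .mean_sem)
  est <- ms$disease["mean"] - ms$control["mean"]
  degenerate <- var(d$value) == 0
  if (degenerate) {
    p <- 1
    model <- "degenerate (zero variance)"
  } else {
    fit <- tryCatch(
      nlme::lme(value ~ group, random = ~ 1 | animal_id, data = d,
                method = "REML"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tt <- summary(fit)$tTable
      est <- unname(tt["groupdisease", "Value"])
      p <- unname(tt["groupdisease", "p-value"])
      model <- "lme: value ~ group, random = ~1 | animal (REML)"
    } else {
      # fall back to a t-test on per-animal means if the mixed fit fails
      am <- tapply(d$value, list(d$animal_id, d$group), mean)
      tc <- am[!is.na(am[, "control"]), "control"]
      td <- am[!is.na(am[, "disease"]), "disease"]
      ht <- t.test(td, tc, var.equal = TRUE)
      p <- ht$p.value
      model <- "fallback: Student t-test on per-animal means"
    }
  }
  structure(list(metric = metric,
                 control = ms$control, disease = ms$disease,
                 n_animals = n_animals,
                 estimate = unname(est),
                 percent_change = percent_change(ms$control["mean"],
                                                 ms$disease["mean"]),
                 p_value = unname(p),
                 alpha = 0.05,
                 model = model,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: control %.4g +/- %.3g (n=%d), disease %.4g +/- %.3g (n=%d)\n",
              x$metric, x$control["mean"], x$control["sem"],
              as.integer(x$control["n"]), x$disease["mean"], x$disease["sem"],
              as.integer(x$disease["n"])))
  cat(sprintf("  change %.3g%% (loss relative to control), p = %.4g [%s]\n",
              unname(x$percent_change), x$p_value, x$model))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(metric = x$metric,
             control_mean = unname(x$control["mean"]),
             control_sem = unname(x$control["sem"]),
             control_n = unname(x$control["n"]),
             disease_mean = unname(x$disease["mean"]),
             disease_sem = unname(x$disease["sem"]),
             disease_n = unname(x$disease["n"]),
             estimate = x$estimate,
             percent_change = unname(x$percent_change),
             p_value = x$p_value,
             model = x$model)
}

#' Densitometry comparison of normalized band intensities
#'
#' Normalizes the target band to the loading control per lane, collapses
#' technical replicates to one value per biological sample (preventing
#' pseudo-replication), and compares groups with Student's unpaired
#' two-sided t-test at the sample (animal) level.
#'
#' @param table data.frame with columns `sample_id`, `group`
#'   ("control"/"disease"), `target_band_intensity`,
#'   `loading_control_band_intensity`, optional `replicate`.
#' @return A `group_comparison` on the normalized expression values
#'   (means over biological samples).
#' @export
densitometry_compare <- function(table) {
  table <- as.data.frame(table)
  need <- c("sample_id", "group", "target_band_intensity",
            "loading_control_band_intensity")
  nc_check(all(need %in% names(table)),
           paste("densitometry table must contain",
                 paste(need, collapse = ", ")), "nc_schema_error")
  nc_check(all(table$target_band_intensity > 0) &&
             all(table$loading_control_band_intensity > 0),
           "band intensities must be positive")
  nc_check(all(table$group %in% .group_levels),
           "group must be 'control' or 'disease'")
  table$normalized <- table$target_band_intensity /
    table$loading_control_band_intensity
  per_sample <- stats::aggregate(normalized ~ sample_id + group, table, mean)
  counts <- table(per_sample$group)
  if (length(counts) < 2 || any(counts < 2))
    nc_stop("each group needs at least two biological samples",
            "nc_inference_error")
  vc <- per_sample$normalized[per_sample$group == "control"]
  vd <- per_sample$normalized[per_sample$group == "disease"]
  if (var(c(vc, vd)) == 0) {
    p <- 1
    model <- "degenerate (zero variance)"
  } else {
    ht <- t.test(vd, vc, var.equal = TRUE)
    p <- ht$p.value
    model <- "Student's unpaired t-test on per-sample normalized means"
  }
  structure(list(metric = "normalized_expression",
                 control = .mean_sem(vc), disease = .mean_sem(vd),
                 n_animals = c(control = length(vc), disease = length(vd)),
                 estimate = mean(vd) - mean(vc),
                 percent_change = percent_change(mean(vc), mean(vd)),
                 p_value = p,
                 alpha = 0.05,
                 model = model,
                 degenerate = identical(model, "degenerate (zero variance)")),
            class = "group_comparison")
}
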