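#' One-way ANOVA with Tukey HSD and post-hoc power
#'
#' Classical one-way ANOVA via [stats::aov()], Tukey honest significant
#' difference pairwise comparisons, and post-hoc power computed from the
#' observed effect size: Cohen's \eqn{f^2 = \eta^2/(1-\eta^2)},
#' noncentrality \eqn{\lambda = f^2 N}, power
#' \eqn{P(F_{k-1,N-k,\lambda} > F_{crit})} at the stated alpha.
#'
#' @param table `data.frame` with the response and a grouping column.
#' @param value_col,group_col Column names.
#' @param alpha Significance level.
#' @return List with `f_statistic`, `df`, `p_value`, `tukey`
#'   (`data.frame` of pairwise comparisons), `power`, `effect_eta_sq`,
#'   `group_means`.
#' @export
one_way_anova <- function(table, value_col = "value", group_col = "group",
                          alpha = 0.05) {
  g <- factor(table[[group_col]])
  y <- table[[value_col]]
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 2L)) stop("need at least 2 samples per group")
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  ss_between <- an[1, "Sum Sq"]
  ss_within <- an[2, "Sum Sq"]
  ss_total <- ss_between + ss_within
  if (ss_within <= 1e-12 * max(ss_total, 1e-300) && ss_between > 0)
    stop("zero within-group variance: F undefined")
  df1 <- an[1, "Df"]; df2 <- an[2, "Df"]
  if (ss_between <= 1e-12 * max(ss_total, 1e-300)) {
    fstat <- 0; pval <- 1
  } else {
    fstat <- an[1, "F value"]; pval <- an[1, "Pr(>F)"]
  }
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  eta2 <- ss_between / (ss_between + ss_within)
  N <- length(y)
  if (eta2 < 1) {
    lambda <- eta2 / (1 - eta2) * N
    fcrit <- stats::qf(1 - alpha, df1, df2)
    power <- stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
  } else power <- 1
  means <- tapply(y, g, mean)
  list(f_statistic = fstat, df = c(df1, df2), p_value = pval,
       tukey = tukey, power = power, effect_eta_sq = eta2,
       group_means = data.frame(group = names(means),
                                mean = as.numeric(means),
                                sd = as.numeric(tapply(y, g, stats::sd)),
                                n = as.integer(table(g)),
                                row.names = NULL))
}

#' Two-sided paired t-test
#'
#' Thin wrapper over [stats::t.test()] used to compare cycle-1 and cycle-8
#' hysteresis energies per specimen.
#'
#' @param x,y Paired measurements (equal length, >= 2 pairs).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("pairs must have equal lengths")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1L, p_value = 1,
                mean_difference = 0))
  if (stats::sd(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Cell density from image counts
#'
#' The imaging volume is the field-of-view area times the Z thickness;
#' density is the cell count over that volume.
#'
#' @param cell_count Number of counted nuclei (>= 0).
#' @param fov_area_mm2 Field-of-view area, mm^2.
#' @param z_thickness_mm Image stack thickness, mm.
#' @return Cells per mm^3.
#' @export
cell_density <- function(cell_count, fov_area_mm2, z_thickness_mm) {
  if (cell_count < 0) stop("cell_count must be >= 0")
  if (fov_area_mm2 <= 0 || z_thickness_mm <= 0)
    stop("volume factors must be positive")
  cell_count / (fov_area_mm2 * z_thickness_mm)
}

#' Assemble a cohort report bundle
#'
#' Collects the per-specimen DMA endpoints, hysteresis energy pairs, decay
#' fits and any morphometry/transport/field summaries into deterministic
#' tables (group means +/- sd per endpoint, cycle-1/cycle-8 energy pairs,
#' decay parameters).
#'
#' @param endpoints `data.frame` with columns `sample_id`, `group` and one
#'   column per endpoint (long or wide; wide expected).
#' @param energy_pairs Optional `data.frame` from [compare_first_last()]
#'   (plus `group` column if available).
#' @param decay_fits Optional named list of `decay_fit` objects.
#' @param morphometry Optional `morphometry_result` (or list of them).
#' @param transport Optional `transport_result` or [field_context()] list.
#' @param field Optional `field_estimate`.
#' @return List of class `cohort_report` with `endpoint_summary`,
#'   `endpoints`, `energy_pairs`, `decay_table` and the pass-through
#'   summaries.
#' @export
build_report <- function(endpoints, energy_pairs = NULL, decay_fits = NULL,
                         morphometry = NULL, transport = NULL,
                         field = NULL) {
  if (anyDuplicated(endpoints$sample_id))
    stop("conflicting sample ids in endpoint table")
  num_cols <- setdiff(names(endpoints)[vapply(endpoints, is.numeric,
                                              logical(1))],
                      c("sample_id"))
  ep <- endpoints[order(endpoints$group, endpoints$sample_id), ]
  summ <- do.call(rbind, lapply(sort(unique(ep$group)), function(grp) {
    sub <- ep[ep$group == grp, ]
    do.call(rbind, lapply(sort(num_cols), function(col) {
      data.frame(group = grp, endpoint = col,
                 mean = mean(sub[[col]]), sd = stats::sd(sub[[col]]),
                 n = nrow(sub))
    }))
  }))
  decay_table <- NULL
  if (!is.null(decay_fits)) {
    decay_table <- do.call(rbind, lapply(sort(names(decay_fits)),
                                         function(id) {
      f <- decay_fits[[id]]
      data.frame(sample_id = id, A = f$A, tau = f$tau, y0 = f$y0,
                 rmse = f$rmse, r_squared = f$r_squared,
                 f_statistic = f$f_statistic, p_value = f$p_value)
    }))
  }
  structure(list(endpoint_summary = summ, endpoints = ep,
                 energy_pairs = energy_pairs, decay_table = decay_table,
                 morphometry = morphometry, transport = transport,
                 field = field),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' CSV tables plus a JSON summary, written with deterministic ordering so
#' regeneration from identical inputs is byte-identical.
#'
#' @param report A `cohort_report` from [build_report()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(df, p)
    paths <<- c(paths, p)
  }
  wr(report$endpoint_summary, "endpoint_summary.csv")
  wr(report$endpoints, "endpoints.csv")
  if (!is.null(report$energy_pairs)) wr(report$energy_pairs,
                                        "energy_pairs.csv")
  if (!is.null(report$decay_table)) wr(report$decay_table,
                                       "decay_fits.csv")
  summary_json <- list(
    n_samples = nrow(report$endpoints),
    groups = sort(unique(report$endpoints$group)),
    endpoint_summary = report$endpoint_summary,
    morphometry = if (!is.null(report$morphometry))
      unclass(report$morphometry)[
        !vapply(unclass(report$morphometry), is.list, logical(1))],
    transport = if (!is.null(report$transport))
      report$transport[c("tortuosity_factor", "d_eff_ratio",
                         "volume_fraction", "percolation")],
    field = if (!is.null(report$field)) unclass(report$field))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
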