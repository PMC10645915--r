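#' Mean image value over a region of interest
#'
#' @param image an [image_volume()].
#' @param atlas a [label_volume()], or `NULL` when `roi` is a mask.
#' @param roi integer atlas label, or a binary mask ([image_volume()] or
#'   logical array on the same grid).
#' @return arithmetic mean of the image over the ROI voxels.
#' @export
roi_mean <- function(image, atlas = NULL, roi) {
  if (inherits(roi, "image_volume")) {
    stop_if_grid_mismatch(image$grid, roi$grid, "image and ROI mask")
    sel <- roi$values > 0
  } else if (is.array(roi) || is.logical(roi)) {
    sel <- as.array(roi) > 0
  } else {
    if (is.null(atlas)) stop("atlas required for label ROIs")
    stop_if_grid_mismatch(image$grid, atlas$grid, "image and atlas")
    if (!roi %in% atlas$labels)
      stop("empty-ROI error: label ", roi, " absent from atlas")
    sel <- atlas$labels == roi
  }
  if (!any(sel)) stop("empty-ROI error: ROI contains no voxels")
  mean(image$values[sel])
}

#' Relative bias (percent)
#'
#' `100 * (PET_MRAC - PET_CTAC) / PET_CTAC`: the candidate reconstruction's
#' ROI mean relative to the reference reconstruction's.
#'
#' @param pet_mrac candidate ROI-mean activity.
#' @param pet_ctac reference ROI-mean activity (> 0).
#' @return relative bias in percent.
#' @export
relative_bias <- function(pet_mrac, pet_ctac) {
  if (any(pet_ctac <= 0)) stop("domain error: reference ROI mean must be > 0")
  100 * (pet_mrac - pet_ctac) / pet_ctac
}

#' Relative absolute bias (percent)
#'
#' `100 * |PET_MRAC - PET_CTAC| / PET_CTAC`; always equals
#' `|relative_bias|`.
#'
#' @inheritParams relative_bias
#' @return absolute bias in percent.
#' @export
absolute_bias <- function(pet_mrac, pet_ctac) {
  abs(relative_bias(pet_mrac, pet_ctac))
}

#' One bias record
#'
#' @param subject_id,roi_id,roi_name,method,condition identifiers;
#'   `condition` is one of `"with_background"`, `"lesion_only"`,
#'   `"original"`.
#' @param pet_mrac,pet_ctac ROI-mean activities of candidate and reference.
#' @return one-row data.frame with relative and absolute bias in percent.
#' @export
bias_record <- function(subject_id, roi_id, roi_name, method, condition,
                        pet_mrac, pet_ctac) {
  condition <- match.arg(condition,
                         c("with_background", "lesion_only", "original"))
  data.frame(subject_id = subject_id, condition = condition,
             roi_id = roi_id, roi_name = roi_name, method = method,
             pet_mrac = pet_mrac, pet_ctac = pet_ctac,
             relative_bias_pct = relative_bias(pet_mrac, pet_ctac),
             absolute_bias_pct = absolute_bias(pet_mrac, pet_ctac),
             stringsAsFactors = FALSE)
}

#' Cohort summary: median and IQR per group
#'
#' Groups records by method, ROI and condition and reports the median and
#' interquartile range (linear-interpolation, type-7 quantiles) of the
#' relative bias, plus the group size.
#'
#' @param records data.frame of bias records (see [bias_record()]).
#' @param value_col column to summarize, default `"relative_bias_pct"`.
#' @return data.frame with `method`, `roi_id`, `roi_name`, `condition`,
#'   `median_pct`, `q1_pct`, `q3_pct`, `n_subjects`.
#' @export
cohort_summary <- function(records, value_col = "relative_bias_pct") {
  if (nrow(records) == 0)
    return(data.frame(method = character(), roi_id = integer(),
                      roi_name = character(), condition = character(),
                      median_pct = numeric(), q1_pct = numeric(),
                      q3_pct = numeric(), n_subjects = integer(),
                      stringsAsFactors = FALSE))
  key <- interaction(records$method, records$roi_id, records$condition,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    v <- g[[value_col]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(method = g$method[1], roi_id = g$roi_id[1],
               roi_name = g$roi_name[1], condition = g$condition[1],
               median_pct = q[2], q1_pct = q[1], q3_pct = q[3],
               n_subjects = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$roi_id, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired t-tests against the reference method with BH adjustment
#'
#' For each ROI and each non-reference method, a two-sided paired t-test of
#' the absolute bias against the reference method, over matched subjects.
#' All p-values produced in one call form one family and are adjusted by
#' the Benjamini-Hochberg step-up procedure. Zero-variance differences
#' yield p = 1 by convention (with a warning).
#'
#' @param records data.frame with columns `subject_id`, `roi_id`, `method`
#'   and `absolute_bias_pct` (one condition at a time).
#' @param reference_method method the others are compared to, default
#'   `"dl_dixon"`.
#' @return data.frame with `roi_id`, `comparison`, `t_statistic`,
#'   `p_value`, `p_adjusted`, `n_pairs`.
#' @export
paired_t_bh <- function(records, reference_method = "dl_dixon") {
  methods <- setdiff(unique(records$method), reference_method)
  rois <- unique(records$roi_id)
  rows <- list()
  for (roi in rois) {
    ref <- records[records$roi_id == roi & records$method == reference_method, ]
    for (m in methods) {
      oth <- records[records$roi_id == roi & records$method == m, ]
      common <- intersect(ref$subject_id, oth$subject_id)
      if (length(common) < 3)
        stop("insufficient-data error: fewer than 3 paired subjects for roi ",
             roi, ", method ", m)
      a <- ref$absolute_bias_pct[match(common, ref$subject_id)]
      b <- oth$absolute_bias_pct[match(common, oth$subject_id)]
      d <- b - a
      if (stats::sd(d) == 0) {
        warning("zero variance of paired differences (roi ", roi,
                ", ", m, "); p set to 1")
        tt <- list(statistic = if (mean(d) == 0) 0 else Inf, p.value = 1)
      } else {
        tt <- stats::t.test(b, a, paired = TRUE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(roi_id = roi,
                   comparison = paste(reference_method, "vs", m),
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, n_pairs = length(common),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("roi_id", "comparison", "t_statistic", "p_value", "p_adjusted",
          "n_pairs")]
}

#' Write the evaluation report
#'
#' Tidy CSV (one row per bias record), JSON summary (group medians/IQRs,
#' test results, and boxplot-ready per-group value lists), with
#' deterministic row ordering.
#'
#' @param records bias-record data.frame.
#' @param summaries output of [cohort_summary()].
#' @param stats_tbl output of [paired_t_bh()] (may be `NULL`).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`csv`, `json`).
#' @export
build_report <- function(records, summaries, stats_tbl = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("subject_id", "condition", "roi_id", "roi_name", "method",
            "pet_mrac", "pet_ctac", "relative_bias_pct", "absolute_bias_pct")
  if (nrow(records) > 0) {
    records <- records[order(records$subject_id, records$condition,
                             records$roi_id, records$method), cols]
  } else {
    records <- stats::setNames(
      data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  }
  csv_path <- file.path(dir, "bias_records.csv")
  utils::write.csv(records, csv_path, row.names = FALSE)

  groups <- if (nrow(records) > 0)
    lapply(split(records, interaction(records$method, records$roi_id,
                                      records$condition, drop = TRUE)),
           function(g) list(method = g$method[1], roi_id = g$roi_id[1],
                            condition = g$condition[1],
                            values_pct = g$relative_bias_pct))
  else list()
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(summaries = summaries, stats = stats_tbl,
                            groups = unname(groups)),
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(csv = csv_path, json = json_path))
}
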