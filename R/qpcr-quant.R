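# Relative quantification of Cq tables: delta-Cq against the housekeeping
# gene, fold change by 2^-ddCq against a calibrator group, scaled relative
# abundance, and the group-level detectability filter.

#' Panel and analysis configuration
#'
#' @param genes Character vector of panel gene identifiers.
#' @param housekeeping_gene Housekeeping gene used for within-sample
#'   normalisation; must not be a panel gene.
#' @param calibrator_div Day whose samples form the calibrator group for
#'   fold-change computation (day 0 = undifferentiated cells).
#' @param segments Segment table from [default_segments()] or of the same
#'   shape; consecutive segments must share their boundary day.
#' @param alpha Significance level for trend classification.
#' @param detection_cq_max Cq cutoff: a measurement counts as detected only if
#'   its Cq is strictly below this value.
#' @param min_detected_fraction Minimum fraction of detected replicate
#'   measurements required at every assayed day for a gene to count as
#'   detected in a group.
#' @param ancova_scale Scale on which index slopes are fitted and compared:
#'   `"log2"` (default; variance-stabilising for multiplicative expression
#'   noise) or `"linear"`.
#' @param index_level Whether index slopes use replicate-level values
#'   (default) or per-day means.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(genes,
                         housekeeping_gene = "GAPDH",
                         calibrator_div = 0,
                         segments = default_segments(),
                         alpha = 0.05,
                         detection_cq_max = 40,
                         min_detected_fraction = 0.5,
                         ancova_scale = c("log2", "linear"),
                         index_level = c("replicate", "day_mean")) {
  if (housekeeping_gene %in% genes) {
    stop("housekeeping gene cannot be a panel gene", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (min_detected_fraction < 0 || min_detected_fraction > 1) {
    stop("`min_detected_fraction` must lie in [0, 1]", call. = FALSE)
  }
  segments <- validate_segments(segments)
  structure(
    list(genes = genes, housekeeping_gene = housekeeping_gene,
         calibrator_div = calibrator_div, segments = segments, alpha = alpha,
         detection_cq_max = detection_cq_max,
         min_detected_fraction = min_detected_fraction,
         ancova_scale = match.arg(ancova_scale),
         index_level = match.arg(index_level)),
    class = "panel_config"
  )
}

cq_columns <- c("sample_id", "organoid_type", "treatment", "div", "replicate",
                "gene", "cq", "nd")

#' Validate a replicate-level Cq table
#'
#' Checks column presence, the Cq range (0, 40] for measured values, and
#' uniqueness of (sample, gene) pairs.
#'
#' @param cq A Cq table as returned by [simulate_cq_table()] or
#'   [read_cq_csv()].
#' @param max_cq Upper bound of admissible Cq values (run length).
#' @return The table, invisibly, if valid.
#' @export
validate_cq_table <- function(cq, max_cq = 40) {
  missing_cols <- setdiff(cq_columns, names(cq))
  if (length(missing_cols)) {
    stop("Cq table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(cq$cq) & (cq$cq <= 0 | cq$cq > max_cq))
  if (length(bad)) {
    stop("Cq values outside (0, ", max_cq, "] at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(cq$sample_id, cq$gene, sep = "\r")
  if (anyDuplicated(key) > 0) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicated (sample, gene) pairs at row(s): ",
         paste(utils::head(d, 10), collapse = ", "), call. = FALSE)
  }
  invisible(cq)
}

expression_table <- function(cq_like, value, value_kind) {
  tibble::tibble(
    sample_id = cq_like$sample_id,
    organoid_type = cq_like$organoid_type,
    treatment = cq_like$treatment,
    div = cq_like$div,
    replicate = cq_like$replicate,
    gene = cq_like$gene,
    value = value,
    value_kind = value_kind
  )
}

#' Delta-Cq normalisation against the housekeeping gene
#'
#' For every sample and panel gene, delta-Cq = Cq(gene) - Cq(housekeeping).
#' Not-detected measurements propagate as missing values. Errors if the
#' housekeeping gene is missing or not detected in any sample.
#'
#' @param cq A validated Cq table.
#' @param config A [panel_config()].
#' @return An expression table with `value_kind = "dcq"`.
#' @export
compute_dcq <- function(cq, config) {
  validate_cq_table(cq, max_cq = config$detection_cq_max)
  hk <- cq[cq$gene == config$housekeeping_gene, ]
  ok <- !hk$nd & !is.na(hk$cq)
  miss <- setdiff(unique(cq$sample_id), hk$sample_id[ok])
  if (length(miss)) {
    stop("housekeeping gene '", config$housekeeping_gene,
         "' missing or not detected in sample(s): ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  genes <- cq[cq$gene != config$housekeeping_gene, ]
  hk_cq <- hk$cq[match(genes$sample_id, hk$sample_id)]
  value <- ifelse(genes$nd | is.na(genes$cq), NA_real_, genes$cq - hk_cq)
  expression_table(genes, value, "dcq")
}

#' Fold change by the 2^-ddCq method
#'
#' Per gene, ddCq is the sample delta-Cq minus the arithmetic mean delta-Cq of
#' the calibrator group (equivalently, the geometric mean of calibrator
#' expression), and fold change is `2^-ddCq`.
#'
#' @param dcq An expression table with `value_kind = "dcq"`.
#' @param config A [panel_config()]; `config$calibrator_div` selects the
#'   calibrator samples.
#' @return An expression table with `value_kind = "fold_change"`.
#' @export
compute_fold_change <- function(dcq, config) {
  stopifnot(all(dcq$value_kind == "dcq"))
  cal <- dcq[dcq$div == config$calibrator_div & !is.na(dcq$value), ]
  cal_mean <- tapply(cal$value, cal$gene, mean)
  absent <- setdiff(unique(dcq$gene), names(cal_mean))
  if (length(absent)) {
    stop("no detected calibrator measurement for gene(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ddcq <- dcq$value - as.vector(cal_mean[dcq$gene])
  expression_table(dcq, 2^(-ddcq), "fold_change")
}

#' Scaled relative abundance
#'
#' Expression relative to the housekeeping gene: `2^-dCq * 10000`.
#'
#' @param dcq An expression table with `value_kind = "dcq"`.
#' @return An expression table with `value_kind = "scaled_abundance"`.
#' @export
scaled_relative_abundance <- function(dcq) {
  stopifnot(all(dcq$value_kind == "dcq"))
  expression_table(dcq, 2^(-dcq$value) * 1e4, "scaled_abundance")
}

#' Group-level detectability filter
#'
#' A gene counts as detected in a group if, at every assayed day of the group,
#' the fraction of replicate measurements with Cq strictly below
#' `detection_cq_max` is at least `min_detected_fraction`.
#'
#' @param cq A validated Cq table.
#' @param config A [panel_config()].
#' @param group_keys Metadata columns defining the groups (default: organoid
#'   type and treatment arm).
#' @return A tibble with the group columns, `gene`, and logical `detected`.
#' @export
detectability_filter <- function(cq, config,
                                 group_keys = c("organoid_type", "treatment")) {
  if (!all(group_keys %in% names(cq))) {
    stop("`group_keys` must be metadata columns of the Cq table", call. = FALSE)
  }
  if (nrow(cq) == 0) stop("empty group: no Cq measurements", call. = FALSE)
  cq$.detected <- !cq$nd & !is.na(cq$cq) & cq$cq < config$detection_cq_max
  per_day <- dplyr::summarise(
    dplyr::group_by(cq, dplyr::across(dplyr::all_of(c(group_keys, "gene", "div")))),
    frac = mean(.data$.detected), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_day, dplyr::across(dplyr::all_of(c(group_keys, "gene")))),
    detected = all(.data$frac >= config$min_detected_fraction),
    .groups = "drop"
  )
  out
}

#' Arm-over-arm fold-change ratio table
#'
#' Heatmap-ready long table of the ratio of mean fold change in one arm over
#' another, per gene and day.
#'
#' @param expr An expression table with `value_kind = "fold_change"`.
#' @param arm_a,arm_b Treatment labels; the ratio is `mean(arm_a) /
#'   mean(arm_b)`.
#' @param divs Days to tabulate; defaults to all days present.
#' @return A tibble with columns `gene`, `div`, `ratio`.
#' @export
fold_change_ratio_table <- function(expr, arm_a = "ALLO", arm_b = "DMSO",
                                    divs = NULL) {
  stopifnot(all(expr$value_kind == "fold_change"))
  if (is.null(divs)) divs <- sort(unique(expr$div))
  sub <- expr[expr$treatment %in% c(arm_a, arm_b) & expr$div %in% divs &
                !is.na(expr$value), ]
  means <- dplyr::summarise(
    dplyr::group_by(sub, .data$gene, .data$div, .data$treatment),
    m = mean(.data$value), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "treatment",
                             values_from = "m")
  for (arm in c(arm_a, arm_b)) {
    if (!arm %in% names(wide)) wide[[arm]] <- NA_real_
  }
  one_sided <- xor(is.na(wide[[arm_a]]), is.na(wide[[arm_b]]))
  if (any(one_sided)) {
    bad <- wide[one_sided, c("gene", "div")]
    stop("day measured in one arm only: ",
         paste(sprintf("%s/DIV%s", bad$gene, bad$div), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(gene = wide$gene, div = wide$div,
                 ratio = wide[[arm_a]] / wide[[arm_b]])
}
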