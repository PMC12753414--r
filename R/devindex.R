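# Segmented developmental index: per-segment gene trend classification in the
# control arm, equal-weight up/down expression ratio per sample, per-segment
# maturation slopes, and ANCOVA comparison of slopes between arms.

#' Default developmental segments
#'
#' Four consecutive day-in-vitro intervals; consecutive segments share their
#' boundary day, so the boundary day's samples contribute to both.
#'
#' @return A tibble with columns `label`, `start_div`, `end_div`.
#' @export
default_segments <- function() {
  tibble::tibble(
    label = c("DIV26-DIV55", "DIV55-DIV78", "DIV78-DIV95", "DIV95-DIV138"),
    start_div = c(26, 55, 78, 95),
    end_div = c(55, 78, 95, 138)
  )
}

validate_segments <- function(segments) {
  if (!all(c("label", "start_div", "end_div") %in% names(segments))) {
    stop("segments need columns label, start_div, end_div", call. = FALSE)
  }
  if (any(segments$start_div >= segments$end_div)) {
    stop("each segment needs start_div < end_div", call. = FALSE)
  }
  n <- nrow(segments)
  if (n > 1 &&
      !all(segments$start_div[-1] == segments$end_div[-n])) {
    stop("consecutive segments must share their boundary day", call. = FALSE)
  }
  segments
}

as_segment <- function(segment) {
  if (is.null(segment$label)) segment$label <- paste0("DIV", segment$start_div,
                                                      "-DIV", segment$end_div)
  list(label = as.character(segment$label[[1]]),
       start_div = as.numeric(segment$start_div[[1]]),
       end_div = as.numeric(segment$end_div[[1]]))
}

#' Classify gene trends within a segment
#'
#' Pearson correlation of replicate-level log2 fold change against day, over
#' all control-arm observations whose day falls inside the segment (boundary
#' days included). A gene is `up` if r > 0 and p < alpha, `down` if r < 0 and
#' p < alpha, otherwise `ns`. The p-value is the two-sided t-transform of r
#' with `n - 2` degrees of freedom. Genes with fewer than 3 observations or
#' zero variance are `ns` (the former with a warning).
#'
#' @param expr Expression table with `value_kind = "fold_change"`.
#' @param segment One row of a segment table (or a list with `start_div`,
#'   `end_div`, `label`).
#' @param control_arm Treatment label of the arm used for classification.
#' @param alpha Significance level.
#' @return A tibble with columns `gene`, `n_obs`, `r`, `p`, `direction`, and
#'   the segment stored in attribute `"segment"`.
#' @export
classify_segment_genes <- function(expr, segment, control_arm = "DMSO",
                                   alpha = 0.05) {
  stopifnot(all(expr$value_kind == "fold_change"))
  seg <- as_segment(segment)
  sel <- expr$treatment == control_arm &
    expr$div >= seg$start_div & expr$div <= seg$end_div
  if (!any(sel)) {
    stop("segment ", seg$label, " has no control-arm data", call. = FALSE)
  }
  x_all <- expr$div[sel]
  g_all <- expr$gene[sel]
  y_all <- log2(expr$value[sel])
  genes <- unique(g_all)
  idx <- split(seq_along(g_all), g_all)

  n_obs <- integer(length(genes))
  r <- p <- rep(NA_real_, length(genes))
  direction <- rep("ns", length(genes))
  few <- character(0)
  for (k in seq_along(genes)) {
    i <- idx[[genes[k]]]
    keep <- is.finite(y_all[i])
    x <- x_all[i][keep]; y <- y_all[i][keep]
    n <- length(y)
    n_obs[k] <- n
    if (n < 3) { few <- c(few, genes[k]); next }
    if (stats::var(y) == 0 || stats::var(x) == 0) next
    rk <- stats::cor(x, y)
    r[k] <- rk
    if (1 - rk^2 <= .Machine$double.eps) {
      p[k] <- 0
    } else {
      tk <- rk * sqrt((n - 2) / (1 - rk^2))
      p[k] <- 2 * stats::pt(-abs(tk), n - 2)
    }
    if (p[k] < alpha) direction[k] <- if (rk > 0) "up" else "down"
  }
  if (length(few)) {
    warning("classified ns for lack of observations (< 3): ",
            paste(few, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(gene = genes, n_obs = n_obs, r = r, p = p,
                        direction = direction)
  attr(out, "segment") <- seg
  attr(out, "alpha") <- alpha
  out
}

#' Per-sample developmental index within a segment
#'
#' Each gene's fold change is first rescaled by that gene's mean fold change
#' over the control arm within the segment, so every gene enters with equal
#' weight; the index of a sample is the mean rescaled fold change over the
#' up-set divided by the mean over the down-set. The control-derived gene sets
#' and rescaling constants are applied unchanged to every requested arm.
#'
#' @param expr Expression table with `value_kind = "fold_change"`.
#' @param cls Output of [classify_segment_genes()] (carries the segment).
#' @param arm Treatment label(s) for which index values are computed.
#' @param control_arm Arm providing the rescaling constants.
#' @return A tibble with columns `sample_id`, `treatment`, `div`, `replicate`,
#'   `segment`, `index`. If either gene set is empty the result has zero rows,
#'   attribute `"evaluable"` is `FALSE`, and a warning is raised.
#' @export
compute_index <- function(expr, cls, arm, control_arm = "DMSO") {
  seg <- attr(cls, "segment")
  if (is.null(seg)) stop("`cls` must come from classify_segment_genes()",
                         call. = FALSE)
  up <- cls$gene[cls$direction == "up"]
  dn <- cls$gene[cls$direction == "down"]
  empty_result <- function(reason) {
    warning("segment ", seg$label, " non-evaluable: ", reason, call. = FALSE)
    out <- tibble::tibble(sample_id = character(), treatment = character(),
                          div = numeric(), replicate = integer(),
                          segment = character(), index = numeric())
    attr(out, "evaluable") <- FALSE
    attr(out, "reason") <- reason
    attr(out, "segment") <- seg
    out
  }
  if (length(up) == 0 || length(dn) == 0) {
    return(empty_result(paste0(
      "empty ", paste(c("up", "down")[c(length(up) == 0, length(dn) == 0)],
                      collapse = " and "), "-regulated gene set")))
  }
  in_seg <- expr$div >= seg$start_div & expr$div <= seg$end_div &
    expr$gene %in% c(up, dn)
  ctrl <- in_seg & expr$treatment == control_arm & !is.na(expr$value)
  cg <- tapply(expr$value[ctrl], expr$gene[ctrl], mean)
  if (!all(c(up, dn) %in% names(cg))) {
    return(empty_result("control arm lacks detected values for a set gene"))
  }

  rows <- in_seg & expr$treatment %in% arm & !is.na(expr$value)
  sub <- expr[rows, ]
  resc <- sub$value / unname(cg[sub$gene])
  is_up <- sub$gene %in% up
  key <- sub$sample_id
  mean_by <- function(v, k) {
    s <- rowsum(v, k)
    n <- rowsum(rep(1, length(v)), k)
    stats::setNames(as.vector(s / n), rownames(s))
  }
  up_mean <- mean_by(resc[is_up], key[is_up])
  dn_mean <- mean_by(resc[!is_up], key[!is_up])
  ids <- intersect(names(up_mean), names(dn_mean))
  index <- up_mean[ids] / dn_mean[ids]
  out <- tibble::as_tibble(sub[match(ids, sub$sample_id),
                               c("sample_id", "treatment", "div", "replicate")])
  out$segment <- seg$label
  out$index <- unname(index)
  out <- out[order(match(out$treatment, arm), out$div, out$replicate), ]
  drop <- !is.finite(out$index) | out$index <= 0
  if (any(drop)) {
    warning("dropped ", sum(drop), " sample(s) with undefined index in ",
            seg$label, call. = FALSE)
    out <- out[!drop, ]
  }
  attr(out, "evaluable") <- TRUE
  attr(out, "segment") <- seg
  attr(out, "gene_sets") <- list(up = up, down = dn)
  attr(out, "rescale") <- cg[c(up, dn)]
  out
}

index_response <- function(index, scale) {
  if (scale == "log2") log2(index) else index
}

day_means <- function(series) {
  agg <- stats::aggregate(index ~ treatment + div + segment, data = series,
                          FUN = mean)
  agg$replicate <- 1L
  agg$sample_id <- paste(agg$treatment, agg$div, sep = "_")
  tibble::as_tibble(agg)
}

#' Ordinary least-squares maturation slope of the index
#'
#' @param series An index series from [compute_index()].
#' @param arm Treatment label of the arm to fit.
#' @param segment Optional segment (row or label) to restrict to.
#' @param scale `"log2"` (default) fits the slope of log2 index against day;
#'   `"linear"` fits the raw index.
#' @return The slope, in (log2) index units per day.
#' @export
fit_segment_slopes <- function(series, arm, segment = NULL,
                               scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  rows <- series$treatment == arm
  if (!is.null(segment)) {
    lab <- if (is.character(segment)) segment else as_segment(segment)$label
    rows <- rows & series$segment == lab
  }
  sub <- series[rows, ]
  if (length(unique(sub$div)) < 2) {
    stop("slope undefined: fewer than 2 distinct days with index values",
         call. = FALSE)
  }
  y <- index_response(sub$index, scale)
  unname(stats::coef(stats::lm(y ~ sub$div))[2])
}

#' ANCOVA comparison of index slopes between arms
#'
#' Fits `response ~ day * arm` on replicate-level index values of a segment
#' and reports the F-test of the day-by-arm interaction together with the
#' per-arm slopes from the full model. A fit with (numerically) zero residual
#' variance is flagged degenerate; its p-value is recorded as 0 when the
#' interaction carries signal and 1 when the arms coincide.
#'
#' @param series Index series holding both arms.
#' @param segment Optional segment (row or label) to restrict to.
#' @param control_arm,treated_arm Treatment labels.
#' @param scale `"log2"` (default) or `"linear"` response scale.
#' @return A one-row tibble: `segment`, `slope_control`, `slope_treated`,
#'   `interaction_F`, `interaction_p`, `df_num`, `df_den`, `n_obs`,
#'   `evaluable`, `degenerate`.
#' @export
compare_slopes_ancova <- function(series, segment = NULL,
                                  control_arm = "DMSO", treated_arm = "ALLO",
                                  scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  lab <- if (is.null(segment)) unique(series$segment)[1]
  else if (is.character(segment)) segment else as_segment(segment)$label
  sub <- series[series$segment == lab &
                  series$treatment %in% c(control_arm, treated_arm), ]
  not_eval <- function(reason) {
    tibble::tibble(segment = lab, slope_control = NA_real_,
                   slope_treated = NA_real_, interaction_F = NA_real_,
                   interaction_p = NA_real_, df_num = NA_integer_,
                   df_den = NA_integer_, n_obs = nrow(sub), evaluable = FALSE,
                   degenerate = NA, note = reason)
  }
  for (a in c(control_arm, treated_arm)) {
    nd <- length(unique(sub$div[sub$treatment == a]))
    if (nd < 2) {
      return(not_eval(paste0("arm ", a, " has ", nd, " distinct day(s)")))
    }
  }
  d <- data.frame(
    y = index_response(sub$index, scale),
    div = sub$div,
    arm = factor(sub$treatment, levels = c(control_arm, treated_arm))
  )
  fit <- stats::lm(y ~ div * arm, data = d)
  # perfect fits are handled via the degeneracy flag below; anova()'s warning
  # about them is expected there
  a <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ss <- a[["Sum Sq"]]
  names(ss) <- rownames(a)
  tss <- sum(ss)
  rss <- ss[["Residuals"]]
  ss_int <- ss[["div:arm"]]
  tol <- 1e-8 * (tss + .Machine$double.eps)
  degenerate <- rss <= tol
  if (degenerate) {
    if (ss_int <= tol) {
      f_int <- 0; p_int <- 1
    } else {
      f_int <- Inf; p_int <- 0
    }
  } else {
    f_int <- a["div:arm", "F value"]
    p_int <- a["div:arm", "Pr(>F)"]
  }
  cf <- stats::coef(fit)
  tibble::tibble(
    segment = lab,
    slope_control = unname(cf[["div"]]),
    slope_treated = unname(cf[["div"]] + cf[[grep("^div:arm", names(cf),
                                                  value = TRUE)[1]]]),
    interaction_F = f_int, interaction_p = p_int,
    df_num = 1L, df_den = a["Residuals", "Df"],
    n_obs = nrow(sub), evaluable = TRUE, degenerate = degenerate,
    note = NA_character_
  )
}

#' Run the full segmented developmental-index pipeline
#'
#' For each configured segment, in order: classify gene trends in the control
#' arm, compute the index in both arms with control-derived gene sets and
#' rescaling constants, and compare arm slopes by ANCOVA. A failure in one
#' segment is recorded on that segment; the remaining segments still run.
#'
#' @param expr Expression table with `value_kind = "fold_change"`.
#' @param config A [panel_config()].
#' @param control_arm,treated_arm Treatment labels.
#' @return An object of class `devindex_result`: a list with tibbles
#'   `classification`, `index`, `slopes`, plus `gene_sets`, `rescale`,
#'   `alpha`, `scale`.
#' @export
run_devindex_pipeline <- function(expr, config, control_arm = "DMSO",
                                  treated_arm = "ALLO") {
  segs <- config$segments
  cls_list <- idx_list <- cmp_list <- vector("list", nrow(segs))
  gene_sets <- rescale <- stats::setNames(vector("list", nrow(segs)),
                                          segs$label)
  for (s in seq_len(nrow(segs))) {
    seg <- segs[s, ]
    res <- tryCatch({
      cls <- classify_segment_genes(expr, seg, control_arm = control_arm,
                                    alpha = config$alpha)
      idx <- compute_index(expr, cls, arm = c(control_arm, treated_arm),
                           control_arm = control_arm)
      cmp <- if (isTRUE(attr(idx, "evaluable"))) {
        idx_for_fit <- if (config$index_level == "day_mean") day_means(idx)
        else idx
        compare_slopes_ancova(idx_for_fit, segment = seg$label,
                              control_arm = control_arm,
                              treated_arm = treated_arm,
                              scale = config$ancova_scale)
      } else {
        tibble::tibble(segment = seg$label, slope_control = NA_real_,
                       slope_treated = NA_real_, interaction_F = NA_real_,
                       interaction_p = NA_real_, df_num = NA_integer_,
                       df_den = NA_integer_, n_obs = 0L, evaluable = FALSE,
                       degenerate = NA, note = attr(idx, "reason"))
      }
      list(cls = cls, idx = idx, cmp = cmp)
    }, error = function(e) {
      list(cls = NULL, idx = NULL,
           cmp = tibble::tibble(segment = seg$label, slope_control = NA_real_,
                                slope_treated = NA_real_,
                                interaction_F = NA_real_,
                                interaction_p = NA_real_,
                                df_num = NA_integer_, df_den = NA_integer_,
                                n_obs = 0L, evaluable = FALSE, degenerate = NA,
                                note = conditionMessage(e)))
    })
    if (!is.null(res$cls)) {
      cls_list[[s]] <- tibble::tibble(segment = seg$label, res$cls)
      gene_sets[[seg$label]] <- attr(res$idx, "gene_sets")
      rescale[[seg$label]] <- attr(res$idx, "rescale")
    }
    idx_list[[s]] <- res$idx
    cmp_list[[s]] <- res$cmp
  }
  structure(
    list(
      classification = dplyr::bind_rows(cls_list),
      index = dplyr::bind_rows(idx_list),
      slopes = dplyr::bind_rows(cmp_list),
      gene_sets = gene_sets,
      rescale = rescale,
      alpha = config$alpha,
      scale = config$ancova_scale,
      control_arm = control_arm,
      treated_arm = treated_arm
    ),
    class = "devindex_result"
  )
}

#' @export
print.devindex_result <- function(x, ...) {
  cat("Segmented developmental index (", x$scale, " ANCOVA, alpha = ",
      x$alpha, ")\n", sep = "")
  df <- as.data.frame(x$slopes[, c("segment", "slope_control", "slope_treated",
                                   "interaction_F", "interaction_p",
                                   "evaluable")])
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Monte-Carlo interaction-test study over simulated datasets
#'
#' Repeatedly simulates a preset study, quantifies it, runs the full pipeline
#' and collects the per-segment ANCOVA interaction p-values. Used to measure
#' the null calibration (preset `"null"`) and the delay detection power
#' (preset `"withdrawal_delay"`).
#'
#' @param preset_name Passed to [preset()].
#' @param n_sims Number of simulated datasets.
#' @param seed Base seed; per-simulation seeds are drawn once from a stream
#'   seeded with it, so different base seeds give disjoint studies.
#' @param ... Further design overrides passed to [preset()].
#' @return A tibble with columns `sim`, `segment`, `interaction_p`,
#'   `evaluable`, `degenerate`.
#' @export
mc_interaction_rates <- function(preset_name = c("null", "withdrawal_delay"),
                                 n_sims = 1000, seed = 0, ...) {
  preset_name <- match.arg(preset_name)
  sim_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_sims))
  out <- vector("list", n_sims)
  config <- NULL
  for (i in seq_len(n_sims)) {
    truth <- preset(preset_name, seed = sim_seeds[i], ...)
    if (is.null(config)) {
      config <- panel_config(genes = truth$gene_specs$gene,
                             housekeeping_gene = truth$housekeeping_gene)
    }
    cq <- simulate_cq_table(truth)
    fc <- compute_fold_change(compute_dcq(cq, config), config)
    res <- suppressWarnings(run_devindex_pipeline(fc, config))
    sl <- res$slopes
    out[[i]] <- tibble::tibble(sim = i, segment = sl$segment,
                               interaction_p = sl$interaction_p,
                               evaluable = sl$evaluable,
                               degenerate = sl$degenerate)
  }
  dplyr::bind_rows(out)
}
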