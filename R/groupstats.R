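# Group-comparison machinery: two-way factorial ANOVA with Type II sums of
# squares, Benjamini-Hochberg adjustment, Welch post-hoc contrasts by stratum,
# and percent-change reporting.

#' Two-way factorial ANOVA
#'
#' F-tests for both main effects and their interaction, using Type II sums of
#' squares so unbalanced designs (unequal replicate counts) are handled; on
#' balanced designs this coincides with the classical two-way decomposition.
#' Term p-values are Benjamini-Hochberg adjusted within the model.
#'
#' @param data A data frame of observations.
#' @param response,factor_a,factor_b Column names (character).
#' @return A tibble with one row per term (plus residuals): `term`, `df`,
#'   `sum_sq`, `statistic`, `p`, `p_adj`. Attributes `n_obs` and `design`
#'   record the layout.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("(%s=%s, %s=%s)", factor_a, rownames(cells)[empty[, 1]],
                       factor_b, colnames(cells)[empty[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  d <- data.frame(y = y, A = A, B = B)
  fit <- stats::lm(y ~ A * B, data = d,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals")
  rss <- stats::deviance(fit)
  tss <- sum((y - mean(y))^2)
  tol <- 1e-12 * (tss + .Machine$double.eps)
  if (rss <= tol) {
    # zero residual variance: car::Anova refuses the fit, so take the Type II
    # sums of squares from nested least-squares fits and report each term's
    # F as 0 (no signal) or Inf (signal) instead of dividing by zero
    dev <- function(form) stats::deviance(stats::lm(form, data = d))
    ss <- c(dev(y ~ B) - dev(y ~ A + B), dev(y ~ A) - dev(y ~ A + B),
            dev(y ~ A + B) - rss, rss)
    nl <- c(nlevels(A), nlevels(B))
    df <- c(nl[1] - 1, nl[2] - 1, prod(nl - 1), nrow(d) - prod(nl))
    f <- c(ifelse(ss[1:3] <= tol, 0, Inf), NA_real_)
    p <- c(ifelse(ss[1:3] <= tol, 1, 0), NA_real_)
  } else {
    tab <- car::Anova(fit, type = 2)
    ss <- tab[["Sum Sq"]]
    df <- tab[["Df"]]
    f <- tab[["F value"]]
    p <- tab[["Pr(>F)"]]
  }
  out <- tibble::tibble(term = terms, df = as.integer(df), sum_sq = ss,
                        statistic = f, p = p,
                        p_adj = c(bh_adjust(p[seq_len(3)]), NA_real_))
  attr(out, "n_obs") <- nrow(d)
  attr(out, "design") <- list(levels_a = levels(A), levels_b = levels(B),
                              cells = cells)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorted ascending, the i-th smallest p-value becomes `p * m / i`, the
#' cumulative minimum is enforced from the largest rank down, values are
#' capped at 1, and results return in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-stratum Welch contrasts with BH adjustment across strata
#'
#' Within each stratum (for example, each day), compares the two treatment
#' arms with a Welch two-sample t-test; adjusted p-values apply the
#' Benjamini-Hochberg correction across the strata of the family.
#'
#' @param data A data frame of observations.
#' @param response,arm_factor,stratum_factor Column names (character).
#' @param reference Arm whose mean is subtracted in the contrast estimate
#'   (default: first level alphabetically).
#' @return A tibble with columns `stratum`, `contrast`, `estimate`,
#'   `statistic`, `df`, `p`, `p_adj`.
#' @export
posthoc_by_stratum <- function(data, response, arm_factor, stratum_factor,
                               reference = NULL) {
  strata <- sort(unique(data[[stratum_factor]]))
  rows <- lapply(strata, function(s) {
    sub <- data[data[[stratum_factor]] == s, ]
    arms <- sort(unique(as.character(sub[[arm_factor]])))
    if (length(arms) != 2) {
      warning("stratum ", s, " skipped: needs exactly 2 arms, has ",
              length(arms), call. = FALSE)
      return(NULL)
    }
    ref <- if (is.null(reference)) arms[1] else reference
    if (!ref %in% arms) stop("reference arm '", ref, "' absent in stratum ",
                             s, call. = FALSE)
    other <- setdiff(arms, ref)
    y_ref <- sub[[response]][sub[[arm_factor]] == ref]
    y_oth <- sub[[response]][sub[[arm_factor]] == other]
    tt <- stats::t.test(y_oth, y_ref)
    tibble::tibble(stratum = s, contrast = paste(other, "-", ref),
                   estimate = mean(y_oth) - mean(y_ref),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no stratum with two arms", call. = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Percent change between arms
#'
#' Reporting convenience: `100 * (mean(arm_a) / mean(arm_b) - 1)` for one gene
#' at one day, so a halving reads as -50 and a doubling as +100.
#'
#' @param expr An expression table.
#' @param gene,div Gene and day to report.
#' @param arm_a,arm_b Treatment labels (numerator and denominator arms).
#' @return The percent change (scalar).
#' @export
percent_change <- function(expr, gene, div, arm_a = "ALLO", arm_b = "DMSO") {
  sel <- expr$gene == gene & expr$div == div & !is.na(expr$value)
  ya <- expr$value[sel & expr$treatment == arm_a]
  yb <- expr$value[sel & expr$treatment == arm_b]
  if (length(ya) == 0 || length(yb) == 0) {
    stop("both arms need measurements for ", gene, " at DIV", div,
         call. = FALSE)
  }
  mb <- mean(yb)
  if (mb == 0) stop("denominator arm mean is zero", call. = FALSE)
  100 * (mean(ya) / mb - 1)
}
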