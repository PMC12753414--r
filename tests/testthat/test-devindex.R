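test_that("segment trend classification matches the frozen correlation oracle", {
  div <- rep(c(26, 55), each = 3)
  y <- c(0.9, 1.0, 1.1, 1.9, 2.0, 2.1)
  cls <- classify_segment_genes(make_trend_expr(div, y), seg1())
  # frozen from oracle_pearson before the build
  expect_equal(cls$r, 0.9869275424, tolerance = 1e-9)
  expect_equal(cls$p, 2.552167e-4, tolerance = 1e-5)
  expect_identical(cls$direction, "up")
  # sign symmetry: same values decreasing in time
  cls_dn <- classify_segment_genes(make_trend_expr(div, rev(y)), seg1())
  expect_equal(cls_dn$r, -cls$r, tolerance = 1e-12)
  expect_equal(cls_dn$p, cls$p, tolerance = 1e-12)
  expect_identical(cls_dn$direction, "down")
})

test_that("degenerate genes are ns: zero variance, or too few observations", {
  const <- classify_segment_genes(make_trend_expr(rep(c(26, 55), each = 3),
                                                  rep(1.5, 6)), seg1())
  expect_identical(const$direction, "ns")
  expect_true(is.na(const$r))
  expect_warning(
    few <- classify_segment_genes(make_trend_expr(c(26, 55), c(1, 2)), seg1()),
    "lack of observations"
  )
  expect_identical(few$direction, "ns")
  expect_error(classify_segment_genes(make_trend_expr(138, 1), seg1()),
               "no control-arm data")
})

test_that("classification always equals the sign rule applied to (r, p)", {
  for (s in 1:25) {
    set.seed(s)
    div <- rep(c(26, 40, 55), each = 2)
    expr <- do.call(rbind, lapply(sprintf("G%d", 1:6), function(g) {
      make_trend_expr(div, rnorm(6, mean = runif(1, -0.1, 0.1) * div), gene = g)
    }))
    cls <- classify_segment_genes(expr, seg1(), alpha = 0.05)
    expected <- ifelse(is.na(cls$r) | cls$p >= 0.05, "ns",
                       ifelse(cls$r > 0, "up", "down"))
    expect_identical(cls$direction, expected)
  }
})

test_that("index is the stated up/down ratio of rescaled expression", {
  cls <- make_cls(up = c("U1", "U2"), down = c("D1", "D2"))
  # control arm sets the rescaling constants (means 1, 2, 1, 4)
  expr <- rbind(
    make_expr(gene = c("U1", "U2", "D1", "D2"), value = c(0.5, 1, 0.5, 2),
              div = 26, treatment = "DMSO"),
    make_expr(gene = c("U1", "U2", "D1", "D2"), value = c(1.5, 3, 1.5, 6),
              div = 55, treatment = "DMSO"),
    # target sample: rescaled up {2, 2}, rescaled down {0.5, 0.5}
    make_expr(gene = c("U1", "U2", "D1", "D2"), value = c(2, 4, 0.5, 2),
              div = 40, treatment = "ALLO")
  )
  idx <- compute_index(expr, cls, arm = "ALLO")
  expect_equal(idx$index, 4.0)
  # all rescaled values equal -> index 1
  even <- make_expr(gene = c("U1", "U2", "D1", "D2"), value = c(1, 2, 1, 4),
                    div = 40, treatment = "ALLO")
  expect_equal(compute_index(rbind(expr[expr$treatment == "DMSO", ], even),
                             cls, arm = "ALLO")$index, 1.0)
  # control sample sitting at the gene-wise segment means -> index 1
  at_mean <- compute_index(rbind(expr[expr$treatment == "DMSO", ],
                                 make_expr(gene = c("U1", "U2", "D1", "D2"),
                                           value = c(1, 2, 1, 4), div = 40,
                                           treatment = "DMSO", replicate = 9L)),
                           cls, arm = "DMSO")
  expect_equal(at_mean$index[at_mean$div == 40], 1.0)
})

test_that("index swaps to its reciprocal under set relabelling and ignores per-gene scale", {
  set.seed(99)
  genes <- c("U1", "U2", "U3", "D1", "D2")
  expr <- do.call(rbind, lapply(c(26, 40, 55), function(d) {
    do.call(rbind, lapply(1:3, function(r) {
      make_expr(gene = genes, value = exp(rnorm(5, 0, 0.4)), div = d,
                replicate = r, treatment = "DMSO")
    }))
  }))
  cls <- make_cls(up = c("U1", "U2", "U3"), down = c("D1", "D2"))
  swapped <- make_cls(up = c("D1", "D2"), down = c("U1", "U2", "U3"))
  i1 <- compute_index(expr, cls, arm = "DMSO")
  i2 <- compute_index(expr, swapped, arm = "DMSO")
  expect_equal(i2$index, 1 / i1$index, tolerance = 1e-12)
  # multiplying every value of one gene by a positive constant changes nothing
  scaled <- expr
  scaled$value[scaled$gene == "U2"] <- scaled$value[scaled$gene == "U2"] * 7.3
  i3 <- compute_index(scaled, cls, arm = "DMSO")
  expect_equal(i3$index, i1$index, tolerance = 1e-12)
})

test_that("empty gene sets flag the segment non-evaluable", {
  cls <- make_cls(up = c("U1", "U2"), down = character(0))
  expr <- make_expr(gene = c("U1", "U2"), value = c(1, 2), treatment = "DMSO")
  expect_warning(idx <- compute_index(expr, cls, arm = "DMSO"),
                 "non-evaluable")
  expect_identical(nrow(idx), 0L)
  expect_false(attr(idx, "evaluable"))
})

test_that("segment slopes are ordinary least squares on index vs day", {
  series <- tibble::tibble(
    sample_id = paste0("s", 1:6), treatment = "DMSO",
    div = rep(c(26, 55), each = 3), replicate = rep(1:3, 2),
    segment = "DIV26-DIV55",
    index = c(1, 1, 1, 2, 2, 2)
  )
  expect_equal(fit_segment_slopes(series, "DMSO", scale = "linear"), 1 / 29)
  series$index <- rep(1.4, 6)
  expect_equal(fit_segment_slopes(series, "DMSO", scale = "linear"), 0)
  series$index <- c(1.0, 1.2, 1.1, 1.9, 2.1, 2.0)
  # frozen from brute-force normal equations: slope = 0.9 / 29
  expect_equal(fit_segment_slopes(series, "DMSO", scale = "linear"), 0.9 / 29)
  one_day <- series[series$div == 26, ]
  expect_error(fit_segment_slopes(one_day, "DMSO", scale = "linear"),
               "fewer than 2 distinct days")
})

test_that("ANCOVA reports no interaction for row-identical arms", {
  set.seed(4)
  base <- c(1.0, 1.1, 0.9, 2.0, 2.2, 1.8)
  series <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    treatment = rep(c("DMSO", "ALLO"), each = 6),
    div = rep(rep(c(26, 55), each = 3), 2), replicate = rep(1:3, 4),
    segment = "DIV26-DIV55", index = c(base, base)
  )
  cmp <- compare_slopes_ancova(series)
  expect_true(cmp$evaluable)
  expect_equal(cmp$interaction_F, 0, tolerance = 1e-20)
  expect_equal(cmp$interaction_p, 1)
  expect_equal(cmp$slope_control, cmp$slope_treated)
})

test_that("zero residual variance with distinct slopes is flagged, not divided by", {
  series <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    treatment = rep(c("DMSO", "ALLO"), each = 6),
    div = rep(rep(c(26, 55), each = 3), 2), replicate = rep(1:3, 4),
    segment = "DIV26-DIV55",
    index = c(1, 1, 1, 2, 2, 2,        # slope 1/29
              1, 1, 1, 1.5, 1.5, 1.5)  # slope 0.5/29
  )
  cmp <- compare_slopes_ancova(series, scale = "linear")
  expect_true(cmp$degenerate)
  expect_identical(cmp$interaction_p, 0)
  expect_equal(cmp$slope_control, 1 / 29)
  expect_equal(cmp$slope_treated, 0.5 / 29)
})

test_that("pipeline ANCOVA matches an independent design-matrix oracle", {
  truth <- preset("withdrawal_delay", seed = 0)
  cfg <- panel_config(genes = truth$gene_specs$gene)
  fc <- compute_fold_change(compute_dcq(simulate_cq_table(truth), cfg), cfg)
  res <- run_devindex_pipeline(fc, cfg)
  idx <- res$index[res$index$segment == "DIV55-DIV78", ]
  expect_identical(nrow(idx), 12L)
  cmp <- res$slopes[res$slopes$segment == "DIV55-DIV78", ]
  orc <- oracle_interaction_F(idx$div,
                              factor(idx$treatment,
                                     levels = c("DMSO", "ALLO")),
                              log2(idx$index))
  expect_equal(cmp$interaction_F, orc$F, tolerance = 1e-8)
  expect_equal(cmp$interaction_p, orc$p, tolerance = 1e-8)
})

test_that("pipeline returns one evaluable comparison per segment", {
  truth <- preset("null", seed = 0)
  cfg <- panel_config(genes = truth$gene_specs$gene)
  fc <- compute_fold_change(compute_dcq(simulate_cq_table(truth), cfg), cfg)
  res <- run_devindex_pipeline(fc, cfg)
  expect_identical(nrow(res$slopes), 4L)
  expect_true(all(res$slopes$evaluable))
  expect_identical(res$slopes$segment, default_segments()$label)
  expect_identical(sort(unique(res$classification$segment)),
                   sort(default_segments()$label))
})

test_that("with zero noise the delay is detected exactly in its window", {
  truth <- preset("withdrawal_delay", noise_sd = 0, seed = 0)
  cfg <- panel_config(genes = truth$gene_specs$gene)
  fc <- compute_fold_change(compute_dcq(simulate_cq_table(truth), cfg), cfg)
  res <- run_devindex_pipeline(fc, cfg)
  detected <- res$slopes$interaction_p < 0.05
  expect_identical(detected, c(FALSE, TRUE, TRUE, FALSE))
  # outside the delay window arms share the maturation rate exactly
  expect_equal(res$slopes$slope_control[1], res$slopes$slope_treated[1])
  expect_equal(res$slopes$slope_control[4], res$slopes$slope_treated[4])
})

test_that("a segment that cannot form both gene sets does not stop the others", {
  # panel with only rising genes: down-set is empty in every segment
  specs <- gene_trends(c("U1", "U2", "U3"), baseline_dcq = c(10, 11, 12),
                       slope = c(-0.08, -0.08, -0.08))
  truth <- synthetic_truth(specs, sim_design(seed = 6))
  cfg <- panel_config(genes = specs$gene)
  fc <- compute_fold_change(compute_dcq(simulate_cq_table(truth), cfg), cfg)
  res <- suppressWarnings(run_devindex_pipeline(fc, cfg))
  expect_identical(nrow(res$slopes), 4L)
  expect_true(all(!res$slopes$evaluable))
  expect_true(all(grepl("down-regulated gene set", res$slopes$note)))
})

test_that("day-mean index level is available as a configured option", {
  truth <- preset("null", seed = 13, divs = c(0, 26, 40, 55),
                  n_reps = 3)
  segs <- tibble::tibble(label = "DIV26-DIV55", start_div = 26, end_div = 55)
  cfg <- panel_config(genes = truth$gene_specs$gene, segments = segs,
                      index_level = "day_mean")
  fc <- compute_fold_change(compute_dcq(simulate_cq_table(truth), cfg), cfg)
  res <- run_devindex_pipeline(fc, cfg)
  # 3 days x 2 arms of day means -> 6 observations in the ANCOVA
  expect_identical(res$slopes$n_obs, 6L)
  expect_true(res$slopes$evaluable)
})
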