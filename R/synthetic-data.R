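# Synthetic Cq-table generator: per-gene monotone maturation trends, replicate
# noise on the delta-Cq scale, and a treatment-arm maturation delay confined to
# a post-withdrawal window, with the ground truth retained for recovery tests.

#' Per-gene maturation trend specifications
#'
#' Builds the table of latent linear trends used by [simulate_cq_table()].
#' Each gene's expected delta-Cq (Cq relative to the housekeeping gene) is
#' `baseline_dcq + slope * clock`, where `clock` is the maturation clock in
#' days (see [maturation_clock()]). A negative slope means expression rises
#' as the culture matures (Cq falls).
#'
#' @param gene Character vector of unique gene identifiers.
#' @param baseline_dcq Numeric, delta-Cq at day 0 (cycles).
#' @param slope Numeric, cycles of delta-Cq per maturation day. A slope of
#'   exactly 0 marks the gene as flat.
#' @return A tibble with columns `gene`, `baseline_dcq`, `slope`, `flat`.
#' @export
gene_trends <- function(gene, baseline_dcq, slope) {
  if (!is.character(gene) || anyDuplicated(gene) > 0) {
    stop("`gene` must be a character vector without duplicates", call. = FALSE)
  }
  if (!all(is.finite(baseline_dcq)) || !all(is.finite(slope))) {
    stop("`baseline_dcq` and `slope` must be finite", call. = FALSE)
  }
  tibble::tibble(
    gene = gene,
    baseline_dcq = as.numeric(baseline_dcq),
    slope = as.numeric(slope),
    flat = slope == 0
  )
}

#' Simulation design for a two-arm organoid time course
#'
#' Encodes the study layout the generator emulates: assay days, replicates per
#' arm per day, the treatment exposure window, the post-withdrawal delay
#' window, the delay fraction, and the Cq noise level.
#'
#' @param divs Strictly increasing assay days (days in vitro).
#' @param n_reps Replicates per arm per day (at least 2).
#' @param rep_override Optional named integer vector overriding `n_reps` for
#'   specific days, e.g. `c("138" = 6)` for late-time-point imbalance.
#' @param exposure_window Two days `c(day_on, day_off)` bounding treatment
#'   exposure; the maturation delay of the treated arm starts at `day_off`.
#' @param recovery_div Day at which the treated arm's maturation rate has
#'   recovered; after it the accumulated delay persists as a constant offset.
#' @param delta Delay fraction in `[0, 1]`: inside the delay window the treated
#'   arm matures at rate `1 - delta` relative to the control arm.
#' @param noise_sd Standard deviation of replicate noise on the delta-Cq
#'   (log2-expression) scale, in cycles.
#' @param housekeeping_cq Housekeeping-gene Cq, constant by default.
#' @param housekeeping_sd Optional Gaussian noise on the housekeeping Cq
#'   (cycles); 0 keeps delta-Cq noise single-sourced.
#' @param max_cq Run length in cycles; simulated Cq values are clipped here and
#'   clipped values flagged not-detected.
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(divs = c(0, 26, 55, 78, 95, 138),
                       n_reps = 3,
                       rep_override = NULL,
                       exposure_window = c(28, 67),
                       recovery_div = 95,
                       delta = 0,
                       noise_sd = 0.3,
                       housekeeping_cq = 20,
                       housekeeping_sd = 0,
                       max_cq = 40,
                       seed = NULL) {
  if (any(divs < 0) || is.unsorted(divs, strictly = TRUE)) {
    stop("`divs` must be non-negative and strictly increasing", call. = FALSE)
  }
  if (n_reps < 2) stop("`n_reps` must be at least 2", call. = FALSE)
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0 || housekeeping_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (length(exposure_window) != 2 ||
      !(exposure_window[1] < exposure_window[2] &&
        exposure_window[2] < recovery_div)) {
    stop("need day_on < day_off < recovery_div", call. = FALSE)
  }
  if (!is.null(rep_override)) {
    if (is.null(names(rep_override)) ||
        !all(names(rep_override) %in% as.character(divs))) {
      stop("`rep_override` must be named by assay day", call. = FALSE)
    }
    if (any(rep_override < 2)) stop("replicate overrides must be >= 2", call. = FALSE)
  }
  structure(
    list(
      divs = as.numeric(divs), n_reps = as.integer(n_reps),
      rep_override = rep_override,
      exposure_window = as.numeric(exposure_window),
      recovery_div = as.numeric(recovery_div),
      delay_window = c(exposure_window[2], recovery_div),
      delta = as.numeric(delta), noise_sd = as.numeric(noise_sd),
      housekeeping_cq = as.numeric(housekeeping_cq),
      housekeeping_sd = as.numeric(housekeeping_sd),
      max_cq = as.numeric(max_cq),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' Latent maturation clock
#'
#' Maps calendar day to maturation-units per arm. The control clock is the
#' identity. The treated clock equals the control clock up to treatment
#' withdrawal (`day_off`), advances at rate `1 - delta` between withdrawal and
#' `recovery_div`, and thereafter advances at the control rate so the
#' accumulated delay persists as a constant offset.
#'
#' @param day Non-negative day(s) in vitro.
#' @param arm `"control"` or `"treated"`.
#' @param design A [sim_design()] object.
#' @return Numeric maturation-units, same length as `day`.
#' @export
maturation_clock <- function(day, arm = c("control", "treated"), design) {
  arm <- match.arg(arm)
  if (any(day < 0)) stop("`day` must be non-negative", call. = FALSE)
  day <- as.numeric(day)
  if (arm == "control") return(day)
  off <- design$exposure_window[2]
  rec <- design$recovery_div
  d <- design$delta
  at_rec <- off + (1 - d) * (rec - off)
  ifelse(day <= off, day,
         ifelse(day <= rec, off + (1 - d) * (day - off),
                at_rec + (day - rec)))
}

#' Ground-truth container for a simulated study
#'
#' Bundles the gene trend panel with the simulation design and records the
#' arm-by-day maturation clock, so downstream recovery tests can compare
#' estimated quantities against their generative values.
#'
#' @param gene_specs A [gene_trends()] tibble.
#' @param design A [sim_design()] object.
#' @param housekeeping_gene Housekeeping gene identifier; must not appear in
#'   `gene_specs`.
#' @param organoid_type Organoid-type label carried into the sample metadata.
#' @param treatment_labels Named character vector mapping the `control` and
#'   `treated` arms to treatment labels in the emitted table.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(gene_specs, design,
                            housekeeping_gene = "GAPDH",
                            organoid_type = "VCO",
                            treatment_labels = c(control = "DMSO",
                                                 treated = "ALLO")) {
  stopifnot(inherits(design, "sim_design"))
  if (!all(c("gene", "baseline_dcq", "slope", "flat") %in% names(gene_specs))) {
    stop("`gene_specs` must come from gene_trends()", call. = FALSE)
  }
  if (!identical(gene_specs$flat, gene_specs$slope == 0)) {
    stop("`flat` must hold exactly when slope == 0", call. = FALSE)
  }
  if (housekeeping_gene %in% gene_specs$gene) {
    stop("housekeeping gene must not be part of the trend panel", call. = FALSE)
  }
  if (!all(c("control", "treated") %in% names(treatment_labels))) {
    stop("`treatment_labels` needs entries 'control' and 'treated'", call. = FALSE)
  }
  clock <- do.call(rbind, lapply(c("control", "treated"), function(a) {
    data.frame(arm = a, div = design$divs,
               clock = maturation_clock(design$divs, a, design))
  }))
  structure(
    list(gene_specs = gene_specs, design = design,
         housekeeping_gene = housekeeping_gene,
         organoid_type = organoid_type,
         treatment_labels = treatment_labels,
         maturation_clock = tibble::as_tibble(clock)),
    class = "synthetic_truth"
  )
}

replicates_for_div <- function(design, div) {
  ov <- design$rep_override
  if (!is.null(ov) && as.character(div) %in% names(ov)) {
    as.integer(ov[[as.character(div)]])
  } else {
    design$n_reps
  }
}

#' Simulate a replicate-level Cq table
#'
#' Draws one row per (arm, day, replicate, gene), housekeeping gene included.
#' Gene delta-Cq is `baseline_dcq + slope * clock(day, arm)` plus Gaussian
#' noise; the gene Cq is the sample's housekeeping Cq plus that delta-Cq.
#' Cq values are clipped to the run length and clipped rows are flagged
#' not-detected (`nd`). With the design seed set, output is fully
#' deterministic.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A tibble with columns `sample_id`, `organoid_type`, `treatment`,
#'   `div`, `replicate`, `gene`, `cq`, `nd`.
#' @export
simulate_cq_table <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  des <- truth$design
  draw <- function() {
    arms <- c("control", "treated")
    samples <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(des$divs, function(d) {
        n <- replicates_for_div(des, d)
        data.frame(arm = a, treatment = unname(truth$treatment_labels[[a]]),
                   div = d, replicate = seq_len(n))
      }))
    }))
    samples$sample_id <- sprintf("%s_%s_DIV%03d_R%d", truth$organoid_type,
                                 samples$treatment, samples$div,
                                 samples$replicate)
    samples$clock <- ifelse(samples$arm == "control",
                            maturation_clock(samples$div, "control", des),
                            maturation_clock(samples$div, "treated", des))
    ns <- nrow(samples)
    hk_cq <- des$housekeeping_cq + rnorm(ns, 0, des$housekeeping_sd)

    gs <- truth$gene_specs
    ng <- nrow(gs)
    si <- rep(seq_len(ns), each = ng)
    gi <- rep(seq_len(ng), times = ns)
    dcq <- gs$baseline_dcq[gi] + gs$slope[gi] * samples$clock[si] +
      rnorm(ns * ng, 0, des$noise_sd)
    cq_raw <- hk_cq[si] + dcq
    gene_rows <- data.frame(
      sample_id = samples$sample_id[si],
      organoid_type = truth$organoid_type,
      treatment = samples$treatment[si],
      div = samples$div[si],
      replicate = samples$replicate[si],
      gene = gs$gene[gi],
      cq = pmin(cq_raw, des$max_cq),
      nd = cq_raw >= des$max_cq
    )
    hk_rows <- data.frame(
      sample_id = samples$sample_id,
      organoid_type = truth$organoid_type,
      treatment = samples$treatment,
      div = samples$div,
      replicate = samples$replicate,
      gene = truth$housekeeping_gene,
      cq = pmin(hk_cq, des$max_cq),
      nd = hk_cq >= des$max_cq
    )
    out <- rbind(gene_rows, hk_rows)
    if (any(out$cq <= 0)) {
      stop("simulated Cq values fell at or below 0; check baselines and slopes",
           call. = FALSE)
    }
    out <- out[order(out$treatment, out$div, out$replicate, out$gene), ]
    rownames(out) <- NULL
    tibble::as_tibble(out)
  }
  if (!is.null(des$seed)) withr::with_seed(des$seed, draw()) else draw()
}

# 23-transcript neuronal-development panel: 13 rising markers of neuronal
# differentiation/maturation, 8 falling progenitor/proliferation markers,
# 2 flat steroidogenic enzymes. Slopes are homogeneous within each set so the
# log2 developmental index is exactly linear in the maturation clock and
# segment-level ground truth stays closed-form.
default_panel <- function() {
  up <- c(DCX = 13, MAP2 = 12, RBFOX3 = 14, TUBB3 = 10, SYP = 12.5,
          NEFL = 11.5, CALB2 = 13.5, SST = 15, GAD1 = 12, GAD2 = 12.5,
          LHX6 = 11, NR2F2 = 10.5, GFAP = 13)
  down <- c(PCNA = 4, MKI67 = 5, SOX2 = 3.5, NES = 4.5, VIM = 3,
            ASCL1 = 6, TTF1 = 7, HES1 = 5.5)
  flat <- c(AKR1C2 = 8, AKR1C3 = 9)
  gene_trends(
    gene = c(names(up), names(down), names(flat)),
    baseline_dcq = c(unname(up), unname(down), unname(flat)),
    slope = c(rep(-0.08, length(up)), rep(0.06, length(down)),
              rep(0, length(flat)))
  )
}

#' Preset study conditions
#'
#' Returns a ready-made [synthetic_truth()] describing the default organoid
#' study: a 23-transcript developmental panel plus housekeeping gene, days 0,
#' 26, 55, 78, 95, 138, three replicates per arm per day, exposure over days
#' 28-67, and replicate noise of 0.3 cycles. `"null"` sets the delay fraction
#' to 0 (arms exchangeable); `"withdrawal_delay"` sets it to 0.5 over the
#' delay window (days 67-95).
#'
#' @param name `"null"` or `"withdrawal_delay"`.
#' @param ... Overrides forwarded to [sim_design()] (for example `seed`,
#'   `noise_sd`, `rep_override`).
#' @return A `synthetic_truth` object.
#' @export
preset <- function(name = c("null", "withdrawal_delay"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  if (is.null(dots$delta)) {
    dots$delta <- switch(name, null = 0, withdrawal_delay = 0.5)
  }
  synthetic_truth(default_panel(), do.call(sim_design, dots))
}
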