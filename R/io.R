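# File formats and run provenance: the long-format Cq CSV dialect, generator
# truth files, and run manifests with file digests.

#' Read a long-format Cq CSV file
#'
#' One measurement per row; header required; UTF-8, comma-separated; days are
#' integers and Cq values use a decimal point. Not-detected cells may be
#' empty or the literal `ND`. An optional logical `nd` column (written by
#' [write_cq_csv()]) marks measurements clipped at the run length.
#'
#' @param path Path to the CSV file.
#' @param max_cq Run length; Cq values must lie in `(0, max_cq]`.
#' @return A validated Cq tibble (see [simulate_cq_table()] for the columns).
#' @export
read_cq_csv <- function(path, max_cq = 40) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  needed <- c("sample_id", "organoid_type", "treatment", "div", "replicate",
              "gene", "cq")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("Cq CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cq_chr <- trimws(raw$cq)
  is_nd <- cq_chr == "" | toupper(cq_chr) == "ND"
  cq <- suppressWarnings(as.numeric(cq_chr))
  bad_num <- which(!is_nd & is.na(cq))
  if (length(bad_num)) {
    stop("unparseable Cq value at data row(s): ",
         paste(utils::head(bad_num, 10), collapse = ", "), call. = FALSE)
  }
  cq[is_nd] <- NA_real_
  nd <- if ("nd" %in% names(raw)) {
    as.logical(raw$nd) | is_nd
  } else {
    is_nd
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    organoid_type = raw$organoid_type,
    treatment = raw$treatment,
    div = as.integer(raw$div),
    replicate = as.integer(raw$replicate),
    gene = raw$gene,
    cq = cq,
    nd = nd
  )
  validate_cq_table(out, max_cq = max_cq)
  out
}

#' Write a Cq table as long-format CSV
#'
#' Missing Cq values are written as the literal `ND`.
#'
#' @param cq A Cq tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_csv <- function(cq, path) {
  readr::write_csv(cq, path, na = "ND", progress = FALSE)
  invisible(path)
}

#' Write a derived table as CSV
#'
#' @param x A tibble (expression table, classification, index series, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write generator ground truth as a YAML text file
#'
#' Records every generator parameter (panel trends, design, seed) so a run can
#' be reproduced bit-identically and recovery tests can read back the truth.
#'
#' @param truth A [synthetic_truth()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  des <- truth$design
  obj <- list(
    gene_specs = lapply(seq_len(nrow(truth$gene_specs)), function(i) {
      list(gene = truth$gene_specs$gene[i],
           baseline_dcq = truth$gene_specs$baseline_dcq[i],
           slope = truth$gene_specs$slope[i])
    }),
    design = list(
      divs = des$divs, n_reps = des$n_reps,
      rep_override = as.list(des$rep_override),
      exposure_window = des$exposure_window,
      recovery_div = des$recovery_div, delta = des$delta,
      noise_sd = des$noise_sd, housekeeping_cq = des$housekeeping_cq,
      housekeeping_sd = des$housekeeping_sd, max_cq = des$max_cq,
      seed = des$seed
    ),
    housekeeping_gene = truth$housekeeping_gene,
    organoid_type = truth$organoid_type,
    treatment_labels = as.list(truth$treatment_labels)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read generator ground truth back from YAML
#'
#' @param path Path written by [write_truth_yaml()].
#' @return A [synthetic_truth()] object.
#' @export
read_truth_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- gene_trends(
    gene = vapply(obj$gene_specs, `[[`, character(1), "gene"),
    baseline_dcq = vapply(obj$gene_specs, `[[`, numeric(1), "baseline_dcq"),
    slope = vapply(obj$gene_specs, `[[`, numeric(1), "slope")
  )
  d <- obj$design
  rep_override <- if (length(d$rep_override)) {
    stats::setNames(as.integer(unlist(d$rep_override)),
                    names(d$rep_override))
  } else NULL
  des <- sim_design(
    divs = unlist(d$divs), n_reps = d$n_reps, rep_override = rep_override,
    exposure_window = unlist(d$exposure_window),
    recovery_div = d$recovery_div, delta = d$delta, noise_sd = d$noise_sd,
    housekeeping_cq = d$housekeeping_cq, housekeeping_sd = d$housekeeping_sd,
    max_cq = d$max_cq, seed = d$seed
  )
  synthetic_truth(specs, des, housekeeping_gene = obj$housekeeping_gene,
                  organoid_type = obj$organoid_type,
                  treatment_labels = unlist(obj$treatment_labels))
}

#' Write a run manifest
#'
#' A YAML record of the package version, the seed, a parameter snapshot, the
#' MD5 digest of every output file, and per-stage status. Timestamps are
#' omitted by default so deterministic stages reproduce their manifests
#' bit-identically.
#'
#' @param path Manifest output path.
#' @param outputs Character vector of output file paths to digest.
#' @param params Named list: configuration snapshot.
#' @param seed Integer seed(s) used, if any.
#' @param stages Named character vector of per-stage status, if any.
#' @param include_timestamp Record the wall-clock time (breaks bit-identical
#'   reproduction; off by default).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, outputs, params = list(), seed = NULL,
                               stages = NULL, include_timestamp = FALSE) {
  digests <- lapply(outputs, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  obj <- list(
    package = "devindexr",
    version = as.character(utils::packageVersion("devindexr")),
    seed = seed,
    params = params,
    outputs = digests,
    stages = as.list(stages)
  )
  if (include_timestamp) obj$timestamp <- format(Sys.time(), tz = "UTC")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest path.
#' @return The manifest as a list.
#' @export
read_run_manifest <- function(path) {
  yaml::read_yaml(path)
}
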