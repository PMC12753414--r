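# In-code fixtures for small deterministic tables.

# Cq table from parallel vectors, defaults filled in.
make_cq <- function(gene, cq, div = 26, replicate = 1L, treatment = "DMSO",
                    organoid_type = "VCO", nd = is.na(cq)) {
  n <- max(length(gene), length(cq), length(div), length(replicate),
           length(treatment))
  out <- tibble::tibble(
    organoid_type = rep_len(organoid_type, n),
    treatment = rep_len(treatment, n),
    div = rep_len(div, n),
    replicate = rep_len(as.integer(replicate), n),
    gene = rep_len(gene, n),
    cq = rep_len(cq, n),
    nd = rep_len(nd, n)
  )
  out$sample_id <- sprintf("%s_%s_DIV%03d_R%d", out$organoid_type,
                           out$treatment, out$div, out$replicate)
  out[, c("sample_id", "organoid_type", "treatment", "div", "replicate",
          "gene", "cq", "nd")]
}

# Expression table from parallel vectors.
make_expr <- function(gene, value, div = 26, replicate = 1L,
                      treatment = "DMSO", value_kind = "fold_change",
                      organoid_type = "VCO") {
  n <- max(length(gene), length(value), length(div), length(replicate),
           length(treatment))
  out <- tibble::tibble(
    organoid_type = rep_len(organoid_type, n),
    treatment = rep_len(treatment, n),
    div = rep_len(div, n),
    replicate = rep_len(as.integer(replicate), n),
    gene = rep_len(gene, n),
    value = rep_len(value, n),
    value_kind = rep_len(value_kind, n)
  )
  out$sample_id <- sprintf("%s_%s_DIV%03d_R%d", out$organoid_type,
                           out$treatment, out$div, out$replicate)
  out[, c("sample_id", "organoid_type", "treatment", "div", "replicate",
          "gene", "value", "value_kind")]
}

# Gene classification object with the attributes compute_index() expects.
make_cls <- function(up, down, start_div = 26, end_div = 55,
                     label = "DIV26-DIV55") {
  genes <- c(up, down)
  out <- tibble::tibble(gene = genes, n_obs = 6L,
                        r = c(rep(1, length(up)), rep(-1, length(down))),
                        p = 0,
                        direction = c(rep("up", length(up)),
                                      rep("down", length(down))))
  attr(out, "segment") <- list(label = label, start_div = start_div,
                               end_div = end_div)
  attr(out, "alpha") <- 0.05
  out
}

# One-gene control-arm fold-change table from day/log2fc vectors.
make_trend_expr <- function(div, log2fc, gene = "G1", treatment = "DMSO") {
  reps <- stats::ave(seq_along(div), div, FUN = seq_along)
  make_expr(gene = gene, value = 2^log2fc, div = div, replicate = reps,
            treatment = treatment)
}

seg1 <- function() list(label = "DIV26-DIV55", start_div = 26, end_div = 55)
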