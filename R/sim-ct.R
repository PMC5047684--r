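#' Generate a synthetic qPCR threshold-cycle (C_T) table
#'
#' Builds a long-format C_T table with planted expression offsets: each
#' gene's planted effect is its -dCT relative to the reference gene, so
#' `C_T(gene) = C_T(reference) - effect` before noise.
#'
#' @param genes Character vector of gene names.
#' @param samples Character vector of sample names.
#' @param reference_gene Housekeeping gene; must be among `genes`.
#' @param effect_map Named numeric vector of planted -dCT values per gene;
#'   genes not named get 0.  The reference gene's effect is always 0.
#' @param reference_ct Baseline C_T of the reference gene.
#' @param noise_sd Gaussian C_T noise SD (cycles).
#' @param seed Integer seed.
#' @return Tibble `sample`, `gene`, `ct`, with the planted effects in the
#'   `planted_neg_delta_ct` attribute.
#' @export
generate_ct_table <- function(genes, samples, reference_gene,
                              effect_map = NULL, reference_ct = 20,
                              noise_sd = 0, seed = 1L) {
  if (!reference_gene %in% genes) {
    abort("reference_gene must be among genes",
          class = "myospark_input_error")
  }
  if (anyDuplicated(genes) || anyDuplicated(samples)) {
    abort("duplicate gene or sample names", class = "myospark_input_error")
  }
  eff <- setNames(rep(0, length(genes)), genes)
  if (!is.null(effect_map)) eff[names(effect_map)] <- effect_map
  eff[reference_gene] <- 0
  withr::with_seed(as.integer(seed), {
    tab <- tidyr::expand_grid(sample = samples, gene = genes)
    tab$ct <- reference_ct - eff[tab$gene] +
      if (noise_sd > 0) rnorm(nrow(tab), 0, noise_sd) else 0
    tab <- as_tibble(tab)
    attr(tab, "planted_neg_delta_ct") <- eff
    tab
  })
}
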