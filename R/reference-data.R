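#' Reference sex-specific pig linkage-map lengths
#'
#' Published per-chromosome autosomal linkage-map lengths (cM) for five
#' commercial pig breeds (Landrace, Duroc, Large White, Pietrain and a
#' synthetic line), by sex, together with physical chromosome lengths (Mb)
#' and SNP counts. Useful as a realistic parameterisation target for the
#' simulator and for internal-consistency checks (per-chromosome lengths
#' summing to genome totals).
#'
#' @return data.frame with columns `chrom`, `mb`, `n_snps` and one column
#'   per breed/sex combination (`lr_m`, `lr_f`, ..., `sy_f`) of map length
#'   in cM.
#' @examples
#' ref <- referenceMapLengths()
#' colSums(ref[, c("lr_m", "lw_f")])  # genome totals, cM
#' @export
referenceMapLengths <- function() {
  utils::read.delim(system.file("extdata", "pig_linkage_map_lengths.tsv",
                                package = "xoverscan"),
                    stringsAsFactors = FALSE)
}
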