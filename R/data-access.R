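#' Expression constructs of the two Abp1p SH3 domains
#'
#' The his-tagged constructs of the Saccharomyces cerevisiae (AbpSC) and
#' Batrachochytrium dendrobatidis (AbpBD) Abp1p SH3 domains, shipped as a
#' FASTA file. The S. cerevisiae construct carries 4 lysines against 8
#' aspartates and 9 glutamates, i.e. a net charge of -13 including the tag
#' region - the charge asymmetry that drives the domain's salt-sensitive
#' folding.
#'
#' @return Tibble with columns `id`, `sequence` (ids "AbpSC", "AbpBD").
#' @export
#' @examples
#' seqs <- abp_constructs()
#' net_charge(seqs$sequence[seqs$id == "AbpSC"])
abp_constructs <- function() {
  path <- system.file("extdata", "abp_sh3_constructs.fasta",
                      package = "saltfold", mustWork = TRUE)
  out <- read_fasta_tbl(path)
  out$id <- sub(" .*", "", out$id)
  out
}
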