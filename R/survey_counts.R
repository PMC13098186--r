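#' Published survey summary counts shipped with the package
#'
#' Two small tables of headline counts from a published large-scale
#' survey of CA genes across public genomes and metagenomes, used to
#' recompute its printed percentages from raw counts:
#' `presence` (genomes with at least one CA per stratum and class) and
#' `alignment_filtering` (per-class representative counts before the
#' fragment/metal-binding filter and the number removed).
#'
#' @return A list of two data.frames, `presence` and
#'   `alignment_filtering`.
#' @export
survey_counts <- function() {
  pres <- read_tsv(system.file("extdata", "survey_presence_counts.tsv",
                               package = "cacensus", mustWork = TRUE))
  aln <- read_tsv(system.file("extdata", "survey_alignment_counts.tsv",
                              package = "cacensus", mustWork = TRUE))
  list(presence = pres, alignment_filtering = aln)
}
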