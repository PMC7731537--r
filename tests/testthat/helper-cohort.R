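# Run the correction -> MPE -> precursor-normalization chain on a generated
# cohort and join the recovered anaplerotic fractions to the truth table.
recover_cohort <- function(cohort, tracer_name = "u13c5",
                           fragments = NULL) {
  if (is.null(fragments)) {
    fragments <- read_fragment_catalog()
    fragments <- fragments[unique(cohort$intensities$metabolite)]
  }
  corrected <- correct_intensity_table(cohort$intensities, fragments)
  rel <- normalize_to_precursor(corrected$mpe, cohort$plasma_enrichment)
  rel <- recover_anaplerotic_fraction(rel, tracer_name)
  merge(rel, cohort$truth, by = c("sample_id", "metabolite"))
}
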