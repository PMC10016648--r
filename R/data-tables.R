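#' Published Orthoptera species summary table
#'
#' Loads the bundled species-level summary of a published flow-cytometric
#' genome-size survey of 50 Orthoptera species (families Acrididae,
#' Gryllidae, Tetrigidae, Tettigoniidae): per-species female and male mean 1C
#' genome sizes (pg), species-mean GC content (percent), and the male
#' karyotype. `male_2n` is the autosome-count group label used for the
#' chromosome-number analyses (the number before "+X0"/"+XY");
#' `congeneric_2n` marks karyotypes known only from a congeneric species.
#'
#' @return data.frame with columns species, family, n_female, n_male,
#'   c1_female_pg, c1_male_pg, gc_percent, karyotype, male_2n, sex_system,
#'   congeneric_2n.
#' @export
orthoptera_species_table <- function() {
  path <- system.file("extdata", "orthoptera_species_table.csv",
                      package = "gsflow", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$male_2n <- as.integer(sub("\\+.*$", "", tab$karyotype))
  tab$sex_system <- ifelse(grepl("XY$", tab$karyotype), "XX_XY", "XX_X0")
  tab$congeneric_2n <- grepl("\\*$", tab$karyotype)
  tab
}
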