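# fixtures are built in code; the only stored files are the transcribed
# published summary tables under inst/extdata

extdata <- function(name) system.file("extdata", name, package = "riskspectra")

read_table3 <- function() {
  suppressMessages(read_literature_counts(extdata("disease_literature_counts.tsv")))
}

read_table2 <- function() {
  readr::read_tsv(extdata("disease_mira_counts.tsv"), show_col_types = FALSE)
}

read_table1 <- function() {
  readr::read_tsv(extdata("platform_selected_counts.tsv"), show_col_types = FALSE)
}

# small hand-made association tibble
make_assoc <- function(freqs, disease = "d", snp_prefix = "rs") {
  tibble::tibble(
    disease = disease,
    snp_id = paste0(snp_prefix, seq_along(freqs)),
    risk_allele_freq = freqs,
    sample_size = NA_real_,
    p_value = NA_real_
  )
}

quiet <- function(expr) suppressMessages(expr)
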