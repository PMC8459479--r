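# Shared helpers for building small inputs in code.

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

random_protein <- function(n, seed) {
  set.seed(seed)
  protein_sequence(sprintf("rand%d", seed),
                   paste(sample(amino_acids(), n, replace = TRUE),
                         collapse = ""))
}
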