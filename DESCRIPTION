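Package: sonifyseq
Title: Parameter-Mapping Sonification of Protein Sequences and Alignments
Version: 1.0.0
Authors@R: person("sonifyseq", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts protein sequences (FASTA) and protein multiple
    sequence alignments (aligned FASTA) into note-event streams and
    standard MIDI files using five parameter-mapping sonification
    algorithms: per-residue pitch from the Goldman-Engelman-Steitz (GES)
    hydrophobicity scale, a four-group reduced amino-acid alphabet mapped
    to a pentatonic pitch set, a combined pitch-plus-instrument mapping,
    per-column Shannon entropy of an alignment standardised to a pitch
    profile, and a polyphonic per-column rendering with residue counts
    mapped to note velocity.  Includes seed-deterministic synthetic-data
    generators (tandem-repeat proteins, conserved-domain alignments), a
    Sonic Pi code emitter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
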