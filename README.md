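# sonifyseq

Parameter-mapping sonification of protein sequences and multiple sequence
alignments (MSAs) in R: FASTA in, note events, standard MIDI files or
Sonic Pi code out.

Sonification renders data as non-speech sound. For protein sequences it
offers a complementary channel to visual inspection — repeated motifs
become audible rhythms, conserved alignment blocks become quiet or
low-pitched passages — and it is of particular interest for visually
impaired scientists. `sonifyseq` implements five parameter-mapping
algorithms that map residue/column position to time (one note-slot per
position) and data features to pitch, timbre and loudness:

| Algorithm | Input | Mapping |
|---|---|---|
| I `sonify_hydrophobicity()` | protein sequence | GES hydrophobicity score → pitch (F=50 … R=77), sine voice |
| II `sonify_reduced()` | protein sequence | 4-group reduced alphabet → pentatonic pitches 67/64/62/60 |
| III `sonify_combined()` | protein sequence | GES pitch + group instrument (piano/sine/pluck/tb303) |
| IV `sonify_msa_entropy()` | MSA | column Shannon entropy, z-scored to pitch, saw voice |
| V `sonify_msa_hydrophobicity()` | MSA | polyphonic GES pitches; velocity grows with residue count; gaps silent |

**The core statistics.** Algorithm IV computes, per alignment column *i*,
the Shannon entropy over the symbols present (gap `-` included),

&nbsp;&nbsp;&nbsp;&nbsp;H<sub>i</sub> = −Σ<sub>j</sub> p<sub>j</sub> log₂ p<sub>j</sub>,&nbsp;&nbsp; p<sub>j</sub> = count(j)/n<sub>rows</sub>,

then standardises the profile to MIDI pitch with an affine z-score
transform centred on middle C,

&nbsp;&nbsp;&nbsp;&nbsp;H*<sub>i</sub> = (H<sub>i</sub> − H̄)/s<sub>H</sub> · 10 + 60,

taking the floor and clamping into [0, 127] (s<sub>H</sub> is the sample
standard deviation, n−1 divisor, over all column entropies). Algorithms
I/III/V use a fixed residue→pitch table derived from the
Goldman–Engelman–Steitz hydrophobicity scale, anchored at phenylalanine =
MIDI 50 with each subsequent residue's pitch raised by the (rounded-up)
score increment — see `ges_scale()` and the methods vignette for the one
documented irregularity at glutamine.

## Worked example

```r
library(sonifyseq)

seq <- protein_sequence("demo", "MFRKDE")
track <- sonify_hydrophobicity(seq)
track
#> SonificationTrack [Algorithm I] 'demo': 6 events over 6 slots (0.25 s/slot)
track$events
#>   onset duration pitch velocity voice source_position source_symbol
#> 1     0        1    51      100  sine               1             M
#> 2     1        1    50      100  sine               2             F
#> 3     2        1    77      100  sine               3             R
#> 4     3        1    72      100  sine               4             K
#> 5     4        1    73      100  sine               5             D
#> 6     5        1    71      100  sine               6             E
```

Each residue occupies one 0.25 s slot; hydrophobic residues (F, M) sit
low around MIDI 50–51, hydrophilic ones (R, K, D, E) high around 71–77,
so this sequence sweeps sharply upward after the second note.
`write_midi(track, "demo.mid")` renders it to a standard MIDI file;
`emit_sonic_pi(track, "demo.rb")` emits the equivalent Sonic Pi program.

For alignments:

```r
aln <- make_domain_msa(n_seqs = 5, n_cols = 40, seed = 42)
mp  <- entropy_to_midi(entropy_profile(aln))
mean(mp$pre_floor)  #> 60   (exactly, by construction)
sd(mp$pre_floor)    #> 10
head(mp$pitches, 10)
#> [1] 70 67 70 48 48 48 48 48 55 70
```

Columns 4–8 fall inside a conserved domain of the synthetic alignment:
their entropy is near zero, so they sound low (pitch 48) against the
variable background (67–70).

## Command line

```sh
SONIFY=$(Rscript -e 'cat(system.file("cli", "sonify.R", package = "sonifyseq"))')
Rscript "$SONIFY" fixtures repeat-protein --seed 1 --out repeat.fasta
Rscript "$SONIFY" protein hydro repeat.fasta --out repeat.mid
Rscript "$SONIFY" msa entropy aln.fasta --format events --out profile.tsv
```

Subcommands: `protein {hydro|reduced|combined}`, `msa {entropy|hydro}`,
`fixtures {repeat-protein|domain-msa}`; common flags `--out`, `--format
{midi,sonicpi,events}`, `--note-duration`, `--invert-polarity`,
`--residue-policy {strict,permissive}`, `--record`, `--config`, `--seed`.

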