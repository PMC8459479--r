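---
title: "Methods: how sonifyseq maps sequences and alignments to sound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sonifyseq maps sequences and alignments to sound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonifyseq)
```

`sonifyseq` is a parameter-mapping sonifier: a data feature is wired to a
sound-synthesis parameter, and position in the sequence or alignment is
wired to time. Every algorithm emits one *note-slot* per residue or
column (default 0.25 s per slot), so the listener's clock is also a
sequence coordinate. This vignette explains each mapping, the tunable
parameters, the synthetic-data generators, and the numerical and design
choices that were genuinely open.

## The GES pitch scale (Algorithms I, III, V)

The Goldman–Engelman–Steitz (GES) scale scores amino-acid hydrophobicity
from energetic considerations of residues in α-helices; it orders the 20
residues linearly from phenylalanine (score −3.7, most hydrophobic) to
arginine (+12.3, most hydrophilic). The pitch mapping anchors F at MIDI
note 50 and gives each subsequent residue the previous residue's pitch
plus the score increment, rounded **up** to the nearest integer — the
rounding direction also guarantees a one-to-one mapping when increments
are small. The result spans 50–77, a deliberately narrow band that keeps
melodic patterns easy to follow.

```{r}
ges_scale()
```

One cell of the published table is irregular: glutamine (Q) is printed
as 66 although the rule gives `ceiling(65 + 1.1) = 67`; the rows after Q
continue from 66. `ges_scale()` ships the printed table verbatim — the
published artefact is the canon, and "fixing" Q would silently transpose
every sonification of Q-containing sequences. The construction rule is
still available as `derive_scale_from_scores()`, which applies the
cumulative ceiling rule to any complete 20-residue score set (with a +1
bump on ties to preserve injectivity). Applied to the GES scores it
reproduces the printed table row-by-row at 19 of 20 residues, Q being
the sole, documented exception; because the cumulative form re-anchors
each step on its *own* previous output, its pitches after Q sit one
semitone above the printed ones. Tests pin both behaviours.

## The reduced alphabet (Algorithms II, III)

Four hydrophobicity groups partition the alphabet — FILVWY, ACGMP, KQST,
DEHNR — and are mapped to the first four notes of a C-major pentatonic
scale (67, 64, 62, 60). The pentatonic choice means any group sequence
sounds consonant; the trade-off is a four-level contour instead of a
20-level one. Algorithm III keeps the 20-level GES pitch but moves the
group information into timbre: piano, sine, pluck and tb303 synthesiser
voices respectively. Voice labels are abstract strings at this layer;
their General-MIDI realisation is a rendering decision (below).

## Column entropy (Algorithm IV)

Per column $i$ of an alignment with $n$ rows, the Shannon entropy over
the symbols present (the gap `-` counts as an ordinary symbol) is

$$H_i = -\sum_{j} p_j \log_2 p_j, \qquad p_j = \tilde n_j / n,$$

so $H_i = 0$ for a perfectly conserved column and $H_i \le \log_2 n$.
Counting gaps as symbols is deliberate: a column that is half gaps is
genuinely heterogeneous and should not sound conserved. The profile is
then standardised to pitch by

$$H^*_i = \frac{H_i - \bar H}{s_H}\cdot 10 + 60,$$

with $\bar H$ and $s_H$ the mean and *sample* standard deviation (n−1
divisor, $n$ = number of columns) of all column entropies, floored to an
integer. Centring on 60 puts the profile around middle C; the factor 10
gives roughly a ±2-octave spread at ±2 SD. By construction the pre-floor
values have mean exactly 60 and sample SD exactly 10 for any
non-degenerate profile — the acceptance suite asserts this to 1e−9.

Numerical choices the transform itself does not settle:

* **Degenerate profiles** ($s_H = 0$: perfectly conserved alignment, or
  a single column). All pitches are set to 60 — zero spread means zero
  deviation from the centre.
* **Clamping.** The "listenable range" is taken as the full MIDI range:
  floored values are clamped into [0, 127]. The clamp can only engage
  beyond |z| = 6, which no realistic profile reaches; it is a guard, not
  a design feature.
* **Floor** is mathematical floor (toward −∞), applied after the affine
  transform and before clamping.

## Polyphonic alignment hydrophobicity (Algorithm V)

Each column sounds all of its distinct non-gap residues simultaneously
at their GES pitches on a saw voice; the velocity of each note grows
with the number of rows carrying that residue, and gaps are silent (an
all-gap column is a rest). The source describes the volume rule only
qualitatively ("increases" with count), so the functional form is this
package's choice: linear in the *fraction* of rows,

$$v = \operatorname{round}\!\big(v_\min + \tfrac{c}{n}\,(v_\max - v_\min)\big),$$

defaults $v_\min = 30$, $v_\max = 127$. Fraction-of-rows (rather than raw
count) keeps alignments of different depth comparable: a full consensus
is always maximally loud, a singleton residue in a five-row alignment is
quiet but audible. Velocity is strictly increasing in the count for any
alignment with at most 97 rows (one velocity step per row); both bounds
are configurable through `sonify_params()`.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `note_duration` | 0.25 | s/slot | 240 notes/min: fast enough to hear motifs as rhythm, slow enough to track position. No canonical rate exists; listener feedback on the original design asked for speed control, so it is a first-class knob. |
| `velocity` | 100 | MIDI 1–127 | Constant loudness for Algorithms I–IV, where volume is not a data channel. |
| `v_min`, `v_max` | 30, 127 | MIDI | Velocity range for Algorithm V's count scaling. |
| `invert_polarity` | FALSE | — | Reflects the pitch axis (scale reflection for the discrete maps, z-negation for entropy), answering the "which way is up?" preference some listeners have. Default polarity: hydrophilic/variable = high. |
| `programs` | sine→79, saw→81, piano→0, pluck→45, tb303→87 | GM program | Sonic Pi synth names have no General-MIDI identity; these are the closest common timbres and are presentation-layer only. |

Residue policy: `strict` (default) admits only the 20 standard codes and
fails loudly, naming the offending character and 1-based position;
`permissive` admits `X B Z U O *`, which have no hydrophobicity score and
therefore occupy a **silent slot** — onsets of later residues are never
shifted, keeping the position→time mapping faithful.

## Rendering

MIDI output is a format-1 Standard MIDI File: a conductor track (120 BPM,
480 ticks per quarter) plus one track/channel per distinct voice, with
note-on velocity equal to event velocity and notes starting exactly on
slot boundaries (the MIDI realisation of a zero-attack envelope). The
fixed tempo/resolution makes output byte-identical across runs — the
tests assert this, and an independently written SMF parser (test helper,
sharing no code with the writer) verifies round-trip fidelity of pitch,
velocity and onset order. The Sonic Pi emitter mirrors the original
code-generation pipeline: per slot, `use_synth`/`play` statements (synth
= voice label, `amp` = velocity/127, `attack: 0`) followed by one
`sleep` of a note duration; it targets functional equivalence, not
textual identity with any existing script.

## Synthetic data: what it emulates and what it does not

`make_repeat_protein()` reproduces the geometry of the motif-listening
task: default 253 residues of uniform background with a random 8-residue
motif planted in 4 adjacent copies at a uniformly chosen position.
`make_domain_msa()` reproduces the conserved-domain task: default 5
rows × 200 columns with three non-overlapping domains (each under 50
columns, placed proportionally at ~10%, 38% and 75% of the width with
lengths ~15%, 22% and 12%), modelled as a per-column consensus residue
with i.i.d. substitution noise (default rate 0.05), uniform background
elsewhere, and gaps outside domains at a default rate of 0.1 (0 vs 0.3
is used in tests to emulate compact vs gappy alignments of the same
structure). Both generators are seed-deterministic and their outputs
always pass strict validation.

What the generators do **not** emulate: real substitution processes
(no BLOSUM-like exchange structure), phylogenetic correlation between
rows, alignment-program gap placement, or the identity of any real
protein or Pfam domain. A green test on these fixtures therefore
establishes that the *mappings* behave as specified on inputs with the
stated geometry — not that any biological signal detection threshold is
met.

## Known limitations

* Nucleotide input, Stockholm/Clustal/PHYLIP formats and alignment
  construction are out of scope; inputs must already be aligned FASTA.
* Entropy is unweighted and uncorrected: no sequence weighting, no
  background-frequency (relative) entropy, no gap-exclusion variant.
* Audio is not synthesised; rendering stops at MIDI and Sonic Pi code.
* MIDI capacity caps a track at 16 distinct voices (one channel each);
  the five algorithms use at most four.
* The entropy pitch profile is alignment-relative (z-scored), so pitches
  are not comparable across different alignments — only within one.
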