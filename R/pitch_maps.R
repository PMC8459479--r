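# Residue -> pitch mappings: the GES hydrophobicity scale and the
# four-group reduced alphabet.

# Canonical GES table: residues ordered most hydrophobic (F) to most
# hydrophilic (R); score is the GES hydrophobicity score, increment the
# score difference from the predecessor, midi_pitch the published MIDI
# note number.  The printed table is authoritative (see note on Q in
# derive_scale_from_scores()).
.ges_table <- data.frame(
  residue = c("F", "M", "I", "L", "V", "C", "W", "A", "T", "G",
              "S", "P", "Y", "H", "Q", "N", "E", "K", "D", "R"),
  name = c("Phenylalanine", "Methionine", "Isoleucine", "Leucine",
           "Valine", "Cysteine", "Tryptophan", "Alanine", "Threonine",
           "Glycine", "Serine", "Proline", "Tyrosine", "Histidine",
           "Glutamine", "Asparagine", "Glutamate", "Lysine",
           "Aspartate", "Arginine"),
  ges_score = c(-3.7, -3.4, -3.1, -2.8, -2.6, -2.0, -1.9, -1.6, -1.2,
                -1.0, -0.6, 0.2, 0.7, 3.0, 4.1, 4.8, 8.2, 8.8, 9.2, 12.3),
  increment = c(NA, 0.3, 0.3, 0.3, 0.2, 0.6, 0.1, 0.3, 0.4, 0.2,
                0.4, 0.8, 0.5, 2.3, 1.1, 0.7, 3.4, 0.6, 0.4, 3.1),
  midi_pitch = c(50L, 51L, 52L, 53L, 54L, 55L, 56L, 57L, 58L, 59L,
                 60L, 61L, 62L, 65L, 66L, 67L, 71L, 72L, 73L, 77L),
  stringsAsFactors = FALSE)

.new_pitch_scale <- function(df) {
  stopifnot(nrow(df) == 20L, !anyDuplicated(df$residue),
            !anyDuplicated(df$midi_pitch),
            all(df$midi_pitch >= 0L), all(df$midi_pitch <= 127L))
  structure(df, class = c("PitchScale", "data.frame"))
}

#' The canonical GES hydrophobicity pitch scale
#'
#' Maps each of the 20 amino acids to an integer MIDI note number derived
#' from the Goldman-Engelman-Steitz (GES) hydrophobicity scale.
#' Phenylalanine, the most hydrophobic residue, sits at MIDI 50; pitches
#' rise with hydrophilicity up to arginine at 77, so a one-to-one,
#' order-preserving mapping over a deliberately narrow (just over two
#' octave-free) pitch band.
#'
#' @return A `PitchScale`: a data frame with columns `residue`, `name`,
#'   `ges_score`, `increment` (score difference from the predecessor in
#'   the hydrophobicity ordering) and `midi_pitch`, ordered from most
#'   hydrophobic to most hydrophilic.
#' @examples
#' ges_scale()
#' ges_pitch("F")  # 50
#' @export
ges_scale <- function() .new_pitch_scale(.ges_table)

#' Look up GES pitches for residues
#'
#' @param residues Character vector of single-letter residue codes.
#' @param scale A `PitchScale`; defaults to [ges_scale()].
#' @return Integer MIDI pitches; `NA` for codes absent from the scale
#'   (e.g. ambiguity codes admitted under the permissive policy).
#' @export
ges_pitch <- function(residues, scale = ges_scale()) {
  scale$midi_pitch[match(residues, scale$residue)]
}

#' Derive a pitch scale from hydrophobicity scores
#'
#' Implements the published construction rule: order residues by score,
#' anchor the most hydrophobic at `start_pitch`, and give each subsequent
#' residue the previous residue's pitch plus the score increment, rounded
#' up (ceiling) to the nearest integer.  If two residues tie (increment
#' 0 would repeat a pitch) the later one is bumped by +1 to preserve the
#' one-to-one mapping.
#'
#' Applied to the GES scores, the rule reproduces the published table at
#' 19 of 20 residues when checked row by row; the published glutamine (Q)
#' pitch of 66 disagrees with ceiling(65 + 1.1) = 67.  The table ships
#' unchanged as the canonical mapping ([ges_scale()]); this function
#' documents and verifies the rule, it does not redefine the canon.
#'
#' @param scores Named numeric vector: residue code -> hydrophobicity
#'   score, covering all 20 standard residues, with distinct scores.
#' @param start_pitch MIDI pitch for the lowest-scoring (most
#'   hydrophobic) residue.
#' @return A `PitchScale` (column `name` omitted when scores are custom).
#' @export
derive_scale_from_scores <- function(scores, start_pitch = 50L) {
  aa <- amino_acids()
  if (is.null(names(scores)) || !setequal(names(scores), aa)) {
    stop("`scores` must be named with exactly the 20 standard residues",
         call. = FALSE)
  }
  ord <- order(scores)
  res <- names(scores)[ord]
  sc <- unname(scores[ord])
  inc <- c(NA, diff(sc))
  pitch <- integer(20L)
  pitch[1L] <- as.integer(start_pitch)
  for (k in 2L:20L) {
    p <- as.integer(ceiling(pitch[k - 1L] + inc[k]))
    if (p <= pitch[k - 1L]) p <- pitch[k - 1L] + 1L  # injectivity bump
    pitch[k] <- p
  }
  if (any(pitch < 0L) || any(pitch > 127L)) {
    stop("derived pitches leave the MIDI range [0, 127]", call. = FALSE)
  }
  .new_pitch_scale(data.frame(
    residue = res, name = NA_character_, ges_score = sc,
    increment = inc, midi_pitch = pitch, stringsAsFactors = FALSE))
}

# Reduced alphabet: four hydrophobicity groups on the first four notes of
# a C major pentatonic scale (G4, E4, D4, C4), each with its own synth.
.reduced_groups <- data.frame(
  group = c("FILVWY", "ACGMP", "KQST", "DEHNR"),
  midi_pitch = c(67L, 64L, 62L, 60L),
  instrument = c("piano", "sine", "pluck", "tb303"),
  stringsAsFactors = FALSE)

#' The reduced amino-acid alphabet
#'
#' Partitions the 20 amino acids into four hydrophobicity groups, each
#' with a fixed MIDI pitch (first four notes of a C major pentatonic
#' scale) and an instrument label used by the combined algorithm:
#' FILVWY -> 67/piano, ACGMP -> 64/sine, KQST -> 62/pluck,
#' DEHNR -> 60/tb303.
#'
#' @return Data frame with columns `group`, `midi_pitch`, `instrument`.
#' @export
reduced_alphabet <- function() .reduced_groups

.reduced_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- .reduced_groups
      res <- unlist(strsplit(g$group, "", fixed = TRUE))
      idx <- rep(seq_len(nrow(g)), nchar(g$group))
      tab <<- data.frame(residue = res,
                         midi_pitch = g$midi_pitch[idx],
                         instrument = g$instrument[idx],
                         stringsAsFactors = FALSE)
    }
    tab
  }
})

#' Reduced-alphabet group pitch of residues
#'
#' @param residues Character vector of single-letter residue codes.
#' @return Integer MIDI pitch of the group containing each residue
#'   (one of 67, 64, 62, 60).  Unknown residues raise an error.
#' @export
reduced_pitch <- function(residues) {
  tab <- .reduced_lookup()
  i <- match(residues, tab$residue)
  if (anyNA(i)) {
    stop(sprintf("residue '%s' is not in the reduced alphabet",
                 residues[which(is.na(i))[1L]]), call. = FALSE)
  }
  tab$midi_pitch[i]
}

#' Reduced-alphabet instrument of residues
#'
#' @inheritParams reduced_pitch
#' @return Instrument label per residue: `"piano"` (FILVWY), `"sine"`
#'   (ACGMP), `"pluck"` (KQST) or `"tb303"` (DEHNR).
#' @export
reduced_instrument <- function(residues) {
  tab <- .reduced_lookup()
  i <- match(residues, tab$residue)
  if (anyNA(i)) {
    stop(sprintf("residue '%s' is not in the reduced alphabet",
                 residues[which(is.na(i))[1L]]), call. = FALSE)
  }
  tab$instrument[i]
}

#' Export the GES pitch scale as CSV
#'
#' Writes the canonical residue/score/increment/pitch table to a CSV
#' file.  The same table ships with the package under
#' `inst/extdata/ges_scale.csv`.
#'
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ges_csv <- function(path) {
  utils::write.csv(as.data.frame(ges_scale()), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
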