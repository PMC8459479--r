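# The five sonification algorithms.  Each maps a sequence or alignment
# to a SonificationTrack: residue/column position -> time (one note-slot
# per position), with pitch, velocity and voice carrying the data.

#' Sonification run parameters
#'
#' @param note_duration Seconds per note-slot (one slot per residue or
#'   column).  Default 0.25 s, i.e. 240 notes per minute.
#' @param velocity Constant MIDI velocity (1-127) for the algorithms that
#'   do not use volume as a data channel (I-IV).
#' @param invert_polarity If `TRUE`, flip the pitch axis: the pitch scale
#'   is reflected about its own range (hydrophobicity algorithms) or the
#'   z-score is negated (entropy algorithm), so high pitch means
#'   hydrophobic/conserved instead of the default polarity.
#' @param v_min,v_max Velocity bounds for the polyphonic alignment
#'   algorithm, where velocity encodes how many rows share a residue.
#' @return A list of class `sonify_params`.
#' @export
sonify_params <- function(note_duration = 0.25, velocity = 100L,
                          invert_polarity = FALSE,
                          v_min = 30L, v_max = 127L) {
  stopifnot(note_duration > 0, velocity >= 1L, velocity <= 127L,
            v_min >= 1L, v_max <= 127L, v_min < v_max)
  structure(list(note_duration = note_duration,
                 velocity = as.integer(velocity),
                 invert_polarity = isTRUE(invert_polarity),
                 v_min = as.integer(v_min), v_max = as.integer(v_max)),
            class = "sonify_params")
}

.empty_events <- function() {
  data.frame(onset = integer(), duration = integer(), pitch = integer(),
             velocity = integer(), voice = character(),
             source_position = integer(), source_symbol = character(),
             stringsAsFactors = FALSE)
}

.new_track <- function(algorithm_id, events, slots_total, input_id,
                       note_duration) {
  events <- events[order(events$onset, events$pitch), , drop = FALSE]
  rownames(events) <- NULL
  stopifnot(all(events$onset >= 0L), all(events$duration >= 1L),
            all(events$pitch >= 0L), all(events$pitch <= 127L),
            all(events$velocity >= 1L), all(events$velocity <= 127L))
  structure(
    list(algorithm_id = algorithm_id, events = events,
         slots_total = as.integer(slots_total), input_id = input_id,
         note_duration_seconds = note_duration),
    class = "SonificationTrack")
}

#' @export
print.SonificationTrack <- function(x, ...) {
  cat(sprintf(
    "SonificationTrack [Algorithm %s] '%s': %d events over %d slots (%.3g s/slot)\n",
    x$algorithm_id, x$input_id, nrow(x$events), x$slots_total,
    x$note_duration_seconds))
  invisible(x)
}

# Reflect pitches about the range of their generating scale
# (polarity inversion for the discrete pitch maps).
.reflect <- function(pitch, scale_pitches) {
  min(scale_pitches) + max(scale_pitches) - pitch
}

# Shared body of the three single-sequence algorithms.  pitch_fn and
# voice_fn map a residue vector to pitches / voice labels; residues
# without a pitch (ambiguity codes under the permissive policy) become
# silent one-slot rests: no event, onset sequence unshifted.
.sonify_sequence <- function(seq, params, algorithm_id, pitch_fn, voice_fn) {
  stopifnot(inherits(seq, "ProteinSequence"),
            inherits(params, "sonify_params"))
  chars <- residue_chars(seq)
  pitch <- pitch_fn(chars)
  sound <- !is.na(pitch)
  n <- sum(sound)
  events <- data.frame(
    onset = which(sound) - 1L,
    duration = rep(1L, n),
    pitch = as.integer(pitch[sound]),
    velocity = rep(params$velocity, n),
    voice = voice_fn(chars[sound]),
    source_position = which(sound),
    source_symbol = chars[sound],
    stringsAsFactors = FALSE)
  .new_track(algorithm_id, events, length(chars), seq$id,
             params$note_duration)
}

#' Algorithm I: single-sequence hydrophobicity sonification
#'
#' One note per residue on a sine voice; pitch is the residue's GES
#' hydrophobicity pitch ([ges_scale()]), so hydrophobic residues sound
#' low and hydrophilic residues high.
#'
#' @param seq A [protein_sequence()].
#' @param params A [sonify_params()].
#' @return A `SonificationTrack`; under the strict policy, exactly one
#'   event per residue.
#' @examples
#' sonify_hydrophobicity(protein_sequence("p", "FR"))
#' @export
sonify_hydrophobicity <- function(seq, params = sonify_params()) {
  scale <- ges_scale()
  pf <- function(ch) {
    p <- ges_pitch(ch, scale)
    if (params$invert_polarity) p <- .reflect(p, scale$midi_pitch)
    p
  }
  .sonify_sequence(seq, params, "I", pf, function(ch) rep("sine", length(ch)))
}

#' Algorithm II: reduced-alphabet sonification
#'
#' One note per residue on a sine voice; pitch is the residue's
#' four-group reduced-alphabet pitch (67, 64, 62 or 60), trading
#' per-residue detail for a simpler four-note contour.
#'
#' @inheritParams sonify_hydrophobicity
#' @return A `SonificationTrack`.
#' @export
sonify_reduced <- function(seq, params = sonify_params()) {
  pf <- function(ch) {
    known <- ch %in% amino_acids()
    p <- rep(NA_integer_, length(ch))
    p[known] <- reduced_pitch(ch[known])
    if (params$invert_polarity) {
      p[known] <- .reflect(p[known], reduced_alphabet()$midi_pitch)
    }
    p
  }
  .sonify_sequence(seq, params, "II", pf, function(ch) rep("sine", length(ch)))
}

#' Algorithm III: combined hydrophobicity pitch and reduced-alphabet timbre
#'
#' Pitch as in Algorithm I (GES scale); the instrument changes with the
#' residue's reduced-alphabet group: FILVWY on piano, ACGMP on sine,
#' KQST on pluck, DEHNR on tb303.
#'
#' @inheritParams sonify_hydrophobicity
#' @return A `SonificationTrack` whose pitch stream equals that of
#'   [sonify_hydrophobicity()] on the same input.
#' @export
sonify_combined <- function(seq, params = sonify_params()) {
  scale <- ges_scale()
  pf <- function(ch) {
    p <- ges_pitch(ch, scale)
    if (params$invert_polarity) p <- .reflect(p, scale$midi_pitch)
    p
  }
  .sonify_sequence(seq, params, "III", pf, reduced_instrument)
}

#' Algorithm IV: alignment entropy sonification
#'
#' Monophonic: one note per alignment column on a saw voice.  Pitch is
#' the column's Shannon entropy standardised over the whole profile
#' ([entropy_to_midi()]): variable columns sound high, conserved columns
#' low, centred on middle C.
#'
#' @param aln An [alignment()].
#' @inheritParams sonify_hydrophobicity
#' @return A `SonificationTrack` with exactly one event per column.
#' @export
sonify_msa_entropy <- function(aln, params = sonify_params()) {
  stopifnot(inherits(aln, "Alignment"), inherits(params, "sonify_params"))
  mp <- entropy_to_midi(entropy_profile(aln),
                        invert = params$invert_polarity)
  events <- data.frame(
    onset = seq_len(aln$n_cols) - 1L,
    duration = 1L,
    pitch = mp$pitches,
    velocity = params$velocity,
    voice = "saw",
    source_position = seq_len(aln$n_cols),
    source_symbol = apply(as.matrix(aln), 2L, paste, collapse = ""),
    stringsAsFactors = FALSE)
  .new_track("IV", events, aln$n_cols, paste(aln$ids, collapse = ","),
             params$note_duration)
}

#' Algorithm V: polyphonic alignment hydrophobicity sonification
#'
#' Every row of the alignment sounds at once on a saw voice, using the
#' GES pitch map.  Per column, each distinct non-gap residue yields one
#' note whose velocity grows with the number of rows carrying that
#' residue: a consensus column is one loud note, a near-gap column a
#' quiet one.  Gaps are silent; an all-gap column emits nothing.
#'
#' Velocity is linear in the fraction of rows sharing the residue:
#' `round(v_min + count / n_rows * (v_max - v_min))`.
#'
#' @inheritParams sonify_msa_entropy
#' @return A `SonificationTrack` with, per column, one event per
#'   distinct sounding residue (events at equal onsets are simultaneous).
#' @export
sonify_msa_hydrophobicity <- function(aln, params = sonify_params()) {
  stopifnot(inherits(aln, "Alignment"), inherits(params, "sonify_params"))
  scale <- ges_scale()
  m <- as.matrix(aln)
  per_col <- lapply(seq_len(aln$n_cols), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    col <- col[!is.na(ges_pitch(col, scale))]  # permissive-policy codes rest
    if (length(col) == 0L) return(.empty_events())
    counts <- table(col)
    res <- names(counts)
    pitch <- ges_pitch(res, scale)
    if (params$invert_polarity) pitch <- .reflect(pitch, scale$midi_pitch)
    vel <- as.integer(round(
      params$v_min +
        as.vector(counts) / aln$n_rows * (params$v_max - params$v_min)))
    data.frame(
      onset = j - 1L, duration = 1L, pitch = as.integer(pitch),
      velocity = vel, voice = "saw", source_position = j,
      source_symbol = res, stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, per_col)
  .new_track("V", events, aln$n_cols, paste(aln$ids, collapse = ","),
             params$note_duration)
}

#' Write a track's events as a plain-text table
#'
#' Tab-separated table with one row per note event: `onset`, `duration`
#' (both in note-slots), `pitch`, `velocity`, `voice`,
#' `source_position` (1-based residue/column index), `source_symbol`.
#'
#' @param track A `SonificationTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(track, path) {
  stopifnot(inherits(track, "SonificationTrack"))
  utils::write.table(track$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
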