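# Serialisation of SonificationTracks: Standard MIDI File (format 1)
# writer and a Sonic Pi code emitter mirroring the original
# code-generation pipeline.

#' Rendering parameters
#'
#' @param programs Named integer vector mapping voice labels to General
#'   MIDI program numbers (0-127).  The Sonic Pi synth names have no GM
#'   identity, so the defaults pick the closest common timbres:
#'   sine -> 79 (ocarina), saw -> 81 (saw lead), piano -> 0, pluck -> 45
#'   (pizzicato strings), tb303 -> 87 (bass+lead).
#' @param tempo_bpm MIDI tempo; fixed metadata, the audible rate is set
#'   by the track's `note_duration_seconds`.
#' @param ppq Ticks per quarter note.
#' @return A list of class `render_params`.
#' @export
render_params <- function(programs = c(sine = 79L, saw = 81L, piano = 0L,
                                       pluck = 45L, tb303 = 87L),
                          tempo_bpm = 120L, ppq = 480L) {
  stopifnot(!is.null(names(programs)), all(programs >= 0L),
            all(programs <= 127L), tempo_bpm > 0L, ppq > 0L)
  structure(list(programs = programs, tempo_bpm = as.integer(tempo_bpm),
                 ppq = as.integer(ppq)),
            class = "render_params")
}

# --- low-level byte helpers -------------------------------------------

.uint_bytes <- function(x, n) {
  out <- raw(n)
  for (i in n:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# MIDI variable-length quantity: 7 bits per byte, high bit set on all
# but the last byte.
.vlq <- function(x) {
  stopifnot(x >= 0)
  groups <- integer(0)
  repeat {
    groups <- c(x %% 128, groups)
    x <- x %/% 128
    if (x == 0) break
  }
  b <- as.integer(groups)
  if (length(b) > 1L) b[-length(b)] <- b[-length(b)] + 128L
  as.raw(b)
}

.midi_chunk <- function(type, body) {
  c(charToRaw(type), .uint_bytes(length(body), 4L), body)
}

# --- writer ------------------------------------------------------------

#' Write a track to a Standard MIDI File
#'
#' Produces a format-1 MIDI file: a conductor track holding tempo and
#' time-signature metadata plus one MIDI track (on its own channel, with
#' its voice's program) per distinct voice label.  Note-on velocity is
#' the event velocity, and notes start exactly on their slot boundary
#' (immediate onset, the MIDI realisation of a zero-attack envelope).
#' Output is deterministic: the same track and parameters give a
#' byte-identical file.
#'
#' @param track A `SonificationTrack`.
#' @param path Output `.mid` path.
#' @param params A [render_params()].
#' @return `path`, invisibly.
#' @export
write_midi <- function(track, path, params = render_params()) {
  stopifnot(inherits(track, "SonificationTrack"),
            inherits(params, "render_params"))
  ev <- track$events
  voices <- unique(ev$voice)
  if (length(voices) > 16L) {
    stop(sprintf("track has %d voices; MIDI supports at most 16 channels",
                 length(voices)), call. = FALSE)
  }
  # seconds -> ticks at the fixed tempo: 1 quarter = 60/bpm seconds
  ticks_per_second <- params$ppq * params$tempo_bpm / 60
  slot_ticks <- max(1L, as.integer(round(
    track$note_duration_seconds * ticks_per_second)))

  voice_tracks <- lapply(seq_along(voices), function(vi) {
    ch <- vi - 1L
    vev <- ev[ev$voice == voices[vi], , drop = FALSE]
    prog <- if (voices[vi] %in% names(params$programs)) {
      params$programs[[voices[vi]]]
    } else 0L
    # absolute-tick message list: note-offs sort before note-ons at the
    # same tick so repeated pitches re-trigger cleanly
    msgs <- rbind(
      data.frame(tick = vev$onset * slot_ticks, ord = 1L,
                 status = 0x90L + ch, d1 = vev$pitch, d2 = vev$velocity),
      data.frame(tick = (vev$onset + vev$duration) * slot_ticks, ord = 0L,
                 status = 0x80L + ch, d1 = vev$pitch, d2 = 0L))
    msgs <- msgs[order(msgs$tick, msgs$ord, msgs$d1), , drop = FALSE]
    body <- c(.vlq(0L), as.raw(0xC0L + ch), as.raw(prog))
    last <- 0L
    for (k in seq_len(nrow(msgs))) {
      body <- c(body, .vlq(msgs$tick[k] - last),
                as.raw(c(msgs$status[k], msgs$d1[k], msgs$d2[k])))
      last <- msgs$tick[k]
    }
    body <- c(body, .vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
    .midi_chunk("MTrk", body)
  })

  usec_per_quarter <- as.integer(round(60e6 / params$tempo_bpm))
  conductor <- .midi_chunk("MTrk", c(
    .vlq(0L), as.raw(c(0xFF, 0x58, 0x04, 0x04, 0x02, 0x18, 0x08)),
    .vlq(0L), as.raw(c(0xFF, 0x51, 0x03)), .uint_bytes(usec_per_quarter, 3L),
    .vlq(0L), as.raw(c(0xFF, 0x2F, 0x00))))

  header <- .midi_chunk("MThd", c(
    .uint_bytes(1L, 2L),                        # format 1
    .uint_bytes(1L + length(voice_tracks), 2L), # n tracks
    .uint_bytes(params$ppq, 2L)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, conductor, unlist(voice_tracks)), con)
  invisible(path)
}

#' Emit Sonic Pi code for a track
#'
#' Writes a Sonic Pi (Ruby-dialect) program that replays the track:
#' per note-slot, a `use_synth`/`play` statement per event (synth name =
#' voice label, amplitude = velocity/127, zero attack) followed by a
#' `sleep` of one note duration.  An empty track yields the header only.
#'
#' @param track A `SonificationTrack`.
#' @param path Output path (conventionally `.rb`).
#' @return `path`, invisibly.
#' @export
emit_sonic_pi <- function(track, path) {
  stopifnot(inherits(track, "SonificationTrack"))
  nd <- format(track$note_duration_seconds, digits = 10)
  lines <- c(
    sprintf("# Sonic Pi sonification (Algorithm %s) of '%s'",
            track$algorithm_id, track$input_id),
    sprintf("# %d events over %d note-slots, %s s per slot",
            nrow(track$events), track$slots_total, nd))
  ev <- track$events
  if (nrow(ev) > 0L) {
    slot_lines <- lapply(0:(track$slots_total - 1L), function(s) {
      here <- ev[ev$onset == s, , drop = FALSE]
      out <- character(0)
      if (nrow(here) > 0L) {
        out <- as.vector(rbind(
          sprintf("use_synth :%s", here$voice),
          sprintf("play %d, amp: %s, sustain: %s, attack: 0",
                  here$pitch,
                  format(round(here$velocity / 127, 4), digits = 4),
                  format(here$duration * track$note_duration_seconds,
                         digits = 10))))
      }
      c(out, sprintf("sleep %s", nd))
    })
    lines <- c(lines, unlist(slot_lines))
  }
  writeLines(lines, path)
  invisible(path)
}
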