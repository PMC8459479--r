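# Independent Standard-MIDI-File reader used as the round-trip oracle.
# Written directly from the SMF byte layout (header chunk, track chunks,
# variable-length deltas, channel/meta/sysex messages) and deliberately
# sharing no code with the package's writer.

parse_midi_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  u8 <- function() {
    b <- as.integer(bytes[pos]); pos <<- pos + 1L; b
  }
  uN <- function(n) {
    v <- 0
    for (i in seq_len(n)) v <- v * 256 + u8()
    v
  }
  vlq <- function() {
    v <- 0
    repeat {
      b <- u8()
      v <- v * 128 + (b %% 128)
      if (b < 128) break
    }
    v
  }
  stopifnot(rawToChar(bytes[1:4]) == "MThd")
  pos <- 5L
  stopifnot(uN(4L) == 6)
  format <- uN(2L)
  ntrks <- uN(2L)
  division <- uN(2L)

  notes <- list()
  programs <- list()
  for (trk in seq_len(ntrks)) {
    stopifnot(rawToChar(bytes[pos:(pos + 3L)]) == "MTrk")
    pos <- pos + 4L
    len <- uN(4L)
    track_end <- pos + len
    tick <- 0
    status <- NA_integer_
    while (pos < track_end) {
      tick <- tick + vlq()
      b <- as.integer(bytes[pos])
      if (b >= 128L) {
        status <- b
        pos <- pos + 1L
      }  # else running status: reuse previous
      hi <- status %/% 16L
      ch <- status %% 16L
      if (status == 0xFF) {
        type <- u8()
        mlen <- vlq()
        pos <- pos + mlen
      } else if (status %in% c(0xF0, 0xF7)) {
        mlen <- vlq()
        pos <- pos + mlen
      } else if (hi %in% c(0x8, 0x9, 0xA, 0xB, 0xE)) {
        d1 <- u8(); d2 <- u8()
        if (hi == 0x9 && d2 > 0L) {
          notes[[length(notes) + 1L]] <-
            data.frame(track = trk, tick = tick, channel = ch,
                       pitch = d1, velocity = d2)
        }
      } else if (hi %in% c(0xC, 0xD)) {
        d1 <- u8()
        if (hi == 0xC) {
          programs[[length(programs) + 1L]] <-
            data.frame(track = trk, channel = ch, program = d1)
        }
      } else {
        stop(sprintf("unexpected status byte 0x%X at offset %d", status, pos))
      }
    }
    pos <- track_end
  }
  notes <- if (length(notes)) do.call(rbind, notes) else
    data.frame(track = integer(), tick = numeric(), channel = integer(),
               pitch = integer(), velocity = integer())
  list(format = format, ntrks = ntrks, division = division,
       notes = notes[order(notes$tick, notes$channel, notes$pitch), ,
                     drop = FALSE],
       programs = if (length(programs)) do.call(rbind, programs) else NULL)
}
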