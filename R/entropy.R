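# Per-column Shannon entropy of an alignment and its standardisation to
# a MIDI pitch profile.

#' Shannon entropy of one alignment column
#'
#' H = -sum(p * log2(p)) over the distinct symbols present in the column,
#' with p = count / column length.  The gap character `-` counts as an
#' ordinary symbol: a gap-rich column is informative about conservation
#' and sounds accordingly.
#'
#' @param column Character vector of single symbols, or one string, over
#'   residues and `-`.
#' @return Entropy in bits: 0 for a perfectly conserved column, at most
#'   log2(length(column)).
#' @examples
#' column_entropy("AAAAA")   # 0
#' column_entropy("ACDEF")   # log2(5)
#' @export
column_entropy <- function(column) {
  if (length(column) == 1L && nchar(column) > 1L) {
    column <- strsplit(column, "", fixed = TRUE)[[1L]]
  }
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  p <- as.vector(table(column)) / length(column)
  -sum(p * log2(p))
}

#' Column-entropy profile of an alignment
#'
#' @param aln An [alignment()].
#' @return An `EntropyProfile`: list with `values` (one entropy in bits
#'   per column, in column order), `mean` and `sd` (sample standard
#'   deviation, n-1 divisor, over the column entropies).
#' @export
entropy_profile <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  m <- as.matrix(aln)
  values <- apply(m, 2L, column_entropy)
  structure(
    list(values = unname(values),
         mean = mean(values),
         sd = stats::sd(values)),
    class = "EntropyProfile")
}

#' @export
print.EntropyProfile <- function(x, ...) {
  cat(sprintf("EntropyProfile: %d columns, mean %.4f bits, sd %.4f\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Standardise an entropy profile to MIDI pitches
#'
#' Applies the affine z-score transform H* = (H - mean(H)) / sd(H) * 10
#' + 60 to each column entropy, then floors to an integer and clamps into
#' the MIDI range \[0, 127\].  Centring on 60 puts the profile around
#' middle C; the factor 10 gives the spread.  A degenerate profile
#' (sd = 0, e.g. a perfectly conserved alignment, or a single column)
#' maps every column to 60.
#'
#' @param profile An `EntropyProfile` from [entropy_profile()].
#' @param invert If `TRUE`, negate the z-score so that high entropy gives
#'   a low pitch (polarity flip).
#' @return A `MidiProfile`: list with `pitches` (integer, one per
#'   column) and `pre_floor` (the real-valued transformed values before
#'   flooring/clamping, retained for testing).
#' @export
entropy_to_midi <- function(profile, invert = FALSE) {
  stopifnot(inherits(profile, "EntropyProfile"))
  h <- profile$values
  if (length(h) < 1L) stop("empty profile", call. = FALSE)
  degenerate <- length(h) == 1L || is.na(profile$sd) || profile$sd == 0
  if (degenerate) {
    pre <- rep(60, length(h))
  } else {
    z <- (h - profile$mean) / profile$sd
    if (invert) z <- -z
    pre <- z * 10 + 60
  }
  pitches <- as.integer(pmin(pmax(floor(pre), 0), 127))
  structure(list(pitches = pitches, pre_floor = pre),
            class = "MidiProfile")
}

#' Export a profile as two-column CSV
#'
#' Writes `column` (1-based index) and `value` for an `EntropyProfile`
#' (entropy in bits) or a `MidiProfile` (integer pitch).
#'
#' @param profile An `EntropyProfile` or `MidiProfile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  v <- if (inherits(profile, "MidiProfile")) profile$pitches
       else profile$values
  utils::write.csv(
    data.frame(column = seq_along(v), value = v),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
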