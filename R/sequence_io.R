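# FASTA / aligned-FASTA ingestion into the package's two domain types.
#
# Coordinates are 0-based internally; every user-facing message and every
# provenance field (source_position etc.) is 1-based.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes of the standard proteinogenic amino acids, in
#' alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity / non-standard codes admitted under the permissive policy.
# They carry no hydrophobicity score, so downstream algorithms render them
# as silent one-slot rests.
.permissive_extra <- c("X", "B", "Z", "U", "O", "*")

.check_policy <- function(policy) {
  match.arg(policy, c("strict", "permissive"))
}

# Validate a residue string (no gaps). Returns the normalised (uppercased)
# string or stops with a message naming the first offending character and
# its 1-based position.
.validate_residues <- function(x, policy, id = "<sequence>") {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  allowed <- amino_acids()
  if (policy == "permissive") allowed <- c(allowed, .permissive_extra)
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid residue '%s' at position %d in sequence '%s' (policy: %s)",
      chars[bad[1L]], bad[1L], id, policy), call. = FALSE)
  }
  x
}

#' Construct a validated protein sequence
#'
#' @param id Sequence identifier (first word of the FASTA header).
#' @param residues Amino-acid string; lowercase input is uppercased.
#' @param policy Residue policy: `"strict"` (default) admits only the 20
#'   standard one-letter codes; `"permissive"` also admits the ambiguity
#'   codes `X`, `B`, `Z`, `U`, `O` and `*`, which downstream algorithms
#'   render as silent rests.
#' @param description Free-text remainder of the FASTA header, if any.
#' @return An object of class `ProteinSequence` with fields `id`,
#'   `residues`, `description` and `policy`.
#' @examples
#' protein_sequence("p1", "MKV")
#' @export
protein_sequence <- function(id, residues, policy = "strict",
                             description = "") {
  policy <- .check_policy(policy)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  if (nchar(residues) < 1L) {
    stop(sprintf("empty sequence '%s'", id), call. = FALSE)
  }
  residues <- .validate_residues(residues, policy, id)
  structure(
    list(id = id, residues = residues, description = description,
         policy = policy),
    class = "ProteinSequence")
}

#' @export
length.ProteinSequence <- function(x) nchar(x$residues)

#' @export
print.ProteinSequence <- function(x, ...) {
  cat(sprintf("ProteinSequence '%s': %d residues (%s policy)\n",
              x$id, length(x), x$policy))
  invisible(x)
}

#' Residues of a sequence as a character vector
#'
#' @param x A `ProteinSequence`.
#' @return Character vector of single-character residue codes.
#' @export
residue_chars <- function(x) {
  stopifnot(inherits(x, "ProteinSequence"))
  strsplit(x$residues, "", fixed = TRUE)[[1L]]
}

#' Construct a protein multiple sequence alignment
#'
#' Rows must be equal-length strings over the 20 amino-acid codes plus the
#' gap character `-`.  The alternative gap character `.` is normalised to
#' `-` and lowercase residues are uppercased.
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of aligned sequences, same length as `ids`.
#' @param policy Residue policy, as in [protein_sequence()].
#' @param descriptions Optional header descriptions per row.
#' @return An object of class `Alignment` with fields `ids`, `rows`,
#'   `n_rows`, `n_cols`, `descriptions` and `policy`.
#' @examples
#' alignment(c("a", "b"), c("AC-", "A-C"))
#' @export
alignment <- function(ids, rows, policy = "strict",
                      descriptions = rep("", length(ids))) {
  policy <- .check_policy(policy)
  stopifnot(is.character(ids), is.character(rows),
            length(ids) == length(rows))
  if (length(rows) < 1L) stop("alignment needs at least one row", call. = FALSE)
  rows <- toupper(chartr(".", "-", rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop(sprintf(
      "ragged alignment: row lengths are %s",
      paste(sprintf("%s=%d", ids, widths), collapse = ", ")),
      call. = FALSE)
  }
  if (widths[1L] < 1L) stop("alignment has zero columns", call. = FALSE)
  for (i in seq_along(rows)) {
    .validate_residues(gsub("-", "", rows[i], fixed = TRUE), policy, ids[i])
  }
  structure(
    list(ids = ids, rows = rows, n_rows = length(rows),
         n_cols = widths[1L], descriptions = descriptions, policy = policy),
    class = "Alignment")
}

#' @export
dim.Alignment <- function(x) c(x$n_rows, x$n_cols)

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n", x$n_rows, x$n_cols))
  invisible(x)
}

#' @export
as.matrix.Alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# Shared raw FASTA reader: Biostrings handles the format; we impose the
# package's validation on top.
.read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    empty <- ids[nchar(seqs) == 0L][1L]
    stop(sprintf("empty FASTA record '%s' in '%s'", empty, path),
         call. = FALSE)
  }
  list(ids = ids, descriptions = descs, seqs = unname(seqs))
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file; multi-line records are supported and
#'   the header text after the first whitespace is kept as the description.
#' @inheritParams protein_sequence
#' @return A list of [protein_sequence()] objects, one per record.
#' @export
read_fasta <- function(path, policy = "strict") {
  policy <- .check_policy(policy)
  raw <- .read_fasta_raw(path)
  mapply(function(id, s, d) protein_sequence(id, s, policy, d),
         raw$ids, raw$seqs, raw$descriptions,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' @inheritParams read_fasta
#' @return An [alignment()] object.  Unequal row lengths raise an error
#'   that reports every row length.
#' @export
read_alignment <- function(path, policy = "strict") {
  raw <- .read_fasta_raw(path)
  alignment(raw$ids, raw$seqs, policy = policy,
            descriptions = raw$descriptions)
}

#' Write sequences or an alignment to (aligned) FASTA
#'
#' @param x A `ProteinSequence`, a list of them, or an `Alignment`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "ProteinSequence")) x <- list(x)
  if (inherits(x, "Alignment")) {
    ids <- x$ids; seqs <- x$rows; descs <- x$descriptions
  } else {
    stopifnot(all(vapply(x, inherits, logical(1L), "ProteinSequence")))
    ids <- vapply(x, `[[`, character(1L), "id")
    seqs <- vapply(x, `[[`, character(1L), "residues")
    descs <- vapply(x, `[[`, character(1L), "description")
  }
  headers <- ifelse(nchar(descs) > 0L, paste(ids, descs), ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
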