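# Seed-deterministic synthetic-data generators emulating the geometry of
# the listening-task inputs: a tandem-repeat protein and a
# conserved-domain alignment.  Only the statistical structure matters;
# no real protein identities are reproduced.

# Run fn with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards; with seed = NULL the global stream is used.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a protein with a tandem amino-acid repeat
#'
#' Draws a background sequence uniformly over the 20-letter alphabet and
#' plants a random motif of `motif_len` residues in `n_repeats` adjacent
#' (tandem) copies at a uniformly chosen feasible position.  Defaults
#' reproduce the listening-task geometry: a 253-residue protein with an
#' 8-residue motif repeated four times in tandem.
#'
#' @param total_len Total sequence length.
#' @param motif_len Motif length in residues.
#' @param n_repeats Number of adjacent motif copies.
#' @param seed Integer seed; the same seed always gives the same output.
#' @param id Sequence identifier.
#' @return A [protein_sequence()] with attribute `metadata`: a list with
#'   `motif` (the motif string) and `start` (1-based position of the
#'   first copy).
#' @examples
#' p <- make_repeat_protein(seed = 1)
#' length(p)  # 253
#' @export
make_repeat_protein <- function(total_len = 253L, motif_len = 8L,
                                n_repeats = 4L, seed = NULL,
                                id = "repeat_protein") {
  total_len <- as.integer(total_len)
  motif_len <- as.integer(motif_len)
  n_repeats <- as.integer(n_repeats)
  block <- motif_len * n_repeats
  if (motif_len < 1L || n_repeats < 1L || block > total_len) {
    stop(sprintf(
      "motif block (%d x %d = %d residues) does not fit in total length %d",
      motif_len, n_repeats, block, total_len), call. = FALSE)
  }
  aa <- amino_acids()
  .with_seed(seed, function() {
    chars <- sample(aa, total_len, replace = TRUE)
    motif <- sample(aa, motif_len, replace = TRUE)
    start <- sample.int(total_len - block + 1L, 1L)
    chars[start:(start + block - 1L)] <- rep(motif, n_repeats)
    seq <- protein_sequence(id, paste(chars, collapse = ""))
    attr(seq, "metadata") <- list(motif = paste(motif, collapse = ""),
                                  start = start)
    seq
  })
}

#' Generate an alignment with conserved domain blocks
#'
#' Builds an `n_seqs` x `n_cols` alignment in which columns inside the
#' given domain blocks are near-perfectly conserved (a consensus residue
#' per column with i.i.d. substitution noise), while background columns
#' hold independent uniform residues with gaps inserted at `gap_rate`.
#' Defaults emulate the listening-task geometry: five sequences with
#' three conserved domains, each under 50 columns.
#'
#' @param n_seqs Number of rows.
#' @param n_cols Number of columns.
#' @param domains List of `c(start, length)` pairs (1-based column
#'   coordinates); blocks must fit inside `n_cols` and not overlap.  The
#'   default (`NULL`) places three domains proportionally across the
#'   alignment, sized at roughly 15%, 22% and 12% of `n_cols` (capped at
#'   `max_domain_len`); it needs `n_cols >= 10`.
#' @param gap_rate Per-cell gap probability outside domains.
#' @param sub_rate Per-cell probability that a domain residue deviates
#'   from the column consensus.
#' @param seed Integer seed.
#' @param max_domain_len Guard on domain length (the emulated tasks use
#'   domains under 50 columns); raise it for other geometries.
#' @return An [alignment()] with attribute `metadata`: a list with
#'   `domains` (the coordinate pairs).
#' @export
make_domain_msa <- function(n_seqs = 5L, n_cols = 200L,
                            domains = NULL,
                            gap_rate = 0.1, sub_rate = 0.05, seed = NULL,
                            max_domain_len = 49L) {
  n_seqs <- as.integer(n_seqs)
  n_cols <- as.integer(n_cols)
  stopifnot(n_seqs >= 1L, n_cols >= 1L,
            gap_rate >= 0, gap_rate < 1, sub_rate >= 0, sub_rate < 1)
  if (is.null(domains)) {
    if (n_cols < 10L) {
      stop("default domain layout needs n_cols >= 10; pass `domains`",
           call. = FALSE)
    }
    lens <- pmin(max_domain_len,
                 pmax(1L, as.integer(round(n_cols * c(0.15, 0.22, 0.12)))))
    starts <- pmax(1L, as.integer(round(n_cols * c(0.10, 0.38, 0.75))))
    domains <- Map(c, starts, lens)
  }
  dom <- lapply(domains, function(d) {
    d <- as.integer(d)
    if (length(d) != 2L || d[1L] < 1L || d[2L] < 1L ||
        d[1L] + d[2L] - 1L > n_cols) {
      stop("each domain must be c(start, length) fitting within n_cols",
           call. = FALSE)
    }
    if (d[2L] > max_domain_len) {
      stop(sprintf("domain length %d exceeds max_domain_len %d",
                   d[2L], max_domain_len), call. = FALSE)
    }
    d
  })
  covered <- unlist(lapply(dom, function(d) seq(d[1L], d[1L] + d[2L] - 1L)))
  if (anyDuplicated(covered)) stop("domains overlap", call. = FALSE)
  aa <- amino_acids()
  .with_seed(seed, function() {
    m <- matrix(sample(aa, n_seqs * n_cols, replace = TRUE),
                nrow = n_seqs, ncol = n_cols)
    background <- setdiff(seq_len(n_cols), covered)
    if (gap_rate > 0 && length(background) > 0L) {
      cells <- matrix(stats::runif(n_seqs * length(background)) < gap_rate,
                      nrow = n_seqs)
      m[, background][cells] <- "-"
    }
    for (d in dom) {
      cols <- seq(d[1L], d[1L] + d[2L] - 1L)
      consensus <- sample(aa, length(cols), replace = TRUE)
      block <- matrix(rep(consensus, each = n_seqs), nrow = n_seqs)
      flips <- matrix(stats::runif(n_seqs * length(cols)) < sub_rate,
                      nrow = n_seqs)
      block[flips] <- sample(aa, sum(flips), replace = TRUE)
      m[, cols] <- block
    }
    aln <- alignment(sprintf("seq%d", seq_len(n_seqs)),
                     apply(m, 1L, paste, collapse = ""))
    attr(aln, "metadata") <- list(domains = dom)
    aln
  })
}

#' Write a fixture's metadata sidecar
#'
#' Writes the generator metadata attached to a fixture (motif and its
#' position, or domain coordinates) as key-value text lines.
#'
#' @param x A fixture from [make_repeat_protein()] or [make_domain_msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_metadata <- function(x, path) {
  md <- attr(x, "metadata")
  if (is.null(md)) stop("object carries no fixture metadata", call. = FALSE)
  lines <- if (!is.null(md$motif)) {
    c(sprintf("motif\t%s", md$motif), sprintf("start\t%d", md$start))
  } else {
    vapply(md$domains, function(d) sprintf("domain\t%d\t%d", d[1L], d[2L]),
           character(1L))
  }
  writeLines(lines, path)
  invisible(path)
}
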