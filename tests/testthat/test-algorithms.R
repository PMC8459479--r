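test_that("Algorithm I maps residues to GES pitches, one note per slot", {
  t1 <- sonify_hydrophobicity(protein_sequence("p", "F"))
  expect_identical(nrow(t1$events), 1L)
  expect_identical(t1$events$pitch, 50L)
  expect_identical(t1$events$onset, 0L)
  expect_identical(t1$events$voice, "sine")

  t2 <- sonify_hydrophobicity(protein_sequence("p", "FR"))
  expect_identical(t2$events$pitch, c(50L, 77L))
  expect_identical(t2$events$onset, c(0L, 1L))
  expect_identical(t2$events$velocity, c(100L, 100L))

  # one event per residue, onsets 0..n-1, provenance 1-based
  p <- random_protein(120L, 3)
  tr <- sonify_hydrophobicity(p)
  expect_identical(nrow(tr$events), 120L)
  expect_identical(tr$events$onset, 0:119)
  expect_identical(tr$events$source_position, 1:120)
  expect_identical(tr$events$source_symbol, residue_chars(p))
  expect_identical(tr$slots_total, 120L)
})

test_that("permissive ambiguity codes become silent slots, not shifts", {
  seq <- protein_sequence("p", "MXV", policy = "permissive")
  tr <- sonify_hydrophobicity(seq)
  expect_identical(nrow(tr$events), 2L)
  expect_identical(tr$events$onset, c(0L, 2L))  # slot 1 is a rest
  expect_identical(tr$slots_total, 3L)
  # same behaviour for the reduced mapping
  tr2 <- sonify_reduced(seq)
  expect_identical(tr2$events$onset, c(0L, 2L))
})

test_that("Algorithm II plays the four group pitches", {
  tr <- sonify_reduced(protein_sequence("p", "FAKD"))
  expect_identical(tr$events$pitch, c(67L, 64L, 62L, 60L))
  expect_identical(unique(tr$events$voice), "sine")

  run <- sonify_reduced(protein_sequence("p", "FILVWY"))
  expect_identical(run$events$pitch, rep(67L, 6))

  p <- random_protein(200L, 8)
  expect_true(all(sonify_reduced(p)$events$pitch %in% c(60L, 62L, 64L, 67L)))
})

test_that("Algorithm III combines GES pitch with group instruments", {
  tr <- sonify_combined(protein_sequence("p", "FD"))
  expect_identical(tr$events$pitch, c(50L, 73L))
  expect_identical(tr$events$voice, c("piano", "tb303"))

  p <- random_protein(150L, 21)
  expect_identical(sonify_combined(p)$events$pitch,
                   sonify_hydrophobicity(p)$events$pitch)
  expect_identical(sonify_combined(p)$events$voice,
                   reduced_instrument(residue_chars(p)))
})

test_that("Algorithm IV is monophonic with one saw note per column", {
  conserved <- alignment(c("a", "b", "c"), c("AGFW", "AGFW", "AGFW"))
  tr <- sonify_msa_entropy(conserved)
  expect_identical(nrow(tr$events), 4L)
  expect_identical(tr$events$pitch, rep(60L, 4))
  expect_identical(unique(tr$events$voice), "saw")

  aln <- make_domain_msa(n_seqs = 5, n_cols = 80, seed = 4)
  tr2 <- sonify_msa_entropy(aln)
  expect_identical(nrow(tr2$events), 80L)
  expect_identical(tr2$events$onset, 0:79)       # monophonic: unique onsets
  # a maximally diverse column carries the track's maximum pitch
  rows <- c("ACDEF", "ACDEG", "ACDEH", "ACDEK", "ACDEM")
  div <- alignment(sprintf("s%d", 1:5), rows)    # only column 5 varies
  tr3 <- sonify_msa_entropy(div)
  expect_identical(which.max(tr3$events$pitch), 5L)
})

test_that("Algorithm V emits one note per distinct sounding residue", {
  aln <- alignment(c("a", "b", "c"), c("FF-", "F--", "F--"))
  tr <- sonify_msa_hydrophobicity(aln)
  # column 1: consensus F in 3/3 rows -> one loud note
  c1 <- tr$events[tr$events$onset == 0L, ]
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$pitch, 50L)
  expect_identical(c1$velocity, 127L)
  # column 2: F in 1/3 rows -> one quiet note
  c2 <- tr$events[tr$events$onset == 1L, ]
  expect_identical(c2$velocity, as.integer(round(30 + (1 / 3) * 97)))
  # column 3: all gaps -> silence
  expect_identical(nrow(tr$events[tr$events$onset == 2L, ]), 0L)
  expect_identical(tr$slots_total, 3L)
  expect_identical(unique(tr$events$voice), "saw")
})

test_that("Algorithm V event counts and velocities follow column makeup", {
  aln <- make_domain_msa(n_seqs = 5, n_cols = 60, gap_rate = 0.3, seed = 6)
  tr <- sonify_msa_hydrophobicity(aln)
  m <- as.matrix(aln)
  distinct_per_col <- apply(m, 2, function(col)
    length(unique(col[col != "-"])))
  expect_identical(nrow(tr$events), as.integer(sum(distinct_per_col)))
  for (j in seq_len(ncol(m))) {
    ev <- tr$events[tr$events$onset == j - 1L, ]
    col <- m[, j][m[, j] != "-"]
    expect_setequal(ev$source_symbol, unique(col))
    # velocity strictly increases with the residue's count
    counts <- table(col)[ev$source_symbol]
    if (nrow(ev) > 1L) {
      o <- order(as.vector(counts))
      expect_true(all(diff(ev$velocity[o])[diff(sort(counts)) > 0] > 0))
    }
  }
})

test_that("polarity inversion reflects the pitch axis", {
  inv <- sonify_params(invert_polarity = TRUE)
  expect_identical(sonify_hydrophobicity(protein_sequence("p", "FR"),
                                         inv)$events$pitch,
                   c(77L, 50L))
  expect_identical(sonify_reduced(protein_sequence("p", "FD"),
                                  inv)$events$pitch,
                   c(60L, 67L))
})

test_that("tracks are deterministic and carry run parameters", {
  p <- random_protein(40L, 99)
  expect_identical(sonify_hydrophobicity(p), sonify_hydrophobicity(p))
  tr <- sonify_hydrophobicity(p, sonify_params(note_duration = 0.1,
                                               velocity = 64))
  expect_identical(tr$note_duration_seconds, 0.1)
  expect_identical(unique(tr$events$velocity), 64L)
  expect_error(sonify_params(velocity = 0), "velocity")
})

test_that("event tables round-trip through the plain-text export", {
  tr <- sonify_combined(random_protein(25L, 12))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_events(tr, out)
  tab <- utils::read.delim(out, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), nrow(tr$events))
  expect_identical(tab$pitch, tr$events$pitch)
  expect_identical(tab$voice, tr$events$voice)
})
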