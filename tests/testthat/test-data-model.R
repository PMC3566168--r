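test_that("FASTA reading: round-trip, order, and malformed inputs", {
  path <- write_tmp_fasta(list(p1 = "ACDEFGH"))
  recs <- read_fasta(path)
  expect_length(recs, 1L)
  expect_equal(recs$p1$sequence, "ACDEFGH")
  expect_equal(nchar(recs$p1$sequence), 7L)

  path2 <- write_tmp_fasta(list(p1 = "ACDEF", p2 = "MNPQR"))
  recs2 <- read_fasta(path2)
  expect_equal(names(recs2), c("p1", "p2"))

  dup <- write_tmp_fasta(list(a = "ACD"))
  cat(">p1\nACD\n>p1\nGHI\n", file = dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty))

  zero <- withr::local_tempfile(fileext = ".fasta")
  cat(">p1\n\n>p2\nACD\n", file = zero)
  expect_error(read_fasta(zero), "zero-length")
})

test_that("non-standard residues are mapped to X and reported", {
  path <- write_tmp_fasta(list(p1 = "ACBZUXD"))
  recs <- read_fasta(path)
  expect_equal(recs$p1$sequence, "ACXXXXD")
  expect_match(attr(recs, "load_report"), "p1: 4 non-standard")
})

test_that("annotation loading attaches, validates and rejects rows", {
  recs <- list(p1 = protein_record("p1", "AACAA"))
  ann <- write_tmp_tsv(data.frame(protein_id = "p1", position = 3, residue = "C",
                                  metal = "Fe"))
  out <- read_annotations(ann, recs)
  expect_equal(out$p1$binding_sites$position, 3L)
  expect_equal(out$p1$binding_sites$metal, "Fe")

  bad_res <- write_tmp_tsv(data.frame(protein_id = "p1", position = 3,
                                      residue = "H", metal = "Fe"))
  expect_warning(out2 <- read_annotations(bad_res, recs), "disagrees")
  expect_equal(nrow(out2$p1$binding_sites), 0L)

  unknown <- write_tmp_tsv(data.frame(protein_id = "p9", position = 1,
                                      residue = "C", metal = "Fe"))
  expect_error(read_annotations(unknown, recs), "unknown protein id")

  oob <- write_tmp_tsv(data.frame(protein_id = "p1", position = 9,
                                  residue = "C", metal = "Fe"))
  expect_error(read_annotations(oob, recs), "out of range")

  # annotated residue that is not C/H is skipped with a warning, not fatal
  recs2 <- list(p1 = protein_record("p1", "AAGAA"))
  notch <- write_tmp_tsv(data.frame(protein_id = "p1", position = 3,
                                    residue = "G", metal = "Fe"))
  expect_warning(out3 <- read_annotations(notch, recs2), "not C/H")
  expect_equal(nrow(out3$p1$binding_sites), 0L)
})

test_that("site extraction lists every C/H with correct labels", {
  rec <- make_record("p1", "ACHCA", 2L)
  sites <- extract_sites(rec)
  expect_equal(sites$position, c(2L, 3L, 4L))
  expect_equal(sites$residue, c("C", "H", "C"))
  expect_equal(sites$label, c("binding", "non-binding", "non-binding"))

  expect_equal(nrow(extract_sites(make_record("p0", "AAAAA"))), 0L)

  all_b <- make_record("p2", "CCCC", 1:4)
  expect_true(all(extract_sites(all_b)$label == "binding"))

  # restriction to one residue type
  expect_equal(extract_sites(rec, residue = "H")$position, 3L)
})

test_that("binding plus non-binding sites account for every C and H", {
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(AA_ORDER, 60, replace = TRUE), collapse = "")
    ch <- which(strsplit(seq, "")[[1]] %in% c("C", "H"))
    ann <- if (length(ch)) sample(ch, min(2, length(ch))) else integer(0)
    rec <- make_record(sprintf("r%d", i), seq, ann)
    sites <- extract_sites(rec)
    expect_equal(nrow(sites), length(ch))
    expect_equal(sum(sites$label == "binding"), length(ann))
  }
})

test_that("window extraction pads termini with X only at the edges", {
  rec <- make_record("p1", "ACDEFGHIKLMNP")
  expect_equal(extract_window(rec, 7)$context, "ACDEFGHIKLMNP")
  expect_equal(extract_window(rec, 1)$context, "XXXXXXACDEFGH")
  expect_equal(extract_window(rec, 13)$context, "HIKLMNPXXXXXX")
  expect_error(extract_window(rec, 14), "out of range")
  expect_error(extract_window(rec, 0), "out of range")

  w <- extract_window(rec, 2)
  chars <- strsplit(w$context, "")[[1]]
  expect_equal(chars[7], "C")              # centre equals the site residue
  runs <- rle(chars == "X")
  expect_true(all(which(runs$values) %in% c(1, length(runs$values))))
})

test_that("window extraction is shift-equivariant away from termini", {
  set.seed(7)
  base <- paste(sample(setdiff(AA_ORDER, c("C", "H")), 40, replace = TRUE),
                collapse = "")
  rec <- make_record("a", paste0(base, "C", base))
  for (k in c(1, 5, 12)) {
    prefix <- paste(sample(setdiff(AA_ORDER, c("C", "H")), k, replace = TRUE),
                    collapse = "")
    shifted <- make_record("b", paste0(prefix, rec$sequence))
    expect_equal(extract_window(shifted, 41 + k)$context,
                 extract_window(rec, 41)$context)
  }
})

test_that("FASTA and annotation TSV round-trip the data model exactly", {
  recs <- list(p1 = make_record("p1", "ACHCAMKL", c(2L, 4L)),
               p2 = make_record("p2", "HHCAG", 1L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  an <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(recs, fa)
  write_annotations(recs, an)
  back <- read_annotations(an, read_fasta(fa))
  for (id in names(recs)) {
    expect_equal(back[[id]]$sequence, recs[[id]]$sequence)
    expect_equal(back[[id]]$binding_sites$position, recs[[id]]$binding_sites$position)
    expect_equal(back[[id]]$binding_sites$metal, recs[[id]]$binding_sites$metal)
  }
})
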