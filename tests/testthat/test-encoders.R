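test_that("PSI-BLAST PSSM fixture files parse back to the exact matrix", {
  set.seed(11)
  res <- sample(AA_ORDER, 5, replace = TRUE)
  m <- matrix(sample(-8:11, 100, replace = TRUE), nrow = 5,
              dimnames = list(NULL, AA_ORDER))
  f <- withr::local_tempfile(fileext = ".pssm")
  make_fixture_pssm(res, m, f)
  prof <- parse_psiblast_pssm(f)
  expect_equal(prof$scores, m)
  expect_equal(prof$residues, res)
})

test_that("PSSM parser reports malformed rows with their line number", {
  res <- c("M", "K", "L", "C", "A")
  m <- matrix(0L, nrow = 5, ncol = 20, dimnames = list(NULL, AA_ORDER))
  f <- withr::local_tempfile(fileext = ".pssm")
  make_fixture_pssm(res, m, f)
  lines <- readLines(f)
  row3 <- grep("^\\s*3\\s+L", lines)
  lines[row3] <- substr(lines[row3], 1, 40)   # truncate row 3
  writeLines(lines, f)
  expect_error(parse_psiblast_pssm(f), sprintf("line %d", row3))

  make_fixture_pssm(res, m, f)
  lines <- readLines(f)
  lines[row3] <- sub(" {2}0", "  ?", lines[row3])
  writeLines(lines, f)
  expect_error(parse_psiblast_pssm(f), "non-numeric")
})

test_that("PSSM parser keeps only the first 20 numeric columns", {
  # a minimal dialect with log-odds columns only, plus the full fixture
  # dialect whose trailing percentage/statistics columns must be ignored
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(AA_ORDER, collapse = "  ")),
               paste("    1 M ", paste(1:20, collapse = " ")),
               paste("    2 K ", paste(21:40, collapse = " "))), f)
  prof <- parse_psiblast_pssm(f)
  expect_equal(dim(prof$scores), c(2L, 20L))
  expect_equal(prof$scores[1, ], setNames(as.numeric(1:20), AA_ORDER))
  expect_equal(unname(prof$scores[2, "V"]), 40)
})

test_that("logistic scaling hits its reference values and preserves order", {
  expect_identical(scale_pssm_value(0), 0.5)
  expect_equal(scale_pssm_value(-2), 0.11920, tolerance = 1e-4)
  expect_equal(scale_pssm_value(7), 0.99909, tolerance = 1e-5)
  x <- sort(rnorm(50, sd = 4))
  y <- scale_pssm_value(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 0 & y < 1))
  expect_error(scale_pssm_value(Inf), "non-finite")
})

test_that("AA encoding is one-hot with zero padding rows", {
  rec <- make_record("p1", strrep("C", 13))
  win <- extract_window(rec, 7)
  v <- encode_window(win, "AA")
  expect_length(v, 260L)
  expect_equal(sum(v), 13)
  expect_true(all(v %in% c(0, 1)))

  # each non-padding row sums to 1, padding rows to 0
  rec2 <- make_record("p2", "CDEFGHIKLMNPQ")
  win2 <- extract_window(rec2, 1)   # 6 left-pad positions
  v2 <- encode_window(win2, "AA")
  rows <- matrix(v2, nrow = 13, byrow = TRUE)
  expect_equal(rowSums(rows), c(rep(0, 6), rep(1, 7)))
})

test_that("substitution-matrix encodings are globally rescaled to [0, 1]", {
  rec <- make_record("p1", "ACDEFGHIKLMNP")
  for (enc in c("BLOSUM62", "PAM250")) {
    v <- encode_window(extract_window(rec, 7), enc)
    expect_length(v, 260L)
    expect_true(all(v >= 0 & v <= 1))
  }
  # spot value: BLOSUM62 C/C raw score 9 on a [-4, 11] range
  v <- encode_window(extract_window(make_record("p2", strrep("C", 13)), 7), "BLOSUM62")
  rows <- matrix(v, nrow = 13, byrow = TRUE)
  expect_equal(rows[7, 5], (9 - (-4)) / (11 - (-4)))
})

test_that("PSSM encoding uses the scaled profile row of the right position", {
  rec <- make_record("p1", "ACDEFGHIKLMNP")
  zero <- structure(list(id = "p1", residues = strsplit(rec$sequence, "")[[1]],
                         scores = matrix(0, 13, 20, dimnames = list(NULL, AA_ORDER))),
                    class = "pssm_profile")
  v <- encode_window(extract_window(rec, 7), "PSSM", profile = zero)
  expect_true(all(v == 0.5))

  v1 <- encode_window(extract_window(rec, 1), "PSSM", profile = zero)
  expect_equal(v1[1:120], rep(0, 120))        # 6 left-pad rows are exactly 0
  expect_true(all(v1[121:260] == 0.5))

  expect_error(encode_window(extract_window(rec, 7), "PSSM"), "requires a profile")
})

test_that("padding rows are all-zero under every encoding", {
  rec <- make_record("p1", "CDEFGHIKLMNPQ")
  zero <- structure(list(id = "p1", residues = strsplit(rec$sequence, "")[[1]],
                         scores = matrix(0, 13, 20, dimnames = list(NULL, AA_ORDER))),
                    class = "pssm_profile")
  for (enc in c("AA", "BLOSUM62", "PAM250", "PSSM")) {
    v <- encode_window(extract_window(rec, 1), enc,
                       profile = if (enc == "PSSM") zero)
    expect_equal(v[1:120], rep(0, 120), info = enc)
  }
})

test_that("dataset encoding has the right shape and is deterministic", {
  syn <- generate_synthetic(small_synth_config(seed = 3))
  sites <- syn$sites[1:3, ]
  enc <- encode_dataset(syn$records, sites, "PSSM", syn$profiles)
  expect_equal(dim(enc$x), c(3L, 260L))
  expect_equal(enc$y, as.integer(sites$label == "binding"))
  expect_true(all(enc$x >= 0 & enc$x < 1))

  # appending a 25-pair catalog extends each row to 285 features
  catalog <- rank_saaps(enumerate_pairs(
    metalbindr:::site_window_matrix(syn$records, syn$sites),
    syn$sites$label == "binding"), alpha = 1)
  enc2 <- encode_dataset(syn$records, sites, "PSSM", syn$profiles,
                         saaps = head(catalog, 25))
  expect_equal(ncol(enc2$x), 285L)

  empty <- encode_dataset(syn$records, syn$sites[0, ], "AA")
  expect_equal(nrow(empty$x), 0L)
  expect_length(empty$y, 0L)

  enc3 <- encode_dataset(syn$records, sites, "PSSM", syn$profiles)
  expect_identical(enc$x, enc3$x)

  expect_error(encode_dataset(syn$records, sites, "PSSM"), "requires profiles")
})
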