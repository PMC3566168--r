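win_row <- function(context) matrix(strsplit(context, "")[[1]], nrow = 1)

test_that("pair counting is per-window, centre-free and padding-aware", {
  # positive window with C at offset -4 and P at offset +1
  w1 <- win_row("AACAAACPAAAAA")
  cat1 <- enumerate_pairs(w1, labels = 1)
  row <- cat1[cat1$offset1 == -4 & cat1$aa1 == "C" &
              cat1$offset2 == 1 & cat1$aa2 == "P", ]
  expect_equal(row$n, 1L)
  expect_equal(row$x, 1L)
  expect_false(any(cat1$offset1 == 0 | cat1$offset2 == 0))
  expect_true(all(cat1$offset1 < cat1$offset2))

  # two identical negative windows double n but leave x at 0
  w2 <- rbind(win_row("AACAAACPAAAAA"), win_row("AACAAACPAAAAA"))
  cat2 <- enumerate_pairs(w2, labels = c(0, 0))
  expect_true(all(cat2$n == 2L))
  expect_true(all(cat2$x == 0L))
  expect_equal(attr(cat2, "N"), 2L)
  expect_equal(attr(cat2, "M"), 0L)

  # a padded position never participates in a pair
  w3 <- win_row("XACAAACPAAAAA")
  cat3 <- enumerate_pairs(w3, labels = 1)
  expect_false(any(cat3$offset1 == -6 | cat3$offset2 == -6))

  expect_error(enumerate_pairs(rbind(win_row("AAAAAACAAAAAA"),
                                     win_row("AAAAAAHAAAAAA")), c(1, 0)),
               "mixed centre")
})

test_that("hypergeometric point mass matches direct binomial evaluation", {
  expect_equal(hypergeom_pmf(5, 2, 2, 1), 0.6)
  expect_equal(hypergeom_pmf(10, 10, 3, 3), 1.0)
  expect_equal(hypergeom_pmf(4, 2, 2, 0), 1 / 6)
  expect_error(hypergeom_pmf(5, 6, 2, 1), "M <= N")
  expect_error(hypergeom_pmf(5, 2, 2, 3), "support")
})

test_that("enrichment p-value is the upper-tail sum", {
  expect_equal(saap_pvalue(5, 2, 2, 2), 0.1)
  expect_equal(saap_pvalue(5, 2, 2, 1), 0.7)   # 0.6 + 0.1
  for (args in list(c(9, 4, 3), c(20, 5, 7), c(12, 6, 4))) {
    expect_equal(saap_pvalue(args[1], args[2], args[3], 0), 1.0)
  }
  expect_equal(saap_pvalue(5, 2, 2, 2, type = "point"),
               hypergeom_pmf(5, 2, 2, 2))
})

test_that("tail p-value agrees with the subset-counting oracle (small N)", {
  for (N in c(4L, 7L, 12L)) {
    for (M in 0:N) {
      T <- dp_subset_counts(N, M)
      for (n in 0:N) {
        xs <- max(0L, n - (N - M)):min(n, M)
        expected <- vapply(xs, function(x) dp_tail_pvalue(T, n, x), numeric(1))
        expect_equal(saap_pvalue(N, M, rep(n, length(xs)), xs), expected,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("tail p-values lie in (0, 1] and are non-increasing in x", {
  set.seed(5)
  for (i in 1:40) {
    N <- sample(5:60, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    xs <- max(0L, n - (N - M)):min(n, M)
    p <- saap_pvalue(N, M, rep(n, length(xs)), xs)
    expect_true(all(p > 0 & p <= 1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("ranking filters at alpha and breaks ties deterministically", {
  w <- rbind(win_row("PACAAACPAAAAA"),
             win_row("PACAAACPAAAAA"),
             win_row("AAAAAACAAAAAA"),
             win_row("AAAAAACAAAAAA"))
  cat0 <- enumerate_pairs(w, labels = c(1, 1, 0, 0))
  ranked <- rank_saaps(cat0, alpha = 0.5)
  expect_true(all(ranked$p_value < 0.5))
  expect_true(!is.unsorted(ranked$p_value))
  # equal p-values are ordered lexicographically by (offset1, aa1, offset2, aa2)
  ties <- ranked[ranked$p_value == ranked$p_value[1], ]
  key <- order(ties$offset1, ties$aa1, ties$offset2, ties$aa2)
  expect_equal(key, seq_len(nrow(ties)))
  # identical on a second run
  expect_identical(ranked, rank_saaps(cat0, alpha = 0.5))

  # all-null catalog at alpha below every p empties the result
  cat_neg <- enumerate_pairs(w[3:4, , drop = FALSE], labels = c(0, 0))
  expect_equal(nrow(rank_saaps(cat_neg, alpha = 0.05)), 0L)
  # alpha = 1 keeps every observed pair, including p = 1
  expect_equal(nrow(rank_saaps(cat0, alpha = 1)), nrow(cat0))
})

test_that("SAAP indicators flag exactly the windows containing the pair", {
  catalog <- data.frame(offset1 = -4L, aa1 = "C", offset2 = 1L, aa2 = "P",
                        n = 1L, x = 1L, stringsAsFactors = FALSE)
  with_pair <- win_row("AACAAACPAAAAA")
  without <- win_row("AAAAAACPAAAAA")   # P at +1 but no C at -4
  expect_equal(as.vector(encode_saap_indicators(with_pair, catalog)), 1L)
  expect_equal(as.vector(encode_saap_indicators(without, catalog)), 0L)
  empty <- catalog[0, ]
  expect_equal(ncol(encode_saap_indicators(with_pair, empty)), 0L)
})

test_that("catalog counts are reproducible and internally consistent", {
  syn <- generate_synthetic(small_synth_config(seed = 9))
  wm <- metalbindr:::site_window_matrix(syn$records, syn$sites)
  lab <- syn$sites$label == "binding"
  c1 <- enumerate_pairs(wm, lab)
  c2 <- enumerate_pairs(wm, lab)
  expect_identical(c1, c2)
  expect_true(all(c1$x <= pmin(c1$n, attr(c1, "M"))))
  expect_true(all(c1$n - c1$x <= attr(c1, "N") - attr(c1, "M")))
})

test_that("a strongly planted pair ranks at the top of the catalog", {
  hits <- 0L
  for (s in 1:10) {
    syn <- generate_synthetic(small_synth_config(seed = 100 + s))
    catalog <- mine_saaps(syn$records, syn$sites)
    top3 <- head(catalog, 3)
    if (any(top3$offset1 == -4 & top3$aa1 == "C" &
            top3$offset2 == 1 & top3$aa2 == "P")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("catalog TSV round-trips counts, p-values and totals", {
  syn <- generate_synthetic(small_synth_config(seed = 2))
  catalog <- mine_saaps(syn$records, syn$sites)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_saap_catalog(catalog, f)
  back <- read_saap_catalog(f)
  expect_equal(back$offset1, catalog$offset1)
  expect_equal(back$aa2, catalog$aa2)
  expect_equal(back$n, catalog$n)
  expect_equal(back$x, catalog$x)
  expect_equal(back$p_value, catalog$p_value, tolerance = 1e-5)
  expect_equal(attr(back, "N"), attr(catalog, "N"))
  expect_equal(attr(back, "M"), attr(catalog, "M"))
})
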