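# Shared fixture builders. Everything is generated in code at test time.

write_tmp_fasta <- function(entries) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a protein with annotated binding sites, built directly
make_record <- function(id, sequence, binding_positions = integer(0)) {
  rec <- protein_record(id, sequence)
  if (length(binding_positions))
    rec$binding_sites <- data.frame(position = as.integer(binding_positions),
                                    metal = "Fe", stringsAsFactors = FALSE)
  rec
}

# small strong-signal synthetic study for pipeline tests
small_synth_config <- function(seed, ...) {
  synth_config(n_proteins = 14L, length_range = c(90L, 140L),
               n_positive = 20L, n_negative = 60L, seed = seed, ...)
}

# a deterministic, perfectly separable two-motif dataset: every positive
# window is one fixed string, every negative window another
separable_records <- function(n_pos = 12L, n_neg = 24L) {
  pos_seq <- "AAAAAPAACPAAAAAAA"   # C at 9 with planted (-4P, +1P)-style context
  neg_seq <- "AAAAAAAACAAAAAAAA"   # same C position, no pair
  recs <- list()
  for (i in seq_len(n_pos))
    recs[[sprintf("POS%02d", i)]] <- make_record(sprintf("POS%02d", i), pos_seq, 9L)
  for (i in seq_len(n_neg))
    recs[[sprintf("NEG%02d", i)]] <- make_record(sprintf("NEG%02d", i), neg_seq)
  recs
}

# random training points with a minimum pairwise separation, keeping the
# unridged all-centres kernel system numerically non-singular at sigma = 5
draw_separated <- function(n, d) {
  if (d == 1L) return(matrix(sample(cumsum(runif(n, 2, 5))), ncol = 1))
  repeat {
    x <- matrix(rnorm(n * d, sd = 4), n, d)
    if (min(dist(x)) >= 2) return(x)
  }
}

# uniformised (randomised) upper-tail p-value: exactly Uniform(0,1) when x
# is drawn from the hypergeometric null; standard device for validating
# discrete tests
randomized_saap_pvalue <- function(N, M, n, x) {
  saap_pvalue(N, M, n, x) - stats::runif(length(x)) * hypergeom_pmf(N, M, n, x)
}

# subset-counting oracle for the hypergeometric tail, independent of any
# binomial-coefficient formula: Pascal-style dynamic programme over items.
# Returns T with T[k+1, m+1] = number of k-subsets containing m of the M
# marked items (exact in doubles up to N = 30).
dp_subset_counts <- function(N, M) {
  T <- matrix(0, N + 1L, M + 1L)
  T[1L, 1L] <- 1
  for (i in seq_len(N)) {
    for (k in rev(seq_len(i))) {
      if (i <= M) {
        T[k + 1L, 2L:(M + 1L)] <- T[k + 1L, 2L:(M + 1L)] + T[k, 1L:M]
      } else {
        T[k + 1L, ] <- T[k + 1L, ] + T[k, ]
      }
    }
  }
  T
}

dp_tail_pvalue <- function(T, n, x) {
  row <- T[n + 1L, ]
  sum(row[seq.int(x + 1L, length(row))]) / sum(row)
}
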