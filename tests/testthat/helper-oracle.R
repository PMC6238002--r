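# Independent affine-gap global alignment oracle (iterative three-state
# recursion, no shared code with the aligner) and small data generators.

oracle_align_score <- function(s1, s2, match = 2, mismatch = -2,
                               gap_open = -8, gap_extend = -1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in s2 (s1 char unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in s1
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + gap_extend * i
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# wrap an arbitrary sequence as a degenerate locus so align_allele can be
# used on raw sequence pairs
pair_locus <- function(ref) {
  target_locus(ref, protospacer_start = 1L, protospacer_len = nchar(ref),
               pam_len = 0L, proximal_radius = 0L, locus_id = "pair")
}

# small CBE locus with short flanks for fast property tests
small_locus <- function(editor = editor_spec("BE3", "CBE"), radius = 40,
                        seed = 11) {
  withr::with_seed(seed, {
    proto <- "AGTCCCATGCATGACTAGTA"
    ref <- paste0(random_dna(radius), proto, "AGG",
                  random_dna(radius))
    build_locus(ref, proto, editor, proximal_radius = radius)
  })
}

# independent random mutator (string surgery, no package code) used for
# round-trip checks
mutate_random <- function(ref, n_sub = 3, n_del = 1, n_ins = 1) {
  x <- strsplit(ref, "")[[1]]
  for (k in seq_len(n_sub)) {
    i <- sample(length(x), 1)
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  }
  seq <- paste0(x, collapse = "")
  for (k in seq_len(n_del)) {
    len <- sample(1:8, 1)
    i <- sample(nchar(seq) - len, 1)
    seq <- paste0(substring(seq, 1, i - 1), substring(seq, i + len))
  }
  for (k in seq_len(n_ins)) {
    i <- sample(nchar(seq), 1)
    seq <- paste0(substring(seq, 1, i), random_dna(sample(1:5, 1)),
                  substring(seq, i + 1))
  }
  seq
}
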