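# Shared fixture builders; everything generated in code at test time.

# Small abundance tibble from a taxa-by-samples matrix.
abund_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "taxon")
}

# Random valid abundance table (columns sum to 100).
random_abund <- function(n_taxa = 6, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_taxa * n_samples), nrow = n_taxa,
              dimnames = list(paste0("Genus", seq_len(n_taxa), " species"),
                              paste0("s", seq_len(n_samples))))
  m <- sweep(m, 2, colSums(m), "/") * 100
  abund_tbl(m)
}

# Brute-force Bray-Curtis between two abundance vectors.
bc_formula <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / sum(x + y)
}

# Brute-force canonical k-mer enumeration, the slow obvious way.
slow_canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    out <- c(out, min(w, rc1(w)))
  }
  unique(out)
}

# Brute-force BH step-up q-values.
slow_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
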