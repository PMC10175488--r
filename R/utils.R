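# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route through this so seeds are explicit arguments, never global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Coerce a wide abundance tibble (first column = taxon ids, remaining columns
# = samples) to a numeric matrix with taxa as rows.
abund_matrix <- function(tbl) {
  if (is.matrix(tbl)) {
    storage.mode(tbl) <- "double"
    return(tbl)
  }
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  taxa <- as.character(tbl[[1]])
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  storage.mode(m) <- "double"
  rownames(m) <- taxa
  m
}

# Validate an abundance matrix: no negatives, column sums <= limit + tol.
check_abundance <- function(m, limit = 100, tol = 1e-6) {
  if (any(m < 0)) stop("negative abundance values are not allowed")
  cs <- colSums(m)
  bad <- which(cs > limit + tol)
  if (length(bad) > 0) {
    stop("sample column sum exceeds ", limit, ": ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  invisible(m)
}

# Random-nucleotide sequence of length n.
random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence: each base substituted independently with
# probability `rate`, drawing uniformly from the three other bases.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit) > 0) {
    alphabet <- c("A", "C", "G", "T")
    for (i in hit) {
      bases[i] <- sample(setdiff(alphabet, bases[i]), 1)
    }
  }
  paste(bases, collapse = "")
}

# Reverse complement of a DNA string (A/C/G/T/N).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
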