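test_that("canonical k-mers match hand enumeration and brute force", {
  # ACGTT, k=3: windows ACG,CGT,GTT -> canonical {ACG, ACG, AAC}
  expect_setequal(canonical_kmers("ACGTT", k = 3), c("ACG", "AAC"))

  expect_equal(canonical_kmers("AC", k = 3), character(0))

  # windows containing N are skipped
  expect_setequal(canonical_kmers("ACGNTTT", k = 3),
                  slow_canonical_kmers("ACGNTTT", 3))

  set.seed(23)
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    expect_setequal(canonical_kmers(s, k = 7), slow_canonical_kmers(s, 7))
  }

  expect_error(canonical_kmers("ACGT", k = 4), "odd")
})

test_that("canonical k-mer sets are strand-invariant", {
  set.seed(24)
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_setequal(canonical_kmers(s, k = 23), canonical_kmers(rc, k = 23))
  }
})

test_that("k-mer identity estimates track simulated divergence", {
  gs <- gen_strain_genomes(strain_spec(
    n_species = 1, strains_per_species = 1, genome_length = 50000,
    intra_species_divergence = 0, inter_species_divergence = 0.5, seed = 25
  ))
  g <- gs$genomes[[1]]
  kg <- canonical_kmers(g, k = 23)
  expect_equal(kmer_identity(kg, kg), 100)

  expect_equal(kmer_identity(c("AAA", "ACC"), c("AAA", "ACC"), k = 3), 100)
  expect_equal(kmer_identity(c("AAA"), c("ACC"), k = 3), 0)
  expect_error(kmer_identity(character(0), kg), "empty")

  # a genome mutated at 0.2% reads out close to 99.8% identity
  set.seed(26)
  mutated <- icstools:::mutate_sequence(g, 0.002)
  est <- kmer_identity(kg, canonical_kmers(mutated, k = 23))
  expect_lt(abs(est - 99.8), 0.1)
})

test_that("k-mer identity is symmetric and decreases with divergence", {
  gs <- gen_strain_genomes(strain_spec(
    n_species = 1, strains_per_species = 1, genome_length = 20000,
    intra_species_divergence = 0, inter_species_divergence = 0.5, seed = 27
  ))
  g <- gs$genomes[[1]]
  kg <- canonical_kmers(g, k = 23)
  set.seed(28)
  rates <- c(0.001, 0.005, 0.02, 0.05)
  ids <- vapply(rates, function(r) {
    km <- canonical_kmers(icstools:::mutate_sequence(g, r), k = 23)
    expect_equal(kmer_identity(kg, km), kmer_identity(km, kg))
    kmer_identity(kg, km)
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})

test_that("record filtering applies strict quality thresholds", {
  rec <- tibble::tibble(
    genome = c("exact_comp", "exact_cont", "good", "bad_comp", "bad_cont"),
    completeness = c(50.0, 80, 90, 30, 90),
    contamination = c(1.0, 1.95, 0.5, 0.5, 5)
  )
  kept <- filter_records(rec)
  expect_identical(kept$genome, "good")

  withstats <- tibble::tibble(genome = c("a", "b"),
                              completeness = c(NA, 90),
                              contamination = c(1, NA))
  expect_warning(kept2 <- filter_records(withstats), "lack quality")
  expect_equal(nrow(kept2), 2)

  # brute-force oracle on random records
  set.seed(29)
  rnd <- tibble::tibble(genome = paste0("g", 1:50),
                        completeness = runif(50, 0, 100),
                        contamination = runif(50, 0, 5))
  kept3 <- filter_records(rnd)
  oracle <- rnd[rnd$completeness > 50 & rnd$contamination < 1.95, ]
  expect_identical(kept3, oracle)
})

test_that("species validation keeps near strains and discards far ones", {
  gs <- gen_strain_genomes(strain_spec(
    n_species = 1, strains_per_species = 1, genome_length = 20000,
    intra_species_divergence = 0, inter_species_divergence = 0.5, seed = 30
  ))
  ref <- gs$genomes[[1]]
  set.seed(31)
  near <- icstools:::mutate_sequence(ref, 0.02)   # ~98% identity
  far <- icstools:::mutate_sequence(ref, 0.10)    # ~90% identity
  genomes <- c(self = ref, near = near, far = far)
  species <- c(self = "spA", near = "spA", far = "spA")
  res <- validate_species(genomes, species, c(spA = ref))
  expect_true(res$kept[res$genome == "self"])
  expect_true(res$kept[res$genome == "near"])
  expect_false(res$kept[res$genome == "far"])

  expect_error(validate_species(genomes, c(self = "spB", near = "spB",
                                           far = "spB"),
                                c(spA = ref)),
               "missing reference")
})

test_that("dereplication clusters by single linkage and is idempotent", {
  set.seed(32)
  base <- icstools:::random_sequence(15000)
  twin <- base
  cousin1 <- icstools:::mutate_sequence(base, 0.01)
  cousin2 <- icstools:::mutate_sequence(cousin1, 0.01)
  genomes <- c(a = base, b = twin, c1 = cousin1, c2 = cousin2)

  # byte-identical genomes merge into one representative
  two <- dereplicate(genomes[c("a", "b")])
  expect_equal(length(two$representatives), 1)

  # 1% divergence separates strains at the 99.8 threshold
  three <- dereplicate(c(a = base, c1 = cousin1, c2 = cousin2))
  expect_equal(length(three$representatives), 3)

  # idempotence: dereplicating the representatives changes nothing
  again <- dereplicate(three$representatives)
  expect_setequal(names(again$representatives),
                  names(three$representatives))
})

test_that("dereplication component count matches a graph oracle", {
  set.seed(33)
  base <- icstools:::random_sequence(8000)
  genomes <- c(
    g1 = base,
    g2 = icstools:::mutate_sequence(base, 0.0005),  # links to g1
    g3 = icstools:::mutate_sequence(base, 0.01),    # own component
    g4 = icstools:::mutate_sequence(base, 0.05)     # own component
  )
  k <- 23
  kmers <- lapply(genomes, canonical_kmers, k = k)
  n <- length(genomes)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      kmer_identity(kmers[[i]], kmers[[j]], k = k) > 99.8
  }
  # connected components by repeated BFS
  seen <- rep(FALSE, n)
  n_comp <- 0
  for (i in 1:n) {
    if (seen[i]) next
    n_comp <- n_comp + 1
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  res <- dereplicate(genomes, k = k)
  expect_equal(length(res$representatives), n_comp)
})

test_that("database construction yields disjoint specific k-mer sets", {
  gs <- gen_strain_genomes(strain_spec(
    n_species = 2, strains_per_species = 2, genome_length = 10000,
    inter_species_divergence = 0.1, intra_species_divergence = 0.01,
    seed = 34
  ))
  species <- stats::setNames(gs$truth$species, gs$truth$genome)
  db <- build_database(gs$genomes, species)

  for (s in names(db$species)) {
    ps <- db$species[[s]]$ps
    if (length(ps) > 1) {
      for (i in 1:(length(ps) - 1)) for (j in (i + 1):length(ps)) {
        expect_equal(length(intersect(ps[[i]], ps[[j]])), 0)
      }
    }
  }
  sp_sets <- lapply(db$species, `[[`, "species_specific")
  expect_equal(length(intersect(sp_sets[[1]], sp_sets[[2]])), 0)

  # single species, single PS: specific set = all canonical k-mers
  one <- build_database(gs$genomes[1], species[1])
  expect_setequal(one$species[[1]]$ps[[1]],
                  canonical_kmers(gs$genomes[[1]], k = 23))

  # identical genomes claimed as two species are mutually undetectable
  dup <- c(x = gs$genomes[[1]], y = gs$genomes[[1]])
  expect_warning(db2 <- build_database(dup, c(x = "sp1", y = "sp2")),
                 "undetectable")
  expect_equal(length(db2$species$sp1$species_specific), 0)
  expect_equal(length(db2$species$sp2$species_specific), 0)
})

test_that("unrelated genomes share essentially no k-mers", {
  set.seed(35)
  a <- icstools:::random_sequence(50000)
  b <- icstools:::random_sequence(50000)
  ka <- canonical_kmers(a, k = 23)
  kb <- canonical_kmers(b, k = 23)
  # expected collisions ~ |A||B|/4^23 << 1
  expect_lte(length(intersect(ka, kb)), 1)
})
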