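#' Specify a synthetic infant gut community
#'
#' A community specification describes a mixture of community state types
#' (CSTs): each state is dominated by one or two taxa at a stated mean percent
#' abundance, carries a mixing weight (its expected share of samples) and a
#' host-group composition over HI (healthy urbanized), PI (preterm or
#' critically ill) and RI (rural) infants. Samples are later drawn from a
#' per-state Dirichlet distribution whose concentration vector places the
#' requested mean mass on the dominant taxa.
#'
#' @param n_samples Number of samples to generate.
#' @param icst_defs List of state definitions. Each element is a list with
#'   `name` (character), `dominant` (named numeric vector of mean percent
#'   abundances, names are taxa), `mix` (named numeric vector over
#'   `c("HI","PI","RI")`, summing to 1) and `weight` (mixing weight).
#' @param background_taxa Number of additional low-abundance filler taxa
#'   shared by all states.
#' @param dirichlet_concentration Total Dirichlet concentration (precision);
#'   larger values give tighter, better-separated states.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#'
#' @return An object of class `community_spec`.
#' @seealso [gen_community()], [default_icst_defs()]
#' @export
community_spec <- function(n_samples, icst_defs,
                           background_taxa = 20,
                           dirichlet_concentration = 60,
                           seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("invalid 'n_samples': must be a positive count")
  }
  if (!is.list(icst_defs) || length(icst_defs) == 0) {
    stop("invalid 'icst_defs': must be a nonempty list")
  }
  if (n_samples < length(icst_defs)) {
    stop("invalid 'n_samples': fewer samples than community states")
  }
  if (background_taxa < 0) stop("invalid 'background_taxa': must be >= 0")
  if (dirichlet_concentration <= 0) {
    stop("invalid 'dirichlet_concentration': must be positive")
  }
  weights <- vapply(icst_defs, function(d) d$weight %||% 1, numeric(1))
  weights <- weights / sum(weights)
  for (d in icst_defs) {
    dom <- d$dominant
    if (is.null(dom) || is.null(names(dom)) || any(names(dom) == "")) {
      stop("invalid 'icst_defs': each state needs a named 'dominant' vector")
    }
    if (any(dom <= 0) || any(dom > 100) || sum(dom) > 100) {
      stop("invalid 'icst_defs': dominant mean percents must lie in (0,100] ",
           "and sum to at most 100 (state ", d$name, ")")
    }
    mix <- d$mix %||% c(HI = 1 / 3, PI = 1 / 3, RI = 1 / 3)
    if (abs(sum(mix) - 1) > 1e-9) {
      stop("invalid 'icst_defs': group mix must sum to 1 (state ", d$name, ")")
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), icst_defs = icst_defs,
         weights = weights, background_taxa = as.integer(background_taxa),
         dirichlet_concentration = dirichlet_concentration,
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Default community-state definitions for the synthetic generator
#'
#' Eight states mirroring the composition reported for the eight major infant
#' community state types in a large published survey of 10,935 infant gut
#' metagenomes: each state is dominated by one or two of the 17 core species,
#' the host-group mixes follow the printed HI/PI/RI percentages, and the
#' mixing weights follow the printed state sizes.
#'
#' @return A list suitable for the `icst_defs` argument of [community_spec()].
#' @export
default_icst_defs <- function() {
  def <- function(name, dominant, mix, weight) {
    list(name = name, dominant = dominant, mix = mix / sum(mix),
         weight = weight)
  }
  list(
    def("BI", c("Bifidobacterium longum" = 45),
        c(HI = 68, PI = 19, RI = 14), 2198),
    def("PR", c("Prevotella copri" = 30, "Prevotella spp." = 20),
        c(HI = 42, PI = 12, RI = 46), 1981),
    def("ES", c("Escherichia coli" = 45),
        c(HI = 29, PI = 65, RI = 6), 1818),
    def("BI/EN", c("Bifidobacterium breve" = 28, "Enterobacter hormaechei" = 20),
        c(HI = 50, PI = 49, RI = 1), 1216),
    def("EN", c("Enterococcus faecalis" = 45),
        c(HI = 15, PI = 85, RI = 0), 980),
    def("KL/VE", c("Klebsiella michiganensis" = 28, "Veillonella parvula" = 20),
        c(HI = 31, PI = 69, RI = 1), 873),
    def("KL", c("Klebsiella pneumoniae" = 45),
        c(HI = 17, PI = 83, RI = 0), 735),
    def("ST", c("Staphylococcus epidermidis" = 45),
        c(HI = 13, PI = 87, RI = 0), 569)
  )
}

#' Generate a synthetic community abundance table
#'
#' Draws each sample from its community state's Dirichlet distribution: the
#' concentration vector allocates `dominant` mean percent mass to the state's
#' dominant taxa and spreads the remainder uniformly over all other taxa.
#' Abundances are reported as percentages; every sample column sums to 100.
#'
#' @param spec A [community_spec()].
#' @return A list with `abundance` (wide tibble: `taxon` column + one column
#'   per sample, percent abundances) and `metadata` (tibble with `sample`,
#'   `group`, `icst_true`).
#' @examples
#' sim <- gen_community(community_spec(
#'   n_samples = 12,
#'   icst_defs = default_icst_defs()[1:2],
#'   seed = 42
#' ))
#' colSums(sim$abundance[, -1])
#' @export
gen_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  dominant_taxa <- unique(unlist(lapply(spec$icst_defs,
                                        function(d) names(d$dominant))))
  bg <- if (spec$background_taxa > 0) {
    sprintf("background_taxon_%02d", seq_len(spec$background_taxa))
  } else {
    character(0)
  }
  taxa <- c(dominant_taxa, bg)
  n <- spec$n_samples
  conc <- spec$dirichlet_concentration

  with_seed(spec$seed, {
    state_idx <- sample.int(length(spec$icst_defs), n, replace = TRUE,
                            prob = spec$weights)
    groups <- character(n)
    values <- matrix(0, nrow = length(taxa), ncol = n,
                     dimnames = list(taxa, sprintf("sample_%04d", seq_len(n))))
    for (i in seq_len(n)) {
      d <- spec$icst_defs[[state_idx[i]]]
      mix <- d$mix %||% c(HI = 1 / 3, PI = 1 / 3, RI = 1 / 3)
      groups[i] <- sample(names(mix), 1, prob = mix)
      alpha <- rep(0, length(taxa))
      names(alpha) <- taxa
      dom_frac <- sum(d$dominant) / 100
      alpha[names(d$dominant)] <- conc * d$dominant / 100
      others <- setdiff(taxa, names(d$dominant))
      if (length(others) > 0 && dom_frac < 1) {
        alpha[others] <- conc * (1 - dom_frac) / length(others)
      } else if (length(others) == 0 && dom_frac < 1) {
        # no non-dominant taxa to absorb the remainder: renormalize dominants
        alpha[names(d$dominant)] <- conc * d$dominant / sum(d$dominant)
      }
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      g[alpha == 0] <- 0
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      values[, i] <- 100 * g / sum(g)
    }
    abundance <- tibble::as_tibble(values, rownames = "taxon")
    metadata <- tibble::tibble(
      sample = colnames(values),
      group = groups,
      icst_true = vapply(spec$icst_defs[state_idx],
                         function(d) d$name, character(1))
    )
    list(abundance = abundance, metadata = metadata)
  })
}

#' Specify a set of synthetic strain genomes
#'
#' Genomes are organised as species (descended from a common root mutated at
#' `inter_species_divergence`) each carrying `strains_per_species` strains
#' (population subspecies) mutated from the species ancestor at
#' `intra_species_divergence`. Mutations are i.i.d. substitutions with no
#' indels, so pairwise identity and k-mer retention are analytically
#' predictable.
#'
#' @param n_species,strains_per_species Counts.
#' @param genome_length Genome length in bases (>= 1000).
#' @param inter_species_divergence,intra_species_divergence Per-base
#'   substitution fractions; must satisfy 0 < intra < inter < 1.
#' @param seed Integer seed.
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(n_species = 2, strains_per_species = 3,
                        genome_length = 20000,
                        inter_species_divergence = 0.10,
                        intra_species_divergence = 0.002,
                        seed = 1L) {
  if (genome_length < 1000) stop("invalid 'genome_length': must be >= 1000")
  if (n_species < 1 || strains_per_species < 1) {
    stop("invalid species/strain counts")
  }
  if (!(intra_species_divergence >= 0 &&
        intra_species_divergence < inter_species_divergence &&
        inter_species_divergence < 1)) {
    stop("divergence ordering violated: need ",
         "0 <= intra_species_divergence < inter_species_divergence < 1")
  }
  structure(
    list(n_species = as.integer(n_species),
         strains_per_species = as.integer(strains_per_species),
         genome_length = as.integer(genome_length),
         inter_species_divergence = inter_species_divergence,
         intra_species_divergence = intra_species_divergence,
         seed = as.integer(seed)),
    class = "strain_spec"
  )
}

#' Generate synthetic strain genomes
#'
#' @param spec A [strain_spec()].
#' @return A list with `genomes` (named character vector of sequences, names
#'   `sp<species>_ps<strain>`) and `truth` (tibble: `genome`, `species`,
#'   `ps`).
#' @export
gen_strain_genomes <- function(spec) {
  stopifnot(inherits(spec, "strain_spec"))
  with_seed(spec$seed, {
    root <- random_sequence(spec$genome_length)
    genomes <- character(0)
    truth <- list()
    for (s in seq_len(spec$n_species)) {
      species_id <- sprintf("sp%02d", s)
      ancestor <- mutate_sequence(root, spec$inter_species_divergence)
      for (p in seq_len(spec$strains_per_species)) {
        gid <- sprintf("%s_ps%02d", species_id, p)
        genomes[gid] <- mutate_sequence(ancestor,
                                        spec$intra_species_divergence)
        truth[[gid]] <- tibble::tibble(genome = gid, species = species_id,
                                       ps = gid)
      }
    }
    list(genomes = genomes, truth = dplyr::bind_rows(truth))
  })
}

#' Simulate shotgun reads from a genome mixture
#'
#' Reads start at uniform positions on either strand; each base is substituted
#' independently at `error_rate`. The per-genome read count is
#' `round(depth * genome_length / read_length)`. This is a substitution-only,
#' uniform-coverage simulator adequate for k-mer presence detection; it is not
#' an Illumina error model.
#'
#' @param genomes Named character vector of genome sequences.
#' @param depths Named numeric vector of fold coverages (names must match
#'   `genomes`); missing names default to 0.
#' @param read_length Read length in bases; must not exceed any sampled
#'   genome's length.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `sequence`, `origin`, `start`, `strand`.
#' @export
gen_reads <- function(genomes, depths, read_length = 100, error_rate = 0,
                      seed = 1L) {
  if (length(genomes) == 0) stop("empty mixture: no genomes supplied")
  if (is.null(names(genomes))) stop("'genomes' must be named")
  if (any(depths < 0, na.rm = TRUE)) stop("depths must be >= 0")
  depths <- depths[names(depths) %in% names(genomes)]
  with_seed(seed, {
    out <- list()
    for (g in names(genomes)) {
      depth <- if (g %in% names(depths)) depths[[g]] else 0
      if (depth <= 0) next
      L <- nchar(genomes[[g]])
      if (read_length > L) {
        stop("read_length exceeds length of genome ", g)
      }
      n_reads <- round(depth * L / read_length)
      if (n_reads == 0) next
      starts <- sample.int(L - read_length + 1, n_reads, replace = TRUE)
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- substring(genomes[[g]], starts, starts + read_length - 1)
      rc <- strands == "-"
      if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
      if (error_rate > 0) {
        seqs <- vapply(seqs, mutate_sequence, character(1),
                       rate = error_rate, USE.NAMES = FALSE)
      }
      out[[g]] <- tibble::tibble(
        read_id = sprintf("%s_read_%06d", g, seq_len(n_reads)),
        sequence = seqs, origin = g, start = starts, strand = strands
      )
    }
    if (length(out) == 0) {
      return(tibble::tibble(read_id = character(0), sequence = character(0),
                            origin = character(0), start = integer(0),
                            strand = character(0)))
    }
    dplyr::bind_rows(out)
  })
}

#' Specify a synthetic EC-number abundance matrix
#'
#' Samples belong to `n_clusters` latent enzymatic-profile clusters. A fixed
#' fraction of EC features is informative: each informative EC is elevated by
#' `effect_size` (log10 units) in one cluster. Abundances are log-normal and
#' each sample row is renormalized to relative abundances summing to 1.
#'
#' @param n_samples,n_ecs,n_clusters Counts (`n_ecs >= n_clusters >= 1`).
#' @param effect_size Log10-fold separation applied to informative ECs.
#' @param noise_sd Log10-scale standard deviation of the within-cluster noise.
#' @param informative_fraction Fraction of ECs that carry cluster signal.
#' @param covariates Names of nuisance covariates to simulate
#'   (subset of `c("age_days","delivery","feeding","antibiotics")`).
#' @param seed Integer seed.
#' @return An object of class `ec_spec`.
#' @export
ec_spec <- function(n_samples = 120, n_ecs = 80, n_clusters = 2,
                    effect_size = 1, noise_sd = 0.3,
                    informative_fraction = 0.3,
                    covariates = c("age_days", "delivery"),
                    seed = 1L) {
  if (n_clusters < 1) stop("invalid 'n_clusters': must be >= 1")
  if (n_ecs < n_clusters) stop("invalid 'n_ecs': need n_ecs >= n_clusters")
  if (n_clusters > n_samples) {
    stop("invalid spec: n_clusters exceeds n_samples")
  }
  if (noise_sd <= 0) stop("invalid 'noise_sd': must be positive")
  structure(
    list(n_samples = as.integer(n_samples), n_ecs = as.integer(n_ecs),
         n_clusters = as.integer(n_clusters), effect_size = effect_size,
         noise_sd = noise_sd, informative_fraction = informative_fraction,
         covariates = covariates, seed = as.integer(seed)),
    class = "ec_spec"
  )
}

#' Generate a synthetic EC-number relative-abundance matrix
#'
#' @param spec An [ec_spec()].
#' @return A list with `matrix` (tibble: `sample` column + one column per EC,
#'   rows summing to 1), `truth` (tibble: `sample`, `cluster`), `covariates`
#'   (tibble keyed by `sample`) and `informative_ecs` (tibble: `ec`,
#'   `cluster`).
#' @export
gen_ec_matrix <- function(spec) {
  stopifnot(inherits(spec, "ec_spec"))
  with_seed(spec$seed, {
    ecs <- unique(apply(matrix(sample(1:9, spec$n_ecs * 4, replace = TRUE),
                               ncol = 4), 1, paste, collapse = "."))
    while (length(ecs) < spec$n_ecs) {
      ecs <- unique(c(ecs, paste(sample(1:9, 4, replace = TRUE),
                                 collapse = ".")))
    }
    ecs <- ecs[seq_len(spec$n_ecs)]
    cluster <- rep(seq_len(spec$n_clusters), length.out = spec$n_samples)
    cluster <- sample(cluster)
    samples <- sprintf("sample_%04d", seq_len(spec$n_samples))

    n_inf <- round(spec$informative_fraction * spec$n_ecs)
    inf_idx <- if (n_inf > 0) sample.int(spec$n_ecs, n_inf) else integer(0)
    inf_cluster <- if (n_inf > 0) {
      sample(rep(seq_len(spec$n_clusters), length.out = n_inf))
    } else {
      integer(0)
    }

    mu <- stats::rnorm(spec$n_ecs, mean = 0, sd = 0.5)
    logx <- matrix(rep(mu, each = spec$n_samples),
                   nrow = spec$n_samples, ncol = spec$n_ecs)
    for (j in seq_along(inf_idx)) {
      in_cluster <- cluster == inf_cluster[j]
      logx[in_cluster, inf_idx[j]] <-
        logx[in_cluster, inf_idx[j]] + spec$effect_size
    }
    logx <- logx + matrix(stats::rnorm(length(logx), sd = spec$noise_sd),
                          nrow = spec$n_samples)
    x <- 10^logx
    x <- x / rowSums(x)
    dimnames(x) <- list(samples, ecs)

    covs <- tibble::tibble(sample = samples)
    if ("age_days" %in% spec$covariates) {
      covs$age_days <- stats::rpois(spec$n_samples, lambda = 180)
    }
    if ("delivery" %in% spec$covariates) {
      covs$delivery <- sample(c("vaginal", "cesarean"), spec$n_samples,
                              replace = TRUE)
    }
    if ("feeding" %in% spec$covariates) {
      covs$feeding <- sample(c("breast", "formula", "mixed"), spec$n_samples,
                             replace = TRUE)
    }
    if ("antibiotics" %in% spec$covariates) {
      covs$antibiotics <- sample(c("yes", "no"), spec$n_samples,
                                 replace = TRUE)
    }

    list(
      matrix = tibble::as_tibble(x, rownames = "sample"),
      truth = tibble::tibble(sample = samples, cluster = cluster),
      covariates = covs,
      informative_ecs = tibble::tibble(ec = ecs[inf_idx],
                                       cluster = inf_cluster)
    )
  })
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 80) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  names_vec <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- names_vec[as.integer(names(seqs))]
  toupper(seqs)
}

#' Write reads to a FASTQ file (Phred+33, constant quality)
#'
#' @param reads Tibble with `read_id` and `sequence` columns, as produced by
#'   [gen_reads()].
#' @param path Output path.
#' @param quality_char Single quality character applied to every base.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- rbind(paste0("@", reads$read_id),
                 reads$sequence,
                 "+",
                 vapply(nchar(reads$sequence),
                        function(n) strrep(quality_char, n), character(1)))
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble of reads
#'
#' @param path FASTQ file path.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(0), sequence = character(0)))
  }
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  tibble::tibble(
    read_id = sub("^@", "", lines[seq(1, length(lines), by = 4)]),
    sequence = toupper(lines[seq(2, length(lines), by = 4)])
  )
}
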