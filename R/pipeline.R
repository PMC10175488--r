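#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in order: community profiling (core-species
#' selection), community-state typing, strain database construction with PS
#' screening, and enzymatic-profile clustering. Each stage can be switched
#' off; a stage failure is recorded in the report and dependent stages are
#' skipped. With identical configuration and seed the report content (and
#' any written tables) is identical across runs.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{Integer seed, mandatory.}
#'     \item{abundance_path,metadata_path}{Optional TSV inputs; when absent
#'       a synthetic community is generated from `synth` settings.}
#'     \item{synth}{List passed to [community_spec()] (defaults: 400 samples,
#'       [default_icst_defs()]).}
#'     \item{profiles}{List of thresholds: `detection`, `top_n`,
#'       `prevalence_min`, `major_min`.}
#'     \item{icst}{List: `min_support`, `dominance`, `n_perm`.}
#'     \item{strain}{List or `FALSE` to skip: settings for [strain_spec()]
#'       plus `depth`, `min_fraction`, `min_kmers`.}
#'     \item{ec}{List or `FALSE` to skip: settings for [ec_spec()] plus
#'       `k_range`.}
#'     \item{out_dir}{Optional output directory for TSV/JSON artifacts.}
#'   }
#' @return A `pipeline_report` list: per-stage status and summaries, the
#'   parameters used, and the fitted objects in `$results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a 'seed'")
  seed <- as.integer(config$seed)
  for (p in c("abundance_path", "metadata_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("configured path does not exist: ", config[[p]])
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("icstools")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    stages = list()
  )
  results <- list()

  run_stage <- function(name, deps, fn) {
    failed_dep <- deps[vapply(deps, function(d) {
      !identical(report$stages[[d]]$status, "ok")
    }, logical(1))]
    if (length(failed_dep) > 0) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("dependency failed:",
                                                    failed_dep[1]))
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res$summary)
      results[[name]] <<- res$value
    }
    invisible(NULL)
  }

  run_stage("profiles", character(0), function() {
    if (!is.null(config$abundance_path)) {
      loaded <- read_abundance_table(config$abundance_path,
                                     config$metadata_path)
      abundance <- loaded$abundance
      metadata <- loaded$metadata
    } else {
      synth <- config$synth %||% list()
      spec <- community_spec(
        n_samples = synth$n_samples %||% 400,
        icst_defs = synth$icst_defs %||% default_icst_defs(),
        background_taxa = synth$background_taxa %||% 20,
        dirichlet_concentration = synth$dirichlet_concentration %||% 60,
        seed = seed
      )
      sim <- gen_community(spec)
      abundance <- sim$abundance
      metadata <- sim$metadata
    }
    pp <- config$profiles %||% list()
    report_tbl <- core_species_report(
      abundance,
      detection = pp$detection %||% 0.05,
      top_n = pp$top_n %||% 3,
      prevalence_min = pp$prevalence_min %||% 10,
      major_min = pp$major_min %||% 3
    )
    core <- report_tbl$taxon[report_tbl$is_core]
    if (!is.null(out_dir)) {
      readr::write_tsv(report_tbl, file.path(out_dir, "core_species.tsv"),
                       progress = FALSE)
    }
    list(value = list(abundance = abundance, metadata = metadata,
                      core = core, report = report_tbl),
         summary = list(n_samples = ncol(abundance) - 1,
                        n_taxa = nrow(abundance),
                        n_core = length(core)))
  })

  run_stage("icst", "profiles", function() {
    prof <- results$profiles
    if (length(prof$core) < 2) stop("fewer than 2 core species")
    core_tbl <- prof$abundance[prof$abundance$taxon %in% prof$core, ]
    ii <- config$icst %||% list()
    fit <- fit_icsts(core_tbl, prof$metadata,
                     min_support = ii$min_support %||% 0.0457,
                     dominance = ii$dominance %||% 10)
    assigned <- fit$assignments$cluster != "unassigned"
    perm <- NULL
    if (sum(assigned) > 4 && nrow(fit$clusters) >= 2 &&
        all(table(fit$assignments$cluster[assigned]) >= 2)) {
      d <- bray_curtis(core_tbl[, c(TRUE, assigned), drop = FALSE])
      perm <- permanova(d, fit$assignments$icst[assigned],
                        n_perm = ii$n_perm %||% 1000, seed = seed)
    }
    if (!is.null(out_dir)) {
      readr::write_tsv(fit$assignments,
                       file.path(out_dir, "icst_assignments.tsv"),
                       progress = FALSE)
      readr::write_tsv(fit$clusters,
                       file.path(out_dir, "icst_clusters.tsv"),
                       progress = FALSE)
    }
    list(value = list(fit = fit, permanova = perm),
         summary = list(n_icsts = nrow(fit$clusters),
                        icsts = fit$clusters$icst,
                        permanova_p = if (!is.null(perm)) perm$p_value))
  })

  strain_cfg <- config$strain %||% list()
  if (!isFALSE(strain_cfg)) {
    run_stage("strains", character(0), function() {
      spec <- strain_spec(
        n_species = strain_cfg$n_species %||% 2,
        strains_per_species = strain_cfg$strains_per_species %||% 2,
        genome_length = strain_cfg$genome_length %||% 5000,
        inter_species_divergence =
          strain_cfg$inter_species_divergence %||% 0.10,
        intra_species_divergence =
          strain_cfg$intra_species_divergence %||% 0.01,
        seed = seed + 1L
      )
      gs <- gen_strain_genomes(spec)
      k <- strain_cfg$k %||% 23
      species_map <- stats::setNames(gs$truth$species, gs$truth$genome)
      db <- build_database(gs$genomes, species_map, k = k)
      depth <- strain_cfg$depth %||% 10
      read_sets <- list(
        sampleA = gen_reads(gs$genomes,
                            stats::setNames(c(depth,
                                              rep(0, length(gs$genomes) - 1)),
                                            names(gs$genomes)),
                            seed = seed + 2L),
        sampleB = gen_reads(gs$genomes,
                            stats::setNames(rep(depth, length(gs$genomes)),
                                            names(gs$genomes)),
                            seed = seed + 3L)
      )
      calls <- screen_samples(read_sets, db,
                              min_fraction = strain_cfg$min_fraction %||% 0.10,
                              min_kmers = strain_cfg$min_kmers %||% 50)
      if (!is.null(out_dir)) {
        readr::write_tsv(calls, file.path(out_dir, "ps_calls.tsv"),
                         progress = FALSE)
      }
      list(value = list(db = db, calls = calls, truth = gs$truth),
           summary = list(n_species = spec$n_species,
                          n_ps = nrow(gs$truth),
                          n_calls = nrow(calls)))
    })
  }

  ec_cfg <- config$ec %||% list()
  if (!isFALSE(ec_cfg)) {
    run_stage("ec", character(0), function() {
      spec <- ec_spec(
        n_samples = ec_cfg$n_samples %||% 80,
        n_ecs = ec_cfg$n_ecs %||% 60,
        n_clusters = ec_cfg$n_clusters %||% 2,
        effect_size = ec_cfg$effect_size %||% 1,
        noise_sd = ec_cfg$noise_sd %||% 0.3,
        seed = seed + 4L
      )
      sim <- gen_ec_matrix(spec)
      k_range <- ec_cfg$k_range %||% 2:6
      epm <- cluster_profiles(sim$matrix, k_range = k_range)
      if (!is.null(out_dir)) {
        readr::write_tsv(epm$labels, file.path(out_dir, "ep_labels.tsv"),
                         progress = FALSE)
      }
      list(value = list(model = epm, sim = sim),
           summary = list(k_selected = epm$k))
    })
  }

  report$results <- results
  failed <- vapply(report$stages, function(s) {
    identical(s$status, "failed")
  }, logical(1))
  report$ok <- !any(failed)
  if (!is.null(out_dir)) {
    serializable <- report[setdiff(names(report), "results")]
    jsonlite::write_json(serializable, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, "): ",
      if (x$ok) "ok" else "FAILED", "\n", sep = "")
  for (nm in names(x$stages)) {
    cat("  ", nm, ": ", x$stages[[nm]]$status, "\n", sep = "")
  }
  invisible(x)
}
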