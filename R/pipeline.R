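#' Configuration for an end-to-end pipeline run
#'
#' @param seeds named integer seeds for the four stochastic stages
#'   (`cohort`, `gan`, `bench`, `sor`).
#' @param spec a [cohort_spec][default_spec()] or a path to a JSON spec.
#' @param stages character vector of stages to run, in pipeline order;
#'   any of `"synth"`, `"gan"`, `"fidelity"`, `"bench"`, `"sor"`.
#'   Later stages depend on earlier ones: disabling `synth` or `gan`
#'   disables everything downstream of them.
#' @param gan a [gan_config()] (its seed is overridden by `seeds["gan"]`).
#' @param sor a [sor_config()] (its seed is overridden by `seeds["sor"]`).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seeds = c(cohort = 1L, gan = 2L, bench = 3L,
                                      sor = 4L),
                            spec = default_spec(),
                            stages = c("synth", "gan", "fidelity", "bench",
                                       "sor"),
                            gan = gan_config(), sor = sor_config()) {
  if (is.character(spec)) spec <- read_spec(spec)
  stopifnot(all(c("cohort", "gan", "bench", "sor") %in% names(seeds)),
            all(stages %in% c("synth", "gan", "fidelity", "bench", "sor")))
  structure(list(seeds = vapply(seeds, as.integer, integer(1)), spec = spec,
                 stages = stages, gan = gan, sor = sor),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-cohort generation, conditional-GAN
#' training and sampling, the real-vs-generated fidelity report, the
#' four-classifier bench on the pooled cohort, and the simulated-odds-ratio
#' presets with the bench's random forest. All tabular outputs are written
#' as CSV under `out_dir` and a JSON manifest records inputs, seeds,
#' versions and the MD5 hash of every output, so a rerun with the same
#' configuration reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  skipped <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      skipped <<- c(skipped, name)
      message(sprintf("[pipeline] stage %s: skipped", name))
      return(invisible(NULL))
    }
    message(sprintf("[pipeline] stage %s: running", name))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  run_stage("synth", function() {
    state$real <- sample_cohort(config$spec, seed = config$seeds["cohort"])
    f <- file.path(out_dir, "cohort_real.csv")
    write_cohort(state$real, f)
    outputs <<- c(outputs, f)
  })

  run_stage("gan", function() {
    if (is.null(state$real)) stop("requires the synth stage")
    gcfg <- config$gan
    gcfg$seed <- unname(config$seeds["gan"])
    state$gan <- gan_fit(state$real, gcfg)
    state$fake <- gan_generate(state$gan, nrow(state$real))
    fdir <- file.path(out_dir, "gan_bundle")
    gan_save(state$gan, fdir)
    f <- file.path(out_dir, "cohort_generated.csv")
    write_cohort(state$fake, f)
    outputs <<- c(outputs, f, file.path(fdir, "log.csv"))
  })

  run_stage("fidelity", function() {
    if (is.null(state$fake)) stop("requires the gan stage")
    rep <- compare_cohorts(state$real, state$fake)
    f <- file.path(out_dir, "fidelity_report.csv")
    write_fidelity_report(rep, f)
    outputs <<- c(outputs, f)
  })

  run_stage("bench", function() {
    pooled <- if (is.null(state$fake)) state$real else {
      pool_cohorts(state$real, state$fake)
    }
    if (is.null(pooled)) stop("requires the synth stage")
    state$bench <- bench(pooled, seed = unname(config$seeds["bench"]))
    f <- file.path(out_dir, "bench_table.csv")
    write_bench_table(state$bench, f)
    outputs <<- c(outputs, f)
  })

  run_stage("sor", function() {
    if (is.null(state$bench)) stop("requires the bench stage")
    model <- state$bench$models$rf
    if (is.null(model)) stop("the sor stage needs the random forest model")
    presets <- condition_presets()
    for (nm in names(presets)) {
      scfg <- config$sor
      scfg$seed <- unname(config$seeds["sor"]) + match(nm, names(presets))
      res <- compute_sor(model, presets[[nm]]$target,
                         presets[[nm]]$reference, scfg, config$spec)
      f <- file.path(out_dir, sprintf("sor_%s.csv", nm))
      write_sor(res, f)
      outputs <<- c(outputs, f)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("telepain")),
    r_version = as.character(getRversion()),
    seeds = as.list(config$seeds),
    stages_run = intersect(config$stages,
                           c("synth", "gan", "fidelity", "bench", "sor")),
    stages_skipped = skipped,
    outputs = lapply(outputs, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Pool two cohorts into one, renumbering patient ids
#'
#' @param a,b `patient_cohort`s with identical schema.
#' @return a pooled `patient_cohort`.
#' @export
pool_cohorts <- function(a, b) {
  pooled <- rbind(as.data.frame(a), as.data.frame(b))
  pooled$patient_id <- seq_len(nrow(pooled))
  class(pooled) <- c("patient_cohort", "data.frame")
  pooled
}
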