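#' Pipeline configuration
#'
#' One master seed is fanned out to dataset generation, the train/test split
#' and the swarm, so the whole run is reproducible from `(config, seed)`.
#'
#' @param seed master seed.
#' @param generator a `teac_generator_config`; its own seed is overridden by
#'   the fanned-out dataset seed unless `keep_generator_seed = TRUE`.
#' @param trainer a `trainer_config`; its swarm seed is likewise derived.
#' @param train_fraction train share of the 75/25 partition.
#' @param norm_scope `"full"` (normalize before splitting) or `"train"`.
#' @param keep_generator_seed keep `generator$seed` instead of deriving it.
#' @return a `teac_pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            generator = generator_config(),
                            trainer = NULL,
                            train_fraction = 0.75,
                            norm_scope = c("full", "train"),
                            keep_generator_seed = FALSE) {
  norm_scope <- match.arg(norm_scope)
  gen <- generator
  if (!keep_generator_seed) {
    gen <- generator_config(
      n_samples = generator$n_samples,
      target_correlations = generator$target_correlations,
      max_r2 = generator$max_r2,
      feature_means = generator$feature_means,
      feature_sds = generator$feature_sds,
      target_mean = generator$target_mean,
      target_sd = generator$target_sd,
      seed = derive_seed(seed, "dataset")
    )
  }
  if (is.null(trainer)) {
    trainer <- trainer_config(seed = derive_seed(seed, "trainer"))
  }
  structure(
    list(seed = as.integer(seed), generator = gen, trainer = trainer,
         train_fraction = train_fraction, norm_scope = norm_scope),
    class = "teac_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys `seed`, `train_fraction`, `norm_scope`, and nested
#' `generator` / `trainer` maps mirroring the constructor arguments
#' (generator: `n_samples`, `target_correlations`, `max_r2`, `feature_means`,
#' `feature_sds`, `target_mean`, `target_sd`; trainer: `H`, `activation`,
#' `ridge`, `n_particles`, `max_iterations`, `inertia`, `c1`, `c2`).
#' Unspecified fields keep their documented defaults.
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- if (is.null(doc$seed)) 42L else as.integer(doc$seed)
  gen_args <- doc$generator %||% list()
  for (nm in c("target_correlations", "feature_means", "feature_sds")) {
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  }
  gen <- do.call(generator_config, gen_args)
  trainer <- if (is.null(doc$trainer)) NULL else {
    do.call(trainer_config, c(doc$trainer,
                              list(seed = derive_seed(seed, "trainer"))))
  }
  pipeline_config(
    seed = seed, generator = gen, trainer = trainer,
    train_fraction = doc$train_fraction %||% 0.75,
    norm_scope = doc$norm_scope %||% "full"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full generate / normalize / split / train / evaluate pipeline
#'
#' Executes every stage under the fanned-out seeds and, when `out_dir` is
#' given, writes `dataset.csv`, `model.json`, `report.json` and plot-ready
#' `williams.csv` / `sensitivity.csv` tables. Any stage error aborts with the
#' stage name and removes partially written artifacts.
#'
#' @param config a `teac_pipeline_config`.
#' @param out_dir output directory, created if needed; NULL skips writing.
#' @param dataset optionally, a pre-loaded `teac_dataset` to analyse instead
#'   of generating one (e.g. from [read_dataset()]).
#' @param verbose print stage progress to stderr.
#' @return a `teac_run_report` list: `config_echo`, `metrics` (train/test/
#'   total rows), `ad` (flag counts, suspected rows with phase labels,
#'   warning leverage), `sensitivity`, `fitness_history`, `seeds`,
#'   `artifacts`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "teac_pipeline_config"))
  written <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  dataset <- stage("generate", dataset %||% generate_dataset(config$generator))
  n <- length(dataset$target)
  split <- stage("split", make_split(n, config$train_fraction,
                                     seed = derive_seed(config$seed, "split")))
  norm_params <- stage("normalize",
                       fit_normalizer(dataset, config$norm_scope, split))
  fit <- stage("train", train_pso_elm(dataset, split, norm_params,
                                      config$trainer))
  phases <- stage("evaluate", evaluate_phases(fit$model, dataset, split,
                                              norm_params))
  ad <- stage("ad", {
    normed <- normalize_dataset(dataset, norm_params)
    williams_ad(normed$features[split$train, , drop = FALSE], normed$features,
                dataset$target - phases$predictions, phases$total$rmse)
  })
  sens <- stage("sensitivity", relevancy_factors(dataset))

  phase_of <- ifelse(seq_len(n) %in% split$train, "train", "test")
  suspected <- which(ad$flags != "in_domain")
  report <- structure(
    list(
      config_echo = list(
        seed = config$seed, n_samples = n,
        train_fraction = config$train_fraction,
        norm_scope = config$norm_scope,
        max_r2 = config$generator$max_r2,
        target_correlations = as.list(config$generator$target_correlations),
        H = config$trainer$H, activation = config$trainer$activation,
        ridge = config$trainer$ridge,
        n_particles = config$trainer$pso$n_particles,
        max_iterations = config$trainer$pso$max_iterations
      ),
      metrics = lapply(phases[c("train", "test", "total")],
                       function(m) m[c("r2", "mre_percent", "mse", "rmse",
                                       "std", "n")]),
      ad = list(
        warning_leverage = ad$warning_leverage,
        flag_counts = as.list(table(ad$flags)),
        suspected_rows = lapply(suspected, function(i) {
          list(row = i, phase = phase_of[i], flag = as.character(ad$flags[i]),
               leverage = ad$leverages[i], std_residual = ad$std_residuals[i])
        })
      ),
      sensitivity = as.list(sens$relevancy),
      fitness_history = fit$fitness_history,
      seeds = list(master = config$seed,
                   dataset = config$generator$seed,
                   split = split$seed,
                   pso = config$trainer$pso$seed),
      artifacts = list()
    ),
    class = "teac_run_report"
  )

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        dataset = file.path(out_dir, "dataset.csv"),
        model = file.path(out_dir, "model.json"),
        williams = file.path(out_dir, "williams.csv"),
        sensitivity = file.path(out_dir, "sensitivity.csv"),
        report = file.path(out_dir, "report.json")
      )
      written <- unlist(paths, use.names = FALSE)
      write_dataset(dataset, paths$dataset)
      write_elm_model(fit$model, paths$model, norm_params)
      utils::write.table(
        data.frame(row = seq_len(n), phase = phase_of,
                   leverage = ad$leverages, std_residual = ad$std_residuals,
                   flag = as.character(ad$flags)),
        paths$williams, sep = ",", row.names = FALSE, quote = FALSE, eol = "\n")
      utils::write.table(
        data.frame(feature = names(sens$relevancy),
                   relevancy = unname(sens$relevancy)),
        paths$sensitivity, sep = ",", row.names = FALSE, quote = FALSE,
        eol = "\n")
      report$artifacts <- paths
      jsonlite::write_json(unclass(report), paths$report, digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  report
}

#' @export
print.teac_run_report <- function(x, ...) {
  cat("PSO-ELM run report (seed", x$seeds$master, ")\n")
  for (ph in names(x$metrics)) {
    m <- x$metrics[[ph]]
    cat(sprintf("  %-6s n=%-4d R2=%.3f MRE%%=%.2f MSE=%.2f RMSE=%.2f STD=%.2f\n",
                ph, m$n, m$r2, m$mre_percent, m$mse, m$rmse, m$std))
  }
  cat(sprintf("  AD: h* = %.4f, %d suspected row(s)\n",
              x$ad$warning_leverage, length(x$ad$suspected_rows)))
  cat("  relevancy:",
      paste(sprintf("%s=%+.2f", names(x$sensitivity),
                    unlist(x$sensitivity)), collapse = " "), "\n")
  invisible(x)
}
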