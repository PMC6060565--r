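#' Load a CSV of state labels into a dataset
#'
#' The header must contain every schema variable; cells are state labels
#' and empty cells are missing. Unknown labels raise an error naming the
#' column.
#'
#' @param path CSV file path.
#' @param schema A [bn_schema()].
#' @param weights_col Optional name of a numeric per-record weight column.
#' @return A [bn_dataset()].
#' @export
load_dataset <- function(path, schema, weights_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, colClasses = "character", na.strings = "",
                          data.table = FALSE)
  missing_cols <- setdiff(schema_names(schema), names(df))
  if (length(missing_cols))
    stop("file is missing columns: ", paste(missing_cols, collapse = ", "))
  w <- if (!is.null(weights_col)) as.numeric(df[[weights_col]]) else 1
  bn_dataset(schema, df[schema_names(schema)], w)
}

#' Assemble a pipeline configuration
#'
#' Describes a full synthetic-or-file run of the analysis: data source,
#' split, learner settings, imputation, validation, association screen and
#' profile report.
#'
#' @param generator A [generator_config()] (used when `input_csv` is
#'   `NULL`).
#' @param n Records to simulate when generating.
#' @param input_csv Optional path to a labelled CSV to load instead of
#'   simulating (requires `schema`).
#' @param schema Schema for `input_csv`; defaults to the generator's.
#' @param target Target variable; defaults to the schema's target role.
#' @param test_fraction Held-out fraction for the split (default 0.2).
#' @param alpha Laplace smoothing (default 1).
#' @param passes Imputation passes (default 1).
#' @param candidates Named list of structure learners (default naive Bayes
#'   and TAN).
#' @param grid Profile grid (default [default_profile_grid()] when the
#'   schema has the NHIS profile variables, else `NULL` to skip profiles).
#' @param threshold_pct Profile flagging threshold (default 3.07).
#' @param mode Observational mode for profiles (default `"fixed"`).
#' @param mc_samples Monte-Carlo samples for fixed-mode queries.
#' @param seed Master seed; stage seeds are derived from it and logged.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `bbn_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            n = 100000,
                            input_csv = NULL,
                            schema = NULL,
                            target = NULL,
                            test_fraction = 0.2,
                            alpha = 1,
                            passes = 1,
                            candidates = list(nb = learn_naive_bayes,
                                              tan = learn_tan),
                            grid = NULL,
                            threshold_pct = 3.07,
                            mode = "fixed",
                            mc_samples = 20000,
                            seed = 1L,
                            out_dir = tempfile("bbn_run_")) {
  schema <- schema %||% generator$schema
  target <- target %||% schema_target(schema)
  if (length(target) != 1L) stop("config needs exactly one target variable")
  if (is.null(grid) &&
      all(c("AGE", "SEX", "HRSLEEP", "MOD10DMIN", "MOD10FWK",
            "VIG10DMIN", "VIG10FWK") %in% schema_names(schema)))
    grid <- default_profile_grid()
  structure(list(generator = generator, n = n, input_csv = input_csv,
                 schema = schema, target = target,
                 test_fraction = test_fraction, alpha = alpha,
                 passes = passes, candidates = candidates, grid = grid,
                 threshold_pct = threshold_pct, mode = mode,
                 mc_samples = mc_samples, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "bbn_pipeline_config")
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Stages: generate (or load) -> split -> learn candidate structures and
#' select by total MDL -> impute missing cells -> validate on the held-out
#' split -> association screen -> profile report. Artifacts written to
#' `config$out_dir`: `network.json`, `scores.tsv`, `associations.tsv`,
#' `validation.json`, `profiles.tsv` and `pipeline_log.txt` (stage record
#' counts and every seed used). Any stage failure aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the learnt network, score table,
#'   association table, validation report, profile report and artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bbn_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list(sample = config$seed, missing = config$seed + 1L,
                split = config$seed + 2L, query = config$seed + 3L)
  note("seeds: ", paste(names(seeds), unlist(seeds), sep = "=",
                        collapse = " "))

  ds <- stage("load", {
    if (!is.null(config$input_csv)) {
      d <- load_dataset(config$input_csv, config$schema)
      note("load: ", n_records(d), " records from ", config$input_csv)
      d
    } else {
      net0 <- build_ground_truth(config$generator)
      d <- forward_sample(net0, config$n, seed = seeds$sample)
      d <- inject_missingness(d, config$generator$missingness,
                              seed = seeds$missing)
      note("generate: ", n_records(d), " records, ",
           sum(is.na(d$x)), " missing cells")
      d
    }
  })

  parts <- stage("split", train_test_split(ds, config$test_fraction,
                                           seed = seeds$split))
  note("split: ", n_records(parts$train), " learning / ",
       n_records(parts$test), " test records")

  sel <- stage("learn", select_structure(parts$train, config$target,
                                         config$candidates, config$alpha))
  note("learn: selected '", sel$best, "' by total MDL")

  train_imp <- stage("impute", impute_missing(parts$train, sel$net,
                                              passes = config$passes,
                                              alpha = config$alpha))
  net <- stage("refit", fit_cpts(sel$net$edges, train_imp, config$alpha,
                                 schema = config$schema))
  note("impute: ", attr(train_imp, "diagnostics")$cells_imputed,
       " cells imputed; CPTs refit")

  test_imp <- stage("impute-test", impute_missing(parts$test, net,
                                                  passes = 1,
                                                  alpha = config$alpha))
  report <- stage("validate", validate_classifier(net, test_imp,
                                                  config$target))
  note(sprintf(paste0("validate: precision %.2f%% reliability %.2f%% ",
                      "ROC %.2f%% lift %.2f%%"),
               report$precision_pct, report$reliability_pct,
               report$roc_index_pct, report$lift_index_pct))

  assoc <- stage("associations", association_table(train_imp, config$target))

  profiles <- NULL
  profile_report <- NULL
  if (!is.null(config$grid)) {
    profiles <- stage("profiles",
                      enumerate_profiles(net, config$grid,
                                         target = config$target,
                                         mode = config$mode,
                                         threshold_pct = config$threshold_pct,
                                         mc_samples = config$mc_samples,
                                         seed = seeds$query))
    profile_report <- if (all(c("Age", "Sex", "PA", "Sleep") %in%
                              names(config$grid)))
      stage("profiles", render_profile_report(profiles))
    else as.data.frame(profiles)
    note("profiles: ", nrow(profiles), " cells, ",
         sum(profiles$below_threshold), " below ",
         config$threshold_pct, "%")
  }

  paths <- list(network = file.path(config$out_dir, "network.json"),
                scores = file.path(config$out_dir, "scores.tsv"),
                associations = file.path(config$out_dir, "associations.tsv"),
                validation = file.path(config$out_dir, "validation.json"),
                profiles = file.path(config$out_dir, "profiles.tsv"),
                log = file.path(config$out_dir, "pipeline_log.txt"))
  stage("write", {
    write_bn_json(net, paths$network)
    write_tsv(sel$scores, paths$scores)
    assoc_out <- assoc
    names(assoc_out) <- c("Node", "Mutual information",
                          "Normalized mutual information",
                          "Relative mutual information",
                          "Pearson correlation", "df", "p-value", "flag")
    write_tsv(assoc_out, paths$associations)
    jsonlite::write_json(
      list(n = report$n, precision_pct = report$precision_pct,
           reliability_pct = report$reliability_pct,
           roc_index_pct = report$roc_index_pct,
           lift_index_pct = report$lift_index_pct,
           confusion = as.data.frame(report$confusion)),
      paths$validation, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(profile_report)) write_tsv(profile_report, paths$profiles)
    else paths$profiles <- NULL
    writeLines(c(log_lines, paste0("finished: ", format(Sys.time()))),
               paths$log)
  })
  invisible(list(net = net, selection = sel, association = assoc,
                 validation = report, profiles = profiles,
                 profile_report = profile_report, paths = paths,
                 datasets = list(train = train_imp, test = test_imp)))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments
#' (`n_records` for `n` -- a bare `n` is a YAML boolean -- plus
#' `input_csv`, `test_fraction`, `alpha`, `passes`, `threshold_pct`,
#' `mode`, `mc_samples`, `seed`, `out_dir`) and a `generator` mapping
#' (`prevalence`, `effect_target`, `effect_tree`, `missingness`,
#' `jshape_sleep`, `seed`).
#'
#' @param path YAML file path.
#' @return A `bbn_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  g <- doc$generator %||% list()
  gen <- generator_config(
    prevalence = g$prevalence %||% 0.0307,
    effect_target = g$effect_target %||% 0.15,
    effect_tree = g$effect_tree %||% 0.25,
    missingness = g$missingness %||% 0.02,
    jshape_sleep = isTRUE(g$jshape_sleep),
    seed = g$seed %||% 1L)
  args <- doc[intersect(names(doc),
                        c("input_csv", "test_fraction", "alpha",
                          "passes", "threshold_pct", "mode", "mc_samples",
                          "seed", "out_dir"))]
  if (!is.null(doc$n_records)) args$n <- doc$n_records
  do.call(pipeline_config, c(list(generator = gen), args))
}
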