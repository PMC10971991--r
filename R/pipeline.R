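#' Configuration for an end-to-end panel-selection run
#'
#' Bundles every knob of the pipeline: the cohort source (a
#' [synthetic_config()] or a CSV path), prior mode, the stage-1 metabolite
#' search and stage-2 term search settings, an optional age filter, and
#' the output directory. All randomness flows from the synthetic config's
#' seed; a run is fully reproducible from its manifest.
#'
#' @param cohort a `synthetic_config`, or a CSV file path readable by
#'   [load_table()].
#' @param out_dir output directory (created if needed).
#' @param priors `"proportional"` or `"equal"`.
#' @param stage1 list: `max_k`, `strategy`, `budget`, `patience`,
#'   `beam_width`.
#' @param stage2 list: `max_degree`, `max_vars`, `strategy`, `budget`,
#'   `patience`, `beam_width`.
#' @param age_filter `NULL`, or list with `min_age` and `classes` passed
#'   to [age_filter()].
#' @param map_resolution decision-map grid resolution (default 400).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir,
                            priors = c("proportional", "equal"),
                            stage1 = list(), stage2 = list(),
                            age_filter = NULL, map_resolution = 400) {
  priors <- match.arg(priors)
  s1 <- utils::modifyList(list(max_k = 8, strategy = "forward",
                               budget = 1e5, patience = 2, beam_width = 20),
                          stage1)
  s2 <- utils::modifyList(list(max_degree = 3, max_vars = 8,
                               strategy = "forward", budget = 1e5,
                               patience = 2, beam_width = 20),
                          stage2)
  if (!inherits(cohort, "synthetic_config") && !is.character(cohort))
    stop("cohort must be a synthetic_config or a CSV path", call. = FALSE)
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort file not found: ", cohort, call. = FALSE)
  structure(list(cohort = cohort, out_dir = out_dir, priors = priors,
                 stage1 = s1, stage2 = s2, age_filter = age_filter,
                 map_resolution = map_resolution),
            class = "pipeline_config")
}

#' Run the full two-stage panel-selection pipeline
#'
#' Executes, in order: cohort acquisition (generation or CSV load),
#' optional age filtering, stage-1 metabolite subset search, monomial term
#' expansion over the winning panel, stage-2 variable search, final model
#' fit and leave-one-out evaluation, posterior table, discriminant-region
#' map, and report/manifest writing. Each stage's artifacts are written
#' under `config$out_dir`; rerunning the same configuration reproduces
#' identical numeric outputs. If a stage fails, already-written artifacts
#' are kept and a `FAILED` marker file names the stage and error.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the cohort, stage-1 and stage-2
#'   `search_result`s, the final `lda_model`, `loo_result`,
#'   `posterior_table`, `map_result` and the manifest, plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- "setup"
  res <- tryCatch({
    stage <- "cohort"
    if (inherits(config$cohort, "synthetic_config")) {
      tab <- generate_cohort(config$cohort)
      seed <- config$cohort$seed
    } else {
      tab <- load_table(config$cohort)
      seed <- NA_integer_
    }
    write_table(tab, out("cohort.csv"))
    sizes_pre <- as.list(table(tab$group))

    if (!is.null(config$age_filter)) {
      stage <- "age_filter"
      af <- config$age_filter
      tab <- age_filter(tab, min_age = af$min_age,
                        classes = if (is.null(af$classes))
                          levels(tab$group)[1] else af$classes)
    }
    sizes_post <- as.list(table(tab$group))

    stage <- "stage1"
    s1 <- config$stage1
    stage1 <- stage1_search(tab, max_k = s1$max_k, strategy = s1$strategy,
                            budget = s1$budget, patience = s1$patience,
                            beam_width = s1$beam_width,
                            priors = config$priors)
    write_search_trace(stage1, out("stage1_trace.tsv"))

    stage <- "stage2"
    s2 <- config$stage2
    terms <- expand_terms(stage1$selected_names,
                          max_degree = s2$max_degree)
    stage2 <- stage2_search(tab, terms,
                            max_vars = min(s2$max_vars,
                                           length(terms$labels)),
                            strategy = s2$strategy, budget = s2$budget,
                            patience = s2$patience,
                            beam_width = s2$beam_width,
                            priors = config$priors)
    write_search_trace(stage2, out("stage2_trace.tsv"))

    stage <- "evaluate"
    design <- build_design(tab, terms)
    sel <- design[, stage2$selected_features, drop = FALSE]
    model <- fit_lda(sel, groups = tab$group, priors = config$priors)
    loo <- loo_evaluate(sel, groups = tab$group, priors = config$priors,
                        ids = tab$subject_id)
    post <- posterior_table(loo$records, as.character(tab$group))
    write_lda_json(model, out("final_model.json"))
    write_posteriors_tsv(post, out("posteriors.tsv"))
    write_report_json(loo, out("final_report.json"))

    stage <- "map"
    map <- NULL
    if (ncol(model$axes) >= 2) {
      map <- region_grid(model, x = sel,
                         resolution = config$map_resolution,
                         priors = if (config$priors == "equal") "equal"
                                  else "proportional")
      write_map(map, out("map"))
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("ldapanel")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      priors = config$priors,
      cohort = if (inherits(config$cohort, "synthetic_config"))
        config_to_list(config$cohort) else list(path = config$cohort),
      class_sizes_pre_filter = sizes_pre,
      class_sizes_post_filter = sizes_post,
      stage1 = c(config$stage1,
                 list(selected = stage1$selected_names,
                      accuracy = num12(stage1$selected_accuracy),
                      evaluations = stage1$evaluations)),
      stage2 = c(config$stage2[c("max_degree", "max_vars", "strategy",
                                 "budget", "patience", "beam_width")],
                 list(n_terms = length(terms$labels),
                      selected = stage2$selected_names,
                      accuracy = num12(stage2$selected_accuracy),
                      evaluations = stage2$evaluations)),
      final = list(accuracy = num12(loo$accuracy),
                   ridge_events = loo$ridge_events,
                   ridge_used = num12(model$ridge_used),
                   n_axes = ncol(model$axes),
                   n_true_posterior_gt_half = post$n_true_posterior_gt_half))
    jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    list(cohort = tab, stage1 = stage1, terms = terms, stage2 = stage2,
         model = model, loo = loo, posteriors = post, map = map,
         manifest = manifest, out_dir = config$out_dir)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
               out("FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

config_to_list <- function(cfg) {
  l <- unclass(cfg)
  l$metabolite_names <- NULL   # bulky; reproducible from the seed
  l
}

write_posteriors_tsv <- function(post, path) {
  tab <- post$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], num12)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

write_report_json <- function(loo, path) {
  rep <- loo$report
  obj <- list(orientation = "rows = real class, columns = predicted class",
              class_order = rep$class_order,
              confusion = rep$confusion,
              overall_accuracy = num12(rep$overall_accuracy),
              per_class = rep$per_class,
              macro = as.list(num12(rep$macro)),
              undefined_cells = sum(rep$undefined),
              priors_mode = loo$priors_mode,
              ridge_events = loo$ridge_events,
              n = rep$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
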