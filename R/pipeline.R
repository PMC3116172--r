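# One-command orchestration of the full study design: both descriptor sets
# x both division schemes x four models x all cell lines, producing the
# metric grids, sigma tables, the division-scheme t-test and the SAR
# suggestion report.

.known_models <- c("PLS", "SVR", "Bayes", "SVM")
.known_sets <- c("general", "drug_like_index")
.known_divisions <- c("diverse", "cluster_diverse")

#' Default run configuration
#'
#' Every decision parameter of the pipeline surfaces here with its
#' documented default; [validate_config()] fills unspecified keys from
#' these values.
#'
#' @param mode `"synthetic"` (default) or `"files"`.
#' @param structures,activities Input paths (files mode).
#' @param generator A [generator_config()] (synthetic mode).
#' @param descriptor_sets Descriptor sets to run.
#' @param divisions Division schemes to run.
#' @param train_frac Training fraction (default 0.65).
#' @param models Model back-ends to run.
#' @param cell_lines Cell lines to model (`NULL` = all in the library).
#' @param cutoffs Named IC50 cutoffs; `NULL` uses the generator's.
#' @param cluster_k Cluster count for the cluster-diverse scheme
#'   (`NULL` = max(2, round(N/20))).
#' @param bayes_bins,bayes_sigma Histogram bins and Gaussian smoothing
#'   width of the binary Bayes model.
#' @param cond_limit,pls_ncomp PLS condition limit and component limit.
#' @param svm_cost,svr_cost,svr_epsilon Kernel-model hyperparameters.
#' @param suggest_cell_line Cell line whose model drives the suggestion
#'   engine.
#' @param suggest_descriptor_set Descriptor set used for suggestion
#'   scoring.
#' @param top_n Suggestions kept in the report.
#' @param seed Master seed for every source of randomness.
#' @return A `bq_runconfig` list.
#' @export
run_config <- function(mode = "synthetic", structures = NULL, activities = NULL,
                       generator = generator_config(),
                       descriptor_sets = .known_sets,
                       divisions = .known_divisions,
                       train_frac = 0.65,
                       models = .known_models,
                       cell_lines = NULL, cutoffs = NULL, cluster_k = NULL,
                       bayes_bins = 25L, bayes_sigma = 0.25,
                       cond_limit = 1e6, pls_ncomp = Inf,
                       svm_cost = 1, svr_cost = 1, svr_epsilon = 0.1,
                       suggest_cell_line = "NCI-H446",
                       suggest_descriptor_set = "general",
                       top_n = 10L, seed = 1L) {
  cfg <- list(mode = mode, structures = structures, activities = activities,
              generator = generator, descriptor_sets = descriptor_sets,
              divisions = divisions, train_frac = train_frac, models = models,
              cell_lines = cell_lines, cutoffs = cutoffs, cluster_k = cluster_k,
              bayes_bins = as.integer(bayes_bins), bayes_sigma = bayes_sigma,
              cond_limit = cond_limit, pls_ncomp = pls_ncomp,
              svm_cost = svm_cost, svr_cost = svr_cost,
              svr_epsilon = svr_epsilon,
              suggest_cell_line = suggest_cell_line,
              suggest_descriptor_set = suggest_descriptor_set,
              top_n = as.integer(top_n), seed = as.integer(seed))
  class(cfg) <- "bq_runconfig"
  .check_config(cfg)
  cfg
}

.check_config <- function(cfg) {
  if (!cfg$mode %in% c("synthetic", "files"))
    stop("mode must be 'synthetic' or 'files'", call. = FALSE)
  if (!(cfg$train_frac > 0 && cfg$train_frac < 1))
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  bad <- setdiff(cfg$models, .known_models)
  if (length(bad)) stop("unknown model name: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!length(cfg$models)) stop("at least one model required", call. = FALSE)
  bad <- setdiff(cfg$descriptor_sets, .known_sets)
  if (length(bad)) stop("unknown descriptor set: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!length(cfg$descriptor_sets)) stop("at least one descriptor set required",
                                         call. = FALSE)
  bad <- setdiff(cfg$divisions, .known_divisions)
  if (length(bad)) stop("unknown division scheme: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (cfg$mode == "files" && (is.null(cfg$structures) || is.null(cfg$activities)))
    stop("files mode needs 'structures' and 'activities' paths", call. = FALSE)
  invisible(cfg)
}

#' Validate a JSON run configuration
#'
#' Reads a JSON file (or literal JSON string), rejects unknown keys with a
#' descriptive message, fills defaults from [run_config()], and checks
#' every constraint. An empty file yields the all-defaults synthetic
#' configuration.
#'
#' @param raw Path to a JSON file, or a JSON string.
#' @return A validated `bq_runconfig`.
#' @export
validate_config <- function(raw) {
  txt <- if (file.exists(raw)) paste(readLines(raw, warn = FALSE), collapse = "\n")
         else raw
  parsed <- if (!nzchar(trimws(txt))) list()
            else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  defaults <- run_config()
  allowed <- setdiff(names(defaults), c("generator"))
  unknown <- setdiff(names(parsed), c(allowed, "generator"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- parsed[names(parsed) != "generator"]
  if (!is.null(parsed$generator)) {
    gknown <- names(formals(generator_config))
    gunknown <- setdiff(names(parsed$generator), gknown)
    if (length(gunknown))
      stop("unknown generator key(s): ", paste(gunknown, collapse = ", "),
           call. = FALSE)
    args$generator <- do.call(generator_config, parsed$generator)
  }
  do.call(run_config, args)
}

.model_task <- c(PLS = "regression", SVR = "regression",
                 Bayes = "classification", SVM = "classification")

.fitters <- function(cfg) {
  list(
    PLS = function(X, y) fit_pls(X, y, ncomp = cfg$pls_ncomp,
                                 cond_limit = cfg$cond_limit),
    SVR = function(X, y) fit_svr(X, y, svr_config(cost = cfg$svr_cost,
                                                  epsilon = cfg$svr_epsilon,
                                                  seed = cfg$seed)),
    Bayes = function(X, l) fit_binary_bayes(X, l, bins = cfg$bayes_bins,
                                            sigma = cfg$bayes_sigma),
    SVM = function(X, l) fit_svm(X, l, svm_config(cost = cfg$svm_cost,
                                                  seed = cfg$seed))
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full QSAR pipeline
#'
#' Executes read/generate -> descriptors -> divide -> binarize ->
#' fit/evaluate -> grids and sigma tables -> division t-test -> SAR
#' suggestion report. All randomness derives from `config$seed`; rerunning
#' with the same configuration produces byte-identical artifacts. The
#' training/testing division is computed once per scheme, in the
#' z-scored space of the first requested descriptor set, and shared by
#' both descriptor sets so that sigma compares models on identical
#' partitions.
#'
#' @param config A `bq_runconfig` from [run_config()] or
#'   [validate_config()].
#' @param out_dir Optional output directory for the CSV/JSON artifacts
#'   (grids, sigma tables, t-test record, suggestions, run manifest).
#' @return A `bq_run` list: library, truth (synthetic mode), splits,
#'   grids, sigma tables, t-test, suggestion report, per-combination
#'   reports, and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  .check_config(config)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[bqsar] ", line)
  }

  # --- input stage ---------------------------------------------------------
  truth <- NULL; scaffolds <- NULL
  library <- .stage("input", {
    if (config$mode == "synthetic") {
      gen <- generate_library(config$generator, seed = config$seed)
      truth <- gen$truth; scaffolds <- gen$scaffolds
      gen$library
    } else {
      mols <- read_structures(config$structures,
                              format = if (grepl("\\.smi(les)?$", config$structures))
                                "smiles" else "sdf")
      if (length(attr(mols, "failures")))
        warning("structure parse failures: ",
                paste(attr(mols, "failures"), collapse = "; "), call. = FALSE)
      join_library(mols, read_activity_table(config$activities),
                   permissive = TRUE)
    }
  })
  if (is.null(scaffolds)) scaffolds <- default_scaffolds()
  cells <- config$cell_lines
  if (is.null(cells)) cells <- library$cell_lines
  cutoffs <- config$cutoffs
  if (is.null(cutoffs)) cutoffs <- config$generator$cutoffs
  note("library: %d compounds, %d cell lines", length(library),
       length(cells))

  # --- descriptors ---------------------------------------------------------
  desc <- .stage("descriptors", {
    out <- list()
    for (set in config$descriptor_sets) {
      m <- build_matrix(library, set)
      if (length(m$failures))
        note("descriptor failures [%s]: %d", set, length(m$failures))
      out[[set]] <- m
    }
    out
  })

  # --- division ------------------------------------------------------------
  div_space <- .stage("division", normalize_descriptors(desc[[1]])$matrix)
  splits <- .stage("division", {
    out <- list()
    for (dv in config$divisions) {
      out[[dv]] <- if (dv == "diverse") {
        split_by_rank(rank_diverse(div_space, start = 1L),
                      frac = config$train_frac)
      } else {
        cluster_diverse_split(div_space, k = config$cluster_k,
                              frac = config$train_frac, seed = config$seed)
      }
      note("division %s: train %d / test %d", dv,
           length(out[[dv]]$train), length(out[[dv]]$test))
    }
    out
  })

  # --- modeling ------------------------------------------------------------
  act <- activity_matrix(library)
  fitters <- .fitters(config)
  grids <- list(); reports <- list()
  for (dv in names(splits)) {
    rows <- list()
    for (set in config$descriptor_sets) {
      X <- desc[[set]]$values
      set_short <- if (set == "general") "general" else "drug_like"
      for (cl in cells) {
        y <- log10(act[, cl])
        labels <- binarize(library, cl, cutoffs[[cl]])$labels
        for (mdl in config$models) {
          rep <- .stage(paste0("evaluate/", mdl), {
            if (.model_task[[mdl]] == "regression")
              evaluate_regression(X, y, splits[[dv]], fitters[[mdl]])
            else
              evaluate_classification(X, labels, splits[[dv]], fitters[[mdl]])
          })
          reports[[paste(dv, set_short, cl, mdl, sep = "|")]] <- rep
          metrics <- if (.model_task[[mdl]] == "regression")
            c(R2 = rep$R2, Q2 = rep$Q2, r2 = rep$r2)
          else c(At = rep$At, Av = rep$Av, Ap = rep$Ap)
          for (mt in names(metrics))
            rows[[length(rows) + 1L]] <- data.frame(
              division = dv, model = mdl, metric = mt, cell_line = cl,
              descriptor_set = set_short, value = unname(metrics[[mt]]))
        }
      }
    }
    grids[[dv]] <- results_grid(do.call(rbind, rows))
  }

  # --- sigma + division comparison ----------------------------------------
  sigma_tables <- lapply(grids, sigma_columns)
  ttest <- if (length(grids) == 2L)
    .stage("ttest", paired_ttest(grids[[1]], grids[[2]])) else NULL
  if (!is.null(ttest))
    note("division t-test: t=%.4f p=%.4f over %d pairs",
         ttest$t, ttest$p, ttest$n)

  # --- suggestions ---------------------------------------------------------
  sar <- .stage("suggestions", {
    cl <- config$suggest_cell_line
    if (!cl %in% cells) cl <- cells[1]
    labels <- binarize(library, cl, cutoffs[[cl]])$labels
    set <- config$suggest_descriptor_set
    X <- build_matrix(library, set)$values
    lab <- labels[rownames(X)]
    use <- !is.na(lab)
    model <- fit_binary_bayes(X[use, , drop = FALSE], lab[use],
                              bins = config$bayes_bins,
                              sigma = config$bayes_sigma)
    build_sar_report(model, library, scaffolds, top_n = config$top_n,
                     descriptor_set = set)
  })
  if (nrow(sar)) note("top suggestion: %s (%+.1f%%)", sar$mutation[1],
                      sar$pct_gain[1])

  manifest <- list(
    package_version = as.character(utils::packageVersion("bqsar")),
    seed = config$seed,
    config = config[setdiff(names(config), "generator")],
    generator = if (config$mode == "synthetic") unclass(config$generator),
    n_compounds = length(library),
    cell_lines = cells, cutoffs = as.list(cutoffs),
    split_sizes = lapply(splits, function(s)
      list(train = length(s$train), test = length(s$test))),
    log = log_lines)

  result <- structure(list(library = library, truth = truth, splits = splits,
                           grids = grids, sigma_tables = sigma_tables,
                           ttest = ttest, sar_report = sar,
                           reports = reports, manifest = manifest,
                           scaffolds = scaffolds),
                      class = "bq_run")
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Write a pipeline run's artifacts to a directory
#'
#' Per division scheme: the long results grid and the rendered sigma
#' table; plus the t-test record, the suggestion table, and the run
#' manifest (JSON) holding versions, seeds and every decision parameter.
#'
#' @param run A `bq_run` from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (dv in names(run$grids)) {
    utils::write.csv(as.data.frame(run$grids[[dv]]),
                     file.path(out_dir, sprintf("results_%s.csv", dv)),
                     row.names = FALSE)
    render_grid(run$grids[[dv]],
                csv_path = file.path(out_dir, sprintf("sigma_%s.csv", dv)))
  }
  if (!is.null(run$ttest))
    utils::write.csv(data.frame(t = run$ttest$t, p = run$ttest$p,
                                n_pairs = run$ttest$n,
                                degenerate = run$ttest$degenerate,
                                universe = run$ttest$universe),
                     file.path(out_dir, "ttest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$sar_report),
                   file.path(out_dir, "suggestions.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

#' @export
print.bq_run <- function(x, ...) {
  cat(sprintf("<bq_run: %d compounds, %d division scheme(s), %d grid rows>\n",
              length(x$library), length(x$splits),
              sum(vapply(x$grids, nrow, 0L))))
  invisible(x)
}
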