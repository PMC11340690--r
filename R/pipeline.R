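# Orchestration of the full two-cohort workflow:
# preprocess -> (tune) -> fit -> assign reads -> differential abundance ->
# cross-cohort matching -> validated-community report. Every stage writes its
# outputs and parameters into the run directory; with a fixed config the run
# is bit-for-bit reproducible (no timestamps are written).

#' Read a flat key-value run configuration
#'
#' Parses lines of the form `key = value` (blank lines and `#` comments
#' ignored); values that parse as numbers are converted.
#'
#' @param path Path to the configuration file.
#' @return Named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}

.config_defaults <- function() {
  list(group_column = "group", k = NULL,
       grid_min = 2, grid_max = 10, grid_step = 1,
       filter_threshold = 1e-5, tss_scale = 1e6,
       cosine_threshold = 0.80, p_threshold = 0.05, q_threshold = 0.25,
       rounding = "none", rule = "exploratory-significant",
       label_a = "A", label_b = "B", seed = 1,
       em_tol = 1e-4, max_em_iters = 100, n_restarts = 1)
}

.load_dataset <- function(config, side) {
  tab <- config[[paste0("table_", side)]]
  met <- config[[paste0("meta_", side)]]
  tax <- config[[paste0("taxa_", side)]]
  if (is.null(tab) || is.null(met)) {
    stop("config must provide table_", side, " and meta_", side, call. = FALSE)
  }
  if (is.character(tab)) {
    orient <- config[[paste0("orientation_", side)]]
    if (is.null(orient)) orient <- "samples-in-rows"
    tab <- read_count_table(tab, orientation = orient)
  }
  if (is.character(met)) met <- read_metadata(met, config$group_column)
  if (!is.null(tax) && is.character(tax)) tax <- read_taxa_table(tax)
  list(table = tab, meta = met, taxa = tax)
}

.write_kv <- function(x, path) {
  vals <- vapply(x, function(v) paste(format(v, digits = 15), collapse = ","),
                 "")
  writeLines(paste(names(x), "=", vals), path)
  invisible(path)
}

#' Run the full two-cohort community-typing workflow
#'
#' Executes, for each cohort: optional genus aggregation, low-abundance
#' filtering, optional topic-number tuning, LDA fitting, read-to-topic
#' assignment, topic-level differential abundance and the genus-level
#' Wilcoxon screen; then cross-cohort topic matching and the
#' validated-community report. All stage outputs, parameters and seeds are
#' written under `out_dir`; re-running the same config reproduces the run
#' directory byte-identically.
#'
#' @param config Named list or path to a flat key-value config file
#'   (see [read_run_config()]). Recognized keys: `table_a`, `meta_a`,
#'   `taxa_a`, `orientation_a` (and `_b` counterparts) -- file paths, or
#'   in-memory matrices/data.frames when calling from R; `group_column`;
#'   `k` (fixed topic number; omit to tune), `grid_min`, `grid_max`,
#'   `grid_step`; `filter_threshold` (1e-5), `tss_scale` (1e6),
#'   `cosine_threshold` (0.80), `p_threshold` (0.05), `q_threshold` (0.25);
#'   `rounding` (`"none"`/`"nearest"`), `rule` (see
#'   [validated_communities()]), `label_a`, `label_b`, `seed`, `out_dir`.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisibly, a list with the fitted models, differential results,
#'   the match set, the validated-community report and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  config <- utils::modifyList(.config_defaults(), config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("config must set out_dir", call. = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cat("", file = log_path)
  logit <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logit("stage=", name, " status=failed error=", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  echo <- config
  echo$table_a <- if (is.character(config$table_a)) config$table_a else "<in-memory>"
  echo$table_b <- if (is.character(config$table_b)) config$table_b else "<in-memory>"
  echo$meta_a <- if (is.character(config$meta_a)) config$meta_a else "<in-memory>"
  echo$meta_b <- if (is.character(config$meta_b)) config$meta_b else "<in-memory>"
  echo$taxa_a <- if (is.character(config$taxa_a)) config$taxa_a
    else if (is.null(config$taxa_a)) "<none>" else "<in-memory>"
  echo$taxa_b <- if (is.character(config$taxa_b)) config$taxa_b
    else if (is.null(config$taxa_b)) "<none>" else "<in-memory>"
  .write_kv(echo[order(names(echo))], file.path(out, "config_echo.txt"))

  seed <- as.integer(config$seed)
  vem <- vem_settings(max_em_iters = config$max_em_iters,
                      em_tol = config$em_tol,
                      n_restarts = config$n_restarts, seed = seed)
  sides <- c("a", "b")
  labels <- c(config$label_a, config$label_b)
  prepped <- list()
  for (i in seq_along(sides)) {
    side <- sides[i]
    dir.create(file.path(out, labels[i]), showWarnings = FALSE)
    ds <- stage(paste0("load_", side), .load_dataset(config, side))
    al <- stage(paste0("align_", side),
                suppressMessages(align_tables(ds$table, ds$meta)))
    tab <- al$table
    if (!is.null(ds$taxa)) {
      tab <- stage(paste0("aggregate_", side), aggregate_to_genus(tab, ds$taxa))
      logit("stage=aggregate dataset=", labels[i],
            " n_genera=", ncol(tab))
    }
    fl <- stage(paste0("filter_", side),
                filter_low_abundance(tab, config$filter_threshold))
    logit("stage=filter dataset=", labels[i],
          " threshold=", config$filter_threshold,
          " features=", fl$report$n_features_before, "->",
          fl$report$n_features_after)
    write_count_table(fl$table, file.path(out, labels[i], "filtered_table.tsv"))
    write_filter_report(fl$report, file.path(out, labels[i], "filter_report.tsv"))
    prepped[[side]] <- list(table = fl$table, meta = al$meta)
  }

  # topic number: fixed k bypasses tuning
  if (!is.null(config$k)) {
    k <- as.integer(config$k)
    logit("stage=tune status=bypassed k=", k)
    tunings <- NULL
  } else {
    grid <- seq(as.integer(config$grid_min), as.integer(config$grid_max),
                by = as.integer(config$grid_step))
    tunings <- lapply(seq_along(sides), function(i) {
      tu <- stage(paste0("tune_", sides[i]),
                  tune_topic_number(prepped[[sides[i]]]$table, grid, vem))
      utils::write.table(tu$metrics,
                         file.path(out, labels[i], "tuning.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logit("stage=tune dataset=", labels[i], " seed=", seed,
            " best_cao=", tu$best_k$cao_juan, " best_arun=", tu$best_k$arun)
      tu
    })
    k <- combine_dataset_optima(tunings)
    logit("stage=tune combined_k=", k)
  }

  diff_set <- diff_settings(p_threshold = config$p_threshold,
                            q_threshold = config$q_threshold)
  models <- list(); diffs <- list()
  for (i in seq_along(sides)) {
    side <- sides[i]
    d <- prepped[[side]]
    fit <- stage(paste0("fit_", side),
                 fit_lda(d$table, k, settings = vem))
    logit("stage=fit dataset=", labels[i], " k=", k, " seed=", seed,
          " em_iters=", fit$n_iter,
          " elbo=", format(fit$elbo_trace[fit$n_iter], digits = 15))
    write_count_table(fit$beta, file.path(out, labels[i], "beta.tsv"),
                      id_column = "topic_id")
    write_count_table(fit$gamma, file.path(out, labels[i], "gamma.tsv"))
    .write_kv(list(k = k, alpha = fit$alpha, eta = fit$eta, seed = fit$seed,
                   em_iterations = fit$n_iter,
                   elbo_trace = fit$elbo_trace),
              file.path(out, labels[i], "model_info.txt"))
    ta <- stage(paste0("assign_", side),
                assign_reads_to_topics(fit, d$table, rounding = config$rounding))
    write_count_table(ta, file.path(out, labels[i], "topic_abundance.tsv"))
    logit("stage=assign dataset=", labels[i], " rounding=", config$rounding)
    da <- stage(paste0("topic_da_", side),
                linda_test(ta, d$meta, settings = diff_set))
    utils::write.table(da, file.path(out, labels[i], "topic_da.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logit("stage=topic_da dataset=", labels[i],
          " significant=", sum(da$significant))
    gs <- stage(paste0("genus_da_", side),
                genus_level_screen(d$table, d$meta, settings = diff_set,
                                   scale = config$tss_scale))
    utils::write.table(gs, file.path(out, labels[i], "genus_da.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logit("stage=genus_da dataset=", labels[i],
          " significant=", sum(gs$significant))
    models[[side]] <- fit
    diffs[[side]] <- list(topic = da, genus = gs)
  }

  mt <- stage("match", match_topics(models$a, models$b,
                                    threshold = config$cosine_threshold,
                                    labels = labels))
  write_count_table(mt$similarity, file.path(out, "similarity.tsv"),
                    id_column = "topic_id")
  utils::write.table(mt$matches, file.path(out, "matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mt$communities, file.path(out, "communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logit("stage=match threshold=", config$cosine_threshold,
        " pairs=", nrow(mt$matches),
        " communities=", length(unique(mt$communities$community)))
  report <- stage("report",
                  validated_communities(mt, diffs$a$topic, diffs$b$topic,
                                        rule = config$rule))
  utils::write.table(report, file.path(out, "validated_communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logit("stage=report rule=", config$rule,
        " validated=", sum(report$validated))

  invisible(list(models = models, diffs = diffs, matches = mt,
                 report = report, tunings = tunings, k = k, out_dir = out))
}
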