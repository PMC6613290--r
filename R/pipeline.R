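# Stage orchestration: one configuration, one output directory, one manifest
# per stage. Stages communicate through files only, so each command can be
# rerun (or audited) in isolation. No command mutates its inputs.

#' Pipeline configuration
#'
#' Builds (or loads from YAML/JSON) the single configuration object driving
#' [run_pipeline()]. Every analysis choice with a default — fold counts, the
#' hyperparameter grid, term-analysis parameters, subgroup cutoffs — is a
#' named entry here.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Top-level seed; each stage derives its own child seeds.
#' @param sites Named list of [site_profile()] objects (or lists of
#'   `site_profile()` arguments) for the `generate` stage; use existing data
#'   directories instead by pre-populating `<out_dir>/data/<site>/`.
#' @param embedding List of [embedding_config()] arguments.
#' @param grid Hyperparameter grid ([default_grid()]).
#' @param k_outer,k_inner Outer/inner fold counts.
#' @param max_gap_days,min_words,count_window Cohort rules (see
#'   [build_cohort()]).
#' @param term_k,term_B,mcc_B,top_fraction,alpha Term-screen parameters.
#' @param early_cutoff Early/late violence cutoff in days.
#' @param path YAML or JSON file to load (`pipeline_config_from_file`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sites = NULL,
                            embedding = list(), grid = default_grid(),
                            k_outer = 5, k_inner = 5,
                            max_gap_days = 14, min_words = 100,
                            count_window = "post24h",
                            term_k = 1000, term_B = 1000, mcc_B = 2000,
                            top_fraction = 0.10, alpha = 0.01,
                            early_cutoff = 14) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sites = sites,
                 embedding = embedding, grid = grid, k_outer = k_outer,
                 k_inner = k_inner, max_gap_days = max_gap_days,
                 min_words = min_words, count_window = count_window,
                 term_k = term_k, term_B = term_B, mcc_B = mcc_B,
                 top_fraction = top_fraction, alpha = alpha,
                 early_cutoff = early_cutoff),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_config_from_file <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- raw$sites
  if (!is.null(sites))
    sites <- lapply(sites, function(s) do.call(site_profile, s))
  raw$sites <- sites
  if (!is.null(raw$grid)) raw$grid <- as.data.frame(raw$grid)
  do.call(pipeline_config, raw)
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

require_stage <- function(config, stage, file) {
  path <- file.path(config$out_dir, stage, file)
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s': run the '%s' stage first", file, stage),
         call. = FALSE)
  path
}

stage_manifest <- function(config, stage, ...) {
  write_manifest(file.path(config$out_dir, stage, "manifest.json"),
                 stage = stage, seed = config$seed, ...)
}

#' Run pipeline stages
#'
#' Executes one stage of the full analysis chain, reading the previous
#' stage's artifacts from the configured output directory and writing its
#' own (plus a JSON manifest with seed and record counts). Stages:
#' `generate` (synthetic site corpora), `cohort` (labeled admissions),
#' `internal-cv` (patient-grouped nested cross-validation per site),
#' `transfer` (cross-site exchange of frozen models), `terms` (exploratory
#' term screen), `report` (assembled summary), `all` (everything in order).
#'
#' @param config A [pipeline_config()] (or path to a YAML/JSON file).
#' @param command One of the stage names above.
#' @return Invisibly, the stage's main result object.
#' @export
run_pipeline <- function(config,
                         command = c("all", "generate", "cohort", "internal-cv",
                                     "transfer", "terms", "report")) {
  command <- match.arg(command)
  if (is.character(config)) config <- pipeline_config_from_file(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (command == "all") {
    for (cmd in c("generate", "cohort", "internal-cv", "transfer", "terms", "report"))
      run_pipeline(config, cmd)
    return(invisible(NULL))
  }
  switch(command,
         "generate" = stage_generate(config),
         "cohort" = stage_cohort(config),
         "internal-cv" = stage_internal_cv(config),
         "transfer" = stage_transfer(config),
         "terms" = stage_terms(config),
         "report" = stage_report(config))
}

site_names <- function(config) {
  d <- file.path(config$out_dir, "data")
  if (dir.exists(d)) list.dirs(d, recursive = FALSE, full.names = FALSE)
  else names(config$sites)
}

stage_generate <- function(config) {
  if (is.null(config$sites) || length(config$sites) == 0L)
    stop("no site profiles configured for 'generate'", call. = FALSE)
  profiles <- lapply(config$sites, function(s) {
    if (inherits(s, "site_profile")) s else do.call(site_profile, s)
  })
  dir <- stage_dir(config, "data")
  seeds <- derive_seeds(config$seed, 1L)
  if (length(profiles) == 2L) {
    pair <- generate_pair(profiles[[1]], profiles[[2]], seeds[1])
    corpora <- list(pair$a, pair$b)
  } else {
    corpora <- lapply(seq_along(profiles), function(i)
      generate_site(profiles[[i]], derive_seeds(seeds[1], i)[i]))
  }
  names(corpora) <- vapply(corpora, function(cp) cp$profile$site_id, character(1))
  for (nm in names(corpora)) write_corpus(corpora[[nm]], file.path(dir, nm))
  stage_manifest(config, "data", sites = names(corpora),
                 admissions = vapply(corpora, function(cp) nrow(cp$admissions), 0))
  invisible(corpora)
}

stage_cohort <- function(config) {
  data_dir <- file.path(config$out_dir, "data")
  if (!dir.exists(data_dir))
    stop("missing artifact 'data/': run the 'generate' stage first (or place extracts there)",
         call. = FALSE)
  dir <- stage_dir(config, "cohort")
  out <- list()
  for (site in site_names(config)) {
    corpus <- read_corpus(file.path(data_dir, site))
    cohort <- build_cohort(corpus$admissions, corpus$notes, corpus$incidents,
                           max_gap_days = config$max_gap_days,
                           min_words = config$min_words,
                           count_window = config$count_window)
    flat <- as.data.frame(cohort[, setdiff(names(cohort), "document")])
    write.csv(flat, file.path(dir, paste0(site, "_labeled.csv")), row.names = FALSE)
    docs <- file(file.path(dir, paste0(site, "_documents.jsonl")), "w")
    for (i in seq_len(nrow(cohort)))
      writeLines(jsonlite::toJSON(list(admission_id = cohort$admission_id[i],
                                       document = cohort$document[i]),
                                  auto_unbox = TRUE), docs)
    close(docs)
    saveRDS(cohort, file.path(dir, paste0(site, "_cohort.rds")))
    out[[site]] <- cohort
  }
  stage_manifest(config, "cohort", sites = names(out),
                 retained = vapply(out, nrow, 0),
                 excluded = vapply(out, function(x) attr(x, "n_excluded"), 0))
  invisible(out)
}

load_cohorts <- function(config) {
  sites <- site_names(config)
  setNames(lapply(sites, function(site)
    readRDS(require_stage(config, "cohort", paste0(site, "_cohort.rds")))), sites)
}

stage_internal_cv <- function(config) {
  cohorts <- load_cohorts(config)
  dir <- stage_dir(config, "cv")
  seeds <- derive_seeds(config$seed, 2L + 2L * length(cohorts))
  out <- list()
  for (i in seq_along(cohorts)) {
    site <- names(cohorts)[i]
    cohort <- cohorts[[i]]
    emb_cfg <- do.call(embedding_config, modifyList(config$embedding,
                                                    list(seed = seeds[2 * i - 1])))
    model <- train_embedding(setNames(cohort$document, cohort$admission_id), emb_cfg)
    vectors <- embed_documents(model, cohort$document, ids = cohort$admission_id)
    cv <- run_nested_cv(cohort, vectors, grid = config$grid,
                        k_outer = config$k_outer, k_inner = config$k_inner,
                        seed = seeds[2 * i])
    write.csv(as.data.frame(cv$predictions),
              file.path(dir, paste0(site, "_predictions.csv")), row.names = FALSE)
    write.csv(as.data.frame(cv$fold_plan),
              file.path(dir, paste0(site, "_folds.csv")), row.names = FALSE)
    roc <- do.call(rbind, lapply(sort(unique(cv$predictions$fold)), function(f) {
      p <- cv$predictions[cv$predictions$fold == f, ]
      cbind(fold = f, as.data.frame(roc_points(p$score, p$label)))
    }))
    write.csv(roc, file.path(dir, paste0(site, "_roc.csv")), row.names = FALSE)
    saveRDS(list(cv = cv, embedding = model),
            file.path(dir, paste0(site, "_cv.rds")))
    out[[site]] <- cv
  }
  stage_manifest(config, "cv", sites = names(out),
                 auc_fold_mean = vapply(out, function(x) x$auc, 0),
                 auc_pooled = vapply(out, function(x) x$auc_pooled, 0))
  invisible(out)
}

stage_transfer <- function(config) {
  sites <- site_names(config)
  if (length(sites) != 2L)
    stop("the 'transfer' stage needs exactly two sites", call. = FALSE)
  cohorts <- load_cohorts(config)
  internal <- lapply(sites, function(site)
    readRDS(require_stage(config, "cv", paste0(site, "_cv.rds"))))
  names(internal) <- sites
  dir <- stage_dir(config, "transfer")
  seeds <- derive_seeds(config$seed + 7L, length(sites))
  out <- list()
  for (i in seq_along(sites)) {
    src <- sites[i]; dst <- sites[-i][1]
    emb_cfg <- do.call(embedding_config, config$embedding)
    frozen <- freeze_site_model(cohorts[[src]], embed_config = emb_cfg,
                                grid = config$grid, k = config$k_outer,
                                seed = seeds[i])
    res <- transfer_evaluate(frozen, cohorts[[dst]],
                             internal_result = internal[[dst]]$cv)
    key <- paste0(src, "_to_", dst)
    write.csv(as.data.frame(res$predictions),
              file.path(dir, paste0(key, "_predictions.csv")), row.names = FALSE)
    saveRDS(res, file.path(dir, paste0(key, ".rds")))
    out[[key]] <- res
  }
  stage_manifest(config, "transfer", experiments = names(out),
                 auc = vapply(out, function(x) x$auc, 0))
  invisible(out)
}

stage_terms <- function(config) {
  cohorts <- load_cohorts(config)
  dir <- stage_dir(config, "terms")
  seeds <- derive_seeds(config$seed + 13L, length(cohorts))
  out <- list()
  for (i in seq_along(cohorts)) {
    site <- names(cohorts)[i]
    scr <- term_screen(cohorts[[i]], k = config$term_k, B = config$term_B,
                       mcc_B = config$mcc_B, top_fraction = config$top_fraction,
                       alpha = config$alpha, seed = seeds[i])
    write.csv(as.data.frame(scr), file.path(dir, paste0(site, "_terms.csv")),
              row.names = FALSE)
    out[[site]] <- scr
  }
  stage_manifest(config, "terms", sites = names(out),
                 significant = vapply(out, function(x) sum(x$significant), 0))
  invisible(out)
}

stage_report <- function(config) {
  sites <- site_names(config)
  dir <- stage_dir(config, "report")
  lines <- c("Violence risk assessment pipeline report", "")
  cvs <- lapply(sites, function(site)
    readRDS(require_stage(config, "cv", paste0(site, "_cv.rds")))$cv)
  names(cvs) <- sites
  lines <- c(lines, "Internal cross-validation:")
  for (site in sites) {
    cv <- cvs[[site]]
    m <- cv$metrics
    lines <- c(lines, sprintf(
      "  %s: AUC %.3f (pooled %.3f, 95%% CI %.3f-%.3f, SE %.3f); TN %d FN %d TP %d FP %d; sens %.3f spec %.3f RR %s",
      site, cv$auc, cv$auc_pooled, cv$ci_low, cv$ci_high, cv$se,
      m$tn, m$fn, m$tp, m$fp, m$sensitivity, m$specificity,
      ifelse(is.na(m$relative_risk), "undefined", sprintf("%.3f", m$relative_risk))))
  }
  tdir <- file.path(config$out_dir, "transfer")
  if (length(sites) == 2L && dir.exists(tdir)) {
    lines <- c(lines, "", "Cross-site transfer:")
    for (i in seq_along(sites)) {
      key <- paste0(sites[i], "_to_", sites[-i][1])
      path <- file.path(tdir, paste0(key, ".rds"))
      if (!file.exists(path)) next
      res <- readRDS(path)
      lines <- c(lines, sprintf(
        "  %s: AUC %.3f (95%% CI %.3f-%.3f); paired DeLong vs internal: diff %.3f, p = %s",
        key, res$auc, res$ci_low, res$ci_high,
        res$comparison$auc_diff, format.pval(res$comparison$p_value, digits = 3)))
    }
  }
  for (site in sites) {
    path <- file.path(config$out_dir, "terms", paste0(site, "_terms.csv"))
    if (!file.exists(path)) next
    scr <- read.csv(path, stringsAsFactors = FALSE)
    lines <- c(lines, "", sprintf("Top terms, %s (significant after Holm-Bonferroni: %d):",
                                  site, sum(scr$significant)))
    top <- head(scr, 10)
    lines <- c(lines, sprintf("  %2d. %-24s ratio %.2f  MCC %+.2f (%+.2f to %+.2f)  p %s",
                              top$rank, top$term, top$stability_ratio, top$mcc,
                              top$mcc_ci_low, top$mcc_ci_high,
                              format.pval(top$p_adjusted, digits = 2)))
  }
  writeLines(lines, file.path(dir, "report.txt"))
  stage_manifest(config, "report")
  invisible(lines)
}
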