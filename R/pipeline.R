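#' Pipeline configuration
#'
#' Collects every tunable parameter of the three-phase analysis with the
#' package defaults: top-25 state restriction, severity-based substitution
#' costs with constant INDEL 1 and expansion 0.05 per square-root-transformed
#' day of spell duration (pricing a typical duration difference on the same
#' scale as one severity level, so composition is not swamped by follow-up
#' length), four primary Markov
#' clusters, a Phase-2 scan over k = 2..20, merging down to 2 with
#' multi-metric selection, 75% representative coverage with at most 10
#' representatives, and cluster 1 as the survival reference.
#'
#' @param top_k number of most frequent states kept.
#' @param restrict_strategy `"drop"` or `"other"`.
#' @param min_visits minimum assessments per patient.
#' @param scheme,indel,expansion,transform,units,sev_floor cost-model
#'   parameters, see [build_cost_model()].
#' @param k_primary number of Phase-1 Markov components.
#' @param alpha Markov smoothing pseudo-count.
#' @param phase1_init,phase1_n_init Phase-1 initialization: a single run
#'   from random row-stochastic transition matrices by default. Phase 1 only
#'   needs a coarse partition for the distance phases to refine, and a
#'   maximally pure likelihood optimum is not the goal; see
#'   [fit_markov_mixture()] for the restart-based alternative.
#' @param k_range Phase-2 candidate sub-cluster counts.
#' @param merge_floor_k smallest k reached by Phase-3 merging.
#' @param max_k optional interpretability cap for the selected k.
#' @param trep,nrep_max,pradius representative-extraction parameters.
#' @param reference_cluster survival reference cluster id.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(top_k = 25L, restrict_strategy = "drop",
                            min_visits = 3L, scheme = "severity", indel = 1.0,
                            expansion = 0.05, transform = "sqrt",
                            units = "days", sev_floor = 0.1, k_primary = 4L,
                            alpha = 0.5, phase1_init = "dirichlet",
                            phase1_n_init = 1L,
                            k_range = 2:20, merge_floor_k = 2L,
                            max_k = Inf, trep = 0.75, nrep_max = 10L,
                            pradius = 0.10, reference_cluster = 1L,
                            seed = 1L) {
  structure(list(top_k = as.integer(top_k),
                 restrict_strategy = restrict_strategy,
                 min_visits = as.integer(min_visits), scheme = scheme,
                 indel = indel, expansion = expansion, transform = transform,
                 units = units, sev_floor = sev_floor,
                 k_primary = as.integer(k_primary), alpha = alpha,
                 phase1_init = phase1_init,
                 phase1_n_init = as.integer(phase1_n_init),
                 k_range = as.integer(k_range),
                 merge_floor_k = as.integer(merge_floor_k), max_k = max_k,
                 trep = trep, nrep_max = as.integer(nrep_max),
                 pradius = pradius,
                 reference_cluster = as.integer(reference_cluster),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# semantic hash of a configuration (for the run manifest)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tmp))
}

#' Read the long assessment CSV
#'
#' Expects the schema
#' `patient_id,day,B,G,D,F,S,W,T,L,U,age,sex,death_day,censor_day` with
#' strict 0/1 domain columns; an empty `death_day` means censored. Schema
#' violations raise row-identified errors.
#'
#' @param path CSV file.
#' @return an [assessment_records()] table.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty assessment file: ", path)
  need <- c("patient_id", "day", adl_domains(), "age", "sex", "censor_day")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (d in adl_domains()) {
    bad <- which(!(df[[d]] %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop("non-binary value in domain column ", d, " at data row ", bad[1])
    }
  }
  bad <- which(is.na(df$day) | df$day < 0)
  if (length(bad) > 0L) stop("negative or missing day at data row ", bad[1])
  assessment_records(df)
}

#' Run the full three-phase pipeline
#'
#' Executes cohort preparation (exclusions, spell construction, top-K state
#' restriction, frequency-weight merging), Phase 1 (Markov-mixture primary
#' clusters), Phase 2 (per-primary-cluster hierarchical + weighted PAM with
#' silhouette-driven k), Phase 3 (global reassignment to pooled medoids,
#' quality-driven merging, multi-metric k selection), representative
#' extraction and the mortality analysis.
#'
#' @param records an [assessment_records()] table (or the `records` element
#'   of [simulate_cohort()] output).
#' @param config a [pipeline_config()].
#' @return object of class `adltraj_result`; see the elements `pool`,
#'   `phase1`, `phase2`, `trace`, `final` (labels, medoids, k),
#'   `representatives`, `survival`, `manifest`.
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  ts <- Sys.time()
  excl <- apply_exclusions(records, min_visits = config$min_visits)
  seqs <- build_sequences(excl$records)
  n_states <- length(unique(unlist(lapply(seqs, `[[`, "states"))))
  if (config$top_k < n_states) {
    seqs <- restrict_states(seqs, K = config$top_k,
                            strategy = config$restrict_strategy,
                            min_visits = config$min_visits)
  }
  pool <- merge_identical(seqs)
  tick("prepare", ts)

  cost <- build_cost_model(pool$alphabet, scheme = config$scheme,
                           indel = config$indel, expansion = config$expansion,
                           transform = config$transform, units = config$units,
                           sev_floor = config$sev_floor)

  ts <- Sys.time()
  phase1 <- fit_markov_mixture(pool, k = config$k_primary,
                               seed = .stage_seed(config$seed, "phase1"),
                               alpha = config$alpha,
                               init = config$phase1_init,
                               n_init = config$phase1_n_init)
  tick("phase1", ts)

  ts <- Sys.time()
  phase2 <- lapply(sort(unique(phase1$assignment)), function(cl) {
    idx <- which(phase1$assignment == cl)
    D <- distance_matrix(pool, cost, subset = idx)
    scan <- select_k_by_asww(D, pool$weights[idx], k_range = config$k_range)
    list(primary = cl, idx = idx, scan = scan,
         medoids = idx[scan$solution$medoids])
  })
  medoid_pool <- unlist(lapply(phase2, `[[`, "medoids"))
  tick("phase2", ts)

  ts <- Sys.time()
  init <- global_reassign(pool, medoid_pool, cost)
  D <- distance_matrix(pool, cost)
  if (init$k >= 3L) {
    trace <- run_merging(init, D, pool$weights,
                         down_to_k = config$merge_floor_k)
    sel <- select_optimal_k(trace, max_k = config$max_k)
    final <- trace$solutions[[as.character(sel$k)]]
  } else {
    trace <- structure(list(report = cbind(
      quality_report(D, pool$weights, init$labels),
      merged_from = NA_integer_, merged_into = NA_integer_),
      solutions = stats::setNames(list(init), init$k)), class = "merge_trace")
    sel <- list(k = init$k, composite = NULL)
    final <- init
  }
  tick("refine", ts)

  ts <- Sys.time()
  reps <- cluster_representatives(pool, D, final$labels, trep = config$trep,
                                  nrep_max = config$nrep_max,
                                  pradius = config$pradius,
                                  alpha = config$alpha)
  tick("represent", ts)

  ts <- Sys.time()
  surv_tab <- survival_table(excl$records, pool, final$labels)
  surv <- list(table = surv_tab, km = NULL, cox = NULL, sensitivity = NULL)
  if (length(unique(surv_tab$cluster)) >= 2L &&
      length(unique(surv_tab$time[surv_tab$event == 1])) >= 2L) {
    surv$km <- km_curve(surv_tab, group_by = "cluster")
    ref <- if (config$reference_cluster %in% surv_tab$cluster) {
      config$reference_cluster
    } else min(surv_tab$cluster)
    surv$cox <- tryCatch(cox_fit(surv_tab, reference_cluster = ref),
                         error = function(e) {
                           warning("Cox model skipped: ", conditionMessage(e))
                           NULL
                         })
    surv$sensitivity <- tryCatch(sensitivity_suite(surv_tab, ref),
                                 error = function(e) NULL)
  }
  tick("survive", ts)

  manifest <- list(
    package = "adltraj",
    version = as.character(utils::packageVersion("adltraj")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stage_seeds = list(phase1 = .stage_seed(config$seed, "phase1")),
    config = unclass(config),
    config_hash = .config_hash(config),
    n_patients = length(unique(excl$records$patient_id)),
    n_patterns = pool_size(pool),
    exclusions = as.list(excl$audit),
    k_final = final$k,
    cox_formula = if (!is.null(surv$cox)) surv$cox$formula else NA,
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(pool = pool, cost = cost, audit = excl$audit,
                 records = excl$records, phase1 = phase1, phase2 = phase2,
                 initial = init, trace = trace, selection = sel,
                 final = final, D = D, representatives = reps,
                 survival = surv, manifest = manifest),
            class = "adltraj_result")
}

#' @export
print.adltraj_result <- function(x, ...) {
  cat("<adltraj_result> ", x$manifest$n_patients, " patients, ",
      x$manifest$n_patterns, " unique patterns, k_final=", x$final$k,
      "\n", sep = "")
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Deterministic file names; CSV for tables, JSON for models and reports.
#' The run manifest is written last, so its presence marks a complete
#' artifact set.
#'
#' @param result an [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
write_solution <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  pool <- result$pool
  labels <- result$final$labels
  wcsv(data.frame(
    patient_id = unlist(pool$members, use.names = FALSE),
    pattern_id = rep(seq_along(pool$seqs), times = lengths(pool$members)),
    cluster = rep(labels, times = lengths(pool$members))), "labels.csv")
  wcsv(do.call(rbind, lapply(seq_along(pool$seqs), function(i) {
    sp <- pool$seqs[[i]]$spells
    data.frame(pattern_id = i, state_code = sp$state, begin_day = sp$begin,
               end_day = sp$end)
  })), "spells.csv")
  wcsv(data.frame(pattern_id = seq_along(pool$seqs), weight = pool$weights),
       "weights.csv")
  wcsv(data.frame(cluster = seq_along(result$final$medoids),
                  medoid_pattern = result$final$medoids), "medoids.csv")
  wcsv(result$trace$report, "merge_trace.csv")
  for (ph in result$phase2) {
    wcsv(ph$scan$report, sprintf("phase2_scan_%d.csv", ph$primary))
  }
  reps <- lapply(result$representatives, function(r) {
    list(criterion = r$best$criterion, coverage = r$best$coverage,
         gain = r$best$gain, n_reps = r$best$n_reps,
         reps = lapply(r$best$reps, function(i) {
           sp <- pool$seqs[[i]]$spells
           mapply(function(s, d) c(s, d), sp$state, sp$duration,
                  SIMPLIFY = FALSE)
         }))
  })
  p <- file.path(outdir, "representatives.json")
  jsonlite::write_json(reps, p, auto_unbox = TRUE, digits = 10)
  files <- c(files, p)
  if (!is.null(result$survival$km)) wcsv(result$survival$km, "km.csv")
  if (!is.null(result$survival$cox)) {
    wcsv(result$survival$cox$table, "cox.csv")
  }
  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}
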