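#' Pipeline configuration
#'
#' Analysis settings for [run_pipeline()]. Defaults follow the study
#' design this package reimplements: FN >= 3 structural threshold,
#' sparsity sweep 0.10-0.34 step 0.01 for functional networks, 100 random
#' networks for small-world normalization, 10,000 mediation bootstraps,
#' FDR q = 0.05, stage-1 covariates age/sex/BMI (education added at stage
#' 2, frame-wise displacement added for FC-derived metrics).
#'
#' `include_functional` is off by default: per-sparsity small-world
#' normalization of 25 functional graphs per subject is by far the most
#' expensive stage and is rarely needed when the structural chain is the
#' question; enable it to add functional AUC metrics to the screens.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fn_threshold = 3,
    s_min = 0.10, s_max = 0.34, step = 0.01,
    n_random = 100L,
    n_boot = 10000L,
    q = 0.05,
    min_edges = 5L,
    covariates_stage1 = c("age", "sex", "bmi"),
    covariates_stage2 = c("age", "sex", "bmi", "education"),
    fd_column = "fd",
    enterotype_k = NULL,
    include_nodal = TRUE,
    include_coupling = TRUE,
    include_functional = FALSE,
    outcomes = c("acc_3back", "rt_3back", "ds_forward", "ds_backward",
                 "acc_nogo", "acc_go", "rt_go")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(cfg$fn_threshold > 0, cfg$n_random >= 1, cfg$n_boot >= 100,
            cfg$q > 0, cfg$q < 1)
  structure(cfg, class = "pipeline_config")
}

screen_family <- function(cohort, metric_cols, exposure, covs, fc_metrics,
                          fd_column, q, family) {
  ok <- vapply(metric_cols, function(mc) {
    v <- cohort[[mc]]
    !anyNA(v) && stats::sd(v) > 0
  }, logical(1))
  if (!any(ok)) return(NULL)
  tryCatch(
    association_screen(cohort, metric_cols[ok], exposure = exposure,
                       covariates = covs, fc_metrics = fc_metrics,
                       fd_column = fd_column, q = q, family = family),
    error = function(e) NULL)
}

#' Run the full multi-stage gut-brain-cognition pipeline
#'
#' Executes, on a cohort of count tables and paired SC/FC matrices:
#' (1) alpha diversity and enterotyping; (2) structural graph metrics at
#' the FN threshold, optional functional AUC metrics across the sparsity
#' sweep, and per-region SC-FC coupling; (3) stage-1 association screens of
#' every metric family against Shannon, Simpson and enterotype; (4) stage-2
#' cognition screens restricted to stage-1 hits; (5) percentile-bootstrap
#' mediation for every exposure-metric-outcome triple significant in both
#' stages. Mediation is gated by data dependency: no triple is tested
#' unless its exposure-metric pair passed stage 1 and its metric-outcome
#' pair passed stage 2.
#'
#' @param cohort A [simulate_cohort()] result, or a list with elements
#'   `counts` ([count_table()]), `networks` (named per-subject lists with
#'   `sc`, `fc`) and `cohort` (metadata `data.frame` in subject order).
#' @param config [pipeline_config()].
#' @param rng_seed Root seed; null-model and bootstrap substreams are
#'   derived from it.
#' @param out_dir Optional directory; when given, every stage's tidy table
#'   plus a run log are written there.
#' @return List of class `pipeline_result`: augmented `cohort` table,
#'   `enterotypes`, `global_metrics`, `nodal_metrics`, `coupling`,
#'   `stage1`, `stage2`, `mediation` (data.frame; zero rows when nothing
#'   passed both screens), `mediation_fits`, `config`, `rng_seed`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), rng_seed = 1,
                         out_dir = NULL) {
  counts <- cohort$counts
  networks <- cohort$networks
  meta <- cohort$cohort
  stopifnot(inherits(counts, "count_table"), length(networks) > 0,
            is.data.frame(meta))
  n <- nrow(meta)
  if (length(networks) != n) {
    stop("pipeline: metadata rows and network count disagree", call. = FALSE)
  }

  ## stage 0: diversity + enterotypes -------------------------------------
  meta$shannon <- unname(shannon(counts))
  meta$simpson <- unname(simpson(counts))
  ent <- enterotype(counts, fixed_k = config$enterotype_k,
                    rng_seed = rng_seed)
  meta$enterotype <- ent$labels

  ## stage 1 inputs: network metrics ---------------------------------------
  set.seed(rng_seed + 1L)
  graphs <- lapply(networks, function(s)
    threshold_structural(s$sc, config$fn_threshold))
  glob_rows <- vector("list", n)
  nodal_rows <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- network_profile(graphs[[i]], "structural_single_threshold",
                            n_random = config$n_random)
    glob_rows[[i]] <- as.data.frame(prof$global[global_metric_names])
    if (config$include_nodal) {
      nm <- prof$nodal
      nodal_rows[[i]] <- c(stats::setNames(nm$Dnodal,
                                           paste0("Dnodal_", names(nm$Dnodal))),
                           stats::setNames(nm$Enodal,
                                           paste0("Enodal_", names(nm$Enodal))),
                           stats::setNames(nm$Bnodal,
                                           paste0("Bnodal_", names(nm$Bnodal))))
    }
  }
  global_metrics <- do.call(rbind, glob_rows)
  rownames(global_metrics) <- meta$subject_id
  meta <- cbind(meta, global_metrics)
  nodal_metrics_df <- NULL
  if (config$include_nodal) {
    nodal_metrics_df <- as.data.frame(do.call(rbind, nodal_rows))
    rownames(nodal_metrics_df) <- meta$subject_id
    meta <- cbind(meta, nodal_metrics_df)
  }

  functional_cols <- character()
  if (config$include_functional) {
    fun_rows <- vector("list", n)
    for (i in seq_len(n)) {
      sw <- sparsity_sweep(networks[[i]]$fc, config$s_min, config$s_max,
                           config$step)
      prof <- network_profile(sw, "functional_auc",
                              n_random = config$n_random)
      fun_rows[[i]] <- prof$global
    }
    fun <- as.data.frame(do.call(rbind, fun_rows))
    names(fun) <- paste0("fcauc_", names(fun))
    functional_cols <- names(fun)
    meta <- cbind(meta, fun)
  }

  coupling_df <- NULL
  coupling_cols <- character()
  if (config$include_coupling) {
    pairs <- lapply(networks, function(s)
      list(sc = s$sc, fc = fisher_z(s$fc)))
    coupling_df <- coupling_table(pairs, config$min_edges)
    wide <- stats::reshape(coupling_df[, c("subject", "region", "r")],
                           idvar = "subject", timevar = "region",
                           direction = "wide")
    names(wide) <- sub("^r\\.", "coupling_", names(wide))
    coupling_cols <- setdiff(names(wide), "subject")
    meta <- cbind(meta, wide[match(meta$subject_id, wide$subject),
                             coupling_cols, drop = FALSE])
  }

  ## stage 1: microbiota -> network screens --------------------------------
  families <- list(sc_global = list(cols = global_metric_names, fc = FALSE))
  if (config$include_nodal) {
    labels <- graphs[[1]]$region_labels
    for (m in nodal_metric_names) {
      families[[paste0("sc_", m)]] <-
        list(cols = paste0(m, "_", labels), fc = FALSE)
    }
  }
  if (length(functional_cols) > 0) {
    families$fc_global_auc <- list(cols = functional_cols, fc = TRUE)
  }
  if (length(coupling_cols) > 0) {
    families$coupling <- list(cols = coupling_cols, fc = TRUE)
  }

  stage1 <- list()
  for (fam in names(families)) {
    cols <- families[[fam]]$cols
    fc_flag <- if (families[[fam]]$fc) cols else character()
    for (expo in c("shannon", "simpson", "enterotype")) {
      res <- screen_family(meta, cols, expo, config$covariates_stage1,
                           fc_flag, config$fd_column, config$q, fam)
      if (!is.null(res)) stage1[[paste(fam, expo, sep = ".")]] <- res
    }
  }
  stage1 <- if (length(stage1) > 0) {
    do.call(rbind, c(stage1, list(make.row.names = FALSE)))
  } else {
    data.frame(exposure = character(), metric = character(),
               family = character(), estimate = numeric(), p = numeric(),
               p_adjusted = numeric(), significant = logical())
  }

  hits1 <- stage1[stage1$significant, c("exposure", "metric", "family")]

  ## stage 2: network -> cognition screens for stage-1 hits ---------------
  outcomes <- intersect(config$outcomes, names(meta))
  stage2 <- NULL
  if (nrow(hits1) > 0 && length(outcomes) > 0) {
    fc_all <- unlist(lapply(families[vapply(families, `[[`, TRUE, "fc")],
                            `[[`, "cols"))
    mets <- unique(hits1$metric)
    rows <- lapply(mets, function(mc) {
      covs <- config$covariates_stage2
      if (mc %in% fc_all) covs <- union(covs, config$fd_column)
      out <- lapply(outcomes, function(oc) {
        pc <- tryCatch(
          partial_correlation(meta[[mc]], meta[[oc]],
                              meta[, covs, drop = FALSE]),
          error = function(e) NULL)
        if (is.null(pc)) return(NULL)
        data.frame(metric = mc, outcome = oc, estimate = pc$pr, p = pc$p,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, out)
      if (is.null(out)) return(NULL)
      adj <- fdr_bh(out$p, config$q)
      out$p_adjusted <- adj$p_adjusted
      out$significant <- adj$rejected
      out
    })
    stage2 <- do.call(rbind, rows)
  }

  ## stage 3: mediation for doubly significant triples ---------------------
  mediation <- data.frame()
  mediation_fits <- list()
  if (!is.null(stage2) && any(stage2$significant)) {
    hits2 <- stage2[stage2$significant, c("metric", "outcome")]
    triples <- merge(hits1, hits2, by = "metric")
    fc_all <- unlist(lapply(families[vapply(families, `[[`, TRUE, "fc")],
                            `[[`, "cols"))
    med_rows <- list()
    for (t_i in seq_len(nrow(triples))) {
      tr <- triples[t_i, ]
      covs <- config$covariates_stage2
      if (tr$metric %in% fc_all) covs <- union(covs, config$fd_column)
      x <- if (tr$exposure == "enterotype") factor(meta$enterotype) else
        meta[[tr$exposure]]
      fit <- mediate(x, meta[[tr$metric]], meta[[tr$outcome]],
                     covariates = meta[, covs, drop = FALSE],
                     n_boot = config$n_boot,
                     rng_seed = rng_seed + 100L + t_i)
      fits <- if (inherits(fit, "mediation_result")) list(fit) else fit
      for (f in fits) {
        key <- paste(tr$exposure, tr$metric, tr$outcome, f$level, sep = ".")
        mediation_fits[[key]] <- f
        med_rows[[key]] <- data.frame(
          exposure = tr$exposure, metric = tr$metric, outcome = tr$outcome,
          level = f$level, a = f$a, b = f$b, c = f$c, c_prime = f$c_prime,
          indirect = f$indirect, ci_lo = f$boot_ci[1], ci_hi = f$boot_ci[2],
          significant = f$significant, stringsAsFactors = FALSE)
      }
    }
    mediation <- do.call(rbind, c(med_rows, list(make.row.names = FALSE)))
    if (is.null(mediation)) mediation <- data.frame()
  }

  result <- structure(list(
    cohort = meta, enterotypes = ent, global_metrics = global_metrics,
    nodal_metrics = nodal_metrics_df, coupling = coupling_df,
    stage1 = stage1, stage2 = stage2, mediation = mediation,
    mediation_fits = mediation_fits, config = config, rng_seed = rng_seed
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, enterotype k = %d\n",
              nrow(x$cohort), x$enterotypes$k))
  cat(sprintf("  stage 1: %d/%d significant; stage 2: %d/%d; mediation: %d triples (%d significant)\n",
              sum(x$stage1$significant), nrow(x$stage1),
              if (is.null(x$stage2)) 0 else sum(x$stage2$significant),
              if (is.null(x$stage2)) 0 else nrow(x$stage2),
              nrow(x$mediation),
              if (nrow(x$mediation)) sum(x$mediation$significant) else 0L))
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(result$cohort, "cohort.tsv")
  wt(result$stage1, "stage1_associations.tsv")
  wt(result$stage2, "stage2_cognition.tsv")
  wt(result$mediation, "stage3_mediation.tsv")
  wt(result$coupling, "coupling.tsv")
  jsonlite::write_json(
    list(labels = result$enterotypes$labels, k = result$enterotypes$k,
         driver_taxa = result$enterotypes$driver_taxa,
         ch_scores = as.list(result$enterotypes$ch_scores)),
    file.path(out_dir, "enterotypes.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(rng_seed = result$rng_seed,
         config = unclass(result$config),
         package_version = as.character(utils::packageVersion("gutbrainnet")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
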