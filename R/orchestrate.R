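# End-to-end experiment orchestration: centre-wise splits, the full
# segmentation -> feature inference -> classification -> evaluation ->
# explanation chain, manifest writing and a small command-line front end.

#' Centre-wise split plan
#'
#' @param train_centres,internal_val_centres,external_centres disjoint
#'   centre-id character vectors whose union covers the cohort.
#' @return a `split_plan` object.
#' @export
split_plan <- function(train_centres, internal_val_centres, external_centres) {
  all <- c(train_centres, internal_val_centres, external_centres)
  if (anyDuplicated(all)) stop("split plan centres must be pairwise disjoint")
  structure(list(train_centres = train_centres,
                 internal_val_centres = internal_val_centres,
                 external_centres = external_centres),
            class = "split_plan")
}

#' Split a cohort by centre
#'
#' Assignment is purely by `centre_id`; every patient lands in exactly one
#' of the three lists.
#'
#' @param cohort list of `case_record` objects.
#' @param plan a [split_plan]; every centre it names must occur in the
#'   cohort, and every cohort centre must be planned.
#' @return list with `train`, `internal`, `external` case lists.
#' @export
centre_split <- function(cohort, plan) {
  stopifnot(inherits(plan, "split_plan"))
  ids <- vapply(cohort, function(x) x$centre_id, "")
  planned <- c(plan$train_centres, plan$internal_val_centres, plan$external_centres)
  missing_in_cohort <- setdiff(planned, unique(ids))
  if (length(missing_in_cohort) > 0)
    stop("centre(s) in plan absent from cohort: ",
         paste(missing_in_cohort, collapse = ", "))
  unplanned <- setdiff(unique(ids), planned)
  if (length(unplanned) > 0)
    stop("cohort centre(s) not covered by plan: ",
         paste(unplanned, collapse = ", "))
  list(train = cohort[ids %in% plan$train_centres],
       internal = cohort[ids %in% plan$internal_val_centres],
       external = cohort[ids %in% plan$external_centres])
}

#' Experiment configuration
#'
#' Bundles the phantom parameters, network configurations, split plan and
#' evaluation settings of one end-to-end run. Defaults are desk-scale: they
#' keep the full pipeline runnable on one CPU in minutes while preserving
#' the structure of the full protocol (9 centres split 4/2/3, 4-fold
#' segmentation CV, six classifier variants, Youden threshold transfer,
#' bootstrap CIs).
#'
#' @param n_cases cohort size.
#' @param n_centres number of centres.
#' @param plan a [split_plan] over the centre ids `C1..Cn`.
#' @param phantom a [phantom_spec].
#' @param p_emvi,p_cr label prevalences.
#' @param arms channel arms to run: subset of `c("DWI", "DWI+T2W")`.
#' @param targets tasks: subset of `c("emvi", "cr")`.
#' @param variants classifier variants to run.
#' @param seg_config a [unet_config] (input channels set per arm).
#' @param cls_config a [classifier_config] (variant/channels set per run).
#' @param seg_epochs,seg_cv_folds,seg_cv_epochs,cls_lr,seg_lr training knobs.
#' @param n_boot bootstrap replications for the metric reports.
#' @param attention_cases number of external cases to map with Grad-CAM++.
#' @param seed global seed; all stage seeds are derived from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_cases = 60L, n_centres = 9L,
                              plan = split_plan(paste0("C", 1:4),
                                                paste0("C", 5:6),
                                                paste0("C", 7:9)),
                              phantom = phantom_spec(),
                              p_emvi = 0.60, p_cr = 0.28,
                              arms = "DWI", targets = c("emvi", "cr"),
                              variants = CLS_VARIANTS,
                              seg_config = unet_config(),
                              cls_config = classifier_config(),
                              seg_epochs = 10L, seg_cv_folds = 4L,
                              seg_cv_epochs = 6L, seg_lr = 1e-3,
                              cls_lr = 1e-3, n_boot = 1000L,
                              attention_cases = 2L, seed = 1L) {
  stopifnot(length(arms) >= 1, all(arms %in% c("DWI", "DWI+T2W")),
            all(targets %in% c("emvi", "cr")), all(variants %in% CLS_VARIANTS))
  structure(as.list(environment()), class = "experiment_config")
}

arm_channels <- function(arm) if (arm == "DWI") 1L else 2L

# record which patient ids touched which pipeline stage, and assert that
# external cases never influenced training or threshold selection
assert_no_leak <- function(trace) {
  ext <- trace$external_ids
  for (stage in c("segmentation_train", "classifier_train",
                  "checkpoint_selection", "threshold_selection")) {
    leak <- intersect(trace[[stage]], ext)
    if (length(leak) > 0)
      stop("information leak: external case(s) in stage ", stage, ": ",
           paste(leak, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full desk-scale experiment
#'
#' Generates the cohort, then per channel arm: k-fold segmentation CV on
#' the development centres, full development segmentation training with
#' internal-validation checkpointing, feature-pyramid inference for every
#' case, classifier training for each requested variant and task, Youden
#' operating point on internal validation with threshold transfer, metric
#' reports with bootstrap CIs on internal and external sets, attention maps
#' for selected external cases, and the cohort summary table. All artefacts
#' are written under `run_dir` with an md5 manifest; the id trace proves
#' external cases never touch training or threshold selection.
#'
#' @param config an [experiment_config].
#' @param run_dir output directory.
#' @return the report bundle (invisibly written to disk): per-arm, per-task
#'   score sets, metric reports, thresholds, segmentation CV results, the
#'   cohort summary, the id trace and the manifest.
#' @export
run_experiment <- function(config, run_dir = tempfile("mlnet3d_run_")) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- function(k) (config$seed * 131L + k) %% 2000000000L
  centres <- default_centre_profiles(config$n_centres, seed = stage_seed(1L))
  cohort <- generate_cohort(config$n_cases, centres, config$p_emvi, config$p_cr,
                            seed = stage_seed(2L), spec = config$phantom)
  splits <- centre_split(cohort, config$plan)
  dev_cases <- c(splits$train, splits$internal)
  pid <- function(cases) vapply(cases, function(x) x$patient_id, "")
  trace <- list(external_ids = pid(splits$external),
                segmentation_train = pid(dev_cases),
                classifier_train = pid(splits$train),
                checkpoint_selection = pid(splits$internal),
                threshold_selection = pid(splits$internal),
                external_evaluation = pid(splits$external))
  assert_no_leak(trace)

  bundle <- list(config = config, trace = trace, arms = list())
  bundle$summary <- summarize_cohort(
    list(All = cohort, Development = dev_cases, External = splits$external),
    compare = c("Development", "External"))
  write.csv(bundle$summary, file.path(run_dir, "cohort_summary.csv"),
            row.names = FALSE)

  for (arm in config$arms) {
    ch <- arm_channels(arm)
    scfg <- config$seg_config
    scfg$input_channels <- ch
    scfg$seed <- stage_seed(10L)
    cv <- crossval_segmentation(dev_cases, k = config$seg_cv_folds, scfg,
                                epochs = config$seg_cv_epochs, lr = config$seg_lr)
    seg <- train_segmenter(splits$train, scfg, epochs = config$seg_epochs,
                           val_cases = splits$internal, lr = config$seg_lr)
    pyramids <- setNames(lapply(cohort, function(cs) {
      py <- extract_features(seg$model, cs$image)
      prepare_injection(py, dim(cs$image$data)[1:3],
                        classifier_config("mlnet", input_channels = ch))
    }), pid(cohort))
    pch <- extract_features(seg$model, cohort[[1]]$image)$channels

    arm_res <- list(seg_cv = cv[c("fold_dice", "mean_dice", "sd_dice")],
                    seg_log = seg$log, pyramid_channels = pch, tasks = list())
    for (target in config$targets) {
      ccfg <- config$cls_config
      ccfg$input_channels <- ch
      ccfg$learning_rate <- config$cls_lr
      ccfg$seed <- stage_seed(20L)
      abl <- run_ablation(splits, pyramids, ccfg, target = target,
                          variants = config$variants, keep_models = TRUE)
      task <- list()
      for (v in names(abl)) {
        op <- youden_threshold(abl[[v]]$internal)
        task[[v]] <- list(
          threshold = op$threshold, youden_J = op$youden_J,
          internal = abl[[v]]$internal, external = abl[[v]]$external,
          report_internal = metric_report(abl[[v]]$internal, op$threshold,
                                          n_boot = config$n_boot,
                                          seed = stage_seed(30L)),
          report_external = metric_report(abl[[v]]$external, op$threshold,
                                          n_boot = config$n_boot,
                                          seed = stage_seed(31L)),
          log = abl[[v]]$log)
        sc <- abl[[v]]$external
        write.csv(sc, file.path(run_dir, sprintf("scores_%s_%s_%s.csv",
                                                 gsub("\\+", "", arm), target, v)),
                  row.names = FALSE)
      }
      # attention maps for the first external cases, mlnet when available
      vmap <- if ("mlnet" %in% names(abl)) "mlnet" else names(abl)[1]
      n_att <- min(config$attention_cases, length(splits$external))
      if (n_att > 0) {
        task$attention <- lapply(splits$external[seq_len(n_att)], function(cs) {
          amap <- gradcam_pp(abl[[vmap]]$model, cs,
                             pyramid = pyramids[[cs$patient_id]])
          list(patient_id = cs$patient_id,
               overlap = attention_overlap(amap, cs$mask))
        })
      }
      arm_res$tasks[[target]] <- task
    }
    bundle$arms[[arm]] <- arm_res
  }
  cfg_txt <- utils::capture.output(utils::str(config, max.level = 2))
  writeLines(cfg_txt, file.path(run_dir, "config.txt"))
  files <- sort(list.files(run_dir, full.names = TRUE, recursive = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  bundle$manifest <- manifest
  bundle$run_dir <- run_dir
  class(bundle) <- "experiment_bundle"
  invisible(bundle)
}

fmt_ci <- function(m) sprintf("%.2f (%.2f-%.2f)", m["point"], m["lo"], m["hi"])

#' Format an experiment bundle into per-task tables and ROC data
#'
#' One table per arm and task: a row per variant with each metric shown as
#' `point (lo-hi)`; the per-column maxima are flagged in `best` columns
#' (the bolding rule of a results table). ROC points are recomputed from
#' the stored external score sets, and Mann-Whitney tests compare the
#' per-case absolute prediction errors of every variant against the first.
#'
#' @param bundle an `experiment_bundle` from [run_experiment].
#' @return list per arm/task with `table`, `roc` (per variant) and
#'   `mann_whitney` comparison data frames.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  out <- list()
  metrics <- c("auc", "sensitivity", "specificity", "ppv", "npv", "f1")
  for (arm in names(bundle$arms)) {
    for (target in names(bundle$arms[[arm]]$tasks)) {
      task <- bundle$arms[[arm]]$tasks[[target]]
      vs <- setdiff(names(task), "attention")
      tab <- do.call(rbind, lapply(vs, function(v) {
        r <- task[[v]]$report_external
        row <- data.frame(network = v, stringsAsFactors = FALSE)
        for (m in metrics) row[[m]] <- fmt_ci(r[[m]])
        row
      }))
      pts <- sapply(metrics, function(m)
        vapply(vs, function(v) task[[v]]$report_external[[m]]["point"], 1))
      pts <- matrix(pts, nrow = length(vs),
                    dimnames = list(vs, metrics))
      for (m in metrics)
        tab[[paste0("best_", m)]] <- pts[, m] >= max(pts[, m]) - 1e-12
      roc <- lapply(setNames(vs, vs), function(v) roc_curve(task[[v]]$external))
      mw <- NULL
      if (length(vs) > 1) {
        ref <- task[[vs[1]]]$external
        err <- function(ss) abs(ss$score - ss$label)
        mw <- do.call(rbind, lapply(vs[-1], function(v) {
          t <- mann_whitney(err(ref), err(task[[v]]$external))
          data.frame(reference = vs[1], comparison = v, U = t$U,
                     p_value = t$p_value, stringsAsFactors = FALSE)
        }))
      }
      out[[arm]][[target]] <- list(table = tab, roc = roc, mann_whitney = mw)
    }
  }
  out
}

#' Minimal command-line entry point
#'
#' Subcommands: `phantom generate --n --centres --p-emvi --p-cr --seed --out`
#' writes a NIfTI cohort with its sidecar; `run --n --seed --out` executes a
#' desk-scale [run_experiment].
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status 0 on success, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (length(args) >= 2 && args[1] == "phantom" && args[2] == "generate") {
    n <- as.integer(opt("n", "20"))
    ncen <- as.integer(opt("centres", "9"))
    out <- opt("out", "phantom_cohort")
    centres <- default_centre_profiles(ncen)
    cohort <- generate_cohort(n, centres,
                              p_emvi = as.numeric(opt("p-emvi", "0.60")),
                              p_cr = as.numeric(opt("p-cr", "0.28")),
                              seed = as.integer(opt("seed", "1")))
    write_cohort(cohort, out)
    message(sprintf("wrote %d cases to %s", n, out))
  } else if (length(args) >= 1 && args[1] == "run") {
    cfg <- experiment_config(n_cases = as.integer(opt("n", "40")),
                             seed = as.integer(opt("seed", "1")),
                             variants = c("plain_resnet10", "mlnet"),
                             targets = "emvi")
    bundle <- run_experiment(cfg, run_dir = opt("out", "mlnet3d_run"))
    message("run complete: ", bundle$run_dir)
  } else {
    message("usage: mlnet3d phantom generate [--n N] [--centres K] [--p-emvi P]",
            " [--p-cr P] [--seed S] [--out DIR]\n",
            "       mlnet3d run [--n N] [--seed S] [--out DIR]")
    return(invisible(1L))
  }
  invisible(0L)
}
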