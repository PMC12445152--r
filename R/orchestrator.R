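# Experiment orchestration: profiles, one-call reproducible runs over one
# or both mapping conditions, artifact writing, and condition comparison.

#' Experiment configuration
#'
#' Bundles every module's settings under a named profile. The `"paper"`
#' profile mirrors the full-scale protocol (224 x 224 canvas, 50 dot
#' parameter sets x 12 images, 4500/900 comparison trials per task, 20
#' epochs per stage); the `"desk"` profile is the reduced configuration
#' used by the test suite and acceptance runs (64 px dot canvas, 2x
#' numeral replication, 10 parameter sets, 2000/400 trials, 8 epochs),
#' sized to keep a full curriculum run in CPU-minutes. Any field can be
#' overridden through `...` (nested lists are merged).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param seed Master seed; every source of randomness in the run derives
#'   from it.
#' @param conditions Mapping conditions to run.
#' @param out_dir Optional artifact directory.
#' @param ... Named overrides merged into the profile (e.g.
#'   `curriculum = list(epochs = 4)`).
#' @return A `numalign_config`.
#' @export
experiment_config <- function(profile = c("desk", "paper"), seed = 1L,
                              conditions = c("cross_format", "cross_label"),
                              out_dir = NULL, ...) {
  profile <- match.arg(profile)
  conditions <- match.arg(conditions, several.ok = TRUE)
  base <- default_profile(profile)
  overrides <- list(...)
  for (nm in names(overrides))
    base[[nm]] <- modifyList(base[[nm]] %||% list(), overrides[[nm]])
  structure(c(list(profile = profile, seed = as.integer(seed),
                   conditions = conditions, out_dir = out_dir), base),
            class = "numalign_config")
}

default_profile <- function(profile) {
  if (profile == "paper") {
    list(stimuli = list(canvas_size = 224L, upsample = 8L,
                        n_param_sets = 50L, images_per_set = 12L,
                        train_per_set = 10L,
                        images_per_numerosity = 600L,
                        train_per_numerosity = 500L),
         datasets = list(n_train = 4500L, n_test = 900L),
         network = list(channels = c(V1 = 64L, V2 = 128L, V3 = 256L,
                                     IPS = 512L), recurrence = 1L),
         curriculum = list(epochs = 20L, lr = 1e-3, batch_size = 32L))
  } else {
    list(stimuli = list(canvas_size = 64L, upsample = 2L,
                        n_param_sets = 10L, images_per_set = 12L,
                        train_per_set = 10L,
                        images_per_numerosity = 120L,
                        train_per_numerosity = 100L),
         datasets = list(n_train = 2000L, n_test = 400L),
         network = list(channels = c(V1 = 16L, V2 = 32L, V3 = 32L,
                                     IPS = 64L), recurrence = 1L),
         curriculum = list(epochs = 8L, lr = 1e-3, batch_size = 32L))
  }
}

config_model <- function(config, seed = 1L) {
  ch <- config$network$channels
  rec <- config$network$recurrence %||% 1L
  model_config(blocks = list(
    V1 = list(channels = ch[["V1"]], stride = 2, recurrence = rec),
    V2 = list(channels = ch[["V2"]], stride = 2, recurrence = rec),
    V3 = list(channels = ch[["V3"]], stride = 2, recurrence = rec),
    IPS = list(channels = ch[["IPS"]], stride = 2, recurrence = rec)),
    seed = seed)
}

#' Generate all stimuli and task datasets for a run
#'
#' Dot and numeral pools plus the three comparison datasets and the merged
#' labeling dataset, all derived deterministically from one seed.
#'
#' @param config A [experiment_config()].
#' @param seed Seed (defaults to the config's).
#' @return Named list of datasets (also carrying `pools`).
#' @export
build_experiment_datasets <- function(config, seed = config$seed) {
  st <- config$stimuli
  seeds <- derive_seeds(seed, 7L)
  dots <- generate_dot_dataset(st$n_param_sets, st$images_per_set,
                               st$train_per_set, seed = seeds[1L],
                               canvas_size = st$canvas_size)
  numerals <- generate_numeral_dataset(st$images_per_numerosity,
                                       st$train_per_numerosity,
                                       seed = seeds[2L],
                                       upsample = st$upsample)
  pools <- make_pools(dots, numerals)
  ds <- config$datasets
  list(pools = pools,
       nonsymbolic = build_comparison_dataset("nonsymbolic", ds$n_train,
                                              ds$n_test, pools, seeds[3L]),
       cross_format = build_comparison_dataset("cross_format", ds$n_train,
                                               ds$n_test, pools, seeds[4L]),
       symbolic = build_comparison_dataset("symbolic", ds$n_train,
                                           ds$n_test, pools, seeds[5L]),
       labeling = build_labeling_dataset(c("nonsymbolic", "symbolic"),
                                         pools, seeds[6L]))
}

#' Run the full experiment
#'
#' Generates stimuli and datasets once, then runs the three-stage
#' curriculum under each requested mapping condition on identical data.
#' When `config$out_dir` is set, per-epoch accuracy logs, pair tables,
#' NRS/MDS/alignment artifacts, stage checkpoints and a manifest are
#' written beneath it.
#'
#' @param config A [experiment_config()].
#' @param stages Stage prefix to run (default all three).
#' @return A `numalign_experiment`: `datasets`, one `numalign_curriculum`
#'   per condition, and the echoed config.
#' @export
run_experiment <- function(config, stages = 1:3) {
  stopifnot(inherits(config, "numalign_config"))
  datasets <- build_experiment_datasets(config)
  cur <- config$curriculum
  runs <- list()
  for (cond in config$conditions) {
    runs[[cond]] <- run_curriculum(
      datasets, condition = cond,
      model_cfg = config_model(config),
      epochs = cur$epochs, lr = cur$lr, batch_size = cur$batch_size,
      seed = config$seed, stages = stages)
  }
  res <- structure(list(config = config, datasets = datasets,
                        conditions = runs),
                   class = "numalign_experiment")
  if (!is.null(config$out_dir)) write_experiment(res, config$out_dir)
  res
}

#' @export
print.numalign_experiment <- function(x, ...) {
  cat(sprintf("<numalign_experiment> profile=%s seed=%d\n",
              x$config$profile, x$config$seed))
  for (cond in names(x$conditions)) {
    cat(sprintf("-- condition %s --\n", cond))
    print(x$conditions[[cond]])
  }
  invisible(x)
}

#' Write all artifacts of an experiment run
#'
#' @param results A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return A manifest data.frame of written files, invisibly.
#' @export
write_experiment <- function(results, dir) {
  stopifnot(inherits(results, "numalign_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  add <- function(p) files <<- c(files, p)
  cfg <- results$config
  jsonlite::write_json(list(profile = cfg$profile, seed = cfg$seed,
                            conditions = cfg$conditions,
                            stimuli = cfg$stimuli, datasets = cfg$datasets,
                            network = as.list(cfg$network$channels),
                            curriculum = cfg$curriculum),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  add(file.path(dir, "config.json"))
  for (cond in names(results$conditions)) {
    run <- results$conditions[[cond]]
    cdir <- file.path(dir, cond)
    if (!dir.exists(cdir)) dir.create(cdir)
    traj <- do.call(rbind, lapply(names(run$records), function(nm) {
      r <- run$records[[nm]]
      data.frame(stage = nm, epoch = seq_len(r$epochs), r$accuracy,
                 train_loss = r$train_loss)
    }))
    write.csv(traj, file.path(cdir, "accuracy_log.csv"), row.names = FALSE)
    add(file.path(cdir, "accuracy_log.csv"))
    for (nm in names(run$analyses)) {
      a <- run$analyses[[nm]]
      for (task in names(a$pair_tables)) {
        p <- file.path(cdir, sprintf("%s_pairs_%s.csv", nm, task))
        write_pair_table(a$pair_tables[[task]], p)
        add(p)
      }
      write_representation(a, cdir, prefix = nm)
      add(file.path(cdir, paste0(nm, "_alignment.json")))
    }
    ck <- file.path(cdir, "final_checkpoint.rds")
    save_checkpoint(run$model, ck)
    add(ck)
    if (!is.null(run$forgotten_nonsymbolic)) {
      p <- file.path(cdir, "forgotten_nonsymbolic.json")
      jsonlite::write_json(unname(apply(run$forgotten_nonsymbolic, 1L,
                                        function(r) as.list(unname(r)))),
                           p, auto_unbox = TRUE)
      add(p)
    }
  }
  manifest <- data.frame(file = files, exists = file.exists(files))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Compare the two mapping conditions
#'
#' Tabulates, at the stage-2 (mapping) boundary, symbolic comparison
#' accuracy, alignment correlation and normalized distance per condition,
#' their differences, and the qualitative orderings as booleans.
#'
#' @param a,b `numalign_curriculum` runs at matching stages (typically the
#'   cross-format and cross-label runs of one experiment).
#' @return A list with a `metrics` data.frame (one row per condition),
#'   `deltas` (a minus b) and `orderings` (logical flags).
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "numalign_curriculum"),
            inherits(b, "numalign_curriculum"))
  if (!identical(names(a$analyses), names(b$analyses)))
    stop("runs are at different stages and cannot be compared", call. = FALSE)
  if (!("mapping" %in% names(a$analyses)))
    stop("both runs must include the mapping stage", call. = FALSE)
  pull <- function(run) {
    m <- run$analyses$mapping
    c(symbolic_accuracy = unname(m$accuracy["symbolic"]),
      correlation = m$alignment$correlation,
      norm_distance = m$alignment$norm_distance)
  }
  ma <- pull(a); mb <- pull(b)
  metrics <- data.frame(condition = c(a$condition, b$condition),
                        rbind(ma, mb), row.names = NULL)
  list(metrics = metrics, deltas = ma - mb,
       orderings = c(symbolic_accuracy_a_gt_b = unname(ma[1] > mb[1]),
                     correlation_a_gt_b = unname(ma[2] > mb[2]),
                     norm_distance_a_lt_b = unname(ma[3] < mb[3])))
}
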