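#' Experiment configuration for the three-stage pipeline
#'
#' Mirrors the published workflow: of the patients entering the
#' feature-generation stage, four serve as KNN reference points and four as
#' validation inputs for the genetic search; the evolved formula, with the
#' same reference points and k = 100, then classifies the held-out patients.
#'
#' Each group is class-balanced by seeded random undersampling of the
#' majority class, and additionally capped at `group_max_per_class`
#' segments per class so the wrapper fitness stays cheap (the search only
#' needs a small, balanced sample).
#'
#' @param segmentation a [segmentation_config()].
#' @param gp a [gp_config()].
#' @param knn_k neighbour count of the classification stage.
#' @param n_reference_patients,n_validation_patients patients assigned to
#'   the two fitness groups (patient-level split; no patient contributes to
#'   both).
#' @param group_max_per_class cap on segments per class per group.
#' @param balance_seed seed for group assignment and undersampling.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(segmentation = segmentation_config(),
                              gp = gp_config(), knn_k = 100L,
                              n_reference_patients = 4L,
                              n_validation_patients = 4L,
                              group_max_per_class = 200L,
                              balance_seed = 1L) {
  if (n_reference_patients < 1L || n_validation_patients < 1L)
    stop("group split counts must be >= 1", call. = FALSE)
  structure(list(segmentation = segmentation, gp = gp,
                 knn_k = as.integer(knn_k),
                 n_reference_patients = as.integer(n_reference_patients),
                 n_validation_patients = as.integer(n_validation_patients),
                 group_max_per_class = as.integer(group_max_per_class),
                 balance_seed = as.integer(balance_seed)),
            class = "experiment_config")
}

#' Assign patients to balanced reference / validation groups
#'
#' Patients (not segments) are randomly partitioned into the two fitness
#' groups; within each group the classes are balanced by seeded
#' undersampling and capped at `group_max_per_class`.
#'
#' @param feature_tables named list, one labelled feature table (as from
#'   [compute_feature_table()]) per patient.
#' @param cfg an [experiment_config()].
#' @return a [fitness_context()] with attributes `reference_patients` and
#'   `validation_patients`.
#' @export
build_groups <- function(feature_tables, cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  n_need <- cfg$n_reference_patients + cfg$n_validation_patients
  ids <- names(feature_tables)
  if (is.null(ids) || anyDuplicated(ids))
    stop("feature_tables must be a named list with unique patient ids",
         call. = FALSE)
  if (length(ids) < n_need)
    stop("need at least ", n_need, " patients, got ", length(ids),
         call. = FALSE)
  set.seed(cfg$balance_seed)
  perm <- sample(ids)
  ref_ids <- perm[seq_len(cfg$n_reference_patients)]
  val_ids <- perm[cfg$n_reference_patients + seq_len(cfg$n_validation_patients)]
  ref <- balance_group(do.call(rbind, feature_tables[ref_ids]),
                       cfg$group_max_per_class, "reference")
  val <- balance_group(do.call(rbind, feature_tables[val_ids]),
                       cfg$group_max_per_class, "validation")
  ctx <- fitness_context(ref, val, k = cfg$knn_k)
  attr(ctx, "reference_patients") <- ref_ids
  attr(ctx, "validation_patients") <- val_ids
  ctx
}

balance_group <- function(df, cap, what) {
  sp <- which(df$label == "spike")
  np <- which(df$label == "nonspike")
  if (length(sp) == 0L)
    stop(what, " group has zero spike segments", call. = FALSE)
  m <- min(length(sp), length(np), cap)
  keep <- c(resample(sp, m), resample(np, m))
  df[sort(keep), , drop = FALSE]
}

#' Run the full three-stage pipeline
#'
#' Preprocess the training patients, build balanced groups, evolve the best
#' formula, freeze the KNN reference points, then detect and evaluate on
#' the held-out patients. Training and evaluation patient sets must be
#' disjoint (asserted), matching the patient-independent protocol.
#'
#' @param train named list of training patients, each a list with elements
#'   `recording` (an `meg_recording`) and `events` (annotation data frame)
#'   — the shape returned by [simulate_recording()].
#' @param holdout named list of held-out patients, same shape.
#' @param cfg an [experiment_config()].
#' @param seed master seed; every stochastic stage (group balancing is
#'   additionally governed by `cfg$balance_seed`, the GP by
#'   `cfg$gp$rng_seed` when set) runs under this seed, so a rerun with the
#'   same inputs and config is bit-identical.
#' @param out_dir optional run directory; when given, the evolved formula,
#'   reference points, fitness trace, per-window decisions, evaluation
#'   report and a YAML manifest are written there.
#' @return list with `formula`, `gp_result`, `model`, `decisions` (pooled
#'   across evaluation patients, with a `patient` column), `evaluation`,
#'   `manifest`.
#' @export
run_pipeline <- function(train, holdout, cfg = experiment_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(names(train)) || is.null(names(holdout)))
    stop("train and eval must be named lists of patients", call. = FALSE)
  if (length(intersect(names(train), names(holdout))) > 0L)
    stop("training and evaluation patients must be disjoint", call. = FALSE)
  set.seed(seed)
  feats <- lapply(train, function(p)
    compute_feature_table(p$recording, p$events, cfg$segmentation))
  ctx <- build_groups(feats, cfg)
  set.seed(seed + 1L)                     # GP stream, post-balancing
  gp_res <- evolve_formula(ctx, cfg$gp)
  formula <- gp_res$best
  ref_scalars <- evaluate_formula(formula, ctx$reference_x)
  model <- knn_model(ref_scalars, ctx$reference_labels, k = cfg$knn_k)
  decisions <- do.call(rbind, lapply(names(holdout), function(id) {
    d <- detect_spikes(holdout[[id]]$recording, formula, model,
                       cfg$segmentation, annotations = holdout[[id]]$events)
    cbind(patient = id, d)
  }))
  evaluation <- evaluate_detections(decisions)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("spikegp")),
    formula = deparse_formula(formula),
    gp_best_fitness = gp_res$best_fitness,
    reference_patients = attr(ctx, "reference_patients"),
    validation_patients = attr(ctx, "validation_patients"),
    evaluation_patients = names(holdout),
    knn_k = model$k,
    config = list(
      window_ms = cfg$segmentation$window_ms,
      overlap_fraction = cfg$segmentation$overlap_fraction,
      median_filter_order = cfg$segmentation$median_filter_order,
      population_size = cfg$gp$population_size,
      n_generations = cfg$gp$n_generations,
      max_tree_level = cfg$gp$max_tree_level,
      group_max_per_class = cfg$group_max_per_class,
      balance_seed = cfg$balance_seed),
    sensitivity = evaluation$sensitivity,
    specificity = evaluation$specificity,
    counts = as.list(evaluation$counts))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_formula(formula, file.path(out_dir, "formula.sexp"))
    write_trace(gp_res, file.path(out_dir, "fitness_trace.tsv"))
    write_reference_points(model, file.path(out_dir, "reference_points.tsv"))
    write_detections(decisions, file.path(out_dir, "decisions.tsv"))
    writeLines(c(sprintf("sensitivity\t%s", format(evaluation$sensitivity)),
                 sprintf("specificity\t%s", format(evaluation$specificity)),
                 sprintf("%s\t%d", names(evaluation$counts),
                         evaluation$counts)),
               file.path(out_dir, "evaluation.txt"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(formula = formula, gp_result = gp_res, model = model,
       decisions = decisions, evaluation = evaluation, manifest = manifest)
}
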