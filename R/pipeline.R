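.cowpipe_cache <- new.env(parent = emptyenv())

#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end run with the frozen defaults.
#' Values can be overridden per call, or loaded from a YAML profile with
#' [read_config] (the segmentation block is where per-scanner profiles
#' would live for clinical data).
#'
#' @param seed integer seed recorded in every output.
#' @param atlas an [atlas_landmarks] (default: the phantom-derived atlas).
#' @param reference a [cow_volume] or NIfTI path used as the histogram
#'   matching reference; `NULL` uses the canonical noise-free complete
#'   phantom.
#' @param target_spacing isotropic atlas grid spacing in mm.
#' @param strict,relaxed [segmentation_params] for the two phases.
#' @param spur_min_voxels,prune_min_voxels,bignode_radius_mm skeleton and
#'   graph parameters.
#' @param label a [label_params].
#' @param features an [fscore_params].
#' @return a list of class `cow_config`.
#' @export
cow_config <- function(seed = 1L, atlas = NULL, reference = NULL,
                       target_spacing = 0.5,
                       strict = segmentation_params("strict"),
                       relaxed = segmentation_params("relaxed"),
                       spur_min_voxels = 3L, prune_min_voxels = 10L,
                       bignode_radius_mm = 5,
                       label = label_params(),
                       features = fscore_params()) {
  structure(list(seed = as.integer(seed), atlas = atlas,
                 reference = reference, target_spacing = target_spacing,
                 strict = strict, relaxed = relaxed,
                 spur_min_voxels = as.integer(spur_min_voxels),
                 prune_min_voxels = as.integer(prune_min_voxels),
                 bignode_radius_mm = bignode_radius_mm,
                 label = label, features = features),
            class = "cow_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [cow_config] arguments.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- cow_config()
  for (nm in intersect(names(y), c("seed", "target_spacing",
                                   "spur_min_voxels", "prune_min_voxels",
                                   "bignode_radius_mm")))
    cfg[[nm]] <- y[[nm]]
  for (ph in c("strict", "relaxed"))
    if (!is.null(y[[ph]]))
      cfg[[ph]] <- do.call(segmentation_params,
                           c(list(phase = ph), y[[ph]]))
  if (!is.null(y$label)) cfg$label <- do.call(label_params, y$label)
  if (!is.null(y$features)) cfg$features <- do.call(fscore_params, y$features)
  if (!is.null(y$atlas)) cfg$atlas <- read_atlas(y$atlas)
  if (!is.null(y$reference)) cfg$reference <- y$reference
  cfg
}

default_reference <- function() {
  if (is.null(.cowpipe_cache$reference)) {
    cfg <- phantom_config(variant = "complete", noise_sigma = 0)
    .cowpipe_cache$reference <- rasterize(build_cow_spec(cfg)$specs, cfg)
  }
  .cowpipe_cache$reference
}

#' Run the full Circle of Willis labeling pipeline
#'
#' preprocess (histogram match, atlas resampling) -> two-phase
#' segmentation -> skeletonization with Phase-1 preservation -> vascular
#' graph, pruning and big-node merging -> basilar and M1/A1 labeling ->
#' A1 variant classification -> bilateral A1 features and the F / F*
#' scores. Outputs are identical for identical inputs, config and seed.
#'
#' @param input a [cow_volume] or path to a NIfTI volume (assumed
#'   skull-free and rigidly aligned to atlas space; plug external tools
#'   upstream for clinical data).
#' @param config a [cow_config].
#' @param out_dir optional output directory: writes the run report JSON,
#'   both masks, the merged skeleton and a labeled node overlay as NIfTI.
#' @return a `cow_report` list: per-stage timings, all scores, the label
#'   result, per-side A1 features, final classifications, config snapshot
#'   and package version.
#' @export
run_pipeline <- function(input, config = cow_config(), out_dir = NULL) {
  t_all <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, t0)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  stage_failed <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  vol <- if (inherits(input, "cow_volume")) input else read_volume(input)
  atlas <- config$atlas %||% default_atlas()
  reference <- config$reference %||% default_reference()
  if (is.character(reference)) reference <- read_volume(reference)

  t0 <- proc.time()[["elapsed"]]
  pre <- tryCatch({
    v <- histogram_match(vol, reference)
    resample_to_atlas(v, config$target_spacing)
  }, error = function(e) stage_failed("preprocess", e))
  tick("preprocess", t0)

  t0 <- proc.time()[["elapsed"]]
  seg <- tryCatch(two_phase_segment(pre, config$strict, config$relaxed),
                  error = function(e) stage_failed("segment", e))
  tick("segment", t0)

  t0 <- proc.time()[["elapsed"]]
  skel <- tryCatch({
    s1 <- skeletonize3d(seg$mask_strict, spacing = pre$spacing,
                        origin = pre$origin,
                        spur_min_voxels = config$spur_min_voxels,
                        phase = "strict")
    s2 <- skeletonize3d(seg$mask_relaxed, preserve = s1,
                        spacing = pre$spacing, origin = pre$origin,
                        spur_min_voxels = config$spur_min_voxels,
                        phase = "merged")
    list(strict = s1, merged = s2)
  }, error = function(e) stage_failed("skeletonize", e))
  tick("skeletonize", t0)

  t0 <- proc.time()[["elapsed"]]
  graph <- tryCatch({
    g <- skeleton_to_graph(skel$merged)
    prune(g, config$prune_min_voxels)
  }, error = function(e) stage_failed("graph", e))
  bignodes <- merge_big_nodes(graph, config$bignode_radius_mm)
  tick("graph", t0)

  t0 <- proc.time()[["elapsed"]]
  lp <- config$label
  basilar <- label_basilar(bignodes, graph, atlas, k = lp$n_candidates,
                           negate_midline_term = lp$negate_midline_term)
  m1a1 <- label_m1a1(graph, bignodes, atlas, lp, exclude = basilar$node)
  a1_call <- classify_a1(m1a1, lp$s_threshold)
  tick("label", t0)

  t0 <- proc.time()[["elapsed"]]
  m <- atlas$median_sagittal_y
  feat_l <- a1_features(graph, m1a1$left, m, seg$mask_relaxed, pre)
  feat_r <- a1_features(graph, m1a1$right, m, seg$mask_relaxed, pre)
  fstar <- f_score <- NA_real_
  hypo <- "indeterminate"
  if (feat_l$status == "ok" && feat_r$status == "ok") {
    f_score <- score_F(feat_l, feat_r, config$features)
    fstar <- score_Fstar(feat_l, feat_r, config$features)
    hypo <- classify_hypoplasia(fstar, config$features$fstar_threshold)
  }
  tick("features", t0)
  timings$total <- round(proc.time()[["elapsed"]] - t_all, 3)

  report <- structure(list(
    version = as.character(utils::packageVersion("cowpipe")),
    seed = config$seed,
    timings = timings,
    segmentation = list(
      n_strict = sum(seg$mask_strict), n_relaxed = sum(seg$mask_relaxed),
      strict_status = seg$diagnostics$strict$status,
      relaxed_status = seg$diagnostics$relaxed$status),
    graph = list(n_nodes = nrow(graph$nodes), n_edges = length(graph$edges),
                 n_bignodes = length(bignodes)),
    basilar = list(status = basilar$status,
                   center = if (!is.null(basilar$node)) basilar$node$center,
                   B = basilar$scores),
    m1a1 = list(status = m1a1$status, S = m1a1$S,
                left_center = if (!is.null(m1a1$left)) m1a1$left$center,
                right_center = if (!is.null(m1a1$right)) m1a1$right$center,
                pairs = m1a1$pairs, e = m1a1$e),
    a1_classification = a1_call,
    features = list(
      left = feat_l[c("r", "p", "T", "has_endpoint", "status")],
      right = feat_r[c("r", "p", "T", "has_endpoint", "status")],
      F = f_score, Fstar = fstar, hypoplasia = hypo),
    config = config_snapshot(config)),
    class = "cow_report")

  if (!is.null(out_dir)) write_report_outputs(report, out_dir, pre, seg,
                                              skel, graph, basilar, m1a1)
  report
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$atlas <- if (is.null(snap$atlas)) "default" else unclass(snap$atlas)
  snap$reference <- if (is.null(snap$reference)) "default"
  else if (is.character(snap$reference)) snap$reference else "supplied"
  lapply(snap, function(x) if (is.list(x)) unclass(x) else x)
}

write_report_outputs <- function(report, out_dir, pre, seg, skel, graph,
                                 basilar, m1a1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_volume(mask_volume(pre, seg$mask_strict),
               file.path(out_dir, "mask_strict.nii.gz"), datatype = "uint8")
  write_volume(mask_volume(pre, seg$mask_relaxed),
               file.path(out_dir, "mask_relaxed.nii.gz"), datatype = "uint8")
  write_volume(mask_volume(pre, skel$merged$mask),
               file.path(out_dir, "skeleton.nii.gz"), datatype = "uint8")
  # labeled overlay: spheres of value 1 (basilar) / 2 (left) / 3 (right)
  ov <- array(0, dim(pre$data))
  paint <- function(ov, center, val, r = 3) {
    if (is.null(center)) return(ov)
    ctr <- round(world_to_voxel(pre, center))
    d <- dim(ov)
    span <- ceiling(r / pre$spacing)
    rng <- lapply(1:3, function(a)
      max(1, ctr[a] - span[a]):min(d[a], ctr[a] + span[a]))
    box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    dd <- sweep(sweep(box, 2, ctr), 2, pre$spacing, "*")
    ov[box[rowSums(dd^2) <= r^2, , drop = FALSE]] <- val
    ov
  }
  ov <- paint(ov, report$basilar$center, 1)
  ov <- paint(ov, report$m1a1$left_center, 2)
  ov <- paint(ov, report$m1a1$right_center, 3)
  write_volume(cow_volume(ov, pre$spacing, pre$origin),
               file.path(out_dir, "labeled_nodes.nii.gz"), datatype = "uint8")
  export_graph(graph, file.path(out_dir, "graph.json"))
  invisible(out_dir)
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$m1a1$pairs <- if (nrow(r$m1a1$pairs)) as.list(r$m1a1$pairs) else NULL
  r
}

#' Serialize a vascular graph to JSON
#' @param graph a `cow_graph`.
#' @param path output JSON path.
#' @export
export_graph <- function(graph, path) {
  nodes <- graph$nodes
  edges <- lapply(graph$edges, function(e)
    list(from = e$from, to = e$to, length_mm = e$length_mm,
         path = unname(as.matrix(e$path))))
  jsonlite::write_json(list(nodes = nodes, edges = edges,
                            spacing = graph$spacing, origin = graph$origin),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cow_report <- function(x, ...) {
  cat("<cow_report>\n")
  cat(sprintf("  basilar: %s\n", x$basilar$status))
  cat(sprintf("  M1/A1: %s (S = %.3f)\n", x$m1a1$status, x$m1a1$S))
  cat(sprintf("  A1 classification: %s (%s)\n", x$a1_classification$status,
              x$a1_classification$reason))
  if (is.finite(x$features$Fstar))
    cat(sprintf("  F* = %.4f -> %s\n", x$features$Fstar,
                x$features$hypoplasia))
  cat(sprintf("  total %.1f s\n", x$timings$total))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique score values (equal scores
#' collapse to one threshold) and integrates the curve by the trapezoidal
#' rule. The convention is that higher scores indicate the positive class.
#'
#' @param scores numeric score per case.
#' @param labels 0/1 (or logical/two-level) class labels; both classes
#'   must be present.
#' @return list with `auc` and the `curve` data frame (fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  stopifnot(length(scores) == length(labels))
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  list(auc = as.numeric(r$auc), curve = curve)
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_per_class` phantoms for each requested variant with distinct
#' seeds, their ground-truth JSONs, and a manifest CSV tying files,
#' variants and normal/variant labels together.
#'
#' @param n_per_class phantoms per variant (>= 1).
#' @param variants character vector of phantom variants.
#' @param seed base seed; phantom i of the cohort uses `seed * 1000 + i`.
#' @param dir output directory.
#' @param config_fn optional function(variant, seed) returning the
#'   [phantom_config] to use (defaults to standard study conditions).
#' @return the manifest data frame (also written as `manifest.csv`).
#' @export
make_cohort <- function(n_per_class, variants, seed = 1L, dir,
                        config_fn = NULL) {
  stopifnot(n_per_class >= 1, length(variants) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config_fn))
    config_fn <- function(variant, seed)
      phantom_config(variant = variant, seed = seed)
  rows <- list()
  idx <- 0L
  for (v in variants) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- as.integer(seed) * 1000L + idx
      ph <- make_phantom(config_fn(v, s))
      stem <- sprintf("%s_%03d", v, i)
      vol_file <- file.path(dir, paste0(stem, ".nii.gz"))
      gt_file <- file.path(dir, paste0(stem, "_gt.json"))
      write_volume(ph$volume, vol_file)
      write_ground_truth(ph$ground_truth, gt_file)
      rows[[idx]] <- data.frame(file = basename(vol_file),
                                gt_file = basename(gt_file),
                                variant = v,
                                label = if (v == "complete") "normal"
                                else "variant",
                                seed = s)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
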