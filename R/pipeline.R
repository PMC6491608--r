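#' Pipeline run configuration
#'
#' Collects everything an end-to-end run needs: input volume, voxel
#' spacing, preprocessing and segmentation parameters, the graph weight
#' threshold, and the output directory. Referenced files are checked at
#' construction time.
#'
#' @param input path to the input volume (TIFF or NIfTI).
#' @param output_dir directory for all artifacts (created if missing).
#' @param spacing voxel size in micrometres.
#' @param pre a [preprocess_params()].
#' @param seg a [segmentation_params()].
#' @param graph_threshold cluster weight threshold for
#'   [partition_clusters()].
#' @param exclusion optional path to an exclusion-mask volume (non-zero =
#'   excluded), e.g. a delineated lymph node.
#' @param debug_dir optional directory for intermediate stage dumps.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(input, output_dir, spacing = c(1, 1, 1),
                       pre = preprocess_params(), seg = segmentation_params(),
                       graph_threshold = 0.05, exclusion = NULL,
                       debug_dir = NULL) {
  if (!file.exists(input))
    lob_stop(sprintf("input volume '%s' does not exist", input), "lobuseg_io_error")
  if (!is.null(exclusion) && !file.exists(exclusion))
    lob_stop(sprintf("exclusion mask '%s' does not exist", exclusion), "lobuseg_io_error")
  structure(list(input = input, output_dir = output_dir,
                 spacing = as.numeric(spacing), pre = pre, seg = seg,
                 graph_threshold = graph_threshold, exclusion = exclusion,
                 debug_dir = debug_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised top-level keys: `input`, `output_dir`, `spacing`,
#' `exclusion`, `graph: {weight_threshold}`, and `preprocess:` /
#' `segmentation:` blocks whose entries are passed to
#' [preprocess_params()] / [segmentation_params()].
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read (same names as
#'   [run_config()] arguments).
#' @return a [run_config()].
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path))
    lob_stop(sprintf("config file '%s' does not exist", path), "lobuseg_io_error")
  y <- yaml::read_yaml(path)
  args <- list(
    input = y$input, output_dir = y$output_dir,
    spacing = if (!is.null(y$spacing)) unlist(y$spacing) else c(1, 1, 1),
    pre = do.call(preprocess_params, if (is.null(y$preprocess)) list() else y$preprocess),
    seg = do.call(segmentation_params, if (is.null(y$segmentation)) list() else y$segmentation),
    graph_threshold = if (!is.null(y$graph$weight_threshold)) y$graph$weight_threshold else 0.05,
    exclusion = y$exclusion, debug_dir = y$debug_dir)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

#' Run the full pipeline: segment, quantify, graph
#'
#' Reads the input volume, separates the Segmentable Lobule Area, segments
#' the subunits, computes morphometrics and contact surfaces, builds and
#' partitions the connectivity graph, and writes `labels.nii`,
#' `volumes.csv`, `edges.csv`, `graph.graphml`, `summary.json` and a
#' provenance record (`config_echo.yaml`) into the output directory. The
#' pipeline is deterministic: identical configuration yields byte-identical
#' CSV outputs.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [load_config()].
#' @return invisibly, a list with the in-memory results (`labels`,
#'   `records`, `edges`, `graph`, `clusters`, `summary`) and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  message("[lobuseg] reading ", config$input)
  vol <- read_volume(config$input, spacing = config$spacing)
  exclusion <- NULL
  if (!is.null(config$exclusion)) {
    exclusion <- as_mask(read_volume(config$exclusion, spacing = config$spacing) > 0)
  }

  message("[lobuseg] separating SLA from periphery")
  comp <- separate_sla(vol, config$pre, exclusion)
  message(sprintf("[lobuseg]   SLA %d voxels, periphery %d voxels",
                  sum(comp$sla), sum(comp$periphery)))

  message("[lobuseg] segmenting lobules")
  labels <- segment_lobules(vol, config$pre, config$seg, sla = comp$sla,
                            exclusion = exclusion,
                            debug_dir = config$debug_dir)
  records <- subunit_volumes(labels)
  edges <- contact_surfaces(labels)
  message(sprintf("[lobuseg]   %d subunits, %d contact edges",
                  nrow(records), nrow(edges)))

  graph <- build_graph(records, edges)
  clusters <- partition_clusters(graph, config$graph_threshold)

  sp <- vol_spacing(vol)
  vox_mm3 <- prod(sp) * 1e-9
  fat_pad_mm3 <- (sum(comp$sla) + sum(comp$periphery) +
                    if (is.null(exclusion)) 0 else sum(exclusion)) * vox_mm3
  sla_mm3 <- sum(comp$sla) * vox_mm3
  summary <- list(
    n_subunits = nrow(records),
    n_contact_edges = nrow(edges),
    n_clusters = length(unique(clusters$cluster)),
    fat_pad_volume_mm3 = fat_pad_mm3,
    sla_volume_mm3 = sla_mm3,
    sla_ratio_percent = sla_ratio(sla_mm3, fat_pad_mm3),
    total_subunit_volume_mm3 = sum(records$volume_mm3),
    mean_subunit_volume_mm3 = mean(records$volume_mm3))

  write_volume(labels, out("labels.nii"))
  write.csv(format_num_df(records), out("volumes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(format_num_df(edges), out("edges.csv"), row.names = FALSE, quote = FALSE)
  export_graph(graph, out("graph.graphml"), "graphml")
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE, digits = NA)
  prov <- list(tool = "lobuseg",
               version = as.character(utils::packageVersion("lobuseg")),
               config = list(input = config$input, spacing = config$spacing,
                             output_dir = config$output_dir,
                             exclusion = config$exclusion,
                             graph_threshold = config$graph_threshold,
                             preprocess = unclass(config$pre),
                             segmentation = unclass(config$seg)))
  yaml::write_yaml(prov, out("config_echo.yaml"))

  invisible(list(labels = labels, records = records, edges = edges,
                 graph = graph, clusters = clusters, summary = summary,
                 paths = vapply(c("labels.nii", "volumes.csv", "edges.csv",
                                  "graph.graphml", "summary.json",
                                  "config_echo.yaml"), out, character(1))))
}

# Stable decimal formatting so CSV outputs are platform-independent and
# byte-identical across repeated runs.
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}
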