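# Config-driven end-to-end execution: the package's analogue of a saved
# interactive image-analysis pipeline. A YAML config names the channels,
# segmentation/classification parameters and the enabled analyses;
# running it produces object tables, profile tables, overlays, a log and
# a resolved-config snapshot that reproduces the run exactly.

.analysisChannel <- c(hypoxia = "pimonidazole", death = "DRAQ7",
                      infiltration = "PBMC", fucci = "mAG")

pipelineDefaults <- function() {
  list(
    schema_version = 1L,
    input = list(stack = NULL, files = NULL),
    channel_role_map = list(),
    pixel_size_um = NULL,
    nuclei_source = "DAPI",
    nuclei = list(diameter_min_px = 4, diameter_max_px = 20,
                  threshold_strategy = "automatic", manual_threshold = NULL,
                  declump_smoothing_px = 4, maxima_min_distance_px = 5,
                  pre_smoothing_px = 0, fill_holes = TRUE,
                  exclude_border = TRUE),
    pbmc = list(diameter_min_px = 2, diameter_max_px = 16,
                threshold_strategy = "automatic", manual_threshold = NULL,
                declump_smoothing_px = 2, maxima_min_distance_px = 4,
                pre_smoothing_px = 0, fill_holes = TRUE,
                exclude_border = FALSE),
    secondary = list(max_expansion_px = 5,
                     guide_threshold_strategy = "automatic",
                     guide_manual_threshold = NULL),
    spheroid = list(diameter_estimate_px = NULL,
                    threshold_strategy = "manual",
                    manual_threshold = NULL,
                    source = NULL),
    positivity = list(),  # per channel: list(strategy, manual_threshold)
    bin_width_um = 25,
    normalize = "ring_area",
    analyses = list(hypoxia = FALSE, death = FALSE,
                    infiltration = FALSE, fucci = FALSE),
    output_dir = ".",
    seed = 1L)
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a pipeline configuration
#'
#' Reads a YAML config and materialises all defaults, giving a fully
#' resolved configuration list.
#'
#' @param path YAML file path.
#' @return resolved config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(pipelineDefaults(), user)
}

#' Validate a pipeline configuration
#'
#' Returns all invariant violations as a character vector (empty =
#' valid); never mutates the config and never throws for violations.
#'
#' @param config a (possibly partial) config list; defaults are
#'   materialised before checking.
#' @return character vector of violations.
#' @export
validateConfig <- function(config) {
  cfg <- mergeConfig(pipelineDefaults(), config)
  v <- character(0)
  roles <- names(cfg$channel_role_map)
  hasStack <- !is.null(cfg$input$stack)
  hasFiles <- !is.null(cfg$input$files)
  if (!hasStack && !hasFiles)
    v <- c(v, "input: neither a stack path nor per-channel files given")
  if (hasFiles) roles <- union(roles, names(cfg$input$files))
  for (an in names(.analysisChannel)) {
    if (isTRUE(cfg$analyses[[an]])) {
      need <- .analysisChannel[[an]]
      if (an == "fucci") need <- c("mAG", "mKO2")
      missing <- setdiff(need, roles)
      if (length(missing))
        v <- c(v, sprintf("analysis '%s' enabled but channel role '%s' is not mapped",
                          an, paste(missing, collapse = "', '")))
    }
  }
  nuc <- cfg$nuclei_source
  nucRoles <- if (is.list(nuc)) unlist(nuc$merge) else nuc
  if (is.null(nucRoles) || length(nucRoles) == 0L)
    v <- c(v, "nuclei_source: no nuclei source resolvable")
  else if (length(setdiff(nucRoles, roles)))
    v <- c(v, sprintf("nuclei_source: unmapped channel role '%s'",
                      paste(setdiff(nucRoles, roles), collapse = "', '")))
  if (!is.numeric(cfg$bin_width_um) || cfg$bin_width_um <= 0)
    v <- c(v, "bin_width_um must be positive")
  if (!is.null(cfg$pixel_size_um) && cfg$pixel_size_um <= 0)
    v <- c(v, "pixel_size_um must be positive")
  for (fld in c("nuclei", "pbmc"))
    if (cfg[[fld]]$threshold_strategy == "manual" &&
        is.null(cfg[[fld]]$manual_threshold))
      v <- c(v, sprintf("%s: manual threshold strategy without manual_threshold", fld))
  v
}

primaryParamsFromConfig <- function(p)
  primaryParams(diameterMinPx = p$diameter_min_px,
                diameterMaxPx = p$diameter_max_px,
                thresholdStrategy = p$threshold_strategy,
                manualThreshold = p$manual_threshold,
                declumpSmoothingPx = p$declump_smoothing_px,
                maximaMinDistancePx = p$maxima_min_distance_px,
                preSmoothingPx = p$pre_smoothing_px,
                fillHoles = isTRUE(p$fill_holes),
                excludeBorder = isTRUE(p$exclude_border))

positivityFromConfig <- function(cfg, channel, means) {
  p <- cfg$positivity[[channel]]
  strategy <- if (!is.null(p$strategy)) p$strategy else "automatic"
  classifyPositive(means, strategy, p$manual_threshold)
}

#' Run the spheroid analysis pipeline
#'
#' Executes the full analysis described by the config: load the stack or
#' per-channel files, optionally merge the nuclei source, identify
#' nuclei, (for the hypoxia analysis) grow secondary cell objects on the
#' pimonidazole channel and measure cell intensities there — other
#' analyses measure on the nuclei or PBMC objects directly — identify
#' the spheroid, relate objects to its surface, classify positives, and
#' build the enabled depth profiles. All artefacts (object CSVs, profile
#' CSVs, overlay PNGs, a structured log and a resolved-config snapshot)
#' are written to the output directory; any stage error aborts the run,
#' removes partial outputs, and names the failing stage.
#'
#' @param config config list (see \code{\link{readPipelineConfig}}) or a
#'   YAML path.
#' @return invisible list with the run's in-memory results (records,
#'   profiles, spheroid, label maps, paths).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  viol <- validateConfig(cfg)
  if (length(viol))
    stopCondition("config_error",
                  paste0("invalid config:\n  ", paste(viol, collapse = "\n  ")))

  outDir <- cfg$output_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  staging <- file.path(outDir, sprintf(".staging_%d", Sys.getpid()))
  dir.create(staging, showWarnings = FALSE)
  logLines <- character(0)
  stage <- "setup"
  logIt <- function(fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    message(line)
  }

  result <- tryCatch({
    # --- load channels ---
    stage <- "load"
    channels <- list()
    if (!is.null(cfg$input$stack)) {
      stk <- readStack(cfg$input$stack, pixelSizeUm = cfg$pixel_size_um)
      for (role in names(cfg$channel_role_map)) {
        plane <- cfg$channel_role_map[[role]]
        ch <- getChannel(stk, plane)
        channels[[role]] <- ChannelImage(role, ch@pixels, ch@pixelSizeUm)
      }
    }
    if (!is.null(cfg$input$files)) {
      for (role in names(cfg$input$files)) {
        stk <- readStack(cfg$input$files[[role]],
                         pixelSizeUm = cfg$pixel_size_um)
        channels[[role]] <- ChannelImage(role, stk@channels[[1]]@pixels,
                                         stk@channels[[1]]@pixelSizeUm)
      }
    }
    logIt("loaded %d channel(s): %s", length(channels),
          paste(names(channels), collapse = ", "))

    # --- nuclei source ---
    stage <- "nuclei_source"
    nucRoles <- if (is.list(cfg$nuclei_source)) unlist(cfg$nuclei_source$merge)
                else cfg$nuclei_source
    nucImage <- if (length(nucRoles) > 1L)
      mergeChannels(channels[nucRoles]) else channels[[nucRoles]]
    logIt("nuclei source: %s", paste(nucRoles, collapse = " + "))

    # --- primary objects ---
    stage <- "identify_nuclei"
    nuclei <- identifyPrimaryObjects(nucImage,
                                     primaryParamsFromConfig(cfg$nuclei))
    logIt("identified %d nuclei (%d accepted), threshold %.4g",
          length(nuclei@categories), length(acceptedLabels(nuclei)),
          attr(nuclei, "threshold"))

    # --- spheroid ---
    stage <- "identify_spheroid"
    sphSource <- if (!is.null(cfg$spheroid$source)) channels[[cfg$spheroid$source]]
                 else nucImage
    dEst <- cfg$spheroid$diameter_estimate_px
    if (is.null(dEst)) dEst <- min(dim(nucImage@pixels)) * 0.7
    spheroid <- identifySpheroid(sphSource, dEst,
                                 cfg$spheroid$threshold_strategy,
                                 cfg$spheroid$manual_threshold)
    logIt("spheroid equivalent diameter %.1f px (%.1f um)",
          spheroid@equivalentDiameterPx,
          spheroid@equivalentDiameterPx * spheroid@pixelSizeUm)

    # --- measurement objects: cells for hypoxia, nuclei otherwise ---
    stage <- "identify_cells"
    cells <- NULL
    if (isTRUE(cfg$analyses$hypoxia)) {
      sp <- cfg$secondary
      cells <- identifySecondaryObjects(
        nuclei, channels$pimonidazole,
        secondaryParams(sp$max_expansion_px, sp$guide_threshold_strategy,
                        sp$guide_manual_threshold))
      logIt("grew %d secondary cell objects (guide threshold %.4g)",
            length(cells@categories), attr(cells, "guideThreshold"))
    }

    # --- relate + measure ---
    stage <- "relate_objects"
    records <- relateObjects(if (!is.null(cells)) cells else nuclei, spheroid)
    logIt("%d object records, %d inside the spheroid", nrow(records),
          sum(records$inside_spheroid))

    stage <- "measure"
    measureObjects <- if (!is.null(cells)) cells else nuclei
    measureRoles <- intersect(c("pimonidazole", "DRAQ7", "mAG", "mKO2"),
                              names(channels))
    for (role in measureRoles) {
      target <- if (role == "pimonidazole" && !is.null(cells)) cells
                else nuclei
      feats <- measureObjectIntensity(target, channels[[role]])
      records[[paste0(role, "_mean")]] <- feats$mean
      records[[paste0(role, "_median")]] <- feats$median
      records[[paste0(role, "_integrated")]] <- feats$integrated
    }

    stage <- "classify"
    for (role in intersect(c("DRAQ7", "mAG", "mKO2"), measureRoles)) {
      flags <- positivityFromConfig(cfg, role,
                                    records[[paste0(role, "_mean")]])
      records[[paste0(role, "_positive")]] <- as.logical(flags)
      logIt("%s positivity threshold %.4g: %d positive", role,
            attr(flags, "threshold"), sum(flags))
    }

    # --- profiles ---
    stage <- "profiles"
    Rum <- spheroid@equivalentDiameterPx / 2 * spheroid@pixelSizeUm
    profiles <- list()
    if (isTRUE(cfg$analyses$hypoxia))
      profiles$hypoxia <- meanIntensityProfile(records, "pimonidazole",
                                               cfg$bin_width_um)
    if (isTRUE(cfg$analyses$death))
      profiles$death <- positiveFractionProfile(records, "DRAQ7",
                                                cfg$bin_width_um)
    if (isTRUE(cfg$analyses$fucci))
      profiles$fucci <- ratioProfile(records, "mKO2", "mAG",
                                     cfg$bin_width_um)
    pbmcRecords <- NULL
    if (isTRUE(cfg$analyses$infiltration)) {
      stage <- "identify_pbmc"
      pbmcMap <- identifyPrimaryObjects(channels$PBMC,
                                        primaryParamsFromConfig(cfg$pbmc))
      logIt("identified %d PBMC objects (%d accepted)",
            length(pbmcMap@categories), length(acceptedLabels(pbmcMap)))
      pbmcRecords <- relateObjects(pbmcMap, spheroid)
      stage <- "profiles"
      profiles$infiltration <- infiltrationCountProfile(
        pbmcRecords, cfg$bin_width_um, normalize = cfg$normalize,
        spheroidRadiusUm = Rum)
    }
    logIt("built %d profile(s): %s", length(profiles),
          paste(names(profiles), collapse = ", "))

    # --- write artefacts into staging ---
    stage <- "write"
    writeObjectTable(records, file.path(staging, "objects.csv"))
    if (!is.null(pbmcRecords))
      writeObjectTable(pbmcRecords, file.path(staging, "pbmc_objects.csv"))
    for (nm in names(profiles))
      writeProfileTable(profiles[[nm]],
                        file.path(staging, sprintf("profile_%s.csv", nm)))
    writeOverlayPNG(renderOverlay(nucImage, nuclei, "outlines"),
                    file.path(staging, "overlay_nuclei.png"))
    sphLab <- LabelMap(matrix(as.integer(spheroid@mask),
                              nrow(spheroid@mask)),
                       "accepted", spheroid@pixelSizeUm)
    writeOverlayPNG(renderOverlay(nucImage, sphLab, "outlines"),
                    file.path(staging, "overlay_spheroid.png"))
    yaml::write_yaml(cfg, file.path(staging, "resolved_config.yaml"))
    writeLines(logLines, file.path(staging, "run_log.txt"))

    # --- promote staging to final ---
    for (f in list.files(staging))
      file.rename(file.path(staging, f), file.path(outDir, f))
    unlink(staging, recursive = TRUE)
    list(records = records, pbmc_records = pbmcRecords,
         profiles = profiles, nuclei = nuclei, cells = cells,
         spheroid = spheroid, config = cfg, output_dir = outDir)
  }, error = function(e) {
    unlink(staging, recursive = TRUE)
    stopCondition("pipeline_error",
                  sprintf("pipeline failed at stage '%s': %s", stage,
                          conditionMessage(e)))
  })
  invisible(result)
}

#' Write a phantom as pipeline-ready artefacts
#'
#' Writes the phantom's six channels as a multi-plane 16-bit TIFF
#' (values rounded to integer DN) plus ground-truth CSVs, so the
#' simulate and analyze steps compose.
#'
#' @param params a \code{\link{spheroidPhantomParams}} object.
#' @param outDir output directory.
#' @return invisible list with \code{stack_path}, \code{truth_paths} and
#'   the in-memory phantom.
#' @export
writePhantom <- function(params, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  ph <- generatePhantom(params)
  rounded <- MultiChannelImage(lapply(ph$image@channels, function(ch)
    ChannelImage(ch@channelName, pmin(round(ch@pixels), 65535),
                 ch@pixelSizeUm)))
  stackPath <- file.path(outDir, "phantom_stack.tif")
  writeStack(rounded, stackPath)
  nucPath <- file.path(outDir, "phantom_truth_nuclei.csv")
  pbmcPath <- file.path(outDir, "phantom_truth_pbmc.csv")
  writeObjectTable(ph$truth$nuclei, nucPath)
  writeObjectTable(ph$truth$pbmc, pbmcPath)
  invisible(list(stack_path = stackPath,
                 truth_paths = c(nucPath, pbmcPath), phantom = ph))
}
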