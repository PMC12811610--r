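## cli_orchestrator: single-command pipeline execution with logging, QC
## artifacts, and machine-readable provenance.

## documented stage-specific exit codes
hsExitCodes <- c(label_io = 10L, topology = 20L, meshing = 30L,
                 boundary = 40L, laplace_param = 50L, features = 60L,
                 cli = 70L, align_stats = 80L, phantom = 90L)

#' Run the full per-hemisphere pipeline
#'
#' Executes label reading -> body mask -> topology check -> meshing ->
#' boundary detection -> coordinate system -> mid-surface grid -> thickness,
#' curvature and geometric summaries, writing all declared outputs, a
#' structured log, QC images, and a provenance record. On any fatal
#' condition the stage-specific documented exit code is reported and a
#' previous successful run's outputs are left untouched (outputs are staged
#' and moved into place only on success).
#'
#' @param input path to the label volume, or a [LabelVolume-class].
#' @param outDir output directory.
#' @param config configuration list (see [hipposheetDefaults()] /
#'   [readPipelineConfig()]); fields can be overridden via `...`.
#' @param ... individual config overrides (e.g. `N = 40`, `dialect =
#'   "ashs"`).
#' @return invisibly, a list with `exitCode` (0 = success), `stage`,
#'   `message`, and on success the result objects and output paths.
#' @export
runPipeline <- function(input, outDir, config = hipposheetDefaults(), ...) {
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(config))
      return(invisible(list(exitCode = hsExitCodes[["cli"]], stage = "cli",
                            message = sprintf("unknown config key '%s'", nm))))
    config[[nm]] <- over[[nm]]
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  logCon <- file(logPath, "w")
  logms <- function(stage, msg)
    writeLines(sprintf("[%s] [%s] %s",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg),
               logCon)
  stage <- "cli"
  staging <- file.path(outDir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, showWarnings = FALSE)
  result <- tryCatch({
    set.seed(config$seed)
    stage <- "label_io"
    logms(stage, "loading label volume")
    vol <- if (is(input, "LabelVolume")) input
      else loadLabelVolume(input, config$dialect)
    mask <- prepareBodyMask(vol, config$closureIterations)
    writeLabelVolume(new("LabelVolume",
                         data = array(as.integer(mask@mask), dim(mask@mask)),
                         affine = mask@affine, dialect = vol@dialect,
                         labels = vol@labels),
                     file.path(staging, "body_mask.nii.gz"))
    stage <- "topology"
    topo <- checkMaskTopology(mask)
    logms(stage, sprintf("components=%d backgroundComponents=%d eulerBoundary=%d",
                         topo$nComponents, topo$nBackgroundComponents,
                         topo$eulerBoundary))
    if (topo$fatal)
      hsError("topology",
              "mask is topologically defective (%d components, %d background components); refusing to process",
              topo$nComponents, topo$nBackgroundComponents)
    stage <- "meshing"
    logms(stage, "building tetrahedral mesh")
    mesh <- buildBodyTetMesh(mask, config$smoothingIterations,
                             config$implicitSigma)
    mesh <- transferLabels(mesh, vol, config$guardDistance)
    surf <- labelSurfaceFromMesh(surfaceFromMesh(mesh), mesh)
    writeSurfacePLY(surf, file.path(staging, "surface.ply"))
    writeTetVTK(mesh, file.path(staging, "tetmesh.vtk"))
    writeVertexTable(data.frame(vertex = seq_len(nrow(surf@vertices)),
                                label = surf@vertexData$subfield),
                     file.path(staging, "surface_labels.csv"))
    stage <- "boundary"
    logms(stage, "anisotropic eigenfunction and boundary entities")
    open <- cutOpenSurface(surf)
    eig <- anisotropicLaplaceEigenfunction(open, config$anisotropy,
                                           config$eigenK)
    spec <- deriveBoundarySpec(open, eig)
    writeVertexTable(data.frame(vertex = seq_along(eig@values),
                                eigenfunction = eig@values),
                     file.path(staging, "eigenfunction.csv"))
    ents <- rbind(
      data.frame(entity = "C_m", vertex = spec@cm),
      data.frame(entity = "C_l", vertex = spec@cl),
      data.frame(entity = "anterior_ring", vertex = spec@anteriorRing),
      data.frame(entity = "posterior_ring", vertex = spec@posteriorRing))
    writeVertexTable(ents, file.path(staging, "boundaries.csv"))
    stage <- "laplace_param"
    logms(stage, "solving the three Laplace coordinates")
    cs <- buildCoordinateSystem(mesh, spec, open)
    writeVertexTable(data.frame(vertex = seq_len(nrow(mesh@vertices)),
                                u_ml = cs@uml@values, u_ap = cs@uap@values,
                                u_ie = cs@uie@values),
                     file.path(staging, "coordinates.csv"))
    stage <- "features"
    logms(stage, sprintf("mid-surface %d x %d grid, thickness, curvature",
                         config$N, config$M))
    mid <- extractIsosurface(cs, "interior_exterior", 0.5)
    grid <- sampleMidsurfaceGrid(mid, config$N, config$M)
    grid <- computeThicknessMap(grid, cs)
    grid <- computeCurvatureMap(mid, grid)
    writeSurfacePLY(mid, file.path(staging, "midsurface.ply"),
                    scalars = list(u_ml = mid@vertexData$uml,
                                   u_ap = mid@vertexData$uap))
    writeGridTable(grid, file.path(staging, "thickness_grid.csv"))
    summ <- geometricSummaries(cs, grid, mid)
    sdf <- data.frame(measure = c("length_x_mm", "length_y_mm",
                                  "length_z_mm", "circumference_mm",
                                  "interior_exterior_ratio",
                                  "surface_area_mm2", "shape_index_per_mm"),
                      value = c(summ@lengthX, summ@lengthY, summ@lengthZ,
                                summ@circumference,
                                summ@interiorExteriorRatio,
                                summ@surfaceArea, summ@shapeIndex))
    writeVertexTable(sdf, file.path(staging, "summary_measures.csv"))
    writeVertexTable(summ@rowTable, file.path(staging, "slice_table.csv"))
    qcImages(staging, mask, eig, open, grid)
    prov <- list(package = "hipposheet",
                 version = as.character(utils::packageVersion("hipposheet")),
                 rVersion = R.version.string,
                 config = config[order(names(config))],
                 input = if (is.character(input)) input else "in-memory",
                 outputs = sort(list.files(staging)),
                 checksums = as.list(vapply(
                   sort(list.files(staging, full.names = TRUE)),
                   function(f) as.character(sum(as.integer(
                     readBin(f, "raw", file.info(f)$size)))),
                   character(1))))
    names(prov$checksums) <- sort(list.files(staging))
    jsonlite::write_json(prov, file.path(staging, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ## success: move staged outputs into place
    for (f in list.files(staging)) {
      file.copy(file.path(staging, f), file.path(outDir, f),
                overwrite = TRUE)
    }
    unlink(staging, recursive = TRUE)
    logms("done", "pipeline completed")
    list(exitCode = 0L, stage = "done", message = "ok",
         mask = mask, mesh = mesh, surface = surf, open = open,
         eigenfunction = eig, boundarySpec = spec, coords = cs, mid = mid,
         grid = grid, summary = summ, outDir = outDir)
  }, hipposheetError = function(e) {
    st <- if (!is.null(e$stage)) e$stage else stage
    logms(st, paste("FATAL:", conditionMessage(e)))
    unlink(staging, recursive = TRUE)
    code <- if (st %in% names(hsExitCodes)) hsExitCodes[[st]] else 1L
    list(exitCode = code, stage = st, message = conditionMessage(e))
  }, error = function(e) {
    logms(stage, paste("FATAL (unexpected):", conditionMessage(e)))
    unlink(staging, recursive = TRUE)
    list(exitCode = 1L, stage = stage, message = conditionMessage(e))
  })
  close(logCon)
  invisible(result)
}

## QC images (best effort: skipped silently if no graphics device works)
qcImages <- function(dir, mask, eig, open, grid) {
  try({
    grDevices::png(file.path(dir, "qc_mask.png"), width = 600, height = 600)
    mid <- dim(mask@mask)[mask@apAxis] %/% 2
    sl <- switch(mask@apAxis, mask@mask[mid, , ], mask@mask[, mid, ],
                 mask@mask[, , mid])
    graphics::image(sl * 1, main = "body mask, central slice",
                    col = grDevices::gray.colors(2, 0, 1))
    grDevices::dev.off()
    grDevices::png(file.path(dir, "qc_thickness.png"), width = 700, height = 400)
    graphics::image(grid@thickness,
                    main = "thickness flat map (medial/lateral x anterior/posterior)",
                    xlab = "u_ml", ylab = "u_ap")
    grDevices::dev.off()
    grDevices::png(file.path(dir, "qc_curvature.png"), width = 700, height = 400)
    graphics::image(grid@curvature, main = "mean curvature flat map",
                    xlab = "u_ml", ylab = "u_ap")
    grDevices::dev.off()
  }, silent = TRUE)
  invisible(NULL)
}

#' Group statistics over a directory of per-subject grid tables
#'
#' Reads `*_thickness_grid.csv` exports, performs curvature-based
#' alignment, fits the grid-point-wise model for a two-group contrast with
#' covariates, and applies joint FDR correction.
#'
#' @param gridFiles named character vector of grid-table paths (names =
#'   subject ids).
#' @param covariates data.frame with rownames or `subject` column matching,
#'   plus `group` and optional `age`, `sex`.
#' @param q FDR level.
#' @param sMax alignment shift bound.
#' @return list with the [GridStatResult-class] and the alignment shifts.
#' @export
runGroupStats <- function(gridFiles, covariates, q = 0.05,
                          sMax = hipposheetDefaults()$sMax) {
  subs <- lapply(gridFiles, function(f) {
    g <- readGridTable(f)
    list(thickness = g@thickness, curvature = g@curvature)
  })
  al <- alignThicknessMaps(subs, sMax = sMax)
  maps <- lapply(al$subjects, `[[`, "thickness")
  res <- vertexwiseGLM(maps, covariates, q = q)
  list(result = res, shifts = al$shifts)
}
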