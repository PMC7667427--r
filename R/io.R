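# File I/O: CSV exports of curves and metric series, JSON windows and
# configs, TIFF scene stacks with a JSON sidecar. Readers and writers
# round-trip: floats via full-precision text, integer stacks bit-exactly.

#' Write uptake curves to CSV
#'
#' Columns: `t_min`, `Cf_T`, `Cb_T`, `Cf_C`, `roi_T`, `roi_C` (empty
#' channels as `NA`).
#'
#' @param curves an [UptakeCurves-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeUptakeCurves <- function(curves, path) {
  df <- as.data.frame(curves)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read uptake curves from CSV
#' @param path file written by [writeUptakeCurves()].
#' @return An [UptakeCurves-class].
#' @export
readUptakeCurves <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_min", "Cf_T", "Cb_T", "Cf_C", "roi_T", "roi_C")
  if (!all(need %in% names(df)))
    stop("malformed curves CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  take <- function(col) if (all(is.na(df[[col]]))) numeric() else df[[col]]
  new("UptakeCurves", time = df$t_min, cfT = take("Cf_T"),
      cbT = take("Cb_T"), cfC = take("Cf_C"), roiT = take("roi_T"),
      roiC = take("roi_C"))
}

#' Write a metric time series to CSV
#'
#' Columns: `t_min`, `cvr`, `auroc`, `protocol`.
#' @param series a [MetricTimeSeries-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetricSeries <- function(series, path) {
  utils::write.csv(format(as.data.frame(series), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric time series from CSV
#' @param path file written by [writeMetricSeries()].
#' @return A [MetricTimeSeries-class].
#' @export
readMetricSeries <- function(path) {
  df <- utils::read.csv(path)
  new("MetricTimeSeries", time = df$t_min, cvr = df$cvr, auroc = df$auroc,
      protocol = as.character(df$protocol[1]))
}

#' Write a contrast window as a JSON record
#' @param window a [ContrastWindow-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContrastWindow <- function(window, path) {
  jsonlite::write_json(
    list(t_max = window@tMax, cvr_max = window@cvrMax,
         t_start_98 = window@tStart98, t_end_98 = window@tEnd98,
         at_boundary = window@atBoundary),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a lookup grid to CSV with axis headers
#'
#' First row: protocol and axis labels; second row: axis-2 values; then
#' one row per axis-1 value.
#'
#' @param grid matrix from [tmaxLookupGrid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTmaxGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  axes <- attr(grid, "axes")
  writeLines(paste(c(attr(grid, "protocol"), axes), collapse = ","), con)
  writeLines(paste(c("", colnames(grid)), collapse = ","), con)
  for (i in seq_len(nrow(grid)))
    writeLines(paste(c(rownames(grid)[i],
                       format(grid[i, ], digits = 17, trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' Read or write a run configuration (YAML or JSON by extension)
#'
#' Configurations are flat or nested lists; round-trip is lossless for
#' numeric, character and logical scalars and vectors.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return The configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", path, call. = FALSE)
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("\\.(yaml|yml)$", path)) yaml::write_yaml(config, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("unsupported config format: ", path, call. = FALSE)
  invisible(path)
}

# 16/12/8-bit stack <-> multi-frame TIFF. Values are stored as
# value / (2^bits - 1); readTIFF(as.is = TRUE) recovers the integers
# bit-exactly.
.writeStackTIFF <- function(stack, path, bits) {
  full <- 2^bits - 1
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(f) stack[, , f] / full)
  tiff::writeTIFF(frames, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

.readStackTIFF <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write a rendered scene to a directory
#'
#' Writes `targeted.tif` and `control.tif` (multi-frame, at the detector
#' bit depth), `preinjection_targeted.tif` / `preinjection_control.tif`,
#' `masks.tif` (label image: 1 = tumor, 2 = background) and
#' `sidecar.json` (frame times, seed, scale, run-length-encoded masks and
#' a spec echo).
#'
#' @param scene a [RenderedScene-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "RenderedScene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bits <- scene@spec@detector@bits
  .writeStackTIFF(scene@targeted, file.path(dir, "targeted.tif"), bits)
  .writeStackTIFF(scene@control, file.path(dir, "control.tif"), bits)
  d <- dim(scene@targeted)
  .writeStackTIFF(array(scene@preT, c(d[1:2], 1)),
                  file.path(dir, "preinjection_targeted.tif"), bits)
  .writeStackTIFF(array(scene@preC, c(d[1:2], 1)),
                  file.path(dir, "preinjection_control.tif"), bits)
  label <- matrix(0L, d[1], d[2])
  label[scene@bgMask] <- 2L
  label[scene@tumorMask] <- 1L
  .writeStackTIFF(array(label, c(d[1:2], 1)), file.path(dir, "masks.tif"), 8)
  rle2list <- function(mask) {
    r <- rle(as.vector(mask))
    list(lengths = r$lengths, values = r$values)
  }
  spec <- scene@spec
  sidecar <- list(
    package_version = .packageVersionString(),
    frame_times_min = scene@frameTimes,
    seed = spec@seed,
    scale = scene@scale,
    dim = spec@dim,
    masks = list(tumor = rle2list(scene@tumorMask),
                 background = rle2list(scene@bgMask)),
    spec = list(
      tumorCenter = spec@tumorCenter, tumorRadius = spec@tumorRadius,
      bgInner = spec@bgInner, bgOuter = spec@bgOuter,
      tumorParams = spec@tumorParams, backgroundParams = spec@backgroundParams,
      kon = spec@kon, koff = spec@koff,
      plasma = list(A = spec@plasma@A, alpha = spec@plasma@alpha,
                    B = spec@plasma@B, beta = spec@plasma@beta,
                    scale = spec@plasma@scale),
      detector = list(bits = spec@detector@bits,
                      fraction = spec@detector@fraction,
                      noise = spec@detector@noise),
      autofluorescence = spec@autofluorescence,
      etaT = spec@etaT, etaC = spec@etaC, vp = spec@vp))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory written by [writeScene()]
#'
#' @param dir scene directory.
#' @return A list with `targeted`, `control`, `preT`, `preC`,
#'   `frameTimes`, `tumorMask`, `bgMask`, `scale`, `seed` and the sidecar
#'   list as `sidecar`.
#' @export
readScene <- function(dir) {
  sidecar <- jsonlite::fromJSON(file.path(dir, "sidecar.json"),
                                simplifyVector = TRUE)
  fromRLE <- function(x, d)
    matrix(inverse.rle(structure(list(lengths = x$lengths,
                                      values = as.logical(x$values)),
                                 class = "rle")), d[1], d[2])
  d <- as.integer(sidecar$dim)
  list(targeted = .readStackTIFF(file.path(dir, "targeted.tif")),
       control = .readStackTIFF(file.path(dir, "control.tif")),
       preT = .readStackTIFF(file.path(dir, "preinjection_targeted.tif"))[, , 1],
       preC = .readStackTIFF(file.path(dir, "preinjection_control.tif"))[, , 1],
       frameTimes = sidecar$frame_times_min,
       tumorMask = fromRLE(sidecar$masks$tumor, d),
       bgMask = fromRLE(sidecar$masks$background, d),
       scale = sidecar$scale, seed = sidecar$seed, sidecar = sidecar)
}

#' Write study records and summary
#'
#' Records go to `records.csv`, the summary (with seed, iteration count
#' and plasma mode) to `summary.json`, and the class-by-protocol table to
#' `table_tmax.csv`.
#'
#' @param result a [StudyResult-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStudyResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(studyRecords(result), file.path(dir, "records.csv"),
                   row.names = FALSE)
  s <- studySummary(result)
  s$seed <- result@seed
  s$n_iterations <- result@nIterations
  s$plasma_mode <- result@plasmaMode
  s$package_version <- .packageVersionString()
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(summarizeTmaxByClass(result), file.path(dir, "table_tmax.csv"),
                   row.names = FALSE)
  invisible(dir)
}
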