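#' Read and write FIDs as JSON
#'
#' A FID is stored as a JSON record with a `metadata` object (dwell, t0,
#' nucleus, voxel dimensions, timestamp) and parallel `real` / `imag`
#' arrays.
#'
#' @param fid a [Fid-class]
#' @param path file path
#' @return `readFidJson` returns a [Fid-class]; `writeFidJson` returns
#'   `path` invisibly
#' @export
writeFidJson <- function(fid, path) {
  stopIfNot(is(fid, "Fid"), "fid must be a Fid")
  rec <- list(
    metadata = list(dwell_ms = fid@dwell, t0_ms = fid@t0,
                    nucleus = fid@nucleus, voxel_dims_mm = fid@voxelDims,
                    timestamp_s = fid@timestamp),
    real = Re(fid@samples), imag = Im(fid@samples))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeFidJson
#' @export
readFidJson <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  md <- rec$metadata
  Fid(complex(real = rec$real, imaginary = rec$imag),
      dwell = md$dwell_ms, t0 = md$t0_ms, nucleus = md$nucleus,
      voxelDims = if (is.null(md$voxel_dims_mm)) rep(NA_real_, 3)
                  else unlist(md$voxel_dims_mm),
      timestamp = if (is.null(md$timestamp_s)) NA_real_ else md$timestamp_s)
}

#' Read and write echo amplitude series as CSV
#'
#' Two-column CSV with header `te_ms,value`.
#'
#' @param series an [EchoAmplitudeSeries-class]
#' @param path file path
#' @return `readEchoSeriesCsv` returns an [EchoAmplitudeSeries-class]
#' @export
writeEchoSeriesCsv <- function(series, path) {
  stopIfNot(is(series, "EchoAmplitudeSeries"),
            "series must be an EchoAmplitudeSeries")
  utils::write.csv(data.frame(te_ms = echoTimes(series),
                              value = amplitudes(series)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEchoSeriesCsv
#' @param source source tag for the object read back
#' @export
readEchoSeriesCsv <- function(path, source = "fitted") {
  d <- utils::read.csv(path)
  EchoAmplitudeSeries(d$te_ms, d$value, source = source)
}

#' Read and write dynamic series as CSV
#'
#' Columns `time_s,value` plus per-file metadata columns `modality`,
#' `baseline`, `subject`, `group`.
#'
#' @param series a [DynamicSeries-class]
#' @param path file path
#' @return `readDynamicSeriesCsv` returns a [DynamicSeries-class]
#' @export
writeDynamicSeriesCsv <- function(series, path) {
  stopIfNot(is(series, "DynamicSeries"), "series must be a DynamicSeries")
  utils::write.csv(data.frame(time_s = timestamps(series),
                              value = values(series),
                              modality = modality(series),
                              baseline = baselineValue(series),
                              subject = series@subject,
                              group = series@group),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDynamicSeriesCsv
#' @export
readDynamicSeriesCsv <- function(path) {
  d <- utils::read.csv(path)
  DynamicSeries(d$time_s, d$value, modality = d$modality[1],
                baselineValue = d$baseline[1], subject = as.character(d$subject[1]),
                group = d$group[1])
}

#' NIfTI volume IO
#'
#' Thin wrappers writing/reading numeric arrays as NIfTI with voxel
#' dimensions recorded in the header.
#'
#' @param volume numeric array
#' @param path file path (`.nii` or `.nii.gz`)
#' @param voxelDims voxel dimensions in mm (length matching the array rank)
#' @return `readVolumeNifti` returns a plain numeric array
#' @export
writeVolumeNifti <- function(volume, path, voxelDims = NULL) {
  img <- RNifti::asNifti(as.array(volume))
  if (!is.null(voxelDims)) RNifti::pixdim(img) <- voxelDims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Read a cohort specification from YAML
#'
#' Expects a top-level `cohort:` block with `n_per_group`, `seed`, optional
#' `timeline` (`na_scan_duration_s`, `h_scan_duration_s`, `n_cycles`,
#' `post_exercise_span_s`) and optional per-group blocks `hv:` / `dp:`
#' mapping parameter names to `{mean, sd}` pairs.
#'
#' @param path YAML file path
#' @param seed optional seed overriding the file's value
#' @return a [CohortSpec-class]
#' @export
readCohortConfig <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(!is.null(cfg$cohort), "config must contain a 'cohort' block")
  co <- cfg$cohort
  tl <- co$timeline
  timeline <- AcquisitionTimeline(
    naScanDuration = tl$na_scan_duration_s %||% 129,
    hScanDuration = tl$h_scan_duration_s %||% 45,
    nCycles = tl$n_cycles,
    postExerciseSpan = tl$post_exercise_span_s %||% 1800)
  mergeTab <- function(base, blk) {
    if (is.null(blk)) return(base)
    for (p in names(blk)) {
      i <- match(p, base$parameter)
      stopIfNot(!is.na(i), paste("unknown cohort parameter:", p))
      if (!is.null(blk[[p]]$mean)) base$mean[i] <- blk[[p]]$mean
      if (!is.null(blk[[p]]$sd)) base$sd[i] <- blk[[p]]$sd
    }
    base
  }
  cohortSpec(nPerGroup = co$n_per_group %||% 10,
             hv = mergeTab(groupParameterTable("HV"), co$hv),
             dp = mergeTab(groupParameterTable("DP"), co$dp),
             seed = seed %||% co$seed %||% 1L,
             timeline = timeline)
}

#' Read a phantom configuration from YAML
#'
#' Expects a `phantom:` block with a `reference:` entry and optionally a
#' `standards:` list, each with `concentration_mM`, `m_slow`, `m_fast`,
#' `t2s_slow_ms`, `t2s_fast_ms`.
#'
#' @param path YAML file path
#' @return list with `reference` (a [PhantomStandard-class]) and
#'   `standards` (list of [PhantomStandard-class])
#' @export
readPhantomConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(!is.null(cfg$phantom), "config must contain a 'phantom' block")
  mk <- function(b) PhantomStandard(
    concentration = b$concentration_mM %||% 20,
    mSlow = b$m_slow %||% 1, mFast = b$m_fast %||% 0,
    t2sSlow = b$t2s_slow_ms %||% 55, t2sFast = b$t2s_fast_ms %||% 30)
  list(reference = mk(cfg$phantom$reference %||% list()),
       standards = lapply(cfg$phantom$standards %||% list(), mk))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
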