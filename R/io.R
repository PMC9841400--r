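#' @include AllClasses.R
NULL

#' Write an ImageStack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...). Axes, channel names, pixel size and z-step go to
#' `<file>.json` since baseline TIFF carries no standard axes tags.
#' Intensities are stored as 32-bit floats.
#'
#' @param stack an [ImageStack-class].
#' @param file output TIFF path.
#' @return invisibly, `file`.
#' @export
writeImageStack <- function(stack, file) {
    v <- stack@voxels
    d <- dim(v)
    pages <- vector("list", d[1L] * d[2L])
    i <- 1L
    for (ch in seq_len(d[1L])) for (z in seq_len(d[2L])) {
        m <- v[ch, z, , ]
        dim(m) <- d[3:4]
        pages[[i]] <- m
        i <- i + 1L
    }
    # scale to [0,1] floats for the tiff writer; record the scale
    mx <- max(v, 1)
    tiff::writeTIFF(lapply(pages, function(m) m / mx), file,
                    bits.per.sample = 32L)
    meta <- list(axes = "CZYX", shape = d,
                 channel_names = stack@channelNames,
                 pixel_size_um = stack@pixelSize,
                 z_step_um = stack@zStep, intensity_scale = mx)
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(file)
}

#' Read an ImageStack written by [writeImageStack()]
#'
#' @param file TIFF path (expects `<file>.json` sidecar).
#' @param pixelSize,zStepUm optional overrides of the sidecar geometry.
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(file, pixelSize = NULL, zStepUm = NULL) {
    meta <- jsonlite::read_json(paste0(file, ".json"),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(file, all = TRUE)
    d <- as.integer(meta$shape)
    v <- array(0, dim = d)
    i <- 1L
    for (ch in seq_len(d[1L])) for (z in seq_len(d[2L])) {
        v[ch, z, , ] <- pages[[i]] * meta$intensity_scale
        i <- i + 1L
    }
    imageStack(v,
               pixelSize = if (is.null(pixelSize)) meta$pixel_size_um
                           else pixelSize,
               zStep = if (is.null(zStepUm)) meta$z_step_um else zStepUm,
               channelNames = meta$channel_names)
}

#' Write a FRAP trace to CSV
#'
#' Columns `time_s`, `bleached`, `reference`; the pre-bleach frame count
#' travels in a comment-free extra column `n_pre_frames` (constant).
#'
#' @param trace a [RecoveryTrace-class].
#' @param file output CSV path.
#' @return invisibly, `file`.
#' @export
writeFrapTrace <- function(trace, file) {
    utils::write.csv(data.frame(time_s = trace@times,
                                bleached = trace@bleached,
                                reference = trace@reference,
                                n_pre_frames = trace@nPreFrames),
                     file, row.names = FALSE)
    invisible(file)
}

#' Write foci-quantification results to CSV files
#'
#' Writes `foci.csv` (one row per focus), `nuclei.csv` (one row per
#' nucleus) and `fields.csv` (one row per field summary).
#'
#' @param results list as returned by [quantifyFoci()], or a list of
#'   such lists (one per field).
#' @param outDir output directory.
#' @return invisibly, the paths written.
#' @export
writeFociResults <- function(results, outDir) {
    if (!is.null(results$foci)) results <- list(results)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    addField <- function(df, i) {
        if (is.null(df) || !nrow(df)) return(NULL)
        cbind(field = i, df)
    }
    foci <- do.call(rbind, lapply(seq_along(results),
                                  function(i) addField(results[[i]]$foci, i)))
    nuc <- do.call(rbind, lapply(seq_along(results),
                                 function(i) addField(results[[i]]$nuclei, i)))
    fld <- do.call(rbind, lapply(seq_along(results),
                                 function(i) addField(results[[i]]$summary, i)))
    paths <- character(0)
    for (nm in c("foci", "nuclei", "fields")) {
        df <- switch(nm, foci = foci, nuclei = nuc, fields = fld)
        p <- file.path(outDir, paste0(nm, ".csv"))
        utils::write.csv(if (is.null(df)) data.frame() else df, p,
                         row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}
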