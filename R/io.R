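# TIFF and CSV interchange for the pipeline's containers.

#' Write a WormVideo (or bare stack) as a multi-frame grayscale TIFF
#'
#' @param video a \linkS4class{WormVideo} or a [row, col, frame] array in
#'   [0, 1].
#' @param path output .tif path.
#' @param bits 8 or 16.
#' @return path, invisibly.
#' @export
writeTiffStack <- function(video, path, bits = 16L) {
  stack <- if (methods::is(video, "WormVideo")) video@frames else video
  fr <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(fr, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a multi-frame grayscale TIFF into a WormVideo
#'
#' @param path .tif path.
#' @param fps,mm_per_px acquisition metadata (not stored in plain TIFF).
#' @return a \linkS4class{WormVideo}.
#' @export
readTiffStack <- function(path, fps, mm_per_px) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  fr <- lapply(fr, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
  stack <- array(unlist(fr), c(dim(fr[[1]]), length(fr)))
  methods::new("WormVideo", frames = stack, fps = fps, mmPerPx = mm_per_px,
               protocol = data.frame(), meta = list(path = path))
}

#' Write a midline series as long-format CSV plus a per-frame QC table
#'
#' @param series a \linkS4class{MidlineSeries}.
#' @param midlines_path CSV (frame, point_idx, row, col) for valid frames.
#' @param qc_path optional CSV (frame, valid, invalid_reason,
#'   arc_length_px).
#' @return midlines_path, invisibly.
#' @export
writeMidlinesCsv <- function(series, midlines_path, qc_path = NULL) {
  vi <- which(series@valid)
  nP <- dim(series@points)[1]
  rows <- lapply(vi, function(i)
    data.frame(frame = i, point_idx = seq_len(nP),
               row = series@points[, 1, i], col = series@points[, 2, i]))
  utils::write.csv(do.call(rbind, rows), midlines_path, row.names = FALSE)
  if (!is.null(qc_path))
    utils::write.csv(
      data.frame(frame = seq_along(series@valid), valid = series@valid,
                 invalid_reason = series@invalidReason,
                 arc_length_px = series@arcLengthPx),
      qc_path, row.names = FALSE)
  invisible(midlines_path)
}

#' Read a midline CSV back into a MidlineSeries
#' @param path CSV written by \code{\link{writeMidlinesCsv}}.
#' @param n_frames total frame count (frames absent from the CSV are
#'   invalid); default the largest frame index present.
#' @return a \linkS4class{MidlineSeries} (marked oriented; orientation is
#'   whatever was saved).
#' @export
readMidlinesCsv <- function(path, n_frames = NULL) {
  d <- utils::read.csv(path)
  nP <- max(d$point_idx)
  if (is.null(n_frames)) n_frames <- max(d$frame)
  pts <- array(NA_real_, c(nP, 2L, n_frames))
  th <- matrix(NA_real_, nP - 1L, n_frames)
  valid <- logical(n_frames)
  arc <- rep(NA_real_, n_frames)
  for (i in unique(d$frame)) {
    di <- d[d$frame == i, ]
    di <- di[order(di$point_idx), ]
    pts[, , i] <- cbind(di$row, di$col)
    dd <- diff(pts[, , i])
    th[, i] <- atan2(dd[, 1], dd[, 2])
    arc[i] <- sum(sqrt(rowSums(dd^2)))
    valid[i] <- TRUE
  }
  methods::new("MidlineSeries", points = pts, theta = th, valid = valid,
               invalidReason = ifelse(valid, NA_character_, "no_worm"),
               arcLengthPx = arc, oriented = TRUE)
}

#' Write a fluorescence trace table
#' @param traces list of \linkS4class{Trace}s.
#' @param path CSV path.
#' @return path, invisibly.
#' @export
writeTracesCsv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(time_s = tr@time, roi = tr@roi, channel = tr@channel,
               raw = tr@raw, background = tr@background,
               corrected = tr@corrected, normalized = tr@normalized))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
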