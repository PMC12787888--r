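#' Read a MOT-dialect detection file
#'
#' Comma-separated `frame,id,x,y,w,h,conf[,...]` records; frames are
#' 1-based on disk and 0-based in memory. A header line is optional (the
#' first field being non-numeric marks one); extra columns -- embeddings
#' `e1..eD`, regression logits `reg1..regN`, `gt_id`, precomputed
#' `quality_q` -- are preserved when headers name them. Malformed rows and
#' non-positive box sizes are rejected with the offending line number;
#' out-of-order frames are sorted with a warning.
#'
#' @param path Detection file.
#' @return Detection data.frame with 0-based `frame`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!has_header) {
    base <- c("frame", "id", "x", "y", "w", "h", "conf")
    if (ncol(df) < 7) stop("detection file needs at least 7 columns: ", path)
    names(df)[seq_len(7)] <- base
    if (ncol(df) > 7)
      names(df)[8:ncol(df)] <- paste0("e", seq_len(ncol(df) - 7L))
  }
  need <- c("frame", "id", "x", "y", "w", "h", "conf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("detection file missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("malformed value in column '", col, "' at line ",
           bad[1] + has_header, " of ", path)
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(df$w <= 0 | df$h <= 0)
  if (length(bad))
    stop("non-positive box size at line ", bad[1] + has_header, " of ", path)
  if (is.unsorted(df$frame)) {
    warning("detection frames out of order; sorting")
    df <- df[order(df$frame), , drop = FALSE]
  }
  df$frame <- as.integer(df$frame) - 1L
  df$id <- as.integer(df$id)
  rownames(df) <- NULL
  df
}

#' Write detections in the MOT dialect
#'
#' Inverse of [read_detections()]: a header line, 1-based frames, fixed
#' 6-decimal formatting so identical inputs produce byte-identical files.
#'
#' @param detections Detection data.frame (0-based `frame`).
#' @param path Output file.
#' @export
write_detections <- function(detections, path) {
  d <- detections
  d$frame <- d$frame + 1L
  write_fixed_csv(d, path)
}

write_mot_csv <- function(df, path) {
  d <- df
  d$frame <- d$frame + 1L
  write_fixed_csv(d, path)
}

# fixed-format CSV writer: numbers at 6 decimals, integers bare
write_fixed_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- sprintf("%.6f", col)
      out[!is.finite(col)] <- ""
      out
    } else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write track output files
#'
#' CSV `frame,track_id,x,y,w,h,conf,status[,box_depth_m,height_m]`,
#' 1-based frames on disk.
#'
#' @param path File path.
#' @return `read_tracks` returns the records with 0-based `frame`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$frame <- as.integer(df$frame) - 1L
  df
}

#' @rdname read_tracks
#' @param tracks Track records data.frame.
#' @export
write_tracks <- function(tracks, path) {
  write_mot_csv(tracks, path)
}

#' Split a detection table into per-frame pieces
#'
#' @param detections Detection data.frame with 0-based `frame`.
#' @param n_frames Sequence length (defaults to `max(frame) + 1`).
#' @return List of per-frame data.frames (possibly empty), length
#'   `n_frames`.
#' @export
split_by_frame <- function(detections, n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  lapply(seq_len(n_frames) - 1L,
         function(f) detections[detections$frame == f, , drop = FALSE])
}
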