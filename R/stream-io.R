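## Delimited-text I/O for sensor streams and interval annotations.
##
## Stream CSV header (fixed):
##   t,a_v,a_l,a_f,rssi,antenna_id,phase,channel,participant_id,gender
## Annotation CSV header: start,end,label
## Annotation intervals are half-open [start, end): adjacent activities
## partition time with no double-labeling.

stream_columns <- function() {
  c("t", "a_v", "a_l", "a_f", "rssi", "antenna_id", "phase", "channel",
    "participant_id", "gender")
}

#' Read a sensor observation stream
#'
#' Reads one trial's stream of RFID sensor observations from a CSV file and
#' validates it against the room's antenna set.  Each row is one tag read:
#' time `t` (seconds), acceleration `a_v`, `a_l`, `a_f` (g, vertical /
#' lateral / frontal sensor axes, full scale +/- 3 g), `rssi` (dBm),
#' `antenna_id`, RF `phase` (radians, wrapped into `[0, 2*pi)`), frequency
#' `channel` (integer index), `participant_id` and `gender` (0/1).
#'
#' Rows with missing numeric fields or accelerations beyond the +/- 3 g
#' sensor range are rejected with a row-indexed warning.  An `antenna_id`
#' outside the room's antenna set is a schema error; timestamps must be
#' non-decreasing (ties keep file order).
#'
#' @param path path to a CSV file with the fixed header.
#' @param room a [room_config()].
#' @return data.frame of class `sensor_stream`, rows ordered by `t`.
#' @seealso [write_stream()], [read_annotations()]
#' @export
read_stream <- function(path, room) {
  if (!file.exists(path)) stop("stream file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(stream_columns(), names(df))
  if (length(missing_cols)) {
    stop("stream file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[stream_columns()]
  validate_stream(df, room)
}

#' Validate an in-memory sensor stream
#'
#' Applies the same checks as [read_stream()] to a data.frame already in
#' memory (e.g. produced by the simulator).
#' @param df data.frame with the stream columns.
#' @inheritParams read_stream
#' @return the validated `sensor_stream` data.frame.
#' @export
validate_stream <- function(df, room) {
  if (nrow(df) == 0) {
    class(df) <- c("sensor_stream", "data.frame")
    return(df)
  }
  num_cols <- c("t", "a_v", "a_l", "a_f", "rssi", "phase", "channel")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])

  bad <- rowSums(is.na(df[num_cols])) > 0
  over_range <- !bad &
    (abs(df$a_v) > 3 | abs(df$a_l) > 3 | abs(df$a_f) > 3)
  drop <- bad | over_range
  if (any(drop)) {
    warning(sum(drop), " invalid stream row(s) rejected (rows ",
            paste(utils::head(which(drop), 10L), collapse = ", "),
            if (sum(drop) > 10L) ", ..." else "",
            "): missing fields or acceleration beyond +/-3 g")
    df <- df[!drop, , drop = FALSE]
  }
  unknown <- setdiff(unique(df$antenna_id), room_antenna_ids(room))
  if (length(unknown)) {
    stop("unknown antenna_id for ", room$room_id, ": ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(df) > 1 && any(diff(df$t) < 0)) {
    stop("stream timestamps are not non-decreasing (first offence near row ",
         which(diff(df$t) < 0)[1] + 1L, ")")
  }
  # wrap phase into [0, 2*pi)
  df$phase <- df$phase %% (2 * pi)
  df$channel <- as.integer(df$channel)
  rownames(df) <- NULL
  class(df) <- c("sensor_stream", "data.frame")
  df
}

#' Write a sensor observation stream
#'
#' Inverse of [read_stream()]; writes full double precision so that a
#' write/read round trip is the identity.
#' @param stream a `sensor_stream` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  df <- as.data.frame(stream)[stream_columns()]
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground-truth activity annotations
#'
#' Annotations are intervals `start,end,label` (seconds; label names as in
#' [activity_labels()]).  Intervals are half-open `[start, end)`, must be
#' non-overlapping, and are returned sorted by `start`.
#'
#' @param path path to an annotation CSV.
#' @return data.frame of class `annotations` with columns `start`, `end`
#'   (numeric) and `label` (integer code).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "label")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns start,end,label")
  }
  lab <- if (is.numeric(df$label)) as.integer(df$label)
         else activity_code(df$label)
  make_annotations(df$start, df$end, lab)
}

#' Construct and validate an annotation set
#'
#' @param start,end numeric vectors (seconds), `start < end` elementwise.
#' @param label integer codes or label names.
#' @return validated `annotations` data.frame sorted by `start`.
#' @export
make_annotations <- function(start, end, label) {
  if (is.character(label)) label <- activity_code(label)
  label <- as.integer(label)
  if (any(!label %in% activity_labels())) stop("invalid activity code")
  if (any(end <= start)) stop("annotation intervals need start < end")
  ord <- order(start)
  df <- data.frame(start = as.numeric(start)[ord],
                   end = as.numeric(end)[ord],
                   label = label[ord])
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)] - 1e-12)) {
    stop("annotation intervals overlap")
  }
  class(df) <- c("annotations", "data.frame")
  df
}

#' @rdname read_annotations
#' @param annotations an `annotations` data.frame.
#' @param path output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(start = annotations$start, end = annotations$end,
                   label = activity_name(annotations$label))
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ground-truth label at given times
#'
#' Looks up the annotated activity at time `t` under the half-open
#' `[start, end)` interval convention.  Errors if any probe time falls
#' outside the annotated span.
#'
#' @param annotations an `annotations` data.frame.
#' @param t numeric vector of probe times (seconds).
#' @return integer vector of activity codes, same length as `t`.
#' @export
label_at <- function(annotations, t) {
  if (nrow(annotations) == 0) stop("no annotations")
  idx <- findInterval(t, annotations$start)
  ok <- idx >= 1L
  ok[ok] <- t[ok] < annotations$end[idx[ok]]
  if (!all(ok)) {
    stop("time(s) outside annotated span: ",
         paste(utils::head(t[!ok], 5L), collapse = ", "))
  }
  annotations$label[idx]
}
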