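#' Room (antenna deployment) configuration
#'
#' Describes one of the two supported clinic-room antenna deployments.
#' Room 1 has four antennas of which `antenna2` illuminates the chair area
#' and the rest the bed area; Room 1 additionally enables the extended
#' ("dagger") feature set.  Room 2 has three antennas: `antenna1` faces the
#' chair, `antenna2` and `antenna3` the bed.
#'
#' @param room_id `"room1"` or `"room2"` (case-insensitive).
#' @return an object of class `room_config`: a list with elements
#'   `room_id`, `antennas` (data.frame with columns `antenna_id`, `area`)
#'   and `use_dagger_features` (logical).
#' @examples
#' room_config("room2")
#' @export
room_config <- function(room_id = c("room1", "room2")) {
  room_id <- match.arg(tolower(room_id[1]), c("room1", "room2"))
  antennas <- if (room_id == "room1") {
    data.frame(
      antenna_id = paste0("antenna", 1:4),
      area = c("bed", "chair", "bed", "bed"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      antenna_id = paste0("antenna", 1:3),
      area = c("chair", "bed", "bed"),
      stringsAsFactors = FALSE)
  }
  structure(
    list(room_id = room_id,
         antennas = antennas,
         use_dagger_features = (room_id == "room1")),
    class = "room_config")
}

#' @export
print.room_config <- function(x, ...) {
  cat("Room configuration:", x$room_id, "\n")
  cat("  antennas:", paste0(x$antennas$antenna_id, " (", x$antennas$area, ")",
                            collapse = ", "), "\n")
  cat("  extended (dagger) features:", x$use_dagger_features, "\n")
  invisible(x)
}

room_antenna_ids <- function(room) room$antennas$antenna_id

antenna_area <- function(room, antenna_id) {
  idx <- match(antenna_id, room$antennas$antenna_id)
  if (anyNA(idx)) {
    stop("unknown antenna_id for ", room$room_id, ": ",
         paste(unique(antenna_id[is.na(idx)]), collapse = ", "))
  }
  room$antennas$area[idx]
}
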