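## Activity label coding.  The integer codes are part of the public contract:
## 1 Sitting-on-bed, 2 Sitting-on-chair, 3 Lying, 4 Ambulating.

#' Activity labels
#'
#' The four monitored activity classes and their integer codes:
#' 1 = `Sitting-on-bed`, 2 = `Sitting-on-chair`, 3 = `Lying`,
#' 4 = `Ambulating`.  All classifier and recognizer interfaces use these
#' codes; the names are used in annotation files.
#'
#' @return `activity_labels()` returns a named integer vector of length 4
#'   (names are the label strings, values the codes).
#' @examples
#' activity_labels()
#' activity_code("Lying")
#' activity_name(4L)
#' @export
activity_labels <- function() {
  c("Sitting-on-bed" = 1L, "Sitting-on-chair" = 2L,
    "Lying" = 3L, "Ambulating" = 4L)
}

#' @rdname activity_labels
#' @param name character vector of label names.
#' @export
activity_code <- function(name) {
  lab <- activity_labels()
  idx <- match(name, names(lab))
  if (anyNA(idx)) {
    stop("unknown activity label(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  unname(lab[idx])
}

#' @rdname activity_labels
#' @param code integer vector of label codes in 1..4.
#' @export
activity_name <- function(code) {
  lab <- activity_labels()
  if (any(!code %in% lab)) {
    stop("activity codes must be integers in 1..4")
  }
  names(lab)[match(code, lab)]
}

# number of activity classes (K)
n_classes <- function() 4L
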