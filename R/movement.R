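#' Movement classes and fingers
#'
#' The decoding problem distinguishes nine movement classes: four fingers
#' (index, middle, ring, little) times two movement directions (flexion,
#' extension), plus rest. Classes are coded by two-letter abbreviations
#' (`"IF"` = index flexion, ..., `"LE"` = little extension) and `"REST"`.
#'
#' @return `movement_classes()` returns the nine class codes in canonical
#'   order; `fingers()` returns the four finger names.
#' @examples
#' movement_classes()
#' fingers()
#' @export
movement_classes <- function() {
  c("IF", "IE", "MF", "ME", "RF", "RE", "LF", "LE", "REST")
}

#' @rdname movement_classes
#' @export
fingers <- function() {
  c("index", "middle", "ring", "little")
}

#' Map movement classes to fingers and directions
#'
#' @param class character vector of movement class codes (see
#'   [movement_classes()]).
#' @return `class_finger()` returns the finger name (`NA` for `"REST"`);
#'   `class_sign()` returns +1 for flexion, -1 for extension and 0 for rest,
#'   following the storage convention that flexion force is positive.
#' @examples
#' class_finger(c("IF", "RE", "REST"))
#' class_sign(c("IF", "RE", "REST"))
#' @export
class_finger <- function(class) {
  check_movement_class(class)
  map <- c(
    IF = "index", IE = "index", MF = "middle", ME = "middle",
    RF = "ring", RE = "ring", LF = "little", LE = "little", REST = NA_character_
  )
  unname(map[class])
}

#' @rdname class_finger
#' @export
class_sign <- function(class) {
  check_movement_class(class)
  ifelse(class == "REST", 0, ifelse(substr(class, 2, 2) == "F", 1, -1))
}

#' @rdname class_finger
#' @param finger character vector of finger names.
#' @param direction `"F"` (flexion) or `"E"` (extension).
#' @export
finger_class <- function(finger, direction) {
  stopifnot(all(finger %in% fingers()), all(direction %in% c("F", "E")))
  paste0(toupper(substr(finger, 1, 1)), direction)
}

active_classes <- function() setdiff(movement_classes(), "REST")

check_movement_class <- function(class) {
  bad <- setdiff(class, movement_classes())
  if (length(bad) > 0) {
    stop("unknown movement class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(class)
}
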