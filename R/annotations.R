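#' B-scan landmark annotation
#'
#' Container for the manual landmarks placed on one optic-nerve-head OCT
#' B-scan: the two points where Bruch's membrane terminates at the disc
#' margin (the Bruch's membrane opening, BMO) and up to eight points placed
#' on the anterior surface of the lamina cribrosa (LC).  All coordinates are
#' physical micrometres, `(lateral, axial)`; whether the axial coordinate
#' grows towards the back of the eye is recorded explicitly so the sign of
#' the depth measurement is unambiguous.
#'
#' @param scan_index integer scan number within the acquisition volume
#'   (0-based, as emitted by the acquisition software).
#' @param bmo numeric 2 x 2 matrix (rows = points, columns = lateral, axial),
#'   micrometres.  The two points must be distinct.
#' @param lc numeric matrix with 1 to 8 rows, the anterior-LC landmarks,
#'   micrometres.
#' @param axial_positive_is_posterior logical; `TRUE` (default) when larger
#'   axial coordinates are deeper in the eye.
#' @return An object of class `bscan_annotation`.
#' @examples
#' a <- bscan_annotation(0, rbind(c(0, 0), c(1500, 0)),
#'                       rbind(c(400, 350), c(750, 465), c(1100, 350)))
#' scan_lcd(a)
#' @seealso [scan_lcd()], [read_annotations()]
#' @export
bscan_annotation <- function(scan_index, bmo, lc,
                             axial_positive_is_posterior = TRUE) {
  scan_index <- as.integer(scan_index)
  bmo <- as_point_matrix(bmo, "bmo")
  lc <- as_point_matrix(lc, "lc")
  if (length(scan_index) != 1L || is.na(scan_index) || scan_index < 0L)
    stop("scan_index must be a single non-negative integer")
  if (nrow(bmo) != 2L)
    stop(sprintf("scan %d: exactly 2 BMO points are required, got %d",
                 scan_index, nrow(bmo)))
  if (nrow(lc) < 1L || nrow(lc) > 8L)
    stop(sprintf("scan %d: 1 to 8 anterior-LC points are required, got %d",
                 scan_index, nrow(lc)))
  if (!all(is.finite(bmo)) || !all(is.finite(lc)))
    stop(sprintf("scan %d: all coordinates must be finite", scan_index))
  if (sqrt(sum((bmo[1L, ] - bmo[2L, ])^2)) <= 0)
    stop(sprintf("scan %d: BMO points are coincident", scan_index))
  structure(
    list(scan_index = scan_index, bmo = bmo, lc = lc,
         axial_positive_is_posterior = isTRUE(axial_positive_is_posterior)),
    class = "bscan_annotation")
}

as_point_matrix <- function(x, what) {
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop(sprintf("%s points must have 2 columns (lateral, axial)", what))
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("lateral_um", "axial_um"))
  x
}

#' @export
print.bscan_annotation <- function(x, ...) {
  cat(sprintf("B-scan annotation: scan %d, %d LC points, BMO width %.1f um\n",
              x$scan_index, nrow(x$lc),
              sqrt(sum((x$bmo[1L, ] - x$bmo[2L, ])^2))))
  invisible(x)
}

#' Annotated eye (set of B-scan annotations)
#'
#' @param scans list of [bscan_annotation()] objects.
#' @param eye_id character identifier for the eye.
#' @param axial_positive_is_posterior coordinate convention shared by all
#'   scans of the file.
#' @return An object of class `eye_annotations`: a list of
#'   `bscan_annotation` with `eye_id` and convention attributes.
#' @export
eye_annotations <- function(scans, eye_id = "eye",
                            axial_positive_is_posterior = TRUE) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  ok <- vapply(scans, inherits, logical(1), "bscan_annotation")
  if (!all(ok)) stop("all elements of scans must be bscan_annotation objects")
  scans <- lapply(scans, function(s) {
    s$axial_positive_is_posterior <- isTRUE(axial_positive_is_posterior)
    s
  })
  structure(scans, class = "eye_annotations", eye_id = as.character(eye_id),
            axial_positive_is_posterior = isTRUE(axial_positive_is_posterior))
}

#' @export
print.eye_annotations <- function(x, ...) {
  cat(sprintf("Annotated eye '%s': %d B-scans (axial+ = %s)\n",
              attr(x, "eye_id"), length(x),
              if (attr(x, "axial_positive_is_posterior")) "posterior"
              else "anterior"))
  invisible(x)
}

#' Read B-scan landmark annotations from JSON
#'
#' The annotation dialect is a single JSON object
#' `{"eye_id", "axial_positive_is_posterior",
#'   "scans": [{"scan_index", "bmo": [[x,y],[x,y]], "lc": [[x,y], ...]}]}`
#' with all coordinates in micrometres.
#'
#' @param path path to an annotation JSON file.
#' @return An [eye_annotations()] object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stop("malformed annotation JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (f in c("eye_id", "axial_positive_is_posterior", "scans"))
    if (is.null(doc[[f]])) stop("annotation JSON misses field '", f, "'")
  scans <- lapply(doc$scans, function(s) {
    if (is.null(s$scan_index) || is.null(s$bmo) || is.null(s$lc))
      stop("annotation JSON scan entry misses scan_index/bmo/lc")
    tryCatch(
      bscan_annotation(s$scan_index, s$bmo, s$lc,
                       doc$axial_positive_is_posterior),
      error = function(e) stop(conditionMessage(e), call. = FALSE))
  })
  eye_annotations(scans, doc$eye_id, doc$axial_positive_is_posterior)
}

#' Write B-scan landmark annotations to JSON
#'
#' Inverse of [read_annotations()]; round-trips losslessly.
#'
#' @param annotations an [eye_annotations()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "eye_annotations"))
  doc <- list(
    eye_id = attr(annotations, "eye_id"),
    axial_positive_is_posterior =
      attr(annotations, "axial_positive_is_posterior"),
    scans = lapply(annotations, function(s)
      list(scan_index = s$scan_index,
           bmo = unname(s$bmo), lc = unname(s$lc))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
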