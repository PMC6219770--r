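## Landmark geometry: BMO reference line and lamina cribrosa depth.
##
## The depth of the anterior lamina cribrosa surface is measured against the
## line joining the two Bruch's-membrane-opening landmarks ("BMO line").  The
## scan-level LCD is the largest perpendicular distance from any anterior-LC
## landmark to that line, signed so that points on the posterior side (deeper
## in the eye) are positive.

#' BMO reference line of an annotated B-scan
#'
#' @param annotation a [bscan_annotation()].
#' @return An object of class `reference_line` with fields `point_a`,
#'   `point_b` (micrometres) and `alpha_deg`, the signed angle of the line to
#'   the horizontal, in degrees within (-90, 90].
#' @export
bmo_reference_line <- function(annotation) {
  stopifnot(inherits(annotation, "bscan_annotation"))
  a <- annotation$bmo[1L, ]
  b <- annotation$bmo[2L, ]
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len <= 0)
    stop(sprintf("scan %d: degenerate geometry, coincident BMO points",
                 annotation$scan_index))
  alpha <- atan2(d[["axial_um"]], d[["lateral_um"]]) * 180 / pi
  # undirected line: fold into (-90, 90]
  if (alpha <= -90) alpha <- alpha + 180
  if (alpha > 90) alpha <- alpha - 180
  structure(list(point_a = a, point_b = b, alpha_deg = alpha),
            class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("BMO reference line: alpha = %.3f deg\n", x$alpha_deg))
  invisible(x)
}

## Signed perpendicular distances of points to the BMO line, positive on the
## posterior half-plane.  `points` is an n x 2 matrix.
signed_lc_distances <- function(annotation) {
  a <- annotation$bmo[1L, ]
  b <- annotation$bmo[2L, ]
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len <= 0)
    stop(sprintf("scan %d: degenerate geometry, coincident BMO points",
                 annotation$scan_index))
  # unit normal to the line; orient it towards the posterior half-plane
  n <- c(-d[2L], d[1L]) / len
  posterior_axial <- if (annotation$axial_positive_is_posterior) 1 else -1
  if (n[2L] * posterior_axial < 0) {
    n <- -n
  } else if (n[2L] == 0 && n[1L] < 0) {
    # vertical-normal degenerate case (BMO line parallel to the axial axis):
    # fall back to positive-lateral orientation for a deterministic sign
    n <- -n
  }
  sweep(annotation$lc, 2L, a) %*% n
}

#' Scan-level lamina cribrosa depth
#'
#' The LCD of one B-scan: the maximum perpendicular distance between the
#' anterior-LC landmarks and the BMO line, i.e. the distance of the most
#' deeply depressed landmark.  The distance is signed (posterior side
#' positive), so an LC lying entirely anterior to the BMO line yields a
#' negative depth rather than an error.  Ties are broken towards the
#' lowest-index landmark.
#'
#' @param annotation a [bscan_annotation()].
#' @return numeric depth in micrometres, with attribute `which_point`, the
#'   row index of the maximally depressed LC landmark.
#' @export
scan_lcd <- function(annotation) {
  stopifnot(inherits(annotation, "bscan_annotation"))
  d <- signed_lc_distances(annotation)
  i <- which.max(d)  # first maximum = lowest point index on ties
  structure(d[i], which_point = i)
}

#' Eye-level mean LCD over selected central B-scans
#'
#' Averages [scan_lcd()] over a selection of scans.  The selection is either
#' an explicit vector of scan indices (the practice when scans are chosen by
#' hand so that all landmarks can be placed without doubt) or the
#' deterministic central-coverage policy of [select_central_scans()] via `k`
#' and `coverage`.  Eye-level protocols typically average 12-16 central
#' scans; a selection outside that range triggers a warning, not an error.
#'
#' @param annotations an [eye_annotations()] object (or list of
#'   [bscan_annotation()]).
#' @param scan_indices explicit scan indices to use (overrides `k`).
#' @param k number of scans for the automatic central selection.
#' @param coverage fraction of the scanned band the selection spans
#'   (default 0.75, i.e. the central three quarters).
#' @return An object of class `eye_lcd`: list with `per_scan`
#'   (data.frame `scan_index`, `lcd_um`), `mean_lcd` and `n_scans_used`.
#' @export
mean_lcd <- function(annotations, scan_indices = NULL, k = NULL,
                     coverage = 0.75) {
  if (inherits(annotations, "bscan_annotation"))
    annotations <- list(annotations)
  stopifnot(length(annotations) >= 1L)
  idx <- vapply(annotations, `[[`, integer(1), "scan_index")
  if (!is.null(scan_indices)) {
    keep <- idx %in% scan_indices
    if (!any(keep)) stop("empty scan selection: none of the requested ",
                         "scan indices are annotated")
  } else if (!is.null(k)) {
    n_total <- max(idx) + 1L
    sel <- select_central_scans(n_total, k, coverage)
    keep <- idx %in% sel
    if (sum(keep) < k)
      stop("empty or short scan selection: only ", sum(keep), " of the ", k,
           " centrally selected scans are annotated")
  } else {
    keep <- rep(TRUE, length(annotations))
  }
  used <- annotations[keep]
  lcd <- vapply(used, function(a) as.numeric(scan_lcd(a)), numeric(1))
  n <- length(lcd)
  if (n < 12L || n > 16L)
    warning("mean LCD computed over ", n,
            " scans (protocols typically use 12-16 central B-scans)",
            call. = FALSE)
  structure(list(per_scan = data.frame(scan_index = idx[keep], lcd_um = lcd),
                 mean_lcd = mean(lcd), n_scans_used = n),
            class = "eye_lcd")
}

#' @export
print.eye_lcd <- function(x, ...) {
  cat(sprintf("Mean LCD: %.1f um over %d B-scans (range %.1f to %.1f)\n",
              x$mean_lcd, x$n_scans_used, min(x$per_scan$lcd_um),
              max(x$per_scan$lcd_um)))
  invisible(x)
}

#' Deterministic central-scan selection
#'
#' Chooses `k` equidistant scan indices, symmetric about the central scan of
#' a volume of `n_total` scans, spanning the central `coverage` fraction of
#' the index range `[0, n_total - 1]`.  The band limits are first snapped
#' inward to the integer grid; fractional positions ending in .5 are rounded
#' away from the centre so the selection stays symmetric.
#'
#' @param n_total number of scans in the volume.
#' @param k number of scans to select (`1 <= k <=` scans inside the band).
#' @param coverage fraction in (0, 1] of the index range to cover.
#' @return integer vector of `k` 0-based scan indices, increasing.
#' @export
select_central_scans <- function(n_total, k, coverage = 0.75) {
  stopifnot(n_total >= 1L, k >= 1L, coverage > 0, coverage <= 1)
  centre <- (n_total - 1) / 2
  half <- coverage * (n_total - 1) / 2
  lo <- ceiling(centre - half)
  hi <- floor(centre + half)
  n_band <- hi - lo + 1L
  if (k > n_band)
    stop("k = ", k, " exceeds the ", n_band,
         " scans inside the covered band [", lo, ", ", hi, "]")
  pos <- if (k == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = k)
  round_half_away_from <- function(x, c0) {
    r <- round(x)  # round-half-even at .5; fix those cases explicitly
    at_half <- abs(x - floor(x) - 0.5) < 1e-9
    r[at_half] <- ifelse(x[at_half] >= c0,
                         ceiling(x[at_half]), floor(x[at_half]))
    r
  }
  out <- as.integer(round_half_away_from(pos, centre))
  stopifnot(!anyDuplicated(out))
  out
}
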