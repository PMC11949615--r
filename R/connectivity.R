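# Scan segmentation and functional-connectome estimation.
#
# The study design this package targets: Scan 1 is 8 min of rest, Scan 2 is
# a 4-min stop signal task (SST), a 12-s transition slide, then 8 min of
# rest. Both scans are cut into 4-min analysis segments labelled
# R1.1, R1.2 (scan 1) and SST, R2.1, R2.2 (scan 2).

SEGMENT_LABELS <- c("R1.1", "R1.2", "SST", "R2.1", "R2.2")

#' Default five-segment scheme for the rest / task / rest design
#'
#' Builds the volume-index layout for the two scans: scan 1 holds two 4-min
#' rest segments (R1.1, R1.2); scan 2 holds the 4-min task segment (SST), a
#' discarded 12-s transition, and two further 4-min rest segments (R2.1,
#' R2.2). Segment boundaries sit at the nominal 4-min (240 s) marks. The
#' initial `ceiling(7 / tr)` calibration volumes of each scan (steady-state
#' magnetization) are discarded from the *first* segment of that scan only,
#' so R1.1 and SST are slightly shorter while all later segments keep their
#' full nominal length.
#'
#' Intervals are 0-based half-open `[start, end)` volume indices.
#'
#' @param tr_seconds Repetition time in seconds (e.g. 1.2).
#' @param scan1_volumes,scan2_volumes Number of volumes acquired in each
#'   scan; they must match the nominal layout (scan 1: 480 s; scan 2: 732 s).
#' @return A `segment_scheme`: a tibble with columns `label`, `scan`,
#'   `start`, `end`, plus a `discarded` attribute tibble of the same shape.
#' @examples
#' default_scheme(1.2, 400, 610)
#' @export
default_scheme <- function(tr_seconds, scan1_volumes, scan2_volumes) {
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) abort("`tr_seconds` must be > 0.")
  seg <- round(240 / tr_seconds)          # volumes per nominal 4-min segment
  trans <- round(12 / tr_seconds)         # discarded transition volumes
  calib <- ceiling(7 / tr_seconds)        # discarded calibration volumes
  need1 <- 2L * seg
  need2 <- 3L * seg + trans
  if (scan1_volumes != need1) {
    abort(sprintf(
      "Scan 1 has %d volumes but the layout (two 4-min segments at TR = %g s) needs %d.",
      scan1_volumes, tr_seconds, need1))
  }
  if (scan2_volumes != need2) {
    abort(sprintf(
      "Scan 2 has %d volumes but the layout (4-min task + 12-s transition + 8-min rest at TR = %g s) needs %d.",
      scan2_volumes, tr_seconds, need2))
  }
  if (calib >= seg) abort("Calibration period exceeds a segment; TR too long.")

  segments <- tibble::tibble(
    label = SEGMENT_LABELS,
    scan  = c("scan1", "scan1", "scan2", "scan2", "scan2"),
    start = c(calib, seg, calib, seg + trans, 2L * seg + trans),
    end   = c(seg, 2L * seg, seg, 2L * seg + trans, 3L * seg + trans)
  )
  discarded <- tibble::tibble(
    label = c("calibration1", "calibration2", "transition"),
    scan  = c("scan1", "scan2", "scan2"),
    start = c(0L, 0L, seg),
    end   = c(calib, calib, seg + trans)
  )
  structure(segments,
            discarded = discarded,
            tr_seconds = tr_seconds,
            class = c("segment_scheme", class(segments)))
}

#' Slice a BOLD time-series matrix into labelled segments
#'
#' @param ts A numeric T x p matrix (rows = volumes, columns = regions) for
#'   one scan of one subject.
#' @param scheme A [default_scheme()] result (or a compatible tibble with
#'   `label`, `scan`, `start`, `end`).
#' @param scan Which scan `ts` belongs to (`"scan1"` or `"scan2"`).
#' @return A tibble with columns `label` and `data` (list of sub-matrices).
#'   Discarded intervals appear in no output row.
#' @export
split_segments <- function(ts, scheme, scan = c("scan1", "scan2")) {
  scan <- match.arg(scan)
  if (!is.matrix(ts) || !is.numeric(ts)) abort("`ts` must be a numeric matrix.")
  segs <- scheme[scheme$scan == scan, , drop = FALSE]
  if (nrow(segs) == 0) abort(sprintf("Scheme has no segments for %s.", scan))
  if (max(segs$end) > nrow(ts)) {
    abort(sprintf("Scheme needs %d volumes for %s but `ts` has %d rows.",
                  max(segs$end), scan, nrow(ts)))
  }
  tibble::tibble(
    label = segs$label,
    data = purrr::map2(segs$start, segs$end,
                       function(s, e) ts[(s + 1):e, , drop = FALSE])
  )
}

#' Pearson functional connectome of a time-series segment
#'
#' Pairwise Pearson correlation of region time series. The result is a
#' symmetric correlation matrix with unit diagonal; as a Gram matrix of
#' standardized columns it is always positive semidefinite, and singular
#' whenever the region count exceeds the available degrees of freedom
#' (use [regularize()] before any manifold operation in that case).
#'
#' @param segment A T x p numeric matrix, `T >= 3`.
#' @return The p x p correlation matrix (region names preserved).
#' @export
compute_fc <- function(segment) {
  if (!is.matrix(segment) || !is.numeric(segment)) {
    abort("`segment` must be a numeric matrix.")
  }
  if (nrow(segment) < 3) abort("Need at least 3 time points to correlate.")
  if (!all(is.finite(segment))) abort("Time series contain non-finite values.")
  sds <- apply(segment, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- colnames(segment)[bad] %||% as.character(bad)
    abort(sprintf("Zero-variance region(s): %s — correlation undefined.",
                  paste(labs, collapse = ", ")))
  }
  R <- stats::cor(segment)
  R <- symmetrize(R)
  diag(R) <- 1
  R
}

#' Upper-triangle vectorization of a symmetric matrix
#'
#' Row-major scan of the upper triangle, excluding the diagonal by default
#' (an FC diagonal is identically 1 and carries no information; tangent
#' matrices follow the same convention for comparability). The map is
#' injective on symmetric matrices; [unvectorize_sym()] inverts it.
#'
#' @param M Symmetric p x p matrix.
#' @param include_diagonal Include the main diagonal in the scan?
#' @return Numeric vector of length `p(p-1)/2` (or `p(p+1)/2`).
#' @export
vectorize_sym <- function(M, include_diagonal = FALSE) {
  assert_symmetric(M, "M", tol = 1e-8)
  tM <- t(M)  # row-major upper triangle == column-major lower triangle of t(M)
  tM[lower.tri(tM, diag = include_diagonal)]
}

#' @rdname vectorize_sym
#' @param v Vector produced by [vectorize_sym()].
#' @param diagonal Diagonal values to restore when `include_diagonal` was
#'   `FALSE` (scalar or length-p vector; default 0).
#' @export
unvectorize_sym <- function(v, include_diagonal = FALSE, diagonal = 0) {
  m <- length(v)
  p <- if (include_diagonal) (-1 + sqrt(1 + 8 * m)) / 2 else (1 + sqrt(1 + 8 * m)) / 2
  if (abs(p - round(p)) > 1e-8) abort("Vector length does not match a triangle.")
  p <- as.integer(round(p))
  tM <- matrix(0, p, p)
  tM[lower.tri(tM, diag = include_diagonal)] <- v
  M <- t(tM)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  if (!include_diagonal) diag(M) <- diagonal
  symmetrize(M)
}

#' Per-segment functional connectomes for a cohort
#'
#' Maps a cohort time-series table through [split_segments()] and
#' [compute_fc()].
#'
#' @param ts_tbl Tibble with columns `subject_id`, `scan`
#'   (`"scan1"`/`"scan2"`) and `data` (list of T x p matrices).
#' @param scheme A [default_scheme()] result.
#' @return Tibble with columns `subject_id`, `segment`, `fc` (list of p x p
#'   correlation matrices).
#' @export
cohort_fc <- function(ts_tbl, scheme) {
  need <- c("subject_id", "scan", "data")
  if (!all(need %in% names(ts_tbl))) {
    abort("`ts_tbl` needs columns subject_id, scan, data.")
  }
  out <- purrr::pmap(ts_tbl[need], function(subject_id, scan, data) {
    segs <- split_segments(data, scheme, scan)
    tibble::tibble(
      subject_id = subject_id,
      segment = segs$label,
      fc = purrr::map(segs$data, compute_fc)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(match(.data$segment, SEGMENT_LABELS), .data$subject_id)
}
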