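# Correlation-distance comparison of tangent connectomes: identifiability
# matrices, fingerprinting identification rates, reconfiguration vectors.

#' Correlation distance between two feature vectors
#'
#' `1 - cor(x, y)` (Pearson), lying in `[0, 2]`: 0 for perfectly correlated
#' profiles, 1 for uncorrelated, 2 for perfectly anticorrelated.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return Scalar in `[0, 2]`.
#' @examples
#' correlation_distance(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 elements.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation distance is undefined for a constant vector.")
  }
  d <- 1 - stats::cor(x, y)
  min(max(d, 0), 2)
}

tangent_ref_id <- function(M) attr(M, "reference_id", exact = TRUE)

#' Identifiability matrix between two segments' tangent connectomes
#'
#' Entry `(i, j)` is the correlation distance between subject `i`'s tangent
#' connectome in segment A and subject `j`'s in segment B, computed on the
#' diagonal-excluded upper-triangle vectorization. The two lists must share
#' the subject order and — when the matrices carry `reference_id`
#' attributes — the projection reference: distances across different tangent
#' spaces are meaningless and raise an error.
#'
#' @param tfcs_A,tfcs_B Lists of n symmetric matrices (tangent connectomes,
#'   or plain SPD connectomes for a manifold-space comparison).
#' @param segment_pair Character vector of length 2 naming (A, B).
#' @param subject_order Optional subject labels (default names of `tfcs_A`
#'   or `1:n`).
#' @param include_diagonal Passed to [vectorize_sym()].
#' @return An `identifiability_matrix`: the n x n distance matrix with
#'   attributes `segment_pair` and `subject_order`.
#' @export
identifiability_matrix <- function(tfcs_A, tfcs_B,
                                   segment_pair = c("A", "B"),
                                   subject_order = NULL,
                                   include_diagonal = FALSE) {
  if (length(tfcs_A) != length(tfcs_B)) {
    abort("Both segments must hold the same participants.")
  }
  n <- length(tfcs_A)
  if (n < 1) abort("Empty tangent-connectome lists.")
  refs <- c(purrr::map(tfcs_A, tangent_ref_id), purrr::map(tfcs_B, tangent_ref_id))
  refs <- unlist(refs[!vapply(refs, is.null, logical(1))])
  if (length(refs) > 0 && length(unique(refs)) > 1) {
    abort("Tangent matrices were projected at different references; distances across tangent spaces are not comparable.")
  }
  subject_order <- subject_order %||% names(tfcs_A) %||% as.character(seq_len(n))
  VA <- vapply(tfcs_A, vectorize_sym, numeric(length(vectorize_sym(tfcs_A[[1]], include_diagonal))),
               include_diagonal = include_diagonal)
  VB <- vapply(tfcs_B, vectorize_sym, numeric(nrow(VA)),
               include_diagonal = include_diagonal)
  if (any(apply(VA, 2, stats::sd) == 0) || any(apply(VB, 2, stats::sd) == 0)) {
    abort("A vectorized connectome is constant; correlation distance undefined.")
  }
  D <- 1 - stats::cor(VA, VB)
  D[D < 0] <- 0
  D[D > 2] <- 2
  dimnames(D) <- list(subject_order, subject_order)
  structure(D,
            segment_pair = as.character(segment_pair),
            subject_order = subject_order,
            class = c("identifiability_matrix", "matrix", "array"))
}

#' Meta-identifiability matrix over all segment pairs
#'
#' Builds the 5 x 5 grid of identifiability matrices across the segment
#' order R1.1, R1.2, SST, R2.1, R2.2; block `(i, j)` is the transpose of
#' block `(j, i)` (enforced by construction), diagonal blocks are symmetric
#' with zero diagonal.
#'
#' @param tangent_tbl Tibble with columns `subject_id`, `segment`, and a
#'   list-column of tangent matrices (named `tfc`, or the first list-column).
#' @param segments Segment order (default the five design labels).
#' @return A `meta_identifiability` object: a named list of blocks
#'   (`"A|B"`), with attributes `segments` and `subject_order`. Use
#'   [meta_block()] to extract one block and [as.matrix()] to stack the
#'   full `5n x 5n` matrix.
#' @export
meta_identifiability <- function(tangent_tbl, segments = SEGMENT_LABELS) {
  listcol <- if ("tfc" %in% names(tangent_tbl)) "tfc" else {
    cand <- names(tangent_tbl)[vapply(tangent_tbl, is.list, logical(1))]
    if (length(cand) == 0) abort("`tangent_tbl` needs a list-column of matrices.")
    cand[[1]]
  }
  missing <- setdiff(segments, unique(tangent_tbl$segment))
  if (length(missing) > 0) {
    abort(sprintf("Missing segment(s): %s.", paste(missing, collapse = ", ")))
  }
  subj <- sort(unique(tangent_tbl$subject_id))
  by_seg <- purrr::map(segments, function(s) {
    rows <- tangent_tbl[tangent_tbl$segment == s, ]
    rows <- rows[match(subj, rows$subject_id), ]
    if (any(is.na(rows$subject_id))) {
      abort(sprintf("Segment %s does not cover every subject.", s))
    }
    setNames(rows[[listcol]], subj)
  })
  names(by_seg) <- segments

  blocks <- list()
  for (i in seq_along(segments)) {
    for (j in i:length(segments)) {
      B <- identifiability_matrix(by_seg[[i]], by_seg[[j]],
                                  segment_pair = c(segments[i], segments[j]),
                                  subject_order = subj)
      if (i == j) {
        B[] <- symmetrize(unclass(B))
        diag(B) <- 0
      }
      blocks[[paste(segments[i], segments[j], sep = "|")]] <- B
      if (i != j) {
        Bt <- structure(t(unclass(B)),
                        segment_pair = c(segments[j], segments[i]),
                        subject_order = subj,
                        class = c("identifiability_matrix", "matrix", "array"))
        blocks[[paste(segments[j], segments[i], sep = "|")]] <- Bt
      }
    }
  }
  structure(list(blocks = blocks),
            segments = segments, subject_order = subj,
            class = "meta_identifiability")
}

#' @rdname meta_identifiability
#' @param meta A `meta_identifiability` object.
#' @param from,to Segment labels of the block to extract.
#' @export
meta_block <- function(meta, from, to) {
  key <- paste(from, to, sep = "|")
  if (!key %in% names(meta$blocks)) abort(sprintf("No block %s.", key))
  meta$blocks[[key]]
}

#' @export
as.matrix.meta_identifiability <- function(x, ...) {
  segs <- attr(x, "segments")
  rows <- lapply(segs, function(a) {
    do.call(cbind, lapply(segs, function(b) unclass(meta_block(x, a, b))))
  })
  M <- do.call(rbind, rows)
  subj <- attr(x, "subject_order")
  labs <- as.vector(outer(subj, segs, function(s, g) paste(g, s, sep = ":")))
  dimnames(M) <- list(labs, labs)
  M
}

#' Fingerprinting identification rate of an identifiability matrix
#'
#' A participant is identified in the row direction when the smallest
#' distance in their row sits on the main diagonal (their own connectome in
#' the other segment is their nearest match), and likewise for columns. The
#' rate is the average of the two directions, in percent. Ties in the argmin
#' count as misidentification (conservative, deterministic).
#'
#' @param idm An [identifiability_matrix()] for two *different* segments.
#' @return Percentage in `[0, 100]`.
#' @export
identification_rate <- function(idm) {
  pair <- attr(idm, "segment_pair")
  if (!is.null(pair) && length(pair) == 2 && pair[1] == pair[2]) {
    abort("Within-segment identification is degenerate (zero self-distance); use two different segments.")
  }
  D <- unclass(idm)
  n <- nrow(D)
  if (n < 2 || n != ncol(D)) abort("Need a square matrix with n >= 2.")
  hit_dir <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      r <- M[i, ]
      m <- min(r)
      sum(r == m) == 1 && which.min(r) == i
    }, logical(1))
  }
  rate_rows <- mean(hit_dir(D))
  rate_cols <- mean(hit_dir(t(D)))
  100 * (rate_rows + rate_cols) / 2
}

#' Per-participant functional reconfiguration vector
#'
#' The main diagonal of a cross-segment identifiability matrix: each entry
#' is one participant's correlation distance between their own tangent
#' connectomes in the two segments — how much that individual's connectome
#' reconfigured across the transition.
#'
#' @param idm An [identifiability_matrix()] for two different segments.
#' @return A tibble with columns `subject_id`, `from`, `to`, `value`
#'   (class `reconfig_vector`).
#' @export
reconfiguration_vector <- function(idm) {
  D <- unclass(idm)
  if (nrow(D) != ncol(D)) abort("Identifiability matrix must be square.")
  pair <- attr(idm, "segment_pair") %||% c("A", "B")
  if (pair[1] == pair[2]) {
    abort("Reconfiguration is defined across two different segments.")
  }
  out <- tibble::tibble(
    subject_id = attr(idm, "subject_order") %||% as.character(seq_len(nrow(D))),
    from = pair[1],
    to = pair[2],
    value = unname(diag(D))
  )
  class(out) <- c("reconfig_vector", class(out))
  out
}

#' Paired comparison of two reconfiguration vectors
#'
#' Paired t test of per-participant reconfiguration between two transitions
#' (e.g. engaging vs disengaging), plus the Pearson correlation of the two
#' vectors. When the paired differences are exactly constant the t statistic
#' is degenerate: a zero constant reports `t = 0, p = 1`; a nonzero constant
#' reports `t = Inf` (sign of the mean difference) and `p = 0`.
#'
#' @param v1,v2 [reconfiguration_vector()] tibbles over the same subjects
#'   (n >= 3).
#' @return One-row tibble: `transition_1`, `transition_2`, `mean_diff`
#'   (mean of `v1 - v2`), `t`, `df`, `p_value`, `r`.
#' @export
compare_reconfigurations <- function(v1, v2) {
  if (!all(c("subject_id", "value") %in% names(v1)) ||
      !all(c("subject_id", "value") %in% names(v2))) {
    abort("Inputs must be reconfiguration vectors (subject_id, value).")
  }
  if (nrow(v1) != nrow(v2) || !all(v1$subject_id == v2$subject_id)) {
    abort("The two vectors must cover the same subjects in the same order.")
  }
  n <- nrow(v1)
  if (n < 3) abort("Need at least 3 paired observations.")
  d <- v1$value - v2$value
  lab <- function(v) if (all(c("from", "to") %in% names(v))) {
    paste(v$from[1], v$to[1], sep = "->")
  } else "?"
  r <- if (stats::sd(v1$value) > 0 && stats::sd(v2$value) > 0) {
    stats::cor(v1$value, v2$value)
  } else NA_real_
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    md <- mean(d)
    tt <- if (md == 0) 0 else sign(md) * Inf
    pv <- if (md == 0) 1 else 0
    return(tibble::tibble(transition_1 = lab(v1), transition_2 = lab(v2),
                          mean_diff = md, t = tt, df = n - 1, p_value = pv, r = r))
  }
  ht <- stats::t.test(v1$value, v2$value, paired = TRUE)
  tibble::tibble(
    transition_1 = lab(v1), transition_2 = lab(v2),
    mean_diff = unname(ht$estimate), t = unname(ht$statistic),
    df = unname(ht$parameter), p_value = ht$p.value, r = r
  )
}
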