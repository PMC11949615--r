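# End-to-end orchestration: segment -> FC -> regularize -> Karcher reference
# (rest segments only) -> tangent projection -> meta-identifiability ->
# reconfiguration vectors -> covariate models; plus the reference-choice
# comparison and file round-tripping.

TRANSITIONS_DEFAULT <- list(
  engaging = c("R1.2", "SST"),
  disengaging = c("SST", "R2.1"),
  within_rest = c("R2.1", "R2.2")
)

#' Run the full reconfiguration pipeline
#'
#' Executes every stage on a cohort: split scans into the five segments,
#' estimate Pearson connectomes, regularize, compute the Karcher-mean
#' reference from the chosen *resting-state* segment(s) (the task segment
#' is kept out of the reference so its intrinsic structure survives
#' projection), project all connectomes to the tangent space, build the
#' 5 x 5 meta-identifiability matrix and identification rates (tangent and
#' manifold), extract the engaging / disengaging / within-rest
#' reconfiguration vectors, and fit their covariate models.
#'
#' @param cohort A [generate_cohort()] result, or any list with elements
#'   `timeseries` (tibble: `subject_id`, `scan`, `data`) and `covariates`.
#' @param lambda Diagonal regularization value (default 0.001).
#' @param reference_segments Rest segment(s) used for the reference
#'   (`"R1.1"`, `"R2.2"`, or `c("R1.1", "R2.2")`; the task segment is
#'   rejected unless `allow_task_reference = TRUE`).
#' @param predictor_order Covariate order for the additive-R2 sequence.
#' @param scheme Segment scheme; derived from the data via
#'   [default_scheme()] when `NULL`.
#' @param transitions Named list of transitions to model.
#' @param allow_task_reference Permit SST in `reference_segments`.
#' @param out_dir Optional directory: when given, every intermediate
#'   artifact (FC and tangent TSVs, meta matrix, vectors, model JSONs, a
#'   machine-readable run log echoing the configuration) is written there.
#' @return A `reconfig_pipeline` list: `fc`, `tangent`, `reference`, `meta`,
#'   `id_rates`, `reconfig`, `models`, `comparisons`, `config`.
#' @export
run_pipeline <- function(cohort, lambda = 0.001, reference_segments = "R1.1",
                         predictor_order = PREDICTOR_ORDER_DEFAULT,
                         scheme = NULL, transitions = TRANSITIONS_DEFAULT,
                         allow_task_reference = FALSE, out_dir = NULL) {
  if (!all(c("timeseries", "covariates") %in% names(cohort))) {
    abort("`cohort` needs elements `timeseries` and `covariates`.")
  }
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  bad_ref <- setdiff(reference_segments, SEGMENT_LABELS)
  if (length(bad_ref) > 0) {
    abort(sprintf("Unknown reference segment(s): %s.", paste(bad_ref, collapse = ", ")))
  }
  if (!allow_task_reference && "SST" %in% reference_segments) {
    abort("The task segment is excluded from the reference by default (set `allow_task_reference = TRUE` to override).")
  }
  ts_tbl <- cohort$timeseries
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }
  scheme <- scheme %||% stage("scheme", {
    tr <- cohort$config$tr_seconds %||% 1.2
    n1 <- nrow(ts_tbl$data[[which(ts_tbl$scan == "scan1")[1]]])
    n2 <- nrow(ts_tbl$data[[which(ts_tbl$scan == "scan2")[1]]])
    default_scheme(tr, n1, n2)
  })
  fc_tbl <- stage("fc", cohort_fc(ts_tbl, scheme))
  reg_tbl <- stage("regularize", {
    out <- fc_tbl
    out$fc <- purrr::map(fc_tbl$fc, regularize, lambda = lambda)
    out
  })
  C_ref <- stage("reference",
                 riemann_mean(reference_fc_list(reg_tbl, reference_segments)))
  tangent_tbl <- stage("project", project_cohort(reg_tbl, C_ref))
  meta <- stage("meta_identifiability", meta_identifiability(tangent_tbl))
  id_rates <- stage("identification", {
    rates_t <- id_rate_table(meta)
    manifold_tbl <- reg_tbl
    names(manifold_tbl)[names(manifold_tbl) == "fc"] <- "tfc"
    rates_m <- id_rate_table(meta_identifiability(manifold_tbl))
    dplyr::left_join(
      dplyr::rename(rates_t, tangent_rate = "rate"),
      dplyr::rename(rates_m, manifold_rate = "rate"),
      by = c("from", "to")
    )
  })
  reconfig <- stage("reconfiguration", {
    purrr::map(transitions, function(tr) {
      reconfiguration_vector(meta_block(meta, tr[1], tr[2]))
    })
  })
  covs <- cohort$covariates
  covs <- covs[match(attr(meta, "subject_order"), covs$subject_id), ]
  models <- stage("models", {
    purrr::map(reconfig, fit_reconfig_model, X = covs,
               predictor_order = predictor_order)
  })
  comparisons <- stage("paired_tests", {
    nm <- names(reconfig)
    pairs <- utils::combn(seq_along(nm), 2, simplify = FALSE)
    dplyr::bind_rows(purrr::map(pairs, function(ij) {
      compare_reconfigurations(reconfig[[ij[1]]], reconfig[[ij[2]]])
    }))
  })
  result <- structure(list(
    fc = fc_tbl, tangent = tangent_tbl, reference = C_ref, meta = meta,
    id_rates = id_rates, reconfig = reconfig, models = models,
    comparisons = comparisons, scheme = scheme,
    config = list(lambda = lambda, reference_segments = reference_segments,
                  predictor_order = predictor_order,
                  seed = cohort$config$seed %||% NA,
                  package_version = as.character(utils::packageVersion("tangentfc")))
  ), class = "reconfig_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' Identification-rate table over all cross-segment blocks
#'
#' @param meta A [meta_identifiability()] object.
#' @return Tibble with `from`, `to`, `rate` (percent) for the 20
#'   cross-segment blocks.
#' @export
id_rate_table <- function(meta) {
  segs <- attr(meta, "segments")
  grid <- tidyr::expand_grid(from = segs, to = segs)
  grid <- grid[grid$from != grid$to, ]
  grid$rate <- purrr::map2_dbl(grid$from, grid$to, function(a, b) {
    identification_rate(meta_block(meta, a, b))
  })
  grid
}

#' Compare reconfiguration estimates across reference choices
#'
#' Re-runs regularization, reference computation and projection for each
#' reference choice, then correlates — per segment-pair block — the diagonal
#' (per-participant reconfiguration) and off-diagonal (between-participant
#' distance) elements of the identifiability matrices across every pair of
#' choices. High diagonal correlations mean reconfiguration estimates are
#' robust to which rest segment anchors the tangent space.
#'
#' Within-segment blocks have an identically zero diagonal, so their
#' diagonal correlation is reported as `NA`.
#'
#' @param fc_tbl Cohort FC table ([cohort_fc()] output, unregularized).
#' @param ref_choices Named list of reference segment sets, default
#'   `list("R1.1", "R2.2", c("R1.1", "R2.2"))`.
#' @param lambda Regularization value.
#' @return Tibble: `ref_a`, `ref_b`, `from`, `to`, `diag_r`, `offdiag_r`.
#' @export
compare_references <- function(fc_tbl,
                               ref_choices = list(
                                 `R1.1` = "R1.1", `R2.2` = "R2.2",
                                 `R1.1+R2.2` = c("R1.1", "R2.2")
                               ),
                               lambda = 0.001) {
  if (length(ref_choices) < 2) abort("Need at least two reference choices.")
  reg_tbl <- fc_tbl
  reg_tbl$fc <- purrr::map(fc_tbl$fc, regularize, lambda = lambda)
  metas <- purrr::map(ref_choices, function(refs) {
    C_ref <- riemann_mean(reference_fc_list(reg_tbl, refs))
    meta_identifiability(project_cohort(reg_tbl, C_ref))
  })
  segs <- SEGMENT_LABELS
  pairs <- utils::combn(names(ref_choices), 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, function(ab) {
    grid <- tidyr::expand_grid(from = segs, to = segs)
    grid$ref_a <- ab[1]
    grid$ref_b <- ab[2]
    vals <- purrr::map2(grid$from, grid$to, function(f, t) {
      Ma <- unclass(meta_block(metas[[ab[1]]], f, t))
      Mb <- unclass(meta_block(metas[[ab[2]]], f, t))
      off <- row(Ma) != col(Ma)
      c(
        diag_r = if (f == t) NA_real_ else stats::cor(diag(Ma), diag(Mb)),
        offdiag_r = stats::cor(Ma[off], Mb[off])
      )
    })
    grid$diag_r <- purrr::map_dbl(vals, "diag_r")
    grid$offdiag_r <- purrr::map_dbl(vals, "offdiag_r")
    grid[, c("ref_a", "ref_b", "from", "to", "diag_r", "offdiag_r")]
  }))
}

#' @export
print.reconfig_pipeline <- function(x, ...) {
  cat("Functional reconfiguration pipeline run\n")
  cat(sprintf("  subjects: %d, regions: %d\n",
              length(attr(x$meta, "subject_order")), nrow(x$reference)))
  cat(sprintf("  lambda = %g, reference = %s\n", x$config$lambda,
              paste(x$config$reference_segments, collapse = "+")))
  cat(sprintf("  mean cross-segment identification rate: tangent %.1f%%, manifold %.1f%%\n",
              mean(x$id_rates$tangent_rate), mean(x$id_rates$manifold_rate)))
  for (nm in names(x$reconfig)) {
    cat(sprintf("  %s (%s->%s): mean reconfiguration %.3f, model R^2 %.3f\n",
                nm, x$reconfig[[nm]]$from[1], x$reconfig[[nm]]$to[1],
                mean(x$reconfig[[nm]]$value),
                glance(x$models[[nm]])$r_squared))
  }
  invisible(x)
}

# ---- run-directory writing ------------------------------------------------

#' Write every pipeline artifact to a run directory
#'
#' Writes the meta-identifiability matrix, identification rates,
#' reconfiguration vectors, per-model JSON reports with TSV residuals, and
#' a machine-readable `run_log.json` echoing the configuration (seed,
#' package version, lambda, reference choice) so the run is reproducible
#' from the directory alone.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Directory to create/write into.
#' @return `out_dir` invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(as.matrix(result$meta),
                   file.path(out_dir, "meta_identifiability.tsv"))
  readr::write_tsv(result$id_rates, file.path(out_dir, "identification_rates.tsv"))
  for (nm in names(result$reconfig)) {
    readr::write_tsv(result$reconfig[[nm]],
                     file.path(out_dir, sprintf("reconfiguration_%s.tsv", nm)))
    fit <- result$models[[nm]]
    jsonlite::write_json(list(
      transition = fit$transition,
      coefficients = tidy(fit),
      r_squared = glance(fit)$r_squared,
      additive_r2 = as.list(fit$additive_r2)
    ), file.path(out_dir, sprintf("model_%s.json", nm)),
    auto_unbox = TRUE, digits = NA)
    readr::write_tsv(
      tibble::tibble(subject_id = result$reconfig[[nm]]$subject_id,
                     residual = unname(residuals(fit))),
      file.path(out_dir, sprintf("residuals_%s.tsv", nm)))
  }
  write_matrix_tsv(result$reference, file.path(out_dir, "reference.tsv"))
  jsonlite::write_json(result$config, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# ---- cohort file round-tripping -------------------------------------------

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes one TSV per subject x scan
#' (`<subject>_<scan>.tsv`), a covariate CSV, a YAML manifest (subjects,
#' files, TR, scheme) and, for synthetic cohorts, a ground-truth JSON.
#' `read_cohort()` reloads the manifest into the structure
#' [run_pipeline()] accepts.
#'
#' @param cohort A [generate_cohort()]-style list.
#' @param dir Directory to write/read.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- cohort$timeseries
  files <- character(nrow(ts))
  for (i in seq_len(nrow(ts))) {
    files[i] <- sprintf("%s_%s.tsv", ts$subject_id[i], ts$scan[i])
    write_matrix_tsv(ts$data[[i]], file.path(dir, files[i]))
  }
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  manifest <- list(
    tr_seconds = cohort$config$tr_seconds %||% attr(cohort$scheme, "tr_seconds"),
    subjects = unique(ts$subject_id),
    files = purrr::map2(ts$subject_id, ts$scan, function(s, sc) {
      list(subject = s, scan = sc, file = sprintf("%s_%s.tsv", s, sc))
    }),
    covariates = "covariates.csv",
    seed = cohort$config$seed %||% NULL
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(list(
      m_engaging = as.list(gt$m_engaging),
      m_disengaging = as.list(gt$m_disengaging),
      targets = gt$targets, betas = gt$betas
    ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  entries <- manifest$files
  ts <- tibble::tibble(
    subject_id = purrr::map_chr(entries, "subject"),
    scan = purrr::map_chr(entries, "scan"),
    data = purrr::map(entries, function(e) {
      read_matrix_tsv(file.path(dir, e$file))
    })
  )
  covs <- readr::read_csv(file.path(dir, manifest$covariates),
                          show_col_types = FALSE)
  list(timeseries = ts, covariates = covs,
       config = list(tr_seconds = manifest$tr_seconds,
                     seed = manifest$seed %||% NA))
}
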