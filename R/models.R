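# Covariate construction (recent-drinking principal component, SSRT) and
# the multilinear reconfiguration models with additive-R2 sequences,
# leave-one-out stability analyses and the regularization sweep.

PREDICTOR_ORDER_DEFAULT <- c("sex", "age", "education", "ssrt", "cesd",
                             "drinking_score", "fha")

#' Recent-drinking score: first principal component of four drinking measures
#'
#' AUDIT score, drinking days, drinks per week and drinks per drinking day
#' are standardized (zero mean, unit variance) and the first principal
#' component is extracted. The component sign is fixed so the AUDIT loading
#' is positive — higher score always means heavier recent drinking.
#'
#' @param audit,drinking_days,drinks_per_week,drinks_per_drinking_day Equal-
#'   length numeric vectors (n >= 3), none constant.
#' @return A list: `scores` (standardized PC1 scores), `variance_explained`
#'   (leading eigenvalue / 4), `loadings` (named length-4 vector).
#' @export
drinking_score <- function(audit, drinking_days, drinks_per_week,
                           drinks_per_drinking_day) {
  X <- cbind(audit = audit, drinking_days = drinking_days,
             drinks_per_week = drinks_per_week,
             drinks_per_drinking_day = drinks_per_drinking_day)
  if (nrow(X) < 3) abort("Need at least 3 participants.")
  if (!all(is.finite(X))) abort("Drinking measures contain non-finite values.")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant drinking measure(s): %s.",
                  paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1["audit"] < 0) load1 <- -load1
  scores <- drop(Z %*% load1)
  list(
    scores = scores,
    variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    loadings = load1
  )
}

#' Stop signal reaction time (integration method)
#'
#' SSRT = the participant's xth-percentile Go reaction time minus their mean
#' stop signal delay, where x is the stop failure rate. The percentile uses
#' linear interpolation (`stats::quantile` type 7); pass `type` to swap.
#'
#' @param go_rts Go-trial reaction times (ms).
#' @param ssds Stop signal delays (ms).
#' @param stop_failure_rate Fraction of stop trials with a response, in
#'   (0, 1).
#' @param type Quantile type forwarded to [stats::quantile()].
#' @return SSRT in ms.
#' @examples
#' ssrt(c(300, 350, 400, 450, 500), ssds = 200, stop_failure_rate = 0.5)  # 200
#' @export
ssrt <- function(go_rts, ssds, stop_failure_rate, type = 7) {
  if (length(go_rts) == 0 || length(ssds) == 0) abort("Empty input.")
  if (!is.numeric(stop_failure_rate) || stop_failure_rate <= 0 ||
      stop_failure_rate >= 1) {
    abort("`stop_failure_rate` must be strictly between 0 and 1.")
  }
  unname(stats::quantile(go_rts, probs = stop_failure_rate, type = type)) -
    mean(ssds)
}

# ---- multilinear reconfiguration model ------------------------------------

covariate_design <- function(X, predictor_order) {
  if (!is.data.frame(X)) abort("`X` must be a data frame of covariates.")
  missing <- setdiff(predictor_order, names(X))
  if (length(missing) > 0) {
    abort(sprintf("Covariate table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  Xm <- as.data.frame(X)[, predictor_order, drop = FALSE]
  if (any(!vapply(Xm, is.numeric, logical(1)))) {
    abort("All modeled covariates must be numeric.")
  }
  if (anyNA(Xm)) abort("Missing values in modeled covariates.")
  Xm
}

#' Multilinear regression of functional reconfiguration on risk covariates
#'
#' Ordinary least squares with intercept of a per-participant
#' reconfiguration vector on raw (unstandardized) covariates. Besides the
#' final model, the additive-R2 sequence is reported: the R2 of the nested
#' models containing the first k predictors of `predictor_order`, for k =
#' 1..K. Only that sequence depends on the order; final-model coefficients
#' do not.
#'
#' @param y A [reconfiguration_vector()] tibble, or a plain numeric vector.
#' @param X Covariate table (one row per participant, same order as `y`).
#' @param predictor_order Character vector of covariate column names, in the
#'   order predictors enter the additive sequence. Default: sex, age,
#'   education, ssrt, cesd, drinking_score, fha.
#' @param standardize Standardize predictors (and keep y raw) before
#'   fitting? Default `FALSE`: coefficients stay in natural units.
#' @return A `reconfig_model` object (wrapping the [stats::lm] fit) with
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @export
fit_reconfig_model <- function(y, X, predictor_order = PREDICTOR_ORDER_DEFAULT,
                               standardize = FALSE) {
  yv <- if (is.data.frame(y)) y$value else y
  if (!is.numeric(yv)) abort("`y` must be numeric or a reconfiguration vector.")
  Xm <- covariate_design(X, predictor_order)
  n <- length(yv)
  if (n != nrow(Xm)) abort("`y` and `X` must cover the same participants.")
  if (n <= length(predictor_order) + 1) {
    abort(sprintf("Need n > %d participants for %d predictors.",
                  length(predictor_order) + 1, length(predictor_order)))
  }
  if (standardize) Xm[] <- lapply(Xm, function(v) as.numeric(scale(v)))
  qrX <- qr(cbind(1, as.matrix(Xm)))
  if (qrX$rank < ncol(Xm) + 1) {
    dropped <- c("(Intercept)", predictor_order)[-seq_len(qrX$rank)]
    abort(sprintf("Rank-deficient design; collinear column(s) near: %s.",
                  paste(setdiff(dropped, "(Intercept)"), collapse = ", ")))
  }
  dat <- cbind(.y = yv, Xm)
  fit <- stats::lm(.y ~ ., data = dat)
  additive_r2 <- vapply(seq_along(predictor_order), function(k) {
    fk <- stats::lm(.y ~ ., data = cbind(.y = yv, Xm[, seq_len(k), drop = FALSE]))
    summary(fk)$r.squared
  }, numeric(1))
  transition <- if (is.data.frame(y) && all(c("from", "to") %in% names(y))) {
    paste(y$from[1], y$to[1], sep = "->")
  } else NA_character_
  structure(
    list(fit = fit, predictor_order = predictor_order,
         additive_r2 = setNames(additive_r2, predictor_order),
         standardize = standardize, transition = transition),
    class = "reconfig_model"
  )
}

#' @export
print.reconfig_model <- function(x, ...) {
  cat("Functional reconfiguration model",
      if (!is.na(x$transition)) sprintf("(%s)", x$transition), "\n")
  print(tidy(x))
  cat(sprintf("R^2 = %.3f; additive R^2: %s\n",
              summary(x$fit)$r.squared,
              paste(sprintf("%s %.3f", names(x$additive_r2), x$additive_r2),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a reconfiguration model
#'
#' @param x A `reconfig_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy reconfig_model
#' @export
tidy.reconfig_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' Glance at a reconfiguration model
#'
#' @param x A `reconfig_model`.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `sigma`, `df`,
#'   `n`, `transition`.
#' @method glance reconfig_model
#' @export
glance.reconfig_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df = sm$df[2],
    n = length(sm$residuals),
    transition = x$transition
  )
}

#' @export
residuals.reconfig_model <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.reconfig_model <- function(object, ...) stats::fitted(object$fit)

#' @export
coef.reconfig_model <- function(object, ...) stats::coef(object$fit)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- leave-one-out stability ----------------------------------------------

#' Leave-one-out stability of model coefficients
#'
#' Refits the reconfiguration model n times, excluding one participant per
#' fold, and returns the full per-fold coefficient distributions. Spread in
#' these distributions quantifies how much each coefficient depends on any
#' single participant.
#'
#' @inheritParams fit_reconfig_model
#' @return A `loo_distribution` tibble: `fold` (held-out subject), `term`,
#'   `estimate`, with attribute `mode = "model_loo"`.
#' @export
loo_model_stability <- function(y, X, predictor_order = PREDICTOR_ORDER_DEFAULT,
                                standardize = FALSE) {
  yv <- if (is.data.frame(y)) y$value else y
  ids <- if (is.data.frame(y) && "subject_id" %in% names(y)) {
    y$subject_id
  } else as.character(seq_along(yv))
  n <- length(yv)
  out <- purrr::map(seq_len(n), function(i) {
    fit <- fit_reconfig_model(yv[-i], X[-i, , drop = FALSE],
                              predictor_order, standardize)
    tibble::tibble(fold = ids[i],
                   term = names(coef(fit)),
                   estimate = unname(coef(fit)))
  })
  res <- dplyr::bind_rows(out)
  structure(res, mode = "model_loo",
            class = c("loo_distribution", class(res)))
}

#' Leave-one-out stability of the tangent-space reference
#'
#' Quantifies how the choice of participants entering the Karcher-mean
#' reference affects the final model. For each held-out participant the
#' reference is recomputed from the remaining n - 1 reference-segment
#' connectomes, *all* n participants are re-projected at that reference, the
#' transition's reconfiguration vector is recomputed, and the full-n model
#' refit. Unlike [loo_model_stability()], every fold's model uses all n
#' participants — only the reference changes.
#'
#' @param fc_tbl Cohort FC table from [cohort_fc()] (columns `subject_id`,
#'   `segment`, `fc`), *before* regularization.
#' @param X Covariate table (rows in `sort(unique(subject_id))` order).
#' @param transition Length-2 character: (from, to), e.g. `c("R1.2", "SST")`.
#' @param predictor_order Passed to [fit_reconfig_model()].
#' @param lambda Diagonal regularization applied to every FC.
#' @param reference_segment Segment(s) whose FCs build the reference
#'   (default `"R1.1"`).
#' @return A `loo_distribution` tibble (`mode = "reference_loo"`) with an
#'   additional attribute `reference_shift`: per fold, the geodesic distance
#'   between the full-sample and leave-one-out references.
#' @export
loo_reference_stability <- function(fc_tbl, X, transition = c("R1.2", "SST"),
                                    predictor_order = PREDICTOR_ORDER_DEFAULT,
                                    lambda = 0.001,
                                    reference_segment = "R1.1") {
  reg_tbl <- fc_tbl
  reg_tbl$fc <- purrr::map(fc_tbl$fc, regularize, lambda = lambda)
  subj <- sort(unique(reg_tbl$subject_id))
  ref_fcs <- reference_fc_list(reg_tbl, reference_segment)
  full_ref <- riemann_mean(ref_fcs)

  folds <- purrr::map(seq_along(subj), function(i) {
    keep <- setdiff(seq_along(subj), i)
    idx <- unlist(lapply(seq_along(reference_segment) - 1,
                         function(b) b * length(subj) + keep))
    loo_ref <- riemann_mean(ref_fcs[idx])
    tangent_tbl <- project_cohort(reg_tbl, loo_ref)
    rv <- transition_vector(tangent_tbl, transition)
    fit <- fit_reconfig_model(rv, X, predictor_order)
    list(
      coefs = tibble::tibble(fold = subj[i], term = names(coef(fit)),
                             estimate = unname(coef(fit))),
      shift = geodesic_distance(full_ref, loo_ref)
    )
  })
  res <- dplyr::bind_rows(purrr::map(folds, "coefs"))
  structure(res, mode = "reference_loo",
            reference_shift = setNames(purrr::map_dbl(folds, "shift"), subj),
            class = c("loo_distribution", class(res)))
}

# FCs used for the reference, ordered segment-major then subject order
reference_fc_list <- function(reg_tbl, reference_segment) {
  subj <- sort(unique(reg_tbl$subject_id))
  out <- list()
  for (s in reference_segment) {
    rows <- reg_tbl[reg_tbl$segment == s, ]
    rows <- rows[match(subj, rows$subject_id), ]
    if (any(is.na(rows$subject_id))) {
      abort(sprintf("Reference segment %s missing for some subjects.", s))
    }
    out <- c(out, rows$fc)
  }
  out
}

project_cohort <- function(reg_tbl, C_ref) {
  rid <- reference_fingerprint(C_ref)
  out <- reg_tbl
  out$tfc <- purrr::map(reg_tbl$fc, tangent_project, C_ref = C_ref,
                        reference_id = rid)
  out$fc <- NULL
  out
}

transition_vector <- function(tangent_tbl, transition) {
  subj <- sort(unique(tangent_tbl$subject_id))
  pick <- function(s) {
    rows <- tangent_tbl[tangent_tbl$segment == s, ]
    rows <- rows[match(subj, rows$subject_id), ]
    setNames(rows$tfc, subj)
  }
  idm <- identifiability_matrix(pick(transition[1]), pick(transition[2]),
                                segment_pair = transition, subject_order = subj)
  reconfiguration_vector(idm)
}

# ---- regularization sweep -------------------------------------------------

LAMBDA_GRID_DEFAULT <- c(1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.1, 1, 2, 4, 6, 8, 10)

#' Sweep the diagonal-regularization value through the full pipeline
#'
#' For every `lambda`, all FCs are re-regularized, the Karcher reference and
#' tangent projections recomputed, each requested transition's
#' reconfiguration vector rebuilt and its model refit. Alongside model R2,
#' coefficients and p-values, the pooled variance of all vectorized
#' tangent-connectome elements is recorded: growing `lambda` shrinks the
#' range and variance of tangent couplings, which is what eventually starves
#' the regression models of signal.
#'
#' @inheritParams loo_reference_stability
#' @param transitions Named list of length-2 character transitions, e.g.
#'   `list(engaging = c("R1.2", "SST"))`.
#' @param lambdas Strictly increasing positive regularization values
#'   (default: the 12-point grid 1e-4 ... 10).
#' @return A `sweep_result` tibble: one row per (lambda, transition, term)
#'   with `r_squared`, `estimate`, `p_value`, `tangent_variance`.
#' @export
regularization_sweep <- function(fc_tbl, X,
                                 transitions = list(
                                   engaging = c("R1.2", "SST"),
                                   disengaging = c("SST", "R2.1")
                                 ),
                                 lambdas = LAMBDA_GRID_DEFAULT,
                                 predictor_order = PREDICTOR_ORDER_DEFAULT,
                                 reference_segment = "R1.1") {
  if (any(lambdas <= 0) || is.unsorted(lambdas, strictly = TRUE)) {
    abort("`lambdas` must be positive and strictly increasing.")
  }
  rows <- purrr::map(lambdas, function(lam) {
    reg_tbl <- fc_tbl
    reg_tbl$fc <- purrr::map(fc_tbl$fc, regularize, lambda = lam)
    C_ref <- riemann_mean(reference_fc_list(reg_tbl, reference_segment))
    tangent_tbl <- project_cohort(reg_tbl, C_ref)
    pooled <- unlist(purrr::map(tangent_tbl$tfc, vectorize_sym))
    tv <- stats::var(pooled)
    dplyr::bind_rows(purrr::imap(transitions, function(tr, nm) {
      rv <- transition_vector(tangent_tbl, tr)
      fit <- fit_reconfig_model(rv, X, predictor_order)
      td <- tidy(fit)
      tibble::tibble(
        lambda = lam, transition = nm,
        r_squared = glance(fit)$r_squared,
        term = td$term, estimate = td$estimate, p_value = td$p_value,
        tangent_variance = tv
      )
    }))
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("sweep_result", class(res))
  res
}
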