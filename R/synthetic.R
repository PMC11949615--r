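# Seeded synthetic cohorts: multi-segment BOLD time series plus covariates
# with the statistical structure the analysis pipeline assumes — a stable
# per-subject connectome fingerprint, a task-induced connectivity shift
# whose magnitude is driven by covariates, a scan-2 offset, and observation
# noise. The generator emulates a two-scan rest / task / rest design; it is
# a test harness for the method, not a biophysical BOLD model.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the target study design: 54 participants, TR 1.2 s,
#' scan 1 = 400 volumes (8 min rest), scan 2 = 610 volumes (4-min task,
#' 12-s transition, 8-min rest), with covariate distributions calibrated to
#' the published participant characteristics.
#'
#' The generative model, per subject s with latent SPD base `B_s`:
#' rest segments of scan 1 sample from `B_s`; the task segment shifts `B_s`
#' along a common task direction by an engaging magnitude
#' `m_eng = task_effect * exp(-beta_drink_engage z(drink) + beta_cesd z(cesd)
#' - beta_sex (sex - mean))`; scan-2 rest returns toward base by a
#' disengaging magnitude
#' `m_dis = disengage_fraction * task_effect * exp(-beta_fha_disengage (fha -
#' mean) + beta_edu z(edu) + beta_cesd z(cesd))`; all scan-2 segments add a
#' common scan offset of size `scan_effect`. With the default
#' `disengage_fraction = 1` the cohort returns, on average, all the way to
#' its resting base after the task, so within-rest transitions carry only
#' the small covariate-driven mismatch plus sampling noise — the regime in
#' which within-rest reconfiguration is much smaller than task
#' transitions. Time series are multivariate
#' normal with covariance `segment latent + noise_sd^2 I`.
#'
#' @param n_subjects Cohort size (default 54).
#' @param n_regions Parcellation size (default 50; larger values such as 332
#'   are supported but slow).
#' @param tr_seconds Repetition time (default 1.2).
#' All displacement strengths are expressed as the per-element (per
#' functional coupling) root-mean-square size of the whitened tangent
#' displacement they induce, the same scale on which finite-scan sampling
#' noise lives (about `1/sqrt(T)`, i.e. ~0.07 per element at 4-min
#' segments), so defaults of that order yield the realistic regime where
#' within-subject cross-segment tangent correlation distances sit near 0.5
#' and between-subject distances near 1.
#'
#' @param fingerprint_strength Per-element RMS size of the subject-specific
#'   component of `B_s` (default 0.09).
#' @param task_effect Baseline engaging displacement (default 0.07).
#' @param scan_effect Size of the common scan-2 offset (default 0.05).
#' @param noise_sd Observation noise standard deviation added to each
#'   region's signal (latent signals have unit variance; default 0.8).
#' @param disengage_fraction Mean fraction of the task displacement undone
#'   when returning to rest (default 1: full return on average).
#' @param beta_drink_engage,beta_sex,beta_cesd Generating covariate effects
#'   on the engaging magnitude exponent (drinking and male sex reduce it,
#'   CES-D raises it). By default only the drinking effect is nonzero
#'   (0.65): the two headline associations — drinking with engaging, family
#'   history with disengaging — are the generator's default truth, with
#'   secondary channels available as knobs. A covariate entering both
#'   exponents (e.g. CES-D) can have a non-monotone observed effect, since
#'   the correlation-distance geometry couples the two transitions; see the
#'   methods vignette.
#' @param beta_fha_disengage,beta_edu Generating effects on the disengaging
#'   exponent (FHA-positive reduces it, education raises it; CES-D also
#'   enters with `beta_cesd`). Default: only the FHA effect nonzero (0.6).
#' @param seed Mandatory integer seed; every draw is a deterministic
#'   function of `(config, seed)`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 54, n_regions = 50, tr_seconds = 1.2,
                         fingerprint_strength = 0.09, task_effect = 0.07,
                         scan_effect = 0.05, noise_sd = 0.8,
                         disengage_fraction = 1,
                         beta_drink_engage = 0.65, beta_sex = 0,
                         beta_cesd = 0, beta_fha_disengage = 0.6,
                         beta_edu = 0, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory: synthetic cohorts must be reproducible.")
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    tr_seconds = tr_seconds,
    scan1_volumes = 2L * round(240 / tr_seconds),
    scan2_volumes = 3L * round(240 / tr_seconds) + round(12 / tr_seconds),
    fingerprint_strength = fingerprint_strength, task_effect = task_effect,
    scan_effect = scan_effect, noise_sd = noise_sd,
    disengage_fraction = disengage_fraction,
    beta_drink_engage = beta_drink_engage, beta_sex = beta_sex,
    beta_cesd = beta_cesd, beta_fha_disengage = beta_fha_disengage,
    beta_edu = beta_edu, seed = as.integer(seed)
  )
  weights <- c("fingerprint_strength", "task_effect", "scan_effect",
               "noise_sd", "disengage_fraction", "beta_drink_engage",
               "beta_sex", "beta_cesd", "beta_fha_disengage", "beta_edu")
  for (w in weights) {
    if (!is.numeric(cfg[[w]]) || cfg[[w]] < 0) {
      abort(sprintf("`%s` must be a nonnegative number.", w))
    }
  }
  if (cfg$n_subjects < 4) abort("Need at least 4 subjects.")
  if (cfg$n_regions < 2) abort("Need at least 2 regions.")
  structure(cfg, class = "synth_config")
}

subject_ids <- function(n) sprintf(paste0("S%0", max(2, nchar(n)), "d"), seq_len(n))

# Covariate draws calibrated to the published cohort table. Assumes the RNG
# state is already set by the caller.
draw_covariates <- function(config) {
  n <- config$n_subjects
  n_pos <- round(n * 23 / 54)
  fha <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  # male counts: 9/23 within FHA-positive, 25/54 overall
  n_male <- round(n * 25 / 54)
  n_male_pos <- min(round(n_pos * 9 / 23), n_male)
  sex <- integer(n)
  sex[seq_len(n_pos)][seq_len(n_male_pos)] <- 1L
  neg_idx <- which(fha == 0)
  sex[neg_idx[seq_len(min(n_male - n_male_pos, length(neg_idx)))]] <- 1L

  # the four drinking measures index one behaviour: give them a shared
  # latent propensity (loading 0.75, intercorrelations ~0.56) so their
  # first principal component is meaningful, as in questionnaire data
  drink_load <- 0.75
  propensity <- stats::rnorm(n)
  drink_group <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
    e <- drink_load * propensity +
      sqrt(1 - drink_load^2) * stats::rnorm(n)
    mu <- ifelse(fha == 1, mean_pos, mean_neg)
    sg <- ifelse(fha == 1, sd_pos, sd_neg)
    pmax(mu + sg * e, 0)
  }

  age <- pmin(pmax(stats::rnorm(n, 22.64, 1.62), 21), 26)
  education <- stats::rnorm(n, 15.25, 1.20)
  ssrt_ms <- stats::rnorm(n, 238, 51)
  cesd <- pmax(stats::rnorm(n, 5.96, 5.09), 0)
  audit <- drink_group(10.26, 6.52, 7.26, 3.92)
  drinking_days <- drink_group(16.17, 8.02, 10.54, 5.60)
  drinks_per_week <- drink_group(12.27, 11.45, 7.11, 4.91)
  drinks_per_drinking_day <- drink_group(3.66, 1.92, 3.67, 2.39)

  ds <- drinking_score(audit, drinking_days, drinks_per_week,
                       drinks_per_drinking_day)
  tibble::tibble(
    subject_id = subject_ids(n),
    sex = sex, age = age, education = education, ssrt = ssrt_ms,
    cesd = cesd, audit = audit, drinking_days = drinking_days,
    drinks_per_week = drinks_per_week,
    drinks_per_drinking_day = drinks_per_drinking_day,
    drinking_score = ds$scores, fha = fha
  )
}

#' Generate a covariate table calibrated to the published cohort
#'
#' Draws participant covariates whose latent distributions match the
#' published participant-characteristics table: age ~ N(22.64, 1.62^2)
#' clipped to [21, 26], education ~ N(15.25, 1.20^2), SSRT ~ N(238, 51^2),
#' CES-D ~ N(5.96, 5.09^2) floored at 0, and the four drinking measures
#' drawn per family-history group (e.g. drinking days 16.17 vs 10.54).
#' `round(n * 23/54)` subjects are FHA positive and `round(n * 25/54)`
#' male. The recent-drinking score column is the first principal component
#' of the four drinking measures ([drinking_score()]).
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A covariate tibble, one row per participant.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  set.seed(seed)
  draw_covariates(config)
}

# random symmetric direction with unit per-element RMS, so that strength
# parameters read as the typical per-coupling displacement they induce
random_sym_direction <- function(p) {
  A <- matrix(stats::rnorm(p * p), p, p)
  S <- symmetrize(A)
  S / sqrt(mean(S^2))
}

# random correlation-like SPD base: low-rank shared structure + diagonal
random_correlation_base <- function(p, k) {
  A <- matrix(stats::rnorm(p * k), p, k) / sqrt(k)
  G <- tcrossprod(A) + diag(0.5, p)
  stats::cov2cor(G)
}

#' Generate a full synthetic cohort
#'
#' Produces per-subject, per-scan BOLD-like time series plus covariates and
#' the generating ground truth. See [synth_config()] for the generative
#' model. Ground truth includes noise-free per-subject reconfiguration
#' targets: the correlation distances between the population tangent
#' connectomes (derived from the latent segment covariances plus the
#' noise floor, projected at the Karcher mean of the latent reference
#' segment), i.e. the values the pipeline would recover with infinitely
#' long scans.
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @param draw_timeseries Set `FALSE` to skip sampling the BOLD time series
#'   (covariates, latent structure and ground truth only) — useful when the
#'   observations will be drawn later with [mc_reconfig_refits()].
#' @return A list with elements `timeseries` (tibble: `subject_id`, `scan`,
#'   `data`; `NULL` when `draw_timeseries = FALSE`), `covariates`,
#'   `ground_truth`, `scheme`, `config`.
#' @export
generate_cohort <- function(config, seed = config$seed, draw_timeseries = TRUE) {
  set.seed(seed)
  n <- config$n_subjects
  p <- config$n_regions
  covs <- draw_covariates(config)

  k <- max(3L, round(p / 5))
  G <- random_correlation_base(p, k)
  G_half <- spd_sqrt(G)
  task_dir <- random_sym_direction(p)
  scan_dir <- random_sym_direction(p)

  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  eta_eng <- -config$beta_drink_engage * z(covs$drinking_score) +
    config$beta_cesd * z(covs$cesd) -
    config$beta_sex * (covs$sex - mean(covs$sex))
  eta_dis <- -config$beta_fha_disengage * (covs$fha - mean(covs$fha)) +
    config$beta_edu * z(covs$education) +
    config$beta_cesd * z(covs$cesd)
  m_eng <- config$task_effect * exp(eta_eng)
  m_dis <- config$disengage_fraction * config$task_effect * exp(eta_dis)

  bases <- purrr::map(seq_len(n), function(i) {
    Fi <- random_sym_direction(p)
    symmetrize(G_half %*% sym_exp(config$fingerprint_strength * Fi) %*% G_half)
  })

  # latent segment covariances, whitened-tangent displacements at B_s
  latent_sigma <- function(i, segment) {
    B <- bases[[i]]
    T_disp <- switch(segment,
      "R1.1" = , "R1.2" = matrix(0, p, p),
      "SST" = m_eng[i] * task_dir + config$scan_effect * scan_dir,
      "R2.1" = , "R2.2" = (m_eng[i] - m_dis[i]) * task_dir +
        config$scan_effect * scan_dir
    )
    if (all(T_disp == 0)) return(B)
    H <- spd_sqrt(B)
    symmetrize(H %*% sym_exp(T_disp) %*% H)
  }

  scheme <- default_scheme(config$tr_seconds, config$scan1_volumes,
                           config$scan2_volumes)
  seg_per_scan <- list(
    scan1 = c("R1.1", "R1.2"),
    scan2 = c("SST", "R2.1", "R2.2")
  )
  noise_var <- config$noise_sd^2

  draw_scan <- function(i, scan) {
    total <- if (scan == "scan1") config$scan1_volumes else config$scan2_volumes
    ts <- matrix(0, total, p)
    segs <- seg_per_scan[[scan]]
    chol_by_seg <- lapply(segs, function(s) {
      chol(latent_sigma(i, s) + diag(noise_var, p))
    })
    names(chol_by_seg) <- segs
    sch <- scheme[scheme$scan == scan, ]
    # analysis intervals
    for (r in seq_len(nrow(sch))) {
      len <- sch$end[r] - sch$start[r]
      ts[(sch$start[r] + 1):sch$end[r], ] <-
        matrix(stats::rnorm(len * p), len, p) %*% chol_by_seg[[sch$label[r]]]
    }
    # discarded intervals (calibration / transition) filled from the
    # adjacent segment's distribution so files have the full printed length
    disc <- attr(scheme, "discarded")
    disc <- disc[disc$scan == scan, ]
    for (r in seq_len(nrow(disc))) {
      len <- disc$end[r] - disc$start[r]
      adj <- if (disc$label[r] == "transition") "SST" else segs[1]
      ts[(disc$start[r] + 1):disc$end[r], ] <-
        matrix(stats::rnorm(len * p), len, p) %*% chol_by_seg[[adj]]
    }
    colnames(ts) <- sprintf("region%03d", seq_len(p))
    ts
  }

  ids <- covs$subject_id
  ts_tbl <- NULL
  if (draw_timeseries) {
    ts_tbl <- tidyr::expand_grid(subject_id = ids, scan = c("scan1", "scan2"))
    ts_tbl$data <- purrr::map2(match(ts_tbl$subject_id, ids), ts_tbl$scan,
                               draw_scan)
  }

  # ---- noise-free reconfiguration targets --------------------------------
  pop_fc <- function(i, seg) stats::cov2cor(latent_sigma(i, seg) + diag(noise_var, p))
  ref <- riemann_mean(purrr::map(seq_len(n), pop_fc, seg = "R1.1"))
  rid <- reference_fingerprint(ref)
  tproj <- function(i, seg) tangent_project(pop_fc(i, seg), ref, reference_id = rid)
  targets <- tibble::tibble(
    subject_id = ids,
    engaging = purrr::map_dbl(seq_len(n), function(i) {
      correlation_distance(vectorize_sym(tproj(i, "R1.2")),
                           vectorize_sym(tproj(i, "SST")))
    }),
    disengaging = purrr::map_dbl(seq_len(n), function(i) {
      correlation_distance(vectorize_sym(tproj(i, "SST")),
                           vectorize_sym(tproj(i, "R2.1")))
    })
  )

  ground_truth <- list(
    group_base = G, subject_bases = setNames(bases, ids),
    task_direction = task_dir, scan_direction = scan_dir,
    m_engaging = setNames(m_eng, ids), m_disengaging = setNames(m_dis, ids),
    targets = targets,
    latents = purrr::map(seq_len(n), function(i) {
      list(base = bases[[i]], sst = latent_sigma(i, "SST"),
           post = latent_sigma(i, "R2.1"))
    }) |> setNames(ids),
    betas = config[c("beta_drink_engage", "beta_sex", "beta_cesd",
                     "beta_fha_disengage", "beta_edu")]
  )
  list(timeseries = ts_tbl, covariates = covs, ground_truth = ground_truth,
       scheme = scheme, config = config)
}

#' Random SPD matrices with bounded condition number
#'
#' Unit-test fixture generator: eigenvalues are drawn log-uniformly in
#' `[1, condition_number_cap]` and rotated by a random orthogonal basis, so
#' every output is SPD with condition number at most the cap; deterministic
#' per seed.
#'
#' @param p Dimension.
#' @param n Number of matrices.
#' @param condition_number_cap Upper bound on the eigenvalue ratio.
#' @param seed Integer seed.
#' @return List of `n` SPD `p x p` matrices.
#' @export
generate_spd <- function(p, n, condition_number_cap = 100, seed = 1) {
  if (p < 1 || n < 1) abort("`p` and `n` must be >= 1.")
  if (condition_number_cap < 1) abort("`condition_number_cap` must be >= 1.")
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    lam <- exp(stats::runif(p, 0, log(condition_number_cap)))
    if (p == 1) return(matrix(lam, 1, 1))
    Q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    symmetrize(Q %*% (lam * t(Q)))
  })
}

#' Monte-Carlo refits under fresh observation noise
#'
#' Redraws the cohort's time series from the stored latent segment
#' covariances (identical subjects, covariates and latent structure; only
#' the finite-scan sampling noise changes), re-runs the measurement chain
#' (FC, regularization, Karcher reference on the first rest segment,
#' tangent projection, reconfiguration vectors) and refits the engaging and
#' disengaging covariate models on every draw. The mean of the per-draw
#' coefficients estimates the generating effect *on the observed scale* —
#' the estimand an analysis of one realization targets — and their spread
#' its Monte-Carlo uncertainty. Finite-scan distance estimates are
#' nonlinearly compressed relative to the latent geometry, so this observed-
#' scale estimand, not the latent-target coefficient, is the right truth
#' for calibration checks.
#'
#' @param cohort A [generate_cohort()] result (its `ground_truth$latents`
#'   are required).
#' @param n_draws Number of independent noise redraws.
#' @param seed Seed for the redraws.
#' @param lambda Regularization applied to each FC.
#' @param predictor_order Covariates of the refitted models.
#' @return A tibble with one row per (draw, transition, term):
#'   `draw`, `transition`, `term`, `estimate`.
#' @export
mc_reconfig_refits <- function(cohort, n_draws = 12, seed,
                               lambda = 0.001,
                               predictor_order = PREDICTOR_ORDER_DEFAULT) {
  if (missing(seed)) abort("`seed` is required.")
  lat <- cohort$ground_truth$latents
  if (is.null(lat)) abort("Cohort lacks ground-truth latents.")
  set.seed(seed)
  scheme <- cohort$scheme
  len <- setNames(scheme$end - scheme$start, scheme$label)
  p <- nrow(lat[[1]]$base)
  n <- length(lat)
  noise_var <- cohort$config$noise_sd^2
  ids <- names(lat)
  covs <- cohort$covariates[match(ids, cohort$covariates$subject_id), ]

  chol_by_subj <- purrr::map(lat, function(l) {
    list(base = chol(l$base + diag(noise_var, p)),
         sst = chol(l$sst + diag(noise_var, p)),
         post = chol(l$post + diag(noise_var, p)))
  })
  seg_chol <- c("R1.1" = "base", "R1.2" = "base", "SST" = "sst",
                "R2.1" = "post")

  dplyr::bind_rows(purrr::map(seq_len(n_draws), function(d) {
    fcs <- purrr::map(chol_by_subj, function(ch) {
      purrr::imap(seg_chol, function(which_chol, seg) {
        Tn <- len[[seg]]
        regularize(compute_fc(matrix(stats::rnorm(Tn * p), Tn, p) %*%
                                ch[[which_chol]]), lambda)
      })
    })
    C_ref <- riemann_mean(purrr::map(fcs, "R1.1"))
    rid <- reference_fingerprint(C_ref)
    tfc <- purrr::map(fcs, function(f) {
      purrr::map(f, tangent_project, C_ref = C_ref, reference_id = rid)
    })
    dist_tr <- function(a, b) {
      purrr::map_dbl(tfc, function(f) {
        correlation_distance(vectorize_sym(f[[a]]), vectorize_sym(f[[b]]))
      })
    }
    y <- list(engaging = dist_tr("R1.2", "SST"),
              disengaging = dist_tr("SST", "R2.1"))
    dplyr::bind_rows(purrr::imap(y, function(v, nm) {
      fit <- fit_reconfig_model(v, covs, predictor_order)
      td <- tidy(fit)
      tibble::tibble(draw = d, transition = nm, term = td$term,
                     estimate = td$estimate, std_error = td$std_error,
                     p_value = td$p_value,
                     df = glance(fit)$df)
    }))
  }))
}
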