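#' Configuration for the synthetic trauma-registry generator
#'
#' Defaults encode the study conditions of the emulated national trauma
#' cohort: 364,355 submitted records of which 22,051 are paediatric and
#' 21,101 have an incomplete GCS, leaving 321,203 complete adult records
#' whose sub-score marginals are reproduced exactly; 55.9% male; adult ages
#' drawn from a piecewise-linear quantile function through the published
#' quartiles (median 62.7, IQR 44.2-80.8); a discrete ISS distribution with
#' quartiles (9, 9, 17); 30-day mortality calibrated to 6.6% among observed
#' outcomes via a logistic model on the rescored GCS total; and 4.65% of
#' outcomes missing.
#'
#' `extreme3_count` and `extreme15_count` fix the all-minimum and all-maximum
#' response patterns so that the non-extreme complete sample is exactly
#' 48,417 records at full scale.
#'
#' @param n_paediatric,n_incomplete Counts of excluded record classes.
#' @param gcs_marginals Per-item category marginals of the complete adult
#'   sample (see [gcs_registry_marginals()]).
#' @param extreme3_count,extreme15_count Records pinned to GCS totals 3 / 15.
#' @param sex_male_prob Probability of `male`.
#' @param age_quantile_knots Data frame with columns `p` and `age`; the adult
#'   age quantile function is linear between knots.
#' @param iss_distribution Named numeric vector: ISS value -> probability.
#' @param region_probabilities Named numeric vector over body regions.
#' @param mortality_slope Log-odds change in 30-day mortality per rescored
#'   GCS point (negative: higher scores, lower mortality).
#' @param region_offsets Named additive log-odds offsets by region
#'   (unnamed regions default to 0).
#' @param target_mortality Mean 30-day mortality among complete adult
#'   records, used to calibrate the model intercept.
#' @param missing_outcome_rate Probability that the outcome is unrecorded.
#' @param scale Optional proportional shrink factor in (0, 1] applied to all
#'   counts (marginals re-rounded consistently); useful for small test runs.
#' @return A `registry_config` list.
#' @export
registry_config <- function(n_paediatric = 22051L,
                            n_incomplete = 21101L,
                            gcs_marginals = gcs_registry_marginals(),
                            extreme3_count = 8000L,
                            extreme15_count = 264786L,
                            sex_male_prob = 0.559,
                            age_quantile_knots = data.frame(
                              p = c(0, 0.25, 0.5, 0.75, 1),
                              age = c(18, 44.2, 62.7, 80.8, 100)
                            ),
                            iss_distribution = c(
                              "4" = 0.15, "9" = 0.40, "13" = 0.10, "17" = 0.15,
                              "22" = 0.10, "25" = 0.05, "29" = 0.03, "34" = 0.02
                            ),
                            region_probabilities = c(
                              Head = 0.25, Limbs = 0.30, Chest = 0.18,
                              Spine = 0.08, Abdomen = 0.05, Multiple = 0.08,
                              Other = 0.04, Face = 0.02
                            ),
                            mortality_slope = -0.45,
                            region_offsets = c(Head = 0.5),
                            target_mortality = 0.066,
                            missing_outcome_rate = 0.0465,
                            scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  stopifnot(abs(sum(iss_distribution) - 1) < 1e-8,
            abs(sum(region_probabilities) - 1) < 1e-8)
  if (scale < 1) {
    n_complete <- sum(gcs_marginals$eye)
    n_complete_s <- round(n_complete * scale)
    n_nonext_s <- round((n_complete - extreme3_count - extreme15_count) * scale)
    a_s <- round(extreme3_count * scale)
    b_s <- n_complete_s - a_s - n_nonext_s
    gcs_marginals <- lapply(gcs_marginals, function(m) {
      lr_round(m * scale, total = n_complete_s)
    })
    extreme3_count <- a_s
    extreme15_count <- b_s
    n_paediatric <- round(n_paediatric * scale)
    n_incomplete <- round(n_incomplete * scale)
  }
  offs <- stats::setNames(rep(0, length(gcs_regions)), gcs_regions)
  offs[names(region_offsets)] <- region_offsets
  cfg <- list(
    n_paediatric = as.integer(n_paediatric),
    n_incomplete = as.integer(n_incomplete),
    gcs_marginals = gcs_marginals,
    extreme3_count = as.integer(extreme3_count),
    extreme15_count = as.integer(extreme15_count),
    sex_male_prob = sex_male_prob,
    age_quantile_knots = age_quantile_knots,
    iss_distribution = iss_distribution,
    region_probabilities = region_probabilities[gcs_regions],
    mortality_slope = mortality_slope,
    region_offsets = offs,
    target_mortality = target_mortality,
    missing_outcome_rate = missing_outcome_rate,
    scale = scale
  )
  cfg$n_complete <- sum(cfg$gcs_marginals$eye)
  cfg$n_total <- cfg$n_complete + cfg$n_paediatric + cfg$n_incomplete
  structure(cfg, class = "registry_config")
}

#' Calibrate the mortality-model intercept
#'
#' Finds the intercept `b0` of the generator's logistic mortality model so
#' that the mean predicted probability over the supplied covariates equals
#' `target` to within `tol`, by bisection on `[-20, 20]`.
#'
#' @param linear_predictor Numeric vector: the per-record linear predictor
#'   *without* the intercept (slope term plus region offset).
#' @param target Target mean mortality probability.
#' @param tol Convergence tolerance on the mean probability.
#' @return The calibrated intercept (log-odds).
#' @export
calibrate_mortality_intercept <- function(linear_predictor, target,
                                          tol = 1e-6) {
  f <- function(b0) mean(stats::plogis(b0 + linear_predictor)) - target
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target mortality unreachable for intercepts in [-20, 20]",
         call. = FALSE)
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol * 1e-3) {
      lo <- mid
      hi <- mid
      break
    }
    if (fm < 0) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2
  if (abs(f(b0)) > tol) {
    stop("intercept calibration did not reach the requested tolerance",
         call. = FALSE)
  }
  b0
}

#' Generate a synthetic trauma registry
#'
#' Produces a full registry-mimic record set: exactly `n_paediatric`
#' under-18 records, exactly `n_incomplete` adult records with at least one
#' GCS sub-score blanked, and complete adult records realising the joint
#' Eye x Verbal x Motor table of [build_joint_gcs_table()] cell-by-cell
#' (exact allocation, not sampling), so that [apply_exclusions()] reproduces
#' the configured cohort counts exactly. Demographics, ISS, region and the
#' calibrated mortality model follow the configuration. Deterministic given
#' `seed`.
#'
#' @param config A [registry_config()].
#' @param seed Integer seed.
#' @return A registry tibble (same schema as [read_registry()]).
#' @export
generate_registry <- function(config = registry_config(), seed = 1L) {
  withr::with_seed(seed, generate_registry_impl(config, seed))
}

generate_registry_impl <- function(cfg, seed) {
  joint <- build_joint_gcs_table(cfg$gcs_marginals,
                                 cfg$extreme3_count, cfg$extreme15_count)
  dims <- dim(joint)
  cells <- which(array(TRUE, dims), arr.ind = TRUE)
  counts <- as.vector(joint)

  # -- complete adults: exact allocation of the joint table -----------------
  reps <- rep.int(seq_len(nrow(cells)), counts)
  evm <- cells[reps, , drop = FALSE]
  n_c <- nrow(evm)
  evm <- evm[sample.int(n_c), , drop = FALSE]
  complete <- make_records(
    n = n_c,
    eye = evm[, 1], verbal = evm[, 2], motor = evm[, 3],
    adult = TRUE, cfg = cfg
  )

  # -- mortality: calibrated logistic on the rescored GCS total -------------
  pm <- published_rescore_map()
  rt <- pm$eye[complete$eye] + pm$verbal[complete$verbal] +
    pm$motor[complete$motor]
  lp_rest <- cfg$mortality_slope * (rt - 8) +
    cfg$region_offsets[as.character(complete$region)]
  b0 <- calibrate_mortality_intercept(lp_rest, cfg$target_mortality)
  p_dead <- stats::plogis(b0 + lp_rest)
  complete$outcome30d <- ifelse(stats::runif(n_c) < p_dead, "dead", "alive")

  # -- paediatric and incomplete-GCS records --------------------------------
  cell_prob <- counts / sum(counts)
  draw_gcs <- function(n) {
    k <- sample.int(nrow(cells), n, replace = TRUE, prob = cell_prob)
    cells[k, , drop = FALSE]
  }
  ped_gcs <- draw_gcs(cfg$n_paediatric)
  ped <- make_records(cfg$n_paediatric, ped_gcs[, 1], ped_gcs[, 2],
                      ped_gcs[, 3], adult = FALSE, cfg = cfg)
  ped$outcome30d <- ifelse(
    stats::runif(cfg$n_paediatric) < cfg$target_mortality, "dead", "alive")

  inc_gcs <- draw_gcs(cfg$n_incomplete)
  inc <- make_records(cfg$n_incomplete, inc_gcs[, 1], inc_gcs[, 2],
                      inc_gcs[, 3], adult = TRUE, cfg = cfg)
  # blank a uniformly-chosen non-empty subset of the three sub-scores
  pattern <- sample.int(7L, cfg$n_incomplete, replace = TRUE)
  inc$eye[bitwAnd(pattern, 1L) > 0] <- NA_integer_
  inc$verbal[bitwAnd(pattern, 2L) > 0] <- NA_integer_
  inc$motor[bitwAnd(pattern, 4L) > 0] <- NA_integer_
  inc$outcome30d <- ifelse(
    stats::runif(cfg$n_incomplete) < cfg$target_mortality, "dead", "alive")

  rec <- dplyr::bind_rows(complete, ped, inc)
  rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
  rec$id <- sprintf("R%07d", seq_len(nrow(rec)))
  miss <- stats::runif(nrow(rec)) < cfg$missing_outcome_rate
  rec$outcome30d[miss] <- NA_character_
  rec$outcome30d <- factor(rec$outcome30d, levels = c("alive", "dead"))
  rec <- tibble::as_tibble(rec[, c("id", "age", "sex", "iss", "region",
                                   "eye", "verbal", "motor", "outcome30d")])
  attr(rec, "provenance") <- sprintf("synthetic registry (seed %d)", seed)
  rec
}

make_records <- function(n, eye, verbal, motor, adult, cfg) {
  if (n == 0) {
    return(tibble::tibble(
      id = character(0), age = numeric(0),
      sex = factor(character(0), levels = c("male", "female")),
      iss = integer(0), region = factor(character(0), levels = gcs_regions),
      eye = integer(0), verbal = integer(0), motor = integer(0),
      outcome30d = character(0)
    ))
  }
  age <- if (adult) {
    round(pl_quantile(stats::runif(n), cfg$age_quantile_knots$p,
                      cfg$age_quantile_knots$age), 1)
  } else {
    round(stats::runif(n, 0, 17.9), 1)
  }
  tibble::tibble(
    id = NA_character_,
    age = age,
    sex = factor(ifelse(stats::runif(n) < cfg$sex_male_prob, "male", "female"),
                 levels = c("male", "female")),
    iss = as.integer(sample(as.integer(names(cfg$iss_distribution)), n,
                            replace = TRUE, prob = cfg$iss_distribution)),
    region = factor(sample(names(cfg$region_probabilities), n, replace = TRUE,
                           prob = cfg$region_probabilities),
                    levels = gcs_regions),
    eye = as.integer(eye), verbal = as.integer(verbal),
    motor = as.integer(motor),
    outcome30d = NA_character_
  )
}

#' Simulate responses from a partial credit model
#'
#' Draws each response from the PCM category distribution at the person's
#' latent location; person locations are sampled from a normal distribution.
#' Deterministic given `seed`.
#'
#' @param item_thresholds List of per-item threshold vectors (logits),
#'   ordered or disordered.
#' @param n_persons Number of persons.
#' @param theta_mean,theta_sd Latent location distribution (logits).
#' @param seed Integer seed.
#' @return A [response_matrix()]; the sampled locations are attached as the
#'   `theta` attribute.
#' @export
simulate_pcm <- function(item_thresholds, n_persons,
                         theta_mean = 0, theta_sd = 1, seed = 1L) {
  stopifnot(n_persons >= 1, all(lengths(item_thresholds) >= 1))
  withr::with_seed(seed, {
    theta <- stats::rnorm(n_persons, theta_mean, theta_sd)
    resp <- vapply(item_thresholds, function(delta) {
      pr <- pcm_category_probs(theta, delta)
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
      u <- stats::runif(n_persons)
      cum <- matrix(t(apply(pr, 1, cumsum)), nrow = n_persons)
      as.integer(rowSums(u > cum))
    }, integer(n_persons))
    resp <- matrix(resp, nrow = n_persons)
    if (is.null(names(item_thresholds))) {
      colnames(resp) <- paste0("item", seq_along(item_thresholds))
    } else {
      colnames(resp) <- names(item_thresholds)
    }
    rm <- response_matrix(resp, maxima = lengths(item_thresholds))
    attr(rm, "theta") <- theta
    rm
  })
}
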