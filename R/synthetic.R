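#' Configuration for a synthetic SCI-like cohort
#'
#' The defaults state a world shaped like a small spinal-cord-injury
#' surgical registry: 74 patients, 46 predictors (16 vitals summary
#' statistics for HR/SysBP/DiaBP/MAP, 2 time-outside-MAP-threshold
#' features at 76/104 mmHg, ordinal severity scores `AIS_ad` and
#' `MRI_1_BASIC_Score`, binary covariates, `Time_to_OR`, and 22 noise
#' features), and a binary improvement target with 39/74 prevalence.
#' Intraoperative traces are first-order autoregressive around a
#' patient baseline with random-onset, random-duration excursion
#' episodes pushing MAP beyond the true thresholds; the outcome is
#' drawn from a logistic model on the true (noise-free) feature values
#' with the intercept calibrated by bisection to the target prevalence.
#'
#' @param n_patients cohort size.
#' @param prevalence target outcome prevalence in (0, 1).
#' @param lower_threshold,upper_threshold true MAP thresholds (mmHg)
#'   entering the outcome model.
#' @param coefficients named log-odds coefficients: `above_per_hour`,
#'   `below_per_hour`, `severity`, `basic`, `cervical`, `tbi`, `vai`,
#'   `ttor_per_hour`.
#' @param excursion_rate_up,excursion_rate_down expected excursion
#'   episodes per surgery (hypertensive / hypotensive).
#' @param excursion_duration_mean mean episode duration (minutes).
#' @param excursion_shift_mean,excursion_shift_sd episode magnitude
#'   (mmHg) beyond baseline.
#' @param duration_range surgery duration range (minutes).
#' @param sampling_interval vitals sampling interval (minutes).
#' @param ar_rho,ar_sd trace autocorrelation and innovation sd.
#' @param time_to_or_meanlog,time_to_or_sdlog log-normal parameters of
#'   time from hospitalization to surgery (hours).
#' @param n_noise count of independent standard-normal noise features.
#' @param missing_rate per-cell missingness probability on predictors.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 74,
                          prevalence = 39 / 74,
                          lower_threshold = 76,
                          upper_threshold = 104,
                          coefficients = list(above_per_hour = -1.2,
                                              below_per_hour = -0.6,
                                              severity = -0.45,
                                              basic = -0.35,
                                              cervical = -0.4,
                                              tbi = -0.3,
                                              vai = -0.3,
                                              ttor_per_hour = -0.004),
                          excursion_rate_up = 0.9,
                          excursion_rate_down = 0.9,
                          excursion_duration_mean = 45,
                          excursion_shift_mean = 22,
                          excursion_shift_sd = 6,
                          duration_range = c(150, 360),
                          sampling_interval = 1,
                          ar_rho = 0.9,
                          ar_sd = 2,
                          time_to_or_meanlog = log(60),
                          time_to_or_sdlog = 0.5,
                          n_noise = 22,
                          missing_rate = 0.01) {
  stopifnot(prevalence > 0, prevalence < 1, all(duration_range > 0))
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

.severity_of_ais <- function(grade) 5L - match(grade, c("A", "B", "C", "D", "E"))

.simulate_trace <- function(cfg, dur, baseline, n_up, n_down) {
  times <- seq(0, dur, by = cfg$sampling_interval)
  nt <- length(times)
  x <- numeric(nt)
  x[1] <- baseline + rnorm(1, 0, cfg$ar_sd)
  for (t in 2:nt) {
    x[t] <- baseline + cfg$ar_rho * (x[t - 1] - baseline) +
      rnorm(1, 0, cfg$ar_sd)
  }
  shift <- numeric(nt)
  add_episodes <- function(n, sign) {
    for (e in seq_len(n)) {
      onset <- runif(1, 0, dur)
      len <- rexp(1, 1 / cfg$excursion_duration_mean)
      mag <- max(rnorm(1, cfg$excursion_shift_mean, cfg$excursion_shift_sd), 5)
      idx <- times >= onset & times <= onset + len
      shift[idx] <<- shift[idx] + sign * mag
    }
  }
  add_episodes(n_up, +1)
  add_episodes(n_down, -1)
  list(time = times, value = pmax(x + shift, 20))
}

#' Simulate a synthetic SCI-like cohort
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is fully determined by
#'   `(config, seed)`.
#' @return list with `table` (a `feature_table`), `vitals` (long-format
#'   data.frame) and `truth` (latent parameters: calibrated intercept,
#'   per-patient linear predictor and outcome probability, and the
#'   generator's own bookkeeping of time outside each threshold,
#'   computed by an independent code path from the traces).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  cfg <- config
  b <- cfg$coefficients
  .with_seed(seed, {
    n <- cfg$n_patients
    vit_list <- list()
    t_above <- t_below <- numeric(n)
    ais <- character(n); basic <- integer(n)
    cerv <- tbi <- vai <- integer(n)
    ttor <- numeric(n)
    for (i in seq_len(n)) {
      dur <- round(runif(1, cfg$duration_range[1], cfg$duration_range[2]))
      map_base <- rnorm(1, 90, 6)
      n_up <- rpois(1, cfg$excursion_rate_up)
      n_down <- rpois(1, cfg$excursion_rate_down)
      map <- .simulate_trace(cfg, dur, map_base, n_up, n_down)
      hr <- .simulate_trace(cfg, dur, rnorm(1, 80, 9), 0, 0)
      sys <- list(time = map$time,
                  value = pmax(map$value * 1.35 + rnorm(length(map$value), 0, 3), 30))
      dia <- list(time = map$time,
                  value = pmax(map$value * 0.75 + rnorm(length(map$value), 0, 3), 15))
      pid <- sprintf("P%04d", i)
      vit_list[[i]] <- data.frame(
        patient_id = pid,
        signal = rep(c("HR", "SysBP", "DiaBP", "MAP"),
                     each = length(map$time)),
        time_min = rep(map$time, 4),
        value = c(hr$value, sys$value, dia$value, map$value),
        stringsAsFactors = FALSE)
      # independent bookkeeping: strict exceedance count x regular interval
      t_above[i] <- sum(map$value > cfg$upper_threshold) * cfg$sampling_interval
      t_below[i] <- sum(map$value < cfg$lower_threshold) * cfg$sampling_interval
      ais[i] <- sample(c("A", "B", "C", "D", "E"), 1,
                       prob = c(0.25, 0.20, 0.30, 0.20, 0.05))
      basic[i] <- sample(0:4, 1, prob = c(0.15, 0.20, 0.30, 0.20, 0.15))
      cerv[i] <- rbinom(1, 1, 0.55)
      tbi[i] <- rbinom(1, 1, 0.30)
      vai[i] <- rbinom(1, 1, 0.15)
      ttor[i] <- rlnorm(1, cfg$time_to_or_meanlog, cfg$time_to_or_sdlog)
    }
    vitals <- do.call(rbind, vit_list)

    eta <- b$above_per_hour * t_above / 60 +
      b$below_per_hour * t_below / 60 +
      b$severity * .severity_of_ais(ais) +
      b$basic * basic +
      b$cervical * cerv + b$tbi * tbi + b$vai * vai +
      b$ttor_per_hour * ttor
    intercept <- .calibrate_intercept(eta, cfg$prevalence)
    prob <- stats::plogis(intercept + eta)
    y <- rbinom(n, 1, prob)

    summ <- summarize_vitals(vitals)
    stopifnot(identical(summ$patient_id, sprintf("P%04d", seq_len(n))))
    df <- summ[setdiff(names(summ), "patient_id")]
    df$AIS_ad <- ais
    df$MRI_1_BASIC_Score <- basic
    df$Cervical_Injury <- cerv
    df$TBI_Present <- tbi
    df$Vertebral_Artery_Injury <- vai
    df$Time_to_OR <- ttor
    if (cfg$n_noise > 0) {
      noise <- matrix(rnorm(n * cfg$n_noise), n)
      colnames(noise) <- sprintf("noise_%02d", seq_len(cfg$n_noise))
      df <- cbind(df, as.data.frame(noise))
    }
    kinds <- stats::setNames(rep("numeric", ncol(df)), names(df))
    kinds["AIS_ad"] <- "categorical"
    table <- feature_table(df, target = y, kinds = kinds,
                           patient_id = sprintf("P%04d", seq_len(n)))
    table <- build_threshold_features(table, vitals,
                                      lower = cfg$lower_threshold,
                                      upper = cfg$upper_threshold)
    if (cfg$missing_rate > 0) {
      preds <- table$predictors
      for (j in seq_along(preds)) {
        drop_idx <- which(runif(n) < cfg$missing_rate)
        if (length(drop_idx)) preds[drop_idx, j] <- NA
      }
      table <- feature_table(preds, target = y, kinds = table$kinds,
                             patient_id = table$patient_id)
    }
    list(table = table, vitals = vitals,
         truth = list(config = cfg, seed = seed, intercept = intercept,
                      eta = eta, prob = prob,
                      time_above_upper = t_above,
                      time_below_lower = t_below))
  })
}

# Bisection on the intercept so mean outcome probability hits the target.
.calibrate_intercept <- function(eta, prevalence, tol = 1e-8) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("infeasible prevalence for coefficients")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Declare distribution shifts for a drifted validation cohort
#'
#' Emulates evolving clinical practice between a retrospective training
#' era and a prospective validation era: fewer patients, lower outcome
#' prevalence, substantially shorter time-to-surgery, and active
#' prevention of intraoperative hypotension.
#'
#' @param n_patients validation cohort size.
#' @param prevalence validation outcome prevalence (default 14/59).
#' @param time_to_or_mult multiplier on the median time-to-surgery
#'   (default 0.4: surgery much sooner).
#' @param rate_down_mult multiplier on the hypotensive excursion rate
#'   (default 0.25: hypotension largely prevented).
#' @param rate_up_mult multiplier on the hypertensive excursion rate.
#' @return a `drift_spec` list.
#' @export
drift_spec <- function(n_patients = 59, prevalence = 14 / 59,
                       time_to_or_mult = 0.4, rate_down_mult = 0.25,
                       rate_up_mult = 1) {
  stopifnot(time_to_or_mult > 0, rate_down_mult >= 0, rate_up_mult >= 0,
            prevalence > 0, prevalence < 1)
  spec <- as.list(environment())
  class(spec) <- "drift_spec"
  spec
}

#' Simulate a drifted validation cohort
#'
#' Applies a [drift_spec()] to a base [cohort_config()] and simulates a
#' new cohort under the same outcome model (coefficients unchanged; the
#' intercept is recalibrated to the drifted prevalence).
#'
#' @param config base `cohort_config`.
#' @param drift a `drift_spec`.
#' @param seed integer seed.
#' @return as [simulate_cohort()].
#' @export
simulate_drifted_cohort <- function(config = cohort_config(),
                                    drift = drift_spec(), seed = 2) {
  cfg <- config
  cfg$n_patients <- drift$n_patients
  cfg$prevalence <- drift$prevalence
  cfg$time_to_or_meanlog <- cfg$time_to_or_meanlog + log(drift$time_to_or_mult)
  cfg$excursion_rate_down <- cfg$excursion_rate_down * drift$rate_down_mult
  cfg$excursion_rate_up <- cfg$excursion_rate_up * drift$rate_up_mult
  simulate_cohort(cfg, seed)
}

#' Simulate a plain tabular cohort with planted signal features
#'
#' A lighter generator for recovery experiments: `n_signal` standard
#' normal features carry equal log-odds weight `beta`, `n_noise`
#' features are independent of everything; the intercept is calibrated
#' to the target prevalence.
#'
#' @param n patients.
#' @param n_signal,n_noise feature counts.
#' @param beta per-signal-feature log-odds coefficient.
#' @param prevalence target prevalence.
#' @param seed integer seed.
#' @return list with `table` (features `signal_01..`, `noise_01..`) and
#'   `truth` (`eta`, `prob`, `intercept`).
#' @export
simulate_planted_cohort <- function(n = 300, n_signal = 5, n_noise = 15,
                                    beta = 1, prevalence = 0.5, seed = 1) {
  .with_seed(seed, {
    X <- matrix(rnorm(n * (n_signal + n_noise)), n)
    colnames(X) <- c(sprintf("signal_%02d", seq_len(n_signal)),
                     sprintf("noise_%02d", seq_len(n_noise)))
    eta <- as.numeric(X[, seq_len(n_signal), drop = FALSE] %*%
                        rep(beta, n_signal))
    intercept <- .calibrate_intercept(eta, prevalence)
    prob <- stats::plogis(intercept + eta)
    y <- rbinom(n, 1, prob)
    list(table = feature_table(as.data.frame(X), target = y),
         truth = list(eta = eta, prob = prob, intercept = intercept))
  })
}
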