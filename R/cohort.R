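#' Classify an apraxia screen total score
#'
#' The 12-item apraxia screen (imitation 0-7 plus gesture 0-5) classifies
#' a limb as unaffected at a perfect score of 12, pseudo-apraxic at 9-11,
#' and apraxic below 9; scores below 5 additionally flag severe apraxia.
#'
#' @param ast_total integer vector of total screen scores, 0-12.
#' @return data.frame with columns `ast_total`, `group` (factor with
#'   levels `apraxic`, `pseudo_apraxic`, `unaffected`) and `severe`
#'   (logical, score below 5).
#' @examples
#' classify_ast(c(12, 9, 1))
#' @export
classify_ast <- function(ast_total) {
  if (any(!is.finite(ast_total)) || any(ast_total < 0 | ast_total > 12) ||
      any(ast_total != round(ast_total))) {
    stop("ast_total must be integers in [0, 12]")
  }
  group <- ifelse(ast_total == 12, "unaffected",
                  ifelse(ast_total >= 9, "pseudo_apraxic", "apraxic"))
  data.frame(
    ast_total = as.integer(ast_total),
    group = factor(group, levels = vmti_groups()),
    severe = ast_total < 5
  )
}

vmti_groups <- function() c("apraxic", "pseudo_apraxic", "unaffected")

#' Published 22-patient reference cohort
#'
#' The printed demographic and apraxia-screen table for the 22
#' left-hemispheric-stroke patients: education (years), MMSE, disease
#' duration (days), imitation (0-7), gesture (0-5) and total (0-12)
#' screen scores, and group. Per-patient age is not printed and is
#' carried as `NA`; sex is not printed per patient either, so males are
#' assigned to the first rows of each group to match the published group
#' counts (3/7 apraxic, 5/6 pseudo-apraxic, 7/9 unaffected males).
#'
#' @return data.frame with one row per patient and the `patients.csv`
#'   column layout (patient_id, group, sex, age, education, mmse,
#'   disease_duration, ast_imitation, ast_gesture, ast_total).
#' @examples
#' tab <- table1_fixture()
#' table(tab$group)
#' @export
table1_fixture <- function() {
  edu <- c(18, 21, 18, 21, 18, 18, 12,
           18, 18, 12, 18, 18, 18,
           18, 22, 18, 18, 21, 22, 18, 18, 18)
  mmse <- c(25, 25, 25, 30, 27, 26, 25,
            27, 25, 25, 29, 27, 28,
            26, 28, 29, 28, 25, 30, 25, 29, 25)
  dur <- c(61, 280, 68, 42, 397, 18, 1126,
           338, 631, 35, 123, 19, 523,
           54, 48, 628, 47, 120, 556, 47, 15, 48)
  imit <- c(5, 4, 0, 2, 4, 4, 4,
            7, 7, 5, 6, 6, 7,
            rep(7L, 9))
  gest <- c(2, 1, 1, 3, 3, 2, 3,
            4, 3, 4, 3, 3, 4,
            rep(5L, 9))
  grp <- rep(c("apraxic", "pseudo_apraxic", "unaffected"), c(7, 6, 9))
  n_male <- c(apraxic = 3L, pseudo_apraxic = 5L, unaffected = 7L)
  sex_vec <- character(length(grp))
  for (g in vmti_groups()) {
    idx <- which(grp == g)
    sex_vec[idx] <- rep(c("male", "female"),
                        c(n_male[[g]], length(idx) - n_male[[g]]))
  }
  out <- data.frame(
    patient_id = sprintf("P%02d", seq_along(grp)),
    group = factor(grp, levels = vmti_groups()),
    sex = factor(sex_vec, levels = c("male", "female")),
    age = NA_real_,
    education = edu,
    mmse = mmse,
    disease_duration = dur,
    ast_imitation = imit,
    ast_gesture = gest,
    ast_total = imit + gest
  )
  stopifnot(identical(out$group, classify_ast(out$ast_total)$group))
  out
}

#' Default synthetic-cohort configuration
#'
#' Returns the generator configuration. Group sizes and demographic
#' means/SDs (population-SD convention) default to the reference cohort;
#' psychometric ground-truth parameters default to a 300 ms baseline
#' threshold and 0.015 /ms baseline steepness in every condition, with
#' only the active-movement condition coupled to apraxia severity:
#' `ddt_per_point` milliseconds of threshold extension and a
#' `log_steepness_per_point` multiplicative steepness loss per screen
#' point below 12.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return named list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    group_sizes = c(apraxic = 7L, pseudo_apraxic = 6L, unaffected = 9L),
    male_fraction = c(apraxic = 3 / 7, pseudo_apraxic = 5 / 6,
                      unaffected = 7 / 9),
    age = list(mean = c(apraxic = 74.0, pseudo_apraxic = 57.2,
                        unaffected = 69.3),
               sd = c(apraxic = 11.7, pseudo_apraxic = 16.5,
                      unaffected = 13.9),
               range = c(30, 95)),
    education = list(mean = c(apraxic = 18.0, pseudo_apraxic = 17.0,
                              unaffected = 19.2),
                     sd = c(apraxic = 2.8, pseudo_apraxic = 2.2,
                            unaffected = 1.7),
                     range = c(9, 24)),
    mmse = list(mean = c(apraxic = 26.1, pseudo_apraxic = 26.8,
                         unaffected = 27.2),
                sd = c(apraxic = 1.7, pseudo_apraxic = 1.5,
                       unaffected = 1.9),
                range = c(25, 30)),
    disease_duration = list(mean = c(apraxic = 284.6, pseudo_apraxic = 278.2,
                                     unaffected = 173.7),
                            sd = c(apraxic = 367.9, pseudo_apraxic = 237.5,
                                   unaffected = 225.7),
                            range = c(10, 2000)),
    base_ddt = 300,              # ms, all conditions at a perfect screen
    ddt_per_point = 25,          # ms active-condition DDT per point lost
    ddt_noise_sd = 40,           # ms between-patient jitter
    base_steepness = 0.015,      # 1/ms
    log_steepness_per_point = 0.12,  # active-condition log-loss per point
    steepness_noise_sdlog = 0.2
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

# all (imitation, gesture) pairs consistent with a total-score range
ast_pairs <- function(lo, hi) {
  grid <- expand.grid(imitation = 0:7, gesture = 0:5)
  grid[grid$imitation + grid$gesture >= lo &
         grid$imitation + grid$gesture <= hi, , drop = FALSE]
}

sample_clamped <- function(n, mean, sd, range) {
  pmin(pmax(rnorm(n, mean, sd), range[1]), range[2])
}

#' Generate a synthetic patient cohort with psychometric ground truth
#'
#' Samples group membership, demographics, and apraxia-screen subscores
#' (uniformly over the (imitation, gesture) pairs consistent with each
#' group's total-score range), then draws per-patient, per-condition
#' true psychometric parameters. Tactile- and passive-condition
#' parameters come from one severity-independent distribution; active-
#' condition parameters degrade with screen points lost:
#' \deqn{t_{DDT} = base + \beta (12 - total) + \epsilon, \quad
#'       a = a_0 \exp(-\gamma (12 - total)) \cdot \eta}
#' with Gaussian threshold noise and log-normal steepness noise.
#'
#' @param config list from [cohort_config()].
#' @param seed integer root seed.
#' @return list with `patients` (data.frame as in [table1_fixture()])
#'   and `truth` (data.frame: patient_id, condition, steepness, ddt,
#'   plus per-patient columns merged on demand). The `truth` element
#'   also carries `attr(, "config")` for provenance.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' nrow(cohort$patients)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  sizes <- config$group_sizes
  if (any(sizes < 0)) stop("group sizes must be non-negative")
  with_stream_seed(seed, "cohort", {
    grp <- rep(vmti_groups(), sizes[vmti_groups()])
    n <- length(grp)
    ranges <- list(apraxic = c(0, 8), pseudo_apraxic = c(9, 11),
                   unaffected = c(12, 12))
    imit <- integer(n); gest <- integer(n)
    for (i in seq_len(n)) {
      pairs <- ast_pairs(ranges[[grp[i]]][1], ranges[[grp[i]]][2])
      j <- sample.int(nrow(pairs), 1L)
      imit[i] <- pairs$imitation[j]; gest[i] <- pairs$gesture[j]
    }
    total <- imit + gest
    demo <- function(field) {
      out <- numeric(n)
      for (g in vmti_groups()) {
        idx <- grp == g
        out[idx] <- sample_clamped(sum(idx), config[[field]]$mean[[g]],
                                   config[[field]]$sd[[g]],
                                   config[[field]]$range)
      }
      out
    }
    mmse <- round(demo("mmse"))
    patients <- data.frame(
      patient_id = sprintf("S%02d", seq_len(n)),
      group = factor(grp, levels = vmti_groups()),
      sex = factor(ifelse(runif(n) < config$male_fraction[grp],
                          "male", "female"),
                   levels = c("male", "female")),
      age = round(demo("age")),
      education = round(demo("education")),
      mmse = mmse,
      disease_duration = round(demo("disease_duration")),
      ast_imitation = imit,
      ast_gesture = gest,
      ast_total = total
    )
    lost <- 12 - total
    conds <- vmti_conditions()
    truth <- do.call(rbind, lapply(conds, function(cond) {
      if (cond == "active") {
        ddt <- config$base_ddt + config$ddt_per_point * lost +
          rnorm(n, 0, config$ddt_noise_sd)
        a <- config$base_steepness *
          exp(-config$log_steepness_per_point * lost) *
          rlnorm(n, 0, config$steepness_noise_sdlog)
      } else {
        ddt <- config$base_ddt + rnorm(n, 0, config$ddt_noise_sd)
        a <- config$base_steepness * rlnorm(n, 0, config$steepness_noise_sdlog)
      }
      data.frame(patient_id = patients$patient_id, condition = cond,
                 steepness = a, ddt = pmin(pmax(ddt, 0), 1200))
    }))
    if (any(truth$steepness <= 0)) {
      stop("coupling configuration produced non-positive steepness")
    }
    rownames(truth) <- NULL
    attr(truth, "config") <- config
    list(patients = patients, truth = truth)
  })
}

vmti_conditions <- function() c("tactile", "passive", "active")

vmti_delays <- function() c(33, 100, 200, 300, 400, 500, 600)

#' Simulate delayed-feedback detection trials
#'
#' For every patient, condition and set, presents the seven delay levels
#' in random order and draws a Bernoulli "delayed" response with
#' probability given by the logistic detection curve at that patient's
#' true parameters.
#'
#' @param patients data.frame of patients (needs `patient_id`).
#' @param truth ground-truth data.frame from [generate_cohort()].
#' @param n_sets sets per condition (default 7, giving 3 x 7 x 7 = 147
#'   trials per patient).
#' @param delays delay levels in ms.
#' @param seed integer root seed.
#' @return data.frame of trials: patient_id, condition, delay_ms,
#'   set_index, response ("delayed"/"not_delayed").
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' trials <- generate_trials(cohort$patients, cohort$truth, seed = 1)
#' nrow(trials) / nrow(cohort$patients)  # 147
#' @export
generate_trials <- function(patients, truth, n_sets = 7,
                            delays = vmti_delays(), seed = 1) {
  key <- paste(truth$patient_id, truth$condition)
  missing <- setdiff(paste(rep(patients$patient_id, each = 3),
                           vmti_conditions()), key)
  if (length(missing)) {
    stop("missing ground truth for: ", paste(missing, collapse = ", "))
  }
  nd <- length(delays)
  with_stream_seed(seed, "trials", {
    rows <- vector("list", nrow(patients) * 3L)
    r <- 0L
    for (pid in patients$patient_id) {
      for (cond in vmti_conditions()) {
        tr <- truth[truth$patient_id == pid & truth$condition == cond, ]
        # randomized presentation order of the delay levels within a set
        d <- as.vector(vapply(seq_len(n_sets), function(s) sample(delays),
                              numeric(nd)))
        p <- predict_logistic(tr$steepness, tr$ddt, d)
        r <- r + 1L
        rows[[r]] <- data.frame(
          patient_id = pid, condition = cond, delay_ms = d,
          set_index = rep(seq_len(n_sets), each = nd),
          response = ifelse(rbinom(length(d), 1, p) == 1,
                            "delayed", "not_delayed"))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
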