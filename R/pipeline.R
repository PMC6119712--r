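#' Default end-to-end pipeline configuration
#'
#' Bundles the design constants (7 delay levels of 33-600 ms, 7 sets,
#' 3 stimulation conditions), the generator settings, and the analysis
#' options: significance level 0.05, uncapped Bonferroni, the 20%
#' voxel-coverage rule, minimum per-voxel group size 2, and FDR q =
#' 0.05. A YAML file with any subset of these fields can override the
#' defaults via [load_pipeline_config()].
#'
#' @param ... named overrides.
#' @return nested named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    delays = vmti_delays(),
    n_sets = 7L,
    cohort = cohort_config(),
    lesion = lesion_config(),
    alpha = 0.05,
    min_fraction = 0.20,
    min_per_group = 2L,
    fdr_q = 0.05
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (is.unsorted(cfg$delays, strictly = TRUE)) {
    stop("delays must be strictly increasing")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with overrides.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]])
      } else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_into(cfg, raw)
}

# short deterministic provenance hash of a config list
config_hash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Behavioral analysis stage: curves, fits, and group statistics
#'
#' From a patient table and raw trials, computes per-patient detection
#' curves and psychometric fits, then the group battery: split-plot
#' ANOVA on the DDT (group x condition), per-condition Kruskal-Wallis
#' on steepness with Mann-Whitney post hocs, Friedman across conditions
#' on steepness per group with Wilcoxon post hocs, Tukey-Kramer and
#' Bonferroni-corrected paired-t post hocs on the DDT, and Spearman
#' correlations of apraxia severity with DDT and steepness per
#' condition. Patients whose curves cannot be fitted in every condition
#' are listed in `$excluded` and omitted from the group analyses, never
#' silently dropped.
#'
#' @param patients patient data.frame.
#' @param trials trial data.frame.
#' @param config list from [pipeline_config()].
#' @return list (class `behavioral_bundle`) with elements `fits`,
#'   `excluded`, `descriptives`, `demographics`, `anova_ddt`,
#'   `tukey_ddt`, `paired_t_ddt`, `kruskal_steepness`,
#'   `friedman_steepness`, `correlations`, `ddt_matrix`,
#'   `steepness_matrix`, `groups`.
#' @export
run_behavioral <- function(patients, trials, config = pipeline_config()) {
  fits <- fit_cohort(trials)
  ok_fit <- tapply(fits$converged, fits$patient_id, all)
  excluded <- names(ok_fit)[!ok_fit]
  keep <- setdiff(patients$patient_id, excluded)
  pats <- patients[patients$patient_id %in% keep, ]
  fits_ok <- fits[fits$patient_id %in% keep, ]
  conds <- vmti_conditions()
  to_matrix <- function(var) {
    m <- sapply(conds, function(cd) {
      v <- fits_ok[[var]][fits_ok$condition == cd]
      v[match(pats$patient_id,
              fits_ok$patient_id[fits_ok$condition == cd])]
    })
    rownames(m) <- pats$patient_id
    m
  }
  ddt_m <- to_matrix("ddt")
  steep_m <- to_matrix("steepness")
  groups <- pats$group
  demographics <- list(
    sex = pearson_chi_square(table(pats$group, pats$sex)),
    education = kruskal_wallis(pats$education, pats$group),
    mmse = kruskal_wallis(pats$mmse, pats$group),
    disease_duration = kruskal_wallis(pats$disease_duration, pats$group)
  )
  descriptives <- list(
    education = describe_groups(pats$education, groups),
    mmse = describe_groups(pats$mmse, groups),
    disease_duration = describe_groups(pats$disease_duration, groups),
    ast_imitation = describe_groups(pats$ast_imitation, groups),
    ast_gesture = describe_groups(pats$ast_gesture, groups),
    ast_total = describe_groups(pats$ast_total, groups)
  )
  kr_st <- lapply(setNames(conds, conds), function(cd) {
    kruskal_wallis(steep_m[, cd], groups)
  })
  fr_st <- lapply(split(seq_len(nrow(steep_m)), groups), function(idx) {
    nonparametric_compare("friedman", steep_m[idx, , drop = FALSE])
  })
  correlations <- do.call(rbind, lapply(conds, function(cd) {
    rd <- spearman_correlation(pats$ast_total, ddt_m[, cd])
    rs <- spearman_correlation(pats$ast_total, steep_m[, cd])
    data.frame(condition = cd,
               measure = c("ddt", "steepness"),
               rho = c(rd$estimate, rs$estimate),
               p_value = c(rd$p_value, rs$p_value))
  }))
  structure(list(
    fits = fits, excluded = excluded,
    descriptives = descriptives, demographics = demographics,
    anova_ddt = mixed_anova(ddt_m, groups),
    tukey_ddt = posthoc_interaction(ddt_m, groups, "tukey"),
    paired_t_ddt = posthoc_interaction(ddt_m, groups, "paired_t"),
    kruskal_steepness = kr_st,
    friedman_steepness = fr_st,
    correlations = correlations,
    ddt_matrix = ddt_m, steepness_matrix = steep_m, groups = groups
  ), class = "behavioral_bundle")
}

#' Lesion analysis stage: overlap, subtraction, VLSM, volume correlations
#'
#' Computes group overlap maps, the apraxic-minus-others percentage
#' subtraction map, VLSM for the five behavioral factors (total,
#' imitation and gesture screen scores, active-condition DDT and
#' steepness), and Spearman correlations of lesion volume with severity
#' and the active-condition measures. The coverage cutoff is recomputed
#' from the patients actually carrying masks.
#'
#' @param masks named list of binary lesion arrays (patient_id names).
#' @param patients patient data.frame.
#' @param behavioral optional `behavioral_bundle` supplying fitted
#'   active-condition DDT/steepness; when NULL those VLSM factors are
#'   skipped.
#' @param config list from [pipeline_config()].
#' @return list (class `lesion_bundle`) with `overlap` (per group +
#'   all), `subtraction`, `vlsm` (per factor), `volumes`,
#'   `volume_correlations`, `n_patients`, `missing_masks`.
#' @export
run_lesion <- function(masks, patients, behavioral = NULL,
                       config = pipeline_config()) {
  dims <- lapply(masks, dim)
  bad <- names(masks)[!sapply(dims, identical, dims[[1]])]
  if (length(bad)) stop("grid mismatch for patient(s): ",
                        paste(bad, collapse = ", "))
  have <- intersect(patients$patient_id, names(masks))
  missing_masks <- setdiff(patients$patient_id, have)
  pats <- patients[match(have, patients$patient_id), ]
  masks <- masks[have]
  grp <- pats$group
  ov_groups <- lapply(split(seq_along(masks), grp), function(idx) {
    if (length(idx)) overlap_map(masks[idx]) else NULL
  })
  ov_all <- overlap_map(masks)
  apraxic <- masks[grp == "apraxic"]
  others <- masks[grp != "apraxic"]
  subtraction <- if (length(apraxic) && length(others)) {
    subtraction_map(apraxic, others)
  } else NULL
  scores <- list(ast_total = setNames(pats$ast_total, have),
                 ast_imitation = setNames(pats$ast_imitation, have),
                 ast_gesture = setNames(pats$ast_gesture, have))
  if (!is.null(behavioral)) {
    dm <- behavioral$ddt_matrix; sm <- behavioral$steepness_matrix
    ids <- intersect(have, rownames(dm))
    scores$active_ddt <- setNames(dm[ids, "active"], ids)
    scores$active_steepness <- setNames(sm[ids, "active"], ids)
  }
  vl <- lapply(scores, function(sc) {
    ids <- intersect(have, names(sc))
    vlsm(masks[ids], sc[ids], min_fraction = config$min_fraction,
         min_per_group = config$min_per_group, fdr_q = config$fdr_q)
  })
  vols <- lesion_volumes(masks)
  corr_with <- c(scores["ast_total"],
                 scores[intersect(c("active_ddt", "active_steepness"),
                                  names(scores))])
  volume_correlations <- do.call(rbind, lapply(names(corr_with), function(nm) {
    sc <- corr_with[[nm]]
    ids <- intersect(names(vols), names(sc))
    ct <- spearman_correlation(vols[ids], sc[ids])
    data.frame(measure = nm, rho = ct$estimate, p_value = ct$p_value)
  }))
  structure(list(
    overlap = c(ov_groups, list(all = ov_all)),
    subtraction = subtraction, vlsm = vl, volumes = vols,
    volume_correlations = volume_correlations,
    n_patients = length(masks), missing_masks = missing_masks
  ), class = "lesion_bundle")
}

#' Run the full simulate-fit-analyse pipeline
#'
#' Generates a cohort, trials and lesions from one root seed, then runs
#' the behavioral and lesion stages.
#'
#' @param config list from [pipeline_config()].
#' @param seed integer root seed; all stage seeds derive from it.
#' @param stages analysis stages to run; the generators always run.
#' @return list with `patients`, `truth`, `trials`, `lesions`,
#'   `behavioral`, `lesion` (NULL for stages not requested).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         stages = c("behavioral", "lesion")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cohort <- generate_cohort(config$cohort, seed = seed)
  trials <- generate_trials(cohort$patients, cohort$truth,
                            n_sets = config$n_sets, delays = config$delays,
                            seed = seed)
  lesions <- generate_lesions(cohort$patients, config$lesion, seed = seed)
  behavioral <- if ("behavioral" %in% stages) {
    run_behavioral(cohort$patients, trials, config)
  }
  lesion <- if ("lesion" %in% stages) {
    run_lesion(lesions$masks, cohort$patients, behavioral, config)
  }
  list(patients = cohort$patients, truth = cohort$truth, trials = trials,
       lesions = lesions, behavioral = behavioral, lesion = lesion)
}

# flatten a vmti_test into one report row
test_row <- function(x) {
  data.frame(test_name = x$test_name,
             statistic = x$statistic,
             df = paste(signif(x$df, 6), collapse = ","),
             p_value = x$p_value, p_adjusted = x$p_adjusted)
}

#' Write report tables for a pipeline run
#'
#' Emits TSV/JSON tables: the cohort table (reference-table layout),
#' group descriptives, the statistical battery, psychometric fits,
#' lesion-volume correlations and per-map summaries, plus a
#' `provenance.json` with the config hash and seed. Nothing is written
#' if the cohort is empty.
#'
#' @param result list from [run_pipeline()] (or one assembled from the
#'   stage functions with the same element names).
#' @param out output directory.
#' @param config the configuration used.
#' @param seed the root seed used.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(result, out, config = pipeline_config(), seed = NA) {
  if (is.null(result$patients) || nrow(result$patients) == 0) {
    stop("empty cohort; nothing to report")
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out, name)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$patients, "patients.tsv")
  beh <- result$behavioral
  if (!is.null(beh)) {
    wr(beh$fits, "fits.tsv")
    desc <- do.call(rbind, lapply(names(beh$descriptives), function(nm) {
      cbind(variable = nm, beh$descriptives[[nm]])
    }))
    wr(desc, "descriptives.tsv")
    stats_rows <- rbind(
      do.call(rbind, lapply(beh$demographics, test_row)),
      do.call(rbind, lapply(beh$anova_ddt, test_row)),
      do.call(rbind, lapply(beh$kruskal_steepness, test_row)),
      do.call(rbind, lapply(beh$friedman_steepness, test_row)))
    wr(stats_rows, "group_tests.tsv")
    wr(beh$tukey_ddt, "tukey_ddt.tsv")
    wr(beh$paired_t_ddt, "paired_t_ddt.tsv")
    wr(beh$correlations, "severity_correlations.tsv")
    if (length(beh$excluded)) {
      wr(data.frame(patient_id = beh$excluded, reason = "unfittable"),
         "excluded_patients.tsv")
    }
  }
  les <- result$lesion
  if (!is.null(les)) {
    vl_rows <- do.call(rbind, lapply(names(les$vlsm), function(nm) {
      v <- les$vlsm[[nm]]
      data.frame(factor = nm, n_patients = v$n_patients,
                 n_included = v$n_included,
                 n_significant = v$n_significant,
                 critical_p = v$critical_p, z_threshold = v$z_threshold)
    }))
    wr(vl_rows, "vlsm_summary.tsv")
    wr(les$volume_correlations, "volume_correlations.tsv")
    if (length(les$missing_masks)) {
      wr(data.frame(patient_id = les$missing_masks, reason = "no mask"),
         "missing_masks.tsv")
    }
  }
  prov <- list(config_hash = config_hash(config), seed = seed,
               package_version = as.character(utils::packageVersion("vmti")),
               n_patients = nrow(result$patients))
  pj <- file.path(out, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, pj)
  invisible(paths)
}
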