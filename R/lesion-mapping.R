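#' Read binary lesion masks from NIfTI files
#'
#' Loads per-patient lesion volumes, enforcing a shared grid and strict
#' 0/1 values. Non-binary input is rejected unless `binarize` supplies
#' an intensity window, in which case [binarize_normalized_map()] is
#' applied.
#'
#' @param paths character vector of NIfTI file paths; names (or file
#'   basenames) become patient identifiers.
#' @param binarize NULL, or `c(min, max)` intensity window.
#' @return named list of 3-D 0/1 arrays with `voxel_size` attributes.
#' @export
load_lesion_masks <- function(paths, binarize = NULL) {
  ids <- names(paths) %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  masks <- list()
  ref_dim <- NULL
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    arr <- as.array(img)
    if (length(dim(arr)) != 3) stop("non-3-D volume: ", paths[i])
    if (is.null(ref_dim)) ref_dim <- dim(arr)
    if (!identical(dim(arr), ref_dim)) {
      stop("grid mismatch for ", ids[i], ": ",
           paste(dim(arr), collapse = "x"), " vs ",
           paste(ref_dim, collapse = "x"))
    }
    if (!is.null(binarize)) {
      arr <- binarize_normalized_map(arr, binarize[1], binarize[2])
    } else if (!all(arr %in% c(0, 1))) {
      stop("non-binary values in ", ids[i],
           " (pass binarize = c(min, max) to threshold)")
    }
    m <- array(as.integer(arr), dim(arr))
    attr(m, "voxel_size") <- RNifti::pixdim(img)[1:3]
    masks[[ids[i]]] <- m
  }
  masks
}

#' Write a volume (mask or statistical map) as NIfTI
#'
#' @param volume 3-D array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm per axis (defaults to the array's `voxel_size`
#'   attribute, else 1 mm).
#' @return the path, invisibly.
#' @export
write_lesion_volume <- function(volume, path, voxel_size = NULL) {
  vs <- voxel_size %||% attr(volume, "voxel_size") %||% c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binarize a spatially normalised lesion map by intensity window
#'
#' A voxel is lesioned iff `min_thr <= value <= max_thr` (both bounds
#' inclusive); defaults reproduce the 100-255 intensity filter applied
#' to normalised lesion maps.
#'
#' @param volume numeric array.
#' @param min_thr,max_thr inclusive intensity window.
#' @return integer 0/1 array of the same shape.
#' @examples
#' binarize_normalized_map(array(c(99, 100, 255, 256), c(4, 1, 1)))
#' @export
binarize_normalized_map <- function(volume, min_thr = 100, max_thr = 255) {
  if (min_thr > max_thr) stop("min_thr must not exceed max_thr")
  out <- array(as.integer(volume >= min_thr & volume <= max_thr),
               dim(volume))
  attr(out, "voxel_size") <- attr(volume, "voxel_size")
  out
}

#' Voxelwise lesion overlap map
#'
#' Counts, per voxel, the number of patients lesioned there.
#'
#' @param masks list of binary arrays on a shared grid.
#' @return integer array of counts with attribute `n_patients`.
#' @export
overlap_map <- function(masks) {
  if (length(masks) == 0) stop("empty mask list")
  dims <- lapply(masks, dim)
  if (!all(sapply(dims, identical, dims[[1]]))) stop("grid mismatch")
  out <- Reduce(`+`, masks)
  out <- array(as.integer(out), dim(out))
  attr(out, "n_patients") <- length(masks)
  attr(out, "voxel_size") <- attr(masks[[1]], "voxel_size")
  out
}

#' Percentage subtraction map between two patient groups
#'
#' Per voxel, the lesion-overlap percentage of group B is subtracted
#' from that of group A: \eqn{100 n_A/N_A - 100 n_B/N_B}, reported as
#' integer percentages. Rounding is toward zero by default (71.43 -> 71,
#' 57.14 -> 57); `rounding = "half_up"` is available.
#'
#' @param masks_a,masks_b lists of binary masks for the two groups.
#' @param rounding "truncate" (toward zero) or "half_up".
#' @return integer array in [-100, 100].
#' @examples
#' a <- list(array(1L, c(2, 2, 1)))
#' b <- list(array(0L, c(2, 2, 1)))
#' subtraction_map(a, b)[1, 1, 1]  # 100
#' @export
subtraction_map <- function(masks_a, masks_b,
                            rounding = c("truncate", "half_up")) {
  rounding <- match.arg(rounding)
  if (length(masks_a) == 0 || length(masks_b) == 0) stop("empty group")
  ov_a <- overlap_map(masks_a)
  ov_b <- overlap_map(masks_b)
  if (!identical(dim(ov_a), dim(ov_b))) stop("grid mismatch between groups")
  pct <- 100 * ov_a / length(masks_a) - 100 * ov_b / length(masks_b)
  out <- if (rounding == "truncate") trunc(pct) else
    sign(pct) * floor(abs(pct) + 0.5)
  out <- array(as.integer(out), dim(out))
  attr(out, "voxel_size") <- attr(masks_a[[1]], "voxel_size")
  out
}

#' Voxel inclusion mask by minimum lesion coverage
#'
#' A voxel enters VLSM only if it is lesioned in at least
#' `min_fraction` of the cohort (default 20%): included iff
#' `N / cohort >= min_fraction`, so a 19-patient cohort requires at
#' least 4 lesioned patients.
#'
#' @param overlap overlap map from [overlap_map()].
#' @param n_patients cohort size (defaults to the map's attribute).
#' @param min_fraction minimum lesioned fraction, in (0, 1].
#' @return logical array.
#' @export
coverage_filter <- function(overlap, n_patients = attr(overlap, "n_patients"),
                            min_fraction = 0.20) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  array(overlap / n_patients >= min_fraction, dim(overlap))
}

#' Brunner-Munzel rank test for two independent samples
#'
#' Tests the relative effect \eqn{\hat p = P(X < Y) + 0.5 P(X = Y)}
#' against 0.5 using the studentized mid-rank statistic with
#' Satterthwaite-type degrees of freedom; two-sided p from the t
#' distribution. The relative effect is computed from the mid-rank
#' identity \eqn{(\bar R_2 - (n_2 + 1)/2)/n_1}, which equals the
#' pairwise-count definition exactly.
#'
#' When every value is tied the result is flagged `degenerate`
#' (statistic 0, p 1). When the two samples are completely separated
#' with zero within-sample rank variance the studentized statistic is
#' undefined; the result is flagged and the permutation floor
#' \eqn{p = 2/\binom{N}{n_1}} is reported with the correspondingly
#' signed statistic, so that maximally informative splits are retained
#' rather than dropped.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return a `vmti_test` result with extras `relative_effect` and
#'   `degenerate`. Positive statistic means the second sample tends to
#'   have larger values.
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  r <- midranks(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  w1 <- midranks(x); w2 <- midranks(y)
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - w1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - w2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (length(unique(c(x, y))) == 1) {
    return(test_result("brunner_munzel", statistic = 0, df = NA_real_,
                       p_value = 1,
                       extra = list(relative_effect = 0.5,
                                    degenerate = TRUE)))
  }
  if (v1 + v2 == 0) {
    # complete separation: studentized statistic undefined
    p_floor <- min(1, 2 / choose(N, n1))
    return(test_result("brunner_munzel",
                       statistic = sign(m2 - m1) * Inf, df = NA_real_,
                       p_value = p_floor,
                       effect_direction = sign(m2 - m1),
                       extra = list(relative_effect = p_hat,
                                    degenerate = TRUE)))
  }
  stat <- n1 * n2 * (m2 - m1) / (N * sqrt(n1 * v1 + n2 * v2))
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  test_result("brunner_munzel", statistic = stat, df = df, p_value = p,
              effect_direction = sign(stat),
              extra = list(relative_effect = p_hat, degenerate = FALSE))
}

#' Benjamini-Hochberg step-up FDR threshold
#'
#' Finds the largest k with \eqn{p_{(k)} \le k q / V} over the V tested
#' p-values; all p-values at or below \eqn{p_{(k)}} are declared
#' significant (none if no such k exists).
#'
#' @param p p-values in [0, 1].
#' @param q target false discovery rate.
#' @return list with `critical_p` (NA if nothing passes) and
#'   `significant` (logical vector aligned with `p`).
#' @examples
#' bh_fdr(c(0.001, 0.012, 0.014, 0.20, 0.85), q = 0.05)
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  v <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(v) * q / v)
  if (length(ok) == 0) {
    return(list(critical_p = NA_real_,
                significant = rep(FALSE, v)))
  }
  crit <- ps[max(ok)]
  list(critical_p = crit, significant = !is.na(p) & p <= crit)
}

# studentized Brunner-Munzel statistic for a lesioned/intact split of a
# fixed score vector, computed from precomputed dense value codes
# (1..u) and combined mid-ranks; within-sample mid-ranks come from
# value counts, avoiding per-call sorting. Positive when the intact
# side tends to score higher (i.e. lesioned patients score lower).
bm_split_stat <- function(codes, r_all, les, u, cnt_tot) {
  n <- length(codes)
  n1 <- sum(les); n2 <- n - n1
  c1 <- tabulate(codes[les], u)
  c2 <- cnt_tot - c1
  cum1 <- cumsum(c1); cum2 <- cumsum(c2)
  pre1 <- c(0, cum1[-u]) + (c1 + 1) / 2  # within-group midrank by code
  pre2 <- c(0, cum2[-u]) + (c2 + 1) / 2
  r1 <- r_all[les]; r2 <- r_all[!les]
  w1 <- pre1[codes[les]]; w2 <- pre2[codes[!les]]
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- sum((r1 - w1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - w2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  denom <- n * sqrt(n1 * v1 + n2 * v2)
  if (denom == 0) {
    if (m1 == m2) 0 else sign(m2 - m1) * Inf
  } else {
    n1 * n2 * (m2 - m1) / denom
  }
}

#' Voxel-based lesion-symptom mapping
#'
#' For every voxel lesioned in at least `min_fraction` of patients (and
#' with at least `min_per_group` patients on each side of the
#' lesioned/intact split), compares the behavioral scores of lesioned
#' vs intact patients with the Brunner-Munzel test, then applies
#' Benjamini-Hochberg FDR over the included voxels only.
#'
#' By default the per-voxel two-sided p-value is calibrated by
#' permutation: for each lesioned-count the null distribution of the
#' studentized Brunner-Munzel statistic is built from `n_perm` random
#' reassignments of patients to the lesioned/intact split, and
#' \eqn{p = (1 + \#\{|T^*| \ge |T|\})/(n_{perm} + 1)}. This guards
#' against the anti-conservative far tail of the analytic t
#' approximation at the small per-voxel group sizes typical of lesion
#' cohorts. The draws come from a fixed internal random stream, so
#' identical inputs always yield identical maps. `p_method = "t"`
#' selects the analytic Satterthwaite-t p instead.
#'
#' The z map is signed so that POSITIVE z means lesioned patients score
#' LOWER: severity scores (higher = better) give positive z over
#' deleterious voxels, while threshold-type scores (higher = worse)
#' give negative z there. z is derived from the two-sided p as
#' \eqn{z = s \, \Phi^{-1}(1 - p/2)} with s the direction sign.
#'
#' @param masks named list of binary lesion arrays on one grid.
#' @param scores numeric vector of behavioral scores, one per patient,
#'   aligned with (or named by) the masks.
#' @param min_fraction minimum lesioned fraction for inclusion.
#' @param min_per_group minimum patients on each side of the split.
#' @param fdr_q FDR level.
#' @param p_method "permutation" (default) or "t".
#' @param n_perm permutation draws per lesioned-count.
#' @return object of class `vlsm_result`: list with arrays `z`, `p`,
#'   `included`, `significant`, and scalars `critical_p`,
#'   `z_threshold` (smallest |z| declared significant), `n_included`,
#'   `n_significant`, `n_patients`.
#' @export
vlsm <- function(masks, scores, min_fraction = 0.20, min_per_group = 2,
                 fdr_q = 0.05, p_method = c("permutation", "t"),
                 n_perm = 1000) {
  p_method <- match.arg(p_method)
  n <- length(masks)
  if (length(scores) != n) stop("one score per patient required")
  if (!is.null(names(masks)) && !is.null(names(scores))) {
    scores <- scores[names(masks)]
  }
  if (anyNA(scores)) stop("missing scores")
  if (length(unique(scores)) == 1) stop("constant scores")
  ov <- overlap_map(masks)
  inc <- coverage_filter(ov, n, min_fraction) &
    ov <= n - min_per_group & ov >= min_per_group
  idx <- which(inc)
  if (length(idx) == 0) stop("all voxels excluded by the coverage filter")
  lesmat <- vapply(masks, function(m) m[idx] == 1L, logical(length(idx)))
  if (is.null(dim(lesmat))) lesmat <- matrix(lesmat, nrow = 1)
  # many voxels share one lesioned-patient pattern; test each pattern once
  key <- as.vector(lesmat %*% 2^(seq_len(n) - 1))
  upat <- !duplicated(key)
  urows <- which(upat)
  r_all <- rank(scores)
  codes <- match(scores, sort(unique(scores)))
  u <- max(codes)
  cnt_tot <- tabulate(codes, u)
  stat_u <- vapply(urows, function(j) {
    bm_split_stat(codes, r_all, lesmat[j, ], u, cnt_tot)
  }, numeric(1))
  if (p_method == "permutation") {
    ms <- rowSums(lesmat[urows, , drop = FALSE])
    p_u <- numeric(length(urows))
    with_stream_seed(0L, "vlsm-permutation", {
      for (m in unique(ms)) {
        null_abs <- vapply(seq_len(n_perm), function(b) {
          les_b <- logical(n)
          les_b[sample.int(n, m)] <- TRUE
          abs(bm_split_stat(codes, r_all, les_b, u, cnt_tot))
        }, numeric(1))
        sel <- ms == m
        p_u[sel] <- vapply(abs(stat_u[sel]), function(s) {
          (1 + sum(null_abs >= s - 1e-12)) / (n_perm + 1)
        }, numeric(1))
      }
    })
  } else {
    p_u <- vapply(urows, function(j) {
      les <- lesmat[j, ]
      brunner_munzel(scores[les], scores[!les])$p_value
    }, numeric(1))
  }
  map_back <- match(key, key[upat])
  ps <- p_u[map_back]
  sgn <- sign(stat_u)[map_back]
  zs <- sgn * stats::qnorm(1 - pmin(ps, 1) / 2)
  fdr <- bh_fdr(ps, fdr_q)
  zmap <- array(0, dim(ov)); pmap <- array(NA_real_, dim(ov))
  sig <- array(FALSE, dim(ov))
  zmap[idx] <- zs; pmap[idx] <- ps
  sig[idx] <- fdr$significant
  structure(list(
    z = zmap, p = pmap, included = inc, significant = sig,
    critical_p = fdr$critical_p,
    z_threshold = if (any(fdr$significant))
      min(abs(zs[fdr$significant])) else NA_real_,
    fdr_q = fdr_q, n_included = length(idx),
    n_significant = sum(fdr$significant), n_patients = n),
    class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat("Voxel-based lesion-symptom mapping\n")
  cat(sprintf("  patients: %d   included voxels: %d\n",
              x$n_patients, x$n_included))
  cat(sprintf("  significant voxels at FDR q = %.2f: %d", x$fdr_q,
              x$n_significant))
  if (!is.na(x$critical_p)) {
    cat(sprintf(" (critical p = %.4g, |z| >= %.2f)",
                x$critical_p, x$z_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Per-region extrema of a statistical or overlap map
#'
#' For each labelled region, reports the maximum-magnitude map value,
#' its voxel coordinates, the region's voxel count, and the count of
#' suprathreshold voxels within the region.
#'
#' @param map numeric array.
#' @param labels integer array of region labels on the same grid (0 =
#'   unlabelled).
#' @param label_names optional named character vector mapping label
#'   values to region names.
#' @param threshold value above which (in magnitude) a voxel counts as
#'   suprathreshold; default 0 counts all nonzero voxels.
#' @return data.frame: region, label, n_voxels, n_suprathreshold,
#'   peak_value, peak_x, peak_y, peak_z.
#' @export
region_summary <- function(map, labels, label_names = NULL, threshold = 0) {
  if (!identical(dim(map), dim(labels))) stop("grid mismatch")
  labs <- sort(unique(labels[labels != 0]))
  rows <- lapply(labs, function(lb) {
    idx <- which(labels == lb)
    vals <- map[idx]
    peak <- idx[which.max(abs(vals))]
    co <- arrayInd(peak, dim(map))
    data.frame(
      region = if (!is.null(label_names)) label_names[[as.character(lb)]]
               else paste0("region_", lb),
      label = lb, n_voxels = length(idx),
      n_suprathreshold = sum(abs(vals) > threshold),
      peak_value = vals[which.max(abs(vals))],
      peak_x = co[1], peak_y = co[2], peak_z = co[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
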