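#' Default lesion-simulation configuration
#'
#' The lesion space is an abstract 3-D grid (default 40 x 48 x 40
#' voxels at 4 mm isotropic), not a stereotaxic template. Lesions are
#' unions of axis-aligned ellipsoid blobs with a Poisson-distributed
#' count (mean 2) and uniform centres; in addition, a designated
#' critical region (an ellipsoid, configurable) is damaged in
#' proportion to apraxia severity: the target damaged fraction of the
#' critical region is `critical_coupling * (12 - ast_total)/12` plus
#' uniform jitter.
#'
#' @param ... named overrides.
#' @return named list of settings.
#' @export
lesion_config <- function(...) {
  cfg <- list(
    grid_shape = c(40L, 48L, 40L),
    voxel_size = c(4, 4, 4),             # mm
    blob_count_mean = 2,                 # Poisson mean per patient
    blob_radius_range = c(2, 5),         # voxels, per axis
    critical_center = c(12, 26, 22),     # voxel coordinates
    critical_radii = c(5, 6, 5),         # voxels, per axis
    critical_coupling = 0.9,             # max damaged fraction at total 0
    critical_jitter = 0.05               # uniform +/- jitter on the fraction
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

# logical mask of an axis-aligned ellipsoid on the grid
ellipsoid_mask <- function(grid_shape, center, radii) {
  ax <- lapply(1:3, function(i) ((seq_len(grid_shape[i]) - center[i]) /
                                   radii[i])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  d2 <= 1
}

#' Generate severity-coupled binary lesion masks
#'
#' Each patient receives a binary lesion volume composed of (a) a
#' severity-driven portion of the critical region -- the voxels of the
#' region closest to its centre, sized so the damaged fraction matches
#' the coupling target -- and (b) Poisson-many random background
#' ellipsoid blobs. The realised critical damaged fraction is appended
#' to the returned truth table.
#'
#' @param patients patient data.frame (needs patient_id, ast_total).
#' @param config list from [lesion_config()].
#' @param seed integer root seed.
#' @return list with `masks` (named list of 3-D 0/1 arrays, one per
#'   patient, with `voxel_size` attribute), `critical` (logical array of
#'   the critical region), and `damage` (data.frame patient_id,
#'   critical_damage_fraction).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' les <- generate_lesions(cohort$patients, seed = 1)
#' range(les$masks[[1]])
#' @export
generate_lesions <- function(patients, config = lesion_config(), seed = 1) {
  gs <- config$grid_shape
  critical <- ellipsoid_mask(gs, config$critical_center, config$critical_radii)
  if (!any(critical)) stop("critical region is empty on this grid")
  crit_idx <- which(critical)
  # critical voxels ordered by scaled distance from the region centre
  coords <- arrayInd(crit_idx, gs)
  d2 <- rowSums(sweep(sweep(coords, 2, config$critical_center), 2,
                      config$critical_radii, `/`)^2)
  crit_ord <- crit_idx[order(d2)]
  with_stream_seed(seed, "lesions", {
    masks <- list()
    frac <- numeric(nrow(patients))
    for (i in seq_len(nrow(patients))) {
      mask <- array(0L, gs)
      lost <- 12 - patients$ast_total[i]
      target <- config$critical_coupling * lost / 12 +
        runif(1, -config$critical_jitter, config$critical_jitter)
      target <- min(max(target, 0), 1)
      k <- round(target * length(crit_ord))
      if (k > 0) mask[crit_ord[seq_len(k)]] <- 1L
      n_blob <- rpois(1, config$blob_count_mean)
      for (b in seq_len(n_blob)) {
        center <- sapply(gs, function(s) runif(1, 1, s))
        radii <- runif(3, config$blob_radius_range[1],
                       config$blob_radius_range[2])
        mask[ellipsoid_mask(gs, center, radii)] <- 1L
      }
      frac[i] <- sum(mask[crit_idx]) / length(crit_idx)
      attr(mask, "voxel_size") <- config$voxel_size
      masks[[patients$patient_id[i]]] <- mask
    }
    list(masks = masks, critical = critical,
         damage = data.frame(patient_id = patients$patient_id,
                             critical_damage_fraction = frac))
  })
}

#' Lesion volume per patient
#'
#' Voxel count times voxel volume, in millilitres.
#'
#' @param masks named list of binary lesion arrays with a `voxel_size`
#'   attribute (mm per axis).
#' @return named numeric vector of volumes (ml).
#' @export
lesion_volumes <- function(masks) {
  sapply(masks, function(m) {
    vs <- attr(m, "voxel_size") %||% c(1, 1, 1)
    sum(m) * prod(vs) / 1000
  })
}
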