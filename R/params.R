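#' Mapping parameters
#'
#' Central configuration for the automatic mapping pipeline.  All thresholds
#' are LOD (log10 likelihood-ratio) units unless noted.
#'
#' @param lod_framework order-robustness threshold for framework maps: a
#'   marker is kept only if the best map beats the best alternative
#'   single-marker repositioning by at least this LOD (default 3.0).
#' @param lod_assign minimum 2-point LOD linking a marker to a group for
#'   assignment (default 6).
#' @param assign_gap minimum LOD gap between the best and second-best group
#'   for an unambiguous assignment (default 3).
#' @param group_lod 2-point LOD defining the linkage graph whose connected
#'   components seed the linkage groups (default 6).
#' @param seed_lod minimum mutual LOD of a seed pair (default 10).
#' @param seed_rmin,seed_rmax recombination-fraction window for a seed
#'   pair (defaults 0.05 and 0.25): the seed interval must carry enough
#'   recombination information to orient candidate markers on either side
#'   of it, so very tight pairs are excluded.
#' @param seed_max_missing maximum missing-call fraction of seed markers.
#' @param scaffold_rmin,scaffold_rmax seriation acceptance window for the
#'   2-point r between a candidate and the scaffold end (defaults 0.05 and
#'   0.25: keeps the scaffold sparse yet able to reach chromosome ends).
#' @param eps genotyping-error emission rate used in multipoint models
#'   during map construction and error detection while error correction is
#'   active (default 0.01; deliberately conservative so that ordering and
#'   detection are robust to miscalls).
#' @param eps_final emission error rate for the final distance
#'   re-estimation, after detected errors have been masked (default 1e-4,
#'   the usual order of magnitude assumed for residual undetected errors in
#'   map-distance estimation; the construction value would bias distances
#'   downward by absorbing genuine crossovers).
#' @param error_correction logical: detect-and-mask putative genotyping
#'   errors and use the error emission model (default TRUE).  When FALSE the
#'   emission error rate is forced to 0 and no calls are masked.
#' @param error_threshold posterior compatibility threshold below which a
#'   call is flagged (default 0.01).  Must sit above the plateau that the
#'   error emission model itself assigns to a fully contradicted call
#'   (about eps/4 at a 1 cM marker spacing), otherwise the detector can
#'   never fire.
#' @param singleton_window flank window (cM) of the singleton rule.
#' @param twin_min_overlap minimum co-typed individuals for twin grouping.
#' @param refit_every full EM refit (and error re-detection) cadence during
#'   framework densification, in accepted markers (default 25).
#' @param try_k how many top candidates to try per scaffold elongation step.
#' @param mapping_fun `"haldane"` (default; matches the no-interference
#'   crossover model of the simulator) or `"kosambi"` for distance
#'   reporting.
#' @return a named list of class `map_params`.
#' @export
map_params <- function(lod_framework = 3.0,
                       lod_assign = 6,
                       assign_gap = 3,
                       group_lod = 6,
                       seed_lod = 10,
                       seed_rmin = 0.05,
                       seed_rmax = 0.25,
                       seed_max_missing = 0.2,
                       scaffold_rmin = 0.05,
                       scaffold_rmax = 0.25,
                       eps = 0.01,
                       eps_final = 1e-4,
                       error_correction = TRUE,
                       error_threshold = 0.01,
                       singleton_window = 10,
                       twin_min_overlap = 20L,
                       refit_every = 25L,
                       try_k = 10L,
                       mapping_fun = c("haldane", "kosambi")) {
  structure(list(
    lod_framework = lod_framework, lod_assign = lod_assign,
    assign_gap = assign_gap, group_lod = group_lod,
    seed_lod = seed_lod, seed_rmin = seed_rmin, seed_rmax = seed_rmax,
    seed_max_missing = seed_max_missing,
    scaffold_rmin = scaffold_rmin, scaffold_rmax = scaffold_rmax,
    eps = eps, eps_final = eps_final,
    error_correction = error_correction,
    error_threshold = error_threshold,
    singleton_window = singleton_window,
    twin_min_overlap = twin_min_overlap,
    refit_every = refit_every, try_k = try_k,
    mapping_fun = match.arg(mapping_fun)
  ), class = "map_params")
}

eff_eps <- function(params) if (params$error_correction) params$eps else 0
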