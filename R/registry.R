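#' The 92-feature registry
#'
#' Ordered catalogue of every feature the extractor computes: 13 first-order
#' intensity features, 22 morphological features (17 purely shape-based,
#' 5 uptake-geometry hybrids), and 57 textural features (26 GLCM, 16 GLSZM,
#' 15 GLRLM). Exactly 4 features are flagged conventional (SUVmax, SUVmean,
#' SUVpeak, ROI-volume) and exactly 75 use uptake information. The registry
#' is data-driven: pass `path` to load an alternative definition table (a
#' CSV with the same columns), e.g. to re-point the extractor at a revised
#' feature list without code changes.
#'
#' @param path optional CSV to read instead of the built-in registry. The
#'   canonical table also ships as
#'   `system.file("extdata", "feature_registry.csv", package = "datradiomics")`.
#' @return data.frame with columns `name`, `category`
#'   (first_order/morphological/textural), `subfamily` (GLCM/GLSZM/GLRLM or
#'   ""), `uses_uptake`, `is_conventional`.
#' @export
feature_registry <- function(path = NULL) {
  if (!is.null(path)) {
    reg <- utils::read.csv(path, stringsAsFactors = FALSE)
    reg$uses_uptake <- as.logical(reg$uses_uptake)
    reg$is_conventional <- as.logical(reg$is_conventional)
    return(validate_registry(reg))
  }
  fo <- c("fo_suv_max", "fo_suv_mean", "fo_suv_peak", "fo_min", "fo_median",
          "fo_sd", "fo_skewness", "fo_kurtosis", "fo_energy", "fo_entropy",
          "fo_cov", "fo_p10", "fo_p90")
  morph_shape <- c("morph_volume_mm3", "morph_surface_area_mm2",
                   "morph_sphericity", "morph_compactness1",
                   "morph_compactness2", "morph_spherical_disproportion",
                   "morph_max_diameter_mm", "morph_major_axis_mm",
                   "morph_minor_axis_mm", "morph_least_axis_mm",
                   "morph_elongation", "morph_flatness",
                   "morph_surface_to_volume", "morph_extent",
                   "morph_solidity", "morph_bbox_volume_mm3",
                   "morph_centroid_surface_dist_mm")
  morph_hybrid <- c("morph_iw_centroid_shift_mm", "morph_v50_mm3",
                    "morph_v50_fraction", "morph_uptake_asymmetry",
                    "morph_radial_gradient")
  glcm <- c("glcm_joint_max", "glcm_joint_average", "glcm_joint_variance",
            "glcm_joint_entropy", "glcm_diff_average", "glcm_diff_variance",
            "glcm_diff_entropy", "glcm_sum_average", "glcm_sum_variance",
            "glcm_sum_entropy", "glcm_energy", "glcm_contrast",
            "glcm_dissimilarity", "glcm_inverse_difference",
            "glcm_inverse_difference_norm", "glcm_idm", "glcm_idm_norm",
            "glcm_inverse_variance", "glcm_correlation",
            "glcm_autocorrelation", "glcm_cluster_tendency",
            "glcm_cluster_shade", "glcm_cluster_prominence",
            "glcm_imc1", "glcm_imc2", "glcm_mcc")
  glszm <- c("glszm_sze", "glszm_lze", "glszm_gln", "glszm_gln_norm",
             "glszm_zsn", "glszm_zsn_norm", "glszm_zone_percentage",
             "glszm_lgze", "glszm_hgze", "glszm_szlge", "glszm_szhge",
             "glszm_lzlge", "glszm_lzhge", "glszm_gl_variance",
             "glszm_zs_variance", "glszm_zs_entropy")
  glrlm <- c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln",
             "glrlm_rln_norm", "glrlm_rp", "glrlm_lgre", "glrlm_hgre",
             "glrlm_srlge", "glrlm_srhge", "glrlm_lrlge", "glrlm_lrhge",
             "glrlm_gl_variance", "glrlm_rl_variance", "glrlm_run_entropy")
  reg <- data.frame(
    name = c(fo, morph_shape, morph_hybrid, glcm, glszm, glrlm),
    category = c(rep("first_order", length(fo)),
                 rep("morphological", length(morph_shape) + length(morph_hybrid)),
                 rep("textural", length(glcm) + length(glszm) + length(glrlm))),
    subfamily = c(rep("", length(fo) + 22L),
                  rep("GLCM", length(glcm)), rep("GLSZM", length(glszm)),
                  rep("GLRLM", length(glrlm))),
    uses_uptake = c(rep(TRUE, length(fo)),
                    rep(FALSE, length(morph_shape)),
                    rep(TRUE, length(morph_hybrid)),
                    rep(TRUE, length(glcm) + length(glszm) + length(glrlm))),
    is_conventional = FALSE,
    stringsAsFactors = FALSE
  )
  reg$is_conventional[reg$name %in% c("fo_suv_max", "fo_suv_mean",
                                      "fo_suv_peak", "morph_volume_mm3")] <- TRUE
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(nrow(reg) == 92L,
            sum(reg$category == "first_order") == 13L,
            sum(reg$category == "morphological") == 22L,
            sum(reg$category == "textural") == 57L,
            sum(reg$subfamily == "GLCM") == 26L,
            sum(reg$subfamily == "GLSZM") == 16L,
            sum(reg$subfamily == "GLRLM") == 15L,
            sum(reg$uses_uptake) == 75L,
            sum(!reg$uses_uptake) == 17L,
            sum(reg$is_conventional) == 4L,
            !anyDuplicated(reg$name))
  reg
}

#' Write the registry as the versioned CSV shipped with the package
#' @param path output CSV path.
#' @keywords internal
write_feature_registry <- function(path) {
  utils::write.csv(feature_registry(), path, row.names = FALSE)
  invisible(path)
}
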