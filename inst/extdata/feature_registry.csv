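"name","category","subfamily","uses_uptake","is_conventional"
"fo_suv_max","first_order","",TRUE,TRUE
"fo_suv_mean","first_order","",TRUE,TRUE
"fo_suv_peak","first_order","",TRUE,TRUE
"fo_min","first_order","",TRUE,FALSE
"fo_median","first_order","",TRUE,FALSE
"fo_sd","first_order","",TRUE,FALSE
"fo_skewness","first_order","",TRUE,FALSE
"fo_kurtosis","first_order","",TRUE,FALSE
"fo_energy","first_order","",TRUE,FALSE
"fo_entropy","first_order","",TRUE,FALSE
"fo_cov","first_order","",TRUE,FALSE
"fo_p10","first_order","",TRUE,FALSE
"fo_p90","first_order","",TRUE,FALSE
"morph_volume_mm3","morphological","",FALSE,TRUE
"morph_surface_area_mm2","morphological","",FALSE,FALSE
"morph_sphericity","morphological","",FALSE,FALSE
"morph_compactness1","morphological","",FALSE,FALSE
"morph_compactness2","morphological","",FALSE,FALSE
"morph_spherical_disproportion","morphological","",FALSE,FALSE
"morph_max_diameter_mm","morphological","",FALSE,FALSE
"morph_major_axis_mm","morphological","",FALSE,FALSE
"morph_minor_axis_mm","morphological","",FALSE,FALSE
"morph_least_axis_mm","morphological","",FALSE,FALSE
"morph_elongation","morphological","",FALSE,FALSE
"morph_flatness","morphological","",FALSE,FALSE
"morph_surface_to_volume","morphological","",FALSE,FALSE
"morph_extent","morphological","",FALSE,FALSE
"morph_solidity","morphological","",FALSE,FALSE
"morph_bbox_volume_mm3","morphological","",FALSE,FALSE
"morph_centroid_surface_dist_mm","morphological","",FALSE,FALSE
"morph_iw_centroid_shift_mm","morphological","",TRUE,FALSE
"morph_v50_mm3","morphological","",TRUE,FALSE
"morph_v50_fraction","morphological","",TRUE,FALSE
"morph_uptake_asymmetry","morphological","",TRUE,FALSE
"morph_radial_gradient","morphological","",TRUE,FALSE
"glcm_joint_max","textural","GLCM",TRUE,FALSE
"glcm_joint_average","textural","GLCM",TRUE,FALSE
"glcm_joint_variance","textural","GLCM",TRUE,FALSE
"glcm_joint_entropy","textural","GLCM",TRUE,FALSE
"glcm_diff_average","textural","GLCM",TRUE,FALSE
"glcm_diff_variance","textural","GLCM",TRUE,FALSE
"glcm_diff_entropy","textural","GLCM",TRUE,FALSE
"glcm_sum_average","textural","GLCM",TRUE,FALSE
"glcm_sum_variance","textural","GLCM",TRUE,FALSE
"glcm_sum_entropy","textural","GLCM",TRUE,FALSE
"glcm_energy","textural","GLCM",TRUE,FALSE
"glcm_contrast","textural","GLCM",TRUE,FALSE
"glcm_dissimilarity","textural","GLCM",TRUE,FALSE
"glcm_inverse_difference","textural","GLCM",TRUE,FALSE
"glcm_inverse_difference_norm","textural","GLCM",TRUE,FALSE
"glcm_idm","textural","GLCM",TRUE,FALSE
"glcm_idm_norm","textural","GLCM",TRUE,FALSE
"glcm_inverse_variance","textural","GLCM",TRUE,FALSE
"glcm_correlation","textural","GLCM",TRUE,FALSE
"glcm_autocorrelation","textural","GLCM",TRUE,FALSE
"glcm_cluster_tendency","textural","GLCM",TRUE,FALSE
"glcm_cluster_shade","textural","GLCM",TRUE,FALSE
"glcm_cluster_prominence","textural","GLCM",TRUE,FALSE
"glcm_imc1","textural","GLCM",TRUE,FALSE
"glcm_imc2","textural","GLCM",TRUE,FALSE
"glcm_mcc","textural","GLCM",TRUE,FALSE
"glszm_sze","textural","GLSZM",TRUE,FALSE
"glszm_lze","textural","GLSZM",TRUE,FALSE
"glszm_gln","textural","GLSZM",TRUE,FALSE
"glszm_gln_norm","textural","GLSZM",TRUE,FALSE
"glszm_zsn","textural","GLSZM",TRUE,FALSE
"glszm_zsn_norm","textural","GLSZM",TRUE,FALSE
"glszm_zone_percentage","textural","GLSZM",TRUE,FALSE
"glszm_lgze","textural","GLSZM",TRUE,FALSE
"glszm_hgze","textural","GLSZM",TRUE,FALSE
"glszm_szlge","textural","GLSZM",TRUE,FALSE
"glszm_szhge","textural","GLSZM",TRUE,FALSE
"glszm_lzlge","textural","GLSZM",TRUE,FALSE
"glszm_lzhge","textural","GLSZM",TRUE,FALSE
"glszm_gl_variance","textural","GLSZM",TRUE,FALSE
"glszm_zs_variance","textural","GLSZM",TRUE,FALSE
"glszm_zs_entropy","textural","GLSZM",TRUE,FALSE
"glrlm_sre","textural","GLRLM",TRUE,FALSE
"glrlm_lre","textural","GLRLM",TRUE,FALSE
"glrlm_gln","textural","GLRLM",TRUE,FALSE
"glrlm_rln","textural","GLRLM",TRUE,FALSE
"glrlm_rln_norm","textural","GLRLM",TRUE,FALSE
"glrlm_rp","textural","GLRLM",TRUE,FALSE
"glrlm_lgre","textural","GLRLM",TRUE,FALSE
"glrlm_hgre","textural","GLRLM",TRUE,FALSE
"glrlm_srlge","textural","GLRLM",TRUE,FALSE
"glrlm_srhge","textural","GLRLM",TRUE,FALSE
"glrlm_lrlge","textural","GLRLM",TRUE,FALSE
"glrlm_lrhge","textural","GLRLM",TRUE,FALSE
"glrlm_gl_variance","textural","GLRLM",TRUE,FALSE
"glrlm_rl_variance","textural","GLRLM",TRUE,FALSE
"glrlm_run_entropy","textural","GLRLM",TRUE,FALSE
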