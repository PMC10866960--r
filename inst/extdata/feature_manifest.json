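{
  "manifest_version": "1.0",
  "n_levels_default": 32,
  "directions": ["d0", "d45", "d90", "d135", "avg"],
  "first_order": [
    "mean", "median", "minimum", "maximum", "range", "variance", "std_dev",
    "skewness", "kurtosis", "energy", "entropy", "uniformity", "p10", "p90",
    "iqr", "mad", "rmad", "rms", "cv", "total_intensity"
  ],
  "glcm": [
    "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "joint_energy",
    "joint_entropy", "idm", "id", "inverse_variance", "maximum_probability",
    "sum_average", "sum_entropy", "sum_squares", "imc1"
  ],
  "glrlm": [
    "sre", "lre", "gln", "rln", "rp", "lglre", "hglre",
    "srlgle", "srhgle", "lrlgle", "lrhgle"
  ],
  "shape": [
    "volume", "n_voxels", "surface_area", "surface_to_volume", "sphericity",
    "compactness1", "compactness2", "spherical_disproportion",
    "max_3d_diameter", "max_2d_diameter_axial", "max_2d_diameter_coronal",
    "max_2d_diameter_sagittal", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness", "bbox_dim_x", "bbox_dim_y",
    "bbox_dim_z", "bbox_volume", "extent", "equiv_sphere_diameter",
    "radius_of_gyration"
  ]
}
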