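#' implantsize: dental implant size classification from radiographic key points
#'
#' Pipeline for classifying bone level dental implants into nine catalogue
#' sizes from three key points annotated on periapical radiographs:
#' annotation and metadata I/O ([read_labelme()], [read_pixel_spacing()],
#' [stratified_split()]), key-point geometry ([extract_feature()]), the
#' diameter-weighted k-means++ classifier ([fit_size_model()],
#' [tune_weight()], [predict.size_km()]), one-vs-rest evaluation
#' ([metrics_table()], [auc_ci_delong()], [compare_before_after()]), a
#' synthetic annotation generator ([sim_config()], [generate_dataset()])
#' and a command-line interface ([cli_main()]).
#'
#' @keywords internal
#' @importFrom stats var rnorm runif setNames chisq.test
#' @importFrom utils read.csv packageVersion
"_PACKAGE"

utils::globalVariables(c("D_mm", "L_mm"))
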