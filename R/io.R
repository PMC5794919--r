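# Serialization: NIfTI for image volumes (voxel size in the header), CSV
# for age-estimate tables and reports, YAML for study configurations.
# Round trips are lossless (full-precision CSV; shortest-roundtrip YAML).

#' Write an image volume as NIfTI
#'
#' Voxel size goes into the header `pixdim`; the provenance label into
#' `descrip`.
#'
#' @param image An `image_volume` (magnitude written).
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_image_nifti <- function(image, file) {
  stopifnot(inherits(image, "image_volume"))
  img <- RNifti::asNifti(Mod(image$values))
  RNifti::pixdim(img) <- image$voxel_size
  img <- RNifti::asNifti(img, descrip = image$provenance)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read an image volume from NIfTI
#'
#' @param file NIfTI path written by [write_image_nifti()].
#' @return An `image_volume` (provenance restored from `descrip` when it
#'   matches a known label, otherwise `"ground-truth"`).
#' @export
read_image_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  vs <- RNifti::pixdim(img)[1:3]
  prov <- RNifti::niftiHeader(img)$descrip
  known <- c("ground-truth", "zero-filled", "tgv", "acquired-sim")
  if (!prov %in% known) prov <- "ground-truth"
  vals <- array(as.numeric(img), dim = dim(img))
  image_volume(vals, voxel_size = vs, provenance = prov)
}

#' Write / read the age-estimate table as CSV
#'
#' Header `subject,rater,condition,age`; ages at full double precision so
#' the round trip is exact.
#'
#' @param table An [age_estimate_table()].
#' @param file CSV path.
#' @return `file` invisibly / the table.
#' @export
write_age_table <- function(table, file) {
  table <- age_estimate_table(table)
  tw <- table
  tw$age <- sprintf("%.17g", tw$age)
  utils::write.csv(tw, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_age_table
#' @export
read_age_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$age <- as.numeric(df$age)
  age_estimate_table(df)
}

#' Write / read a study configuration as YAML
#'
#' `NULL` entries (auto-selected regularization weights, no output
#' directory) are stored as `"auto"` / omitted and restored on read; the
#' round trip reproduces the configuration exactly.
#'
#' @param config A [study_config()].
#' @param file YAML path.
#' @return `file` invisibly / the `study_config`.
#' @export
write_study_config <- function(config, file) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$recon <- unclass(x$recon)
  x$recon$alpha1 <- if (is.null(x$recon$alpha1)) "auto" else x$recon$alpha1
  x$recon$alpha0 <- if (is.null(x$recon$alpha0)) "auto" else x$recon$alpha0
  x$output_dir <- if (is.null(x$output_dir)) "none" else x$output_dir
  x$af_ladder <- lapply(seq_len(nrow(config$af_ladder)), function(i)
    as.list(config$af_ladder[i, ]))
  writeLines(yaml::as.yaml(x, precision = 17), file)
  invisible(file)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(file) {
  x <- yaml::read_yaml(file)
  lad <- do.call(rbind, lapply(x$af_ladder, as.data.frame))
  lad$R1 <- as.integer(lad$R1); lad$R2 <- as.integer(lad$R2)
  lad$shift <- as.integer(lad$shift); lad$t_acq <- as.integer(lad$t_acq)
  a1 <- if (identical(x$recon$alpha1, "auto")) NULL else x$recon$alpha1
  a0 <- if (identical(x$recon$alpha0, "auto")) NULL else x$recon$alpha0
  study_config(n_subjects = x$n_subjects, age_range = x$age_range,
               af_ladder = lad, noise_sigma = x$noise_sigma,
               grid_shape = x$grid_shape, voxel_size = x$voxel_size,
               n_bones = x$n_bones, n_coils = x$n_coils,
               n_virtual = x$n_virtual, n_calib = x$n_calib,
               recon = recon_config(lambda_data = x$recon$lambda_data,
                                    alpha1 = a1, alpha0 = a0,
                                    n_iter = x$recon$n_iter,
                                    check_every = x$recon$check_every,
                                    tol = x$recon$tol,
                                    cg_warmup = x$recon$cg_warmup,
                                    step_ratio = x$recon$step_ratio),
               seed = x$seed,
               output_dir = if (identical(x$output_dir, "none")) NULL
                            else x$output_dir)
}

#' Write a reliability report as CSV + JSON
#'
#' Emits `<stem>_per_condition.csv`, `<stem>_inter_rater.csv`, and
#' `<stem>.json` with both blocks.
#'
#' @param report A `reliability_report`.
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "reliability_report"))
  utils::write.csv(report$per_condition,
                   paste0(stem, "_per_condition.csv"), row.names = FALSE)
  if (!is.null(report$inter_rater))
    utils::write.csv(report$inter_rater,
                     paste0(stem, "_inter_rater.csv"), row.names = FALSE)
  jsonlite::write_json(list(per_condition = report$per_condition,
                            inter_rater = report$inter_rater,
                            reference = report$reference,
                            pooling = report$pooling),
                       paste0(stem, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
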