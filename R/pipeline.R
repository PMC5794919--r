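# Orchestration of the full synthetic study: per subject, phantom ->
# k-space -> per-AF CAIPIRINHA masking -> coil compression -> ESPIRiT ->
# TGV reconstruction -> proxy age measurements; then the reliability
# report over the resulting age-estimate table.

#' Study configuration
#'
#' Defaults emulate the reference cohort at desk scale: 15 subjects with
#' ages uniform over 13.77-23.15 years, the six-step acceleration ladder,
#' a 64 x 64 x 16 grid with six ossification sites, 8 physical coils
#' compressed to 4 virtual coils, 12 calibration lines, and complex noise
#' of SD 0.02 on the unit intensity scale.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param age_range Years, `c(min, max)` (default `c(13.77, 23.15)`).
#' @param af_ladder data.frame as from [af_ladder()] (columns `condition`,
#'   `AF`, `R1`, `R2`, `shift`, `t_acq`).
#' @param noise_sigma Complex k-space noise SD (default 0.02).
#' @param grid_shape,voxel_size Phantom grid (defaults 64 x 64 x 16 at
#'   0.45 x 0.45 x 0.90 mm).
#' @param n_bones Ossification sites per subject (default 6).
#' @param n_coils Physical receive coils (default 8).
#' @param n_virtual Virtual coils after compression (default 4).
#' @param n_calib Calibration lines per phase-encode axis (default 12).
#' @param recon A [recon_config()]; the default runs 100 primal-dual
#'   iterations with early stopping at relative change 1e-5.
#' @param seed Master seed; per-subject seeds are derived as
#'   `(seed * 10007 + 13 * subject) mod (2^31 - 1)` so no stage consumes
#'   global random state.
#' @param output_dir Optional directory for stage artifacts (NIfTI
#'   volumes, CSV tables, YAML config). `NULL` keeps everything in memory.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 15L,
                         age_range = c(13.77, 23.15),
                         af_ladder = agesim::af_ladder(),
                         noise_sigma = 0.02,
                         grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.45, 0.45, 0.90),
                         n_bones = 6L,
                         n_coils = 8L,
                         n_virtual = 4L,
                         n_calib = 12L,
                         recon = recon_config(n_iter = 100L,
                                              check_every = 20L,
                                              tol = 1e-5),
                         seed = 1L,
                         output_dir = NULL) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (any(af_ladder$AF < 1)) stop("acceleration factors must be >= 1")
  row.names(af_ladder) <- NULL
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = age_range, af_ladder = af_ladder,
                 noise_sigma = noise_sigma,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_bones = as.integer(n_bones),
                 n_coils = as.integer(n_coils),
                 n_virtual = as.integer(n_virtual),
                 n_calib = as.integer(n_calib), recon = recon,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

subject_seed <- function(master, s) {
  as.integer((as.double(master) * 10007 + 13 * s) %% 2147483647)
}

#' Run the full synthetic acceleration study
#'
#' For each subject: draw an age, build the phantom and coil maps,
#' simulate noisy multi-coil k-space once, compress coils and estimate
#' ESPIRiT maps from the (always fully sampled) calibration block, then
#' for every rung of the acceleration ladder retrospectively mask the same
#' k-space and reconstruct with TGV. The fully sampled coil-combined
#' reconstruction serves as the `orig` condition. Gap widths are measured
#' on every reconstruction and converted to a continuous proxy age
#' (`proxy_cont`) and its Greulich-Pyle-style quantization (`proxy_gp`).
#'
#' @param config A [study_config()].
#' @param verbose Print per-subject progress (default FALSE).
#' @return List with `table` (the [age_estimate_table()]), `report`
#'   (from [build_report()]), `nrmse` (per subject x condition NRMSE of
#'   the reconstruction against the fully sampled one), `failures`
#'   (data.frame of aborted subjects, if any), and `config`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  gs <- config$grid_shape
  full <- caipirinha_pattern(gs[2:3], 1L, 1L, 0L, config$n_calib,
                             AF_nominal = 1)
  rows <- list(); nrmse_rows <- list(); failures <- list()
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  for (s in seq_len(config$n_subjects)) {
    sseed <- subject_seed(config$seed, s)
    res <- tryCatch({
      age <- with_seed(sseed, stats::runif(1, config$age_range[1],
                                           config$age_range[2]))
      spec <- phantom_spec(age, grid_shape = gs,
                           voxel_size = config$voxel_size,
                           n_bones = config$n_bones,
                           noise_sigma = config$noise_sigma, seed = sseed)
      ph <- make_hand_phantom(spec)
      sites <- attr(ph, "sites")
      maps_true <- make_coil_maps(config$n_coils, gs, config$voxel_size,
                                  seed = sseed + 1L)
      ks <- simulate_kspace(ph, maps_true, config$noise_sigma,
                            seed = sseed + 2L)
      comp <- compress_coils(ks, config$n_virtual, full)
      calib <- extract_calibration(comp$kspace, full)
      maps <- estimate_sensitivities(calib, gs,
                                     voxel_size = config$voxel_size)
      orig <- zero_filled_recon(comp$kspace, maps, full)
      w0 <- measure_gap_widths(orig, sites)
      subj_rows <- list(
        data.frame(subject = s, rater = "proxy_cont", condition = "orig",
                   age = gaps_to_age(w0, spec$fusion_age)),
        data.frame(subject = s, rater = "proxy_gp", condition = "orig",
                   age = gp_quantize(gaps_to_age(w0, spec$fusion_age))))
      subj_nrmse <- list()
      for (i in seq_len(nrow(config$af_ladder))) {
        lad <- config$af_ladder[i, ]
        pat <- caipirinha_pattern(gs[2:3], lad$R1, lad$R2, lad$shift,
                                  config$n_calib, AF_nominal = lad$AF)
        ku <- apply_pattern(comp$kspace, pat)
        # AF 1 means no lines are dropped: the "accelerated" acquisition is
        # the original one and gets the same standard reconstruction
        rec <- if (lad$R1 == 1L && lad$R2 == 1L)
          zero_filled_recon(ku, maps, pat)
        else tgv2_reconstruct(ku, maps, pat, config$recon)
        wi <- measure_gap_widths(rec, sites)
        est <- gaps_to_age(wi, spec$fusion_age)
        subj_rows <- c(subj_rows, list(
          data.frame(subject = s, rater = "proxy_cont",
                     condition = lad$condition, age = est),
          data.frame(subject = s, rater = "proxy_gp",
                     condition = lad$condition, age = gp_quantize(est))))
        subj_nrmse <- c(subj_nrmse, list(
          data.frame(subject = s, condition = lad$condition, AF = lad$AF,
                     nrmse = image_quality(rec, orig)$nrmse)))
        if (!is.null(out_dir))
          write_image_nifti(rec, file.path(out_dir,
            sprintf("subject%02d_%s_tgv.nii.gz", s, lad$condition)))
      }
      if (!is.null(out_dir))
        write_image_nifti(orig, file.path(out_dir,
          sprintf("subject%02d_orig.nii.gz", s)))
      list(rows = subj_rows, nrmse = subj_nrmse)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(subject = s, error = conditionMessage(res))
      if (verbose) message(sprintf("subject %d failed: %s", s,
                                   conditionMessage(res)))
      next
    }
    rows <- c(rows, res$rows)
    nrmse_rows <- c(nrmse_rows, res$nrmse)
    if (verbose) message(sprintf("subject %d/%d done", s,
                                 config$n_subjects))
  }
  if (length(rows) == 0) stop("every subject failed")
  table <- age_estimate_table(do.call(rbind, rows))
  report <- build_report(table)
  nrmse <- do.call(rbind, nrmse_rows)
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  if (!is.null(out_dir)) {
    write_age_table(table, file.path(out_dir, "age_estimates.csv"))
    write_study_config(config, file.path(out_dir, "study_config.yaml"))
    write_report(report, file.path(out_dir, "reliability_report"))
  }
  list(table = table, report = report, nrmse = nrmse,
       failures = failures, config = config)
}

#' Retrospective vs freshly simulated acquisition consistency check
#'
#' Reconstructs the same phantom twice with an identical undersampling
#' pattern: once from retrospectively masked data (noise realization A)
#' and once from an independently simulated "acquired" data set with
#' fresh noise (realization B). Both arms run the identical compression /
#' sensitivity / TGV pipeline; reported are the two NRMSEs against the
#' noiseless ground truth and their difference. With `noise_seed_b` equal
#' to `noise_seed_a` the two arms are identical by construction.
#'
#' @param config A [study_config()] (the first ladder entry with
#'   `af_index` selects the pattern).
#' @param subject Subject index (drives the subject seed).
#' @param af_index Row of `config$af_ladder` to use (default 2).
#' @param noise_seed_a,noise_seed_b Seeds of the two noise realizations.
#' @return List with `nrmse_retro`, `nrmse_acquired`, `difference`, and
#'   the two `quality_metrics` objects.
#' @export
simulate_vs_matched_pattern_check <- function(config = study_config(),
                                              subject = 1L, af_index = 2L,
                                              noise_seed_a = 101L,
                                              noise_seed_b = 202L) {
  gs <- config$grid_shape
  sseed <- subject_seed(config$seed, subject)
  age <- with_seed(sseed, stats::runif(1, config$age_range[1],
                                       config$age_range[2]))
  spec <- phantom_spec(age, grid_shape = gs, voxel_size = config$voxel_size,
                       n_bones = config$n_bones,
                       noise_sigma = config$noise_sigma, seed = sseed)
  ph <- make_hand_phantom(spec)
  maps_true <- make_coil_maps(config$n_coils, gs, config$voxel_size,
                              seed = sseed + 1L)
  lad <- config$af_ladder[af_index, ]
  pat <- caipirinha_pattern(gs[2:3], lad$R1, lad$R2, lad$shift,
                            config$n_calib, AF_nominal = lad$AF)
  full <- caipirinha_pattern(gs[2:3], 1L, 1L, 0L, config$n_calib,
                             AF_nominal = 1)
  recon_arm <- function(noise_seed) {
    ks <- simulate_kspace(ph, maps_true, config$noise_sigma,
                          seed = noise_seed)
    ku <- apply_pattern(ks, pat)
    comp <- compress_coils(ku, config$n_virtual, pat)
    calib <- extract_calibration(comp$kspace, pat)
    maps <- estimate_sensitivities(calib, gs,
                                   voxel_size = config$voxel_size)
    rec <- tgv2_reconstruct(comp$kspace, maps, pat, config$recon)
    image_quality(rec, ph)
  }
  qa <- recon_arm(noise_seed_a)
  qb <- recon_arm(noise_seed_b)
  list(nrmse_retro = qa$nrmse, nrmse_acquired = qb$nrmse,
       difference = qa$nrmse - qb$nrmse, metrics_retro = qa,
       metrics_acquired = qb)
}
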