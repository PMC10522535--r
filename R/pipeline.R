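# End-to-end pipeline: simulate -> preprocess -> travelling-wave analysis
# -> pRF fitting -> evaluation -> coverage -> ROI report.
#
# Driven by a YAML (or list) configuration; every stage writes its outputs
# as TSV under the run directory and a manifest records the seed,
# thresholds and package version. All randomness is owned by the config
# seed, so a given config reproduces byte-identical tables.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master random seed.
#' @param nx,ny Patch lattice size.
#' @param n_subjects Number of simulated subjects.
#' @param families Model families to fit.
#' @param run_spec Per-paradigm run counts (see [simulation_config()]).
#' @param noise_sd,ar1,drift_amplitude Noise model (see
#'   [simulation_config()]).
#' @param coherence_threshold Travelling-wave coherence threshold used to
#'   restrict the fitted voxel set (the study convention is 0.3).
#' @param r2_threshold Adjusted r-squared threshold for map outputs.
#' @param p_threshold Corrected p-value threshold for travelling-wave maps.
#' @param restrict_to_tw_roi Fit only voxels above the coherence threshold.
#' @return Configuration list.
#' @export
pipeline_config <- function(seed = 1L, nx = 12L, ny = 12L, n_subjects = 1L,
                            families = PRF_FAMILIES,
                            run_spec = list(
                              between = c(forward = 1L, reverse = 1L),
                              within = c(forward = 1L, reverse = 1L),
                              diagonal = c(forward = 1L, reverse = 0L)),
                            noise_sd = 2, ar1 = 0, drift_amplitude = 0,
                            coherence_threshold = 0.3, r2_threshold = 0,
                            p_threshold = 0.05,
                            restrict_to_tw_roi = FALSE) {
  list(seed = seed, nx = nx, ny = ny, n_subjects = n_subjects,
       families = families, run_spec = run_spec, noise_sd = noise_sd,
       ar1 = ar1, drift_amplitude = drift_amplitude,
       coherence_threshold = coherence_threshold,
       r2_threshold = r2_threshold, p_threshold = p_threshold,
       restrict_to_tw_roi = restrict_to_tw_roi)
}

#' Run the full synthetic pRF pipeline
#'
#' Simulates a session, preprocesses it, runs the travelling-wave analysis
#' for the between- and within-digit paradigms, fits the requested pRF
#' families, compares pRF and travelling-wave label maps (Dice) and the
#' families against each other (AIC preference), builds per-area coverage
#' maps for the 2D Gaussian family, aggregates pRF sizes over ROIs, and
#' scores parameter recovery against the ground truth. Each stage's tables
#' land in `out_dir`; a failure stops with a stage-named error while
#' preserving the artefacts written so far.
#'
#' @param config A [pipeline_config()] list or path to a YAML file with the
#'   same fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`truth`,
#'   `fits`, `tw_between`, `tw_within`, `dice`, `aic_preference`,
#'   `recovery`, `sizes`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.list(config$run_spec)) {
    config$run_spec <- lapply(config$run_spec, unlist)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate --------------------------------------------------------------
  sim <- stage("simulate", {
    patch <- generate_patch(nx = config$nx, ny = config$ny,
                            n_subjects = config$n_subjects,
                            seed = config$seed)
    sc <- simulation_config(run_spec = config$run_spec,
                            noise_sd = config$noise_sd, ar1 = config$ar1,
                            drift_amplitude = config$drift_amplitude,
                            seed = config$seed + 1L)
    s <- simulate_session(patch, sc)
    write_tsv(patch, file.path(out_dir, "truth.tsv"))
    write_stim_tsv(s$seq, file.path(out_dir, "stimulus.tsv"))
    s
  })

  # -- preprocess ------------------------------------------------------------
  Ypsc <- stage("preprocess", {
    preprocess_timeseries(sim$Y, tr = sim$seq$tr, runs = sim$seq$runs)
  })

  # -- travelling wave -------------------------------------------------------
  tw <- stage("tw", {
    out <- list(between = tw_analysis(Ypsc, sim$seq, "between"),
                within = tw_analysis(Ypsc, sim$seq, "within"))
    write_tsv(out$between, file.path(out_dir, "tw_between.tsv"))
    write_tsv(out$within, file.path(out_dir, "tw_within.tsv"))
    out
  })

  # -- fit -------------------------------------------------------------------
  fits <- stage("fit", {
    vox <- seq_len(ncol(Ypsc))
    if (isTRUE(config$restrict_to_tw_roi)) {
      coh <- pmax(tw$between$coherence, tw$within$coherence)
      vox <- vox[coh > config$coherence_threshold]
      if (length(vox) == 0) stop("no voxels above the coherence threshold")
    }
    ft <- fit_patch(Ypsc[, vox, drop = FALSE], families = config$families,
                    seq = sim$seq, voxel_ids = vox)
    write_tsv(ft, file.path(out_dir, "fits.tsv"))
    ft
  })

  # -- evaluate --------------------------------------------------------------
  eval_out <- stage("evaluate", {
    dice <- list()
    for (fam in config$families) {
      sub <- fits[fits$family == fam, ]
      keep <- !is.na(sub$adjusted_r2) & sub$adjusted_r2 > config$r2_threshold
      sub <- sub[keep, ]
      twd <- tw$between$label[sub$voxel]
      twp <- tw$within$label[sub$voxel]
      dice[[fam]] <- list(
        digit = dice_matrix(twd, location_to_label(sub$pref_digit)),
        pd = dice_matrix(twp, location_to_label(sub$pref_pd)))
      write_tsv(as.data.frame(dice[[fam]]$digit),
                file.path(out_dir, paste0("dice_digit_", fam, ".tsv")))
    }
    pref <- if (length(config$families) > 1L) {
      m <- aic_preference_matrix(fits)
      write_tsv(as.data.frame(m), file.path(out_dir, "aic_preference.tsv"))
      m
    } else NULL
    list(dice = dice, aic_preference = pref)
  })

  # -- coverage --------------------------------------------------------------
  coverage <- stage("coverage", {
    if (!"gaussian2d" %in% config$families) return(NULL)
    pmat <- attr(fits, "params")[["gaussian2d"]]
    sub <- fits[fits$family == "gaussian2d", ]
    truth_rows <- match(sub$voxel, sim$truth$voxel)
    areas <- sim$truth$area[truth_rows]
    subj <- sim$truth$subject[truth_rows]
    widths <- list()
    for (a in unique(areas)) {
      sel <- which(areas == a)
      if (length(sel) < 4L) next
      maps <- coverage_from_params(pmat[sel, , drop = FALSE], "gaussian2d")
      avg <- pca_average(maps, subject_ids = subj[sel])
      aligned <- suppressWarnings(peak_align(maps, axis = "both"))
      widths[[a]] <- data.frame(area = a, t(coverage_width(aligned)),
                                t(coverage_width(avg$average)))
    }
    wtab <- do.call(rbind, widths)
    if (!is.null(wtab)) {
      names(wtab) <- c("area", "aligned_width_digit", "aligned_width_pd",
                       "avg_width_digit", "avg_width_pd")
      write_tsv(wtab, file.path(out_dir, "coverage_widths.tsv"))
    }
    wtab
  })

  # -- report ----------------------------------------------------------------
  report <- stage("report", {
    labels <- roi_labels(sim$truth$voxel, sim$truth$subject,
                         sim$truth$digit, sim$truth$pd, sim$truth$area)
    fam0 <- intersect("gaussian2d", config$families)
    sizes <- recovery <- NULL
    if (length(fam0)) {
      f2 <- fits[fits$family == "gaussian2d", ]
      sizes <- suppressWarnings(aggregate_prf_size(f2, labels,
                                                   scheme = "area"))
      write_tsv(sizes$by_roi, file.path(out_dir, "roi_sizes.tsv"))
      recovery <- score_recovery(sim$truth, f2)
      write_tsv(recovery$per_parameter,
                file.path(out_dir, "recovery.tsv"))
    }
    manifest <- list(
      package = "somatoprf",
      version = as.character(utils::packageVersion("somatoprf")),
      seed = config$seed,
      thresholds = list(adjusted_r2 = config$r2_threshold,
                        coherence = config$coherence_threshold,
                        p_corrected = config$p_threshold),
      families = config$families,
      patch = list(nx = config$nx, ny = config$ny,
                   n_subjects = config$n_subjects),
      n_volumes = nrow(sim$Y)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(sizes = sizes, recovery = recovery, manifest = manifest)
  })

  invisible(list(truth = sim$truth, fits = fits, tw_between = tw$between,
                 tw_within = tw$within, dice = eval_out$dice,
                 aic_preference = eval_out$aic_preference,
                 coverage_widths = coverage, sizes = report$sizes,
                 recovery = report$recovery, manifest = report$manifest))
}

#' Write a voxel map as a NIfTI volume
#'
#' Thin optional wrapper (requires the RNifti package) that reshapes a
#' per-voxel statistic back onto its lattice and writes a NIfTI file.
#'
#' @param values Per-voxel values (length `nx * ny`).
#' @param nx,ny Lattice dimensions.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, nx, ny, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI output")
  }
  vol <- array(values, dim = c(nx, ny, 1))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
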