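#' Read a diffusion-weighted volume with its gradient table
#'
#' Reads a 4-D NIfTI-1 volume together with FSL-style `bval` (1 x K)
#' and `bvec` (3 x K) whitespace-delimited text files. bvec columns are
#' normalized to unit length (zero columns, conventional at b = 0, are
#' accepted); entries with b < 10 s/mm^2 are treated as b = 0
#' references.
#'
#' @param dwi_path path to the 4-D NIfTI volume.
#' @param bval_path path to the bval text file.
#' @param bvec_path path to the bvec text file.
#' @return list with `image` (4-D array) and `scheme`
#'   ([gradient_scheme()]).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  for (p in c(dwi_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- tryCatch(RNifti::readNifti(dwi_path),
                  error = function(e) stop("unreadable NIfTI header/volume at ",
                                           dwi_path, ": ", conditionMessage(e)))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # plain array, no NIfTI baggage
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D volume, got ", length(dim(arr)), "-D at ", dwi_path)
  bvals <- tryCatch(scan(bval_path, quiet = TRUE),
                    error = function(e) stop("non-numeric gradient table at ",
                                             bval_path))
  bvecs <- tryCatch(matrix(scan(bvec_path, quiet = TRUE), nrow = 3,
                           byrow = TRUE),
                    error = function(e) stop("non-numeric gradient table at ",
                                             bvec_path))
  K <- dim(arr)[4]
  if (length(bvals) != K)
    stop("bval count (", length(bvals), ") does not match image volumes (",
         K, ")")
  if (ncol(bvecs) != K)
    stop("bvec count (", ncol(bvecs), ") does not match image volumes (",
         K, ")")
  dirs <- .normalize_rows(t(bvecs))
  list(image = arr, scheme = gradient_scheme(dirs, bvals))
}

#' Write a gradient scheme as FSL-style bval/bvec text files
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "dbsi_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Write a numeric array as a NIfTI-1 volume
#'
#' @param arr 3-D or 4-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel dimensions in mm.
#' @return invisibly, `path`.
#' @export
write_nifti_map <- function(arr, path, pixdim = c(0.0586, 0.0586, 1)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixdim, rep(1, length(dim(arr)) - 3L))[
    seq_len(length(dim(arr)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' One directory per nerve with the DWI volume, metric and whole-nerve
#' masks (NIfTI-1), plus shared bval/bvec files and the ground-truth
#' table as CSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scheme(cohort$scheme, file.path(dir, "cohort.bval"),
               file.path(dir, "cohort.bvec"))
  vd <- cohort$spec$voxel_dims
  for (nerve in cohort$nerves) {
    tag <- paste0(nerve$animal, "_", nerve$eye, "_day", nerve$day)
    write_nifti_map(nerve$dwi, file.path(dir, paste0(tag, "_dwi.nii.gz")), vd)
    write_nifti_map(nerve$mask_metric,
                    file.path(dir, paste0(tag, "_mask_metric.nii.gz")), vd)
    write_nifti_map(nerve$mask_whole,
                    file.path(dir, paste0(tag, "_mask_whole.nii.gz")), vd)
  }
  .write_stamped_csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                     seed = cohort$spec$seed)
  invisible(dir)
}

# deterministic config fingerprint: md5 of the deparsed object
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

# CSV with a provenance comment line; deterministic content
.write_stamped_csv <- function(df, path, seed = NA, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed ", seed,
                    if (!is.null(hash)) paste0(" config ", hash) else ""), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> per-voxel fit -> ROI metrics -> group
#' statistics, writing tidy and summary CSVs (stamped with the seed and
#' a configuration hash) plus a plain-text log to the output directory.
#' Re-running with the same configuration reproduces byte-identical
#' CSVs.
#'
#' The configuration is a named list (or the path of a YAML/JSON file)
#' with fields
#' * `mode`: `"invivo"` or `"exvivo"`;
#' * `seed`: integer master seed;
#' * `output_dir`: where results are written;
#' * `cohort`: simulation settings (`days`, `n_per_group`, `snr`,
#'   `voxel_dims`) -- or, alternatively, `paths` with `dwi`, `bval`,
#'   `bvec`, `mask` for fitting an existing volume;
#' * `fit`: optional [dbsi_fit_config()] overrides (`ridge_penalty`,
#'   `outer_grid_step`, `fiber_gate`);
#' * `write_maps`: write per-metric NIfTI maps (default FALSE for
#'   cohorts, TRUE for single volumes).
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return invisibly, a list with the output paths and the tidy metric
#'   table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  mode <- if (is.null(config$mode)) "invivo" else config$mode
  seed <- as.integer(config$seed)
  # validate referenced paths before any computation
  if (!is.null(config$paths)) {
    need <- c("dwi", "bval", "bvec", "mask")
    for (nm in need) {
      p <- config$paths[[nm]]
      if (is.null(p)) stop("config$paths$", nm, " is required")
      if (!file.exists(p)) stop("config$paths$", nm, " does not exist: ", p)
    }
  } else if (is.null(config$cohort)) {
    stop("config needs either a 'cohort' simulation block or input 'paths'")
  }
  hash <- .config_hash(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pipeline config hash ", hash, " seed ", seed, " mode ", mode)
  logf("note: group statistics use fixed-effects two-way ANOVA ",
       "(eyes treated as independent observations)")

  fit_args <- config$fit
  cfg <- do.call(dbsi_fit_config,
                 c(list(partition = partition_config(mode)),
                   fit_args[names(fit_args) %in%
                              setdiff(names(formals(dbsi_fit_config)),
                                      "partition")]))
  outputs <- list(log = log_path)

  if (!is.null(config$cohort)) {
    logf("stage simulate: cohort mode ", mode)
    cs_args <- config$cohort
    spec <- do.call(cohort_spec,
                    c(list(mode = mode, seed = seed),
                      cs_args[names(cs_args) %in% c("days", "n_per_group",
                                                    "snr", "voxel_dims")]))
    cohort <- tryCatch(simulate_cohort(spec), error = function(e)
      stop("stage simulate failed: ", conditionMessage(e)))
    logf("stage fit: ", length(cohort$nerves), " nerves")
    table <- tryCatch(summarize_cohort(cohort, cfg), error = function(e)
      stop("stage fit/roi failed: ", conditionMessage(e)))
    metrics_path <- file.path(out_dir, "metrics.csv")
    .write_stamped_csv(table, metrics_path, seed, hash)
    summary_path <- file.path(out_dir, "summary.csv")
    .write_stamped_csv(group_summary(table), summary_path, seed, hash)
    outputs$metrics <- metrics_path
    outputs$summary <- summary_path
    logf("stage stats")
    if (length(unique(table$day)) >= 2L) {
      stats <- do.call(rbind, lapply(unique(table$metric), function(m) {
        a <- two_way_anova(table, m)
        cbind(metric = m, a)
      }))
      stats_path <- file.path(out_dir, "anova.csv")
      .write_stamped_csv(stats, stats_path, seed, hash)
      outputs$anova <- stats_path
    }
    truth_path <- file.path(out_dir, "ground_truth.csv")
    .write_stamped_csv(cohort$truth, truth_path, seed, hash)
    outputs$truth <- truth_path
    outputs$table <- table
  } else {
    logf("stage read: ", config$paths$dwi)
    inp <- read_dwi(config$paths$dwi, config$paths$bval, config$paths$bvec)
    mask <- as.array(RNifti::readNifti(config$paths$mask))
    logf("stage fit: ", sum(mask > 0), " voxels")
    maps <- tryCatch(fit_volume(inp$image, inp$scheme, mask, cfg),
                     error = function(e)
                       stop("stage fit failed: ", conditionMessage(e)))
    write_maps <- if (is.null(config$write_maps)) TRUE else config$write_maps
    if (write_maps) {
      for (nm in names(maps)) {
        p <- file.path(out_dir, paste0("map_", nm, ".nii.gz"))
        write_nifti_map(maps[[nm]], p)
        outputs[[paste0("map_", nm)]] <- p
      }
    }
    roi <- roi_spec(mask, prod(RNifti::pixdim(RNifti::readNifti(
      config$paths$mask))[1:3]), "metric_roi")
    vals <- vapply(names(maps), function(nm) roi_mean(maps[[nm]], roi), 0)
    df <- data.frame(metric = names(vals), value = unname(vals))
    metrics_path <- file.path(out_dir, "metrics.csv")
    .write_stamped_csv(df, metrics_path, seed, hash)
    outputs$metrics <- metrics_path
    outputs$table <- df
  }
  logf("pipeline complete")
  invisible(outputs)
}
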