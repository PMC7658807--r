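#' Run a configured analysis end to end
#'
#' Umbrella entry point dispatching to the module pipelines. A run is
#' described by a configuration (an R list or a JSON file) with fields:
#'
#' * `task`: one of `"simulate"`, `"dynamics"`, `"architecture"`, `"frap"`,
#'   `"bfa"`, `"snpindex"`, `"report"`.
#' * `inputs`: character vector of input paths or globs (not used by
#'   `simulate`).
#' * `params`: named list of task parameters (for `simulate`: `kind` plus
#'   generator arguments; for analyses: thresholds, intervals, etc.).
#' * `out_dir`: output directory, created if needed; all artifacts go
#'   there and inputs are never modified.
#' * `seed`: integer recorded in the manifest and forwarded to any
#'   randomized step.
#'
#' Every run writes its result CSVs plus `manifest.json` recording the
#' configuration, package version, seeds, MD5 hashes of inputs and
#' outputs, and any warnings raised (non-converged fits, empty skeletons,
#' lenient substitutions). Re-running an identical configuration on
#' identical inputs reproduces the result CSVs byte for byte.
#'
#' @param config list or path to a JSON configuration file.
#' @return Invisibly, the manifest as a list.
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$task) || is.null(config$out_dir)) {
    abort("config must be a list (or JSON file) with at least 'task' and 'out_dir'")
  }
  task <- match.arg(config$task, c("simulate", "dynamics", "architecture",
                                   "frap", "bfa", "snpindex", "report"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config$params)) list() else config$params
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  inputs <- character(0)
  if (!is.null(config$inputs)) {
    inputs <- unlist(lapply(config$inputs, Sys.glob))
    if (length(inputs) == 0L && task != "simulate") {
      abort("no input files match: %s", paste(config$inputs, collapse = ", "))
    }
  }

  warnings_seen <- character(0)
  outputs <- withCallingHandlers(
    switch(task,
      simulate = run_simulate(params, seed, out_dir),
      dynamics = run_dynamics(inputs, params, out_dir),
      architecture = run_architecture(inputs, params, out_dir),
      frap = run_frap(inputs, params, out_dir),
      bfa = run_bfa(inputs, params, out_dir),
      snpindex = run_snpindex(inputs, params, out_dir),
      report = run_report(inputs, params, out_dir)),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  manifest <- list(
    task = task,
    package = "actomap",
    version = as.character(utils::packageVersion("actomap")),
    seed = seed,
    params = params,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)),
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# --- task runners ----------------------------------------------------------

run_simulate <- function(params, seed, out_dir) {
  kind <- match.arg(params$kind, c("timelapse", "frap", "bfa", "variants"))
  params$kind <- NULL
  params$seed <- seed
  if (kind == "timelapse") {
    sim <- do.call(make_filament_timelapse, params)
    scale <- max(1, max(unlist(lapply(sim$stack$frames, max))))
    frames <- lapply(sim$stack$frames, function(f) pmax(f, 0) / scale)
    stack_path <- file.path(out_dir, "timelapse.tif")
    write_image_stack(frames, stack_path, bits = 16L)
    truth_path <- file.path(out_dir, "timelapse_truth.json")
    jsonlite::write_json(c(sim$truth, intensity_scale = scale), truth_path,
                         auto_unbox = TRUE, digits = NA)
    c(stack_path, truth_path)
  } else if (kind == "frap") {
    sim <- do.call(make_frap_trace, params)
    trace_path <- file.path(out_dir, "frap_trace.csv")
    write.csv(data.frame(time = sim$trace$times,
                         intensity = sim$trace$intensities),
              trace_path, row.names = FALSE)
    truth_path <- file.path(out_dir, "frap_truth.json")
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
    c(trace_path, truth_path)
  } else if (kind == "bfa") {
    sim <- do.call(make_bfa_image, params)
    scale <- max(1, max(sim$image))
    img_path <- file.path(out_dir, "bfa_image.tif")
    write_image_stack(pmax(sim$image, 0) / scale, img_path, bits = 16L)
    truth_path <- file.path(out_dir, "bfa_truth.csv")
    write.csv(sim$truth, truth_path, row.names = FALSE)
    c(img_path, truth_path)
  } else {
    sim <- do.call(make_allele_counts, params)
    counts_path <- file.path(out_dir, "allele_counts.tsv")
    write.table(sim$counts, counts_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    truth_path <- file.path(out_dir, "genotype_truth.csv")
    write.csv(sim$truth, truth_path, row.names = FALSE)
    c(counts_path, truth_path)
  }
}

run_dynamics <- function(inputs, params, out_dir) {
  interval <- if (is.null(params$interval)) 2.5 else params$interval
  results <- lapply(inputs, function(p) {
    stack <- read_image_stack(p, kind = "timelapse", frame_interval = interval,
                              cell_id = basename(p))
    framewise_dynamics(stack)
  })
  out <- file.path(out_dir, "dynamics.csv")
  write.csv(dynamics_table(results), out, row.names = FALSE)
  out
}

run_architecture <- function(inputs, params, out_dir) {
  threshold <- if (is.null(params$threshold)) "otsu" else params$threshold
  min_obj <- if (is.null(params$min_object_px)) 10 else params$min_object_px
  rows <- lapply(inputs, function(p) {
    slices <- read_image_stack(p, kind = "zstack")
    sk <- segment_and_skeletonize(slices, threshold = threshold,
                                  min_object_px = min_obj)
    mask <- matrix(TRUE, nrow(sk$skeleton), ncol(sk$skeleton))
    data.frame(
      image = basename(p),
      threshold_method = sk$threshold_used$method,
      n_skeleton_pixels = sk$n_skeleton_pixels,
      skewness = if (sk$n_skeleton_pixels >= 3) bundling_skewness(sk) else NA_real_,
      occupancy = occupancy(sk, mask))
  })
  out <- file.path(out_dir, "architecture.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

run_frap <- function(inputs, params, out_dir) {
  npre <- if (is.null(params$n_prebleach)) 3 else params$n_prebleach
  fits <- list()
  for (p in inputs) {
    traces <- read_frap_csv(p, n_prebleach = npre)
    for (id in names(traces)) {
      tr <- traces[[id]]
      norm <- normalize_trace(tr, reference = attr(tr, "reference"))
      fits[[paste(basename(p), id, sep = ":")]] <- fit_recovery(norm)
    }
  }
  out <- file.path(out_dir, "frap.csv")
  write.csv(frap_table(fits), out, row.names = FALSE)
  out
}

run_bfa <- function(inputs, params, out_dir) {
  threshold <- if (is.null(params$threshold)) "otsu" else params$threshold
  min_area <- if (is.null(params$min_area)) 4 else params$min_area
  tabs <- lapply(inputs, function(p) {
    img <- read_image_stack(p, kind = "image")
    tab <- quantify_particles(img, threshold = threshold, min_area = min_area)
    if (nrow(tab) > 0) cbind(image = basename(p), as.data.frame(tab)) else NULL
  })
  out <- file.path(out_dir, "bfa_particles.csv")
  write.csv(do.call(rbind, tabs), out, row.names = FALSE)
  out
}

run_snpindex <- function(inputs, params, out_dir) {
  min_depth <- if (is.null(params$min_depth)) 5 else params$min_depth
  min_index <- if (is.null(params$min_index)) 0.9 else params$min_index
  counts <- do.call(rbind, lapply(inputs, read_allele_counts))
  indexed <- compute_snp_index(counts)
  candidates <- extract_homozygous(indexed, min_depth = min_depth,
                                   min_index = min_index)
  out_all <- file.path(out_dir, "snp_index.csv")
  out_cand <- file.path(out_dir, "homozygous_candidates.csv")
  write.csv(indexed, out_all, row.names = FALSE)
  write.csv(candidates, out_cand, row.names = FALSE)
  c(out_all, out_cand)
}

run_report <- function(inputs, params, out_dir) {
  if (is.null(params$response) || is.null(params$factors) || is.null(params$method)) {
    abort("report task needs params: response, factors, method")
  }
  data <- do.call(rbind, lapply(inputs, read.csv, stringsAsFactors = FALSE))
  res <- compare_groups(data, response = params$response,
                        factors = unlist(params$factors),
                        method = params$method)
  out <- file.path(out_dir, "group_stats.csv")
  write.csv(as.data.frame(res), out, row.names = FALSE)
  out
}
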