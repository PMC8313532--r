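# End-to-end driver: generate-code -> make-mask -> phantom -> simulate ->
# reconstruct -> evaluate, with every artifact written as plain text and a
# manifest of content hashes for provenance.

#' Build and validate a run configuration
#'
#' A run configuration is a plain list (or a JSON file of one) with
#' components `code` (`method` + `p`/`q` or `m`/`taps`), `layout`
#' (`p`, `q`), `geometry`, `acquisition` (`M`, `noise`, `sigma`,
#' `photons_per_unit`, `delta0`), `phantom` (`kind` + parameters), and
#' `seed`. Cross-field consistency (code order == layout p*q, coprimality,
#' noise parameters) is checked here, before any computation.
#'
#' The default reproduces the reference rectangular configuration:
#' twin-prime code of order 10,403 folded 101 x 103, M = 5, noiseless
#' resolution-target phantom.
#'
#' @param config list or path to a JSON file; `NULL` gives the default.
#' @return validated config list (class `spi_run_config`).
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  default <- list(
    code = list(method = "twin_prime", p = 101, q = 103),
    layout = list(p = 101, q = 103),
    geometry = list(cell_width_um = 1.5, pattern_radius_mm = 55, rotation_rpm = 600),
    acquisition = list(M = 5, noise = "none", sigma = 0,
                       photons_per_unit = 1e4, delta0 = 0),
    phantom = list(kind = "resolution_target", bar_widths = c(1, 2, 4, 8)),
    reconstruction = list(deblend = TRUE),
    seed = 1
  )
  cfg <- utils::modifyList(default, if (is.null(config)) list() else config)
  order <- switch(cfg$code$method,
    quadratic_residue = cfg$code$p,
    twin_prime = cfg$code$p * cfg$code$q,
    m_sequence = 2^cfg$code$m - 1,
    stop("unknown code method: ", cfg$code$method))
  if (order != cfg$layout$p * cfg$layout$q)
    stop("config rejected: code order ", order, " != layout p*q = ",
         cfg$layout$p * cfg$layout$q)
  if (.gcd(cfg$layout$p, cfg$layout$q) != 1)
    stop("config rejected: layout p, q must be coprime")
  if (!cfg$acquisition$noise %in% c("none", "gaussian", "shot"))
    stop("config rejected: unknown noise model ", cfg$acquisition$noise)
  if (cfg$acquisition$M < 1 || cfg$acquisition$sigma < 0 ||
      cfg$acquisition$photons_per_unit <= 0)
    stop("config rejected: invalid acquisition parameters")
  cfg$order <- order
  class(cfg) <- "spi_run_config"
  cfg
}

.build_code <- function(spec) {
  switch(spec$method,
         quadratic_residue = qr_code(spec$p),
         twin_prime = twin_prime_code(spec$p, spec$q),
         m_sequence = m_sequence_code(spec$m, spec$taps))
}

.build_phantom <- function(spec, p, q, seed) {
  switch(spec$kind,
    resolution_target = resolution_target(p, q,
      bar_widths = if (is.null(spec$bar_widths)) c(1, 2, 4, 8) else spec$bar_widths),
    worm_like = worm_like_sequence(p, q, n_frames = 1L, seed = seed)[[1L]],
    user_image = load_user_image(spec$path, p, q),
    stop("unknown phantom kind: ", spec$kind))
}

.log_stage <- function(log_lines, stage, detail) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                  stage, detail)
  message(line)
  c(log_lines, line)
}

#' Run the full single-frame pipeline
#'
#' Executes code generation, layout folding, phantom synthesis, acquisition
#' simulation and fused reconstruction, writing every artifact under
#' `out_dir`: the code text file, layout JSON, phantom PGM (+ ground-truth
#' JSON), trace CSV (+ sidecar), reconstruction PGM, metrics JSON, the
#' resolved config, and a run log. Deterministic given `config$seed`.
#'
#' @param config see [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a manifest list: `files` (name -> path), `hashes`
#'   (md5 of every data artifact; the timestamped log is listed unhashed),
#'   and `metrics`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("spi_run_")) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage <- "config"
  result <- tryCatch({
    log_lines <- .log_stage(log_lines, "config",
                            sprintf("order N = %d, layout %d x %d, M = %d, noise = %s, seed = %d",
                                    cfg$order, cfg$layout$p, cfg$layout$q,
                                    cfg$acquisition$M, cfg$acquisition$noise,
                                    as.integer(cfg$seed)))
    stage <- "generate-code"
    code <- .build_code(cfg$code)
    report <- validate_code(code)
    if (!report$ok) stop("generated code failed S-matrix validation")
    log_lines <- .log_stage(log_lines, stage,
                            sprintf("method %s, weight %d, cond %.4g",
                                    code$method, code$weight, report$condition_number))
    stage <- "make-layout"
    layout <- fold_crt(code, cfg$layout$p, cfg$layout$q)
    stage <- "phantom"
    phantom <- .build_phantom(cfg$phantom, cfg$layout$p, cfg$layout$q, cfg$seed)
    log_lines <- .log_stage(log_lines, stage, sprintf("kind %s", phantom$kind))
    stage <- "simulate"
    geom <- do.call(mask_geometry, cfg$geometry)
    acq <- acquisition_config(M = cfg$acquisition$M, noise = cfg$acquisition$noise,
                              sigma = cfg$acquisition$sigma,
                              photons_per_unit = cfg$acquisition$photons_per_unit,
                              seed = cfg$seed, delta0 = cfg$acquisition$delta0,
                              geometry = geom)
    trace <- acquire(code, unfold(layout, phantom$image), acq)
    log_lines <- .log_stage(log_lines, stage,
                            sprintf("%d samples (M*N), time step %.4g s",
                                    length(trace$samples), trace$time_step))
    stage <- "reconstruct"
    est <- fuse(trace, code, layout,
                deblend = isTRUE(cfg$reconstruction$deblend))
    stage <- "evaluate"
    metrics <- image_metrics(est, phantom)
    metrics$residual_norm <- est$residual_norm
    log_lines <- .log_stage(log_lines, stage,
                            sprintf("RMSE %.4g, PSNR %.4g dB", metrics$rmse, metrics$psnr_db))
    stage <- "write"
    files <- c(
      code = write_code(code, file.path(out_dir, "code.txt")),
      layout = write_layout(layout, file.path(out_dir, "layout.json")),
      phantom = write_pgm(phantom$image, file.path(out_dir, "phantom.pgm")),
      trace = write_trace(trace, file.path(out_dir, "trace.csv")),
      trace_meta = file.path(out_dir, "trace.csv.json"),
      reconstruction = write_pgm(pmin(pmax(est$image, 0), 1),
                                 file.path(out_dir, "reconstruction.pgm")),
      metrics = {
        jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        file.path(out_dir, "metrics.json")
      },
      config = {
        cfg_out <- unclass(cfg)
        jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                             auto_unbox = TRUE, digits = NA)
        file.path(out_dir, "config.json")
      })
    list(files = files, metrics = metrics, estimate = est, phantom = phantom)
  }, error = function(e) {
    log_lines <<- .log_stage(log_lines, "ERROR",
                             sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  hashes <- vapply(result$files, function(f) unname(tools::md5sum(f)), character(1))
  manifest <- list(files = c(result$files, log = log_path),
                   hashes = hashes, metrics = result$metrics)
  jsonlite::write_json(list(files = as.list(manifest$files),
                            hashes = as.list(manifest$hashes)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(manifest, result["estimate"], result["phantom"]))
}

#' Run the video pipeline
#'
#' Generates an `n_frames` worm-like sequence (or replicates a static
#' phantom), acquires one trace per frame with frame-derived noise seeds,
#' fuses each frame, and writes per-frame trace CSVs, reconstruction PGMs
#' and metrics plus a multi-frame manifest.
#'
#' @param config see [run_config()]; `config$phantom$kind` of `"worm_like"`
#'   animates, anything else is held static across frames.
#' @param n_frames number of frames, >= 2.
#' @param out_dir output directory.
#' @return (invisibly) manifest with per-frame `metrics` and `hashes`.
#' @export
video_pipeline <- function(config = NULL, n_frames = 5L,
                           out_dir = tempfile("spi_video_")) {
  n_frames <- .check_count(n_frames, "n_frames")
  if (n_frames < 2) stop("a video needs n_frames >= 2")
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  code <- .build_code(cfg$code)
  layout <- fold_crt(code, cfg$layout$p, cfg$layout$q)
  phantoms <- if (identical(cfg$phantom$kind, "worm_like")) {
    worm_like_sequence(cfg$layout$p, cfg$layout$q, n_frames, seed = cfg$seed)
  } else {
    rep(list(.build_phantom(cfg$phantom, cfg$layout$p, cfg$layout$q, cfg$seed)),
        n_frames)
  }
  geom <- do.call(mask_geometry, cfg$geometry)
  acq <- acquisition_config(M = cfg$acquisition$M, noise = cfg$acquisition$noise,
                            sigma = cfg$acquisition$sigma,
                            photons_per_unit = cfg$acquisition$photons_per_unit,
                            seed = cfg$seed, delta0 = cfg$acquisition$delta0,
                            geometry = geom)
  traces <- acquire_video(code, phantoms, layout, acq)
  files <- c(code = write_code(code, file.path(out_dir, "code.txt")),
             layout = write_layout(layout, file.path(out_dir, "layout.json")))
  metrics <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    est <- fuse(traces[[f]], code, layout,
                deblend = isTRUE(cfg$reconstruction$deblend))
    metrics[[f]] <- image_metrics(est, phantoms[[f]])
    tag <- sprintf("frame%03d", f)
    files[paste0("phantom_", tag)] <-
      write_pgm(phantoms[[f]]$image, file.path(out_dir, paste0("phantom_", tag, ".pgm")))
    files[paste0("trace_", tag)] <-
      write_trace(traces[[f]], file.path(out_dir, paste0("trace_", tag, ".csv")))
    files[paste0("recon_", tag)] <-
      write_pgm(pmin(pmax(est$image, 0), 1),
                file.path(out_dir, paste0("recon_", tag, ".pgm")))
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  files["metrics"] <- file.path(out_dir, "metrics.json")
  hashes <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  manifest <- list(files = files, hashes = hashes, metrics = metrics,
                   n_frames = n_frames)
  jsonlite::write_json(list(files = as.list(files), hashes = as.list(hashes),
                            n_frames = n_frames),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
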