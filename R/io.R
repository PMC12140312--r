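# File formats and pipeline plumbing: multi-page TIFF stacks with JSON
# metadata sidecars, run configurations, and the end-to-end dispatcher used
# by the command-line interface (inst/cli/fdpr.R).

# round doubles to float32 precision (what a 32-bit TIFF sample can hold)
.as_float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L)
  r <- rawConnectionValue(con)
  close(con)
  out <- readBin(r, "numeric", n = length(x), size = 4L)
  if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
}

# minimal multi-page 32-bit IEEE-float TIFF writer (little endian).
# The tiff package reads float TIFFs but only writes integer samples, so
# float frames are serialized here: per page, a strip of row-major float32
# samples followed by its IFD (ImageWidth, ImageLength, BitsPerSample 32,
# Compression none, Photometric black-is-zero, StripOffsets/ByteCounts,
# RowsPerStrip, SampleFormat IEEE float).
.write_float_tiff <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  n <- length(frames)
  # layout: header(8) | [data_i][IFD_i]...
  entry_n <- 9L
  ifd_size <- 2L + entry_n * 12L + 4L
  offsets <- integer(n); ifd_at <- integer(n)
  cur <- 8L
  for (i in seq_len(n)) {
    nb <- length(frames[[i]]) * 4L
    offsets[i] <- cur
    ifd_at[i] <- cur + nb
    cur <- cur + nb + ifd_size
  }
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  w4(ifd_at[1L])
  for (i in seq_len(n)) {
    f <- frames[[i]]
    writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
    ent <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }
    w2(entry_n)
    ent(256L, 4L, 1L, ncol(f))            # ImageWidth
    ent(257L, 4L, 1L, nrow(f))            # ImageLength
    ent(258L, 3L, 1L, 32L)                # BitsPerSample
    ent(259L, 3L, 1L, 1L)                 # Compression: none
    ent(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    ent(273L, 4L, 1L, offsets[i])         # StripOffsets
    ent(278L, 4L, 1L, nrow(f))            # RowsPerStrip
    ent(279L, 4L, 1L, length(f) * 4L)     # StripByteCounts
    ent(339L, 3L, 1L, 3L)                 # SampleFormat: IEEE float
    w4(if (i < n) ifd_at[i + 1L] else 0L) # next IFD
  }
  invisible(path)
}

#' Write an observation stack to disk
#'
#' Frames go to a multi-page 32-bit IEEE-float TIFF (values stored in
#' physical units, not normalized); metadata goes to a JSON sidecar
#' `<path>.json`. Samples are float32, so frames already at float32
#' precision round-trip bit-identically.
#'
#' @param obs an [observation_set()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(obs, path) {
  frames <- lapply(obs$frames, .as_float32)
  .write_float_tiff(frames, path)
  sidecar <- list(scale = 1, n_frames = length(frames),
                  meta = obs$meta, illum = obs$illum)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an observation stack from disk
#'
#' Accepts a multi-page TIFF (with its JSON sidecar as written by
#' [write_stack()]) or a directory of PNG frames. 8/16-bit integer samples
#' arrive scaled to [0, 1]; the sidecar's `scale` restores physical units.
#' A missing sidecar is tolerated with a warning and default metadata.
#'
#' @param path TIFF file or directory of PNG frames.
#' @return an [observation_set()].
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames in ", path, call. = FALSE)
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG frames", call. = FALSE)
    frames <- lapply(seq_along(files), function(i) {
      f <- tryCatch(png::readPNG(files[i]), error = function(e)
        stop(sprintf("frame %d (%s) unreadable: %s", i, files[i],
                     conditionMessage(e)), call. = FALSE))
      if (length(dim(f)) == 3L) f <- f[, , 1L]
      f
    })
    sidecar_path <- file.path(path, "stack.json")
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e)
      stop("unreadable TIFF ", path, ": ", conditionMessage(e), call. = FALSE))
    frames <- lapply(seq_along(raw), function(i) {
      f <- raw[[i]]
      if (length(dim(f)) == 3L) f <- f[, , 1L]
      if (any(!is.finite(f)))
        stop(sprintf("frame %d of %s has non-finite samples", i, path),
             call. = FALSE)
      f
    })
    sidecar_path <- paste0(path, ".json")
  }
  scale <- 1
  meta <- list(wavelength_um = 0.532, pixel_pitch_um = 1)
  illum <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    scale <- sc$scale %||% 1
    if (!is.null(sc$meta)) meta <- utils::modifyList(meta, sc$meta)
    illum <- sc$illum
  } else {
    warning("missing sidecar ", sidecar_path, "; applying default metadata",
            call. = FALSE)
  }
  frames <- lapply(frames, function(f) pmax(f * scale, 0))
  observation_set(frames, illum = illum, meta = meta)
}

#' Read a run configuration
#'
#' JSON (or YAML, when the yaml package is installed) describing a full
#' run: modality, input stack, output directory, system parameters and the
#' feature/loss/constraint/solver specifications. All physical units are
#' micrometres and radians.
#'
#' @param path config file path.
#' @return named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(cfg$modality) ||
      !cfg$modality %in% c("fpm", "coded", "holography"))
    stop("config must set modality to fpm, coded or holography", call. = FALSE)
  structure(cfg, class = "run_config")
}

# rebuild spec objects from their config echoes
.spec_from_config <- function(cfg) {
  ex <- do.call(feature_extractor_spec, cfg$features %||% list())
  lo <- do.call(loss_spec, cfg$loss %||% list())
  sc <- cfg$solver %||% list()
  if (!is.null(sc$learning_rates)) sc$learning_rates <- unlist(sc$learning_rates)
  so <- do.call(solver_config, sc)
  cons <- lapply(cfg$constraints %||% list(), function(c) do.call(constraint_spec, c))
  list(extractor = ex, loss = lo, solver = so, constraints = cons)
}

#' Execute a configured reconstruction run
#'
#' Dispatches to the feature-domain solver (or a baseline) for the
#' configured modality, then writes the recovered amplitude, phase and
#' operator parameters as float32 TIFFs plus a loss trace and config echo
#' into the output directory.
#'
#' @param config a `run_config` (from [read_run_config()]) or an equivalent
#'   named list.
#' @param observation optional pre-loaded [observation_set()]; otherwise
#'   `config$input` is read with [read_stack()].
#' @return list with `fit`, `report` (a [quality_report()]) and the output
#'   paths, invisibly.
#' @export
run_pipeline <- function(config, observation = NULL) {
  specs <- .spec_from_config(config)
  if (is.null(observation)) observation <- read_stack(config$input)
  out_dir <- config$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- switch(config$modality,
    fpm = {
      sp <- config$system
      kv <- if (!is.null(sp$led_kvectors))
        matrix(unlist(sp$led_kvectors), ncol = 2L, byrow = TRUE)
      else led_grid_kvectors(sp$led_n_side, sp$led_spacing_um,
                             sp$led_height_um, sp$wavelength_um)
      sys <- fpm_system(unlist(sp$object_pixels), sp$objective_na,
                        sp$wavelength_um, sp$object_pitch_um, kv,
                        sp$downsample_factor %||% 2L)
      fdpr_model_fpm(sys, learn_pupil = sp$learn_pupil %||% TRUE)
    },
    holography = {
      sp <- config$system
      fdpr_model_holography(sp$distance_um, dim(observation$frames[[1L]]),
                            observation$meta$pixel_pitch_um,
                            observation$meta$wavelength_um)
    },
    coded = stop("coded-modality runs need an in-memory lensless_system; ",
                 "use fd_solve() with fdpr_model_coded() directly",
                 call. = FALSE))
  fit <- fd_solve(observation, model, specs$extractor, specs$loss,
                  specs$constraints, specs$solver)
  obj <- recovered_object(fit)
  rep <- quality_report(Mod(obj)^2)
  amp_path <- file.path(out_dir, "amplitude.tif")
  ph_path <- file.path(out_dir, "phase.tif")
  tiff::writeTIFF(.as_float32(Mod(obj) / max(Mod(obj), 1)), amp_path,
                  bits.per.sample = 32L)
  tiff::writeTIFF(.as_float32((Arg(obj) + pi) / (2 * pi)), ph_path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(loss_trace = fit$loss_trace,
                            best_iter = fit$best_iter, seed = fit$seed,
                            config = unclass(config)),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, report = rep,
                 paths = c(amplitude = amp_path, phase = ph_path)))
}
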