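#' Write a dose grid or structure mask as an array-volume file
#'
#' The array-volume format is a gzip-compressed text container: the first
#' line is a JSON header (format tag, kind, shape, spacing, origin and, for
#' masks, name and role), followed by one voxel value per line in
#' column-major (R array) order. Doses are written with 17 significant
#' digits, so write/read round-trips are bit-identical; masks are written as
#' 0/1. The format keeps all fixtures plain-text and download-free.
#'
#' @param x A `dose_grid` or `structure_mask`.
#' @param path Output path (conventionally `.rtv.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "dose_grid")) {
    header <- list(format = "rtv1", kind = "dose", shape = x$geometry$shape,
                   spacing = x$geometry$spacing, origin = x$geometry$origin)
    values <- sprintf("%.17g", as.vector(x$dose))
  } else if (inherits(x, "structure_mask")) {
    header <- list(format = "rtv1", kind = "mask", shape = x$geometry$shape,
                   spacing = x$geometry$spacing, origin = x$geometry$origin,
                   name = x$name, role = x$role)
    values <- as.character(as.integer(as.vector(x$occupancy)))
  } else {
    stop("`x` must be a dose_grid or structure_mask")
  }
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
               values), con)
  invisible(path)
}

#' Read an array-volume file
#'
#' @param path Path written by [write_volume()].
#' @return A `dose_grid` or `structure_mask` according to the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "rtv1")) {
    stop("unsupported volume format in ", path,
         " (expected an 'rtv1' array-volume file)")
  }
  g <- volume_geometry(header$shape, header$spacing, header$origin)
  n <- prod(g$shape)
  vals <- as.numeric(lines[1 + seq_len(n)])
  if (anyNA(vals)) stop("corrupt array-volume payload in ", path)
  if (identical(header$kind, "dose")) {
    dose_grid(array(vals, g$shape), g)
  } else if (identical(header$kind, "mask")) {
    structure_mask(array(vals != 0, g$shape), g,
                   name = header$name %||% "structure",
                   role = header$role %||% "OAR")
  } else {
    stop("unsupported volume kind: ", header$kind)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dose grid from an array-volume file
#' @param path File path.
#' @return A `dose_grid`.
#' @export
read_dose <- function(path) {
  x <- read_volume(path)
  if (!inherits(x, "dose_grid")) stop(path, " does not contain a dose grid")
  x
}

#' Write / read a structure set as a directory of array-volume files
#'
#' Each mask is written to `<name>.rtv.gz` inside `dir`; `read_structures`
#' loads every `.rtv.gz` mask in the directory (or an explicit vector of
#' file paths) into a named list.
#'
#' @param structures Named list of `structure_mask`s.
#' @param dir Directory (created if missing).
#' @param paths For `read_structures`: a directory or vector of file paths.
#' @return `write_structure_set`: the directory, invisibly;
#'   `read_structures`: named list of `structure_mask`s.
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(structures)) {
    write_volume(structures[[nm]], file.path(dir, paste0(nm, ".rtv.gz")))
  }
  invisible(dir)
}

#' @rdname write_structure_set
#' @export
read_structures <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.rtv\\.gz$", full.names = TRUE)
  }
  if (length(paths) == 0) stop("no array-volume files found")
  out <- lapply(paths, read_volume)
  if (!all(vapply(out, inherits, TRUE, "structure_mask"))) {
    stop("structure set contains non-mask volumes")
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# FNV-1a hash of a config (stable across sessions; used to stamp outputs)
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a validated pipeline run configuration
#'
#' @param out_dir Output directory for reports.
#' @param seed Integer seed.
#' @param laterality Phantom/plan laterality.
#' @param phantom_shape,phantom_spacing Phantom grid.
#' @param medial_tangent Medial tangent angle, degrees; `NULL` for the
#'   laterality default.
#' @param n_medial_extra,pab_offset_adjust Arrangement parameters.
#' @param card `"left"`, `"right"`, `"comparison"` or a JSON card path.
#' @param jitter_sd_mm Anatomical jitter, mm.
#' @param n_pairs If `> 0`, additionally run the paired-cohort comparison
#'   stage with this many pairs.
#' @param gamma_self_check Run a gamma self-consistency stage on the
#'   simulated dose.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, laterality = "LEFT",
                       phantom_shape = c(64, 64, 48),
                       phantom_spacing = c(4, 4, 4),
                       medial_tangent = NULL, n_medial_extra = 1L,
                       pab_offset_adjust = 0L, card = "left",
                       jitter_sd_mm = 0, n_pairs = 0L,
                       gamma_self_check = FALSE) {
  if (is.null(medial_tangent)) medial_tangent <- default_medial_tangent(laterality)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              laterality = toupper(laterality),
              phantom_shape = as.integer(phantom_shape),
              phantom_spacing = as.numeric(phantom_spacing),
              medial_tangent = medial_tangent,
              n_medial_extra = as.integer(n_medial_extra),
              pab_offset_adjust = as.integer(pab_offset_adjust),
              card = card, jitter_sd_mm = jitter_sd_mm,
              n_pairs = as.integer(n_pairs),
              gamma_self_check = isTRUE(gamma_self_check))
  stopifnot(cfg$laterality %in% c("LEFT", "RIGHT"),
            cfg$n_medial_extra >= 0, cfg$n_medial_extra <= 4,
            cfg$pab_offset_adjust %in% c(-8L, 0L, 8L), cfg$n_pairs >= 0)
  structure(cfg, class = "run_config")
}

resolve_card <- function(card) {
  if (card %in% c("left", "right", "comparison")) return(packaged_card(card))
  if (!file.exists(card)) stop("card file not found: ", card)
  load_card(card)
}

#' Run the phantom planning pipeline end to end
#'
#' Stages: phantom construction (volumes), beam placement, dose simulation,
#' DVH metrics, scorecard scoring, and optionally a gamma self-check and the
#' paired-cohort comparison. All outputs (metrics CSV, score CSV, JSON
#' summary) are written under `config$out_dir` and stamped with the config
#' hash; reruns with an identical config are byte-identical. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report bundle: `score_report`, `metrics`, paths,
#'   and optional `gamma` / `comparison` results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ph <- stage("volumes", build_phantom(phantom_spec(
    config$laterality, config$phantom_shape, config$phantom_spacing,
    seed = config$seed, jitter_sd_mm = config$jitter_sd_mm)))
  arr <- stage("beams", generate_arrangement(
    config$medial_tangent, config$laterality,
    config$n_medial_extra, config$pab_offset_adjust))
  dose <- stage("dose", simulate_dose(arr, ph))
  card <- stage("card", resolve_card(config$card))
  specs <- do.call(rbind, lapply(card$functions, function(fn) {
    data.frame(structure = fn$structure, metric = fn$metric,
               stringsAsFactors = FALSE)
  }))
  metrics <- stage("metrics", metrics_table(dose, ph$structures, specs))
  report <- stage("score", score_plan(card, metrics))

  metrics_path <- file.path(config$out_dir, "metrics.csv")
  score_path <- file.path(config$out_dir, "score.csv")
  utils::write.csv(cbind(metrics, config_hash = hash), metrics_path,
                   row.names = FALSE)
  utils::write.csv(cbind(report$rows, config_hash = hash), score_path,
                   row.names = FALSE)

  bundle <- list(config_hash = hash, score_report = report, metrics = metrics,
                 paths = c(metrics = metrics_path, score = score_path))

  if (config$gamma_self_check) {
    bundle$gamma <- stage("gamma", gamma_index(dose, dose))
  }
  if (config$n_pairs > 0) {
    cohort <- stage("cohort", make_cohort(
      n_pairs = config$n_pairs, seed = config$seed,
      laterality = config$laterality, shape = config$phantom_shape,
      spacing = config$phantom_spacing,
      jitter_sd_mm = max(config$jitter_sd_mm, 3)))
    bundle$comparison <- stage("compare", compare_cohorts(cohort$samples))
    cmp_path <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(cbind(bundle$comparison, config_hash = hash), cmp_path,
                     row.names = FALSE)
    bundle$paths <- c(bundle$paths, comparison = cmp_path)
  }

  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(
    config_hash = hash, config = unclass(config),
    total = report$total, max_total = report$max_total,
    n_fields = nrow(arr$fields)
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$paths <- c(bundle$paths, summary = summary_path)
  invisible(bundle)
}
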