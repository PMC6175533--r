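# Pipeline orchestration: simulate -> segment -> features -> classify ->
# analyze, driven by a config list (typically read from YAML). Every stage
# writes its artifacts under `out_dir` and logs its parameters.

#' Default run configuration
#'
#' All tunable constants in one place: segmentation criteria, feature
#' parameters, the shipped classifier, the KDE bandwidth factor.
#'
#' @return nested list; see fields.
#' @export
default_run_config <- function() {
  list(
    px_per_nm = NULL,           # nm per pixel in x/y; NULL = stack spacing
    az = NULL,                  # active-zone point, c(x, y, z) nm (required)
    seed = 1L,
    criteria = particle_criteria(),
    features = feature_params(),
    model = "default",          # "default" or a model YAML path
    bandwidth_factor = 0.07,
    out_dir = "."
  )
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file fall back to [default_run_config()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (nm == "criteria") cfg$criteria <- do.call(particle_criteria,
                                                  user$criteria)
    else if (nm == "features") cfg$features <- do.call(feature_params,
                                                       user$features)
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

resolve_model <- function(model) {
  if (inherits(model, "vesisort_model")) return(model)
  if (identical(model, "default")) return(default_model())
  read_model(model)
}

#' Run the full classification pipeline
#'
#' Segments the input stack (or a freshly simulated phantom), extracts
#' features, classifies them and writes all artifacts: `labels.tif`,
#' `scaled.tif`, `features.csv`, `classified.csv`, `result.log`,
#' `label_color.tif`, `composite.tif`, `summary.json` and `run_params.json`.
#' With fixed seeds the CSV outputs are bit-identical across reruns.
#'
#' @param config list as from [default_run_config()]; must contain either
#'   `input` (stack path) or `simulate` (a [phantom_spec()] or TRUE), and an
#'   `az` point unless simulating (then the phantom's AZ is used).
#' @return list of artifact paths and in-memory results, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$out_dir, f)

  if (!is.null(cfg$simulate)) {
    spec <- if (inherits(cfg$simulate, "phantom_spec")) cfg$simulate
            else phantom_spec()
    ph <- generate_phantom_stack(spec, seed = cfg$seed)
    stack <- ph$stack
    write_stack(stack, art("input.tif"))
    write.csv(ph$truth, art("truth.csv"), row.names = FALSE, quote = FALSE)
    if (is.null(cfg$az)) cfg$az <- spec$az
  } else {
    if (is.null(cfg$input)) stop("config needs 'input' or 'simulate'",
                                 call. = FALSE)
    stack <- read_stack(cfg$input, spacing = cfg$spacing)
  }
  if (is.null(cfg$az)) stop("config needs an active-zone point 'az'",
                            call. = FALSE)

  seg <- segment(stack, nm_per_px = cfg$px_per_nm, criteria = cfg$criteria)
  write_stack(seg$scaled, art("scaled.tif"))
  write_label_tiff(seg$labels, art("labels.tif"))

  feats <- extract_feature_table(seg$scaled, seg$labels, cfg$az,
                                 params = cfg$features)
  write.csv(feats, art("features.csv"), row.names = FALSE, quote = FALSE)

  model <- resolve_model(cfg$model)
  classified <- classify_table(feats, model)
  write.csv(classified, art("classified.csv"), row.names = FALSE,
            quote = FALSE)
  write_result_log(classified, art("result.log"))
  if (nrow(classified) > 0) {
    cls <- setNames(classified$class, as.character(classified$id))
    write_color_label_stack(seg$labels, cls, path = art("label_color.tif"),
                            original = seg$scaled,
                            composite_path = art("composite.tif"))
  }

  sums <- summarize_groups(list(run = classified), states = "run")
  counts <- attr(classified, "counts")
  jsonlite::write_json(
    list(n_vesicles = nrow(classified),
         counts = as.list(counts),
         dcv_percent = if (nrow(classified) > 0)
           dcv_ratio(counts[["DCV"]], sum(counts)) else NA,
         summary = sums$summary),
    art("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("vesisort")),
         seed = cfg$seed, az = as.numeric(cfg$az),
         criteria = cfg$criteria, features = cfg$features,
         model = if (is.character(cfg$model)) cfg$model else "inline"),
    art("run_params.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(labels = seg$labels, scaled = seg$scaled,
                 features = feats, classified = classified,
                 out_dir = cfg$out_dir))
}

# 16-bit label TIFF (ids up to 65535)
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(z) labels[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(as.integer(round(unlist(pages))),
        dim = c(dim(pages[[1]]), length(pages)))
}
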