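#' Default run configuration
#'
#' Assembles the full configuration of an end-to-end run: input paths (or a
#' synthetic-set request), pre-processing parameters, PCA/cluster
#' parameters, quantification band windows and the seed. Unknown keys in
#' `...` or in a YAML file are rejected — a misspelt parameter must never
#' silently fall back to a default.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated list of class `run_config` with entries:
#' * `inputs`: data.frame of `path`, `sample_name`, `nx`, `ny` (or `NULL`
#'   when `synth$n_case`/`n_control` request generated data);
#' * `annotations`: path to an annotation table (optional);
#' * `synth`: list `n_case`, `n_control`, `nx`, `ny` (used when `inputs`
#'   is `NULL`);
#' * `preprocess`: arguments for [preprocess_params];
#' * `pca`: list `n_components`;
#' * `cluster`: list `n_neighbors`, `resolution`;
#' * `bands`: named list of `c(lo, hi)` quantification windows;
#' * `seed`: integer master seed;
#' * `outdir`: output directory.
#' @export
run_config <- function(...) {
  defaults <- list(
    inputs = NULL,
    annotations = NULL,
    synth = list(n_case = 3L, n_control = 3L, nx = 32L, ny = 32L),
    preprocess = list(),
    pca = list(n_components = 15L),
    cluster = list(n_neighbors = 15L, resolution = 1),
    bands = list(amide_I = c(1600, 1700), lipid_CH2 = c(2830, 2950)),
    seed = 0L,
    outdir = "spectromap_run")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    abort_sm(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")), "configuration")
  cfg <- utils::modifyList(defaults, over)
  cfg$seed <- as.integer(cfg$seed)
  bad_pp <- setdiff(names(cfg$preprocess), names(formals(preprocess_params)))
  if (length(bad_pp))
    abort_sm(sprintf("unknown preprocess key(s): %s",
                     paste(bad_pp, collapse = ", ")), "configuration")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path; top-level keys as in [run_config].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$inputs)) cfg$inputs <- as.data.frame(cfg$inputs)
  do.call(run_config, cfg)
}

# Deterministic table writer: fixed formatting so identical runs produce
# bitwise-identical artifacts.
write_artifact <- function(df, path) {
  num_cols <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x)
    sprintf("%.15g", x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order — (optional) synthetic generation, read,
#' QC (empty + scatter), mask application, CO2 excision, vector
#' normalization, second derivative, PCA, Leiden clustering, band
#' quantification, secondary-structure estimation, spatial maps — writing
#' every stage's artifact as delimited text under `config$outdir` along
#' with a provenance log (`run.log`) and the effective configuration
#' (`config.yaml`). Any stage failure aborts with the failing stage named.
#' Re-running with an identical configuration reproduces all delimited-text
#' artifacts bitwise.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Invisibly, a list of in-memory stage results (`maps`, `mask`,
#'   `pca`, `clusters`, `quant`, `structure`, `images`, `outdir`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) abort_sm(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)), "stage"))
  }

  # -- input stage: synthetic set or files ---------------------------------
  if (is.null(config$inputs)) {
    sset <- stage("synth", make_sample_set(
      n_case = config$synth$n_case, n_control = config$synth$n_control,
      nx = config$synth$nx, ny = config$synth$ny, seed = config$seed))
    maps <- sset$maps
    annotations <- sset$annotations
    log_add("synth", sprintf("generated %d synthetic sample(s), seed %d",
                             length(maps), config$seed))
  } else {
    inputs <- config$inputs
    annotations <- if (!is.null(config$annotations))
      stage("read", read_annotations(config$annotations)) else
      data.frame(sample_name = unique(inputs$sample_name))
    maps <- stage("read", lapply(seq_len(nrow(inputs)), function(i) {
      g <- if (!is.null(inputs$nx))
        grid_spec(inputs$nx[i], inputs$ny[i]) else NULL
      read_spectral_table(inputs$path[i], sample_id = inputs$sample_name[i],
                          grid = g)
    }))
    log_add("read", sprintf("read %d sample file(s)", length(maps)))
  }
  grids <- lapply(maps, `[[`, "grid")
  pp <- do.call(preprocess_params, config$preprocess)

  # -- QC per sample, then joint analysis ----------------------------------
  masks <- stage("qc", lapply(maps, function(m)
    combine_masks(detect_empty(m, pp), detect_scatter(m, pp))))
  for (i in seq_along(masks))
    write_qc_mask(masks[[i]], file.path(outdir, sprintf(
      "qc_mask_%s.csv", maps[[i]]$sample_ids[1])))
  log_add("qc", sprintf("excluded %s pixel(s) per sample",
                        paste(vapply(masks, function(m) sum(!m$keep),
                                     integer(1)), collapse = "/")))

  retained <- stage("qc", Map(apply_mask, maps, masks))
  joint <- stage("concat", concat_samples(retained, annotations))
  joint <- stage("co2", exclude_co2(joint, pp))
  joint <- stage("normalize", vector_normalize(joint))
  deriv <- stage("derivative", second_derivative(joint, pp))
  log_add("preprocess",
          sprintf("CO2 excised, normalized, 2nd derivative; %d x %d matrix",
                  nrow(deriv$absorbance), ncol(deriv$absorbance)))

  pca <- stage("pca", fit_pca(deriv, config$pca$n_components))
  write_artifact(data.frame(component = seq_along(pca$explained_variance_ratio),
                            explained_variance_ratio =
                              pca$explained_variance_ratio,
                            cumulative = cumulative_variance(pca)),
                 file.path(outdir, "pca_variance.csv"))
  write_artifact(cbind(data.frame(wavenumber = pca$axis),
                       as.data.frame(t(pca$eigen_spectra)) |>
                         stats::setNames(paste0("PC", seq_len(nrow(pca$eigen_spectra))))),
                 file.path(outdir, "pca_eigenspectra.csv"))
  log_add("pca", sprintf("%d components, cumulative EV %.4f",
                         config$pca$n_components,
                         max(cumulative_variance(pca))))

  clusters <- stage("cluster", cluster_pixels(
    pca$scores, n_neighbors = config$cluster$n_neighbors,
    resolution = config$cluster$resolution, seed = config$seed))
  log_add("cluster", sprintf("%d cluster(s) at resolution %g, seed %d",
                             length(unique(clusters$labels)),
                             config$cluster$resolution, config$seed))

  # -- quantification on the normalized (pre-derivative) spectra ------------
  quants <- stage("quantify", lapply(config$bands, function(wdw)
    integrate_band(joint, band_window(wdw[1], wdw[2],
                                      baseline = "linear_endpoints"))))
  struct <- stage("quantify", estimate_secondary_structure(joint))

  # per-pixel result table keyed by sample + original pixel index
  orig_index <- unlist(lapply(seq_along(masks), function(i)
    which(masks[[i]]$keep) - 1L))
  res <- data.frame(sample_name = joint$sample_ids,
                    pixel_index = orig_index,
                    cluster = clusters$labels)
  for (b in names(quants)) res[[paste0("area_", b)]] <- quants[[b]]$values
  res <- cbind(res, struct[, setdiff(names(struct),
                                     c("pixel_index", "undefined")),
                           drop = FALSE])
  write_artifact(res, file.path(outdir, "pixel_results.csv"))

  # -- spatial maps per sample ---------------------------------------------
  images <- list()
  split_idx <- split(seq_len(nrow(res)), res$sample_name)
  for (i in seq_along(maps)) {
    sid <- maps[[i]]$sample_ids[1]
    if (is.null(grids[[i]])) next
    rows <- split_idx[[sid]]
    images[[paste0(sid, "_clusters")]] <- map_clusters(
      res$cluster[rows], masks[[i]], grids[[i]],
      file = file.path(outdir, sprintf("map_clusters_%s", sid)))
    for (b in names(quants))
      images[[paste0(sid, "_", b)]] <- to_grid(
        repopulate(res[[paste0("area_", b)]][rows], masks[[i]]),
        grids[[i]], kind = "scalar")
    write_spatial_image(images[[paste0(sid, "_", names(quants)[1])]],
                        file.path(outdir, sprintf(
                          "map_%s_%s", names(quants)[1], sid)))
  }
  log_add("map", sprintf("wrote %d spatial map image(s)", length(images)))

  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(maps = maps, mask = masks, joint = joint, deriv = deriv,
                 pca = pca, clusters = clusters, quant = quants,
                 structure = struct, images = images,
                 annotations = annotations, outdir = outdir))
}
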