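#' Read a delimited table with schema validation
#'
#' Delimiter is inferred from the extension (.csv or .tsv). Required columns
#' must be present and must carry unit suffixes from the package's naming
#' convention (`_um2`, `_um`, `_min`, `_s`, `_px`, `_um2s`) where the schema
#' says so; extra columns are preserved untouched.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  unit_re <- "_(um2|um|min|s|px|um2s|per_min)$"
  bare <- intersect(names(df), c("x", "y", "t", "area", "width", "da"))
  if (length(bare))
    stop("column(s) without unit suffix: ", paste(bare, collapse = ", "),
         " (use e.g. x_um, t_min, area_um2)")
  invisible(unit_re)  # convention documented above
  df
}

#' Write a table to CSV/TSV (round-trip safe)
#'
#' @param df data.frame.
#' @param path destination; extension selects the delimiter.
#' @return the path, invisibly.
#' @export
write_table_checked <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on synthetic inputs and
#' writes each stage's outputs under `outdir`. Stages: `simulate` (synthetic
#' tracks, growth trajectories, omics tables, populations), `growth`
#' (growth-rate series), `tracks` (linking, D_a, mixture fit, per-cell active
#' fractions), `slopes` (protein slopes), `ratio` (binned population ratio +
#' decay fit), `model` (ODE trajectories under both genome laws). Every
#' stochastic stage receives an explicit seed derived from the global seed by
#' a fixed offset, so a rerun with the same config is bit-identical.
#'
#' @param config list or path to a YAML file with fields `outdir`, `seed`,
#'   `stages` (character vector; default all) and optional per-stage
#'   parameter lists (`simulate`, `growth`, `tracks`, `slopes`, `ratio`,
#'   `model`).
#' @return manifest list (config, package version, per-output md5 checksums,
#'   timings in seconds), also written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  outdir <- config$outdir %||% stop("config$outdir is required")
  seed <- config$seed %||% 1L
  all_stages <- c("simulate", "growth", "tracks", "slopes", "ratio", "model")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("dnalim")),
                   outputs = list(), timings_s = list())
  stage_seed <- function(k) seed + 1000L * k
  note <- function(stage, paths, elapsed) {
    manifest$outputs[[stage]] <<- as.list(tools::md5sum(paths))
    manifest$timings_s[[stage]] <<- unname(elapsed)
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    sim <- config$simulate %||% list()
    tr <- sim_tracks(n_tracks = sim$n_tracks %||% 500,
                     weights = sim$weights %||% c(0.7, 0.25, 0.05),
                     d_um2s = sim$d_um2s %||% c(0.04, 0.7, 3.0),
                     track_length = 12, n_cells = 20, seed = stage_seed(1))
    gr <- sim_growth(n_cells = sim$n_cells %||% 20, mode = "exponential",
                     k = 0.01, a0 = 2, t_end = 120, sample_interval = 1,
                     noise_sd = 0.02, seed = stage_seed(2))
    om <- sim_omics(n_entities = sim$n_entities %||% 100, seed = stage_seed(3))
    pp <- sim_populations(bin_edges = 2:8, true_ratio_per_bin = 0.8,
                          n_per_bin_a = 60, n_per_bin_b = 120,
                          n_replicates = 3, seed = stage_seed(4))
    paths <- file.path(outdir, c("tracks.csv", "growth.csv", "peptides.tsv",
                                 "channel_meta.csv", "populations.csv"))
    write_table_checked(tr$tracks, paths[1])
    write_table_checked(gr, paths[2])
    write_table_checked(om$peptides, paths[3])
    write_table_checked(om$meta, paths[4])
    write_table_checked(pp, paths[5])
    note("simulate", paths, proc.time()[3] - t0)
  }
  if ("growth" %in% stages) {
    t0 <- proc.time()[3]
    gr <- read_table_checked(file.path(outdir, "growth.csv"),
                             c("cell_id", "t_min", "area_um2"))
    gs <- do.call(rbind, lapply(split(gr, gr$cell_id), function(g) {
      out <- growth_rates(g$t_min, g$area_um2,
                          window = (config$growth %||% list())$window %||% 5)
      out <- truncate_filament(out)
      cbind(cell_id = g$cell_id[1], out)
    }))
    p <- file.path(outdir, "growth_rates.csv")
    write_table_checked(gs, p)
    note("growth", p, proc.time()[3] - t0)
  }
  if ("tracks" %in% stages) {
    t0 <- proc.time()[3]
    pars <- config$tracks %||% list()
    tr <- read_table_checked(file.path(outdir, "tracks.csv"),
                             c("track_id", "frame", "x_um", "y_um", "cell_id"))
    rec <- apparent_diffusion(tr, frame_time = pars$frame_time %||% 0.0107,
                              min_displacements = pars$min_disp %||% 9)
    gmm <- fit_gmm_log_da(rec, k = 3)
    frac <- cell_active_fractions(rec, gmm, min_tracks = pars$min_tracks %||% 10)
    paths <- file.path(outdir, c("diffusion_records.csv", "gmm_fit.json",
                                 "active_fractions.csv"))
    write_table_checked(rec, paths[1])
    jsonlite::write_json(gmm[c("weights", "means", "sds", "k", "loglik")],
                         paths[2], auto_unbox = TRUE, digits = NA)
    write_table_checked(frac, paths[3])
    note("tracks", paths, proc.time()[3] - t0)
  }
  if ("slopes" %in% stages) {
    t0 <- proc.time()[3]
    pep <- read_table_checked(file.path(outdir, "peptides.tsv"),
                              c("peptide_id", "protein_id"))
    meta <- read_table_checked(file.path(outdir, "channel_meta.csv"),
                               c("channel", "area_um2"))
    sl <- protein_slopes(pep, meta,
                         min_peptides = (config$slopes %||% list())$min_peptides %||% 3)
    p <- file.path(outdir, "protein_slopes.tsv")
    write_table_checked(sl, p)
    note("slopes", p, proc.time()[3] - t0)
  }
  if ("ratio" %in% stages) {
    t0 <- proc.time()[3]
    pp <- read_table_checked(file.path(outdir, "populations.csv"),
                             c("area_um2", "signal", "replicate", "population"))
    br <- ratio_vs_area(pp, bin_edges = 2:8, seed = stage_seed(5))
    fit <- fit_exponential_decay(br)
    paths <- file.path(outdir, c("binned_ratio.csv", "decay_fit.json"))
    write_table_checked(as.data.frame(unclass(br)), paths[1])
    jsonlite::write_json(fit[c("a", "b", "r_squared")], paths[2],
                         auto_unbox = TRUE, digits = NA)
    note("ratio", paths, proc.time()[3] - t0)
  }
  if ("model" %in% stages) {
    t0 <- proc.time()[3]
    p0 <- do.call(model_params, config$model %||% list())
    init <- balanced_growth_init(p0, Y_target = 2.5 / p0$c_prime)
    multi <- simulate_model(p0, "multiN", init["X"], init["Y"], t_end = 300)
    one <- simulate_model(p0, "oneN", init["X"], init["Y"], t_end = 300)
    paths <- file.path(outdir, c("model_multiN.csv", "model_oneN.csv"))
    write_table_checked(as.data.frame(unclass(multi)), paths[1])
    write_table_checked(as.data.frame(unclass(one)), paths[2])
    note("model", paths, proc.time()[3] - t0)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Read label masks from TIFF files
#'
#' Reads one or more single-page TIFFs (or one multi-page TIFF) of integer
#' label masks, as written by segmentation tools, into a list of integer
#' matrices suitable for [link_masks()].
#'
#' @param paths TIFF file path(s).
#' @return list of integer matrices, frames in order.
#' @export
read_label_masks <- function(paths) {
  out <- list()
  for (p in paths) {
    img <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(img)) img <- list(img)
    out <- c(out, lapply(img, function(m) {
      storage.mode(m) <- "integer"
      m
    }))
  }
  out
}
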