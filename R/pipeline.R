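# Reproducible pipeline commands: a YAML-round-trippable run configuration
# and the simulate / sinuosity / variants entry points used by the
# command-line wrapper.

#' Build a pipeline run configuration
#'
#' A validated, YAML-serializable bundle of every tunable of the pipeline.
#' Each stochastic stage's seed is part of the configuration and is recorded
#' in output metadata, so a rerun with the same configuration reproduces all
#' deterministic outputs bit-identically.
#'
#' @param output_dir directory for outputs.
#' @param inputs character vector of input paths (stacks or VCF, per command).
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param min_fraction noise-filter area fraction.
#' @param angle_threshold direction-change split threshold, degrees.
#' @param frac LOWESS span.
#' @param sa_iterations,sa_cooling simulated-annealing schedule.
#' @param seed master seed for stochastic stages.
#' @param voxel_size voxel sizes `(vx, vy, vz)` in micrometres, used when a
#'   stack has no sidecar.
#' @param gff,genome,comparison_vcfs variant-command inputs.
#' @param simulate list of generator specifications for [cmd_simulate()]:
#'   entries named `tubes` (list of [tube_render_spec()]), `textures` (list of
#'   [filament_texture_spec()]) and/or `variants` (list of
#'   [synthetic_variant_spec()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = ".", inputs = character(0),
                       threshold = "otsu", min_fraction = 0.01,
                       angle_threshold = 45, frac = 0.1,
                       sa_iterations = 10000, sa_cooling = 0.995, seed = 1L,
                       voxel_size = c(0.4, 0.4, 0.4),
                       gff = NULL, genome = NULL,
                       comparison_vcfs = character(0), simulate = list()) {
  assert_that(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  assert_that(angle_threshold > 0, "angle_threshold must be > 0")
  structure(list(output_dir = output_dir, inputs = inputs,
                 threshold = threshold, min_fraction = min_fraction,
                 angle_threshold = angle_threshold, frac = frac,
                 sa_iterations = sa_iterations, sa_cooling = sa_cooling,
                 seed = seed, voxel_size = voxel_size, gff = gff,
                 genome = genome, comparison_vcfs = comparison_vcfs,
                 simulate = simulate),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The YAML serialization round-trips losslessly: reading a written
#' configuration restores an identical object (generator specifications are
#' rebuilt through their constructors).
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  ser <- unclass(config)
  ser$simulate <- lapply(config$simulate, function(group) {
    lapply(group, function(sp) {
      kind <- class(sp)[1]
      flat <- lapply(unclass(sp), function(v) {
        if (inherits(v, "centerline_spec")) {
          c(list(.spec = "centerline_spec"),
            lapply(unclass(v), function(w) if (is.matrix(w)) as.data.frame(w) else w))
        } else {
          v
        }
      })
      # named atomic vectors lose their names in YAML; store as maps
      if (!is.null(flat$orientation)) flat$orientation <- as.list(flat$orientation)
      c(list(.spec = kind), flat)
    })
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild_spec <- function(x) {
    kind <- x$.spec
    x$.spec <- NULL
    x <- lapply(x, function(v) {
      if (is.list(v) && identical(v$.spec, "centerline_spec")) rebuild_spec(v) else v
    })
    drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
    switch(kind,
      centerline_spec = {
        if (!is.null(x$waypoints)) x$waypoints <- as.matrix(as.data.frame(x$waypoints))
        do.call(centerline_spec, drop_null(x[intersect(names(x), names(formals(centerline_spec)))]))
      },
      tube_render_spec = {
        x$orientation <- unlist(x$orientation)
        do.call(tube_render_spec, drop_null(x[intersect(names(x), names(formals(tube_render_spec)))]))
      },
      filament_texture_spec =
        do.call(filament_texture_spec, drop_null(x[intersect(names(x), names(formals(filament_texture_spec)))])),
      synthetic_variant_spec =
        do.call(synthetic_variant_spec, drop_null(x[intersect(names(x), names(formals(synthetic_variant_spec)))])),
      stop_config(sprintf("unknown spec kind '%s' in config", kind)))
  }
  raw$simulate <- lapply(raw$simulate, function(group) lapply(group, rebuild_spec))
  cfg <- do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
  cfg
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

run_manifest <- function(config, outputs, path) {
  yaml::write_yaml(list(config_hash = config_hash(config),
                        seed = config$seed,
                        outputs = outputs,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                   path)
}

#' Generate synthetic fixtures on disk
#'
#' Renders every generator specification in `config$simulate` and writes the
#' results with ground-truth sidecars: tube stacks as multi-page TIFF + YAML,
#' filament textures as TIFF + YAML (with the truth mask path), variant
#' tables as VCF (+ a `truth` column sidecar). A manifest with the config
#' hash and seeds is written alongside.
#'
#' @param config a [run_config()] with a `simulate` entry.
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  out <- ensure_dir(config$output_dir)
  written <- character(0)
  for (i in seq_along(config$simulate$tubes)) {
    stk <- render_tube_stack(config$simulate$tubes[[i]])
    p <- file.path(out, sprintf("tube_%02d.tif", i))
    write_image_stack(stk, p)
    written <- c(written, p, paste0(p, ".yml"))
  }
  for (i in seq_along(config$simulate$textures)) {
    tex <- make_filament_texture(config$simulate$textures[[i]])
    p <- file.path(out, sprintf("texture_%02d.tif", i))
    write_image_stack(image_stack(tex$image, voxel_size = c(config$voxel_size[1:2], 1),
                                  metadata = list(bundle_factor = tex$spec$bundle_factor,
                                                  seed = tex$spec$seed)), p)
    written <- c(written, p, paste0(p, ".yml"))
  }
  for (i in seq_along(config$simulate$variants)) {
    tab <- make_variant_table(config$simulate$variants[[i]])
    p <- file.path(out, sprintf("variants_%02d.vcf", i))
    write_variant_vcf(tab$records, p)
    write.csv(data.frame(truth = tab$truth), paste0(p, ".truth.csv"), row.names = FALSE)
    cp <- file.path(out, sprintf("variants_%02d_comparison.vcf", i))
    cmp1 <- tab$comparison_sets[[1]]
    cmp1$qual <- 50; cmp1$dp <- 50
    write_variant_vcf(cmp1, cp)
    written <- c(written, p, paste0(p, ".truth.csv"), cp)
  }
  run_manifest(config, written, file.path(out, "simulate_manifest.yml"))
  invisible(written)
}

#' Measure sinuosity for a batch of stacks
#'
#' Runs [measure_sinuosity()] on every input stack and writes one CSV row per
#' stack (stack, n_slices, n_points, L_um, D_um, sinuosity_pct, n_fragments,
#' seed). Unreadable or degenerate stacks are reported in an `error` column
#' and the run continues.
#'
#' @param config a [run_config()] whose `inputs` are stack paths.
#' @return The results data frame, invisibly; also written to
#'   `sinuosity_results.csv` in the output directory.
#' @export
cmd_sinuosity <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  out <- ensure_dir(config$output_dir)
  rows <- lapply(config$inputs, function(p) {
    res <- tryCatch({
      stk <- read_image_stack(p, voxel_size = config$voxel_size)
      m <- measure_sinuosity(stk, threshold = config$threshold,
                             min_fraction = config$min_fraction,
                             angle_threshold = config$angle_threshold,
                             frac = config$frac,
                             sa = sa_params(iterations = config$sa_iterations,
                                            cooling_rate = config$sa_cooling,
                                            seed = config$seed))
      data.frame(stack = p, n_slices = dim(stk)[3], n_points = m$n_points,
                 L_um = m$path_length_um, D_um = m$chord_um,
                 sinuosity_pct = m$sinuosity_pct, n_fragments = m$n_fragments,
                 seed = config$seed, error = NA_character_)
    }, error = function(e) {
      message(sprintf("[sinuosity] %s: %s", p, conditionMessage(e)))
      data.frame(stack = p, n_slices = NA, n_points = NA, L_um = NA, D_um = NA,
                 sinuosity_pct = NA, n_fragments = NA, seed = config$seed,
                 error = conditionMessage(e))
    })
    res
  })
  df <- do.call(rbind, rows)
  csv <- file.path(out, "sinuosity_results.csv")
  write.csv(df, csv, row.names = FALSE)
  run_manifest(config, csv, file.path(out, "sinuosity_manifest.yml"))
  invisible(df)
}

#' Run the variant cascade on a VCF
#'
#' Reads the focal VCF (first entry of `inputs`), the comparison VCFs, and --
#' when given -- the gene models and genome, runs [run_cascade()] and writes
#' the candidate table (TSV) plus the per-stage count report.
#'
#' @param config a [run_config()] with `inputs[1]` the focal VCF and
#'   optionally `comparison_vcfs`, `gff`, `genome` set.
#' @return The `cascade_report`, invisibly.
#' @export
cmd_variants <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  assert_that(length(config$inputs) >= 1, "config$inputs must name the focal VCF")
  out <- ensure_dir(config$output_dir)
  records <- read_variant_vcf(config$inputs[1], line_id = "focal")
  comparison <- lapply(config$comparison_vcfs, read_variant_vcf)
  models <- if (!is.null(config$gff)) read_gene_models(config$gff)
  genome <- if (!is.null(config$genome)) Biostrings::readDNAStringSet(config$genome)
  rep <- run_cascade(records, comparison_sets = comparison, models = models,
                     genome = genome)
  cand <- rep$candidates
  keep <- intersect(c("chrom", "pos", "ref", "alt", "gene_id", "consequence"),
                    names(cand))
  write.table(cand[, keep, drop = FALSE], file.path(out, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("stage\tn_in\tn_out",
               sprintf("%s\t%d\t%d", rep$counts$stage, rep$counts$n_in,
                       rep$counts$n_out)),
             file.path(out, "cascade_counts.tsv"))
  run_manifest(config, file.path(out, c("candidates.tsv", "cascade_counts.tsv")),
               file.path(out, "variants_manifest.yml"))
  invisible(rep)
}
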