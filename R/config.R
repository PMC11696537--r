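# YAML experiment configuration and pipeline commands.
#
# An experiment is fully described by a YAML file plus a master seed: the
# phantom spec, the noise ladders, the GAN and classifier configurations,
# the strategy list, and an output directory. Every stage derives its own
# seed from (master_seed, stage name, indices) via derive_seed(), so any
# artifact on disk is reproducible from the config file and master seed
# alone. cmd_fixtures / cmd_dream / cmd_run wrap the pipeline stages; a thin
# command-line wrapper over these functions ships in
# inst/scripts/dreamon-cli.R.

#' Assemble an experiment configuration
#'
#' @param phantom a [phantom_spec()].
#' @param noise list of [noise_spec()]s (default: all three families at
#'   their default base intensities).
#' @param gan a [gan_config()].
#' @param train a [train_config()].
#' @param strategies character vector of augmentation strategies.
#' @param output_dir output directory for artifacts.
#' @param master_seed master integer seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              noise = lapply(c("gaussian", "speckle",
                                               "salt_pepper"), noise_spec),
                              gan = gan_config(),
                              train = train_config(),
                              strategies = STRATEGIES,
                              output_dir = "dreamon_runs",
                              master_seed = 1L) {
  bad <- setdiff(strategies, STRATEGIES)
  if (length(bad))
    stop("unknown strategies: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(phantom = phantom, noise = noise, gan = gan, train = train,
                 strategies = strategies, output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Any field omitted from the YAML falls back to the package default; the
#' YAML mirrors the constructor arguments, e.g.
#' ```yaml
#' phantom: {n_images: 780, image_size: 128}
#' noise:
#'   - {family: gaussian, base_intensity: 0.02}
#' train: {epochs: 100, batch_size: 20, learning_rate: 0.001}
#' strategies: [vanilla, dreamon]
#' master_seed: 1
#' ```
#'
#' @param path YAML file path.
#' @param tiny if `TRUE`, apply the desk-scale preset on top (32 px
#'   phantoms, tiny classifier, short GAN schedules).
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path, tiny = FALSE) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config(
    phantom = do.call(phantom_spec, y$phantom %||% list()),
    noise = if (is.null(y$noise))
      lapply(c("gaussian", "speckle", "salt_pepper"), noise_spec)
    else lapply(y$noise, function(ns) do.call(noise_spec, ns)),
    gan = do.call(gan_config, y$gan %||% list()),
    train = do.call(train_config, y$train %||% list()),
    strategies = y$strategies %||% STRATEGIES,
    output_dir = y$output_dir %||% "dreamon_runs",
    master_seed = y$master_seed %||% 1L)
  if (tiny) tiny_preset(cfg) else cfg
}

#' Desk-scale preset for tests and demos
#'
#' Shrinks an experiment to sizes that complete in minutes on one CPU:
#' 32 px phantoms, the tiny classifier, short GAN schedules, and a single
#' run, leaving the scientific structure (splits, ladders, composition
#' rules) untouched.
#'
#' @param cfg an `experiment_config`.
#' @param n_images phantom count (default 240).
#' @return the modified `experiment_config`.
#' @export
tiny_preset <- function(cfg, n_images = 240L) {
  cfg$phantom$n_images <- as.integer(n_images)
  cfg$phantom$image_size <- 32L
  cfg$gan$image_size <- 32L
  cfg$gan$steps <- 200L
  cfg$gan$hidden <- 128L
  cfg$gan$batch_size <- 16L
  cfg$train$arch_scale <- "tiny"
  cfg$train$epochs <- 40L
  cfg$train$runs <- 1L
  cfg
}

#' Validate a configuration without computing anything
#'
#' The `--dry-run` path: re-runs all constructor invariants and checks the
#' split arithmetic, then reports the derived stage seeds.
#'
#' @param cfg an `experiment_config`.
#' @return `TRUE` (invisibly) if valid; otherwise an error is thrown.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  do.call(phantom_spec, unclass(cfg$phantom))
  for (ns in cfg$noise) do.call(noise_spec, unclass(ns))
  do.call(gan_config, unclass(cfg$gan))
  do.call(train_config, unclass(cfg$train))
  sizes <- largest_remainder(cfg$phantom$n_images, c(600, 90, 90) / 780)
  message("split sizes: ", paste(sizes, collapse = "/"))
  message("stage seeds: split=", derive_seed(cfg$master_seed, "split"),
          " noise=", derive_seed(cfg$master_seed, "noise"),
          " gan_mask=", derive_seed(cfg$master_seed, "gan_mask"),
          " gan_image=", derive_seed(cfg$master_seed, "gan_image"))
  invisible(TRUE)
}

#' Generate and write the phantom fixture dataset
#'
#' Wraps [generate_phantom_dataset()] + [split_dataset()] and writes one
#' PNG+manifest directory per split under `output_dir/fixtures/`.
#'
#' @param cfg an `experiment_config`.
#' @return named list of the three split manifests, invisibly.
#' @export
cmd_fixtures <- function(cfg) {
  ds <- generate_phantom_dataset(cfg$phantom)
  sizes <- largest_remainder(cfg$phantom$n_images, c(600, 90, 90) / 780)
  splits <- split_dataset(ds, sizes,
                          seed = derive_seed(cfg$master_seed, "split"))
  out <- lapply(names(splits), function(s)
    write_dataset(splits[[s]], file.path(cfg$output_dir, "fixtures", s)))
  invisible(stats::setNames(out, names(splits)))
}

#' Train the GANs and write DreamOn / DreamOff sets
#'
#' Reads the training fixture split, trains `G_m` and `G_s`, and writes
#' generated sets of the same size as the training split under
#' `output_dir/generated/`.
#'
#' @param cfg an `experiment_config`.
#' @return list with the two generated datasets, invisibly.
#' @export
cmd_dream <- function(cfg) {
  train <- read_dataset(file.path(cfg$output_dir, "fixtures", "train"))
  gm_cfg <- cfg$gan; gm_cfg$seed <- derive_seed(cfg$master_seed, "gan_mask")
  gs_cfg <- cfg$gan; gs_cfg$seed <- derive_seed(cfg$master_seed, "gan_image")
  G_m <- train_mask_gan(train$masks, gm_cfg)
  G_s <- train_image_gan(train, gs_cfg)
  n <- length(train)
  dre <- generate_dreamon_set(G_m, G_s, n, cfg$phantom$class_proportions,
                              seed = derive_seed(cfg$master_seed,
                                                 "dreamon_set"))
  off <- generate_dreamoff_set(G_m, G_s, n, cfg$phantom$class_proportions,
                               seed = derive_seed(cfg$master_seed,
                                                  "dreamoff_set"))
  write_dataset(dre, file.path(cfg$output_dir, "generated", "dreamon"))
  write_dataset(off, file.path(cfg$output_dir, "generated", "dreamoff"))
  invisible(list(dreamon = dre, dreamoff = off))
}

#' Run the full robustness experiment and write the report
#'
#' Wraps [run_experiment()] over the configured strategy grid and writes
#' the report (cells CSV + aggregates JSON) under `output_dir/report/`.
#'
#' @param cfg an `experiment_config`.
#' @return the `robustness_report`, invisibly.
#' @export
cmd_run <- function(cfg) {
  report <- run_experiment(cfg$strategies, cfg$phantom, cfg$noise,
                           config = cfg$train, gan = cfg$gan,
                           master_seed = cfg$master_seed)
  write_report(report, file.path(cfg$output_dir, "report"))
  invisible(report)
}
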