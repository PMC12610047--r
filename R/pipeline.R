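# End-to-end pipeline: YAML-configurable synth -> preprocess -> balance ->
# train -> evaluate run with a reproducibility manifest, plus the canned
# fixture builder used by the test suite.

#' Default pipeline configuration
#'
#' Nested stage configurations with one global seed fanned out
#' deterministically to every randomized stage. Round-trips losslessly
#' through YAML.
#'
#' @param seed Global seed.
#' @param n_subjects Synthetic cohort size.
#' @param arch Architecture: one of `"bilstm"`, `"spdae"`, `"rec_spdae"`,
#'   `"rcnn"`, `"deepconvlstm"`.
#' @param hidden_units Hidden units of the chosen architecture.
#' @param max_epochs Training epochs.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 6L, arch = "bilstm",
                            hidden_units = 32L, max_epochs = 30L,
                            out_dir = tempfile("mmhar_run_")) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synth = list(n_subjects = as.integer(n_subjects),
                 imbalance_n_fraction = 0.4, load_kg = 10, cycles = 12,
                 noise_sd = 0.02),
    balance = list(noise_sd_fraction = 0.05, max_ratio = 1.1),
    train = list(arch = arch, hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs), batch_size = 128L,
                 initial_lr = 1e-3, lr_drop_factor = 0.1,
                 lr_drop_period = 10L, l2 = 1e-4),
    eval = list(train_fraction = 0.7))
  validate_run_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

validate_run_config <- function(cfg) {
  need <- function(path, check) {
    node <- cfg
    for (k in path) {
      if (is.null(node[[k]])) {
        stop("config error at /", paste(path, collapse = "/"),
             ": missing entry", call. = FALSE)
      }
      node <- node[[k]]
    }
    if (!check(node)) {
      stop("config error at /", paste(path, collapse = "/"),
           ": invalid value", call. = FALSE)
    }
  }
  is_count <- function(x) is.numeric(x) && length(x) == 1 && x >= 1
  need("seed", function(x) is.numeric(x) && length(x) == 1)
  need(c("synth", "n_subjects"), is_count)
  need(c("train", "arch"),
       function(x) x %in% c("bilstm", "spdae", "rec_spdae", "rcnn",
                            "deepconvlstm"))
  need(c("train", "hidden_units"), is_count)
  need(c("train", "max_epochs"), is_count)
  need(c("eval", "train_fraction"),
       function(x) is.numeric(x) && x > 0 && x < 1)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

arch_builder_for <- function(arch, h) {
  switch(arch,
    bilstm = function() build_bilstm(h),
    rcnn = function() build_rcnn(h),
    deepconvlstm = function() build_deepconvlstm(h),
    spdae = NULL,  # handled by the two-phase trainer
    rec_spdae = NULL,
    stop("unknown architecture: ", arch, call. = FALSE))
}

#' Run the full pipeline from a configuration
#'
#' Generates the synthetic cohort, preprocesses and pools the windows,
#' splits 70-30 (stratified), balances the training portion, trains the
#' configured network, evaluates on the untouched test portion, and writes
#' the evaluation summary plus a manifest (config hash, seeds, artifact
#' paths) to the output directory.
#'
#' @param cfg A `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return Invisibly, a list with `eval` (the `eval_result`), `model`,
#'   `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  cohort <- generate_cohort(cfg$synth$n_subjects,
                            default_protocol(cfg$synth$load_kg,
                                             cfg$synth$cycles),
                            master_seed = derive_seed(seed, 1L),
                            imbalance_n_fraction = cfg$synth$imbalance_n_fraction,
                            noise_sd = cfg$synth$noise_sd)
  pooled <- preprocess_cohort(cohort)
  sp <- split_70_30(pooled, seed = derive_seed(seed, 2L),
                    train_fraction = cfg$eval$train_fraction)
  bal <- balance_dataset(sp$train,
                         balance_config(noise_sd_fraction = cfg$balance$noise_sd_fraction,
                                        seed = derive_seed(seed, 3L),
                                        max_ratio = cfg$balance$max_ratio))
  tc <- train_config(max_epochs = cfg$train$max_epochs,
                     batch_size = cfg$train$batch_size,
                     initial_lr = cfg$train$initial_lr,
                     lr_drop_factor = cfg$train$lr_drop_factor,
                     lr_drop_period = cfg$train$lr_drop_period,
                     l2 = cfg$train$l2, seed = derive_seed(seed, 4L))
  h <- cfg$train$hidden_units
  model <- switch(cfg$train$arch,
    spdae = train_spdae(bal, build_spdae(spdae_config(hidden_units = h,
                                                      seed = tc$seed)),
                        head_config = tc),
    rec_spdae = train_recurrent_spdae(
      bal, build_recurrent_spdae(h, max(8L, h %/% 2L)),
      spdae_cfg = spdae_config(hidden_units = h, seed = tc$seed),
      head_config = tc),
    train_network(bal, arch_builder_for(cfg$train$arch, h)(), tc))
  res <- evaluate_model(model, sp$test)

  cfg_for_hash <- unclass(cfg); cfg_for_hash$out_dir <- NULL
  manifest <- list(
    config = unclass(cfg),
    config_hash = config_hash(cfg_for_hash),
    stage_seeds = list(synth = derive_seed(seed, 1L),
                       split = derive_seed(seed, 2L),
                       balance = derive_seed(seed, 3L),
                       train = derive_seed(seed, 4L)),
    n_train = n_segments(bal), n_test = n_segments(sp$test),
    metrics = list(macro_f1 = res$macro_f1, accuracy = res$accuracy,
                   macro_precision = res$macro_precision))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yml"), precision = 15L)
  utils::write.csv(as.data.frame(res$cm),
                   file.path(cfg$out_dir, "confusion.csv"),
                   row.names = FALSE)
  yaml::write_yaml(manifest$metrics, file.path(cfg$out_dir, "metrics.yml"), precision = 15L)
  invisible(list(eval = res, model = model, manifest = manifest,
                 out_dir = cfg$out_dir))
}

# order-independent hash of the config tree (djb2 over serialized text)
config_hash <- function(x) {
  txt <- yaml::as.yaml(x)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build the canned test fixtures
#'
#' A small, fully deterministic bundle used by the test suite: a balanced
#' segment set covering all seven classes and a tiny trained BiLSTM
#' checkpoint.
#'
#' @param seed Integer seed.
#' @param n_subjects Number of synthetic subjects.
#' @param epochs Training epochs of the canned checkpoint.
#' @return List with `segments` (a [segment_set()]), `model` (a
#'   `har_model`), and `cohort`.
#' @export
make_fixtures <- function(seed = 1L, n_subjects = 2L, epochs = 3L) {
  cohort <- generate_cohort(n_subjects, default_protocol(cycles = 1L),
                            master_seed = seed)
  segments <- preprocess_cohort(cohort)
  model <- train_network(segments, build_bilstm(8L),
                         train_config(max_epochs = epochs, seed = seed))
  list(segments = segments, model = model, cohort = cohort)
}
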