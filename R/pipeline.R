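# End-to-end orchestration from a single plain-text (YAML) config:
# simulate or load a study -> SOM QC with permutation significance ->
# covariate-adjusted differential profile -> pathway enrichment ->
# gene- and pathway-level concordance against a disease target ->
# radial embedding of a compound library. Every output file carries the
# config hash and the stage seed in a comment header, and a manifest
# lists every output with its content hash. A single global seed
# deterministically derives per-stage seeds so stages are independently
# reproducible.

# stage seeds: global seed offset by a fixed stride per stage (kept well
# below .Machine$integer.max)
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, som = 2L, profile = 3L, enrich = 4L,
              concord = 5L, embed = 6L)
  (as.integer(seed) + 1009L * stages[[stage]]) %% .Machine$integer.max
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML config (or takes an equivalent named list) and checks it
#' against the schema before any compute. Either a `simulate` block
#' (passed to the synthetic generators) or explicit `inputs` paths must be
#' present.
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated config list of class `RunConfig`, with defaults
#'   filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
  } else cfg <- config
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  defaults <- list(seed = 1L, z_threshold = 2,
                   som = list(rows = 10L, cols = 10L, epochs = 10L,
                              n_perm = 200L, mode = "regress"),
                   enrichment = list(n_null = 500L),
                   embedding = list(transform = "chord", restarts = 3L))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  has_sim <- !is.null(cfg$simulate)
  has_inputs <- !is.null(cfg$inputs)
  if (!has_sim && !has_inputs)
    stop("config needs a 'simulate' block or an 'inputs' block")
  if (has_inputs) {
    for (key in c("matrix", "annotations"))
      if (is.null(cfg$inputs[[key]]))
        stop("inputs block lacks '", key, "'")
    for (key in c("matrix", "annotations")) {
      p <- cfg$inputs[[key]]
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    for (key in c("gmt", "target_profile"))
      if (!is.null(cfg$inputs[[key]]) && !file.exists(cfg$inputs[[key]]))
        stop("input path does not exist: ", cfg$inputs[[key]])
  }
  if (!cfg$som$mode %in% c("retrain", "regress"))
    stop("som mode must be 'retrain' or 'regress'")
  if (!cfg$embedding$transform %in% c("chord", "half"))
    stop("embedding transform must be 'chord' or 'half'")
  structure(cfg, class = c("RunConfig", "list"))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full signature-reversal pipeline
#'
#' Executes every stage on the configured (or simulated) inputs and writes
#' tab-separated outputs plus a `manifest.tsv` of content hashes into
#' `out_dir`. Stages: simulate/load, SOM QC (treatment and sex node maps,
#' permutation test, sex-residualised treatment map), differential
#' profile, pathway enrichment, gene- and pathway-level concordance
#' against the target, radial embedding of the drug library.
#'
#' @param config A [run_config()], a path to one, or a named list.
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "RunConfig")) config else run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- c(sprintf("config_hash=%s", hash),
           sprintf("seed=%d", as.integer(cfg$seed)))
  outputs <- character(0)
  emit <- function(df, file, stage) {
    path <- file.path(out_dir, file)
    write_tsv_commented(df, path,
                        c(hdr, sprintf("stage=%s seed=%d", stage,
                                       stage_seed(cfg$seed, stage))))
    outputs <<- c(outputs, path)
    path
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    des <- study_design(
      n_genes = sim$n_genes %||% 2000,
      n_treated = sim$n_treated %||% 7, n_control = sim$n_control %||% 10,
      effect_fraction = sim$effect_fraction %||% 0.05,
      effect_size = sim$effect_size %||% 2,
      sex_effect_size = sim$sex_effect_size %||% 1,
      noise_sd = sim$noise_sd %||% 1,
      seed = stage_seed(cfg$seed, "simulate"))
    synth <- generate_expression_study(des)
    study <- synth$study
    universe <- rownames(study$values)
    collection <- generate_gene_set_collection(
      n_sets = sim$n_sets %||% 200, size_range = sim$size_range %||% c(10, 100),
      universe = universe, seed = stage_seed(cfg$seed, "simulate") + 1L)
    target <- NULL   # built below from a profile family
  } else {
    study <- read_expression(cfg$inputs$matrix, cfg$inputs$annotations)
    collection <- if (!is.null(cfg$inputs$gmt)) read_gmt(cfg$inputs$gmt)
    target <- if (!is.null(cfg$inputs$target_profile))
      read_profile(cfg$inputs$target_profile, name = "target")
  }

  # -- SOM QC ---------------------------------------------------------------
  std <- standardize(study)
  grid <- som_grid(rows = cfg$som$rows, cols = cfg$som$cols,
                   seed = stage_seed(cfg$seed, "som"))
  trained <- train_som(std, grid, epochs = cfg$som$epochs)
  map_tr <- regress_weights(trained, "treatment", std$annotations)
  map_sex <- regress_weights(trained, "sex", std$annotations)
  perm <- permutation_significance(
    std, "treatment", n_perm = cfg$som$n_perm,
    seed = stage_seed(cfg$seed, "som"), mode = cfg$som$mode,
    grid = grid, epochs = cfg$som$epochs)
  resid <- residualize(study, "sex")
  trained_res <- train_som(standardize(resid), grid,
                           epochs = cfg$som$epochs)
  map_res <- regress_weights(trained_res, "treatment", std$annotations)
  emit(as.data.frame(unclass(map_tr)), "som_treatment_z.tsv", "som")
  emit(as.data.frame(unclass(map_sex)), "som_sex_z.tsv", "som")
  emit(as.data.frame(unclass(map_res)), "som_treatment_residual_z.tsv",
       "som")
  emit(data.frame(null_max_abs_z = perm$null), "som_permutation_null.tsv",
       "som")
  emit(data.frame(statistic = perm$statistic, n_perm = perm$n_perm,
                  n_exceed = perm$n_exceed, p = perm$p, mode = perm$mode),
       "som_permutation_test.tsv", "som")

  # -- differential profile -------------------------------------------------
  prof <- differential_profile(study, name = "treatment_profile")
  emit(as.data.frame(prof), "profile.tsv", "profile")
  tc <- threshold_counts(prof, cfg$z_threshold)
  emit(data.frame(n_up = tc$n_up, n_down = tc$n_down,
                  threshold = tc$threshold),
       "profile_threshold_counts.tsv", "profile")

  # -- enrichment -----------------------------------------------------------
  enr <- NULL
  if (!is.null(collection)) {
    enr <- enrich_collection(prof, collection,
                             n_null = cfg$enrichment$n_null,
                             seed = stage_seed(cfg$seed, "enrich"))
    emit(as.data.frame(enr), "enrichment.tsv", "enrich")
  }

  # -- target + concordance -------------------------------------------------
  if (is.null(target) && !is.null(cfg$simulate)) {
    # disease family whose shared signal is the reverse of the treatment
    # profile: the scenario the analysis is built to detect
    fam <- generate_profile_family(profile_family_design(
      n_genes = nrow(study$values),
      n_profiles = cfg$simulate$n_disease_profiles %||% 12,
      shared_fraction = cfg$simulate$shared_fraction %||% 0.5,
      seed = stage_seed(cfg$seed, "concord")),
      common_signal = -prof$z)
    target <- composite_profile(fam, name = "disease_composite")
  }
  concord <- NULL
  # an overlap with no co-significant feature is a legitimate (null)
  # outcome at pipeline level: record an empty table instead of aborting
  concord_df <- function(a, b, level) {
    rep <- tryCatch(concordance_report(a, b, level = level,
                                       z_threshold = cfg$z_threshold),
                    error = function(e) NULL)
    if (is.null(rep)) {
      message("concordance (", level, "): no co-significant features")
      return(list(rep = NULL,
                  df = data.frame(UU = 0L, UD = 0L, DU = 0L, DD = 0L,
                                  c = NA_real_, p = NA_real_,
                                  alternative = "anti",
                                  threshold = cfg$z_threshold,
                                  level = level)))
    }
    list(rep = rep, df = with(rep, data.frame(
      UU = table$UU, UD = table$UD, DU = table$DU, DD = table$DD,
      c = c, p = p, alternative = alternative, threshold = threshold,
      level = level)))
  }
  if (!is.null(target)) {
    cg <- concord_df(prof, target, "gene")
    concord <- cg$rep
    emit(cg$df, "concordance_gene.tsv", "concord")
    if (!is.null(enr) && !is.null(collection)) {
      enr_target <- enrich_collection(target, collection,
                                      n_null = cfg$enrichment$n_null,
                                      seed = stage_seed(cfg$seed, "enrich"))
      cp <- concord_df(enrichment_z_profile(enr),
                       enrichment_z_profile(enr_target), "pathway")
      emit(cp$df, "concordance_pathway.tsv", "concord")
    }
  }

  # -- embedding ------------------------------------------------------------
  layout <- NULL
  if (!is.null(target) && !is.null(cfg$simulate)) {
    drugs <- generate_drug_library(
      target, n_drugs = cfg$simulate$n_drugs %||% 20,
      planted_correlations = cfg$simulate$planted_correlations %||%
        seq(-0.8, 0.8, length.out = cfg$simulate$n_drugs %||% 20),
      seed = stage_seed(cfg$seed, "embed"))
    model <- build_distance_model(target, drugs,
                                  z_threshold = cfg$z_threshold,
                                  transform = cfg$embedding$transform)
    layout <- optimize_layout(model, seed = stage_seed(cfg$seed, "embed"),
                              restarts = cfg$embedding$restarts)
    emit(as.data.frame(layout), "layout.tsv", "embed")
  }

  # -- manifest -------------------------------------------------------------
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  write_tsv_commented(manifest, file.path(out_dir, "manifest.tsv"), hdr)
  invisible(list(study = study, som = list(treatment = map_tr,
                                           sex = map_sex,
                                           residual = map_res,
                                           permutation = perm),
                 profile = prof, enrichment = enr, concordance = concord,
                 layout = layout, manifest = manifest, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
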