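# End-to-end pipeline: simulate -> fitness -> niche space -> evolution ->
# statistics, with a reproducibility manifest.

#' Run the full pipeline
#'
#' Executes every stage with one configuration and one seed: builds the
#' 29-combination design, simulates the fitness-assay study from the
#' ground-truth landscape, estimates replicate and aggregated growth
#' rates, computes all niche-space S values and their evolutionary
#' changes, simulates one serial-transfer evolution per genome, runs the
#' Evo-vs-Anc significance matrix and the deletion-size correlations, and
#' writes everything as CSV plus a JSON manifest (seed, versions, file
#' hashes, row counts). Identical (config, seed) pairs produce identical
#' outputs.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Overrides `config$out_dir` when given.
#' @param quiet Suppress stage progress messages.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = default_config(), seed = NULL, out_dir = NULL,
                    quiet = FALSE) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  seed <- as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[nichespan] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("design: building medium combinations")
  lv <- config$design$levels_per_compound
  if (length(lv) == 1 && is.null(names(lv))) {
    lv <- stats::setNames(rep(as.integer(lv), 7), compound_names())
  }
  design <- stage("design", build_design_matrix(
    levels_per_compound = lv, log_step = config$design$log_step))
  utils::write.csv(design_ions_table(design),
                   file.path(out, "design_ions.csv"), row.names = FALSE)
  utils::write.csv(design_compounds_table(design),
                   file.path(out, "design_compounds.csv"),
                   row.names = FALSE)

  say("simulate: growth curves for the full study")
  ls_cfg <- config$landscape
  landscape <- stage("landscape", fitness_landscape(
    design, mu0 = ls_cfg$mu0, deficit_per_mb = ls_cfg$deficit_per_mb,
    recovery_per_mb = ls_cfg$recovery_per_mb, width = ls_cfg$width,
    narrow_per_mb = ls_cfg$narrow_per_mb,
    narrowed_constituents = ls_cfg$narrowed_constituents,
    floor_mu = ls_cfg$floor_mu))
  st <- config$study
  curves <- stage("simulate", simulate_study(
    design, landscape, replicates = st$replicates, seed = seed,
    t_end = st$t_end, dt = st$dt, od0 = st$od0, k_cap = st$k_cap,
    noise_sd_additive = st$noise_sd_additive,
    noise_sd_multiplicative = st$noise_sd_multiplicative,
    lag_h = st$lag_h))
  write_curves(curves, file.path(out, "curves.csv"))

  say("fitness: windowed maximal growth rates")
  reps <- stage("fitness", fitness_replicates(
    curves, window = config$kinetics$window,
    od_floor = config$kinetics$od_floor,
    blank_od = config$kinetics$blank_od))
  fit_tab <- fitness_table(reps)
  utils::write.csv(reps, file.path(out, "fitness_replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_tab, file.path(out, "fitness.csv"),
                   row.names = FALSE)

  say("niche: S values and niche broadness")
  S <- stage("niche", batch_S(
    fit_tab, design,
    pseudo_floor_decades = config$design$pseudo_floor_decades,
    clip_negative = config$niche$clip_negative))
  utils::write.csv(S$S_values, file.path(out, "S_values.csv"),
                   row.names = FALSE)
  utils::write.csv(S$broadness, file.path(out, "S_totals.csv"),
                   row.names = FALSE)
  utils::write.csv(S$delta, file.path(out, "S_delta.csv"),
                   row.names = FALSE)
  utils::write.csv(S$delta_totals, file.path(out, "S_delta_totals.csv"),
                   row.names = FALSE)

  say("evolve: serial-transfer simulations per genome")
  ev <- config$evolution
  protocol <- transfer_protocol(selection_od = ev$selection_od,
                                total_days = ev$total_days,
                                k_cap = ev$k_cap, init_od = ev$init_od)
  model <- mutation_model(rate_per_gen = ev$rate_per_gen,
                          supply_per_mb = ev$supply_per_mb,
                          effect_mean = ev$effect_mean,
                          diminishing_returns = ev$diminishing_returns,
                          effect_shape = ev$effect_shape,
                          f0 = ev$f0, fix_threshold = ev$fix_threshold)
  trajectories <- stage("evolve", {
    trs <- list()
    for (i in seq_len(nrow(landscape$genomes))) {
      g <- landscape$genomes$genome[i]
      anc_peak <- landscape_row(landscape, g, "Anc", "glucose")$mu_at_peak
      trs[[g]] <- run_evolution(
        base_mu = anc_peak,
        deletion_kb = landscape$genomes$deletion_kb[i],
        protocol = protocol, model = model,
        seed = stable_hash(seed, "evolution", g), genome = g)
    }
    trs
  })
  traj_tab <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(genome = tr$genome, tr$transfers)
  }))
  rownames(traj_tab) <- NULL
  utils::write.csv(traj_tab, file.path(out, "trajectories.csv"),
                   row.names = FALSE)
  mut_tab <- do.call(rbind, lapply(trajectories, function(tr) {
    if (nrow(tr$mutations) == 0) return(NULL)
    data.frame(genome = tr$genome, tr$mutations)
  }))
  if (is.null(mut_tab)) {
    mut_tab <- data.frame(genome = character(0), label = character(0),
                          effect = numeric(0),
                          appearance_generation = numeric(0),
                          fixation_generation = numeric(0),
                          mu_before = numeric(0))
  }
  rownames(mut_tab) <- NULL
  utils::write.csv(mut_tab, file.path(out, "mutations.csv"),
                   row.names = FALSE)

  say("report: significance matrix, correlations, figure tables")
  sig <- stage("report", anc_evo_tests(reps))
  utils::write.csv(sig$table, file.path(out, "significance.csv"),
                   row.names = FALSE)
  cors <- stage("report", pipeline_correlations(
    fit_tab, S, trajectories, landscape$genomes, design$reference_id))
  utils::write.csv(cors, file.path(out, "correlations.csv"),
                   row.names = FALSE)
  figure_tables(S, genomes = landscape$genomes,
                trajectories = trajectories,
                out_dir = file.path(out, "tables"))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[grepl("\\.csv$", files)]
  manifest <- list(
    package = "nichespan",
    version = as.character(utils::packageVersion("nichespan")),
    seed = seed,
    n_combinations = length(design$combinations),
    n_constituents = length(constituent_names()),
    n_curves = nrow(unique(curves[c("genome", "population",
                                    "combination_id", "replicate")])),
    n_S_values = nrow(S$S_values),
    n_delta_S = nrow(S$delta),
    files = lapply(files, function(f) {
      list(path = sub(paste0("^", out, "/?"), "", f),
           md5 = unname(tools::md5sum(f)),
           rows = nrow(utils::read.csv(f)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Deletion-size correlations across the genome panel, in the reference
# environment: ancestral fitness, evolved/ancestral ratio, change in S_T,
# and the within-ladder pre-fixation-rate vs gain correlation.
pipeline_correlations <- function(fit_tab, S, trajectories, genomes,
                                  reference_id) {
  ref <- fit_tab[fit_tab$combination_id == reference_id, ]
  anc <- ref[ref$population == "Anc", c("genome", "mu_mean")]
  evo <- ref[ref$population == "Evo", c("genome", "mu_mean")]
  m <- merge(merge(anc, evo, by = "genome", suffixes = c("_anc", "_evo")),
             genomes, by = "genome")
  rows <- list()
  add <- function(name, cr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = name, rho = cr$rho, p_value = cr$p_value, n = cr$n,
      method = cr$method)
  }
  add("deletion_vs_anc_mu_C0",
      spearman(m$deletion_kb, m$mu_mean_anc))
  add("deletion_vs_mu_ratio_C0",
      spearman(m$deletion_kb, m$mu_mean_evo / m$mu_mean_anc))
  dt <- merge(S$delta_totals, genomes, by = "genome")
  if (nrow(dt) >= 3) {
    add("deletion_vs_delta_S_T", spearman(dt$deletion_kb, dt$delta_S_T))
  }
  sa <- merge(stats::aggregate(S ~ genome,
                               S$S_values[S$S_values$population == "Anc", ],
                               sum),
              genomes, by = "genome")
  if (nrow(sa) >= 3) {
    add("deletion_vs_anc_S_T", spearman(sa$deletion_kb, sa$S))
  }
  lad <- do.call(rbind, lapply(trajectories, function(tr) tr$mutations))
  if (!is.null(lad) && nrow(lad) >= 3 && stats::sd(lad$mu_before) > 0) {
    add("pre_fixation_mu_vs_gain", spearman(lad$mu_before, lad$effect))
  }
  do.call(rbind, rows)
}
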