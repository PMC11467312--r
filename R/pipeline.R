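#' Config-driven study pipeline
#'
#' A study configuration (YAML or an R list) drives the full chain:
#' simulate -> preprocess -> behavior -> connectivity -> network -> stats.
#' [simulate_study()] writes a study directory (per-subject epoch files,
#' behavior logs, cohort table, manifest); [run_study()] consumes it and
#' writes connectivity matrices, metric tables, cluster-test results, and
#' behavioral comparisons. [reproduce_cohort_stats()] recomputes the cohort
#' comparison table from the bundled reference cohort.
#'
#' @name pipeline
NULL

default_config <- function() {
  list(
    seed = 1L,
    study = list(
      n_subacute = 13L, n_chronic = 14L,
      sampling_rate = 250, n_trials = 75,
      epoch_window = c(-300, 500),
      noise_exponent = 1, osc_snr = 2, noise_amp_uv = 10,
      coupling = list()
    ),
    behavior = list(
      hit_p = 0.95, fa_p = 0.15, rt_sdlog = 0.25,
      rt_median_subacute_ms = 450, rt_median_chronic_ms = 520,
      rt_between_sdlog = 0.15
    ),
    bands = c("theta", "alpha", "beta", "gamma"),
    preproc = list(reference = "FCz", reject_uv = 150),
    connectivity = list(trial_selector = "NoGo-CR", guard_fraction = 0.1),
    network = list(gamma = 1, n_restarts = 100),
    stats = list(n_perm = 1024, cluster_alpha = 0.05)
  )
}

config_schema <- function() {
  list(
    seed = "numeric",
    study = list(
      n_subacute = "numeric", n_chronic = "numeric",
      sampling_rate = "numeric", n_trials = "numeric",
      epoch_window = "numeric", noise_exponent = "numeric",
      osc_snr = "numeric", noise_amp_uv = "numeric", coupling = "list"
    ),
    behavior = list(
      hit_p = "numeric", fa_p = "numeric", rt_sdlog = "numeric",
      rt_median_subacute_ms = "numeric", rt_median_chronic_ms = "numeric",
      rt_between_sdlog = "numeric"
    ),
    bands = "character",
    preproc = list(reference = "character", reject_uv = "numeric"),
    connectivity = list(trial_selector = "character",
                        guard_fraction = "numeric"),
    network = list(gamma = "numeric", n_restarts = "numeric"),
    stats = list(n_perm = "numeric", cluster_alpha = "numeric")
  )
}

check_against_schema <- function(x, schema, path = "") {
  for (key in names(x)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema)) stop("unknown config key: ", full)
    sch <- schema[[key]]
    if (is.list(sch)) {
      if (!is.list(x[[key]])) stop("config key ", full, " must be a section")
      check_against_schema(x[[key]], sch, full)
    } else if (sch == "numeric" && !is.numeric(x[[key]])) {
      stop("config key ", full, " must be numeric")
    } else if (sch == "character" && !is.character(x[[key]])) {
      stop("config key ", full, " must be character")
    }
  }
  invisible(x)
}

#' Load and validate a study configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults. Coupling
#' entries are lists with `group`, `pair` (2 labels), `band`, and optional
#' `phase_lag` (radians) and `strength`.
#'
#' @param config path to a YAML file, or a config list
#' @return the validated, default-completed config list
#' @export
study_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_against_schema(config, config_schema())
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  # modifyList merges by name and would drop the unnamed coupling entries
  if (!is.null(config$study$coupling)) {
    cfg$study$coupling <- config$study$coupling
  }
  for (b in cfg$bands) band_spec(b)  # errors on unknown band names
  for (cp in cfg$study$coupling) {
    stopifnot(is.list(cp))
    need <- setdiff(c("group", "pair", "band"), names(cp))
    if (length(need)) stop("coupling entry missing: ",
                           paste(need, collapse = ", "))
    if (!cp$group %in% c("subacute", "chronic")) {
      stop("coupling group must be subacute or chronic: ", cp$group)
    }
    bs <- band_spec(cp$band)
    if (!is.null(cp$low) || !is.null(cp$high)) stop("unknown coupling keys")
    coupling_spec(cp$pair, bs,
                  phase_lag = cp$phase_lag %||% pi / 2,
                  strength = cp$strength %||% 1)  # validates
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_to_study_spec <- function(cfg) {
  coupling <- list(subacute = list(), chronic = list())
  for (cp in cfg$study$coupling) {
    cs <- coupling_spec(cp$pair, band_spec(cp$band),
                        phase_lag = cp$phase_lag %||% pi / 2,
                        strength = cp$strength %||% 1)
    coupling[[cp$group]] <- c(coupling[[cp$group]], list(cs))
  }
  study_spec(
    n_subjects = c(subacute = as.integer(cfg$study$n_subacute),
                   chronic = as.integer(cfg$study$n_chronic)),
    sampling_rate = cfg$study$sampling_rate,
    n_trials = cfg$study$n_trials,
    epoch_window = cfg$study$epoch_window,
    coupling = coupling,
    noise_exponent = cfg$study$noise_exponent,
    osc_snr = cfg$study$osc_snr,
    noise_amp_uv = cfg$study$noise_amp_uv,
    seed = cfg$seed
  )
}

#' Simulate a study directory
#'
#' Writes one epochs file pair and one behavior log per subject, the cohort
#' CSV, the resolved config, and `manifest.json`.
#'
#' @param config a [study_config()] input (list or YAML path)
#' @param dir output directory (created if needed)
#' @return the manifest list, invisibly
#' @export
simulate_study <- function(config = list(), dir) {
  cfg <- study_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("unwritable study directory: ", dir)
  spec <- config_to_study_spec(cfg)
  recs <- generate_coupled_epochs(spec)
  groups <- vapply(recs, attr, "", "group")

  local_rng(cfg$seed + 1)
  beh_seeds <- sample.int(2147483646, length(recs))
  rt_mults <- exp(stats::rnorm(length(recs), 0, cfg$behavior$rt_between_sdlog))

  subjects <- list()
  for (i in seq_along(recs)) {
    stem <- file.path(dir, names(recs)[i])
    write_epochs(recs[[i]], stem)
    med <- if (groups[i] == "subacute") {
      cfg$behavior$rt_median_subacute_ms
    } else {
      cfg$behavior$rt_median_chronic_ms
    }
    log <- generate_behavior(
      task_spec(),
      subject = list(hit_p = cfg$behavior$hit_p, fa_p = cfg$behavior$fa_p,
                     rt_median_ms = med * rt_mults[i],
                     rt_sdlog = cfg$behavior$rt_sdlog),
      seed = beh_seeds[i])
    write_trial_log(log, paste0(stem, "_behavior.csv"))
    subjects[[i]] <- list(id = names(recs)[i], group = groups[i],
                          epochs = paste0(names(recs)[i], c(".bin", ".json")),
                          behavior = paste0(names(recs)[i], "_behavior.csv"))
  }
  cohort <- generate_cohort(cohort_spec(n_subacute = cfg$study$n_subacute,
                                        n_chronic = cfg$study$n_chronic),
                            seed = cfg$seed + 2)
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- list(
    format = "ciplvnet-study", version = 1L, seed = cfg$seed,
    config_md5 = unname(tools::md5sum(file.path(dir, "config.yaml"))),
    n_subjects = length(recs), subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# nodal metric matrix (subjects x channels) for one metric/band
nodal_feature_matrix <- function(metric_sets, band, metric) {
  t(vapply(metric_sets, function(ms) ms[[band]][[metric]],
           numeric(length(metric_sets[[1]][[band]][[metric]]))))
}

#' Run the analysis chain on a simulated study directory
#'
#' Per subject: artifact rejection, re-referencing, ciPLV connectivity per
#' band over the selected trials, and graph metrics. Group level: edge-space
#' cluster tests per band, sensor-space cluster tests per band and nodal
#' metric, Mann-Whitney comparisons of the global metrics, and behavioral
#' scoring with RT and d' comparisons. All outputs are written under
#' `out_dir`; a run log records seeds, the config hash, and per-stage counts.
#'
#' @param study_dir directory written by [simulate_study()]
#' @param out_dir output directory (default `<study_dir>/results`)
#' @param config optional config overriding the one stored in the study
#'   directory
#' @return a list with the main results (invisibly returns file paths too)
#' @export
run_study <- function(study_dir, out_dir = file.path(study_dir, "results"),
                      config = NULL) {
  manifest <- jsonlite::read_json(file.path(study_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!identical(manifest$format, "ciplvnet-study")) {
    stop("not a study directory: ", study_dir)
  }
  cfg <- study_config(config %||% file.path(study_dir, "config.yaml"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bands <- lapply(cfg$bands, band_spec)
  names(bands) <- cfg$bands

  ids <- vapply(manifest$subjects, `[[`, "", "id")
  groups <- vapply(manifest$subjects, `[[`, "", "group")
  n_rejected <- integer(length(ids))
  conn <- list()      # conn[[subject]][[band]] connectivity_matrix
  metrics <- list()   # metrics[[subject]][[band]] network_metric_set
  behavior <- list()

  local_rng(cfg$seed + 3)
  louvain_seeds <- matrix(sample.int(2147483646, length(ids) * length(bands)),
                          nrow = length(ids))
  for (i in seq_along(ids)) {
    rec <- read_epochs(file.path(study_dir, ids[i]))
    rec <- reject_epochs(rec, cfg$preproc$reject_uv)
    n_rejected[i] <- attr(rec, "rejection_log")$n_rejected
    rec <- rereference(rec, cfg$preproc$reference)
    conn[[ids[i]]] <- lapply(bands, function(b) {
      connectivity_matrix(rec, b,
                          trial_selector = cfg$connectivity$trial_selector,
                          guard_fraction = cfg$connectivity$guard_fraction)
    })
    metrics[[ids[i]]] <- lapply(seq_along(bands), function(bi) {
      metric_set(conn[[ids[i]]][[bi]], gamma = cfg$network$gamma,
                 n_restarts = cfg$network$n_restarts,
                 seed = louvain_seeds[i, bi])
    })
    names(metrics[[ids[i]]]) <- names(bands)
    behavior[[ids[i]]] <- score_log(
      read_trial_log(file.path(study_dir, paste0(ids[i], "_behavior.csv"))))
  }
  channels <- conn[[1]][[1]]$channels

  # stacked connectivity container: subjects x bands x channels x channels
  arr <- array(NA_real_, c(length(ids), length(bands), length(channels),
                           length(channels)))
  for (i in seq_along(ids)) {
    for (bi in seq_along(bands)) arr[i, bi, , ] <- conn[[i]][[bi]]$values
  }
  con <- file(file.path(out_dir, "connectivity.bin"), "wb")
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "ciplvnet-connectivity-stack", version = 1L,
         dim = dim(arr), subjects = ids, bands = names(bands),
         channels = channels),
    file.path(out_dir, "connectivity.json"), auto_unbox = TRUE, digits = NA)

  # nodal metric table
  metric_names <- c("nodal_efficiency", "nodal_clustering", "nodal_modularity")
  rows <- list()
  for (i in seq_along(ids)) {
    for (b in names(bands)) {
      ms <- metrics[[i]][[b]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = ids[i], group = groups[i], band = b, channel = channels,
        nodal_efficiency = unname(ms$nodal_efficiency),
        nodal_clustering = unname(ms$nodal_clustering),
        nodal_modularity = unname(ms$nodal_modularity),
        global_efficiency = ms$global_efficiency,
        global_clustering = ms$global_clustering,
        modularity_Q = ms$modularity_Q,
        stringsAsFactors = FALSE)
    }
  }
  metric_table <- do.call(rbind, rows)
  utils::write.csv(metric_table, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  # group-level cluster tests
  local_rng(cfg$seed + 4)
  stat_seeds <- sample.int(2147483646, length(bands) * (1 + length(metric_names)))
  e_adj <- edge_adjacency(channels)
  s_adj <- sensor_adjacency(montage_subset(standard_montage_32(), channels))
  is_a <- groups == "subacute"
  edge_tests <- list()
  sensor_tests <- list()
  si <- 0
  for (b in names(bands)) {
    feats <- edge_features(lapply(seq_along(ids), function(i) conn[[i]][[b]]))
    si <- si + 1
    edge_tests[[b]] <- cluster_permutation_test(
      feats[is_a, , drop = FALSE], feats[!is_a, , drop = FALSE], e_adj,
      n_perm = cfg$stats$n_perm, cluster_alpha = cfg$stats$cluster_alpha,
      seed = stat_seeds[si])
    sensor_tests[[b]] <- list()
    for (mn in metric_names) {
      nf <- nodal_feature_matrix(metrics, b, mn)
      colnames(nf) <- channels
      si <- si + 1
      sensor_tests[[b]][[mn]] <- cluster_permutation_test(
        nf[is_a, , drop = FALSE], nf[!is_a, , drop = FALSE], s_adj,
        n_perm = cfg$stats$n_perm, cluster_alpha = cfg$stats$cluster_alpha,
        seed = stat_seeds[si])
    }
  }
  cluster_json <- lapply(names(bands), function(b) {
    et <- edge_tests[[b]]
    list(band = b,
         edge_clusters = lapply(seq_along(et$clusters), function(k) {
           list(features = et$cluster_features[[k]],
                mass = et$cluster_mass[k], p_value = et$p_value[k])
         }),
         edge_test = list(n_perm = et$n_perm, t_threshold = et$t_threshold,
                          seed = et$seed),
         sensor_clusters = lapply(metric_names, function(mn) {
           st <- sensor_tests[[b]][[mn]]
           list(metric = mn, n_perm = st$n_perm, seed = st$seed,
                clusters = lapply(seq_along(st$clusters), function(k) {
                  list(features = st$cluster_features[[k]],
                       mass = st$cluster_mass[k], p_value = st$p_value[k])
                }))
         }))
  })
  jsonlite::write_json(cluster_json, file.path(out_dir, "cluster_tests.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # global metric group comparisons (Mann-Whitney)
  gm_rows <- list()
  for (b in names(bands)) {
    for (gmn in c("global_efficiency", "global_clustering", "modularity_Q")) {
      v <- vapply(seq_along(ids), function(i) metrics[[i]][[b]][[gmn]], 0)
      u <- mann_whitney_u(v[is_a], v[!is_a])
      gm_rows[[length(gm_rows) + 1]] <- data.frame(
        band = b, metric = gmn,
        mean_subacute = mean(v[is_a]), mean_chronic = mean(v[!is_a]),
        pct_diff_vs_subacute = 100 * (mean(v[is_a]) - mean(v[!is_a])) /
          mean(v[is_a]),
        U = u$U, p_value = u$p_value, stringsAsFactors = FALSE)
    }
  }
  global_comparison <- do.call(rbind, gm_rows)
  utils::write.csv(global_comparison,
                   file.path(out_dir, "global_metrics_comparison.csv"),
                   row.names = FALSE)

  # behavior summaries + group comparisons
  beh <- data.frame(
    subject = ids, group = groups,
    hits = vapply(behavior, `[[`, 0, "hits"),
    false_alarms = vapply(behavior, `[[`, 0, "false_alarms"),
    hit_rate = vapply(behavior, `[[`, 0, "hit_rate"),
    fa_rate = vapply(behavior, `[[`, 0, "fa_rate"),
    d_prime = vapply(behavior, `[[`, 0, "d_prime"),
    mean_rt = vapply(behavior, `[[`, 0, "mean_rt"),
    median_rt = vapply(behavior, `[[`, 0, "median_rt"),
    stringsAsFactors = FALSE)
  utils::write.csv(beh, file.path(out_dir, "behavior.csv"), row.names = FALSE)
  rt_u <- mann_whitney_u(beh$mean_rt[is_a], beh$mean_rt[!is_a])
  dp_u <- mann_whitney_u(beh$d_prime[is_a], beh$d_prime[!is_a])
  behavior_comparison <- data.frame(
    measure = c("mean_rt_ms", "d_prime"),
    U = c(rt_u$U, dp_u$U),
    p_value = c(rt_u$p_value, dp_u$p_value))
  utils::write.csv(behavior_comparison,
                   file.path(out_dir, "behavior_comparison.csv"),
                   row.names = FALSE)

  run_log <- list(
    config_md5 = unname(tools::md5sum(file.path(study_dir, "config.yaml"))),
    seed = cfg$seed, n_subjects = length(ids),
    trials_rejected = as.list(stats::setNames(n_rejected, ids)),
    n_edge_clusters = vapply(edge_tests, function(t) length(t$clusters), 0L),
    n_perm = cfg$stats$n_perm
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(edge_tests = edge_tests, sensor_tests = sensor_tests,
                 global_comparison = global_comparison,
                 behavior = beh, behavior_comparison = behavior_comparison,
                 metric_table = metric_table, out_dir = out_dir))
}

#' Recompute the reference-cohort comparison table
#'
#' Runs [cohort_stats()] on the bundled cohort and reports the published
#' values alongside the recomputed ones.
#'
#' @return data frame with recomputed and published statistics per variable
#' @export
reproduce_cohort_stats <- function() {
  st <- cohort_stats(load_reference_cohort())
  st$published_statistic <- c(1.45, 0.0, -2.42, 7.42)
  st$published_p <- c(0.16, 0.001, 0.025, 0.006)
  st$published_p_is_upper_bound <- c(FALSE, TRUE, FALSE, FALSE)
  st
}
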