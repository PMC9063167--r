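#' Pipeline configuration
#'
#' Bundles the simulation config, paradigm spec, connectivity and NBS
#' settings for [run_pipeline()]. Study-scale defaults: both metrics, all
#' five bands, 10 s epochs with 1 s edge trim, 10 mm motion rejection,
#' minimum 3 trials per condition, primary thresholds t = 3.0 (both
#' metrics) and F = 7, 5000 permutations, Bonferroni within metric.
#'
#' @param sim A [simulation_config()].
#' @param paradigm A [paradigm_spec()]; its trial counts set the simulated
#'   familiar/unfamiliar trial numbers per subject.
#' @param metrics Metrics to compute (`"AEC"`, `"wPLI"`).
#' @param analyses Which NBS analyses to run: subset of `"within"`,
#'   `"between"`, `"interaction"`.
#' @param mode `"whole_brain"` or `"roi"`.
#' @param seeds Seed parcel indices for ROI mode.
#' @param epoch_s Epoch length (s).
#' @param trim_s Hilbert edge trim (s).
#' @param motion_threshold_mm Motion rejection threshold.
#' @param min_trials Minimum trials per condition for inclusion.
#' @param thresholds Named list of primary thresholds (`AEC`, `wPLI` in t
#'   units, `interaction` in F units).
#' @param n_permutations NBS permutations.
#' @param alpha Component-level alpha before Bonferroni.
#' @param n_rest_trials Simulated resting trials (each `trial_duration_s`).
#' @param groups Group labels (first label = group 1 in contrasts).
#' @param use_sensors Route the simulation through sensor space (forward
#'   projection, ICA artifact removal, LCMV beamforming) instead of using
#'   parcel signals directly.
#' @param behavior Optional behavior table (`subject`, `group`, score
#'   columns); synthesized when `NULL` and behavior analysis is requested.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, paradigm,
                            metrics = c("AEC", "wPLI"),
                            analyses = c("within", "between", "interaction"),
                            mode = c("whole_brain", "roi"), seeds = NULL,
                            epoch_s = 10, trim_s = 1,
                            motion_threshold_mm = 10, min_trials = 3L,
                            thresholds = list(AEC = 3.0, wPLI = 3.0,
                                              interaction = 7),
                            n_permutations = 5000L, alpha = 0.05,
                            n_rest_trials = 2L,
                            groups = c("ASD", "TD"),
                            use_sensors = FALSE, behavior = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "simulation_config"),
            inherits(paradigm, "paradigm_spec"),
            all(metrics %in% c("AEC", "wPLI")),
            all(analyses %in% c("within", "between", "interaction")),
            length(groups) == 2,
            epoch_s > 0, motion_threshold_mm > 0, min_trials >= 1,
            n_permutations >= 1)
  if (mode == "roi" && (is.null(seeds) || length(seeds) == 0)) {
    stop("ROI mode requires seed indices", call. = FALSE)
  }
  structure(list(sim = sim, paradigm = paradigm, metrics = metrics,
                 analyses = analyses, mode = mode, seeds = seeds,
                 epoch_s = epoch_s, trim_s = trim_s,
                 motion_threshold_mm = motion_threshold_mm,
                 min_trials = as.integer(min_trials),
                 thresholds = thresholds,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 n_rest_trials = as.integer(n_rest_trials), groups = groups,
                 use_sensors = use_sensors, behavior = behavior),
            class = "pipeline_config")
}

# per-trial connectivity matrices for every band and metric
trial_connectivity <- function(trials_data, fs, cfg) {
  bands <- cfg$sim$bands
  res <- list()
  n_trials <- dim(trials_data)[1]
  for (tr in seq_len(n_trials)) {
    filtered <- bandpass_filterbank(trials_data[tr, , ], bands, fs)
    for (b in bands$label) {
      epochs <- epoch_trials(filtered[[b]], cfg$epoch_s, fs)
      for (m in cfg$metrics) {
        M <- build_adjacency(epochs, fs, metric = m, mode = "whole_brain",
                             trim_s = cfg$trim_s)
        res[[b]][[m]][[tr]] <- M
      }
    }
  }
  res
}

sensor_roundtrip <- function(src, cfg, seed) {
  set.seed(seed)
  L <- make_leadfield(cfg$sim$sensor_count, cfg$sim$n_parcels)
  loadings <- if (cfg$sim$artifact_components > 0) {
    matrix(stats::rnorm(cfg$sim$sensor_count * cfg$sim$artifact_components),
           cfg$sim$sensor_count)
  } else NULL
  sens <- project_to_sensors(src, L, loadings, noise_sd = cfg$sim$noise_sd,
                             artifact_amplitude = 5)
  epochs <- sens$data
  if (!is.null(loadings)) {
    cleaned <- remove_artifact_components(epochs, sens$references,
                                          seed = seed)
    epochs <- cleaned$epochs
  }
  # covariance over all task epochs of this subject
  ns <- dim(epochs)[2]
  C <- matrix(0, ns, ns)
  n_obs <- 0
  for (tr in seq_len(dim(epochs)[1])) {
    X <- epochs[tr, , ]
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
    n_obs <- n_obs + ncol(X)
  }
  C <- C / n_obs
  W <- compute_lcmv_weights(L, C, regularization = 0.05)
  src$data <- reconstruct_parcel_timeseries(W, epochs)
  src
}

simulate_behavior_table <- function(subjects, groups, seed) {
  set.seed(seed)
  g1 <- groups == groups[1]
  data.frame(
    subject = subjects, group = groups,
    scq = round(pmax(0, ifelse(g1, 19.3, 4.2) +
                       stats::rnorm(length(subjects), 0,
                                    ifelse(g1, 6.3, 2.9))), 1),
    rbsr = round(pmax(0, ifelse(g1, 14.2, 1.9) +
                        stats::rnorm(length(subjects), 0,
                                     ifelse(g1, 11.6, 3.7))), 1),
    ados = ifelse(g1, round(pmax(1, 6.8 + stats::rnorm(length(subjects),
                                                       0, 2.1)), 1), NA),
    stringsAsFactors = FALSE
  )
}

#' Run the full connectivity analysis pipeline
#'
#' Simulates the cohort (or routes it through sensor space and back via
#' the beamformer), preprocesses (motion rejection, trial-count QC,
#' filterbank, epoching), computes per-trial AEC/wPLI adjacency matrices,
#' averages and baselines against rest, runs the requested NBS analyses in
#' every band and metric (both one-sided directions for t contrasts),
#' applies Bonferroni correction within metric, and correlates strengths
#' of significant between-group networks with behavioral scores.
#' Everything is deterministic given the configuration's seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, the manifest, QC report,
#'   NBS table, baselined matrices, exported networks and a run log are
#'   written as TSV/text files.
#' @return List of class `pipeline_result` with elements `qc`, `subjects`,
#'   `matrices` (per subject/condition/band/metric baselined matrices),
#'   `nbs` (result table), `components`, `behavior`, `log`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim
  fs <- sim$sampling_rate_hz
  groups <- rep(cfg$groups, each = sim$n_subjects_per_group)
  subjects <- sprintf("%s%02d", groups,
                      rep(seq_len(sim$n_subjects_per_group), times = 2))
  manifests <- list()
  subject_mats <- list()
  drop_log <- list()

  for (si in seq_along(subjects)) {
    sub <- subjects[si]; grp <- groups[si]
    sub_seed <- (sim$seed + 104729L * si) %% .Machine$integer.max
    set.seed(sub_seed)
    man <- build_paradigm(cfg$paradigm, subject = sub, group = grp,
                          shuffle = TRUE,
                          response_flip_rate = sim$response_flip_rate)
    conds <- c("familiar", "unfamiliar")
    blocks <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      n_tr <- sum(!man$is_rest & man$condition_response == cond)
      if (n_tr > 0) {
        blocks[[cond]] <- simulate_subject_timeseries(
          sim, sub, grp, cond, n_tr, seed = sub_seed + ci)
      }
    }
    rest <- simulate_subject_timeseries(sim, sub, grp, "rest",
                                        cfg$n_rest_trials,
                                        seed = sub_seed + 10L)
    # motion from the simulator's ground truth, in manifest order
    for (cond in names(blocks)) {
      rows <- which(!man$is_rest & man$condition_response == cond)
      man$motion_mm[rows] <- blocks[[cond]]$ground_truth$motion_mm
    }
    man$motion_mm[man$is_rest] <-
      utils::head(rest$ground_truth$motion_mm, sum(man$is_rest))
    mk <- reject_motion_trials(man, cfg$motion_threshold_mm)
    man_kept <- mk$manifest
    manifests[[sub]] <- man_kept
    drop_log[[sub]] <- mk$report

    if (cfg$use_sensors) {
      for (cond in names(blocks)) {
        blocks[[cond]] <- sensor_roundtrip(blocks[[cond]], cfg, sub_seed + 20L)
      }
      rest <- sensor_roundtrip(rest, cfg, sub_seed + 21L)
    }

    # keep only motion-passing trials, in simulation order per condition
    cond_mats <- list()
    rest_mats <- trial_connectivity(rest$data, fs, cfg)
    for (cond in names(blocks)) {
      rows_all <- which(!man$is_rest & man$condition_response == cond)
      keep_idx <- which(man$motion_mm[rows_all] <= cfg$motion_threshold_mm)
      if (length(keep_idx) == 0) next
      dat <- blocks[[cond]]$data[keep_idx, , , drop = FALSE]
      cond_mats[[cond]] <- trial_connectivity(dat, fs, cfg)
    }
    for (b in sim$bands$label) {
      for (m in cfg$metrics) {
        for (cond in names(cond_mats)) {
          subject_mats[[sub]][[cond]][[b]][[m]] <- average_and_baseline(
            cond_mats[[cond]][[b]][[m]], rest_mats[[b]][[m]])
        }
      }
    }
  }

  qc <- qc_min_trials(do.call(rbind, manifests), cfg$min_trials)
  included <- qc$included
  inc_groups <- groups[match(included, subjects)]
  g1 <- included[inc_groups == cfg$groups[1]]
  g2 <- included[inc_groups == cfg$groups[2]]

  gather <- function(subs, cond, band, metric) {
    lapply(subs, function(s) subject_mats[[s]][[cond]][[band]][[metric]])
  }
  maybe_roi <- function(mats) {
    if (cfg$mode != "roi") return(mats)
    lapply(mats, function(M) {
      embed_roi_map(M[, cfg$seeds, drop = FALSE], cfg$seeds, nrow(M))
    })
  }

  nbs_rows <- list()
  components <- list()
  add_result <- function(res, band, metric, analysis, direction, family) {
    corr <- if (length(res$components) > 0) {
      bonferroni_band_correction(
        vapply(res$components, `[[`, numeric(1), "p_fwer"), family, cfg$alpha)
    } else NULL
    for (k in seq_along(res$components)) {
      cc <- res$components[[k]]
      key <- sprintf("%s_%s_%s_%s_c%d", band, metric, analysis, direction, k)
      components[[key]] <<- cc
      nbs_rows[[length(nbs_rows) + 1]] <<- data.frame(
        band = band, metric = metric, analysis = analysis,
        direction = direction, component = k, n_edges = cc$n_edges,
        n_nodes = cc$n_nodes, p_fwer = cc$p_fwer,
        p_threshold = corr$threshold,
        significant = corr$significant[k], stringsAsFactors = FALSE)
    }
    if (length(res$components) == 0) {
      nbs_rows[[length(nbs_rows) + 1]] <<- data.frame(
        band = band, metric = metric, analysis = analysis,
        direction = direction, component = NA_integer_,
        n_edges = 0L, n_nodes = 0L, p_fwer = NA_real_,
        p_threshold = cfg$alpha / if (is.numeric(family)) family else
          c(between = 4, within = 2)[[family]],
        significant = FALSE, stringsAsFactors = FALSE)
    }
  }
  neg <- function(mats) lapply(mats, function(M) -M)

  for (b in sim$bands$label) {
    for (m in cfg$metrics) {
      thr_t <- cfg$thresholds[[m]]
      if ("within" %in% cfg$analyses) {
        for (gi in 1:2) {
          subs <- if (gi == 1) g1 else g2
          if (length(subs) < 2) next
          fam <- maybe_roi(gather(subs, "familiar", b, m))
          unf <- maybe_roi(gather(subs, "unfamiliar", b, m))
          des <- nbs_design("within_group_paired", thr_t,
                            cfg$n_permutations, cfg$alpha, sim$seed + 1L)
          res <- nbs_permutation_test(list(familiar = fam, unfamiliar = unf),
                                      des)
          add_result(res, b, m, paste0("within_", cfg$groups[gi]),
                     "familiar_gt_unfamiliar", "within")
          res2 <- nbs_permutation_test(list(familiar = neg(fam),
                                            unfamiliar = neg(unf)), des)
          add_result(res2, b, m, paste0("within_", cfg$groups[gi]),
                     "unfamiliar_gt_familiar", "within")
        }
      }
      if ("between" %in% cfg$analyses && length(g1) >= 2 && length(g2) >= 2) {
        for (cond in c("familiar", "unfamiliar")) {
          x1 <- maybe_roi(gather(g1, cond, b, m))
          x2 <- maybe_roi(gather(g2, cond, b, m))
          des <- nbs_design("between_groups", thr_t, cfg$n_permutations,
                            cfg$alpha, sim$seed + 2L)
          res <- nbs_permutation_test(list(group1 = x1, group2 = x2), des)
          add_result(res, b, m, paste0("between_", cond),
                     paste0(cfg$groups[1], "_gt_", cfg$groups[2]), "between")
          res2 <- nbs_permutation_test(list(group1 = x2, group2 = x1), des)
          add_result(res2, b, m, paste0("between_", cond),
                     paste0(cfg$groups[2], "_gt_", cfg$groups[1]), "between")
        }
      }
      if ("interaction" %in% cfg$analyses && length(g1) >= 2 &&
          length(g2) >= 2) {
        des <- nbs_design("interaction_2x2", cfg$thresholds$interaction,
                          cfg$n_permutations, cfg$alpha, sim$seed + 3L)
        res <- nbs_permutation_test(list(
          group1_familiar = maybe_roi(gather(g1, "familiar", b, m)),
          group1_unfamiliar = maybe_roi(gather(g1, "unfamiliar", b, m)),
          group2_familiar = maybe_roi(gather(g2, "familiar", b, m)),
          group2_unfamiliar = maybe_roi(gather(g2, "unfamiliar", b, m))),
          des)
        add_result(res, b, m, "interaction", "2x2", 1)
      }
    }
  }
  nbs_table <- do.call(rbind, nbs_rows)

  behavior_tab <- cfg$behavior
  if (is.null(behavior_tab)) {
    behavior_tab <- simulate_behavior_table(included, inc_groups,
                                            sim$seed + 99L)
  } else {
    behavior_tab <- behavior_tab[match(included, behavior_tab$subject), ,
                                 drop = FALSE]
  }
  behavior_res <- list()
  sig <- nbs_table[!is.na(nbs_table$p_fwer) & nbs_table$significant &
                     grepl("between", nbs_table$analysis), , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    key <- sprintf("%s_%s_%s_%s_c%d", sig$band[r], sig$metric[r],
                   sig$analysis[r], sig$direction[r], sig$component[r])
    cc <- components[[key]]
    cond <- sub("between_", "", sig$analysis[r])
    strengths <- vapply(included, function(s) {
      network_strength(subject_mats[[s]][[cond]][[sig$band[r]]][[sig$metric[r]]],
                       cc$edges)
    }, numeric(1))
    asd <- behavior_tab$group == cfg$groups[1]
    for (score in intersect(c("scq", "rbsr", "ados"), names(behavior_tab))) {
      y <- behavior_tab[[score]][asd]
      x <- strengths[asd]
      res <- tryCatch(correlate_with_behavior(x, y), error = function(e) NULL)
      if (!is.null(res)) {
        behavior_res[[paste(key, score, sep = "_")]] <-
          c(list(network = key, score = score), res)
      }
    }
  }

  log <- list(seed = sim$seed, n_subjects = length(subjects),
              n_included = length(included),
              package_version = as.character(utils::packageVersion("megfc")))
  result <- structure(list(qc = qc, subjects = included,
                           manifests = manifests, matrices = subject_mats,
                           nbs = nbs_table, components = components,
                           behavior = behavior_res,
                           behavior_table = behavior_tab, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, cfg, out_dir)
  result
}

# serialize the text results bundle (deterministic given the result)
write_pipeline_result <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(do.call(rbind, result$manifests),
                 file.path(out_dir, "manifest.tsv"))
  utils::write.table(result$qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$nbs, file.path(out_dir, "nbs_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in result$subjects) {
    for (cond in names(result$matrices[[s]])) {
      for (b in names(result$matrices[[s]][[cond]])) {
        for (m in names(result$matrices[[s]][[cond]][[b]])) {
          fn <- sprintf("conn_%s_%s_%s_%s.tsv", s, cond, b, m)
          write_matrix_tsv(round(result$matrices[[s]][[cond]][[b]][[m]], 10),
                           file.path(out_dir, fn))
        }
      }
    }
  }
  log_lines <- c(sprintf("seed: %d", result$log$seed),
                 sprintf("n_subjects: %d", result$log$n_subjects),
                 sprintf("n_included: %d", result$log$n_included),
                 sprintf("package_version: %s", result$log$package_version))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
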