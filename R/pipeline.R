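#' Configuration of a study-shaped simulation + analysis run
#'
#' Bundles the generator settings and the analysis parameters used by
#' [run_study()]: the affective-category x stimulation designs, the ERP
#' analysis windows (encoding early 200-600 ms, encoding late 600-1200 ms,
#' retrieval 400-1000 ms), the ROI per stage (posterior at encoding;
#' anterior + posterior at retrieval), and the permutation settings. Each
#' window x ROI analysis is run independently with no cross-window
#' correction; the report states this.
#'
#' @param study 1 or 2.
#' @param seed root integer seed (per-stage child streams are derived from
#'   it by fixed offsets).
#' @param n_subjects subject count (defaults: 30 / 65).
#' @param n_perm permutations for cluster tests (default 1000, min 100).
#' @param forming_alpha,min_run cluster-forming parameters (defaults 0.05
#'   and 5 samples).
#' @param n_sensors sensor count of the synthetic layout (default 129).
#' @param behavior list of [behavior_config()] overrides (R, d_fam,
#'   criteria, false_rec).
#' @param erp list of [erp_config()] overrides (noise, effects); by default
#'   one ground-truth patch enhances the unpleasant/taVNS cell over
#'   posterior sensors at 200-600 ms (amplitude 1.5 uV against 1 uV noise)
#'   and a late old/new patch at 400-1000 ms.
#' @param windows named list of analysis windows in ms.
#' @return an object of class `run_config`.
#' @export
run_config <- function(study, seed = 1, n_subjects = NULL, n_perm = 1000,
                       forming_alpha = 0.05, min_run = 5, n_sensors = 129,
                       behavior = list(), erp = list(),
                       windows = list(encoding_early = c(200, 600),
                                      encoding_late = c(600, 1200),
                                      retrieval = c(400, 1000))) {
  stopifnot(study %in% c(1, 2), n_perm >= 100)
  if (is.null(n_subjects)) n_subjects <- if (study == 1) 30L else 65L
  structure(
    list(study = as.integer(study), seed = as.integer(seed),
         n_subjects = as.integer(n_subjects), n_perm = as.integer(n_perm),
         forming_alpha = forming_alpha, min_run = as.integer(min_run),
         n_sensors = as.integer(n_sensors),
         behavior = behavior, erp = erp, windows = windows),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   its path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj[setdiff(names(obj), character(0))])
}

# study-appropriate generator configs derived from a run_config
.materialize <- function(config) {
  study <- config$study
  dialect <- if (study == 1) "eleven_point" else "six_point"
  beh_args <- utils::modifyList(
    list(dialect = dialect,
         # recollection clearly above familiarity-based performance, with a
         # recollection advantage for unpleasant material under taVNS
         R = c(default = 0.33, unpleasant.taVNS = 0.42, unpleasant.on = 0.40,
               unpleasant.off = 0.40),
         d_fam = 1.1),
    config$behavior
  )
  beh <- do.call(behavior_config, beh_args)
  lay <- sensor_layout(config$n_sensors)
  post_center <- lay$rois$posterior[which.min(lay$positions[lay$rois$posterior, "y"])]
  cells <- if (study == 1) {
    c("neutral.taVNS", "neutral.sham", "unpleasant.taVNS", "unpleasant.sham")
  } else {
    c("neutral.on", "neutral.off", "unpleasant.on", "unpleasant.off")
  }
  enc_effects <- if (study == 1) {
    # taVNS enhances the unpleasant-vs-neutral LPP difference (within)
    list(effect_patch(window = c(200, 600),
                      amplitude = c(unpleasant.taVNS = 1.5, unpleasant.sham = 0.4),
                      center = post_center, radius = 2, subject_sd = 0.3))
  } else {
    # between design: emotional LPP everywhere, enhanced in the taVNS group
    list(
      effect_patch(window = c(200, 600),
                   amplitude = c(unpleasant.on = 0.4, unpleasant.off = 0.4),
                   center = post_center, radius = 2, subject_sd = 0.3),
      effect_patch(window = c(200, 600),
                   amplitude = c(unpleasant.on = 1.1, unpleasant.off = 1.1),
                   center = post_center, radius = 2, group = "taVNS")
    )
  }
  erp_args <- utils::modifyList(
    list(n_sensors = config$n_sensors,
         noise = list(sd = 1, spatial_smooth = 2L, ar = 0.5, subject_sd = 0.5),
         effects = enc_effects),
    config$erp
  )
  erp <- do.call(erp_config, erp_args)
  ret_effects <- if (study == 1) {
    list(effect_patch(window = c(400, 1000),
                      amplitude = c(unpleasant.taVNS = 1.8, unpleasant.sham = 0.8,
                                    neutral.taVNS = 0.8, neutral.sham = 0.8),
                      center = post_center, radius = 2, subject_sd = 0.3))
  } else {
    list(
      effect_patch(window = c(400, 1000),
                   amplitude = c(unpleasant.old = 0.8, neutral.old = 0.8),
                   center = post_center, radius = 2, subject_sd = 0.3),
      effect_patch(window = c(400, 1000),
                   amplitude = c(unpleasant.old = 1.0),
                   center = post_center, radius = 2, group = "taVNS")
    )
  }
  ret_erp <- erp_config(n_sensors = config$n_sensors, noise = erp$noise,
                        effects = ret_effects)
  list(behavior = beh, layout = lay, erp_encoding = erp, erp_retrieval = ret_erp,
       cells = cells)
}

#' Simulate one study end to end
#'
#' Generates the design tables, the trial-level recognition behavior and
#' the encoding/retrieval condition-average ERP epoch sets for the
#' configured study, with ground truth attached. When `out_dir` is given,
#' every artifact is written in its documented format (TSV tables, RDS +
#' JSON epochs, JSON layout, YAML config) so [analyze_study()] can re-run
#' from disk without re-simulation.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a list with design, behavior, layout, encoding and retrieval
#'   epoch sets.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  m <- .materialize(config)
  design <- build_design(config$study, config$n_subjects, seed = config$seed)
  behavior <- gen_recognition(design, m$behavior, seed = config$seed)
  enc <- gen_epochs(m$erp_encoding, design, m$layout, seed = config$seed)
  ret_conds <- if (config$study == 1) {
    c(m$cells, "neutral.new", "unpleasant.new")
  } else {
    c("unpleasant.old", "neutral.old", "unpleasant.new", "neutral.new")
  }
  ret <- gen_epochs(m$erp_retrieval, design, m$layout,
                    seed = config$seed + 1L, conditions = ret_conds)
  enc <- baseline_correct(enc)
  ret <- baseline_correct(ret)
  sim <- list(config = config, design = design, behavior = behavior,
              layout = m$layout, encoding = enc, retrieval = ret)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    utils::write.table(design$encoding, file.path(out_dir, "design_encoding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(design$retrieval, file.path(out_dir, "design_retrieval.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_recognition(behavior, file.path(out_dir, "recognition.tsv"))
    write_layout(m$layout, file.path(out_dir, "layout.json"))
    write_epochs(enc, file.path(out_dir, "epochs_encoding.rds"))
    write_epochs(ret, file.path(out_dir, "epochs_retrieval.rds"))
  }
  sim
}

# effect specs for the study's cluster analyses
.study_effects <- function(study) {
  if (study == 1) {
    list(
      encoding = effect_spec(
        "AffectiveCategory x Stimulation", "interaction_within",
        list(a = c("unpleasant.taVNS", "unpleasant.sham"),
             b = c("neutral.taVNS", "neutral.sham"))
      ),
      retrieval = effect_spec(
        "AffectiveCategory x Stimulation (old items)", "interaction_within",
        list(a = c("unpleasant.taVNS", "unpleasant.sham"),
             b = c("neutral.taVNS", "neutral.sham"))
      )
    )
  } else {
    list(
      encoding = effect_spec(
        "AffectiveCategory x Stimulation", "interaction_mixed",
        c("unpleasant", "neutral")
      ),
      encoding3 = effect_spec(
        "AffectiveCategory x Stimulation x StimulationPhase", "three_way_mixed",
        list(a = c("unpleasant.on", "unpleasant.off"),
             b = c("neutral.on", "neutral.off"))
      ),
      retrieval = effect_spec(
        "AffectiveCategory x Stimulation (old items)", "interaction_mixed",
        c("unpleasant.old", "neutral.old")
      )
    )
  }
}

#' Average condition groups into new condition labels
#'
#' @param epochs an [epoch_set()].
#' @param mapping named list: new label -> character vector of existing
#'   condition labels to average.
#' @return an `epoch_set` with the mapped conditions.
#' @export
collapse_conditions <- function(epochs, mapping) {
  stopifnot(all(unlist(mapping) %in% epochs$conditions))
  d <- dim(epochs$values)
  out <- array(0, c(d[1], length(mapping), d[3], d[4]))
  for (k in seq_along(mapping)) {
    ci <- match(mapping[[k]], epochs$conditions)
    out[, k, , ] <- apply(epochs$values[, ci, , , drop = FALSE], c(1, 3, 4), mean)
  }
  epoch_set(out, epochs$time_ms, epochs$sensors, names(mapping),
            epochs$subjects, epochs$sample_rate, epochs$baseline_ms,
            epochs$subject_info)
}

.sig_clusters <- function(res) res$clusters[res$clusters$significant, , drop = FALSE]

#' Analyze a simulated (or loaded) study
#'
#' Runs the full analysis chain on simulate_study output or a directory of
#' saved intermediates: performance-based exclusion and memory indices;
#' random-intercept mixed models (with Satterthwaite df) on Pr and d' plus
#' BIC-approximate Bayes factors per fixed term; cluster-based permutation
#' tests per analysis window; and follow-up statistics on cluster-averaged
#' amplitudes. For retrieval the two-stage logic is followed: the
#' category x stimulation interaction is tested among old-item ERPs, and
#' significant clusters are then compared against correctly-identified-new
#' baselines with paired t-tests.
#'
#' @param sim result of [simulate_study()], or a directory path containing
#'   its written artifacts.
#' @param config optional [run_config()] override (defaults to the one
#'   stored with the simulation).
#' @return an object of class `run_report`.
#' @export
analyze_study <- function(sim, config = NULL) {
  if (is.character(sim)) {
    dir <- sim
    config <- config %||% read_run_config(file.path(dir, "config.yaml"))
    sim <- list(
      config = config,
      behavior = read_recognition(file.path(dir, "recognition.tsv")),
      layout = read_layout(file.path(dir, "layout.json")),
      encoding = read_epochs(file.path(dir, "epochs_encoding.rds")),
      retrieval = read_epochs(file.path(dir, "epochs_retrieval.rds"))
    )
  }
  config <- config %||% sim$config
  study <- config$study
  lay <- sim$layout

  ## ---- behavior: indices, exclusions, mixed models ----
  strata <- if (study == 1) c("subject", "category", "stimulation") else
    c("subject", "category", "phase")
  beh <- exclude_poor_performers(sim$behavior)
  idx <- memory_indices(beh, strata = strata)
  if (study == 2) {
    grp <- dplyr::distinct(sim$behavior, subject, group)
    idx <- dplyr::left_join(idx, grp, by = "subject")
    idx$stimulation <- idx$group
  }
  overall <- idx[idx$memory_class == "overall", ]
  split_dat <- idx[idx$memory_class != "overall", ]
  split_dat$memory <- split_dat$memory_class
  form_overall <- if (study == 1) {
    list(pr = pr ~ category * stimulation, d = d_prime ~ category * stimulation)
  } else {
    list(pr = pr ~ category * stimulation * phase,
         d = d_prime ~ category * stimulation * phase)
  }
  form_split <- if (study == 1) {
    list(pr = pr ~ category * stimulation * memory,
         d = d_prime ~ category * stimulation * memory)
  } else {
    list(pr = pr ~ category * stimulation * phase * memory,
         d = d_prime ~ category * stimulation * phase * memory)
  }
  fit_tab <- function(dat, forms) {
    purrr::imap(forms, function(f, nm) {
      fit <- fit_lmm_ri(dat, f)
      list(fit = fit, tidy = tidy(fit), bf = .term_bfs(dat, f))
    })
  }
  lmm_overall <- fit_tab(overall, form_overall)
  lmm_split <- fit_tab(as.data.frame(split_dat), form_split)

  ## ---- ERP: cluster tests per window ----
  eff <- .study_effects(study)
  post <- layout_roi(lay, "posterior")
  both <- layout_roi(lay, unique(c(lay$rois$posterior, lay$rois$anterior)))
  run_window <- function(epochs, roi, window, effect, seed_off) {
    ep <- subset_epochs(epochs, sensors = roi$ids, window = window)
    cluster_test(ep, effect, roi, n_perm = config$n_perm,
                 seed = config$seed + seed_off,
                 forming_alpha = config$forming_alpha,
                 min_run = config$min_run)
  }
  enc <- sim$encoding
  enc_for_int <- if (study == 2) {
    collapse_conditions(enc, list(
      unpleasant = c("unpleasant.on", "unpleasant.off"),
      neutral = c("neutral.on", "neutral.off")
    ))
  } else {
    enc
  }
  erp <- list(
    encoding_early = run_window(enc_for_int, post,
                                config$windows$encoding_early, eff$encoding, 10L),
    encoding_late = run_window(enc_for_int, post,
                               config$windows$encoding_late, eff$encoding, 20L),
    retrieval = run_window(sim$retrieval, both,
                           config$windows$retrieval, eff$retrieval, 30L)
  )
  if (study == 2) {
    erp$encoding_early_3way <- run_window(enc, post,
                                          config$windows$encoding_early,
                                          eff$encoding3, 40L)
    erp$encoding_late_3way <- run_window(enc, post,
                                         config$windows$encoding_late,
                                         eff$encoding3, 50L)
  }

  ## ---- follow-ups on cluster-averaged amplitudes ----
  followups <- list()
  for (wn in c("encoding_early", "encoding_late")) {
    sig <- .sig_clusters(erp[[wn]])
    if (nrow(sig)) {
      amp <- cluster_mean_amplitude(enc, sig[1, ])
      amp <- tidyr::separate(amp, condition, into = c("category", "cell2"),
                             sep = "\\.", remove = FALSE)
      followups[[wn]] <- if (study == 1) {
        dplyr::rename(amp, stimulation = cell2) |>
          rm_anova_2x2(factors = c("category", "stimulation"))
      } else {
        dplyr::rename(amp, phase = cell2) |>
          rm_anova_2x2(factors = c("category", "phase"))
      }
    }
  }
  # retrieval stage 2: significant interaction clusters vs new baselines
  sig <- .sig_clusters(erp$retrieval)
  if (nrow(sig)) {
    amp <- cluster_mean_amplitude(sim$retrieval, sig[1, ])
    wide <- tidyr::pivot_wider(amp, names_from = condition,
                               values_from = amplitude)
    pairs <- if (study == 1) {
      list(c("unpleasant.taVNS", "unpleasant.new"),
           c("unpleasant.sham", "unpleasant.new"),
           c("neutral.taVNS", "neutral.new"),
           c("neutral.sham", "neutral.new"),
           c("unpleasant.taVNS", "unpleasant.sham"),
           c("neutral.taVNS", "neutral.sham"))
    } else {
      list(c("unpleasant.old", "unpleasant.new"),
           c("neutral.old", "neutral.new"))
    }
    followups$retrieval_old_new <- purrr::map_dfr(pairs, function(pp) {
      out <- paired_t(wide[[pp[1]]], wide[[pp[2]]])
      out$comparison <- paste(pp, collapse = " vs ")
      out
    })
  }

  structure(
    list(
      study = study, config = config,
      memory = list(
        exclusions = exclusion_report(beh),
        indices = idx,
        lmm_overall = lmm_overall, lmm_split = lmm_split
      ),
      erp = erp, followups = followups,
      provenance = list(
        seed = config$seed, n_perm = config$n_perm,
        package_version = as.character(utils::packageVersion("erpmem")),
        note = paste("analysis windows and ROIs are tested independently;",
                     "no cross-window correction is applied")
      )
    ),
    class = "run_report"
  )
}

# BIC-approximate BF for every fixed term: full model vs model without it
.term_bfs <- function(dat, formula) {
  trm <- attr(stats::terms(formula), "term.labels")
  full <- fit_lmm_ri(dat, formula, reml = FALSE)
  purrr::map_dfr(trm, function(tl) {
    dropped <- stats::update(formula,
                             paste("~ . -", gsub(":", ":", tl, fixed = TRUE)))
    red_terms <- attr(stats::terms(dropped), "term.labels")
    if (length(red_terms) == length(trm)) return(tibble::tibble())
    red <- fit_lmm_ri(dat, dropped, reml = FALSE)
    out <- bf10_bic(full, red)
    out$term <- tl
    out
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> Study %d (seed %d)\n", x$study, x$config$seed))
  cat(sprintf("excluded subjects (Pr <= 0): %d\n", nrow(x$memory$exclusions)))
  for (nm in names(x$erp)) {
    g <- glance(x$erp[[nm]])
    cat(sprintf("  %s: %d cluster(s), %d significant (critical mass %.1f)\n",
                nm, g$n_clusters, g$n_significant, g$critical_mass))
  }
  invisible(x)
}

#' Run a full study-shaped pipeline
#'
#' [simulate_study()] then [analyze_study()], fully deterministic given
#' (config, seed). When `out_dir` is given, the simulation artifacts and
#' the report files are written there ([write_report()]).
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a `run_report`.
#' @export
run_study <- function(config, out_dir = NULL) {
  sim <- simulate_study(config, out_dir = out_dir)
  rep <- analyze_study(sim)
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' Write a run report to disk
#'
#' Memory indices and LMM coefficient tables as TSV; cluster results,
#' Bayes-factor comparisons and provenance as JSON. Payloads contain no
#' timestamps, so identical (config, seed) runs write identical bytes.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_memory_indices(report$memory$indices,
                       file.path(dir, "memory_indices.tsv"))
  for (nm in names(report$memory$lmm_overall)) {
    utils::write.table(report$memory$lmm_overall[[nm]]$tidy,
                       file.path(dir, sprintf("lmm_overall_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(report$erp)) {
    write_perm_result(report$erp[[nm]], file.path(dir, sprintf("clusters_%s.json", nm)))
  }
  bf <- purrr::imap_dfr(report$memory$lmm_overall,
                        function(l, nm) dplyr::mutate(l$bf, model = nm))
  jsonlite::write_json(
    list(exclusions = report$memory$exclusions,
         bayes_factors = bf,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
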