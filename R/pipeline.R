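#' Normality-gated test selection
#'
#' Every group is screened with the Shapiro-Wilk test. If all groups pass
#' (p >= 0.05) the parametric route is taken: paired t-test for paired or
#' repeated designs (vs the baseline group), one-way ANOVA for independent
#' groups. If any group fails, the nonparametric route is taken: Wilcoxon
#' signed-rank for two paired groups, Friedman with Nemenyi post-hoc for
#' repeated designs with three or more groups.
#'
#' @param groups list of numeric vectors (one per group/epoch), each with
#'   >= 3 values for the normality gate.
#' @param design `"paired"` (2 groups), `"repeated"` (>= 3 groups, complete
#'   blocks), or `"independent"`.
#' @return list with `test` (one of `"paired t"`, `"Wilcoxon"`,
#'   `"one-way ANOVA"`, `"Friedman+Nemenyi"`) and `gate_p` (per-group
#'   Shapiro-Wilk p-values).
#' @export
select_test <- function(groups, design = c("paired", "repeated", "independent")) {
  design <- match.arg(design)
  if (!is.list(groups) || length(groups) < 2L)
    stop_param("`groups` must be a list of >= 2 numeric vectors")
  if (design == "paired" && length(groups) != 2L)
    stop_param("paired design requires exactly 2 groups")
  if (design == "repeated" && length(groups) < 3L)
    stop_param("repeated design requires >= 3 groups (use \"paired\" for 2)")
  if (any(vapply(groups, length, 1L) < 3L))
    stop_param("every group needs >= 3 values for the normality gate")
  gate_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(0)   # degenerate: route nonparametric
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  normal <- all(gate_p >= 0.05)
  test <- if (normal) {
    if (design == "independent") "one-way ANOVA" else "paired t"
  } else {
    if (design == "paired") "Wilcoxon"
    else if (design == "repeated") "Friedman+Nemenyi"
    else if (length(groups) == 2L) "rank-sum Wilcoxon"
    else "Kruskal-Wallis"
  }
  list(test = test, gate_p = gate_p)
}

# Nemenyi post-hoc for Friedman designs: studentized-range formulation on
# within-block mean ranks, q = |Rbar_i - Rbar_j| / sqrt(k(k+1)/(12 n)),
# p = ptukey(q * sqrt(2), k, Inf, lower = FALSE).
nemenyi_posthoc <- function(mat, baseline = 1L) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1L, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  others <- setdiff(seq_len(k), baseline)
  grp <- if (is.null(colnames(mat))) as.character(seq_len(k)) else colnames(mat)
  data.frame(
    group = grp[others],
    mean_rank_diff = rbar[others] - rbar[baseline],
    q = abs(rbar[others] - rbar[baseline]) / se,
    p = stats::ptukey(abs(rbar[others] - rbar[baseline]) / se * sqrt(2),
                      nmeans = k, df = Inf, lower.tail = FALSE),
    row.names = NULL)
}

#' Gated comparison of condition epochs
#'
#' Runs the test chosen by [select_test()] on a long-format sample table and
#' reports the statistic, p-value and (for Friedman) a Nemenyi post-hoc
#' table against the baseline epoch.
#'
#' @param samples data frame with columns `subject`, `epoch`, `value` (one
#'   value per subject x epoch; complete blocks required for paired/repeated
#'   designs).
#' @param design see [select_test()].
#' @param baseline baseline epoch label (default: first epoch level).
#' @return object of class `stat_report`: `test`, `gate_p`, `statistic`,
#'   `p`, `posthoc` (or NULL), `n`.
#' @export
compare_epochs <- function(samples, design = c("paired", "repeated", "independent"),
                           baseline = NULL) {
  design <- match.arg(design)
  need <- c("subject", "epoch", "value")
  if (!all(need %in% names(samples)))
    stop_param("`samples` must have subject, epoch, value columns")
  samples$epoch <- factor(samples$epoch,
                          levels = unique(as.character(samples$epoch)))
  epochs <- levels(samples$epoch)
  if (is.null(baseline)) baseline <- epochs[1]
  if (!baseline %in% epochs) stop_param("baseline epoch not present")
  groups <- split(samples$value, samples$epoch)
  if (design %in% c("paired", "repeated")) {
    tab <- table(samples$subject, samples$epoch)
    if (any(tab != 1L)) {
      bad <- rownames(tab)[rowSums(tab != 1L) > 0]
      stop_param(paste0("incomplete blocks for subject(s): ",
                        paste(bad, collapse = ", ")))
    }
  }
  sel <- select_test(groups, design)
  mat <- NULL
  if (design %in% c("paired", "repeated")) {
    wide <- stats::reshape(samples[order(samples$subject, samples$epoch), need],
                           idvar = "subject", timevar = "epoch",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    colnames(mat) <- epochs
  }
  # degenerate all-tie case: every subject identical across epochs
  if (!is.null(mat) && all(apply(mat, 1L, function(r) length(unique(r)) == 1L))) {
    return(structure(list(test = sel$test, gate_p = sel$gate_p,
                          statistic = 0, p = 1, posthoc = NULL,
                          n = length(unique(samples$subject)),
                          baseline = baseline),
                     class = "stat_report"))
  }
  report <- switch(sel$test,
    "paired t" = {
      others <- setdiff(epochs, baseline)
      ph <- do.call(rbind, lapply(others, function(ep) {
        tt <- stats::t.test(mat[, ep], mat[, baseline], paired = TRUE)
        data.frame(group = ep, statistic = unname(tt$statistic),
                   p = tt$p.value)
      }))
      list(statistic = ph$statistic[1],
           p = if (length(others) == 1L) ph$p[1] else min(ph$p),
           posthoc = if (length(others) > 1L) ph else NULL)
    },
    "Wilcoxon" = {
      other <- setdiff(epochs, baseline)[1]
      d <- mat[, other] - mat[, baseline]
      if (all(d == 0)) list(statistic = 0, p = 1, posthoc = NULL)
      else {
        # exact distribution where possible (small n, no ties)
        wt <- suppressWarnings(stats::wilcox.test(mat[, other], mat[, baseline],
                                                  paired = TRUE))
        list(statistic = unname(wt$statistic), p = wt$p.value, posthoc = NULL)
      }
    },
    "rank-sum Wilcoxon" = {
      g <- split(samples$value, samples$epoch)
      wt <- stats::wilcox.test(g[[1]], g[[2]], exact = FALSE)
      list(statistic = unname(wt$statistic), p = wt$p.value, posthoc = NULL)
    },
    "Kruskal-Wallis" = {
      kt <- stats::kruskal.test(value ~ epoch, data = samples)
      list(statistic = unname(kt$statistic), p = kt$p.value, posthoc = NULL)
    },
    "one-way ANOVA" = {
      fit <- stats::aov(value ~ epoch, data = samples)
      s <- summary(fit)[[1]]
      list(statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1], posthoc = NULL)
    },
    "Friedman+Nemenyi" = {
      if (all(apply(mat, 1L, function(r) length(unique(r)) == 1L))) {
        # every subject identical across epochs: no effect by construction
        list(statistic = 0, p = 1,
             posthoc = data.frame(group = setdiff(epochs, baseline),
                                  mean_rank_diff = 0, q = 0, p = 1))
      } else {
        ft <- stats::friedman.test(mat)
        list(statistic = unname(ft$statistic), p = ft$p.value,
             posthoc = nemenyi_posthoc(mat, which(epochs == baseline)))
      }
    })
  structure(list(test = sel$test, gate_p = sel$gate_p,
                 statistic = report$statistic, p = report$p,
                 posthoc = report$posthoc,
                 n = length(unique(samples$subject)),
                 baseline = baseline),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("stat_report: %s (gate min p = %.3g), statistic = %.4g, p = %.4g, n = %d\n",
              x$test, min(x$gate_p), x$statistic, x$p, x$n))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post-hoc vs %s:\n", x$baseline))
    print(x$posthoc)
  }
  invisible(x)
}

#' Default pipeline configuration
#'
#' A single nested list with one section per stage; every value can be
#' overridden by the `config` argument of [run_full_pipeline()] or a JSON
#' document with the same structure.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    simulate = list(fs = 2500, duration = 120, f_resp = 1.5, f_hfo = 105,
                    burst_rate = 1.5, coupling_kappa = 8, lock_phase = pi / 4,
                    n_channels = 32, spacing_um = 100, depth_first_um = 100,
                    hfo_dipole_depth = 1600, delta_dipole_depth = 2400,
                    mua_rate = 300),
    spectra = list(welch_window_s = 30),
    bursts = list(threshold_sd = 3),
    coupling = list(phase_centers = c(0.75, 1.5, 2.5, 3.5, 4.5),
                    phase_bandwidth = 1,
                    amp_centers = c(45, 65, 85, 105, 125, 145),
                    amp_bandwidth = 20, n_bins = 18),
    laminar = list(csd_window_s = 0.35, lambda_grid = 10^seq(-6, 0, length.out = 10)),
    stats = list(n_subjects = 6, subject_duration = 20,
                 scalers = list(delta = 1, gamma = 0.25, hfo = 4)),
    epochs = list(baseline_s = 600, early_s = 600, late_s = 600)
  )
}

# recursive list merge: values in `over` replace defaults
merge_config <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      merge_config(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  s <- cfg$simulate
  if (s$fs <= 2 * s$f_hfo)
    stop_param(sprintf("config: fs (%g) must exceed 2*f_hfo (%g)", s$fs, 2 * s$f_hfo))
  if (any(cfg$coupling$amp_centers + cfg$coupling$amp_bandwidth / 2 >= s$fs / 2))
    stop_param("config: amplitude band above Nyquist")
  if (any(unlist(cfg$stats$scalers) <= 0))
    stop_param("config: condition scalers must be > 0")
  invisible(cfg)
}

pipeline_log <- function(logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"), sprintf(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full analysis pipeline on a seeded simulation
#'
#' Simulate -> spectra -> burst detection -> coupling (phase set, ITPC,
#' envelope correlations, comodulogram) -> laminar (depth power, phase shift,
#' kCSD, MUA) -> condition statistics. All numeric intermediates are written
#' as CSV/JSON under `out_dir` together with a run manifest (config hash,
#' seed, versions, file hashes).
#'
#' @param config partial configuration list or path to a JSON file; merged
#'   over [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @return list of class `pipeline_result` with the main stage outputs and
#'   the manifest.
#' @export
run_full_pipeline <- function(config = list(), out_dir = tempfile("obhfo_run_"),
                              seed = 1L) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_config(merge_config(default_config(), config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  stage <- function(name, expr) {
    pipeline_log(logfile, "stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    pipeline_log(logfile, "stage %s: done", name)
    out
  }

  s <- cfg$simulate
  gt <- ground_truth(seed = seed, fs = s$fs, duration = s$duration,
                     f_resp = s$f_resp, f_hfo = s$f_hfo,
                     burst_rate = s$burst_rate,
                     coupling_kappa = s$coupling_kappa,
                     lock_phase = s$lock_phase,
                     hfo_dipole_depth = s$hfo_dipole_depth,
                     delta_dipole_depth = s$delta_dipole_depth,
                     mua_rate = s$mua_rate)
  geom <- probe_geometry(s$n_channels, s$spacing_um, s$depth_first_um)
  sim <- stage("simulate", generate_laminar_recording(gt, geom, seed = seed))
  write_events(sim$bursts, file.path(out_dir, "true_bursts.csv"))

  ref <- sim$reference_channel
  ref_rec <- recording(sim$lfp$samples[ref, ], gt$fs)
  psd <- stage("spectra", welch_psd(ref_rec, window_s = cfg$spectra$welch_window_s,
                                    allow_short = TRUE))
  write_psd(psd, file.path(out_dir, "psd_reference.csv"))
  dom <- dominant_frequency(psd, band_hfo_kx())

  hfo_ref <- bandpass(ref_rec, band_hfo_kx())
  env <- analytic_envelope_phase(hfo_ref)$envelope
  bursts <- stage("bursts",
                  detect_bursts(env, gt$fs, band = band_hfo_kx(),
                                threshold_sd = cfg$bursts$threshold_sd))
  write_events(cbind(bursts, kind = "hfo"), file.path(out_dir, "bursts.csv"))

  coupling <- stage("coupling", {
    delta_ref <- bandpass(ref_rec, band_delta())
    ps <- burst_delta_phase(bursts, delta_ref)
    pb <- band_grid(cfg$coupling$phase_centers, cfg$coupling$phase_bandwidth)
    ab <- band_grid(cfg$coupling$amp_centers, cfg$coupling$amp_bandwidth)
    cm <- comodulogram(ref_rec, pb, ab, n_bins = cfg$coupling$n_bins)
    write_comodulogram(cm, file.path(out_dir, "comodulogram"))
    resp_delta <- bandpass(sim$respiration, band_delta())
    list(phase_set = ps, itpc = itpc(ps),
         lock_phase = circ_mean(ps$phases),
         r_resp_delta = envelope_correlation(resp_delta, delta_ref),
         r_delta_env = envelope_correlation(delta_ref$samples[1, ], env),
         comodulogram = cm, argmax = comodulogram_argmax(cm))
  })

  laminar <- stage("laminar", {
    prof <- depth_power_profile(sim$lfp, band_hfo_kx(),
                                window_s = min(10, gt$duration))
    utils::write.csv(prof, file.path(out_dir, "depth_power.csv"), row.names = FALSE)
    shift <- interchannel_phase_shift(sim$lfp, band_hfo_kx(), ref, bursts)
    utils::write.csv(shift, file.path(out_dir, "phase_shift.csv"), row.names = FALSE)
    pk <- bursts$peak_s[which.max(bursts$peak_env)]
    w <- cfg$laminar$csd_window_s
    i0 <- max(1L, round((pk - w) * gt$fs)); i1 <- min(ncol(sim$lfp$samples), round((pk + w) * gt$fs))
    snap <- recording(sim$lfp$samples[, i0:i1], gt$fs, geometry = geom,
                      t0 = (i0 - 1) / gt$fs)
    csd <- kcsd_reconstruct(snap, lambda_grid = cfg$laminar$lambda_grid)
    csd_hfo <- band_filtered_csd(csd, band_hfo_kx())
    spikes <- detect_mua(sim$lfp)
    hfo_all <- bandpass(sim$lfp, band_hfo_kx())
    mua <- mua_hfo_correlation(spikes, bursts, hfo_all)
    utils::write.csv(data.frame(channel = seq_along(mua$r), r = mua$r),
                     file.path(out_dir, "mua_hfo_r.csv"), row.names = FALSE)
    list(power_profile = prof, phase_shift = shift,
         reversal_um = reversal_depth(shift), csd = csd, csd_hfo = csd_hfo,
         mua = mua)
  })

  stats_out <- stage("stats", {
    st <- cfg$stats
    gt_small <- ground_truth(seed = seed, fs = 1000, duration = st$subject_duration,
                             coupling_kappa = gt$coupling_kappa, mua_rate = 0)
    geom_small <- probe_geometry(4, 800, 200)
    vals <- do.call(rbind, lapply(seq_len(st$n_subjects), function(sj) {
      pair <- generate_condition_pair(gt_small, st$scalers, geom_small,
                                      seed = derive_seed(seed, 100L + sj))
      per_cond <- function(sl, cond) {
        x <- sl$lfp$samples[sl$reference_channel, ]
        p <- welch_psd(x, gt_small$fs, window_s = st$subject_duration / 4,
                       allow_short = TRUE)
        data.frame(subject = sj, epoch = cond,
                   hfo = dominant_frequency(p, band_hfo_kx())$power,
                   gamma = dominant_frequency(p, band_gamma())$power)
      }
      rbind(per_cond(pair$a, "baseline"), per_cond(pair$b, "post"))
    }))
    reports <- lapply(c(hfo = "hfo", gamma = "gamma"), function(m) {
      compare_epochs(data.frame(subject = vals$subject, epoch = vals$epoch,
                                value = vals[[m]]), design = "paired")
    })
    utils::write.csv(vals, file.path(out_dir, "condition_metrics.csv"),
                     row.names = FALSE)
    reports
  })

  report <- list(
    dominant_hfo_freq_hz = dom$freq,
    itpc = coupling$itpc,
    lock_phase_rad = coupling$lock_phase,
    lock_phase_error_rad = circ_dist(coupling$lock_phase, gt$lock_phase),
    comod_argmax_phase_hz = coupling$argmax$phase_freq,
    comod_argmax_amp_hz = coupling$argmax$amp_freq,
    reversal_depth_um = laminar$reversal_um,
    reversal_error_um = abs(laminar$reversal_um - gt$hfo_dipole_depth),
    n_bursts = nrow(bursts),
    hfo_p = stats_out$hfo$p, gamma_p = stats_out$gamma$p)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  outputs <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("obhfo")),
                   files = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(logfile, "pipeline complete: %s", out_dir)

  structure(list(ground_truth = gt, simulation = sim, psd = psd,
                 bursts = bursts, coupling = coupling, laminar = laminar,
                 stats = stats_out, report = report, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  for (nm in names(x$report))
    cat(sprintf("  %-24s %s\n", nm, format(x$report[[nm]], digits = 5)))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
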