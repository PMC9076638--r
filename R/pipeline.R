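# End-to-end orchestration: simulate -> behavior -> spectral -> ISPC ->
# cluster stats -> circular stats -> mediation, with a serializable config,
# derived seeds, a manifest with the config hash, and content-hash stage
# skipping.

#' Default run configuration
#'
#' All stage parameters with the canonical defaults (250 Hz sampling, 50 Hz
#' ISPC grid, 2-40 Hz bank in 50 log steps with 400-104 ms FWHM, ISPC on
#' 5-40 Hz, baseline -500..-200 ms, time of interest 0..2000 ms, response
#' window ±260 ms, 1000 permutations at alpha 0.05, beta bands 15-22 and
#' 25-30 Hz, 4 chains x 10000 iterations with 1000 warmup, 89% HDI).
#' Override entries via `...`.
#'
#' @param ... Named overrides of any config entry.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_young = 12, n_older = 12, n_trials = 60,
    fs = 250, epoch_window = c(-2.5, 2.5),
    p_trt = 0.05, switch_ratio = 5, tap_freq_hz = 2,
    bank = list(fmin = 2, fmax = 40, n = 50,
                fwhm_start_ms = 400, fwhm_end_ms = 104),
    ispc_freq_range = c(5, 40), grid_hz = 50,
    baseline_window_ms = c(-500, -200), toi_window_ms = c(0, 2000),
    response_half_window_ms = 260,
    n_perm = 1000, alpha = 0.05, cluster_forming_p = 0.05,
    bands = list(low_beta = c(15, 22), high_beta = c(25, 30)),
    coupling = list(mean_lag = 0.6, kappa = 4, snr = 1, band = c(15, 22)),
    chains = 4, iter = 10000, warmup = 1000, hdi_mass = 0.89,
    stages = list(simulate = TRUE, behavior = TRUE, connectivity = TRUE,
                  clusters = TRUE, circstats = TRUE, gaba = TRUE,
                  mediation = TRUE),
    seed = 1
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = c("run_config", "list"))
}

#' Reduced configuration for the packaged demo cohort
#'
#' Same structure as [run_config()] with sizes chosen so a full run
#' completes in a couple of minutes: 12 + 12 subjects, 24 trials, a
#' 12-frequency bank, 100 permutations, 4 chains x 1500 iterations.
#'
#' @param ... Named overrides.
#' @return A `run_config`.
#' @export
demo_config <- function(...) {
  run_config(n_trials = 24,
             bank = list(fmin = 5, fmax = 40, n = 12,
                         fwhm_start_ms = 320, fwhm_end_ms = 104),
             ispc_freq_range = c(5, 40),
             n_perm = 100, iter = 1500, warmup = 500, ...)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else
    list(config_hash = "", stages = list())
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_msg <- function(out_dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "logs", "run.log"),
      append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages of `config` into a deterministic directory
#' layout (`data/`, `results/`, `logs/`, `manifest.json`). Every stage is
#' seeded from the master seed; the manifest records the config hash and a
#' completed stage whose hash matches the current config is skipped on
#' rerun. A stage failure aborts with the stage name (never silently
#' continues).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key result tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(file.path(out_dir, "data"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "logs"), showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- read_manifest(out_dir)
  if (!identical(manifest$config_hash, hash))
    manifest <- list(config_hash = hash, stages = list())
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  done <- function(stage) isTRUE(manifest$stages[[stage]] == hash)
  mark <- function(stage) {
    manifest$stages[[stage]] <<- hash
    write_manifest(out_dir, manifest)
  }
  run_stage <- function(stage, code) {
    if (!isTRUE(config$stages[[stage]])) {
      log_msg(out_dir, stage, "disabled")
      return(invisible(NULL))
    }
    if (done(stage)) {
      log_msg(out_dir, stage, "up to date, skipped")
      return(invisible(NULL))
    }
    log_msg(out_dir, stage, "running")
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    mark(stage)
  }

  n_sub <- config$n_young + config$n_older
  subjects <- sprintf("S%03d", seq_len(n_sub))
  groups <- c(rep("young", config$n_young), rep("older", config$n_older))
  dpath <- function(...) file.path(out_dir, "data", ...)
  rpath <- function(...) file.path(out_dir, "results", ...)

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", {
    cohort <- generate_cohort(config$n_young, config$n_older,
                              seed = derive_seed(config$seed, "cohort"))
    readr::write_tsv(cohort, dpath("cohort.tsv"))
    write_ground_truth(attr(cohort, "truth"), dpath("ground_truth.json"))
    for (i in seq_len(n_sub)) {
      sched <- generate_schedule(config$n_trials, config$p_trt,
                                 config$switch_ratio,
                                 seed = derive_seed(config$seed, "sched", i))
      readr::write_tsv(sched, dpath(sprintf("schedule_%s.tsv", subjects[i])))
      taps <- generate_tap_stream(
        sched, config$tap_freq_hz,
        error_model = list(type = "random", p = 0.08, window_ms = 2000),
        seed = derive_seed(config$seed, "taps", i))
      readr::write_tsv(taps, dpath(sprintf("taps_%s.tsv", subjects[i])))
    }
  })

  # -- behavior ------------------------------------------------------------
  run_stage("behavior", {
    beh <- purrr::map_dfr(seq_len(n_sub), function(i) {
      sched <- readr::read_tsv(dpath(sprintf("schedule_%s.tsv", subjects[i])),
                               show_col_types = FALSE)
      taps <- readr::read_tsv(dpath(sprintf("taps_%s.tsv", subjects[i])),
                              show_col_types = FALSE)
      dplyr::mutate(score_trials(taps, sched), subject = subjects[i],
                    group = groups[i], .before = 1)
    })
    readr::write_tsv(beh, rpath("behavior.tsv"))
  })

  # -- connectivity (sources -> TF -> z maps + phase lags) -----------------
  run_stage("connectivity", {
    beh <- readr::read_tsv(rpath("behavior.tsv"), show_col_types = FALSE)
    bank <- design_bank(config$bank$fmin, config$bank$fmax, config$bank$n,
                        config$bank$fwhm_start_ms, config$bank$fwhm_end_ms,
                        config$fs)
    fsel <- bank$freqs >= config$ispc_freq_range[1] &
      bank$freqs <= config$ispc_freq_range[2]
    zmaps <- list(); zmeta <- list(); lags <- list()
    for (i in seq_len(n_sub)) {
      sched <- readr::read_tsv(dpath(sprintf("schedule_%s.tsv", subjects[i])),
                               show_col_types = FALSE)
      cpl <- coupling_spec(config$coupling$band, config$coupling$mean_lag,
                           config$coupling$kappa, config$coupling$snr)
      src <- generate_sources(sched, cpl, config$fs, config$epoch_window,
                              seed = derive_seed(config$seed, "src", i))
      ph_a <- tf_phase(decompose(src, bank, source = "LSM1"))
      ph_b <- tf_phase(decompose(src, bank, source = "RSM1"))
      ph_a <- ph_a[, fsel, , drop = FALSE]
      ph_b <- ph_b[, fsel, , drop = FALSE]
      beh_i <- beh[beh$subject == subjects[i], ]
      for (md in c("in_phase", "anti_phase")) {
        sel <- which(src$trial_info$mode == md)
        if (length(sel) < 2) next
        z <- with_seed(
          derive_seed(config$seed, "wsz", i, md),
          within_subject_z(ph_a[sel, , , drop = FALSE],
                           ph_b[sel, , , drop = FALSE],
                           bank$freqs[fsel], src$time_s,
                           config$toi_window_ms,
                           config$baseline_window_ms,
                           n_perm = config$n_perm, fs = config$fs,
                           grid_hz = config$grid_hz))
        zmaps[[length(zmaps) + 1L]] <- z$values
        zmeta[[length(zmeta) + 1L]] <- tibble::tibble(
          subject = subjects[i], group = groups[i], mode = md)
      }
      lat <- beh_i$latency_ms
      at_t <- ifelse(is.na(lat), NA_real_, lat / 1000)
      for (bd in names(config$bands)) {
        lg <- extract_phase_lag(ph_a, ph_b, bank$freqs[fsel], src$time_s,
                                config$bands[[bd]],
                                ifelse(is.na(at_t), 0.5, at_t))
        lags[[length(lags) + 1L]] <- tibble::tibble(
          subject = subjects[i], group = groups[i], band = bd,
          trial = lg$trial, lag_rad = lg$lag_rad,
          error_fraction = beh_i$error_fraction,
          mode = beh_i$transition_mode, failed = is.na(lat))
      }
    }
    zarr <- array(unlist(zmaps),
                  c(dim(zmaps[[1]]), length(zmaps)))
    zarr <- aperm(zarr, c(3, 1, 2))
    zm <- dplyr::bind_rows(zmeta)
    ztab <- purrr::map_dfr(seq_len(dim(zarr)[1]), function(k) {
      dplyr::mutate(
        tibble::tibble(
          freq_hz = rep(bank$freqs[fsel], times = dim(zarr)[3]),
          time_idx = rep(seq_len(dim(zarr)[3]),
                         each = sum(fsel)),
          z = as.vector(zarr[k, , ])),
        subject = zm$subject[k], group = zm$group[k], mode = zm$mode[k],
        .before = 1)
    })
    readr::write_tsv(ztab, rpath("zispc_maps.tsv"))
    readr::write_tsv(dplyr::bind_rows(lags), rpath("phase_trials.tsv"))
  })

  # -- cluster statistics --------------------------------------------------
  run_stage("clusters", {
    ztab <- readr::read_tsv(rpath("zispc_maps.tsv"), show_col_types = FALSE)
    freqs <- sort(unique(ztab$freq_hz))
    times <- sort(unique(ztab$time_idx))
    key <- dplyr::distinct(ztab, .data$subject, .data$group, .data$mode)
    arr <- array(NA_real_, c(nrow(key), length(freqs), length(times)))
    for (k in seq_len(nrow(key))) {
      sub <- ztab[ztab$subject == key$subject[k] & ztab$mode == key$mode[k], ]
      arr[k, , ] <- matrix(sub$z, length(freqs), length(times))
    }
    arr[!is.finite(arr)] <- 0
    cm <- contrast_maps(arr, key$subject, key$group, key$mode)
    with_seed(derive_seed(config$seed, "clusters"), {
      res <- list(
        interaction = cluster_permutation(
          cm$interaction, "between_group", cm$groups, config$n_perm,
          config$alpha, config$cluster_forming_p, freqs = freqs,
          time_s = times),
        mode_effect = cluster_permutation(
          cm$mode_effect, "one_sample", n_perm = config$n_perm,
          alpha = config$alpha,
          cluster_forming_p = config$cluster_forming_p,
          freqs = freqs, time_s = times),
        group_effect = cluster_permutation(
          cm$group_effect, "between_group", cm$groups, config$n_perm,
          config$alpha, config$cluster_forming_p, freqs = freqs,
          time_s = times))
      for (nm in names(res))
        write_cluster_json(res[[nm]], rpath(sprintf("clusters_%s.json", nm)))
      readr::write_tsv(
        purrr::map_dfr(names(res),
                       function(nm) dplyr::mutate(tidy(res[[nm]]),
                                                  contrast = nm,
                                                  .before = 1)),
        rpath("clusters.tsv"))
    })
  })

  # -- circular statistics -------------------------------------------------
  run_stage("circstats", {
    pt <- readr::read_tsv(rpath("phase_trials.tsv"), show_col_types = FALSE)
    pt <- pt[!pt$failed & is.finite(pt$lag_rad), ]
    cohort <- readr::read_tsv(dpath("cohort.tsv"), show_col_types = FALSE)
    gl <- dichotomize_gaba(cohort$gaba_raw_RIGHT_SM1, cohort$group)
    pt$gaba_level <- gl[match(pt$subject, cohort$subject)]
    res <- pt |>
      dplyr::group_by(.data$group, .data$band) |>
      dplyr::group_modify(function(d, key) {
        ray <- rayleigh_test(d$lag_rad)
        cl <- circ_linear_corr(d$lag_rad, d$error_fraction)
        tibble::tibble(test = c("rayleigh", "circ_linear"),
                       statistic = c(ray$z, cl$rho),
                       p_raw = c(ray$p, cl$p), n = c(ray$n, cl$n))
      }) |>
      dplyr::ungroup()
    aov_res <- pt |>
      dplyr::group_by(.data$band) |>
      dplyr::group_modify(function(d, key) {
        tab <- circ_anova2(d$lag_rad, d$group, d$gaba_level)
        tibble::tibble(test = paste0("circ_anova_", tab$term),
                       statistic = tab$statistic, p_raw = tab$p,
                       n = nrow(d))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(group = "all", .before = 1)
    res <- dplyr::bind_rows(res, aov_res)
    res$p_fdr <- fdr_adjust(res$p_raw)
    readr::write_tsv(res, rpath("circstats.tsv"))
  })

  # -- GABA preparation ----------------------------------------------------
  run_stage("gaba", {
    cohort <- readr::read_tsv(dpath("cohort.tsv"), show_col_types = FALSE)
    gaba <- prepare_gaba(cohort_gaba_long(cohort))
    readr::write_tsv(gaba, rpath("gaba.tsv"))
  })

  # -- mediation -----------------------------------------------------------
  run_stage("mediation", {
    cohort <- readr::read_tsv(dpath("cohort.tsv"), show_col_types = FALSE)
    beh <- readr::read_tsv(rpath("behavior.tsv"), show_col_types = FALSE)
    lat <- beh |>
      dplyr::filter(!is.na(.data$latency_ms)) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(Y_latency = median(.data$latency_ms) / 1000)
    dat <- dplyr::left_join(cohort, lat, by = "subject")
    dat$Y_latency[is.na(dat$Y_latency)] <- median(dat$Y_latency,
                                                  na.rm = TRUE)
    fit <- fit_mediation(dat, outcome = "Y_latency", x = "X", m = "M",
                         w = "W", chains = config$chains,
                         iter = config$iter, warmup = config$warmup,
                         seed = derive_seed(config$seed, "mediation"))
    readr::write_tsv(tidy(fit), rpath("mediation_coefficients.tsv"))
    ce <- conditional_effects(fit)
    ce_sum <- ce |>
      dplyr::group_by(.data$w_level) |>
      dplyr::summarise(dplyr::across(
        c("alpha", "beta", "tau_prime", "indirect"),
        list(mean = mean,
             pd = ~pd(.x),
             hdi_lo = ~hdi(.x, config$hdi_mass)[["lower"]],
             hdi_hi = ~hdi(.x, config$hdi_mass)[["upper"]])))
    readr::write_tsv(ce_sum, rpath("mediation_conditional.tsv"))
  })

  log_msg(out_dir, "pipeline", "complete")
  invisible(list(out_dir = out_dir, config_hash = hash))
}
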