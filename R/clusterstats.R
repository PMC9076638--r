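# Three-step nonparametric inference on time-frequency maps: within-subject
# permutation z-transform, group-level cluster-corrected permutation tests,
# and the group x transition-mode contrast scheme. Applies identically to
# ISPC and dB power maps.

#' Within-subject permutation z-transform of ISPC change
#'
#' Computes the observed baseline-subtracted ISPC map in the time of
#' interest and standardizes it against a permutation null built by randomly
#' exchanging, per trial, the roles of the time-of-interest and baseline
#' segments (a random trial subset swaps assignment in each permutation).
#' `z = (observed - null mean) / null SD` per (frequency, time) cell.
#'
#' @param phases_a,phases_b Phase arrays `[trial, freq, time]` (radians).
#' @param freqs Frequency axis, Hz.
#' @param time_s Time axis, s.
#' @param toi_window_ms Time of interest, ms. Default `c(0, 2000)`.
#' @param baseline_window_ms Baseline window, ms. Default `c(-500, -200)`.
#' @param n_perm Number of permutations. Default 1000.
#' @param fs,grid_hz Sampling and analysis grid rates, Hz.
#' @return An `ispc_map` with variant `"z"` on the TOI grid; cells with a
#'   degenerate (zero-SD) null are `NA` and counted in attribute
#'   `"n_masked"`.
#' @export
within_subject_z <- function(phases_a, phases_b, freqs, time_s,
                             toi_window_ms = c(0, 2000),
                             baseline_window_ms = c(-500, -200),
                             n_perm = 1000, fs = 250, grid_hz = 50) {
  n_tr <- dim(phases_a)[1]
  if (n_tr < 2) stop_invalid("need >= 2 trials")
  step <- max(1L, as.integer(round(fs / grid_hz)))
  grid <- seq(1L, dim(phases_a)[3], by = step)
  tms <- time_s[grid] * 1000
  toi_i <- grid[tms >= toi_window_ms[1] & tms <= toi_window_ms[2]]
  base_i <- grid[tms >= baseline_window_ms[1] & tms <= baseline_window_ms[2]]
  if (!length(toi_i) || !length(base_i))
    stop_invalid("TOI or baseline window outside the epoch")

  z_toi <- exp(1i * (phases_a[, , toi_i, drop = FALSE] -
                       phases_b[, , toi_i, drop = FALSE]))
  z_base <- exp(1i * (phases_a[, , base_i, drop = FALSE] -
                        phases_b[, , base_i, drop = FALSE]))
  nt <- length(toi_i); nb <- length(base_i)
  # tile the baseline segment to TOI length for swapped trials
  tile <- rep_len(seq_len(nb), nt)

  delta <- function(zt, zb) {
    Mod(colMeans(zt)) - rowMeans(Mod(colMeans(zb)))
  }
  obs <- delta(z_toi, z_base)

  acc <- matrix(0, length(freqs), nt)
  acc2 <- matrix(0, length(freqs), nt)
  for (b in seq_len(n_perm)) {
    flip <- runif(n_tr) < 0.5
    zt <- z_toi; zb <- z_base
    if (any(flip)) {
      zt[flip, , ] <- z_base[flip, , tile, drop = FALSE]
      zb[flip, , ] <- z_toi[flip, , seq_len(nb), drop = FALSE]
    }
    d <- delta(zt, zb)
    acc <- acc + d
    acc2 <- acc2 + d * d
  }
  mu <- acc / n_perm
  sdv <- sqrt(pmax(acc2 / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  z <- (obs - mu) / sdv
  n_masked <- sum(!is.finite(z))
  if (n_masked > 0) {
    message(sprintf("within_subject_z: %d cell(s) with degenerate null masked",
                    n_masked))
    z[!is.finite(z)] <- NA_real_
  }
  out <- new_ispc_map(z, freqs, time_s[toi_i], "z",
                      c("a", "b"), "stimulus", n_tr)
  attr(out, "n_masked") <- n_masked
  attr(out, "n_perm") <- n_perm
  out
}

#' Group-level cluster-corrected permutation test
#'
#' Per-cell t statistics (one-sample against zero under sign flipping, or
#' pooled two-sample under group-label permutation) are thresholded at the
#' two-tailed cluster-forming alpha; 4-connected same-signed supra-threshold
#' cells form clusters whose mass (sum of t; cell-count extent available as
#' an alternative) is compared against the permutation distribution of the
#' maximum cluster statistic. Cluster p-values use the `(b + 1) / (m + 1)`
#' correction.
#'
#' @param maps Numeric array `[subject, freq, time]` (NAs not allowed).
#' @param design `"one_sample"` or `"between_group"`.
#' @param groups Group labels (length = subjects) for the between-group
#'   design.
#' @param n_perm Number of permutations. Default 1000 (values below 100
#'   warn: unstable p resolution).
#' @param alpha Cluster-level significance level. Default 0.05.
#' @param cluster_forming_p Two-tailed per-cell threshold p. Default 0.05.
#' @param stat Cluster statistic, `"mass"` (default) or `"extent"`. The
#'   mass default is recorded in the result metadata since descriptions of
#'   this procedure are often phrased in terms of extent.
#' @param freqs,time_s Optional axes for reporting cluster bounds.
#' @return A `cluster_result`: tibble of clusters (`cluster`, `sign`,
#'   `mass`, `extent`, `p_cluster`, bounds, `significant`) plus the t map,
#'   labels, null distribution and settings.
#' @export
cluster_permutation <- function(maps, design = c("one_sample",
                                                 "between_group"),
                                groups = NULL, n_perm = 1000, alpha = 0.05,
                                cluster_forming_p = 0.05,
                                stat = c("mass", "extent"),
                                freqs = NULL, time_s = NULL) {
  design <- match.arg(design)
  stat <- match.arg(stat)
  if (n_perm < 100)
    warning("n_perm < 100 gives unstable cluster p resolution")
  d <- dim(maps)
  if (length(d) != 3) stop_invalid("`maps` must be [subject, freq, time]")
  n_sub <- d[1]
  X <- matrix(maps, nrow = n_sub)   # cells column-major [freq, time]
  if (design == "between_group") {
    if (is.null(groups) || length(groups) != n_sub)
      stop_invalid("`groups` must label every subject")
    g <- as.integer(factor(groups)) - 1L
    if (min(table(g)) < 4) stop_invalid("need >= 4 subjects per group")
    df <- n_sub - 2
  } else {
    if (n_sub < 4) stop_invalid("need >= 4 subjects")
    g <- integer(0)
    df <- n_sub - 1
  }
  thr <- qt(1 - cluster_forming_p / 2, df)
  res <- cluster_perm_cpp(X, d[2], d[3], thr, as.integer(n_perm),
                          stat == "extent", as.integer(g))
  obs_stat <- if (stat == "extent") res$extent else abs(res$mass)
  p_cl <- vapply(obs_stat,
                 function(s) (sum(res$null_max >= s) + 1) / (n_perm + 1),
                 numeric(1))
  freqs <- freqs %||% seq_len(d[2])
  time_s <- time_s %||% seq_len(d[3])
  bounds <- lapply(seq_along(obs_stat), function(k) {
    cells <- which(res$labels == k, arr.ind = TRUE)
    tibble::tibble(freq_lo = min(freqs[cells[, 1]]),
                   freq_hi = max(freqs[cells[, 1]]),
                   time_lo = min(time_s[cells[, 2]]),
                   time_hi = max(time_s[cells[, 2]]))
  })
  clusters <- dplyr::bind_cols(
    tibble::tibble(cluster = seq_along(obs_stat),
                   sign = ifelse(res$mass >= 0, "pos", "neg"),
                   mass = res$mass, extent = res$extent,
                   p_cluster = p_cl),
    if (length(obs_stat)) dplyr::bind_rows(bounds) else
      tibble::tibble(freq_lo = numeric(), freq_hi = numeric(),
                     time_lo = numeric(), time_hi = numeric()))
  clusters$significant <- clusters$p_cluster < alpha
  clusters <- dplyr::arrange(clusters, .data$p_cluster)
  structure(list(clusters = clusters, t_map = res$t, labels = res$labels,
                 null_max = res$null_max, freqs = freqs, time_s = time_s,
                 settings = list(design = design, n_perm = n_perm,
                                 alpha = alpha,
                                 cluster_forming_p = cluster_forming_p,
                                 stat = stat, tail = "two",
                                 note = paste("cluster statistic is",
                                              stat))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s design, %d permutations, %d cluster(s)\n",
              x$settings$design, x$settings$n_perm, nrow(x$clusters)))
  print(x$clusters)
  invisible(x)
}

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The cluster tibble.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' Serialize a cluster result to JSON
#'
#' Records cluster bounding boxes, member cells, masses, p-values and all
#' settings (including the cluster-statistic choice).
#'
#' @param x A `cluster_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(x, path) {
  members <- lapply(x$clusters$cluster, function(k) {
    cells <- which(x$labels == k, arr.ind = TRUE)
    list(freq_idx = cells[, 1], time_idx = cells[, 2])
  })
  jsonlite::write_json(
    list(clusters = x$clusters, members = members,
         settings = x$settings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the group x transition-mode contrast inputs
#'
#' From per-subject, per-mode z maps, forms (i) the per-subject transition
#' mode difference (in-phase minus anti-phase) whose between-group test is
#' the interaction difference-of-differences, (ii) the same difference maps
#' for the one-sample mode main effect, and (iii) per-subject mode-pooled
#' maps for the between-group main effect. Subjects missing a mode are
#' dropped with a message.
#'
#' @param maps Array `[observation, freq, time]`.
#' @param subject,group,mode Vectors (length = observations); `mode` uses
#'   `"in_phase"`/`"anti_phase"`.
#' @return List with arrays `interaction` / `mode_effect` /
#'   `group_effect` and the matching `groups` vector and `subjects`.
#' @export
contrast_maps <- function(maps, subject, group, mode) {
  stopifnot(length(subject) == dim(maps)[1])
  subj_u <- unique(subject)
  keep <- vapply(subj_u, function(s) {
    all(c("in_phase", "anti_phase") %in% mode[subject == s])
  }, logical(1))
  if (any(!keep))
    message(sprintf("contrast_maps: dropped %d subject(s) missing a mode",
                    sum(!keep)))
  subj_u <- subj_u[keep]
  if (!length(subj_u)) stop_invalid("no subject has both modes")
  nf <- dim(maps)[2]; nt <- dim(maps)[3]
  diff_arr <- array(NA_real_, c(length(subj_u), nf, nt))
  pool_arr <- array(NA_real_, c(length(subj_u), nf, nt))
  grp <- character(length(subj_u))
  for (i in seq_along(subj_u)) {
    s <- subj_u[i]
    ip <- which(subject == s & mode == "in_phase")[1]
    ap <- which(subject == s & mode == "anti_phase")[1]
    diff_arr[i, , ] <- maps[ip, , ] - maps[ap, , ]
    pool_arr[i, , ] <- (maps[ip, , ] + maps[ap, , ]) / 2
    grp[i] <- as.character(group[ip])
  }
  list(interaction = diff_arr, mode_effect = diff_arr,
       group_effect = pool_arr, groups = grp, subjects = subj_u)
}
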