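#' Default per-condition parameters of the synthetic study
#'
#' Condition-level means and spreads emulating a breast-carcinoma
#' epithelial-mesenchymal-transition panel: a non-targeting control
#' ("NT"), two guides each ablating NME1 or NME2 in the same carcinoma
#' line, and a normal-like epithelial line ("MCF10A").  Surface
#' tensions (mN/m, mean and sd across aggregates), AFM detachment
#' forces (nN; not measured for the normal-like line), per-field
#' invasion-count means, and target wound coverage at 24 h and 48 h.
#'
#' @return A tibble with one row per condition.
#' @export
study_conditions <- function() {
  tibble(
    condition = c("NT", "NME1-A", "NME1-B", "NME2-A", "NME2-B", "MCF10A"),
    gamma_mean = c(16, 4, 7, 16, 13, 45),
    gamma_sd = c(9, 3, 2, 5, 5, 18),
    detach_mean = c(1.8, 1.4, 1.2, 2.0, 1.9, NA),
    detach_sd = c(0.8, 0.5, 0.4, 1.0, 0.8, NA),
    invasion_mean = c(10, 65, 65, 10, 10, 10),
    coverage_24h = c(0.55, 0.78, 0.78, 0.55, 0.55, 0.70),
    coverage_48h = c(0.90, 1.00, 1.00, 0.90, 0.90, 1.00)
  )
}

#' Configuration of the synthetic study
#'
#' Bundles every tunable of the synthetic-data generator: condition
#' table, magnet calibration, molded-spheroid geometry, sample sizes
#' and noise levels.  The defaults are the study conditions of the
#' emulated panel; the seed is mandatory for stochastic outputs.
#'
#' @param conditions Condition table, see [study_conditions()].
#' @param m_v_a_per_m Magnetic moment per unit volume (A/m; synthetic
#'   calibration value).
#' @param grad_b_t_per_m Magnet field gradient (T/m).
#' @param b_mt Field magnitude (mT, metadata).
#' @param r0_um,r0_sd_um Molded spheroid radius mean and sd (um).
#' @param scale_um_per_px Camera pixel size (um/px).
#' @param n_aggregates Aggregates measured per condition.
#' @param n_afm_curves AFM curves per condition.
#' @param n_scratches Scratch-wound fields per condition.
#' @param n_fields,n_replicates Invasion fields per replicate and
#'   biological replicates.
#' @param obs_noise_sd Multiplicative measurement noise on h, w, V.
#' @param afm_noise_sd_nn AFM force noise (nN).
#' @param wound_noise_sd Noise on realized wound coverage.
#' @param gamma_floor_mn_per_m Truncation floor for drawn tensions.
#' @param n_images_per_condition Rendered QC images per condition.
#' @param seed Random seed (required).
#' @return A list of class `study_config`.
#' @export
study_config <- function(conditions = study_conditions(),
                         m_v_a_per_m = 500, grad_b_t_per_m = 170,
                         b_mt = 530, r0_um = 450, r0_sd_um = 70,
                         scale_um_per_px = 1,
                         n_aggregates = 12L, n_afm_curves = 45L,
                         n_scratches = 30L, n_fields = 5L,
                         n_replicates = 3L, obs_noise_sd = 0.01,
                         afm_noise_sd_nn = 0.1, wound_noise_sd = 0.03,
                         gamma_floor_mn_per_m = 0.5,
                         n_images_per_condition = 0L, seed = 1L) {
  if (is.null(seed) || !is.finite(seed)) {
    abort_input("`seed` is required for the stochastic generators.")
  }
  need <- c("condition", "gamma_mean", "gamma_sd", "detach_mean",
            "detach_sd", "invasion_mean", "coverage_24h", "coverage_48h")
  if (!all(need %in% names(conditions))) {
    abort_input(sprintf("`conditions` must have columns %s.",
                        paste(need, collapse = ", ")))
  }
  for (nm in c("m_v_a_per_m", "grad_b_t_per_m", "r0_um", "r0_sd_um",
               "scale_um_per_px")) {
    if (get(nm) <= 0) abort_input(sprintf("`%s` must be > 0.", nm))
  }
  structure(
    list(
      conditions = as_tibble(conditions),
      m_v_a_per_m = m_v_a_per_m, grad_b_t_per_m = grad_b_t_per_m,
      b_mt = b_mt, r0_um = r0_um, r0_sd_um = r0_sd_um,
      scale_um_per_px = scale_um_per_px,
      n_aggregates = as.integer(n_aggregates),
      n_afm_curves = as.integer(n_afm_curves),
      n_scratches = as.integer(n_scratches),
      n_fields = as.integer(n_fields),
      n_replicates = as.integer(n_replicates),
      obs_noise_sd = obs_noise_sd,
      afm_noise_sd_nn = afm_noise_sd_nn,
      wound_noise_sd = wound_noise_sd,
      gamma_floor_mn_per_m = gamma_floor_mn_per_m,
      n_images_per_condition = as.integer(n_images_per_condition),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

rtruncnorm_pos <- function(n, mean, sd, floor) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= floor)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= floor)
    guard <- guard + 1L
  }
  out[out <= floor] <- floor
  out
}

#' Generate the full synthetic study
#'
#' One call emitting every input of the analysis pipeline with known
#' ground truth: per-aggregate tensiometry observables (true gamma and
#' molded radius drawn per aggregate, equilibrium shape computed with
#' the forward model, multiplicative measurement noise on h, w, V),
#' stacked AFM force curves, scratch-wound area series, per-field
#' invasion counts, and (optionally) rendered side-view images.  All
#' outputs are deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @return A list of class `tm_study` with elements `tension`, `afm`,
#'   `wound`, `invasion`, `images`, `ctx` and `config`.
#' @export
synth_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  withr::local_seed(config$seed)
  ctx <- magnetic_context(config$m_v_a_per_m, config$grad_b_t_per_m,
                          config$b_mt)
  conds <- config$conditions

  tension <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    cd <- conds[i, ]
    gamma <- rtruncnorm_pos(config$n_aggregates, cd$gamma_mean, cd$gamma_sd,
                            config$gamma_floor_mn_per_m)
    r0 <- rtruncnorm_pos(config$n_aggregates, config$r0_um, config$r0_sd_um,
                         config$r0_um / 4)
    purrr::map_dfr(seq_len(config$n_aggregates), function(j) {
      c_um2 <- c_from_gamma(gamma[j], ctx)
      c_sc <- c_um2 * r0[j]^2
      f <- function(b) forward_observables(b, c_sc)[["v"]] - 4 * pi / 3
      b_sc <- uniroot(f, c(0.05, 5), extendInt = "downX", tol = 1e-9)$root
      obs <- forward_observables(b_sc, c_sc)
      noise <- 1 + rnorm(3, 0, config$obs_noise_sd)
      tibble(
        condition = cd$condition, aggregate = j,
        gamma_true = gamma[j], r0_um = r0[j],
        b_true = b_sc / r0[j], c_true = c_um2,
        h = obs[["h"]] * r0[j] * noise[1L],
        w = obs[["w"]] * r0[j] * noise[2L],
        v = obs[["v"]] * r0[j]^3 * noise[3L]
      )
    })
  })
  # measurement noise can leave a near-sphere marginally prolate; the
  # shape model cannot represent h > w, so clamp to the sphere
  tension <- tension %>% mutate(h = pmin(.data$h, .data$w))

  afm_conds <- conds %>% filter(is.finite(.data$detach_mean))
  afm <- purrr::map_dfr(seq_len(nrow(afm_conds)), function(i) {
    cd <- afm_conds[i, ]
    purrr::map_dfr(seq_len(config$n_afm_curves), function(j) {
      dip <- rtruncnorm_pos(1L, cd$detach_mean, cd$detach_sd, 0.05)
      curve <- synth_force_curve(
        dip_nn = dip, noise_sd_nn = config$afm_noise_sd_nn,
        drift_nn_per_s = rnorm(1, 0, 0.02), offset_nn = rnorm(1, 0, 0.3)
      )
      dplyr::bind_cols(
        tibble(condition = cd$condition, curve = j,
               dip_true_nn = dip)[rep(1L, nrow(curve)), ],
        curve
      )
    })
  })

  wound <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    cd <- conds[i, ]
    purrr::map_dfr(seq_len(config$n_scratches), function(j) {
      ser <- synth_wound_series(
        coverage_by_time = c(`0` = 0, `24` = cd$coverage_24h,
                             `48` = cd$coverage_48h),
        coverage_noise_sd = config$wound_noise_sd
      )
      dplyr::bind_cols(tibble(condition = cd$condition, scratch = j),
                       ser$areas)
    })
  })

  invasion <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    synth_invasion_counts(conds$invasion_mean[i], config$n_fields,
                          config$n_replicates,
                          condition = conds$condition[i])
  })

  images <- list()
  if (config$n_images_per_condition > 0L) {
    images <- purrr::map(seq_len(nrow(conds)), function(i) {
      purrr::map(seq_len(config$n_images_per_condition), function(j) {
        synth_aggregate_image(
          gamma_mn_per_m = max(conds$gamma_mean[i],
                               config$gamma_floor_mn_per_m),
          ctx = ctx, r0_um = config$r0_um,
          scale_um_per_px = config$scale_um_per_px,
          blur_sigma_px = 2, noise_sd = 0.05
        )
      })
    })
    names(images) <- conds$condition
  }

  structure(
    list(tension = tension, afm = afm, wound = wound, invasion = invasion,
         images = images, ctx = ctx, config = config),
    class = "tm_study"
  )
}

#' @export
print.tm_study <- function(x, ...) {
  cat(sprintf(
    "<tm_study> %d conditions; %d aggregates, %d force-curve rows, %d wound rows, %d invasion rows (seed %d)\n",
    nrow(x$config$conditions), nrow(x$tension), nrow(x$afm),
    nrow(x$wound), nrow(x$invasion), x$config$seed
  ))
  invisible(x)
}

#' Analyse a synthetic study end to end
#'
#' Runs the full pipeline on a generated study: fits the surface
#' tension of every aggregate from its (h, w, V), computes per-curve
#' detachment forces, wound coverage and invasion indices, and
#' compares every condition against the control with two-sided
#' Mann-Whitney tests.
#'
#' @param study A [synth_study()] result.
#' @param control Control condition label.
#' @return A list of class `study_report`: `tension` (per-aggregate
#'   fits), `tension_summary`, `tension_tests`, `afm`, `afm_summary`,
#'   `afm_tests`, `wound` (per-scratch coverage), `wound_summary`,
#'   `wound_tests` (at 24 h), `invasion` (per-condition indices),
#'   `invasion_tests`.
#' @export
study_report <- function(study, control = "NT") {
  stopifnot(inherits(study, "tm_study"))
  tension <- fit_tension_each(study$tension, study$ctx)
  tension_summary <- tension %>%
    filter(is.finite(.data$gamma_mn_per_m)) %>%
    group_by(.data$condition) %>%
    summarise(gamma_mean = mean(.data$gamma_mn_per_m),
              gamma_sd = sd(.data$gamma_mn_per_m),
              gamma_median = median(.data$gamma_mn_per_m),
              n = dplyr::n(), .groups = "drop")
  tension_tests <- compare_groups(
    tension %>% filter(is.finite(.data$gamma_mn_per_m)),
    value = "gamma_mn_per_m", control = control
  )

  afm <- detachment_force_each(
    study$afm %>% select(-"dip_true_nn")
  )
  afm_summary <- summarize_detachment(afm)
  afm_tests <- compare_groups(afm, value = "detachment_nn",
                              control = control)

  wound <- study$wound %>%
    group_by(.data$condition, .data$scratch) %>%
    wound_coverage() %>%
    ungroup()
  wound_summary <- wound %>%
    group_by(.data$condition, .data$time_h) %>%
    summarise(coverage_mean = mean(.data$coverage),
              coverage_sd = sd(.data$coverage), .groups = "drop")
  wound_tests <- compare_groups(
    wound %>% filter(.data$time_h == 24),
    value = "coverage", control = control
  )

  invasion <- summarize_invasion(study$invasion, control = control)
  invasion_tests <- compare_groups(
    study$invasion %>% mutate(count = as.numeric(.data$count)),
    value = "count", control = control
  )

  structure(
    list(
      tension = tension, tension_summary = tension_summary,
      tension_tests = tension_tests,
      afm = afm, afm_summary = afm_summary, afm_tests = afm_tests,
      wound = wound, wound_summary = wound_summary,
      wound_tests = wound_tests,
      invasion = invasion, invasion_tests = invasion_tests,
      control = control
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n\nSurface tension (mN/m):\n")
  print(as.data.frame(x$tension_summary), row.names = FALSE, digits = 3)
  cat("\nComparisons vs", x$control, "(Mann-Whitney):\n")
  print(as.data.frame(
    x$tension_tests[, c("condition", "u", "p_value", "stars")]
  ), row.names = FALSE, digits = 3)
  cat("\nDetachment force (nN):\n")
  print(as.data.frame(x$afm_summary), row.names = FALSE, digits = 3)
  cat("\nInvasion indices:\n")
  print(as.data.frame(x$invasion), row.names = FALSE, digits = 3)
  invisible(x)
}
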