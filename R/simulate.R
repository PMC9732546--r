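# Synthetic PDX cohort generator. Emulates the study design the analysis
# assumes: per-mouse exponential tumor growth with lognormal rate
# heterogeneity, enrollment at a baseline volume of 60-150 mm^3, weekly
# caliper measurement with multiplicative lognormal noise, treatment as a
# multiplicative reduction of the growth rate, and per-mouse sacrifice once
# the observed volume reaches 500 mm^3.

#' Simulation configuration
#'
#' Defaults reflect the study design being emulated: arms of 4-7 mice
#' (default 6), enrollment window 60-150 mm^3, weekly measurement,
#' sacrifice at 500 mm^3. The default latent growth rate of 0.03/day
#' (doubling time ~23 days) matches slow-growing chordoma-like xenografts
#' followed for 2-3 months before reaching the sacrifice volume;
#' between-mouse heterogeneity (CV 0.3) and measurement noise (CV 0.1) are
#' typical of caliper studies.
#'
#' @param n_per_arm mice per arm (4-7 in the emulated design; default 6).
#' @param growth_rate median per-mouse log-growth rate, per day.
#' @param growth_cv between-mouse lognormal CV of the growth rate.
#' @param measurement_noise_cv multiplicative lognormal CV of observed
#'   volumes.
#' @param enrollment_window baseline-volume interval, mm^3.
#' @param sacrifice_threshold observed volume triggering sacrifice, mm^3.
#' @param measurement_interval days between measurements (default 7).
#' @param max_followup last possible measurement day.
#' @param seed integer RNG seed; per-mouse streams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 6L,
                       growth_rate = 0.03,
                       growth_cv = 0.3,
                       measurement_noise_cv = 0.1,
                       enrollment_window = c(60, 150),
                       sacrifice_threshold = 500,
                       measurement_interval = 7L,
                       max_followup = 120L,
                       seed = 1L) {
  if (any(n_per_arm < 1)) pdx_validation_error("n_per_arm must be >= 1")
  if (growth_rate < 0 || growth_cv < 0 || measurement_noise_cv < 0)
    pdx_validation_error("rates and CVs must be >= 0")
  if (length(enrollment_window) != 2L || enrollment_window[1] <= 0 ||
      enrollment_window[1] > enrollment_window[2] ||
      enrollment_window[2] >= sacrifice_threshold)
    pdx_validation_error(
      "enrollment window must lie within (0, sacrifice_threshold)")
  if (measurement_interval < 1 || max_followup < 1)
    pdx_validation_error("measurement interval and follow-up must be >= 1 day")
  structure(list(n_per_arm = n_per_arm,
                 growth_rate = growth_rate,
                 growth_cv = growth_cv,
                 measurement_noise_cv = measurement_noise_cv,
                 enrollment_window = as.numeric(enrollment_window),
                 sacrifice_threshold = sacrifice_threshold,
                 measurement_interval = as.integer(measurement_interval),
                 max_followup = as.integer(max_followup),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lognormal sdlog giving a multiplicative coefficient of variation `cv`
sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

# deterministic per-mouse seed stream derived from the global seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131071 + k) %% 2147483647)
}

#' Simulate one mouse's growth curve
#'
#' The latent volume follows `V(day) = V1 * exp(g_i * (1 - e) * (day - 1))`
#' with the per-mouse rate `g_i` drawn lognormally around the configured
#' median rate (`e` is the arm's treatment effect: 0 = untreated, 1 = full
#' growth arrest). The baseline `V1` is uniform on the enrollment window,
#' observed volumes carry multiplicative lognormal noise, and measurement
#' stops with sacrifice at the first observation at or above the sacrifice
#' threshold, or at the end of follow-up.
#'
#' @param config a [sim_config()].
#' @param effect treatment effect `e`, multiplicative reduction of the
#'   growth rate (0 = control).
#' @param mouse_id,arm_label identifiers for the curve.
#' @param seed RNG seed for this mouse (default: the config seed).
#' @return a [growth_curve()].
#' @export
simulate_curve <- function(config, effect = 0, mouse_id = "m1",
                           arm_label = "arm", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (effect < 0) pdx_validation_error("treatment effect must be >= 0")
  set.seed(derive_seed(seed, 0L))
  days <- seq(1L, config$max_followup, by = config$measurement_interval)
  v1 <- runif(1, config$enrollment_window[1], config$enrollment_window[2])
  g_i <- config$growth_rate * exp(sdlog_from_cv(config$growth_cv) * rnorm(1))
  latent <- v1 * exp(g_i * (1 - effect) * (days - 1))
  noise <- exp(sdlog_from_cv(config$measurement_noise_cv) * rnorm(length(days)))
  obs <- latent * noise
  hit <- which(obs >= config$sacrifice_threshold)
  if (length(hit) > 0L) {
    keep <- seq_len(hit[1])
    status <- "sacrificed"
  } else {
    keep <- seq_along(days)
    status <- "alive-at-study-end"
  }
  growth_curve(mouse_id, days[keep], obs[keep], arm_label = arm_label,
               terminal_status = status)
}

#' Simulate a multi-arm PDX study
#'
#' Mice are independent; each mouse's random stream is derived
#' deterministically from the configuration seed, so the same seed always
#' reproduces the same study.
#'
#' @param config a [sim_config()]; `n_per_arm` may be a single count or a
#'   vector named by arm.
#' @param effects named numeric vector of treatment effects, one per arm,
#'   e.g. `c(control = 0, palbociclib = 0.6)`.
#' @param control name of the control arm (default `"control"` if present).
#' @return a [pdx_study()].
#' @examples
#' study <- simulate_study(sim_config(seed = 7),
#'                         effects = c(control = 0, treated = 0.6))
#' @export
simulate_study <- function(config, effects = c(control = 0, treated = 0.5),
                           control = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(effects)) || any(names(effects) == ""))
    pdx_validation_error("effects must be a named vector, one entry per arm")
  n_arm <- config$n_per_arm
  if (length(n_arm) == 1L) n_arm <- setNames(rep(n_arm, length(effects)),
                                             names(effects))
  k <- 0L
  arms <- lapply(names(effects), function(a) {
    curves <- lapply(seq_len(n_arm[[a]]), function(j) {
      k <<- k + 1L
      simulate_curve(config, effect = effects[[a]],
                     mouse_id = sprintf("%s_m%02d", a, j),
                     arm_label = a,
                     seed = derive_seed(config$seed, k))
    })
    study_arm(a, curves)
  })
  pdx_study(arms, control = control)
}

#' Simulate an RT-qPCR Ct table
#'
#' Each sample gets a human and a murine TBP reference Ct drawn from
#' `Normal(ref_mean, ref_sd)`; a target gene with log2 expression level `L`
#' amplifies at `Ct = mean(reference Cts) - L + Normal(0, noise_sd)`, so
#' its raw relative expression `N_target` equals `2^L` up to noise. Group
#' shifts are added to the control log2 level, e.g. a shift of -1 halves
#' expression.
#'
#' @param genes character vector of target gene symbols.
#' @param group_shifts named list: treated-group label -> named numeric
#'   vector of per-gene log2 shifts versus control (genes omitted from a
#'   vector shift by 0).
#' @param base_log2 named (or scalar) control log2 expression level
#'   relative to the reference (default 0: target amplifies at the
#'   reference Ct).
#' @param noise_sd per-measurement Ct noise, cycles.
#' @param n_per_group samples per group.
#' @param ref_mean,ref_sd reference-Ct distribution (default 25 +/- 0.5).
#' @param seed RNG seed.
#' @return data.frame in the Ct-table schema (`sample_id`, `group`, `gene`,
#'   `species_tag`, `ct`) with TBP reference rows for both species.
#' @export
simulate_ct_table <- function(genes, group_shifts = list(),
                              base_log2 = 0, noise_sd = 0.5,
                              n_per_group = 4L, ref_mean = 25, ref_sd = 0.5,
                              seed = 1L) {
  if (noise_sd < 0 || ref_sd < 0) pdx_validation_error("noise sd must be >= 0")
  set.seed(derive_seed(seed, 0L))
  groups <- c("control", names(group_shifts))
  base <- if (length(base_log2) == 1L)
    setNames(rep(base_log2, length(genes)), genes) else base_log2[genes]
  rows <- list()
  si <- 0L
  for (grp in groups) {
    shifts <- if (grp == "control") numeric(0) else group_shifts[[grp]]
    for (j in seq_len(n_per_group)) {
      si <- si + 1L
      sample_id <- sprintf("s%02d_%s", si, grp)
      ref_h <- rnorm(1, ref_mean, ref_sd)
      ref_m <- rnorm(1, ref_mean, ref_sd)
      ref <- combine_references(ref_h, ref_m)
      lev <- base
      if (length(shifts) > 0) {
        hit <- intersect(names(shifts), genes)
        lev[hit] <- lev[hit] + shifts[hit]
      }
      ct_target <- ref - lev + rnorm(length(genes), 0, noise_sd)
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(sample_id = sample_id, group = grp, gene = "TBP",
                   species_tag = c("human", "murine"), ct = c(ref_h, ref_m)),
        data.frame(sample_id = sample_id, group = grp, gene = genes,
                   species_tag = "human", ct = unname(ct_target))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
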