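#' Default 16-KPI variable catalogue
#'
#' Mirrors the standard hospital benchmarking catalogue: two access
#' indicators (desirable), six mostly-zero adverse-event safety rates
#' (undesirable), four productivity indicators (two desirable ratios, the
#' neutral bed-occupancy rate with an 80-90 percent optimal band, and an
#' undesirable waiting time), and four care-appropriateness rates.  With
#' 16 variables the default minimum weight is `1/(2*16) = 0.03125`.
#'
#' @return a [variable_specs()] frame with 16 rows.
#' @export
default_variable_specs <- function() {
  variable_specs(
    name = c("first_appointment_on_time", "surgical_list_on_time",
             "pressure_ulcer_rate", "cvc_bloodstream_infection_rate",
             "postop_embolism_rate", "postop_sepsis_rate",
             "instrumented_delivery_trauma_rate",
             "vaginal_delivery_trauma_rate",
             "std_patients_per_doctor", "std_patients_per_nurse",
             "bed_occupancy_rate", "waiting_time_before_surgery",
             "outpatient_surgery_rate", "readmission_30d_rate",
             "stay_over_30d_rate", "hip_fracture_surgery_48h"),
    dimension = c(rep("access", 2), rep("clinical_safety", 6),
                  rep("productivity", 4), rep("care_appropriateness", 4)),
    direction = c("desirable", "desirable",
                  rep("undesirable", 6),
                  "desirable", "desirable", "neutral", "undesirable",
                  "desirable", "undesirable", "undesirable", "desirable"),
    neutral_lo = c(rep(NA, 10), 80, rep(NA, 5)),
    neutral_hi = c(rep(NA, 10), 90, rep(NA, 5))
  )
}

#' Synthetic-panel configuration
#'
#' Defines the study conditions emulated by the generator: four peer
#' groups of 14/11/9/6 entities (40 in all), 65 months from January 2017,
#' a sharp shock in April 2020 hitting access hardest, tier-dependent
#' recovery (designated top entities recover fast and overshoot their
#' pre-shock baseline, low-tier entities settle below it), smaller
#' secondary waves, mostly-zero rare-event safety rates, and about 3
#' percent of cells missing completely at random.
#'
#' @param groups named integer vector of entities per peer group.
#' @param n_months horizon length in months.
#' @param start_month first month, `"YYYY-MM"`.
#' @param shock_month month of the sharp shock, strictly inside the
#'   horizon.
#' @param missing_rate fraction of cells masked, in `[0, 1)`.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param shock_depth named per-dimension dip depth at the shock month
#'   (fraction of baseline performance lost).
#' @param recovery_half_life months to halve the remaining dip, per tier.
#' @param recovery_level post-shock asymptote relative to baseline, per
#'   tier; above 1 means recovery above the pre-shock level.
#' @param later_waves `data.frame(month, scale)` of secondary dips
#'   (relative to `shock_depth`).
#' @param rare_event_rate baseline monthly probability of a nonzero
#'   adverse-event spike.
#' @param quality_range latent-quality range of ordinary entities.
#' @param top_qualities latent qualities of the two designated top
#'   entities per group.
#' @param season_amp amplitude of the mild seasonal term.
#' @param form_sd per-tier standard deviation (log scale) of the
#'   month-to-month operational form factor; weaker entities fluctuate
#'   more, so the monthly benchmark rotates (and occasionally a mid-tier
#'   entity overtakes the top performers) without disturbing long-run
#'   rankings.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(groups = c(B = 14, C = 11, D = 9, E = 6),
                         n_months = 65, start_month = "2017-01",
                         shock_month = "2020-04", missing_rate = 0.03,
                         seed = 1L,
                         shock_depth = c(access = 0.45,
                                         clinical_safety = 0.10,
                                         productivity = 0.30,
                                         care_appropriateness = 0.20),
                         recovery_half_life = c(top = 3, mid = 6,
                                                low = 10),
                         recovery_level = c(top = 1.08, mid = 1.00,
                                            low = 0.94),
                         later_waves = data.frame(
                           month = c("2020-11", "2021-01", "2021-12"),
                           scale = c(0.35, 0.30, 0.25)),
                         rare_event_rate = 0.08,
                         quality_range = c(0.35, 0.70),
                         top_qualities = c(0.85, 0.95),
                         season_amp = 0.015,
                         form_sd = c(top = 0.05, mid = 0.15,
                                     low = 0.18)) {
  stopifnot(n_months >= 2, missing_rate >= 0, missing_rate < 1,
            all(groups >= 1))
  months <- month_seq(start_month, n_months)
  shock_idx <- match(parse_month(shock_month), months)
  if (is.na(shock_idx) || shock_idx <= 1L || shock_idx >= n_months)
    stop("shock_month must lie strictly inside the horizon",
         call. = FALSE)
  structure(list(groups = groups, n_months = n_months,
                 start_month = start_month, months = months,
                 shock_month = shock_month, shock_idx = shock_idx,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 shock_depth = shock_depth,
                 recovery_half_life = recovery_half_life,
                 recovery_level = recovery_level,
                 later_waves = later_waves,
                 rare_event_rate = rare_event_rate,
                 quality_range = quality_range,
                 top_qualities = top_qualities,
                 season_amp = season_amp, form_sd = form_sd),
            class = "synth_config")
}

# tier trajectory multiplier for one dimension: 1 before the shock, a dip
# of `depth` at the shock month followed by exponential recovery towards
# `level`, with smaller superimposed later waves
shock_trajectory <- function(cfg, depth, half_life, level) {
  m <- seq_len(cfg$n_months)
  traj <- rep(1, cfg$n_months)
  after <- m >= cfg$shock_idx
  dt <- m[after] - cfg$shock_idx
  traj[after] <- level - (level - (1 - depth)) * 2^(-dt / half_life)
  for (i in seq_len(nrow(cfg$later_waves))) {
    wi <- match(parse_month(cfg$later_waves$month[i]), cfg$months)
    if (is.na(wi)) next
    hit <- m >= wi
    traj[hit] <- traj[hit] -
      depth * cfg$later_waves$scale[i] * 2^(-(m[hit] - wi) / half_life)
  }
  pmax(traj, 0.05)
}

#' Generate a synthetic hospital-KPI panel with ground truth
#'
#' Every KPI is built as baseline(latent entity quality) x seasonal term x
#' shock trajectory + noise, clipped to its plausible range; the six
#' safety rates are zero-inflated with rare positive spikes; the neutral
#' occupancy variable is derived from synthetic bed-days divided by
#' `beds * 365.25/12`, so it fluctuates around its 80-90 band.  Two
#' designated top entities per group carry the highest latent qualities
#' and recover above their pre-shock baseline.  Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a list with `panel` (a [kpi_panel()], masked at
#'   `cfg$missing_rate`), `truth` (entities with latent quality and tier,
#'   per-tier access trajectories, shock month, and the missing mask), and
#'   `specs` (the [default_variable_specs()]).
#' @export
generate_panel <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  specs <- default_variable_specs()
  months <- cfg$months
  nm <- cfg$n_months
  ents <- data.frame(
    entity = unlist(lapply(names(cfg$groups), function(g)
      sprintf("%s%02d", g, seq_len(cfg$groups[[g]])))),
    group = rep(names(cfg$groups), cfg$groups),
    stringsAsFactors = FALSE
  )
  ord <- order(ents$entity)
  ents <- ents[ord, , drop = FALSE]
  rownames(ents) <- NULL
  ne <- nrow(ents)

  gen <- with_seed(cfg$seed, {
    # latent qualities: ordinary entities evenly spread, two random
    # designated top entities per group
    quality <- numeric(ne)
    tier <- character(ne)
    for (g in names(cfg$groups)) {
      sel <- which(ents$group == g)
      ng <- length(sel)
      top <- sample(sel, 2L)
      rest <- setdiff(sel, top)
      quality[top] <- cfg$top_qualities
      quality[rest] <- seq(cfg$quality_range[1], cfg$quality_range[2],
                           length.out = length(rest))
      third <- ceiling(length(rest) / 3)
      tier[top] <- "top"
      tier[rest[order(quality[rest])]] <-
        c(rep("low", third), rep("mid", length(rest) - third))
    }

    dims <- c("access", "clinical_safety", "productivity",
              "care_appropriateness")
    tiers <- c("top", "mid", "low")
    # trajectory array: tier x month x dimension
    traj <- array(1, dim = c(3, nm, 4),
                  dimnames = list(tiers, months, dims))
    for (ti in tiers) for (d in dims)
      traj[ti, , d] <- shock_trajectory(cfg, cfg$shock_depth[[d]],
                                        cfg$recovery_half_life[[ti]],
                                        cfg$recovery_level[[ti]])

    moy <- as.integer(substr(months, 6, 7))
    season <- 1 + cfg$season_amp * sin(2 * pi * (moy - 1) / 12)

    # month-to-month operational form (lognormal, mean 1): weaker tiers
    # fluctuate more, rotating the monthly benchmark without disturbing
    # long-run rankings
    fsd <- unname(cfg$form_sd[tier])
    form <- matrix(exp(rnorm(ne * nm, 0, rep(fsd, nm)) -
                       rep(fsd, nm)^2 / 2), ne, nm)

    # performance level p in (0, ~1.1]: entity x month x dimension
    p <- array(NA_real_, dim = c(ne, nm, 4),
               dimnames = list(ents$entity, months, dims))
    for (e in seq_len(ne)) for (d in seq_along(dims))
      p[e, , d] <- pmin(pmax(
        quality[e] * season * traj[tier[e], , dims[d]] * form[e, ],
        0.02), 1.15)

    vals <- array(NA_real_, dim = c(ne, nm, nrow(specs)))
    clip01 <- function(x) pmin(pmax(x, 0), 100)
    nmat <- function(sd) matrix(rnorm(ne * nm, 0, sd), ne, nm)

    pa <- p[, , "access"]; ps <- p[, , "clinical_safety"]
    pp <- p[, , "productivity"]; pc <- p[, , "care_appropriateness"]
    # access
    vals[, , 1] <- clip01(30 + 65 * pa + nmat(2.5))
    vals[, , 2] <- clip01(35 + 60 * pa + nmat(2.5))
    # clinical safety: zero-inflated spikes, worse when performance is low
    spike_scale <- c(2.0, 0.5, 300, 800, 3, 1)
    for (v in 3:8) {
      prob <- pmin(pmax(cfg$rare_event_rate * (1.7 - ps), 0.01), 0.9)
      hit <- matrix(runif(ne * nm) < prob, ne, nm)
      mag <- matrix(rexp(ne * nm, rate = 1), ne, nm) *
        spike_scale[v - 2] * (1.6 - ps)
      vals[, , v] <- ifelse(hit, mag, 0)
    }
    # productivity
    vals[, , 9] <- pmax(3 + 4 * pp + nmat(0.15), 0.2)
    vals[, , 10] <- pmax(2 + 3 * pp + nmat(0.12), 0.2)
    # neutral occupancy built from synthetic bed-days over
    # beds * (365.25 / 12) days per month; lockdown months empty wards
    # (occupancy drops far below the 80-90 band) while recovery returns
    # to the band without rewarding overshoot
    beds <- 80 + round(120 * quality)
    occ_target <- 85 + 10 * (quality - 0.6)
    trmat <- t(vapply(seq_len(ne),
                      function(e) traj[tier[e], , "productivity"],
                      numeric(nm)))
    occ <- sweep(60 * pmin(trmat - 1, 0.03), 1, occ_target, `+`)
    bed_days <- sweep(occ / 100, 1, beds * month_length_days(), `*`) +
      nmat(25)
    vals[, , 11] <- pmax(sweep(bed_days, 1,
                               beds * month_length_days(), `/`) * 100, 0)
    vals[, , 12] <- pmax(0.4 + 1.5 * (1 - pp) + nmat(0.05), 0.05)
    # care appropriateness
    vals[, , 13] <- clip01(60 + 35 * pc + nmat(2))
    vals[, , 14] <- pmax(4 + 6 * (1 - pc) + nmat(0.4), 0)
    vals[, , 15] <- pmax(1.5 + 5 * (1 - pc) + nmat(0.35), 0)
    vals[, , 16] <- clip01(20 + 70 * pc + nmat(3))

    list(vals = vals, quality = quality, tier = tier, traj = traj)
  })

  panel <- kpi_panel(gen$vals, ents, months, specs$name)
  mask <- NULL
  if (cfg$missing_rate > 0) {
    masked <- inject_missing(panel, cfg$missing_rate,
                             seed = cfg$seed + 1L)
    panel <- masked$panel
    mask <- masked$mask
  }
  truth <- list(
    entities = data.frame(ents, quality = gen$quality, tier = gen$tier,
                          stringsAsFactors = FALSE),
    shock_month = cfg$shock_month,
    access_trajectory = as.data.frame(t(gen$traj[, , "access"])),
    mask = mask
  )
  list(panel = panel, truth = truth, specs = specs)
}

#' Mask cells of a panel completely at random
#'
#' Each cell is masked independently with probability `rate`; draws are
#' rejected (up to `max_tries`) if any variable would lose all its
#' observed values within a peer group, which would make standardization
#' and imputation impossible.
#'
#' @param panel a [kpi_panel()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @param max_tries resampling attempts before giving up.
#' @return a list with the masked `panel` and the logical `mask` array.
#' @export
inject_missing <- function(panel, rate, seed = 1L, max_tries = 100L) {
  stopifnot(inherits(panel, "kpi_panel"), rate >= 0, rate < 1)
  if (rate == 0)
    return(list(panel = panel,
                mask = array(FALSE, dim = dim(panel$values))))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      mask <- array(runif(length(panel$values)) < rate,
                    dim = dim(panel$values))
      ok <- TRUE
      for (g in unique(panel$entities$group)) {
        sel <- panel$entities$group == g
        for (v in seq_along(panel$variables)) {
          obs <- !is.na(panel$values[sel, , v]) & !mask[sel, , v]
          if (!any(obs)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        panel$values[mask] <- NA_real_
        return(list(panel = panel, mask = mask))
      }
    }
    stop("could not mask without emptying a column; lower the rate",
         call. = FALSE)
  })
}
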