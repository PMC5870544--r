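#' Configuration for the synthetic handling study
#'
#' Emulates the structure of a pre-centrifugation handling experiment:
#' subjects sampled at several delay times under two storage temperatures,
#' with features organised into drift clusters of archetypal kinetics and a
#' minority of features whose drift is irreproducible between subjects.
#'
#' Archetype curves (on the log2 fold-change scale, anchored at the moment
#' of blood draw, t = 0, when no drift has yet occurred):
#' * `increase` / `decrease`: saturating exponential kinetics reaching
#'   +/- `effect` log2 units at the last time point at the warm temperature;
#' * `stable`: flat;
#' * `excursion_3h`: a transient unimodal bump centred at 3 h that has
#'   returned to baseline by 8 h, active only at the cold (4 degC)
#'   temperature by default — emulating the short-lived cold-handling
#'   variability seen in refrigerated delays.
#'
#' Saturating effects are scaled down by `temp_factor` at the colder
#' temperature, and each archetype carries its own time constants per
#' temperature (`tau_warm`, `tau_cold` in `cluster_spec`): temperature
#' changes not only how far features drift but also the relative speed of
#' different metabolic processes, which is what makes storage temperature
#' recognisable from a single sample.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param time_points Delay times in hours (default `c(1, 3, 8, 24, 36)`).
#' @param temperatures Storage temperatures in degC (default `c(4, 22)`).
#' @param n_features Total features (default 478).
#' @param cluster_spec Tibble `archetype`, `n_features`, `effect` (max
#'   |log2 fold-change| at the warm temperature).
#' @param frac_irreproducible Fraction of features with subject-specific,
#'   irreproducible drift (default 0.06).
#' @param noise_sd Log-scale measurement noise sd (default 0.05).
#' @param subject_level_sd Log-scale between-subject baseline sd
#'   (default 0.3).
#' @param dilution_sd Log-scale per-sample dilution sd (default 0.1);
#'   removed by PQN.
#' @param temp_factor Warm/cold effect-size ratio (default 3).
#' @param tau Saturation time constant, hours (default 12).
#' @param irr_effect Log2 effect size of irreproducible drift (default 0.8).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 16,
                       time_points = c(1, 3, 8, 24, 36),
                       temperatures = c(4, 22),
                       n_features = 478,
                       cluster_spec = default_cluster_spec(n_features,
                                                           frac_irreproducible),
                       frac_irreproducible = 0.06,
                       noise_sd = 0.05,
                       subject_level_sd = 0.3,
                       dilution_sd = 0.1,
                       temp_factor = 3,
                       tau = 12,
                       irr_effect = 0.8,
                       seed = 1) {
  cluster_spec <- as_tibble(cluster_spec)
  stopifnot(all(c("archetype", "n_features", "effect") %in%
                  names(cluster_spec)),
            all(cluster_spec$archetype %in%
                  c("increase", "decrease", "stable", "excursion_3h")),
            noise_sd >= 0, subject_level_sd >= 0, dilution_sd >= 0)
  if (!"tau_warm" %in% names(cluster_spec)) cluster_spec$tau_warm <- tau
  if (!"tau_cold" %in% names(cluster_spec)) cluster_spec$tau_cold <- tau * 2.5
  if (!"effect_cold" %in% names(cluster_spec)) {
    cluster_spec$effect_cold <- cluster_spec$effect / temp_factor
  }
  n_irr <- round(frac_irreproducible * n_features)
  if (sum(cluster_spec$n_features) + n_irr != n_features) {
    abort("inconsistent cluster_spec totals: cluster features + irreproducible must equal n_features")
  }
  structure(list(n_subjects = n_subjects, time_points = sort(time_points),
                 temperatures = temperatures, n_features = n_features,
                 cluster_spec = cluster_spec, n_irreproducible = n_irr,
                 frac_irreproducible = frac_irreproducible,
                 noise_sd = noise_sd, subject_level_sd = subject_level_sd,
                 dilution_sd = dilution_sd, temp_factor = temp_factor,
                 tau = tau, irr_effect = irr_effect,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cluster_spec <- function(n_features = 478,
                                 frac_irreproducible = 0.06) {
  n_irr <- round(frac_irreproducible * n_features)
  n_mod <- n_features - n_irr
  n_up <- round(n_mod * 120 / 449)
  n_down <- round(n_mod * 110 / 449)
  n_exc <- round(n_mod * 80 / 449)
  # Cluster archetypes mirror the drift biology of delayed centrifugation:
  # a lactate-like slow glycolytic rise and a pyruvate-like fast rise that
  # is nearly frozen in the cold (temperature markers); a glucose-like
  # consumption decrease with its own temperature sensitivity; a
  # cold-specific monotone release of intracellular metabolites
  # (hemolysis-like, absent at room temperature); the transient cold 3 h
  # excursion; and stable features. Different processes respond to
  # temperature differently, which is what makes storage temperature
  # recognisable from a single sample.
  prop <- c(85, 35, 110, 30, 80) / 449
  n_up <- round(n_mod * prop[1]); n_upf <- round(n_mod * prop[2])
  n_down <- round(n_mod * prop[3]); n_hemo <- round(n_mod * prop[4])
  n_exc <- round(n_mod * prop[5])
  n_stab <- n_mod - n_up - n_upf - n_down - n_hemo - n_exc
  tibble(archetype = c("increase", "increase", "decrease", "increase",
                       "stable", "excursion_3h"),
         n_features = c(n_up, n_upf, n_down, n_hemo, n_stab, n_exc),
         effect = c(1.0, 0.9, 0.8, 0, 0, 0.6),
         effect_cold = c(1 / 3, 0.3, 0.8 / 3, 0.5, 0, 0.6),
         tau_warm = c(6, 2, 18, 12, 12, 12),
         tau_cold = c(30, 50, 9, 12, 12, 12))
}

# Feature-population parameters shared by every batch generated from one
# config: baseline levels and per-feature inter-individual variability.
# Plasma metabolites span a wide range of between-person variance; handling
# markers are typically the tightly regulated (low-variance) ones, so the
# per-feature subject-level sd is subject_level_sd times a log-normal
# multiplier rather than one global value.
sim_feature_params <- function(config) {
  with_seed(sub_seed(config$seed, 7), {
    list(base = exp(rnorm(config$n_features, mean = log(100), sd = 1)),
         subj_sd = config$subject_level_sd *
           exp(rnorm(config$n_features, 0, 0.6)))
  })
}

sim_features <- function(config) {
  cs <- config$cluster_spec
  tibble(
    feature_id = sprintf("d%05.3f", seq(0.5, 9.5,
                                        length.out = config$n_features)),
    archetype = c(rep(cs$archetype, cs$n_features),
                  rep("irreproducible", config$n_irreproducible)),
    effect = c(rep(cs$effect, cs$n_features),
               rep(config$irr_effect, config$n_irreproducible)),
    effect_cold = c(rep(cs$effect_cold, cs$n_features),
                    rep(config$irr_effect / config$temp_factor,
                        config$n_irreproducible)),
    tau_warm = c(rep(cs$tau_warm, cs$n_features),
                 rep(config$tau, config$n_irreproducible)),
    tau_cold = c(rep(cs$tau_cold, cs$n_features),
                 rep(config$tau * 2.5, config$n_irreproducible))
  )
}

# drift factors for all features of one sample; irreproducible features get
# a subject-specific sign and scale on increase-shaped kinetics
feature_drift_row <- function(feats, t, temp, config, sign_row, scale_row) {
  g <- numeric(nrow(feats))
  for (j in seq_len(nrow(feats))) {
    if (feats$archetype[j] == "irreproducible") {
      l2 <- archetype_log2(t, "increase", feats$effect[j], temp, config,
                           feats$tau_warm[j], feats$tau_cold[j],
                           feats$effect_cold[j])
      g[j] <- 2^(sign_row[j] * scale_row[j] * l2)
    } else {
      g[j] <- true_drift(t, feats$archetype[j], feats$effect[j], temp,
                         config, feats$tau_warm[j], feats$tau_cold[j],
                         feats$effect_cold[j])
    }
  }
  g
}

# log2 drift curve for an archetype at a given temperature, anchored at
# t = 0 (blood draw: no drift yet). Vectorized over t.
archetype_log2 <- function(t, archetype, effect, temperature, config,
                           tau_warm = config$tau,
                           tau_cold = config$tau * 2.5,
                           effect_cold = effect / config$temp_factor) {
  warm <- max(config$temperatures)
  tmax <- max(config$time_points)
  tau <- if (temperature == warm) tau_warm else tau_cold
  sat <- function(t, tau) 1 - exp(-t / tau)
  u <- sat(t, tau) / sat(tmax, tau)
  e <- if (temperature == warm) effect else effect_cold
  switch(archetype,
    increase = e * u,
    decrease = -e * u,
    stable = rep(0, length(t)),
    excursion_3h = {
      if (temperature == warm) {
        rep(0, length(t))  # cold-specific transient
      } else {
        effect_cold * exp(-(log(t / 3))^2 / (2 * 0.35^2))
      }
    },
    abort(paste0("unknown archetype: ", archetype))
  )
}

# True multiplicative drift factor g_true(t); g_true(0) = 1.
true_drift <- function(t, archetype, effect, temperature, config,
                       tau_warm = config$tau, tau_cold = config$tau * 2.5,
                       effect_cold = effect / config$temp_factor) {
  2^archetype_log2(t, archetype, effect, temperature, config,
                   tau_warm, tau_cold, effect_cold)
}

#' Simulate a pre-centrifugation handling study
#'
#' Generates intensities `x(s, f, t, T) = baseline(s, f) * g_true(f, T)(t) *
#' dilution(sample) * noise`, all factors log-normal, plus complete ground
#' truth. Irreproducible features drift with a random per-subject sign and
#' scale, so no common drift function exists for them.
#'
#' @param config A [sim_config()].
#' @return List with `table` (feature tibble over all temperatures),
#'   `meta` (sample metadata) and `truth` (list: `features` tibble with the
#'   planted archetype per feature, `curves` function, `config`).
#' @export
simulate_handling_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  feats <- sim_features(config)
  fp <- sim_feature_params(config)
  base_f <- fp$base
  with_seed(config$seed, {
    # fixed draw order makes the generator bit-reproducible under seed
    subj_eff <- matrix(exp(rnorm(config$n_subjects * config$n_features, 0, 1) *
                             rep(fp$subj_sd, each = config$n_subjects)),
                       config$n_subjects, config$n_features)
    irr_sign <- matrix(sample(c(-1, 1),
                              config$n_subjects * config$n_features,
                              replace = TRUE),
                       config$n_subjects, config$n_features)
    irr_scale <- matrix(runif(config$n_subjects * config$n_features, 0.5, 1.5),
                        config$n_subjects, config$n_features)

    subjects <- sprintf("P%02d", seq_len(config$n_subjects))
    design <- tidyr::expand_grid(temperature_c = config$temperatures,
                                 subject_id = subjects,
                                 time_h = config$time_points)
    design$sample_id <- sprintf("S%03d", seq_len(nrow(design)))
    dil <- exp(rnorm(nrow(design), 0, config$dilution_sd))
    x <- matrix(NA_real_, nrow(design), config$n_features,
                dimnames = list(design$sample_id, feats$feature_id))
    for (i in seq_len(nrow(design))) {
      s <- match(design$subject_id[i], subjects)
      g <- feature_drift_row(feats, design$time_h[i],
                             design$temperature_c[i], config,
                             irr_sign[s, ], irr_scale[s, ])
      noise <- exp(rnorm(config$n_features, 0, config$noise_sd))
      x[i, ] <- base_f * subj_eff[s, ] * g * dil[i] * noise
    }
    meta <- tibble(sample_id = design$sample_id,
                   subject_id = design$subject_id,
                   time_h = design$time_h,
                   temperature_c = design$temperature_c)
    truth <- list(
      features = feats,
      # absolute drift factor, anchored at blood draw (t = 0)
      curves = function(t, feature_idx, temperature) {
        a <- feats$archetype[feature_idx]
        if (a == "irreproducible") {
          abort("irreproducible features have no common truth curve")
        }
        true_drift(t, a, feats$effect[feature_idx], temperature, config,
                   feats$tau_warm[feature_idx], feats$tau_cold[feature_idx],
                   feats$effect_cold[feature_idx])
      },
      config = config
    )
    # re-anchored to a reference time, the form a fitted drift model estimates
    truth$curves_anchored <- function(t, feature_idx, temperature, t_ref = 1) {
      truth$curves(t, feature_idx, temperature) /
        truth$curves(t_ref, feature_idx, temperature)
    }
    list(table = ft_tibble(x), meta = meta, truth = truth)
  })
}

#' Effective ground-truth cluster labels at one temperature
#'
#' Planted clusters whose true curves coincide at a given temperature (e.g.
#' the cold-specific 3 h excursion is flat, hence indistinguishable from
#' "stable", at the warm temperature) are merged into one label, giving the
#' partition a clustering run at that temperature can actually recover.
#' Irreproducible features get label `NA`.
#'
#' @param truth The `truth` element of [simulate_handling_study()].
#' @param temperature Temperature in degC.
#' @return Character vector of labels, one per feature; the flat label is
#'   always `"stable"`, non-flat labels are `"<archetype>@<cluster index>"`.
#' @export
truth_labels <- function(truth, temperature) {
  config <- truth$config
  feats <- truth$features
  grid <- seq(min(config$time_points), max(config$time_points),
              length.out = 25)
  key <- vapply(seq_len(nrow(feats)), function(j) {
    if (feats$archetype[j] == "irreproducible") return(NA_character_)
    g <- true_drift(grid, feats$archetype[j], feats$effect[j],
                    temperature, config,
                    feats$tau_warm[j], feats$tau_cold[j],
                    feats$effect_cold[j])
    paste(signif(g, 8), collapse = ",")
  }, character(1))
  flat_key <- paste(signif(rep(1, length(grid)), 8), collapse = ",")
  uk <- setdiff(unique(key[!is.na(key)]), flat_key)
  lab <- rep(NA_character_, nrow(feats))
  lab[!is.na(key) & key == flat_key] <- "stable"
  for (i in seq_along(uk)) {
    sel <- !is.na(key) & key == uk[i]
    lab[sel] <- paste0(feats$archetype[sel][1], "@", i)
  }
  lab
}

#' Simulate a legacy sample batch with coarse time labels
#'
#' Emulates an external batch of archived samples: independent donors (one
#' sample each) stored at one temperature, true delay times drawn uniformly
#' within coarse levels, metadata exposing only the level label, and a
#' global multiplicative batch factor `exp(batch_shift)` applied to all
#' intensities (a peak-shape batch effect, removable by PQN against the
#' training batch's reference).
#'
#' @param config A [sim_config()] (cluster structure and noise reused).
#' @param n_samples Number of legacy samples (default 111).
#' @param levels Named list of time intervals in hours (defaults to
#'   same-day 3-8 h, next-day 8-24 h, later 24-30 h).
#' @param temperature Storage temperature of the batch (default the warm
#'   temperature).
#' @param batch_shift Log batch factor (default 0.2).
#' @param seed Seed for the batch (defaults to `config$seed + 1`).
#' @return List `table`, `meta` (with `group_label`, `time_h = NA`),
#'   `truth_times` (hidden true hours).
#' @export
simulate_legacy_batch <- function(config = sim_config(), n_samples = 111,
                                  levels = list("3-8h" = c(3, 8),
                                                "8-24h" = c(8, 24),
                                                "24-30h" = c(24, 30)),
                                  temperature = max(config$temperatures),
                                  batch_shift = 0.2,
                                  seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  feats <- sim_features(config)
  fp <- sim_feature_params(config)
  base_f <- fp$base
  with_seed(seed, {
    lvl <- rep(names(levels), length.out = n_samples)[sample.int(n_samples)]
    times <- vapply(lvl, function(l) runif(1, levels[[l]][1], levels[[l]][2]),
                    numeric(1))
    subj_eff <- matrix(exp(rnorm(n_samples * config$n_features, 0, 1) *
                             rep(fp$subj_sd, each = n_samples)),
                       n_samples, config$n_features)
    irr_sign <- matrix(sample(c(-1, 1), n_samples * config$n_features,
                              replace = TRUE),
                       n_samples, config$n_features)
    irr_scale <- matrix(runif(n_samples * config$n_features, 0.5, 1.5),
                        n_samples, config$n_features)
    dil <- exp(rnorm(n_samples, 0, config$dilution_sd))
    x <- matrix(NA_real_, n_samples, config$n_features,
                dimnames = list(sprintf("L%03d", seq_len(n_samples)),
                                feats$feature_id))
    for (i in seq_len(n_samples)) {
      g <- feature_drift_row(feats, times[i], temperature, config,
                             irr_sign[i, ], irr_scale[i, ])
      noise <- exp(rnorm(config$n_features, 0, config$noise_sd))
      x[i, ] <- base_f * subj_eff[i, ] * g * dil[i] * noise * exp(batch_shift)
    }
    meta <- tibble(sample_id = rownames(x),
                   subject_id = sprintf("Q%03d", seq_len(n_samples)),
                   time_h = NA_real_,
                   temperature_c = temperature,
                   group_label = lvl)
    list(table = ft_tibble(x), meta = meta, truth_times = unname(times))
  })
}
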