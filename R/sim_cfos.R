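#' Configuration for the synthetic c-Fos experiment
#'
#' Describes a crossed drug-by-anxiety c-Fos screen: two drug states
#' (saline and drug) crossed with four anxiety conditions, plus an optional
#' home-cage group, with a planted "target" region whose drug-state group
#' means are decoupled from the rest of the network.
#'
#' Latent (noise-free) group means follow an additive model
#' `baseline + drug_effect * [drug] + loading[region] * level[condition]`;
#' a single shared anxiety factor with positive per-region loadings makes
#' all regions mutually correlated across conditions, which is what renders
#' the planted decoupling detectable by the network scores.
#'
#' @param regions Ordered character vector of region labels (>= 2).
#' @param conditions Ordered anxiety-condition labels; `"none"` is the
#'   unstressed condition.
#' @param saline_label,drug_label Drug-state labels.
#' @param n_per_group Animals per treatment group.
#' @param baseline Baseline expression level (arbitrary expression units).
#' @param drug_effect Additive shift under drug, must be <= 0 (the drug
#'   lowers expression).
#' @param anxiety_levels Named numeric vector, one scalar per condition:
#'   the anxiety load of each condition.
#' @param anxiety_loadings Numeric vector, one weight per region, coupling
#'   each region to the anxiety load.
#' @param noise_sd Animal-level Gaussian noise SD (> 0).
#' @param target_region Label of the planted decoupled region.
#' @param decoupling Decoupling strength in `[0, 1]`; 1 replaces the target
#'   region's drug-state latent means with an independent random profile.
#' @param include_homecage Add a `homecage` group (saline state, no
#'   stressor, own label)?
#' @param homecage_label Label for the home-cage group.
#' @param sep Separator used to build crossed group labels.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return An object of class `cfos_sim_config`.
#' @seealso [simulate_cfos()]
#' @export
cfos_sim_config <- function(regions = limbic_regions(),
                            conditions = c("none", "EPM", "shock", "shock_EPM"),
                            saline_label = "saline",
                            drug_label = "DZP",
                            n_per_group = 4,
                            baseline = 100,
                            drug_effect = -30,
                            anxiety_levels = c(none = 0, EPM = 0.5,
                                               shock = 1, shock_EPM = 1.5),
                            anxiety_loadings = seq(30, 60,
                                                   length.out = length(regions)),
                            noise_sd = 10,
                            target_region = "CEA",
                            decoupling = 0,
                            include_homecage = TRUE,
                            homecage_label = "homecage",
                            sep = "_",
                            seed = 1L) {
  regions <- as.character(regions)
  if (length(regions) < 2L || anyDuplicated(regions)) {
    stopf("`regions` must be >= 2 unique labels")
  }
  if (!target_region %in% regions) {
    stopf("unknown target_region '%s'", target_region)
  }
  if (!is.numeric(n_per_group) || n_per_group < 1 ||
      n_per_group != trunc(n_per_group)) {
    stopf("`n_per_group` must be a positive integer")
  }
  check_scalar_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_scalar_number(drug_effect, "drug_effect", upper = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(decoupling, "decoupling", lower = 0, upper = 1)
  if (!setequal(names(anxiety_levels), conditions)) {
    stopf("`anxiety_levels` must be named by the conditions")
  }
  if (length(anxiety_loadings) != length(regions)) {
    stopf("`anxiety_loadings` must have one weight per region")
  }
  cfg <- list(regions = regions, conditions = conditions,
              saline_label = saline_label, drug_label = drug_label,
              n_per_group = as.integer(n_per_group), baseline = baseline,
              drug_effect = drug_effect,
              anxiety_levels = anxiety_levels[conditions],
              anxiety_loadings = setNames(as.numeric(anxiety_loadings), regions),
              noise_sd = noise_sd, target_region = target_region,
              decoupling = decoupling,
              include_homecage = isTRUE(include_homecage),
              homecage_label = homecage_label, sep = sep,
              seed = as.integer(seed))
  class(cfg) <- "cfos_sim_config"
  cfg
}

#' Simulate a c-Fos expression table with a planted decoupled region
#'
#' Generates one expression record per (region, group, animal). Each animal
#' belongs to one treatment group and contributes one value per region
#' (latent group mean plus iid Gaussian noise, truncated at zero). For the
#' target region only, the drug-state latent means are blended with an
#' independent random 4-profile in proportion to `decoupling`, which
#' destroys the region's cross-region correlation under drug while leaving
#' the saline state intact.
#'
#' @param config A [cfos_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{expression}{data.frame with columns `region`, `group`,
#'       `animal`, `value` (the expression table).}
#'     \item{truth}{list with `target_region` and `latent_means`, the
#'       noise-free region-by-group mean matrix.}
#'     \item{config}{the config, echoed.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cfos(cfos_sim_config(seed = 7))
#' head(sim$expression)
simulate_cfos <- function(config) {
  if (!inherits(config, "cfos_sim_config")) {
    stopf("`config` must be a cfos_sim_config")
  }
  cfg <- config
  R <- length(cfg$regions)
  states <- c(cfg$saline_label, cfg$drug_label)
  groups <- c(as.vector(vapply(states, group_label, character(length(cfg$conditions)),
                               condition = cfg$conditions, sep = cfg$sep)),
              if (cfg$include_homecage) cfg$homecage_label)
  with_local_seed(cfg$seed, {
    # latent means: region x group
    latent <- matrix(0, R, length(groups), dimnames = list(cfg$regions, groups))
    for (si in seq_along(states)) {
      de <- if (si == 2L) cfg$drug_effect else 0
      for (ci in seq_along(cfg$conditions)) {
        g <- group_label(states[si], cfg$conditions[ci], cfg$sep)
        latent[, g] <- cfg$baseline + de +
          cfg$anxiety_loadings * cfg$anxiety_levels[ci]
      }
    }
    if (cfg$include_homecage) {
      latent[, cfg$homecage_label] <- cfg$baseline +
        cfg$anxiety_loadings * cfg$anxiety_levels["none"]
    }
    # planted decoupling: blend the target's drug-state means with an
    # independent random profile of matching location and spread
    if (cfg$decoupling > 0) {
      drug_groups <- group_label(cfg$drug_label, cfg$conditions, cfg$sep)
      mu <- latent[cfg$target_region, drug_groups]
      spread <- abs(cfg$anxiety_loadings[cfg$target_region]) *
        sd(cfg$anxiety_levels)
      v <- rnorm(length(cfg$conditions))
      v <- v / sd(v)
      rand_profile <- mean(mu) + spread * v
      latent[cfg$target_region, drug_groups] <-
        (1 - cfg$decoupling) * mu + cfg$decoupling * rand_profile
    }
    # animal-level observations: each animal spans all regions
    recs <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      noise <- matrix(rnorm(R * cfg$n_per_group, 0, cfg$noise_sd),
                      R, cfg$n_per_group)
      vals <- pmax(latent[, g] + noise, 0)
      recs[[gi]] <- data.frame(
        region = rep(cfg$regions, times = cfg$n_per_group),
        group = g,
        animal = rep(paste0(g, cfg$sep, "a", seq_len(cfg$n_per_group)),
                     each = R),
        value = as.vector(vals),
        stringsAsFactors = FALSE
      )
    }
    expression <- do.call(rbind, recs)
    # canonical record order: region-major within group
    expression <- expression[order(match(expression$group, groups),
                                   match(expression$region, cfg$regions),
                                   expression$animal), , drop = FALSE]
    rownames(expression) <- NULL
    list(expression = expression,
         truth = list(target_region = cfg$target_region,
                      latent_means = latent),
         config = cfg)
  })
}
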