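#' Configuration for the hierarchical study simulator
#'
#' Encodes the study design the analysis assumes: two cohorts sampled at
#' 4-week intervals at two tape-strip depths, with participant-dominant
#' community structure, a depth-nested richness reduction, small disease
#' effects concentrated on pathobiont (Staphylococcus-like) ASVs,
#' negligible temporal drift, and extraction negatives carrying a
#' contaminant pool.
#'
#' Key parameters (log scale unless noted):
#' * `participant_effect_sd` — sd of the per-participant, per-ASV
#'   log-abundance deviation (interindividual variation);
#' * `participant_occupancy` — probability a pool ASV is in a participant's
#'   surface community at all;
#' * `depth_retention_fraction` — fraction of a participant's non-core
#'   surface ASVs retained within the epidermis (the inner community is a
#'   participant-consistent subset of the outer; core and pathobiont ASVs
#'   are always retained);
#' * `status_effect` — log-fold enrichment of pathobiont ASVs in AD
#'   participants;
#' * `time_effect` — sd of a shared per-timepoint log shift (0 = no
#'   systematic drift, only resampling noise);
#' * `core_log_boost` — added log abundance of a participant's planted core
#'   ASVs, making them effectively always detectable;
#' * `sample_noise_sd` — per-sample, per-ASV log-normal overdispersion: the
#'   residual ("unmeasured parameters and stochastic processes") variance;
#'   with multinomial resampling alone the design factors would explain
#'   nearly all community variance, which no amplicon study shows.
#'
#' @param seed integer master seed.
#' @param n_participants_ad,n_participants_hc cohort sizes (default 20/20).
#' @param n_timepoints visits at 4-week intervals (default 4).
#' @param reads_mean,reads_sdlog sequencing-depth log-normal (mean count,
#'   sd of log depth).
#' @param n_asvs_global size of the biological ASV pool.
#' @param participant_effect_sd,participant_occupancy see above.
#' @param depth_retention_fraction in (0, 1].
#' @param status_effect,time_effect see above (>= 0).
#' @param n_pathobiont_asvs,n_core_asvs_per_participant,core_log_boost
#'   planted structure sizes.
#' @param n_contaminant_asvs,n_negatives,negative_detect_prob,
#'   negative_reads_frac contaminant/negative-control model.
#' @param contaminant_spike_prob,contaminant_spike_weight sporadic
#'   carry-over of contaminants into epidermal-surface samples
#'   (per-sample inclusion probability; relative weight).
#' @param base_log_sd sd of the global log-normal abundance base.
#' @param include_lesional also emit lesional samples for AD participants.
#' @param location_effect_sd sd of per-(location, ASV) log shifts for
#'   lesional samples.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_participants_ad = 20, n_participants_hc = 20,
                             n_timepoints = 4,
                             reads_mean = 42569, reads_sdlog = 0.3,
                             n_asvs_global = 300,
                             participant_effect_sd = 1.5,
                             participant_occupancy = 0.8,
                             depth_retention_fraction = 0.35,
                             status_effect = 0.5, time_effect = 0,
                             sample_noise_sd = 2,
                             n_pathobiont_asvs = 20,
                             n_core_asvs_per_participant = 30,
                             core_log_boost = 3,
                             n_contaminant_asvs = 27, n_negatives = 30,
                             negative_detect_prob = 0.97,
                             negative_reads_frac = 0.05,
                             contaminant_spike_prob = 0.2,
                             contaminant_spike_weight = 0.005,
                             base_log_sd = 1,
                             include_lesional = FALSE,
                             location_effect_sd = 1) {
  cfg <- as.list(environment())
  for (nm in c("participant_effect_sd", "status_effect", "time_effect",
               "base_log_sd", "location_effect_sd", "core_log_boost",
               "sample_noise_sd")) {
    if (cfg[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  for (nm in c("depth_retention_fraction", "participant_occupancy",
               "negative_detect_prob")) {
    v <- cfg[[nm]]
    if (v <= 0 || v > 1) stop("`", nm, "` must be in (0, 1]", call. = FALSE)
  }
  for (nm in c("n_participants_ad", "n_participants_hc", "n_timepoints",
               "n_asvs_global")) {
    assert_count(cfg[[nm]], nm)
  }
  for (nm in c("n_pathobiont_asvs", "n_core_asvs_per_participant",
               "n_contaminant_asvs", "n_negatives")) {
    assert_count(cfg[[nm]], nm, min = 0)
  }
  if (cfg$reads_mean <= 0) stop("`reads_mean` must be positive", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Paper-like simulator preset
#'
#' Defaults tuned so the realized PERMANOVA partition reproduces the effect
#' hierarchy interindividual >> depth > status with time ~ 0, and the mean
#' ASV richness roughly halves from the epidermal surface to within the
#' epidermis. Parameters are the package defaults of [synthetic_config()];
#' overrides (e.g. smaller cohorts for fast tests) are passed through.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
preset_paper_like <- function(seed = 1, ...) {
  synthetic_config(seed = seed, ...)
}

#' Null simulator preset
#'
#' All planted effects removed: no interindividual deviation
#' (`participant_effect_sd = 0`, full occupancy), no depth subsetting
#' (`depth_retention_fraction = 1`), no status or time effect, no planted
#' cores, and no surface spiking of contaminants (which would otherwise
#' induce a depth signal). Every sample is then an i.i.d. multinomial draw
#' from one shared composition, so every design term is null.
#'
#' @param seed master seed.
#' @param ... further overrides forwarded to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
preset_null <- function(seed = 1, ...) {
  synthetic_config(seed = seed, participant_effect_sd = 0,
                   participant_occupancy = 1, depth_retention_fraction = 1,
                   status_effect = 0, time_effect = 0,
                   n_core_asvs_per_participant = 0, core_log_boost = 0,
                   contaminant_spike_prob = 0, ...)
}

.genus_pool <- c("Corynebacterium", "Acinetobacter", "Streptococcus",
                 "Micrococcus", "Anaerococcus", "Granulicatella", "Gemella",
                 "Cutibacterium", "Paracoccus", "Kocuria", "Dermacoccus",
                 "Moraxella", "Enhydrobacter", "Finegoldia", "Rothia")
.kitome_pool <- c("Pseudomonas", "Ralstonia", "Sphingomonas", "Bradyrhizobium",
                  "Burkholderia", "Methylobacterium", "Delftia")
.genus_phylum <- c(Corynebacterium = "Actinobacteriota",
                   Acinetobacter = "Proteobacteria",
                   Streptococcus = "Firmicutes", Micrococcus = "Actinobacteriota",
                   Anaerococcus = "Firmicutes", Granulicatella = "Firmicutes",
                   Gemella = "Firmicutes", Cutibacterium = "Actinobacteriota",
                   Paracoccus = "Proteobacteria", Kocuria = "Actinobacteriota",
                   Dermacoccus = "Actinobacteriota", Moraxella = "Proteobacteria",
                   Enhydrobacter = "Proteobacteria", Finegoldia = "Firmicutes",
                   Rothia = "Actinobacteriota", Staphylococcus = "Firmicutes",
                   Pseudomonas = "Proteobacteria", Ralstonia = "Proteobacteria",
                   Sphingomonas = "Proteobacteria",
                   Bradyrhizobium = "Proteobacteria",
                   Burkholderia = "Proteobacteria",
                   Methylobacterium = "Proteobacteria",
                   Delftia = "Proteobacteria")

#' Generate a synthetic tape-strip study
#'
#' Mechanism: (1) a global log-normal abundance base over the ASV pool;
#' (2) per-participant surface profiles: base plus Normal(0, sd) per-ASV
#' deviations, a Bernoulli occupancy mask, and planted core ASVs forced to
#' high abundance; (3) within-epidermis profiles as a participant-consistent
#' subset of the surface support, renormalized; (4) pathobiont ASVs
#' up-weighted by exp(status_effect) in AD participants; (5) per time point
#' only multinomial read resampling (plus an optional shared log shift when
#' `time_effect > 0`); (6) extraction negatives drawing from the
#' contaminant pool only, with sporadic contaminant carry-over into surface
#' samples; (7) optional lesional samples with per-body-location profile
#' shifts. All randomness flows from `config$seed`; identical configs give
#' bit-identical output.
#'
#' @param config a `synthetic_config`.
#' @return list with `table` (raw-count [asv_table()], negatives included),
#'   `meta` (validated metadata), `taxonomy`, and `truth` (per-participant
#'   core sets, contaminant and pathobiont ids, per-participant
#'   depth-restricted ids, realized effect sizes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_bio <- cfg$n_asvs_global
  bio_ids <- sprintf("ASV%04d", seq_len(n_bio))
  cont_ids <- if (cfg$n_contaminant_asvs > 0) {
    sprintf("CONT%03d", seq_len(cfg$n_contaminant_asvs))
  } else character(0)
  all_ids <- c(bio_ids, cont_ids)
  n_ad <- cfg$n_participants_ad; n_hc <- cfg$n_participants_hc
  participants <- sprintf("P%02d", seq_len(n_ad + n_hc))
  cohort <- c(rep("AD", n_ad), rep("HC", n_hc))
  names(cohort) <- participants

  with_seed(cfg$seed, {
    base_log <- stats::rnorm(n_bio, 0, cfg$base_log_sd)
    pathobionts <- if (cfg$n_pathobiont_asvs > 0) {
      sort(sample(bio_ids, cfg$n_pathobiont_asvs))
    } else character(0)
    time_shift <- if (cfg$time_effect > 0) {
      matrix(stats::rnorm(cfg$n_timepoints * n_bio, 0, cfg$time_effect),
             cfg$n_timepoints, n_bio)
    } else NULL

    core_sets <- list(); support_sets <- list(); within_sets <- list()
    weights <- list()   # per participant: list(surface =, within =) bio weights
    core_candidates <- setdiff(bio_ids, pathobionts)
    for (p in participants) {
      core_p <- if (cfg$n_core_asvs_per_participant > 0) {
        sort(sample(core_candidates, cfg$n_core_asvs_per_participant))
      } else character(0)
      occ <- stats::runif(n_bio) < cfg$participant_occupancy
      support <- union(bio_ids[occ], union(core_p, pathobionts))
      eff <- stats::rnorm(n_bio, 0, cfg$participant_effect_sd)
      l <- base_log + eff
      names(l) <- bio_ids
      l[core_p] <- l[core_p] + cfg$core_log_boost
      if (cohort[p] == "AD" && length(pathobionts)) {
        l[pathobionts] <- l[pathobionts] + cfg$status_effect
      }
      keep_frac <- setdiff(support, union(core_p, pathobionts))
      kept <- keep_frac[stats::runif(length(keep_frac)) <
                          cfg$depth_retention_fraction]
      within <- union(union(core_p, intersect(pathobionts, support)), kept)
      w_surface <- exp(l); w_surface[!(bio_ids %in% support)] <- 0
      w_within <- exp(l); w_within[!(bio_ids %in% within)] <- 0
      core_sets[[p]] <- core_p
      support_sets[[p]] <- sort(support)
      within_sets[[p]] <- sort(within)
      weights[[p]] <- list(surface = w_surface, within = w_within)
    }

    cont_base <- if (length(cont_ids)) {
      stats::setNames(exp(stats::rnorm(length(cont_ids), 0, 1)), cont_ids)
    } else numeric(0)

    filaggrin <- stats::setNames(rep(FALSE, length(participants)), participants)
    filaggrin[participants[cohort == "AD"]] <-
      stats::runif(n_ad) < 0.5
    oscorad_base <- stats::setNames(rep(NA_real_, length(participants)),
                                    participants)
    oscorad_base[cohort == "AD"] <- stats::runif(n_ad, 10, 35)

    loc_shift <- NULL; lesional_loc <- NULL
    if (cfg$include_lesional) {
      loc_shift <- matrix(stats::rnorm(length(.location_levels) * n_bio, 0,
                                       cfg$location_effect_sd),
                          length(.location_levels), n_bio,
                          dimnames = list(.location_levels, bio_ids))
      lesional_loc <- lapply(participants[cohort == "AD"], function(p) {
        loc <- sample(.location_levels, 1)
        locs <- character(cfg$n_timepoints)
        for (t in seq_len(cfg$n_timepoints)) {
          if (t > 1 && stats::runif(1) < 0.2) loc <- sample(.location_levels, 1)
          locs[t] <- loc
        }
        locs
      })
      names(lesional_loc) <- participants[cohort == "AD"]
    }

    rows <- list(); meta_rows <- list()
    draw_reads <- function(mean_reads) {
      max(1L, round(stats::rlnorm(1, log(mean_reads) - cfg$reads_sdlog^2 / 2,
                                  cfg$reads_sdlog)))
    }
    emit_sample <- function(id, w_bio, spike, reads_mean, meta_row) {
      w <- c(w_bio, rep(0, length(cont_ids)))
      names(w) <- all_ids
      if (length(spike)) w[names(spike)] <- spike
      n_reads <- draw_reads(reads_mean)
      counts <- stats::rmultinom(1, n_reads, w)[, 1]
      rows[[id]] <<- counts
      meta_rows[[id]] <<- meta_row
    }

    for (p in participants) {
      for (t in seq_len(cfg$n_timepoints)) {
        osc <- if (cohort[p] == "AD") {
          max(0, oscorad_base[p] + stats::rnorm(1, 0, 2))
        } else NA_real_
        for (dp in c("surface", "within")) {
          w <- weights[[p]][[dp]]
          if (!is.null(time_shift)) w <- w * exp(time_shift[t, ])
          if (cfg$sample_noise_sd > 0) {
            w <- w * exp(stats::rnorm(n_bio, 0, cfg$sample_noise_sd))
          }
          spike <- numeric(0)
          if (dp == "surface" && length(cont_ids) &&
              cfg$contaminant_spike_prob > 0) {
            hit <- stats::runif(length(cont_ids)) < cfg$contaminant_spike_prob
            if (any(hit)) {
              spike <- stats::setNames(
                rep(cfg$contaminant_spike_weight * sum(w), sum(hit)),
                cont_ids[hit])
            }
          }
          id <- sprintf("%s_T%d_%s", p, t, dp)
          emit_sample(id, w, spike, cfg$reads_mean, data.frame(
            sample_id = id, participant_id = p, cohort = cohort[p],
            skin_status = if (cohort[p] == "AD") "NLS" else "HC",
            depth = dp, timepoint = t, body_location = "volar_forearm",
            oscorad = osc, filaggrin_mutation = filaggrin[p],
            is_negative_control = FALSE, stringsAsFactors = FALSE))
          if (cfg$include_lesional && cohort[p] == "AD") {
            loc <- lesional_loc[[p]][t]
            wl <- weights[[p]][[dp]] * exp(loc_shift[loc, ])
            if (!is.null(time_shift)) wl <- wl * exp(time_shift[t, ])
            if (cfg$sample_noise_sd > 0) {
              wl <- wl * exp(stats::rnorm(n_bio, 0, cfg$sample_noise_sd))
            }
            idl <- sprintf("%s_T%d_%s_LS", p, t, dp)
            emit_sample(idl, wl, numeric(0), cfg$reads_mean, data.frame(
              sample_id = idl, participant_id = p, cohort = "AD",
              skin_status = "LS", depth = dp, timepoint = t,
              body_location = loc, oscorad = osc,
              filaggrin_mutation = filaggrin[p],
              is_negative_control = FALSE, stringsAsFactors = FALSE))
          }
        }
      }
    }

    for (k in seq_len(cfg$n_negatives)) {
      id <- sprintf("NEG%02d", k)
      w <- rep(0, length(all_ids)); names(w) <- all_ids
      if (length(cont_ids)) {
        inc <- stats::runif(length(cont_ids)) < cfg$negative_detect_prob
        if (!any(inc)) inc[sample.int(length(cont_ids), 1)] <- TRUE
        w[cont_ids[inc]] <- cont_base[inc]
      }
      n_reads <- draw_reads(cfg$reads_mean * cfg$negative_reads_frac)
      counts <- if (sum(w) > 0) stats::rmultinom(1, n_reads, w)[, 1] else
        stats::setNames(rep(0, length(all_ids)), all_ids)
      rows[[id]] <- counts
      meta_rows[[id]] <- data.frame(
        sample_id = id, participant_id = NA_character_, cohort = NA_character_,
        skin_status = NA_character_, depth = NA_character_,
        timepoint = NA_integer_, body_location = NA_character_,
        oscorad = NA_real_, filaggrin_mutation = NA,
        is_negative_control = TRUE, stringsAsFactors = FALSE)
    }

    genera <- sample(.genus_pool, n_bio, replace = TRUE)
    names(genera) <- bio_ids
    genera[pathobionts] <- "Staphylococcus"
    cont_genera <- if (length(cont_ids)) {
      stats::setNames(sample(.kitome_pool, length(cont_ids), replace = TRUE),
                      cont_ids)
    } else character(0)
    gen_all <- c(genera, cont_genera)
    taxonomy <- data.frame(
      asv_id = all_ids,
      domain = "Bacteria",
      phylum = unname(.genus_phylum[gen_all]),
      class = paste0(unname(.genus_phylum[gen_all]), "_class"),
      order = paste0(gen_all, "ales"),
      family = paste0(gen_all, "aceae"),
      genus = unname(gen_all),
      species = NA_character_,
      stringsAsFactors = FALSE)

    values <- do.call(rbind, rows)
    rownames(values) <- names(rows)
    colnames(values) <- all_ids
    meta <- validate_metadata(do.call(rbind, meta_rows),
                              max_timepoint = cfg$n_timepoints)
    rownames(meta) <- NULL

    truth <- list(
      core = core_sets,
      contaminants = cont_ids,
      pathobionts = pathobionts,
      support = support_sets,
      within_support = within_sets,
      depth_restricted = lapply(participants, function(p) {
        setdiff(support_sets[[p]], within_sets[[p]])
      }),
      realized = list(participant_effect_sd = cfg$participant_effect_sd,
                      depth_retention_fraction = cfg$depth_retention_fraction,
                      status_effect = cfg$status_effect,
                      time_effect = cfg$time_effect)
    )
    names(truth$depth_restricted) <- participants

    list(table = asv_table(values, "raw_counts"), meta = meta,
         taxonomy = taxonomy, truth = truth)
  })
}
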