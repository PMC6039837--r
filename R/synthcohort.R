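#' @title Synthetic rs-MEG cohorts and twin trait datasets
#'
#' @description
#' The synthetic module emulates the two data sources the pipeline consumes:
#' (a) multichannel resting-state recordings whose pairwise phase coupling has
#' a modular block structure that differs by clinical group (non-responder,
#' responder, control), over three runs per subject, and (b) quantitative
#' traits on MZ/DZ/unrelated twin pedigrees with a specified heritability.
#'
#' The signal model is a phase-mixture construction rather than a coupled
#' oscillator ODE: each channel is a sum of narrow-band stochastic
#' oscillations (one per 1-Hz component) whose phase mixes a module-shared
#' component, a globally shared component and an independent component, with
#' variance shares normalized so the marginal variance is constant across
#' channels. This gives direct, analytic control over the expected
#' phase-locking structure, which is what the downstream graph analysis
#' measures.
#' @name synthcohort
NULL

#' Cohort specification
#'
#' Parameters of the synthetic three-group MEG cohort. Group coupling
#' profiles default to values calibrated so that, after PLV connectivity and
#' cost-10% graph analysis, modularity orders controls > responders >
#' non-responders and transitivity the reverse.
#'
#' @param n_per_group named counts for `non_responder`, `responder`,
#'   `control` (defaults 9/14/14, the classification cohort sizes).
#' @param n_channels number of sensor channels (default 248, the magnetometer
#'   count of a MAGNES 3600 system; analyses in this package use smaller
#'   arrays for tractability).
#' @param n_runs runs (sessions) per subject, default 3.
#' @param run_length_s patient run length in seconds (default 300, i.e.
#'   5-minute sessions).
#' @param control_run_length_s control run length (default 360, 6-minute
#'   sessions).
#' @param fs_hz sampling rate, default 508.6.
#' @param n_modules number of ground-truth phase-coupling communities
#'   (default 4; must be at least 2).
#' @param profiles group coupling profiles, see [group_profiles()].
#' @param subject_sd standard deviations of subject-level jitter on the
#'   within/global couplings, named `within` and `global`.
#' @param sedation_fraction fraction of patients flagged as sedated
#'   (default 0.5). Sedation has no simulated effect on the signal by
#'   default; `sedation_effect` adds the given amount to the global coupling
#'   of sedated subjects for power experiments.
#' @param sedation_effect numeric, default 0.
#' @param osc_freqs component centre frequencies generated per channel
#'   (default `4:28`, one per PLV bin; band-restricted analyses may generate
#'   only the components they use).
#' @param seed master RNG seed for the cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(non_responder = 9L, responder = 14L,
                                        control = 14L),
                        n_channels = 248L, n_runs = 3L,
                        run_length_s = 300, control_run_length_s = 360,
                        fs_hz = 508.6, n_modules = 4L,
                        profiles = group_profiles(),
                        subject_sd = c(within = 0.02, global = 0.03),
                        sedation_fraction = 0.5, sedation_effect = 0,
                        osc_freqs = plv_bin_grid(), seed = 1L) {
  groups <- c("non_responder", "responder", "control")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  stopifnot(setequal(names(n_per_group), groups), all(n_per_group >= 0),
            n_channels >= 2, n_runs >= 1,
            run_length_s > 0, control_run_length_s > 0,
            fs_hz > 2 * 30,  # Nyquist above the highest band edge
            n_modules >= 2,
            sedation_fraction >= 0, sedation_fraction <= 1)
  for (g in groups) {
    p <- profiles[[g]]
    stopifnot(p$within >= 0, p$within <= 1, p$global >= 0, p$global <= 1)
  }
  structure(list(n_per_group = n_per_group[groups],
                 n_channels = as.integer(n_channels),
                 n_runs = as.integer(n_runs),
                 run_length_s = run_length_s,
                 control_run_length_s = control_run_length_s,
                 fs_hz = fs_hz, n_modules = as.integer(n_modules),
                 profiles = profiles, subject_sd = subject_sd,
                 sedation_fraction = sedation_fraction,
                 sedation_effect = sedation_effect,
                 osc_freqs = osc_freqs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default group coupling profiles
#'
#' `within` is the variance share of the module-shared phase component,
#' `global` the base variance share of the globally shared component (scaled
#' per channel by a fixed hub-weight ramp, so strong global coupling
#' concentrates the top connections on a cross-module core). Non-responders
#' have the highest global coupling, controls the lowest, responders
#' intermediate: stronger global coupling merges the module structure (lower
#' modularity) and builds a dense core (higher transitivity).
#'
#' @param within named numeric, module-coupling share per group.
#' @param global named numeric, global-coupling share per group.
#' @return named list of per-group profiles.
#' @export
group_profiles <- function(within = c(non_responder = 0.10, responder = 0.17,
                                      control = 0.30),
                           global = c(non_responder = 0.55, responder = 0.32,
                                      control = 0.02)) {
  groups <- c("non_responder", "responder", "control")
  stopifnot(setequal(names(within), groups), setequal(names(global), groups))
  out <- lapply(groups, function(g) list(within = unname(within[g]),
                                         global = unname(global[g])))
  names(out) <- groups
  out
}

#' Per-channel coupling profile for one subject
#'
#' Expands group-level coupling strengths into the per-channel layout used by
#' [generate_run()]: a contiguous module assignment and a hub-weight ramp
#' (evenly spaced multipliers 0.6..1.4 within each module) that scales the
#' globally shared variance share per channel.
#'
#' @param n_channels channel count.
#' @param n_modules module count.
#' @param within,global variance shares in `[0, 1]`.
#' @param fs_hz sampling rate.
#' @param run_length_s run duration in seconds.
#' @param osc_freqs component centre frequencies in Hz (default `4:28`).
#' @param phase_fwhm_hz nominal linewidth of each component's stochastic
#'   phase (default 0.5 Hz, giving ~1-Hz-wide components).
#' @return list of class `coupling_profile`.
#' @export
coupling_profile <- function(n_channels, n_modules, within, global,
                             fs_hz = 508.6, run_length_s = 300,
                             osc_freqs = plv_bin_grid(),
                             phase_fwhm_hz = 0.5) {
  stopifnot(within >= 0, within <= 1, global >= 0, global <= 1,
            n_modules >= 2, n_channels >= 2,
            fs_hz > 2 * max(osc_freqs), run_length_s > 0)
  module <- as.integer(ceiling(seq_len(n_channels) * n_modules / n_channels))
  hub <- numeric(n_channels)
  for (m in seq_len(n_modules)) {
    idx <- which(module == m)
    hub[idx] <- seq(0.6, 1.4, length.out = max(length(idx), 2L))[seq_along(idx)]
  }
  structure(list(module = module, within = within, global = global,
                 hub = hub, fs_hz = fs_hz, run_length_s = run_length_s,
                 osc_freqs = osc_freqs, phase_fwhm_hz = phase_fwhm_hz),
            class = "coupling_profile")
}

# Wiener phase process around a carrier: initial phase uniform, increments
# 2*pi*f/fs plus white jitter whose diffusion gives a Lorentzian line of the
# requested FWHM.
phase_jitter_sd <- function(fwhm_hz, fs_hz) sqrt(2 * pi * fwhm_hz / fs_hz)

phase_process <- function(n, freq_hz, fs_hz, jitter_sd, ncol = 1L) {
  d <- matrix(stats::rnorm(n * ncol, mean = 2 * pi * freq_hz / fs_hz,
                           sd = jitter_sd), nrow = n, ncol = ncol)
  d[1L, ] <- stats::runif(ncol, -pi, pi)  # uniform start phase
  if (ncol == 1L) return(cumsum(d[, 1L]))
  # column-wise cumulative sum, vectorized: cumsum the stacked vector and
  # subtract each column's inherited offset
  v <- cumsum(as.vector(d))
  m <- matrix(v, nrow = n, ncol = ncol)
  offs <- c(0, v[seq_len(ncol - 1L) * n])
  m - rep(offs, each = n)
}

#' Generate one synthetic resting-state run
#'
#' Produces a channels x samples array. Channel i's signal is a sum over the
#' component frequencies of three narrow-band oscillations: one whose phase
#' is shared by all channels of its module (variance share `within`), one
#' whose phase is shared globally (share `global * hub_i^2`, renormalized),
#' and one with an independent phase. Shares are normalized per channel so
#' the marginal variance is constant.
#'
#' @param profile a [coupling_profile()].
#' @param run_index run number (only labels the run).
#' @param seed RNG seed; same seed and profile give bit-identical output.
#' @return a `ts_run` object, see [as_run()].
#' @export
generate_run <- function(profile, run_index = 1L, seed = 1L) {
  stopifnot(inherits(profile, "coupling_profile"))
  if (profile$run_length_s <= 0 || profile$fs_hz <= 0)
    stop("run length and sampling rate must be positive")
  n <- as.integer(round(profile$run_length_s * profile$fs_hz))
  nch <- length(profile$module)
  nmod <- max(profile$module)
  jsd <- phase_jitter_sd(profile$phase_fwhm_hz, profile$fs_hz)

  # per-channel variance shares of (module, global, independent) components
  s_m <- rep(profile$within, nch)
  s_g <- profile$global * profile$hub^2
  s_n <- pmax(1 - profile$within - profile$global, 0)
  tot <- s_m + s_g + s_n
  tot[tot == 0] <- 1
  a_m <- sqrt(s_m / tot); a_g <- sqrt(s_g / tot); a_n <- sqrt(s_n / tot)

  amp <- 1 / sqrt(length(profile$osc_freqs))
  sig <- matrix(0, nrow = n, ncol = nch)
  with_seed(seed, {
    for (f in profile$osc_freqs) {
      pg <- phase_process(n, f, profile$fs_hz, jsd)
      pm <- phase_process(n, f, profile$fs_hz, jsd, ncol = nmod)
      pind <- phase_process(n, f, profile$fs_hz, jsd, ncol = nch)
      shared <- cos(pm[, profile$module, drop = FALSE])
      sig <- sig + amp * (shared * rep(a_m, each = n) +
                          cos(pg) %o% a_g +
                          cos(pind) * rep(a_n, each = n))
    }
  })
  as_run(t(sig), fs_hz = profile$fs_hz,
         channel_names = sprintf("ch%03d", seq_len(nch)),
         run_index = run_index)
}

#' Generate a synthetic cohort
#'
#' Builds the cohort manifest (subject id, group, sedation flag, age, sex,
#' per-subject seed) and the per-subject coupling profiles. Runs themselves
#' are materialized lazily with [subject_runs()] (they are deterministic
#' functions of the recorded seeds), or written to disk with
#' [write_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @return object of class `vns_cohort` with elements `manifest`
#'   (data.frame), `profiles` (per-subject coupling profiles) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  nsub <- length(groups)
  prefix <- c(non_responder = "NR", responder = "R", control = "C")
  ids <- unlist(lapply(names(spec$n_per_group), function(g)
    sprintf("%s%02d", prefix[g], seq_len(spec$n_per_group[g]))),
    use.names = FALSE)

  manifest <- with_seed(spec$seed, {
    age <- ifelse(groups == "control",
                  pmin(pmax(stats::rnorm(nsub, 28.6, 3.9), 22), 36),
                  pmin(pmax(stats::rnorm(nsub, 11.3, 6.9), 1), 30))
    sex <- sample(c("M", "F"), nsub, replace = TRUE)
    sedation <- integer(nsub)
    for (g in c("non_responder", "responder")) {
      idx <- which(groups == g)
      n_sed <- round(spec$sedation_fraction * length(idx))
      if (n_sed > 0) sedation[sample(idx, n_sed)] <- 1L
    }
    data.frame(subject_id = ids, group = groups, sedation = sedation,
               age = round(age, 1), sex = sex,
               seed = child_seed(spec$seed, seq_len(nsub)),
               run_length_s = ifelse(groups == "control",
                                     spec$control_run_length_s,
                                     spec$run_length_s),
               stringsAsFactors = FALSE)
  })

  profiles <- vector("list", nsub)
  names(profiles) <- ids
  for (i in seq_len(nsub)) {
    base <- spec$profiles[[groups[i]]]
    jit <- with_seed(child_seed(manifest$seed[i], 0L),
                     stats::rnorm(2L, 0, c(spec$subject_sd[["within"]],
                                           spec$subject_sd[["global"]])))
    w <- min(max(base$within + jit[1], 0.02), 0.95)
    g <- min(max(base$global + jit[2] +
                   spec$sedation_effect * manifest$sedation[i], 0), 0.95)
    profiles[[i]] <- coupling_profile(spec$n_channels, spec$n_modules,
                                      within = w, global = g,
                                      fs_hz = spec$fs_hz,
                                      run_length_s = manifest$run_length_s[i],
                                      osc_freqs = spec$osc_freqs)
  }
  structure(list(manifest = manifest, profiles = profiles, spec = spec),
            class = "vns_cohort")
}

#' Materialize the runs of one subject
#'
#' @param cohort a `vns_cohort` from [generate_cohort()].
#' @param subject_id subject identifier from the manifest.
#' @return list of `ts_run`, one per run.
#' @export
subject_runs <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "vns_cohort"))
  i <- match(subject_id, cohort$manifest$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id)
  lapply(seq_len(cohort$spec$n_runs), function(r)
    generate_run(cohort$profiles[[i]], run_index = r,
                 seed = child_seed(cohort$manifest$seed[i], r)))
}

#' Write a cohort to disk
#'
#' Writes `manifest.tsv` (columns subject_id, group, sedation, age, sex,
#' run_paths) plus per-run gzipped TSV files (samples x channels, header =
#' channel names) each with a JSON sidecar recording `fs_hz`,
#' `channel_names` and the run seed.
#'
#' @param cohort a `vns_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest with `run_paths` column.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vns_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  run_paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    runs <- subject_runs(cohort, man$subject_id[i])
    paths <- character(length(runs))
    for (r in seq_along(runs)) {
      paths[r] <- file.path(dir, sprintf("%s_run%d.tsv.gz",
                                         man$subject_id[i], r))
      write_run(runs[[r]], paths[r],
                seed = child_seed(man$seed[i], r))
    }
    run_paths[i] <- paste(paths, collapse = ";")
  }
  man$run_paths <- run_paths
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' @rdname write_cohort
#' @param run a `ts_run`.
#' @param path output path ending in `.tsv.gz`.
#' @param seed seed recorded in the sidecar.
#' @export
write_run <- function(run, path, seed = NA) {
  stopifnot(inherits(run, "ts_run"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  df <- as.data.frame(t(run$data))
  names(df) <- run$channel_names
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = run$fs_hz,
                            channel_names = run$channel_names,
                            seed = seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run written by [write_run()]
#'
#' @param path path to the `.tsv.gz` run file (sidecar `<path>.json` must
#'   exist).
#' @return a `ts_run`.
#' @export
read_run <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                          check.names = FALSE)
  as_run(t(as.matrix(df)), fs_hz = side$fs_hz,
         channel_names = side$channel_names)
}

#' Twin pedigree specification
#'
#' Defaults mirror the healthy-control twin design used for heritability:
#' 19 MZ pairs, 13 DZ pairs and 25 singletons (89 individuals).
#'
#' @param n_mz_pairs,n_dz_pairs,n_unrelated pedigree composition.
#' @param h2_true target narrow-sense heritability in `[0, 1]`.
#' @param covariate_betas named effects `sex` (difference for females) and
#'   `age` (per year, applied to mean-centred age) added to the trait.
#' @param seed RNG seed.
#' @return object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(n_mz_pairs = 19L, n_dz_pairs = 13L,
                          n_unrelated = 25L, h2_true = 0.6,
                          covariate_betas = c(sex = 0.25, age = 0.02),
                          seed = 1L) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_unrelated >= 0,
            h2_true >= 0, h2_true <= 1)
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_unrelated = as.integer(n_unrelated),
                 h2_true = h2_true, covariate_betas = covariate_betas,
                 seed = as.integer(seed)),
            class = "pedigree_spec")
}

#' Simulate a twin pedigree with a heritable quantitative trait
#'
#' The trait follows y = X beta + g + e with cov(g) = 2*Phi*sigma_g^2 and
#' cov(e) = I*sigma_e^2, where sigma_g^2 = `h2_true` and sigma_e^2 =
#' 1 - `h2_true` before covariate effects are added. The genetic component is
#' drawn directly from the block structure of 2*Phi: MZ co-twins share g
#' entirely; DZ co-twins share an N(0, sigma_g^2/2) component and add an
#' independent N(0, sigma_g^2/2) part.
#'
#' @param pspec a [pedigree_spec()].
#' @return list with `pedigree` (FAM-like data.frame: family_id,
#'   individual_id, father_id, mother_id, sex, zygosity in MZ/DZ/NT) and
#'   `data` (individual_id, trait, age, sex).
#' @export
generate_twin_traits <- function(pspec) {
  stopifnot(inherits(pspec, "pedigree_spec"))
  if (pspec$h2_true < 0 || pspec$h2_true > 1) stop("h2 outside [0,1]")
  nfam <- pspec$n_mz_pairs + pspec$n_dz_pairs + pspec$n_unrelated
  n <- 2L * (pspec$n_mz_pairs + pspec$n_dz_pairs) + pspec$n_unrelated
  zyg_fam <- rep(c("MZ", "DZ", "NT"),
                 c(pspec$n_mz_pairs, pspec$n_dz_pairs, pspec$n_unrelated))
  fam_size <- ifelse(zyg_fam == "NT", 1L, 2L)
  family_id <- rep(sprintf("F%03d", seq_len(nfam)), fam_size)
  zygosity <- rep(zyg_fam, fam_size)
  individual_id <- sprintf("I%03d", seq_len(n))

  sg <- sqrt(pspec$h2_true)
  se <- sqrt(1 - pspec$h2_true)
  out <- with_seed(pspec$seed, {
    age_fam <- pmin(pmax(stats::rnorm(nfam, 28.6, 3.9), 22), 36)
    age <- rep(age_fam, fam_size)  # twins share age
    sex <- sample(c("M", "F"), n, replace = TRUE)
    g <- numeric(n)
    pos <- 1L
    for (f in seq_len(nfam)) {
      if (zyg_fam[f] == "MZ") {
        g[pos + 0:1] <- stats::rnorm(1, 0, sg)
        pos <- pos + 2L
      } else if (zyg_fam[f] == "DZ") {
        shared <- stats::rnorm(1, 0, sg / sqrt(2))
        g[pos + 0:1] <- shared + stats::rnorm(2, 0, sg / sqrt(2))
        pos <- pos + 2L
      } else {
        g[pos] <- stats::rnorm(1, 0, sg)
        pos <- pos + 1L
      }
    }
    e <- stats::rnorm(n, 0, se)
    b <- pspec$covariate_betas
    trait <- g + e +
      b[["sex"]] * (sex == "F") + b[["age"]] * (age - mean(age))
    list(age = age, sex = sex, trait = trait)
  })

  pedigree <- data.frame(family_id = family_id,
                         individual_id = individual_id,
                         father_id = "0", mother_id = "0",
                         sex = out$sex, zygosity = zygosity,
                         stringsAsFactors = FALSE)
  data <- data.frame(individual_id = individual_id, trait = out$trait,
                     age = out$age, sex = out$sex, stringsAsFactors = FALSE)
  list(pedigree = pedigree, data = data)
}
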