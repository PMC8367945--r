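# Synthetic cohort generator.
#
# Emulates the data shapes of a targeted cfDNA methylation diagnostic study:
# paired tumour/normal tissue matrices for marker discovery, matched
# tissue/plasma pairs for concordance filtering, a case/control plasma cohort
# with a planted hyper-/hypomethylated marker panel whose plasma signal grows
# with stage, per-read CpG state vectors hitting a target co-methylation
# level, and a binary mammography reading with stated sensitivity and
# specificity. Every generator is a pure function of its configuration and
# seed.

# Default stage mix for cancer samples: whole-cohort stage counts of a
# mid-sized breast-cancer case/control study (stages 0/I/II/III), stage IV
# admitted but absent by default.
default_stage_probs <- c("0" = 11, "I" = 68, "II" = 91, "III" = 32, "IV" = 0)

# Panel naming starts with four markers conventionally reported for breast
# cancer plasma (one hypomethylated, three hypermethylated) so synthetic
# fixtures carry field-realistic identifiers.
named_markers <- list(
  hypo = "cg23035715",
  hyper = c("cg16304215", "cg20072171", "cg21501525")
)

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic cohort. Defaults
#' mirror the cohort structure the package is designed around: 40
#' tumour/normal tissue pairs, 204 cancer and 129 control plasma samples, a
#' 26-marker planted panel among 200 targeted regions, tissue effect size
#' 0.3, plasma noise 0.1, and a mammography reading with 70% sensitivity and
#' 92% specificity (typical screening performance).
#'
#' @param n_markers Number of targeted regions (markers).
#' @param n_informative Number of planted truly differential markers.
#' @param n_pairs Number of matched tumour/normal tissue pairs.
#' @param n_cancer,n_control Plasma cohort sizes.
#' @param delta_hyper,delta_hypo Planted mean methylation shift (in beta
#'   units, 0-1) for hyper-/hypomethylated markers.
#' @param noise_sd Gaussian noise SD around group means (levels clipped to
#'   \[0, 1\]).
#' @param stage_gradient Additive per-stage increment of the plasma shift on
#'   informative markers (stage 0 = no increment), emulating methylation
#'   burden growing with tumour burden.
#' @param frac_hypo Fraction of informative markers hypomethylated in cancer.
#' @param plasma_frac Attenuation of the tissue effect in plasma, modelling
#'   dilution of tumour-derived cfDNA by the normal cfDNA background (plasma
#'   shift = `plasma_frac` times the tissue shift).
#' @param marker_sens Probability that an informative marker emits its shift
#'   in a given cancer patient's plasma (per-patient marker detection rate;
#'   models tumour heterogeneity -- no single marker is altered in every
#'   patient, which is why panels beat single markers).
#' @param mammo_sens,mammo_spec Sensitivity/specificity of the binary
#'   mammography call.
#' @param stage_probs Named nonnegative weights over stages 0, I, II, III, IV
#'   for cancer samples.
#' @param seed Integer seed; all generators derive their randomness from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 200L,
                       n_informative = 26L,
                       n_pairs = 40L,
                       n_cancer = 204L,
                       n_control = 129L,
                       delta_hyper = 0.3,
                       delta_hypo = 0.3,
                       noise_sd = 0.1,
                       stage_gradient = 0.05,
                       frac_hypo = 4 / 26,
                       plasma_frac = 0.7,
                       marker_sens = 0.7,
                       mammo_sens = 0.70,
                       mammo_spec = 0.92,
                       stage_probs = default_stage_probs,
                       seed = 1L) {
  cfg <- list(
    n_markers = as.integer(n_markers), n_informative = as.integer(n_informative),
    n_pairs = as.integer(n_pairs), n_cancer = as.integer(n_cancer),
    n_control = as.integer(n_control), delta_hyper = delta_hyper,
    delta_hypo = delta_hypo, noise_sd = noise_sd,
    stage_gradient = stage_gradient, frac_hypo = frac_hypo,
    plasma_frac = plasma_frac, marker_sens = marker_sens, mammo_sens = mammo_sens,
    mammo_spec = mammo_spec, stage_probs = stage_probs, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_markers < 1L || n_pairs < 1L || n_cancer < 1L || n_control < 1L) {
      stop("cohort dimensions must be positive integers", call. = FALSE)
    }
    if (n_informative < 0L || n_informative > n_markers) {
      stop("`n_informative` must lie in [0, n_markers]", call. = FALSE)
    }
    if (delta_hyper <= 0 || delta_hyper > 1 || delta_hypo <= 0 || delta_hypo > 1) {
      stop("planted deltas must lie in (0, 1]", call. = FALSE)
    }
    if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
    if (stage_gradient < 0) stop("`stage_gradient` must be >= 0", call. = FALSE)
    stop_if_not_prob(frac_hypo, "frac_hypo")
    if (plasma_frac <= 0 || plasma_frac > 1) {
      stop("`plasma_frac` must lie in (0, 1]", call. = FALSE)
    }
    stop_if_not_prob(marker_sens, "marker_sens")
    if (mammo_sens <= 0 || mammo_sens > 1 || mammo_spec <= 0 || mammo_spec > 1) {
      stop("mammography sensitivity/specificity must lie in (0, 1]", call. = FALSE)
    }
  })
  sp <- cfg$stage_probs
  if (is.null(names(sp)) || !all(names(sp) %in% c("0", "I", "II", "III", "IV")) ||
      any(sp < 0) || sum(sp) <= 0) {
    stop("`stage_probs` must be named nonnegative weights over stages 0-IV", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Marker identifiers: the four named panel markers first, then synthetic cg ids.
marker_ids_for <- function(n_markers) {
  fixed <- c(named_markers$hypo, named_markers$hyper)
  if (n_markers <= length(fixed)) {
    return(fixed[seq_len(n_markers)])
  }
  c(fixed, sprintf("cg%08d", seq_len(n_markers - length(fixed))))
}

# Ground truth for the planted panel. Hypomethylated markers come first
# (led by the named hypo marker) so `frac_hypo` of the informative set is
# hypo, the rest hyper.
make_truth <- function(cfg) {
  ids <- marker_ids_for(cfg$n_markers)
  n_inf <- cfg$n_informative
  informative <- ids[seq_len(n_inf)]
  n_hypo <- round(cfg$frac_hypo * n_inf)
  direction <- rep("hyper", n_inf)
  # The named hypo marker takes the first hypo slot; remaining hypo slots are
  # filled from the tail so the named hyper markers stay hypermethylated.
  hypo_slots <- integer(0)
  if (n_hypo > 0L) {
    first <- which(informative == named_markers$hypo)[1]
    if (!is.na(first)) hypo_slots <- first
    extra <- n_hypo - length(hypo_slots)
    if (extra > 0L) {
      pool <- setdiff(rev(seq_len(n_inf)), hypo_slots)
      hypo_slots <- c(hypo_slots, pool[seq_len(min(extra, length(pool)))])
    }
    direction[hypo_slots] <- "hypo"
  }
  delta <- ifelse(direction == "hypo", cfg$delta_hypo, cfg$delta_hyper)
  # Baselines leave headroom for the shift plus noise so clipping stays rare.
  base <- stats::runif(cfg$n_markers, 0.10, 0.90)
  names(base) <- ids
  inf_idx <- match(informative, ids)
  lo <- ifelse(direction == "hypo", 0.10 + delta, 0.10)
  hi <- ifelse(direction == "hypo", 0.90, 0.90 - delta)
  base[inf_idx] <- stats::runif(n_inf, lo, hi)
  list(
    marker_ids = ids,
    informative = data.frame(
      marker_id = informative, direction = direction,
      delta = delta, stringsAsFactors = FALSE
    ),
    base_mean = base
  )
}

# Signed per-marker shift vector (length n_markers) for fully shifted samples.
signed_shift <- function(truth) {
  shift <- stats::setNames(numeric(length(truth$marker_ids)), truth$marker_ids)
  if (nrow(truth$informative)) {
    s <- ifelse(truth$informative$direction == "hyper", 1, -1) * truth$informative$delta
    shift[truth$informative$marker_id] <- s
  }
  shift
}

#' Simulate paired tumour and normal tissue methylation matrices
#'
#' Informative markers are shifted by +delta (hyper) or -delta (hypo) in
#' tumour relative to normal tissue; all levels get Gaussian noise and are
#' clipped to \[0, 1\]. Used to exercise tissue-based marker discovery.
#'
#' @param config A [sim_config()].
#' @return List with `tumour` and `normal` (markers x samples matrices with
#'   shared marker rows) and `truth` (planted-panel ground truth).
#' @export
simulate_tissue_pairs <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    truth <- make_truth(config)
    n <- config$n_pairs
    m <- config$n_markers
    shift <- signed_shift(truth)
    noise <- function() matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
    normal <- clip01(truth$base_mean + noise())
    tumour <- clip01(truth$base_mean + shift + noise())
    dimnames(normal) <- list(truth$marker_ids, sprintf("N%03d", seq_len(n)))
    dimnames(tumour) <- list(truth$marker_ids, sprintf("T%03d", seq_len(n)))
    list(tumour = tumour, normal = normal, truth = truth)
  })
}

#' Simulate plasma cfDNA matched to a tissue matrix
#'
#' Matched-pair plasma is the tissue profile plus measurement noise; an
#' optional set of discordant markers is shifted in plasma only, to exercise
#' the concordance filter.
#'
#' @param tissue Markers x samples tissue matrix.
#' @param noise_sd Gaussian noise SD.
#' @param discordant Character vector of marker ids shifted in plasma only.
#' @param discordant_shift Signed shift applied to discordant markers.
#' @param seed Integer seed.
#' @return Markers x samples plasma matrix; column names get a `P` prefix.
#' @export
simulate_matched_plasma <- function(tissue, noise_sd = 0.05, discordant = character(),
                                    discordant_shift = 0.3, seed = 1L) {
  stopifnot(is.matrix(tissue))
  missing_ids <- setdiff(discordant, rownames(tissue))
  if (length(missing_ids)) {
    stop("discordant markers absent from tissue matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    plasma <- tissue + matrix(stats::rnorm(length(tissue), 0, noise_sd),
                              nrow(tissue), ncol(tissue))
    plasma[discordant, ] <- plasma[discordant, ] + discordant_shift
    plasma <- clip01(plasma)
    colnames(plasma) <- sub("^[TN]", "P", colnames(tissue))
    plasma
  })
}

#' Simulate a case/control plasma cohort with stage structure
#'
#' Cancer samples carry the planted shift on informative markers, attenuated
#' by per-patient marker detection (`marker_sens`) and amplified with stage
#' (`stage_gradient`); controls sit at the marker baselines. A binary
#' mammography call is drawn with the configured sensitivity for cancers and
#' specificity for controls. Tumour size and nodal burden are drawn
#' stage-dependently so clinicopathologic associations are realistic.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_tissue_pairs()]; defaults to the
#'   truth regenerated from `config`.
#' @return List with `levels` (markers x samples matrix) and `clinical`
#'   (data frame keyed by `sample_id` with group, specimen, stage, subtype,
#'   age, er, pr, her2, tumour_size_mm, pos_nodes, grade, mammography_call).
#' @export
simulate_plasma_cohort <- function(config, truth = NULL) {
  config <- validate_sim_config(config)
  if (is.null(truth)) {
    truth <- withr::with_seed(config$seed, make_truth(config))
  }
  bad_stage <- setdiff(names(config$stage_probs), c("0", "I", "II", "III", "IV"))
  if (length(bad_stage)) {
    stop("invalid stage labels: ", paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    m <- config$n_markers
    nc <- config$n_cancer
    nh <- config$n_control
    ids_cancer <- sprintf("BC%03d", seq_len(nc))
    ids_control <- sprintf("HC%03d", seq_len(nh))
    stages <- sample(names(config$stage_probs), nc, replace = TRUE,
                     prob = config$stage_probs / sum(config$stage_probs))
    stage_idx <- match(stages, c("0", "I", "II", "III", "IV")) - 1L

    shift <- signed_shift(truth)             # length m, signed deltas
    inf <- truth$informative$marker_id
    # Per-patient detection budget: each cancer patient displays the planted
    # aberration on a fixed-size random subset of the informative markers
    # (round(marker_sens * n_informative) of them), so the marginal
    # per-marker detection rate is marker_sens while which markers fire
    # varies from patient to patient -- tumours are heterogeneous, and no
    # single marker covers every patient.
    k_detect <- round(config$marker_sens * length(inf))
    detect <- matrix(0L, nrow = length(inf), ncol = nc,
                     dimnames = list(inf, ids_cancer))
    if (length(inf) && k_detect > 0L) {
      for (j in seq_len(nc)) {
        detect[sample(length(inf), k_detect), j] <- 1L
      }
    }
    grad <- config$stage_gradient
    cancer <- matrix(truth$base_mean, m, nc,
                     dimnames = list(truth$marker_ids, ids_cancer))
    if (length(inf)) {
      sgn <- sign(shift[inf])
      mag <- abs(shift[inf]) * config$plasma_frac
      # shift magnitude grows additively with stage
      eff <- (mag + outer(rep(1, length(inf)), grad * stage_idx)) * detect
      cancer[inf, ] <- cancer[inf, ] + sgn * eff
    }
    cancer <- clip01(cancer + matrix(stats::rnorm(m * nc, 0, config$noise_sd), m, nc))
    control <- clip01(matrix(truth$base_mean, m, nh) +
                        matrix(stats::rnorm(m * nh, 0, config$noise_sd), m, nh))
    dimnames(control) <- list(truth$marker_ids, ids_control)

    mammo_cancer <- stats::rbinom(nc, 1L, config$mammo_sens)
    mammo_control <- stats::rbinom(nh, 1L, 1 - config$mammo_spec)

    subtype_levels <- c("LuminalA", "LuminalB_HER2pos", "LuminalB_HER2neg",
                        "HER2", "TNBC", "NA_DCIS")
    subtype <- sample(subtype_levels, nc, replace = TRUE,
                      prob = c(53, 31, 58, 15, 23, 24))
    # tumour size and nodal burden scale with stage (stage is defined by them)
    size <- round(exp(stats::rnorm(nc, log(8 + 12 * stage_idx), 0.35)), 1)
    nodes <- stats::rpois(nc, lambda = c(0, 0.2, 1.5, 6, 9)[stage_idx + 1L])
    clinical <- data.frame(
      sample_id = c(ids_cancer, ids_control),
      group = rep(c("cancer", "control"), c(nc, nh)),
      specimen = "plasma",
      stage = c(stages, rep(NA_character_, nh)),
      subtype = c(subtype, rep(NA_character_, nh)),
      age = round(c(stats::rnorm(nc, 52, 8), stats::rnorm(nh, 49, 6))),
      er = c(sample(c("pos", "neg"), nc, TRUE, c(0.7, 0.3)), rep(NA, nh)),
      pr = c(sample(c("pos", "neg"), nc, TRUE, c(0.6, 0.4)), rep(NA, nh)),
      her2 = c(sample(c("pos", "neg"), nc, TRUE, c(0.3, 0.7)), rep(NA, nh)),
      tumour_size_mm = c(size, rep(NA_real_, nh)),
      pos_nodes = c(nodes, rep(NA_integer_, nh)),
      grade = c(sample(c("1", "2", "3"), nc, TRUE, c(0.2, 0.5, 0.3)), rep(NA, nh)),
      mammography_call = c(mammo_cancer, mammo_control),
      stringsAsFactors = FALSE
    )
    list(levels = cbind(cancer, control), clinical = clinical, truth = truth)
  })
}

#' Simulate per-read CpG methylation states at a target co-methylation level
#'
#' Among eligible reads (>= 3 CpGs), a fraction `target_level` is generated
#' co-methylated by planting a run of three methylated CpGs at a uniform
#' position (remaining sites i.i.d. background); the rest are drawn i.i.d.
#' background and rejection-sampled until they fail the sliding-window rule,
#' so the scored fraction matches `target_level` exactly in expectation.
#'
#' @param target_level Target co-methylated fraction in \[0, 1\].
#' @param n_reads Number of reads to generate.
#' @param n_cpgs Integer range (length-2) of CpG counts per read, within
#'   \[1, 50\].
#' @param p_background Per-site background methylation probability.
#' @param region_id Region identifier stamped on each read.
#' @param seed Integer seed.
#' @return Data frame with `read_id`, `region_id`, `states` (comma-separated
#'   0/1 string ordered by genomic position).
#' @export
simulate_reads <- function(target_level, n_reads, n_cpgs = c(3L, 10L),
                           p_background = 0.15, region_id = "region01",
                           seed = 1L) {
  stop_if_not_prob(target_level, "target_level")
  stop_if_not_prob(p_background, "p_background")
  if (n_reads < 1L) stop("`n_reads` must be positive", call. = FALSE)
  n_cpgs <- as.integer(n_cpgs)
  if (length(n_cpgs) == 1L) n_cpgs <- c(n_cpgs, n_cpgs)
  if (n_cpgs[1] < 1L || n_cpgs[2] > 50L || n_cpgs[1] > n_cpgs[2]) {
    stop("`n_cpgs` must be an increasing range within [1, 50]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    len_range <- seq(n_cpgs[1], n_cpgs[2])
    lens <- len_range[sample.int(length(len_range), n_reads, replace = TRUE)]
    states <- vapply(lens, function(len) {
      if (len >= 3L && stats::runif(1) < target_level) {
        s <- stats::rbinom(len, 1L, p_background)
        start <- sample.int(len - 2L, 1L)
        s[start:(start + 2L)] <- 1L
      } else {
        repeat {
          s <- stats::rbinom(len, 1L, p_background)
          if (len < 3L || classify_read(s) != "co_methylated") break
        }
      }
      paste(s, collapse = ",")
    }, character(1))
    data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      region_id = region_id,
      states = states,
      stringsAsFactors = FALSE
    )
  })
}
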