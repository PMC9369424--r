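#' Configuration for the synthetic CCI behavioral study generator
#'
#' Describes the simulated experiment: a chronic constriction injury (CCI)
#' neuropathic-pain study in mice with intrathecal dosing of two drugs
#' (labelled THC and CBD) alone and as a 1:1 fixed-ratio combination,
#' read out by von Frey mechanical paw withdrawal threshold (PWT), acetone
#' response counts, and the rotarod/bar/open-field side-effect battery.
#'
#' The defaults encode the study conditions the analysis assumes: 6 animals
#' per treatment group; a half-log dose ladder spanning 1-178 nmol; latent
#' Hill-shaped anti-allodynic effects with the potency-table parameters
#' (mechanical PWT: THC Emax 85 / ED50 14 / slope 2.6, CBD 79 / 20 / 1.5;
#' acetone: THC 52 / 21 / 1.7, CBD 27 / 11 / 2.2); zero latent effect in the
#' side-effect assays; testing at 1 and 2 h post-injection; and Gaussian
#' residual noise of SD 10 on the %MPE scale, which yields fit standard
#' errors of the magnitude such behavioral dose-response studies report.
#'
#' @param seed Integer seed; every draw in [simulate_cci_study()] descends
#'   from it.
#' @param n_per_group Animals per treatment group (default 6).
#' @param doses Single-drug dose ladder and combination total-dose ladder
#'   (nmol).
#' @param assays Subset of
#'   `c("mechanical_pwt", "acetone", "rotarod", "bar", "open_field")`.
#' @param truth Per-assay generating Hill parameters, a list
#'   `list(<assay> = list(thc = c(emax, ed50, hill), cbd = ...))` for the
#'   assays with a latent drug effect. Assays not listed get zero effect.
#' @param interaction_shift Multiplicative potency factor for the
#'   combination ray: the latent combination effect at total dose D is the
#'   additive-surface effect at `D / interaction_shift`. 1 = additive truth;
#'   values below 1 make the combination more potent than additive
#'   (synergistic truth).
#' @param noise_sd Residual SD on the %MPE scale, applied per record and
#'   back-transformed to raw units.
#' @param timepoints Post-drug timepoints (h) at which each assay is scored.
#' @param ratio Combination fixed-ratio fractions `c(cbd, thc)` of total
#'   dose.
#' @param groups Which treatment arms to generate.
#' @param vehicle_shift Latent %MPE effect in the vehicle group (0 by
#'   default; non-zero only to probe the vehicle stability check).
#' @param acetone_mode `"round"` keeps the latent Hill structure exact by
#'   rounding the continuous back-transformed count; `"poisson"` draws the
#'   count from a Poisson with that mean, for robustness testing.
#' @param baselines Per-assay baseline means/SDs in raw units, a list of
#'   `c(pre_cci_mean, pre_cci_sd, pre_drug_mean, pre_drug_sd)`; the defaults
#'   give allodynic post-CCI baselines (PWT well below the healthy level,
#'   elevated acetone counts).
#' @return A validated `cci_config` list.
#' @export
cci_config <- function(seed = 1L,
                       n_per_group = 6L,
                       doses = c(1, 3.2, 10, 18, 32, 56, 100, 178),
                       assays = c("mechanical_pwt", "acetone", "rotarod",
                                  "bar", "open_field"),
                       truth = default_truth(),
                       interaction_shift = 1,
                       noise_sd = 10,
                       timepoints = c(1, 2),
                       ratio = c(0.5, 0.5),
                       groups = c("vehicle", "THC", "CBD", "THC:CBD"),
                       vehicle_shift = 0,
                       acetone_mode = c("round", "poisson"),
                       baselines = default_baselines()) {
  acetone_mode <- match.arg(acetone_mode)
  stopifnot(n_per_group >= 2, all(doses > 0), interaction_shift > 0,
            noise_sd >= 0, abs(sum(ratio) - 1) < 1e-9, all(ratio > 0))
  assays <- match.arg(assays, several.ok = TRUE)
  for (a in assays) {
    b <- baselines[[a]]
    if (is.null(b) || any(!is.finite(b)) || b[["pre_drug_mean"]] <= 0) {
      stop("baseline configuration for assay '", a,
           "' is missing or out of range", call. = FALSE)
    }
  }
  if (baselines$mechanical_pwt[["pre_drug_mean"]] >= 6.84) {
    stop("mechanical pre-drug baseline at or above the 6.84 g cut-off",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         doses = doses, assays = assays, truth = truth,
         interaction_shift = interaction_shift, noise_sd = noise_sd,
         timepoints = timepoints, ratio = ratio, groups = groups,
         vehicle_shift = vehicle_shift, acetone_mode = acetone_mode,
         baselines = baselines),
    class = "cci_config"
  )
}

#' @rdname cci_config
#' @export
default_truth <- function() {
  list(
    mechanical_pwt = list(thc = c(emax = 85, ed50 = 14, hill = 2.6),
                          cbd = c(emax = 79, ed50 = 20, hill = 1.5)),
    acetone = list(thc = c(emax = 52, ed50 = 21, hill = 1.7),
                   cbd = c(emax = 27, ed50 = 11, hill = 2.2))
  )
}

#' @rdname cci_config
#' @export
default_baselines <- function() {
  list(
    mechanical_pwt = c(pre_cci_mean = 4.0, pre_cci_sd = 0.5,
                       pre_drug_mean = 0.7, pre_drug_sd = 0.15),
    acetone = c(pre_cci_mean = 1.5, pre_cci_sd = 0.8,
                pre_drug_mean = 8, pre_drug_sd = 1.5),
    rotarod = c(pre_cci_mean = 250, pre_cci_sd = 25,
                pre_drug_mean = 240, pre_drug_sd = 25),
    bar = c(pre_cci_mean = 3, pre_cci_sd = 1.5,
            pre_drug_mean = 3, pre_drug_sd = 1.5),
    open_field = c(pre_cci_mean = 60, pre_cci_sd = 10,
                   pre_drug_mean = 55, pre_drug_sd = 10)
  )
}

ASSAY_BOUNDS <- list(
  mechanical_pwt = c(0.2, 6.84),
  acetone = c(0, Inf),
  rotarod = c(0, 300),
  bar = c(0, 120),
  open_field = c(0, Inf)
)

#' Simulate a per-animal CCI combination-study dataset
#'
#' Generates the behavioral record table of a fixed-ratio combination study
#' with the structure [add_mpe()] and the downstream fitting pipeline
#' expect. For each animal (one treatment arm per animal): a healthy pre-CCI
#' baseline and an allodynic post-CCI pre-drug baseline are drawn per assay;
#' the latent drug effect at the animal's dose is computed from the
#' generating Hill curves (single drugs) or from the dose-equivalence
#' additive surface scaled by `interaction_shift` (combination ray);
#' Gaussian %MPE-scale noise is added per timepoint; and the noisy score is
#' back-transformed through the inverse normalization to raw assay units,
#' clipped to the assay bounds (PWT in \[0.2, 6.84\] g, rotarod <= 300 s,
#' bar <= 120 s), with counts rounded to integers. The whole dataset is a
#' deterministic function of the seed.
#'
#' @param config A [cci_config()].
#' @return A tibble of records with columns `animal_id`, `group`,
#'   `drug_a_dose_nmol` (CBD), `drug_b_dose_nmol` (THC), `assay`,
#'   `timepoint_h`, `pre_drug`, `post_drug`, with the config and the
#'   per-animal pre-CCI baselines attached as attributes `config` and
#'   `pre_cci`.
#' @examples
#' recs <- simulate_cci_study(cci_config(seed = 42, assays = "mechanical_pwt"))
#' dplyr::count(recs, group)
#' @export
simulate_cci_study <- function(config = cci_config()) {
  stopifnot(inherits(config, "cci_config"))
  set.seed(config$seed)

  arms <- list()
  for (g in config$groups) {
    if (g == "vehicle") {
      arms[[length(arms) + 1L]] <- tibble::tibble(group = g, a_dose = 0, b_dose = 0)
    } else if (g == "CBD") {
      arms[[length(arms) + 1L]] <- tibble::tibble(group = g, a_dose = config$doses, b_dose = 0)
    } else if (g == "THC") {
      arms[[length(arms) + 1L]] <- tibble::tibble(group = g, a_dose = 0, b_dose = config$doses)
    } else if (g == "THC:CBD") {
      arms[[length(arms) + 1L]] <- tibble::tibble(
        group = g,
        a_dose = config$ratio[1] * config$doses,
        b_dose = config$ratio[2] * config$doses
      )
    } else {
      stop("unknown treatment group '", g, "'", call. = FALSE)
    }
  }
  arms <- dplyr::bind_rows(arms)
  animals <- arms[rep(seq_len(nrow(arms)), each = config$n_per_group), ]
  animals$animal_id <- sprintf("A%03d", seq_len(nrow(animals)))

  surfaces <- purrr::map(config$truth, function(tr) {
    additive_surface(
      hill_params(tr$cbd[["emax"]], tr$cbd[["ed50"]], tr$cbd[["hill"]],
                  drug = "CBD"),
      hill_params(tr$thc[["emax"]], tr$thc[["ed50"]], tr$thc[["hill"]],
                  drug = "THC"),
      frac = config$ratio
    )
  })

  latent_mpe <- function(assay, group, a_dose, b_dose) {
    if (group == "vehicle") return(rep(config$vehicle_shift, length(group)))
    tr <- config$truth[[assay]]
    if (is.null(tr)) return(0)
    if (group == "CBD") {
      hill_effect(a_dose, tr$cbd[["emax"]], tr$cbd[["ed50"]], tr$cbd[["hill"]])
    } else if (group == "THC") {
      hill_effect(b_dose, tr$thc[["emax"]], tr$thc[["ed50"]], tr$thc[["hill"]])
    } else {
      additive_effect(surfaces[[assay]],
                      a_dose / config$interaction_shift,
                      b_dose / config$interaction_shift)
    }
  }

  grid <- tidyr::expand_grid(animals, assay = config$assays)
  grid <- grid |>
    dplyr::mutate(
      pre_cci = draw_baseline(.data$assay, "pre_cci", config),
      pre_drug = draw_baseline(.data$assay, "pre_drug", config),
      latent = purrr::pmap_dbl(
        list(.data$assay, .data$group, .data$a_dose, .data$b_dose),
        latent_mpe
      )
    )

  recs <- tidyr::expand_grid(grid, timepoint_h = config$timepoints) |>
    dplyr::mutate(
      mpe_noisy = .data$latent +
        stats::rnorm(dplyr::n(), sd = config$noise_sd),
      post_drug = purrr::pmap_dbl(
        list(.data$assay, .data$pre_drug, .data$mpe_noisy),
        function(assay, pre, mpe) back_transform(assay, pre, mpe, config)
      )
    )

  out <- recs |>
    dplyr::transmute(
      animal_id = .data$animal_id,
      group = .data$group,
      drug_a_dose_nmol = .data$a_dose,
      drug_b_dose_nmol = .data$b_dose,
      assay = .data$assay,
      timepoint_h = .data$timepoint_h,
      pre_drug = .data$pre_drug,
      post_drug = .data$post_drug
    )
  attr(out, "config") <- config
  attr(out, "pre_cci") <- dplyr::distinct(
    recs[c("animal_id", "assay", "pre_cci")]
  )
  out
}

draw_baseline <- function(assay, which, config) {
  m <- vapply(assay, function(a) config$baselines[[a]][[paste0(which, "_mean")]],
              numeric(1))
  s <- vapply(assay, function(a) config$baselines[[a]][[paste0(which, "_sd")]],
              numeric(1))
  x <- stats::rnorm(length(assay), m, s)
  lo <- vapply(assay, function(a) ASSAY_BOUNDS[[a]][1], numeric(1))
  hi <- vapply(assay, function(a) ASSAY_BOUNDS[[a]][2], numeric(1))
  x <- pmin(pmax(x, pmax(lo, 0.05)), hi)
  # pre-drug mechanical baseline must leave headroom below the cut-off;
  # count-type baselines must be positive integers
  x <- ifelse(assay == "mechanical_pwt", pmin(x, 6.5), x)
  ifelse(assay %in% c("acetone", "open_field"), pmax(round(x), 1), x)
}

back_transform <- function(assay, pre, mpe, config) {
  if (assay == "open_field") {
    # raw-only assay: noise acts directly on the count
    return(max(round(pre * (1 + mpe / 100) - pre + pre), 0))
  }
  post <- mpe_invert(assay, pre, mpe)
  bounds <- ASSAY_BOUNDS[[assay]]
  post <- min(max(post, bounds[1]), bounds[2])
  if (assay == "acetone") {
    post <- if (config$acetone_mode == "poisson") {
      stats::rpois(1, lambda = post)
    } else {
      round(post)
    }
  }
  post
}

#' Check that the vehicle group shows no drug effect
#'
#' Generator/assay sanity check mirroring the study's vehicle control:
#' post-injection scores should not differ from the pre-injection baseline.
#' Returns `TRUE` when the vehicle-group mean %MPE (across the assays with a
#' %MPE definition) is within sampling noise of zero — specifically within
#' three standard errors of the group mean, with an exact-zero test when the
#' scores are noiseless.
#'
#' @param records A record table containing a vehicle group.
#' @param group Vehicle group label.
#' @return `TRUE`/`FALSE`.
#' @export
vehicle_stability_check <- function(records, group = "vehicle") {
  veh <- records |>
    add_mpe() |>
    dplyr::filter(.data$group == !!group, !is.na(.data$mpe))
  if (nrow(veh) == 0L) stop("no vehicle records found", call. = FALSE)
  m <- mean(veh$mpe)
  sem <- stats::sd(veh$mpe) / sqrt(nrow(veh))
  if (!is.finite(sem) || sem == 0) return(abs(m) < 1e-9)
  abs(m) <= 3 * sem
}
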