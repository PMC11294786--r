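#' Group-level nocturnal vital-sign phenotype
#'
#' Bundles the expected nightly physiology of one study group: the mean
#' heartbeat interval, the target spectral band powers of the tachogram, the
#' respiratory-rate level, and the variability structure around those
#' targets. Band powers are absolute (ms^2) over the conventional HRV bands
#' (ULF < 0.0033 Hz, VLF 0.0033-0.04, LF 0.04-0.15, HF 0.15-0.40).
#'
#' Night-to-night variation is lognormal-multiplicative on band powers
#' (keeping them positive) and additive-Gaussian on the heartbeat-interval
#' and respiratory-rate levels. Between-person variation uses one shared
#' lognormal multiplier across the four bands per person, so the LF/HF
#' ratio is a within-person constant up to nightly noise and stays matched
#' between groups whose targets share the same ratio.
#'
#' @param mean_beat_interval mean heartbeat interval (ms).
#' @param ulf,vlf,lf,hf target band powers (ms^2), all `>= 0`.
#' @param mean_rr mean nocturnal respiratory rate (breaths/min), `> 0`.
#' @param rr_sd within-night minute-to-minute respiratory-rate SD
#'   (breaths/min).
#' @param tachypnea_rate expected minutes per night with RR above
#'   21 breaths/min.
#' @param night_to_night_sd lognormal sigma of the per-night, per-band power
#'   multipliers (log scale).
#' @param person_sd lognormal sigma of the shared between-person band-power
#'   amplitude multiplier (log scale), common to the four bands.
#' @param person_band_sd lognormal sigma of the additional independent
#'   between-person multiplier shared within each band pair
#'   (ULF,VLF) / (LF,HF) (log scale); this keeps a person's slow-to-fast
#'   band balance from being a deterministic group fingerprint while the
#'   LF/HF ratio remains person-invariant.
#' @param hr_night_sd,hr_person_sd additive SD (ms) of the nightly /
#'   between-person shifts on the mean heartbeat interval.
#' @param rr_night_sd,rr_person_sd additive SD (breaths/min) of the nightly /
#'   between-person shifts on the mean respiratory rate.
#' @param tachypnea_person_sd lognormal sigma of the between-person
#'   multiplier on `tachypnea_rate`.
#' @return object of class `feature_phenotype`.
#' @seealso [control_phenotype()], [case_phenotype()], [generate_cohort()]
#' @export
feature_phenotype <- function(mean_beat_interval,
                              ulf, vlf, lf, hf,
                              mean_rr, rr_sd = 1.5,
                              tachypnea_rate = 0,
                              night_to_night_sd = 0.5,
                              person_sd = 0.45,
                              person_band_sd = 0.35,
                              hr_night_sd = 25, hr_person_sd = 60,
                              rr_night_sd = 0.8, rr_person_sd = 1.2,
                              tachypnea_person_sd = 1.5) {
  bands <- c(ulf = ulf, vlf = vlf, lf = lf, hf = hf)
  if (any(bands < 0)) stop("band powers must be non-negative")
  if (mean_beat_interval <= 0) stop("'mean_beat_interval' must be positive")
  if (mean_rr <= 0) stop("'mean_rr' must be positive")
  if (rr_sd < 0 || tachypnea_rate < 0) stop("rates and spreads must be non-negative")
  structure(
    list(
      mean_beat_interval = mean_beat_interval,
      band_powers = bands,
      mean_rr = mean_rr, rr_sd = rr_sd,
      tachypnea_rate = tachypnea_rate,
      night_to_night_sd = night_to_night_sd,
      person_sd = person_sd,
      person_band_sd = person_band_sd,
      hr_night_sd = hr_night_sd, hr_person_sd = hr_person_sd,
      rr_night_sd = rr_night_sd, rr_person_sd = rr_person_sd,
      tachypnea_person_sd = tachypnea_person_sd
    ),
    class = "feature_phenotype"
  )
}

#' Default control-group phenotype
#'
#' Nocturnal levels of a middle-aged adult without airflow limitation:
#' heartbeat interval 920 ms (~65 beats/min), total tachogram power
#' ~3900 ms^2 with LF/HF = 1.5, respiratory rate ~15 breaths/min and
#' essentially no tachypnea.
#'
#' @return a [feature_phenotype()].
#' @export
control_phenotype <- function() {
  feature_phenotype(
    mean_beat_interval = 920,
    ulf = 1000, vlf = 900, lf = 1200, hf = 800,
    mean_rr = 15, rr_sd = 1.5,
    tachypnea_rate = 0.05
  )
}

#' Default case-group (COPD) phenotype
#'
#' Elevated sympatho-vagal drive and respiratory load relative to
#' [control_phenotype()]: all band powers raised (HF 2000 vs 800 ms^2, total
#' ~7850 vs ~3900 ms^2) with the same LF/HF ratio of 1.5, faster heart rate
#' (875 ms interval, ~69 beats/min), higher respiratory rate (17.5 vs
#' 15 breaths/min) and a median of ~3 tachypneic minutes per night with wide
#' between-person spread. The group contrasts follow the direction and
#' rough discriminability of published nocturnal COPD monitoring cohorts:
#' respiration features separate the groups most strongly, HRV band powers
#' moderately, heart rate weakly, and the LF/HF ratio not at all.
#'
#' @return a [feature_phenotype()].
#' @export
case_phenotype <- function() {
  feature_phenotype(
    mean_beat_interval = 875,
    ulf = 1500, vlf = 1350, lf = 3000, hf = 2000,
    mean_rr = 17.5, rr_sd = 1.5,
    tachypnea_rate = 3
  )
}

#' Simulation configuration for a multi-night monitoring cohort
#'
#' @param n_cases,n_controls positive participant counts.
#' @param nights_per_person scheduled nights per participant. A single
#'   number gives every participant that many nights; a length-2 vector
#'   `c(median, sdlog)` draws per-person counts from a lognormal with that
#'   median and log-SD (e.g. `c(56.5, 0.93)` reproduces a median of 56.5
#'   nights with IQR roughly 32-113).
#' @param compliance probability that a scheduled night is actually
#'   recorded.
#' @param case,control [feature_phenotype()] objects for the two groups.
#' @param qc_violation_rates named probabilities that a recorded night is
#'   overridden to violate one QC rule; names
#'   `motion`, `sleep_short`, `sleep_long`, `data_loss`, `zero_vital`.
#' @param exacerbation_rate expected acute-exacerbation episodes per case
#'   participant per 30 scheduled nights.
#' @param timescales aggregation windows (days) evaluated downstream.
#' @param start_date first possible enrollment date.
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 50, n_controls = 50,
                       nights_per_person = 60,
                       compliance = 0.73,
                       case = case_phenotype(),
                       control = control_phenotype(),
                       qc_violation_rates = c(motion = 0.02, sleep_short = 0.03,
                                              sleep_long = 0.02, data_loss = 0.02,
                                              zero_vital = 0.01),
                       exacerbation_rate = 0.15,
                       timescales = c(1, 7, 14, 30),
                       start_date = as.Date("2021-01-01"),
                       seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  assert_prob(compliance, "compliance")
  need <- c("motion", "sleep_short", "sleep_long", "data_loss", "zero_vital")
  if (!all(need %in% names(qc_violation_rates))) {
    stop("'qc_violation_rates' must name: ", paste(need, collapse = ", "))
  }
  assert_prob(unname(qc_violation_rates), "qc_violation_rates")
  if (exacerbation_rate < 0) stop("'exacerbation_rate' must be non-negative")
  if (!inherits(case, "feature_phenotype") || !inherits(control, "feature_phenotype")) {
    stop("'case' and 'control' must be feature_phenotype objects")
  }
  if (!(length(nights_per_person) %in% 1:2) || any(nights_per_person[1] <= 0)) {
    stop("'nights_per_person' must be a positive count or c(median, sdlog)")
  }
  structure(
    list(
      n_cases = n_cases, n_controls = n_controls,
      nights_per_person = nights_per_person,
      compliance = compliance,
      case = case, control = control,
      qc_violation_rates = qc_violation_rates[need],
      exacerbation_rate = exacerbation_rate,
      timescales = sort(unique(as.integer(timescales))),
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}
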