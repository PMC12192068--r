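# Reference scenarios transcribed from the two numerical studies: a
# dominant-strain base (I1(0) = 1000 >> I2(0) = 10) with one-parameter
# variations, and an equal-initial-infection base (both 10,000). The
# total population is held at 1e6 throughout (the S(0) variations imply
# an inert pre-immune pool). Caption irregularities are kept verbatim in
# dedicated entries and noted in `caption_note`.
base1 <- list(I1_0 = 1000, I2_0 = 10,
              tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 6e-4)
base9 <- list(I1_0 = 10000, I2_0 = 10000,
              tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 6e-4)

make_scn <- function(base, name, note = NA_character_, N = 1e6, S0 = NULL, ...) {
  args <- utils::modifyList(base, list(...))
  if (is.null(S0)) S0 <- N - args$I1_0 - args$I2_0
  sc <- siirr_scenario(S0 = S0, I1_0 = args$I1_0, I2_0 = args$I2_0,
                       tau1 = args$tau1, tau2 = args$tau2,
                       rho1 = args$rho1, rho2 = args$rho2,
                       N = if (S0 + args$I1_0 + args$I2_0 <= N) N else NULL,
                       label = name)
  tibble(name = name, scenario = list(sc), caption_note = note)
}

#' Registry of reference scenarios
#'
#' Every reference parameter set under a stable name: `fig1_base`, the
#' `S(0)`, `I1(0)`, `I2(0)`, rate variations of the dominant-strain
#' study, `fig9_base` and the variations of the equal-initial-infection
#' study. The total population is 1e6 in all entries; scenarios that
#' lower `S(0)` keep `N` fixed via an inert recovered pool. Entries with
#' known caption irregularities carry a `caption_note` (e.g. the
#' `I1(0) = 5e6` transcription that exceeds the stated total population,
#' and the relabelled transmission-rate panel set, for which corrected
#' values are registered alongside the verbatim ones).
#'
#' @return A tibble with columns `name`, `scenario` (list of
#'   [siirr_scenario()]), `caption_note`.
#' @examples
#' reg <- siirr_scenarios()
#' reg$name
#' @export
siirr_scenarios <- function() {
  rows <- list(
    make_scn(base1, "fig1_base"),
    # S(0) variation, dominant-strain base
    make_scn(base1, "fig2_S0_10000", S0 = 10000),
    make_scn(base1, "fig2_S0_50000", S0 = 50000),
    make_scn(base1, "fig2_S0_99000", S0 = 99000),
    make_scn(base1, "fig2_S0_500000", S0 = 5e5),
    # I1(0) variation
    make_scn(base1, "fig3_I10_5000", I1_0 = 5000),
    make_scn(base1, "fig3_I10_10000", I1_0 = 10000),
    make_scn(base1, "fig3_I10_5000000", I1_0 = 5e6, S0 = 998990, N = 5e6 + 10 + 998990,
             note = "caption value 5,000,000 exceeds the stated total population 1e6; stored verbatim with N from the initial state"),
    # I2(0) variation
    make_scn(base1, "fig4_I20_100", I2_0 = 100),
    make_scn(base1, "fig4_I20_1000", I2_0 = 1000),
    make_scn(base1, "fig4_I20_5000", I2_0 = 5000),
    # tau1 variation (initial infected inherited from the base; the
    # caption omits them)
    make_scn(base1, "fig5_tau1_0.0005", tau1 = 5e-4,
             note = "caption omits I1(0)/I2(0); inherited from fig1_base"),
    make_scn(base1, "fig5_tau1_0.001", tau1 = 1e-3,
             note = "caption omits I1(0)/I2(0); inherited from fig1_base"),
    make_scn(base1, "fig5_tau1_0.005", tau1 = 5e-3,
             note = "caption omits I1(0)/I2(0); inherited from fig1_base"),
    # tau2 variation; the caption mislabels curves as tau1, prints the
    # value set 0.009/0.0011/0.015/0.002 and lists rho1 = 0.005 (0.0005
    # elsewhere). Minimal correction: 0.0011 read as 0.011, rho1 kept at
    # the base value; one verbatim entry retains the printed rho1.
    make_scn(base1, "fig6_tau2_0.002", tau2 = 0.002,
             note = "corrected reading of an inconsistent caption"),
    make_scn(base1, "fig6_tau2_0.009", tau2 = 0.009,
             note = "corrected reading of an inconsistent caption"),
    make_scn(base1, "fig6_tau2_0.011", tau2 = 0.011,
             note = "corrected reading of an inconsistent caption (printed 0.0011)"),
    make_scn(base1, "fig6_tau2_0.015", tau2 = 0.015,
             note = "corrected reading of an inconsistent caption"),
    make_scn(base1, "fig6_verbatim_rho1_0.005", tau2 = 0.002, rho1 = 0.005,
             note = "verbatim caption values incl. rho1 = 0.005"),
    # rho1 variation
    make_scn(base1, "fig7_rho1_0.0005", rho1 = 5e-4),
    make_scn(base1, "fig7_rho1_0.0025", rho1 = 2.5e-3),
    make_scn(base1, "fig7_rho1_0.005", rho1 = 5e-3),
    make_scn(base1, "fig7_rho1_0.0075", rho1 = 7.5e-3),
    # rho2 variation
    make_scn(base1, "fig8_rho2_0.0006", rho2 = 6e-4),
    make_scn(base1, "fig8_rho2_0.00001", rho2 = 1e-5),
    make_scn(base1, "fig8_rho2_0.000001", rho2 = 1e-6),
    # equal-initial-infection base and variations
    make_scn(base9, "fig9_base"),
    make_scn(base9, "fig10_S0_50000", S0 = 50000),
    make_scn(base9, "fig10_S0_60000", S0 = 60000),
    make_scn(base9, "fig10_S0_100000", S0 = 1e5),
    make_scn(base9, "fig10_S0_250000", S0 = 2.5e5),
    make_scn(base9, "fig11_S0_60000", S0 = 60000),
    make_scn(base9, "fig12_rho1_0.0002", rho1 = 2e-4),
    make_scn(base9, "fig12_rho1_0.001", rho1 = 1e-3),
    make_scn(base9, "fig12_rho1_0.003", rho1 = 3e-3),
    make_scn(base9, "fig12_rho1_0.005", rho1 = 5e-3),
    make_scn(base9, "fig13_rho2_0.00005", rho2 = 5e-5),
    make_scn(base9, "fig13_rho2_0.0001", rho2 = 1e-4),
    make_scn(base9, "fig13_rho2_0.0006", rho2 = 6e-4),
    make_scn(base9, "fig13_rho2_0.0008", rho2 = 8e-4),
    make_scn(base9, "fig14_tau1_0.0001", tau1 = 1e-4),
    make_scn(base9, "fig14_tau1_0.004", tau1 = 4e-3),
    make_scn(base9, "fig14_tau1_0.01", tau1 = 1e-2),
    make_scn(base9, "fig14_tau1_0.03", tau1 = 3e-2),
    make_scn(base9, "fig15_tau2_0.005", tau2 = 5e-3),
    make_scn(base9, "fig15_tau2_0.009", tau2 = 9e-3),
    make_scn(base9, "fig15_tau2_0.01", tau2 = 1e-2),
    make_scn(base9, "fig15_tau2_0.03", tau2 = 3e-2)
  )
  dplyr::bind_rows(rows)
}

#' Look up a registered scenario by name
#'
#' @param name A name from [siirr_scenarios()].
#' @return The [siirr_scenario()].
#' @export
get_scenario <- function(name) {
  reg <- siirr_scenarios()
  i <- match(name, reg$name)
  if (is.na(i)) abort(sprintf("unknown scenario '%s'; see siirr_scenarios()", name))
  reg$scenario[[i]]
}

# Maximal runs of grid intervals on which the two infected classes move
# in strictly opposite directions. Derivative signs come from the exact
# right-hand side evaluated at the grid states (not finite differences).
dominance_windows <- function(traj) {
  p <- trajectory_params(traj)
  dI1 <- p$tau1 * traj$S * traj$I1 / p$N - p$rho1 * traj$I1
  dI2 <- p$tau2 * traj$S * traj$I2 / p$N - p$rho2 * traj$I2
  opp <- (dI1 > 0 & dI2 < 0) | (dI1 < 0 & dI2 > 0)
  rising <- ifelse(dI1 > 0, "I1", "I2")
  # runs over grid intervals: both endpoints opposite-signed, same riser
  n <- nrow(traj)
  iv <- opp[-n] & opp[-1] & rising[-n] == rising[-1]
  if (!any(iv)) {
    return(tibble(start = numeric(), end = numeric(),
                  rising = character(), falling = character()))
  }
  r <- rle(iv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  up <- rising[starts[keep]]
  tibble(
    start = traj$t[starts[keep]],
    end = traj$t[ends[keep] + 1],
    rising = up,
    falling = ifelse(up == "I1", "I2", "I1")
  )
}

#' Detect the named popularity-wave effects on a trajectory
#'
#' Fills a wave-effect report from an integrated trajectory:
#' * per-strain peaks and profile classes ([find_peaks()]); "bell-shaped"
#'   means an interior grid maximum exceeding the initial value;
#' * `peak_order`: which strain peaks first;
#' * `dominance_windows`: maximal time intervals on which one infected
#'   class increases while the other decreases (derivative signs from the
#'   exact right-hand side at the grid states);
#' * `suppression` per strain: monotone decay from `t = 0`;
#' * `single_peak`: exactly one strain bell-shaped;
#' * `forgetting`: both infected classes below `forget_frac` (default 1%)
#'   of their own maxima at the end of the horizon — the finite-horizon
#'   proxy for both tending to zero. `NA` ("undetermined") when either
#'   strain is still growing at the end of the horizon;
#' * `stwltl` (short-term win--long-term loss): which strain peaks
#'   first and higher, and each strain's half-peak decay time (time from
#'   its peak until it first falls to half the peak; `NA` if it never
#'   does within the horizon). The effect is present when the
#'   earlier/higher-peaking strain decays to half peak faster.
#'
#' @param traj A `siirr_trajectory`.
#' @param forget_frac Forgetting threshold as a fraction of each strain's
#'   maximum (default 0.01).
#' @return An object of class `wave_effects`; see also
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @examples
#' traj <- siirr_integrate(get_scenario("fig1_base"))
#' detect_effects(traj)
#' @export
detect_effects <- function(traj, forget_frac = 0.01) {
  peaks <- find_peaks(traj)
  cls <- setNames(peaks$profile_class, peaks$compartment)
  bell <- cls == "bell" &
    peaks$value_peak > c(traj$I1[1], traj$I2[1])
  names(bell) <- peaks$compartment
  truncated <- cls == "monotone_growth_truncated"
  peak_order <- if (bell["I1"] && bell["I2"]) {
    if (peaks$t_peak[peaks$compartment == "I2"] <
        peaks$t_peak[peaks$compartment == "I1"]) "I2" else "I1"
  } else NA_character_
  n <- nrow(traj)
  forgetting <- if (any(truncated)) {
    NA # horizon too short: a strain is still growing
  } else {
    traj$I1[n] <= forget_frac * max(traj$I1) &&
      traj$I2[n] <= forget_frac * max(traj$I2)
  }
  half_decay <- vapply(c("I1", "I2"), function(cp) {
    pk <- peaks[peaks$compartment == cp, ]
    y <- traj[[cp]]
    after <- which(traj$t >= pk$t_peak & y <= pk$value_peak / 2)
    if (length(after) == 0) NA_real_ else traj$t[after[1]] - pk$t_peak
  }, numeric(1))
  higher <- peaks$compartment[which.max(peaks$value_peak)]
  stwltl <- list(
    first_peak = peak_order,
    higher_peak = higher,
    half_decay = half_decay,
    present = !is.na(peak_order) &&
      !any(is.na(half_decay)) &&
      half_decay[[peak_order]] < half_decay[[setdiff(c("I1", "I2"), peak_order)]]
  )
  structure(
    list(
      peaks = peaks,
      peak_order = peak_order,
      dominance_windows = dominance_windows(traj),
      suppression = setNames(cls == "monotone_decay", peaks$compartment),
      single_peak = sum(bell) == 1L,
      forgetting = forgetting,
      stwltl = stwltl,
      t_end = traj$t[n]
    ),
    class = "wave_effects"
  )
}

#' @export
print.wave_effects <- function(x, ...) {
  cat("<wave_effects>\n")
  print(x$peaks)
  cat(sprintf("  peak order: %s first | single peak: %s | forgetting: %s\n",
              x$peak_order %||% "-", x$single_peak, x$forgetting))
  cat(sprintf("  suppression: I1=%s I2=%s | dominance windows: %d\n",
              x$suppression[["I1"]], x$suppression[["I2"]],
              nrow(x$dominance_windows)))
  cat(sprintf("  half-peak decay: I1=%s I2=%s (stwltl: %s)\n",
              format(x$stwltl$half_decay[["I1"]]),
              format(x$stwltl$half_decay[["I2"]]), x$stwltl$present))
  invisible(x)
}

#' @rdname detect_effects
#' @param x A `wave_effects` object.
#' @param ... Unused.
#' @export
tidy.wave_effects <- function(x, ...) {
  dplyr::mutate(
    x$peaks,
    suppression = unname(x$suppression[x$peaks$compartment]),
    half_peak_decay = unname(x$stwltl$half_decay[x$peaks$compartment])
  )
}

#' @rdname detect_effects
#' @export
glance.wave_effects <- function(x, ...) {
  tibble(
    peak_order = x$peak_order %||% NA_character_,
    single_peak = x$single_peak,
    forgetting = x$forgetting,
    stwltl = x$stwltl$present,
    n_dominance_windows = nrow(x$dominance_windows),
    t_end = x$t_end
  )
}

sweep_parameters <- c("S0", "I1_0", "I2_0", "tau1", "tau2", "rho1", "rho2")

set_sweep_value <- function(scenario, parameter, value) {
  p <- scenario$params
  y <- scenario$initial
  args <- list(S0 = y[["S"]], I1_0 = y[["I1"]], I2_0 = y[["I2"]],
               tau1 = p$tau1, tau2 = p$tau2, rho1 = p$rho1, rho2 = p$rho2)
  args[[parameter]] <- value
  # keep the base scenario's total population when the varied value fits
  # under it (an inert recovered pool absorbs the difference); otherwise
  # recompute N from the initial state
  tot <- args$S0 + args$I1_0 + args$I2_0
  N <- if (tot <= p$N) p$N else NULL
  siirr_scenario(S0 = args$S0, I1_0 = args$I1_0, I2_0 = args$I2_0,
                 tau1 = args$tau1, tau2 = args$tau2,
                 rho1 = args$rho1, rho2 = args$rho2,
                 N = N, t_end = scenario$t_end, n_out = scenario$n_out,
                 label = sprintf("%s [%s = %g]", scenario$label, parameter, value))
}

#' One-parameter sweep of a scenario
#'
#' Integrates the base scenario once per value of the varied parameter
#' and reports peaks and wave effects per value. Initial-state sweeps
#' (`S0`, `I1_0`, `I2_0`) keep the base scenario's total population when
#' possible (inert recovered pool); rate sweeps leave the initial state
#' untouched. Inadmissible values (e.g. a negative rate) produce a
#' per-value error entry and the sweep continues.
#'
#' @param scenario Base [siirr_scenario()].
#' @param parameter One of `"S0"`, `"I1_0"`, `"I2_0"`, `"tau1"`,
#'   `"tau2"`, `"rho1"`, `"rho2"`.
#' @param values Numeric values to sweep over.
#' @param keep_trajectories Retain each integrated trajectory in a list
#'   column (default `FALSE`).
#' @param ... Passed to [siirr_integrate()].
#' @return A tibble of class `siirr_sweep`: one row per value with
#'   per-strain peak time/height/profile columns, window count, effect
#'   report (list column), and `error` (NA when the run succeeded).
#' @examples
#' sw <- siirr_sweep(get_scenario("fig1_base"), "I1_0", c(5000, 10000))
#' sw[, c("value", "t_peak_I1", "peak_I1", "peak_I2")]
#' @export
siirr_sweep <- function(scenario, parameter, values,
                        keep_trajectories = FALSE, ...) {
  parameter <- match.arg(parameter, sweep_parameters)
  rows <- purrr::map(values, function(v) {
    res <- tryCatch({
      sc <- set_sweep_value(scenario, parameter, v)
      traj <- siirr_integrate(sc, ...)
      eff <- detect_effects(traj)
      pk <- eff$peaks
      tibble(
        value = v,
        t_peak_I1 = pk$t_peak[pk$compartment == "I1"],
        peak_I1 = pk$value_peak[pk$compartment == "I1"],
        class_I1 = pk$profile_class[pk$compartment == "I1"],
        t_peak_I2 = pk$t_peak[pk$compartment == "I2"],
        peak_I2 = pk$value_peak[pk$compartment == "I2"],
        class_I2 = pk$profile_class[pk$compartment == "I2"],
        n_windows = nrow(eff$dominance_windows),
        report = list(eff),
        trajectory = if (keep_trajectories) list(traj) else list(NULL),
        error = NA_character_
      )
    }, error = function(e) {
      tibble(value = v, t_peak_I1 = NA_real_, peak_I1 = NA_real_,
             class_I1 = NA_character_, t_peak_I2 = NA_real_,
             peak_I2 = NA_real_, class_I2 = NA_character_,
             n_windows = NA_integer_, report = list(NULL),
             trajectory = list(NULL), error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "parameter") <- parameter
  attr(out, "base_scenario") <- scenario
  class(out) <- c("siirr_sweep", class(out))
  out
}
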