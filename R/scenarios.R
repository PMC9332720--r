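# Scenario analyses: single-factor elimination gains, exposure-level sweeps,
# simultaneous multi-factor changes at a given age (with or without the
# lagged model), sequential cumulative gains, and survival-curve
# comparisons.

scenario_row <- function(scenario, sex, age, baseline_le, scenario_le, settings) {
  data.frame(
    scenario = scenario, sex = sex, age = age,
    baseline_le = baseline_le, scenario_le = scenario_le,
    delta = scenario_le - baseline_le,
    model = settings$model, mediation = settings$mediation,
    lag = settings$lag, normalization = settings$normalization
  )
}

profile_le <- function(bundle, profile, age, model, mediation, normalization,
                       rr_floor = 0.05, lag = FALSE) {
  lt <- profile_life_table(bundle, profile, model, mediation, normalization,
                           rr_floor, lag = lag)
  list(le = life_expectancy_at(lt, age), settings = attr(lt, "settings"))
}

# Copy a profile, replacing each change event by a constant at `which` level.
flatten_events <- function(profile, which = c("old_value", "new_value")) {
  which <- match.arg(which)
  entries <- lapply(profile$entries, function(e) {
    if (is_change_event(e)) list(value = e[[which]]) else e
  })
  risk_profile(profile$sex, .entries = entries)
}

change_events <- function(profile) {
  Filter(is_change_event, profile$entries)
}

#' Life-expectancy gain from eliminating one risk factor
#'
#' Compares the population-reference profile against a profile with the
#' chosen factor set to its theoretical minimum risk exposure level (TMREL)
#' and every other factor at the population reference. Uses the total-effect
#' (no-mediation) model and no lag, the convention for single-factor
#' effects. The gain may be negative when the TMREL is not the
#' population-wise best level (protective dose-response segments).
#'
#' @param bundle A [parameter_bundle()].
#' @param sex `"male"` or `"female"`.
#' @param factor_id Risk factor to eliminate.
#' @param at_age Age (grid boundary) at which LE is compared; default 0.
#' @param model,normalization,rr_floor Engine settings, see
#'   [adjusted_death_rates()].
#' @return A one-row data frame with `baseline_le`, `scenario_le`, `delta`
#'   and the settings fingerprint.
#' @export
elimination_gain <- function(bundle, sex, factor_id, at_age = 0,
                             model = "additive",
                             normalization = "rr_at_mean", rr_floor = 0.05) {
  frow <- factor_row(bundle, factor_id)
  if (!sex %in% strsplit(frow$applicable_sexes, "|", fixed = TRUE)[[1]]) {
    stop_lexrisk(sprintf("factor '%s' is not applicable to sex '%s'", factor_id, sex))
  }
  tmrel <- if (frow$kind == "continuous") as.numeric(frow$tmrel) else frow$tmrel
  base <- profile_le(bundle, risk_profile(sex), at_age, model, "off",
                     normalization, rr_floor)
  entries <- stats::setNames(list(list(value = tmrel)), factor_id)
  scen <- profile_le(bundle, risk_profile(sex, .entries = entries), at_age,
                     model, "off", normalization, rr_floor)
  out <- scenario_row(sprintf("eliminate:%s", factor_id), sex, at_age,
                      base$le, scen$le, scen$settings)
  out$factor_id <- factor_id
  out
}

#' Life expectancy across a sweep of exposure levels for one factor
#'
#' Evaluates LE (at `at_age`, all other factors at the population reference,
#' total-effect model, constant lifetime exposure) for each level in turn.
#' Deltas are reported against the first level, by convention the best one.
#'
#' @inheritParams elimination_gain
#' @param levels Vector of exposure levels (numeric for continuous factors,
#'   category ids for categorical ones). The first level is the comparator.
#' @return A data frame with one row per level (`level`, `scenario_le`,
#'   `delta` vs. the first level, settings fingerprint).
#' @export
exposure_sweep <- function(bundle, sex, factor_id, levels, at_age = 0,
                           model = "additive",
                           normalization = "rr_at_mean", rr_floor = 0.05) {
  if (length(levels) < 1) stop_lexrisk("need at least one level")
  les <- vapply(levels, function(v) {
    entries <- stats::setNames(list(list(value = v)), factor_id)
    profile_le(bundle, risk_profile(sex, .entries = entries), at_age,
               model, "off", normalization, rr_floor)$le
  }, numeric(1))
  settings <- list(model = model, mediation = "off", lag = FALSE,
                   normalization = normalization)
  out <- scenario_row(sprintf("sweep:%s=%s", factor_id, levels), sex, at_age,
                      les[1], les, settings)
  out$factor_id <- factor_id
  out$level <- levels
  out
}

#' Simultaneous multi-factor change at one age
#'
#' Conditional LE at the change age with all change events applied, minus
#' conditional LE with every changed factor held at its old level. Uses the
#' mediation-adjusted model by default (the convention when several factors
#' move together).
#'
#' @inheritParams elimination_gain
#' @param profile A [risk_profile()] whose change events all share one
#'   `change_age` (on a grid boundary).
#' @param mediation `"on"` (default), `"off"`, or `"auto"`.
#' @param lag Logical; apply the lagged risk-reversal model.
#' @return A one-row data frame with baseline/scenario conditional LE and
#'   their delta.
#' @export
multi_factor_change <- function(bundle, profile, mediation = "on",
                                lag = FALSE, model = "additive",
                                normalization = "rr_at_mean", rr_floor = 0.05) {
  ev <- change_events(profile)
  ages <- unique(vapply(ev, `[[`, numeric(1), "change_age"))
  if (length(ages) > 1) {
    stop_lexrisk("change events have mixed change ages; use sequential_gains()")
  }
  at_age <- if (length(ages)) ages else 0
  base <- profile_le(bundle, flatten_events(profile, "old_value"), at_age,
                     model, mediation, normalization, rr_floor)
  scen <- profile_le(bundle, profile, at_age, model, mediation,
                     normalization, rr_floor, lag = lag)
  scenario_row(sprintf("multi:%d factors", length(ev)), profile$sex, at_age,
               base$le, scen$le, scen$settings)
}

#' Cumulative gains from sequential single-factor changes
#'
#' Applies the profile's change events one factor at a time in the given
#' order; each step's baseline is the previous step's profile, so the last
#' cumulative delta equals the simultaneous [multi_factor_change()] delta
#' regardless of order (when all events share one change age).
#'
#' @inheritParams multi_factor_change
#' @param order Character vector of factor ids, each with a change event in
#'   `profile`, no duplicates.
#' @return A data frame with one row per step: `factor_id`, conditional
#'   `scenario_le`, `step_delta` and `cumulative_delta`.
#' @export
sequential_gains <- function(bundle, profile, order, mediation = "on",
                             lag = FALSE, model = "additive",
                             normalization = "rr_at_mean", rr_floor = 0.05) {
  if (anyDuplicated(order)) stop_lexrisk("a factor is listed twice")
  ev <- change_events(profile)
  missing <- setdiff(order, names(ev))
  if (length(missing)) {
    stop_lexrisk(sprintf("no change event for factor(s): %s",
                         paste(missing, collapse = ", ")))
  }
  ages <- unique(vapply(ev[order], `[[`, numeric(1), "change_age"))
  if (length(ages) > 1) stop_lexrisk("sequential gains require one shared change age")
  at_age <- ages

  step_profile <- function(applied) {
    entries <- profile$entries
    for (id in names(entries)) {
      e <- entries[[id]]
      if (is_change_event(e) && !(id %in% applied)) {
        entries[[id]] <- list(value = e$old_value)
      }
    }
    risk_profile(profile$sex, .entries = entries)
  }

  le0 <- profile_le(bundle, step_profile(character()), at_age, model,
                    mediation, normalization, rr_floor, lag = lag)$le
  prev <- le0
  rows <- vector("list", length(order))
  for (k in seq_along(order)) {
    res <- profile_le(bundle, step_profile(order[seq_len(k)]), at_age, model,
                      mediation, normalization, rr_floor, lag = lag)
    rows[[k]] <- data.frame(
      step = k, factor_id = order[k], sex = profile$sex, age = at_age,
      baseline_le = le0, scenario_le = res$le,
      step_delta = res$le - prev, cumulative_delta = res$le - le0,
      model = res$settings$model, mediation = res$settings$mediation,
      lag = res$settings$lag, normalization = res$settings$normalization
    )
    prev <- res$le
  }
  do.call(rbind, rows)
}

#' Survival-curve comparison around an exposure change
#'
#' Returns three aligned survival curves for a profile with change events:
#' "never exposed" (new levels held for life), "exposed" (old levels held
#' for life) and "with change" (the change events applied, lagged by
#' default). For a beneficial change the with-change curve lies between the
#' other two at every grid boundary at or after the change age.
#'
#' @inheritParams multi_factor_change
#' @param change_age Optional override applied to every change event;
#'   `NULL` keeps the events' own ages.
#' @param lag Logical; default `TRUE`.
#' @return A data frame with columns `age`, `never_exposed`, `exposed`,
#'   `with_change`.
#' @export
survival_comparison <- function(bundle, profile, change_age = NULL,
                                mediation = "auto", lag = TRUE,
                                model = "additive",
                                normalization = "rr_at_mean", rr_floor = 0.05) {
  if (!is.null(change_age)) {
    entries <- lapply(profile$entries, function(e) {
      if (is_change_event(e)) e$change_age <- change_age
      e
    })
    profile <- risk_profile(profile$sex, .entries = entries)
  }
  curve <- function(p, use_lag = FALSE) {
    survival_curve(profile_life_table(bundle, p, model, mediation,
                                      normalization, rr_floor, lag = use_lag))
  }
  never <- curve(flatten_events(profile, "new_value"))
  exposed <- curve(flatten_events(profile, "old_value"))
  changed <- curve(profile, use_lag = lag)
  data.frame(
    age = never$age,
    never_exposed = never$survival,
    exposed = exposed$survival,
    with_change = changed$survival
  )
}
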