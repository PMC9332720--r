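# Abridged period life table (Chiang-style) and derived quantities:
# life expectancy at grid boundaries, survival curves, and horizon-limited
# cause-group death risks.

#' Build an abridged period life table
#'
#' Sums the cause-specific death rates within each (sex, age group) cell to
#' the all-cause rate `m_x` and applies the standard abridged life-table
#' recursion: `q_x = n * m_x / (1 + (n - a_x) * m_x)` for closed intervals
#' with `a_x = n/2` (except `a_0 = 0.1` years, the usual infant-death
#' convention); the open-ended terminal group has `q = 1` and person-years
#' `L = l / m`. The radix is `l_0 = 1`.
#'
#' @param bundle A [parameter_bundle()] (supplies the age grid and the
#'   disease-to-cause-group map).
#' @param rates A death-rate table (`disease_id`, `sex`, `age_start`,
#'   `rate`), e.g. from [adjusted_death_rates()]; defaults to the bundle's
#'   observed rates.
#' @param sex `"male"` or `"female"`.
#' @return A data frame of class `life_table` with columns `age_start`, `n`,
#'   `m`, `a`, `q`, `l`, `d`, `L`, `T`, `e`, plus attributes `sex`,
#'   `cause_rates` (age group x disease rate matrix) and `cause_groups`
#'   (disease id -> cause group) used for cause attribution.
#' @export
#' @examples
#' b <- generate_toy_fixture()
#' lt <- build_life_table(b, sex = "male")
#' lt$e[1]  # life expectancy at birth
build_life_table <- function(bundle, rates = bundle$death_rates, sex) {
  grid <- bundle$age_grid
  k <- n_groups(grid)
  ids <- bundle$diseases$disease_id
  sub <- rates[rates$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0) stop_lexrisk(sprintf("no rates for sex '%s'", sex))

  cause_rates <- matrix(0, k, length(ids), dimnames = list(NULL, ids))
  gi <- match(sub$age_start, grid$age_start)
  di <- match(sub$disease_id, ids)
  if (anyNA(gi) || anyNA(di)) stop_lexrisk("rates reference unknown age groups or diseases")
  cause_rates[cbind(gi, di)] <- sub$rate

  m <- rowSums(cause_rates)
  if (any(m < 0)) stop_lexrisk("negative all-cause death rate")
  if (m[k] <= 0) stop_lexrisk("terminal-group death rate must be > 0")

  n <- grid$n
  a <- n / 2
  a[1] <- 0.1
  q <- n * m / (1 + (n - a) * m)
  q[k] <- 1
  a[k] <- NA_real_

  l <- numeric(k)
  l[1] <- 1
  for (i in seq_len(k - 1)) l[i + 1] <- l[i] * (1 - q[i])
  d <- l * q
  L <- numeric(k)
  L[seq_len(k - 1)] <- n[seq_len(k - 1)] * (l[-1]) + a[seq_len(k - 1)] * d[seq_len(k - 1)]
  L[k] <- l[k] / m[k]
  T <- rev(cumsum(rev(L)))
  e <- T / l

  out <- data.frame(
    age_start = grid$age_start, n = n, m = m, a = a,
    q = q, l = l, d = d, L = L, T = T, e = e
  )
  cg <- bundle$diseases$cause_group
  names(cg) <- ids
  structure(out,
    sex = sex, cause_rates = cause_rates, cause_groups = cg,
    settings = attr(rates, "settings"),
    class = c("life_table", "data.frame")
  )
}

#' Remaining life expectancy at an exact age
#'
#' Conditional on survival to `age`, which must be an age-grid boundary below
#' the terminal group start (no within-interval interpolation).
#'
#' @param table A [build_life_table()] result.
#' @param age Age in years, on a grid boundary.
#' @return Remaining life expectancy `T_age / l_age` in years.
#' @export
life_expectancy_at <- function(table, age) {
  i <- match_boundary(table, age)
  table$T[i] / table$l[i]
}

match_boundary <- function(table, age) {
  i <- which(abs(table$age_start - age) < 1e-9)
  if (length(i) != 1) {
    stop_lexrisk(sprintf(
      "age %g is not an age-grid boundary (boundaries: %s)",
      age, paste(table$age_start, collapse = ", ")
    ))
  }
  i
}

#' Survival curve at age-grid boundaries
#'
#' @param table A [build_life_table()] result.
#' @return Data frame with columns `age` and `survival` (`l_x`); starts at
#'   `(0, 1)` and is non-increasing.
#' @export
survival_curve <- function(table) {
  data.frame(age = table$age_start, survival = table$l)
}

#' Horizon-limited risk of death from a cause group
#'
#' Probability, conditional on being alive at `start_age`, of dying from any
#' disease in `cause_group` within the next `horizon` years. Each age group's
#' deaths are attributed to the cause group in proportion to its share of the
#' all-cause rate in that group.
#'
#' @param table A [build_life_table()] result.
#' @param cause_group Cause-group token (e.g. `"cvd"`).
#' @param start_age Start age, on a grid boundary.
#' @param horizon Horizon in years; `start_age + horizon` must also be a grid
#'   boundary (a zero horizon returns 0).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' b <- generate_toy_fixture()
#' lt <- build_life_table(b, sex = "male")
#' cause_group_death_risk(lt, "cvd", 60, 10)
cause_group_death_risk <- function(table, cause_group, start_age, horizon) {
  if (horizon < 0) stop_lexrisk("horizon must be >= 0")
  if (horizon == 0) return(0)
  i0 <- match_boundary(table, start_age)
  i1 <- match_boundary(table, start_age + horizon)
  cg <- attr(table, "cause_groups")
  if (!cause_group %in% cg) {
    stop_lexrisk(sprintf("unknown cause group '%s'", cause_group))
  }
  cr <- attr(table, "cause_rates")
  idx <- seq(i0, i1 - 1)
  m_cause <- rowSums(cr[idx, cg == cause_group, drop = FALSE])
  share <- ifelse(table$m[idx] > 0, m_cause / table$m[idx], 0)
  sum(table$d[idx] * share) / table$l[i0]
}

#' Build a profile-specific life table in one call
#'
#' Convenience wrapper: computes the profile-adjusted (possibly age-varying,
#' if the profile has change events) death rates and builds the life table.
#'
#' @inheritParams lagged_adjusted_rates
#' @return A [build_life_table()] result for the profile's sex.
#' @export
profile_life_table <- function(bundle, profile, model = "additive",
                               mediation = "auto",
                               normalization = "rr_at_mean",
                               rr_floor = 0.05, lag = FALSE) {
  rates <- lagged_adjusted_rates(bundle, profile, model, mediation,
                                 normalization, rr_floor, lag = lag)
  build_life_table(bundle, rates, profile$sex)
}

#' Write a life table (or survival curve) to CSV
#'
#' @param table A [build_life_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
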