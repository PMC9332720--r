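# Lagged risk-reversal trajectories: after an exposure change, the excess of
# the normalized relative risk decays exponentially toward the new level with
# a half-life specific to the (factor, disease) pair.

#' Construct a lagged relative-risk trajectory
#'
#' @param r_old,r_new Normalized relative risks before and after the change.
#' @param change_age Age (years) at which exposure changes.
#' @param half_life Half-life `h > 0` in years of the excess-risk decay.
#' @param factor_id,disease_id Optional identifiers carried for reporting.
#' @return An object of class `lagged_rr_trajectory`.
#' @export
lagged_rr_trajectory <- function(r_old, r_new, change_age, half_life,
                                 factor_id = NA_character_,
                                 disease_id = NA_character_) {
  if (!is_number(half_life) || half_life <= 0) {
    stop_lexrisk("half_life must be a positive number")
  }
  if (!is_number(change_age) || change_age < 0) {
    stop_lexrisk("change_age must be >= 0")
  }
  structure(
    list(r_old = r_old, r_new = r_new, change_age = change_age,
         half_life = half_life, factor_id = factor_id, disease_id = disease_id),
    class = "lagged_rr_trajectory"
  )
}

#' Evaluate a lagged relative-risk trajectory at an age
#'
#' `r(age) = r_new + (r_old - r_new) * 2^(-(age - change_age) / h)`: the
#' trajectory starts at `r_old` at the change age, reaches the midpoint
#' `(r_old + r_new) / 2` one half-life later, and converges to `r_new`.
#'
#' @param traj A [lagged_rr_trajectory()].
#' @param age Age in years, `>= change_age` (vectorized).
#' @return Normalized relative risk at `age`.
#' @export
#' @examples
#' tr <- lagged_rr_trajectory(r_old = 2, r_new = 1, change_age = 50, half_life = 5)
#' lagged_rr(tr, 60)  # 1.25
lagged_rr <- function(traj, age) {
  if (any(age < traj$change_age)) {
    stop_lexrisk("trajectory is only defined at ages >= change_age")
  }
  traj$r_new + (traj$r_old - traj$r_new) *
    2^(-(age - traj$change_age) / traj$half_life)
}
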