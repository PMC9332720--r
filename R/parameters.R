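# Parameter-bundle domain types, validation and on-disk layout.
#
# A bundle directory contains:
#   manifest.json    country, year, age-grid breaks, file list, generator seed
#   diseases.csv     disease_id,name,cause_group,is_residual
#   death_rates.csv  disease_id,sex,age_start,rate          (per person-year)
#   risk_factors.csv factor_id,name,kind,units,tmrel,categories,
#                    applicable_sexes,age_min,age_max,support_min,support_max
#   exposures.csv    factor_id,sex,age_start,mean,sd,category,prevalence
#   rr_functions.csv factor_id,disease_id,sex,age_start,form,params_json
#   mediation.csv    factor_id,mediator_id,disease_id,mf     (optional)
#   lags.csv         factor_id,disease_id,half_life_years    (optional)

SEXES <- c("male", "female")

#' Construct an abridged age grid
#'
#' Age groups are half-open intervals `[start, end)` in years; the terminal
#' group is open-ended. The default grid is the standard abridged layout
#' `[0,1), [1,5)`, then 5-year groups up to the open-ended `[95, Inf)`
#' (21 groups).
#'
#' @param breaks Strictly increasing numeric vector of group start ages,
#'   beginning at 0. The last break starts the open-ended terminal group.
#' @return An object of class `age_grid` with elements `age_start`,
#'   `age_end` (terminal `Inf`), `n` (group widths, terminal `NA`) and
#'   `mid` (group midpoints; the terminal midpoint uses a nominal 5-year
#'   width).
#' @export
#' @examples
#' g <- age_grid()
#' length(g$age_start)  # 21
age_grid <- function(breaks = c(0, 1, seq(5, 95, by = 5))) {
  if (!is.numeric(breaks) || length(breaks) < 2L) {
    stop_lexrisk("age grid needs at least two breaks")
  }
  if (breaks[1] != 0) stop_lexrisk("age grid must start at 0")
  if (any(diff(breaks) <= 0)) stop_lexrisk("age grid breaks must be strictly increasing")
  k <- length(breaks)
  n <- c(diff(breaks), NA_real_)
  mid <- breaks + ifelse(is.na(n), 5, n) / 2
  structure(
    list(age_start = breaks, age_end = c(breaks[-1], Inf), n = n, mid = mid),
    class = "age_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf(
    "<age_grid> %d groups: [%s)\n", length(x$age_start),
    paste(x$age_start, collapse = ", ")
  ))
  invisible(x)
}

n_groups <- function(grid) length(grid$age_start)

# Index of the group containing `age` (ages on [0, Inf)).
age_group_index <- function(grid, age) {
  if (age < 0) stop_lexrisk("age must be non-negative")
  findInterval(age, grid$age_start)
}

is_grid_boundary <- function(grid, age) {
  any(abs(grid$age_start - age) < 1e-9)
}

# ---------------------------------------------------------------------------
# Bundle constructor

#' Assemble a parameter bundle from its component tables
#'
#' Low-level constructor used by [load_parameter_bundle()] and the synthetic
#' generator. Performs light normalization (column order, type coercion,
#' parsing of dose-response parameters) but does not validate invariants;
#' call [validate_bundle()] for that.
#'
#' @param age_grid An [age_grid()].
#' @param diseases Data frame with columns `disease_id`, `name`,
#'   `cause_group`, `is_residual`.
#' @param death_rates Data frame with columns `disease_id`, `sex`,
#'   `age_start`, `rate` (deaths per person-year).
#' @param risk_factors Data frame with columns `factor_id`, `name`, `kind`
#'   (`"continuous"` or `"categorical"`), `units`, `tmrel`, `categories`
#'   (`|`-separated, empty for continuous), `applicable_sexes`
#'   (`|`-separated), `age_min`, `age_max`, and for continuous factors
#'   `support_min`, `support_max`.
#' @param exposures Data frame with columns `factor_id`, `sex`, `age_start`,
#'   then `mean` (and optional `sd`) for continuous factors or `category`,
#'   `prevalence` rows for categorical factors.
#' @param rr_functions Data frame with columns `factor_id`, `disease_id`,
#'   `sex`, `age_start`, `form` (`"loglinear"`, `"interval"` or
#'   `"categorical"`), and either a `params` list-column or a `params_json`
#'   character column.
#' @param mediation Optional data frame `factor_id`, `mediator_id`,
#'   `disease_id`, `mf`.
#' @param lags Optional data frame `factor_id`, `disease_id`,
#'   `half_life_years`.
#' @param metadata Named list (country, year, source, seed, ...).
#' @return An object of class `parameter_bundle`.
#' @export
parameter_bundle <- function(age_grid, diseases, death_rates, risk_factors,
                             exposures, rr_functions,
                             mediation = NULL, lags = NULL,
                             metadata = list()) {
  stopifnot(inherits(age_grid, "age_grid"))
  diseases <- as.data.frame(diseases)
  diseases$is_residual <- as.logical(diseases$is_residual)
  death_rates <- as.data.frame(death_rates)
  risk_factors <- as.data.frame(risk_factors)
  if (is.null(risk_factors$support_min)) {
    risk_factors$support_min <- rep(-Inf, nrow(risk_factors))
  }
  if (is.null(risk_factors$support_max)) {
    risk_factors$support_max <- rep(Inf, nrow(risk_factors))
  }
  exposures <- as.data.frame(exposures)
  if (is.null(exposures$sd)) exposures$sd <- rep(NA_real_, nrow(exposures))
  if (is.null(exposures$category)) {
    exposures$category <- rep(NA_character_, nrow(exposures))
  }
  if (is.null(exposures$prevalence)) {
    exposures$prevalence <- rep(NA_real_, nrow(exposures))
  }
  if (is.null(exposures$mean)) exposures$mean <- rep(NA_real_, nrow(exposures))
  rr_functions <- as.data.frame(rr_functions)
  if (is.null(rr_functions[["params"]]) && !is.null(rr_functions[["params_json"]])) {
    rr_functions$params <- lapply(rr_functions[["params_json"]], parse_rr_params)
    rr_functions$params_json <- NULL
  }
  if (is.null(mediation)) {
    mediation <- data.frame(
      factor_id = character(), mediator_id = character(),
      disease_id = character(), mf = numeric()
    )
  }
  if (is.null(lags)) {
    lags <- data.frame(
      factor_id = character(), disease_id = character(),
      half_life_years = numeric()
    )
  }
  structure(
    list(
      age_grid = age_grid, diseases = diseases, death_rates = death_rates,
      risk_factors = risk_factors, exposures = exposures,
      rr_functions = rr_functions, mediation = as.data.frame(mediation),
      lags = as.data.frame(lags), metadata = metadata
    ),
    class = "parameter_bundle"
  )
}

parse_rr_params <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (is.atomic(p)) p <- as.list(p)  # flat objects simplify to named vectors
  if (!is.null(p$knots)) p$knots <- matrix(unlist(p$knots), ncol = 2, byrow = !is.matrix(p$knots))
  if (is.matrix(p$knots) && ncol(p$knots) != 2) p$knots <- t(p$knots)
  if (!is.null(p$rr)) p$rr <- unlist(p$rr)
  p
}

#' @export
print.parameter_bundle <- function(x, ...) {
  meta <- x$metadata
  cat(sprintf(
    "<parameter_bundle> %s %s: %d diseases, %d risk factors, %d RR functions\n",
    meta$country %||% "?", meta$year %||% "?",
    nrow(x$diseases), nrow(x$risk_factors), nrow(x$rr_functions)
  ))
  cat(sprintf(
    "  %d mediation entries, %d lag entries, %d age groups\n",
    nrow(x$mediation), nrow(x$lags), n_groups(x$age_grid)
  ))
  invisible(x)
}

factor_row <- function(bundle, factor_id) {
  i <- match(factor_id, bundle$risk_factors$factor_id)
  if (is.na(i)) stop_lexrisk(sprintf("unknown factor '%s'", factor_id))
  bundle$risk_factors[i, , drop = FALSE]
}

factor_categories <- function(frow) {
  strsplit(frow$categories, "|", fixed = TRUE)[[1]]
}

factor_applicable <- function(frow, sex, age_start, age_end) {
  sexes <- strsplit(frow$applicable_sexes, "|", fixed = TRUE)[[1]]
  sex %in% sexes && age_end > frow$age_min && age_start <= frow$age_max
}

# ---------------------------------------------------------------------------
# Validation

violation <- function(code, location, message) {
  data.frame(code = code, location = location, message = message)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the bundle (complete death-rate
#' coverage, categorical prevalences summing to one, positive finite relative
#' risks, mediation factors in `[0, 1]`, referential integrity, ...) and
#' reports violations instead of raising.
#'
#' @param bundle A [parameter_bundle()].
#' @return A data frame with columns `code`, `location`, `message`; zero rows
#'   when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  v <- list()
  add <- function(code, location, message) {
    v[[length(v) + 1L]] <<- violation(code, location, message)
  }
  grid <- bundle$age_grid
  dis <- bundle$diseases
  fac <- bundle$risk_factors

  if (anyDuplicated(dis$disease_id)) {
    add("DISEASE_DUP", "diseases", "duplicated disease_id")
  }
  if (anyDuplicated(fac$factor_id)) {
    add("FACTOR_DUP", "risk_factors", "duplicated factor_id")
  }

  # death rates: full coverage, non-negative
  dr <- bundle$death_rates
  if (any(dr$rate < 0 | !is.finite(dr$rate))) {
    bad <- which(dr$rate < 0 | !is.finite(dr$rate))[1]
    add("RATE_NEGATIVE", sprintf("death_rates row %d", bad),
        "death rate must be finite and >= 0")
  }
  key <- interaction(dr$disease_id, dr$sex, dr$age_start, drop = FALSE)
  if (anyDuplicated(key)) add("RATE_DUP", "death_rates", "duplicated (disease, sex, age) rate")
  expected <- expand.grid(
    disease_id = dis$disease_id, sex = SEXES, age_start = grid$age_start,
    stringsAsFactors = FALSE
  )
  have <- paste(dr$disease_id, dr$sex, dr$age_start)
  missing <- !(paste(expected$disease_id, expected$sex, expected$age_start) %in% have)
  if (any(missing)) {
    m <- expected[which(missing)[1], ]
    add("RATES_MISSING",
        sprintf("death_rates (%s, %s, %g)", m$disease_id, m$sex, m$age_start),
        "every (disease, sex, age group) cell needs a rate (zeros allowed)")
  }

  # risk factors
  for (i in seq_len(nrow(fac))) {
    f <- fac[i, ]
    loc <- sprintf("risk_factors '%s'", f$factor_id)
    sexes <- strsplit(f$applicable_sexes, "|", fixed = TRUE)[[1]]
    if (length(sexes) == 0 || !all(sexes %in% SEXES)) {
      add("APPLICABILITY", loc, "applicable_sexes must be a non-empty subset of male|female")
    }
    if (f$kind == "continuous") {
      tm <- suppressWarnings(as.numeric(f$tmrel))
      if (!is.finite(tm) || tm < f$support_min || tm > f$support_max) {
        add("TMREL_INVALID", loc, "continuous tmrel must lie in the declared support")
      }
    } else if (f$kind == "categorical") {
      cats <- factor_categories(f)
      if (length(cats) < 1) add("CATEGORIES_EMPTY", loc, "categorical factor needs categories")
      if (!(f$tmrel %in% cats)) add("TMREL_INVALID", loc, "tmrel must be a declared category")
    } else {
      add("KIND_INVALID", loc, sprintf("unknown factor kind '%s'", f$kind))
    }
  }

  # exposures
  ex <- bundle$exposures
  for (i in seq_len(nrow(fac))) {
    f <- fac[i, ]
    sexes <- intersect(strsplit(f$applicable_sexes, "|", fixed = TRUE)[[1]], SEXES)
    rows <- ex[ex$factor_id == f$factor_id, ]
    for (sx in sexes) {
      for (a in grid$age_start) {
        if (grid$age_end[match(a, grid$age_start)] <= f$age_min || a > f$age_max) next
        cell <- rows[rows$sex == sx & rows$age_start == a, ]
        loc <- sprintf("exposures (%s, %s, %g)", f$factor_id, sx, a)
        if (nrow(cell) == 0) {
          add("EXPOSURE_MISSING", loc, "no exposure entry for applicable cell")
        } else if (f$kind == "continuous") {
          if (!is.finite(cell$mean[1]) ||
              cell$mean[1] < f$support_min || cell$mean[1] > f$support_max) {
            add("MEAN_SUPPORT", loc, "continuous mean outside declared support")
          }
        } else {
          cats <- factor_categories(f)
          if (any(cell$prevalence < 0, na.rm = TRUE)) {
            add("PREV_NEGATIVE", loc, "prevalence must be >= 0")
          }
          if (!setequal(cell$category, cats)) {
            add("PREV_CATEGORY", loc, "prevalence rows must cover declared categories exactly")
          } else if (abs(sum(cell$prevalence) - 1) > 1e-9) {
            add("PREV_SUM", loc,
                sprintf("categorical prevalences sum to %.12g, expected 1", sum(cell$prevalence)))
          }
        }
      }
    }
  }

  # rr functions
  rr <- bundle$rr_functions
  for (i in seq_len(nrow(rr))) {
    r <- rr[i, ]
    loc <- sprintf("rr_functions row %d (%s, %s, %s, %g)",
                   i, r$factor_id, r$disease_id, r$sex, r$age_start)
    if (!(r$factor_id %in% fac$factor_id)) add("REF_UNKNOWN", loc, "unknown factor_id")
    if (!(r$disease_id %in% dis$disease_id)) add("REF_UNKNOWN", loc, "unknown disease_id")
    p <- r$params[[1]]
    if (r$form == "loglinear") {
      if (!is_number(p$beta_above %||% 0) || !is_number(p$beta_below %||% 0)) {
        add("PARAMS_INVALID", loc, "loglinear needs finite beta_above/beta_below")
      }
    } else if (r$form == "interval") {
      k <- p$knots
      if (is.null(k) || nrow(k) < 1 || any(!is.finite(k))) {
        add("PARAMS_INVALID", loc, "interval needs finite knots")
      } else {
        if (any(diff(k[, 1]) <= 0)) add("KNOTS_ORDER", loc, "knot exposures must be strictly increasing")
        if (any(k[, 2] <= 0)) add("RR_NONPOSITIVE", loc, "interval rr values must be > 0")
      }
    } else if (r$form == "categorical") {
      j <- match(r$factor_id, fac$factor_id)
      if (!is.na(j)) {
        cats <- factor_categories(fac[j, ])
        if (!all(cats %in% names(p$rr))) {
          add("CAT_RR_MISSING", loc, "every declared category needs an rr")
        }
      }
      if (any(unlist(p$rr) <= 0) || any(!is.finite(unlist(p$rr)))) {
        add("RR_NONPOSITIVE", loc, "categorical rr values must be finite and > 0")
      }
    } else {
      add("FORM_INVALID", loc, sprintf("unknown form '%s'", r$form))
    }
  }

  # mediation
  md <- bundle$mediation
  for (i in seq_len(nrow(md))) {
    m <- md[i, ]
    loc <- sprintf("mediation row %d (%s -> %s, %s)", i, m$factor_id, m$mediator_id, m$disease_id)
    if (!is.finite(m$mf) || m$mf < 0 || m$mf > 1) add("MF_RANGE", loc, "mf must lie in [0, 1]")
    if (m$factor_id == m$mediator_id) add("MF_SELF", loc, "mediator must differ from factor")
    if (!(m$factor_id %in% fac$factor_id) || !(m$mediator_id %in% fac$factor_id) ||
        !(m$disease_id %in% dis$disease_id)) {
      add("REF_UNKNOWN", loc, "mediation references unknown factor/disease")
    }
  }
  if (nrow(md) && anyDuplicated(md[c("factor_id", "mediator_id", "disease_id")])) {
    add("MF_DUP", "mediation", "(factor, mediator, disease) must be unique")
  }

  # lags
  lg <- bundle$lags
  for (i in seq_len(nrow(lg))) {
    l <- lg[i, ]
    loc <- sprintf("lags row %d (%s, %s)", i, l$factor_id, l$disease_id)
    if (!is.finite(l$half_life_years) || l$half_life_years <= 0) {
      add("LAG_NONPOSITIVE", loc, "half_life_years must be finite and > 0")
    }
    if (!(l$factor_id %in% fac$factor_id) || !(l$disease_id %in% dis$disease_id)) {
      add("REF_UNKNOWN", loc, "lag references unknown factor/disease")
    }
  }

  if (length(v)) do.call(rbind, v) else violation(character(), character(), character())[0, ]
}

# ---------------------------------------------------------------------------
# I/O

MANDATORY_FILES <- c(
  "manifest.json", "diseases.csv", "death_rates.csv", "risk_factors.csv",
  "exposures.csv", "rr_functions.csv"
)

read_bundle_csv <- function(dir, file, expected, optional_cols = character()) {
  path <- file.path(dir, file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop_lexrisk(sprintf("%s: missing column(s) %s", file, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(expected, optional_cols))
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s) %s", file, paste(extra, collapse = ", ")),
            call. = FALSE)
    df <- df[c(expected, intersect(optional_cols, names(df)))]
  }
  df
}

#' Load a parameter bundle from disk
#'
#' Reads the bundle directory layout (or a `.zip` archive of one), checks for
#' mandatory files and columns, and validates every structural invariant;
#' a bundle that fails validation is rejected with a message naming the
#' offending cell.
#'
#' @param path Directory (or `.zip` archive) containing the bundle layout.
#' @return A validated [parameter_bundle()]. The optional tables
#'   (`mediation.csv`, `lags.csv`) load as empty when absent.
#' @export
load_parameter_bundle <- function(path) {
  if (is_string(path) && grepl("\\.zip$", path) && file.exists(path)) {
    exdir <- tempfile("bundle")
    utils::unzip(path, exdir = exdir)
    inner <- list.dirs(exdir, recursive = FALSE)
    path <- if (file.exists(file.path(exdir, "manifest.json"))) exdir else inner[1]
  }
  if (!dir.exists(path)) stop_lexrisk(sprintf("bundle path '%s' does not exist", path))
  for (f in MANDATORY_FILES) {
    if (!file.exists(file.path(path, f))) {
      stop_lexrisk(sprintf("bundle is missing mandatory file '%s'", f))
    }
  }
  manifest <- jsonlite::fromJSON(file.path(path, "manifest.json"))
  grid <- age_grid(as.numeric(manifest$age_grid %||% c(0, 1, seq(5, 95, by = 5))))

  diseases <- read_bundle_csv(path, "diseases.csv",
    c("disease_id", "name", "cause_group", "is_residual"))
  death_rates <- read_bundle_csv(path, "death_rates.csv",
    c("disease_id", "sex", "age_start", "rate"))
  risk_factors <- read_bundle_csv(path, "risk_factors.csv",
    c("factor_id", "name", "kind", "units", "tmrel", "categories",
      "applicable_sexes", "age_min", "age_max"),
    optional_cols = c("support_min", "support_max"))
  risk_factors$tmrel <- as.character(risk_factors$tmrel)
  risk_factors$categories <- ifelse(is.na(risk_factors$categories), "",
                                    as.character(risk_factors$categories))
  exposures <- read_bundle_csv(path, "exposures.csv",
    c("factor_id", "sex", "age_start"),
    optional_cols = c("mean", "sd", "category", "prevalence"))
  rr_functions <- read_bundle_csv(path, "rr_functions.csv",
    c("factor_id", "disease_id", "sex", "age_start", "form", "params_json"))

  mediation <- lags <- NULL
  if (file.exists(file.path(path, "mediation.csv"))) {
    mediation <- read_bundle_csv(path, "mediation.csv",
      c("factor_id", "mediator_id", "disease_id", "mf"))
  }
  if (file.exists(file.path(path, "lags.csv"))) {
    lags <- read_bundle_csv(path, "lags.csv",
      c("factor_id", "disease_id", "half_life_years"))
  }

  bundle <- parameter_bundle(
    age_grid = grid, diseases = diseases, death_rates = death_rates,
    risk_factors = risk_factors, exposures = exposures,
    rr_functions = rr_functions, mediation = mediation, lags = lags,
    metadata = manifest[setdiff(names(manifest), c("age_grid", "files"))]
  )
  viol <- validate_bundle(bundle)
  if (nrow(viol)) {
    stop_lexrisk(sprintf(
      "bundle failed validation (%d violation(s)); first: [%s] %s: %s",
      nrow(viol), viol$code[1], viol$location[1], viol$message[1]
    ))
  }
  bundle
}

#' Write a parameter bundle to disk
#'
#' Inverse of [load_parameter_bundle()]: emits the full CSV + manifest
#' layout. Loading the written directory reproduces the bundle (text fields
#' exactly, rates to better than 1e-12 relative).
#'
#' @param bundle A [parameter_bundle()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(bundle$metadata, list(
    age_grid = bundle$age_grid$age_start,
    files = c(MANDATORY_FILES, "mediation.csv", "lags.csv")
  ))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(path, file), row.names = FALSE, quote = TRUE)
  }
  wr(bundle$diseases, "diseases.csv")
  wr(bundle$death_rates, "death_rates.csv")
  wr(bundle$risk_factors, "risk_factors.csv")
  wr(bundle$exposures, "exposures.csv")
  rr <- bundle$rr_functions
  rr$params_json <- vapply(rr$params, function(p) {
    if (!is.null(p$rr)) p$rr <- as.list(p$rr)  # keep category names in JSON
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA))
  }, character(1))
  wr(rr[setdiff(names(rr), "params")], "rr_functions.csv")
  wr(bundle$mediation, "mediation.csv")
  wr(bundle$lags, "lags.csv")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Risk profiles

#' Construct a risk profile
#'
#' A risk profile carries a sex and, per risk factor, either a constant
#' lifetime exposure level or a single change event (`old_value`,
#' `new_value`, `change_age`). Factors not listed stay at the population
#' reference level and contribute a normalized relative risk of exactly 1.
#'
#' @param sex `"male"` or `"female"`.
#' @param ... Named factor entries: a scalar exposure value, or a list with
#'   `old_value`, `new_value`, `change_age`.
#' @param .entries Alternatively, a named list of entries.
#' @return An object of class `risk_profile`.
#' @export
#' @examples
#' risk_profile("male", smoke = "exposed")
#' risk_profile("female",
#'   sbp = list(old_value = 150, new_value = 120, change_age = 50))
risk_profile <- function(sex, ..., .entries = NULL) {
  if (!sex %in% SEXES) stop_lexrisk("sex must be 'male' or 'female'")
  entries <- .entries %||% list(...)
  entries <- lapply(entries, function(e) {
    if (is.list(e) && "value" %in% names(e)) {
      e["value"]
    } else if (is.list(e)) {
      need <- c("old_value", "new_value", "change_age")
      if (!all(need %in% names(e))) {
        stop_lexrisk("a change event needs old_value, new_value and change_age")
      }
      if (!is_number(e$change_age) || e$change_age < 0) {
        stop_lexrisk("change_age must be a non-negative number")
      }
      e[need]
    } else {
      list(value = e)
    }
  })
  structure(list(sex = sex, entries = entries), class = "risk_profile")
}

is_change_event <- function(entry) !is.null(entry$change_age)

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("<risk_profile> sex=%s, %d explicit factor(s)\n", x$sex, length(x$entries)))
  for (id in names(x$entries)) {
    e <- x$entries[[id]]
    if (is_change_event(e)) {
      cat(sprintf("  %s: %s -> %s at age %g\n", id, e$old_value, e$new_value, e$change_age))
    } else {
      cat(sprintf("  %s: %s\n", id, e$value))
    }
  }
  invisible(x)
}

check_exposure_value <- function(frow, value, what = "value") {
  if (frow$kind == "continuous") {
    if (!is_number(value)) {
      stop_lexrisk(sprintf("factor '%s': %s must be numeric", frow$factor_id, what))
    }
    if (value < frow$support_min || value > frow$support_max) {
      stop_lexrisk(sprintf(
        "factor '%s': %s %g outside declared support [%g, %g]",
        frow$factor_id, what, value, frow$support_min, frow$support_max
      ))
    }
  } else {
    if (!value %in% factor_categories(frow)) {
      stop_lexrisk(sprintf(
        "factor '%s': %s '%s' is not a declared category", frow$factor_id, what, value
      ))
    }
  }
  invisible(TRUE)
}

#' Resolve a risk profile against a bundle
#'
#' Checks that every explicit factor exists in the bundle and every exposure
#' value is valid for the factor's kind and support.
#'
#' @param profile A [risk_profile()].
#' @param bundle A [parameter_bundle()].
#' @return `profile`, invisibly, on success; otherwise an error naming the
#'   offending factor.
#' @export
resolve_profile <- function(profile, bundle) {
  stopifnot(inherits(profile, "risk_profile"), inherits(bundle, "parameter_bundle"))
  for (id in names(profile$entries)) {
    frow <- factor_row(bundle, id)  # errors on unknown factor
    e <- profile$entries[[id]]
    if (is_change_event(e)) {
      check_exposure_value(frow, e$old_value, "old_value")
      check_exposure_value(frow, e$new_value, "new_value")
    } else {
      check_exposure_value(frow, e$value)
    }
  }
  invisible(profile)
}

#' Load a risk profile from a JSON file
#'
#' The JSON object holds `"sex"` plus one key per explicit factor, mapping to
#' either a constant exposure value or an object
#' `{"old_value": ..., "new_value": ..., "change_age": ...}`.
#'
#' @param path JSON file.
#' @param bundle A [parameter_bundle()] the profile is resolved against.
#' @return A validated [risk_profile()].
#' @export
load_risk_profile <- function(path, bundle) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$sex)) stop_lexrisk("profile JSON must contain 'sex'")
  entries <- obj[setdiff(names(obj), "sex")]
  entries <- lapply(entries, function(e) if (is.list(e)) e else unname(e))
  profile <- risk_profile(obj$sex, .entries = entries)
  resolve_profile(profile, bundle)
  profile
}

#' Write a risk profile to a JSON file
#'
#' @param profile A [risk_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_risk_profile <- function(profile, path) {
  obj <- c(list(sex = profile$sex), lapply(profile$entries, function(e) {
    if (is_change_event(e)) e else e$value
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
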