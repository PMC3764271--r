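#' The six acute event categories
#'
#' Admission categories tracked by the cost-offset model: heart attacks,
#' strokes, heart failure, acute hypoglycaemic attacks, renal failure and
#' coronary bypass surgery.
#'
#' @return Character vector of the six category names.
#' @export
event_categories <- function() {
  c("heart_attack", "stroke", "heart_failure",
    "acute_hypoglycaemic_attack", "renal_failure", "coronary_bypass")
}

# Half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic 31-bit substream seed from a master seed and a stratum key.
# Iterative polynomial string hash keeps every intermediate below 2^53, so the
# result is exact in double arithmetic on any platform.
stratum_seed <- function(master, age_lo, age_hi, sex) {
  key <- sprintf("%d:%d:%s", as.integer(age_lo), as.integer(age_hi), sex)
  h <- as.double(master) %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Validate a named numeric vector covering all six event categories.
validate_category_table <- function(x, what, lower = 0, upper = Inf) {
  if (!is.numeric(x) || is.null(names(x))) {
    abort(sprintf("%s must be a named numeric vector.", what))
  }
  missing <- setdiff(event_categories(), names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing categories: %s.", what,
                  paste(missing, collapse = ", ")))
  }
  x <- x[event_categories()]
  if (any(!is.finite(x)) || any(x < lower) || any(x > upper)) {
    abort(sprintf("%s values must be finite and in [%s, %s].",
                  what, format(lower), format(upper)))
  }
  x
}

profile_bounds <- function() {
  list(sbp = c(70, 250), tc = c(1, 15), hdl = c(0.3, 5), bmi = c(12, 60),
       smoking = c(0, 1), diabetes = c(0, 1), treated_htn = c(0, 1))
}

profile_fields <- function() names(profile_bounds())

# Check profile columns of a strata data frame against the invariant ranges.
# Returns character(0) when clean, otherwise messages naming stratum and field.
profile_violations <- function(strata) {
  bounds <- profile_bounds()
  msgs <- character(0)
  for (field in names(bounds)) {
    v <- strata[[field]]
    bad <- which(!is.finite(v) | v < bounds[[field]][1] | v > bounds[[field]][2])
    for (i in bad) {
      msgs <- c(msgs, sprintf(
        "stratum [%d,%d) %s: %s = %s outside [%s, %s]",
        strata$age_lo[i], strata$age_hi[i], strata$sex[i], field,
        format(v[i]), format(bounds[[field]][1]), format(bounds[[field]][2])))
    }
  }
  msgs
}
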