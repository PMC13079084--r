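#' Libby mean life of radiocarbon (years)
#'
#' Conventional radiocarbon ages are defined as `-8033 * log(F14C)`, where
#' 8033 yr is the Libby mean life (half-life 5568 yr divided by log 2). The
#' constant is fixed by the reporting convention and is deliberately not a
#' tunable parameter; it is exported so that downstream code can audit the
#' arithmetic.
#'
#' @format A length-one numeric.
#' @export
LIBBY_MEAN_LIFE <- 8033

#' Fraction modern (F14C) measurement
#'
#' Constructs a fraction-modern radiocarbon value, optionally with a
#' 1-standard-deviation uncertainty. F14C is normalized so that 1.0 equals
#' the 1950 atmospheric standard; values below 1 indicate radioactive decay
#' (age), values above 1 indicate post-bomb carbon.
#'
#' @param value Fraction modern, dimensionless, must be > 0.
#' @param sigma Optional 1-s.d. uncertainty (dimensionless, >= 0).
#' @return An object of class `fm` with elements `value` and `sigma`.
#' @examples
#' fm(0.76, 0.02)
#' @export
fm <- function(value, sigma = NULL) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value <= 0) {
    stop("F14C must be strictly positive, got ", value, call. = FALSE)
  }
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
    if (sigma < 0) stop("F14C sigma must be >= 0", call. = FALSE)
  }
  structure(list(value = value, sigma = sigma), class = "fm")
}

#' @export
print.fm <- function(x, ...) {
  if (is.null(x$sigma)) {
    cat(sprintf("F14C = %.4f\n", x$value))
  } else {
    cat(sprintf("F14C = %.4f +/- %.4f\n", x$value, x$sigma))
  }
  invisible(x)
}

#' Convert fraction modern to conventional radiocarbon age
#'
#' Applies the reporting convention `age = -LIBBY_MEAN_LIFE * log(F)`,
#' in conventional 14C years BP. When the input carries an uncertainty, the
#' 1-s.d. age offsets are propagated through the log transform exactly:
#' `err_plus = age(F - sigma) - age(F)` and
#' `err_minus = age(F) - age(F + sigma)`. Because the transform is convex,
#' a symmetric F14C uncertainty yields an asymmetric age interval with
#' `err_plus >= err_minus`.
#'
#' F14C values above 1 (post-bomb carbon) are allowed and yield negative
#' conventional ages; the result is returned as-is and flagged via the
#' `post_bomb` field.
#'
#' @param x An [fm()] object, or a bare positive numeric F14C value.
#' @param round Logical; round the age and error offsets to the nearest
#'   year (the conventional presentation). Set `FALSE` to retain full
#'   precision, e.g. for round-trip arithmetic.
#' @return An object of class `rc_age` with fields `age`, `err_plus`,
#'   `err_minus` (the latter two `NA` when no sigma was supplied) and
#'   `post_bomb`.
#' @examples
#' fm_to_age(fm(0.76, 0.02))   # 2204 (+214/-209) 14C yr BP
#' fm_to_age(0.5)$age          # 5568, the Libby half-life
#' @export
fm_to_age <- function(x, round = TRUE) {
  if (is.numeric(x)) x <- fm(x)
  stopifnot(inherits(x, "fm"))
  age <- -LIBBY_MEAN_LIFE * log(x$value)
  err_plus <- err_minus <- NA_real_
  if (!is.null(x$sigma)) {
    if (x$value - x$sigma <= 0) {
      stop("F14C - sigma <= 0: uncertainty spans non-physical fraction modern",
           call. = FALSE)
    }
    err_plus <- -LIBBY_MEAN_LIFE * log(x$value - x$sigma) - age
    err_minus <- age + LIBBY_MEAN_LIFE * log(x$value + x$sigma)
  }
  if (round) {
    age <- round(age)
    err_plus <- round(err_plus)
    err_minus <- round(err_minus)
  }
  if (x$value > 1 && isTRUE(getOption("peatmix.verbose", FALSE))) {
    message("F14C = ", x$value, " > 1: modern, post-bomb (negative age)")
  }
  structure(
    list(age = age, err_plus = err_plus, err_minus = err_minus,
         post_bomb = x$value > 1),
    class = "rc_age"
  )
}

#' @export
print.rc_age <- function(x, ...) {
  if (is.na(x$err_plus)) {
    cat(sprintf("%s 14C yr BP%s\n", format(x$age),
                if (x$post_bomb) " [modern, post-bomb]" else ""))
  } else {
    cat(sprintf("%s (+%s/-%s) 14C yr BP%s\n", format(x$age),
                format(x$err_plus), format(x$err_minus),
                if (x$post_bomb) " [modern, post-bomb]" else ""))
  }
  invisible(x)
}

#' Convert conventional radiocarbon age to fraction modern
#'
#' Inverse of [fm_to_age()]: `F = exp(-age / LIBBY_MEAN_LIFE)`. Round-trips
#' with the unrounded forward conversion to better than 1e-9 relative.
#'
#' @param age Conventional 14C years BP (finite numeric; negative ages,
#'   i.e. post-bomb, are accepted).
#' @return A numeric fraction modern.
#' @examples
#' age_to_fm(5568)  # 0.5
#' @export
age_to_fm <- function(age) {
  stopifnot(is.numeric(age), all(is.finite(age)))
  exp(-age / LIBBY_MEAN_LIFE)
}
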