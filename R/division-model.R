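#' Timer model of nuclear division
#'
#' The nuclear division cycle of a coenocyte is modelled as a timer: each
#' nuclear doubling interval is an independent draw from a normal
#' distribution with mean `mean_doubling_time` and standard deviation
#' `cv * mean_doubling_time`. Intervals are i.i.d. within and across cells;
#' non-positive draws are redrawn (astronomically rare at the CVs of
#' interest, and unbiased in practice).
#'
#' @param mean_doubling_time Mean nuclear doubling time, in hours (> 0).
#'   Default 11 h.
#' @param cv Dimensionless cell-to-cell coefficient of variation of the
#'   division interval (>= 0). Default 0.10.
#'
#' @return An object of class `division_model`.
#' @examples
#' division_model(11, 0.10)
#' @export
division_model <- function(mean_doubling_time = 11, cv = 0.10) {
  if (!is.numeric(mean_doubling_time) || length(mean_doubling_time) != 1 ||
      !is.finite(mean_doubling_time) || mean_doubling_time <= 0) {
    abort("`mean_doubling_time` must be a single positive number (hours).",
          class = "coenocycle_invalid_input")
  }
  if (!is.numeric(cv) || length(cv) != 1 || !is.finite(cv) || cv < 0) {
    abort("`cv` must be a single non-negative number.",
          class = "coenocycle_invalid_input")
  }
  structure(
    list(mean_doubling_time = as.double(mean_doubling_time),
         cv = as.double(cv)),
    class = "division_model"
  )
}

#' @export
print.division_model <- function(x, ...) {
  cat("<division_model> timer: mean", x$mean_doubling_time, "h, CV", x$cv,
      "(sd", format(x$cv * x$mean_doubling_time, digits = 4), "h)\n")
  invisible(x)
}

#' Initial ploidy distribution of a synchronized population
#'
#' A starvation-synchronized starting population consists of small cells
#' with low DNA content (1C, 2C or 4C). This object holds the fraction of
#' cells in each starting ploidy bin; all ploidies must be exact powers of
#' two and the fractions must sum to one.
#'
#' @param fractions Named numeric vector mapping ploidy (in C units, powers
#'   of two) to the fraction of cells, e.g. `c("1" = 0.25, "2" = 0.5,
#'   "4" = 0.25)` (the default).
#'
#' @return An object of class `initial_ploidy_distribution`: a tibble with
#'   columns `ploidy_c` and `fraction`.
#' @examples
#' initial_ploidy_distribution()
#' initial_ploidy_distribution(c("2" = 1))
#' @export
initial_ploidy_distribution <- function(fractions = c("1" = 0.25,
                                                      "2" = 0.50,
                                                      "4" = 0.25)) {
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    abort("`fractions` must be named by ploidy (C units).",
          class = "coenocycle_invalid_input")
  }
  ploidy <- as.double(names(fractions))
  if (any(!is_power_of_two(ploidy)) || any(ploidy < 1)) {
    abort("All initial ploidies must be powers of two >= 1.",
          class = "coenocycle_invalid_input")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("Initial fractions must be non-negative and sum to 1.",
          class = "coenocycle_invalid_input")
  }
  out <- tibble(ploidy_c = ploidy, fraction = as.double(fractions)) |>
    arrange(.data$ploidy_c)
  class(out) <- c("initial_ploidy_distribution", class(out))
  out
}

as_initial_distribution <- function(init) {
  if (inherits(init, "initial_ploidy_distribution")) return(init)
  initial_ploidy_distribution(init)
}
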