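#' Read an all-cause life table
#'
#' Expects a delimited text file with two columns, `age` (integer years) and
#' `q` (annual all-cause death probability), e.g. a national female life
#' table. Ages must be contiguous; the last row is treated as open-ended
#' (its `q` applies to all older ages).
#'
#' @param path Path to a CSV file with columns `age` and `q`.
#' @return A `data.frame` with columns `age` and `q`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (is.null(lt) || nrow(lt) == 0L) {
    stop("life table is empty", call. = FALSE)
  }
  if (!all(c("age", "q") %in% names(lt))) {
    stop("life table must have columns 'age' and 'q'", call. = FALSE)
  }
  lt <- lt[order(lt$age), c("age", "q")]
  if (any(diff(lt$age) != 1L)) {
    stop("life table ages must be contiguous", call. = FALSE)
  }
  if (any(lt$q < 0 | lt$q > 1)) {
    stop("life table q values must lie in [0, 1]", call. = FALSE)
  }
  lt
}

#' Background mortality at the attained age of a model cycle
#'
#' During cycle `t` the cohort is aged `start_age + t - 1`; the annual
#' all-cause death probability at that attained age is looked up in the life
#' table. Ages beyond the end of the table are clamped to the last row so a
#' finite lifetime horizon is guaranteed; ages below the table's first row
#' are clamped likewise.
#'
#' @param life_table A data frame from [read_life_table()] or
#'   [synthetic_life_table()].
#' @param start_age Cohort age (years) at model start.
#' @param cycle_index Model cycle, 1-based.
#' @return Annual all-cause death probability at the attained age.
#' @export
background_mortality <- function(life_table, start_age, cycle_index) {
  life_table <- validate_life_table(life_table)
  stopifnot(cycle_index >= 1)
  age <- start_age + cycle_index - 1
  idx <- pmin(pmax(age - life_table$age[1L] + 1, 1L), nrow(life_table))
  life_table$q[idx]
}

#' Synthetic female all-cause life table
#'
#' Builds a Gompertz-shaped life table, \eqn{q(a) = \min(q_{\max},
#' q_0 e^{b (a - a_0)})}, calibrated loosely to Western-European female
#' mortality: about 0.0025/year at age 55, doubling every 8 years. It stands
#' in for a national life table in examples and tests; analyses of real
#' decisions should supply the official table via [read_life_table()].
#'
#' @param ages Integer vector of contiguous ages (default 0 to 109).
#' @param q55 Annual death probability at age 55.
#' @param doubling_time Years over which mortality doubles.
#' @param q_floor Death probability at young ages (flat below age 30).
#' @param q_max Cap on the annual death probability.
#' @return A `data.frame` with columns `age` and `q`.
#' @export
synthetic_life_table <- function(ages = 0:109, q55 = 0.0025,
                                 doubling_time = 8, q_floor = 5e-4,
                                 q_max = 0.6) {
  b <- log(2) / doubling_time
  q <- pmin(q_max, pmax(q_floor, q55 * exp(b * (ages - 55))))
  data.frame(age = as.integer(ages), q = q)
}
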