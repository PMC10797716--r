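#' Generate a synthetic adult life table (Makeham hazard)
#'
#' Produces an age-indexed table of annual all-cause death probabilities from
#' a Gompertz–Makeham hazard, `qx(age) = 1 - exp(-(a + b*exp(c*age)))`,
#' clipped to `[0, 1]`, with the terminal age forced to `qx = 1` so cohort
#' lifetimes are finite. This synthetic table stands in for national
#' period life tables (which are external data); it is deterministic and
#' labelled synthetic throughout.
#'
#' @param a Age-independent (background) hazard component, per year.
#' @param b Level of the age-dependent hazard component, per year.
#' @param c Exponential aging rate, per year of age.
#' @param ages Integer vector of contiguous ages covered by the table.
#' @param sex Label for the `sex` column: `"combined"`, `"female"` or
#'   `"male"`.
#' @return A `life_table` data frame with columns `age`, `sex`, `qx`.
#' @examples
#' lt <- synthetic_life_table()
#' lt$qx[lt$age == 40]
#' @export
synthetic_life_table <- function(a = 5e-4, b = 3e-5, c = 0.09,
                                 ages = 0:100,
                                 sex = c("combined", "female", "male")) {
  sex <- match.arg(sex)
  stopifnot(a >= 0, b >= 0, length(ages) >= 2L,
            all(diff(ages) == 1L))
  hazard <- a + b * exp(c * ages)
  qx <- 1 - exp(-hazard)
  if (any(qx[-length(qx)] >= 1)) {
    warning("Makeham parameters drive qx to 1 before the terminal age; ",
            "values clipped", call. = FALSE)
  }
  qx <- pmin(pmax(qx, 0), 1)
  qx[length(qx)] <- 1  # terminal closure
  structure(data.frame(age = as.integer(ages), sex = sex, qx = qx,
                       stringsAsFactors = FALSE),
            class = c("life_table", "data.frame"))
}

validate_life_table <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "sex", "qx") %in% names(lt)))
  for (s in unique(lt$sex)) {
    sub <- lt[lt$sex == s, ]
    sub <- sub[order(sub$age), ]
    if (!all(diff(sub$age) == 1L))
      stop("life table ages must be contiguous (sex '", s, "')", call. = FALSE)
    if (any(sub$qx < 0 | sub$qx > 1))
      stop("life table qx must lie in [0, 1]", call. = FALSE)
    if (sub$qx[nrow(sub)] != 1)
      stop("life table must close with qx = 1 at the terminal age (sex '",
           s, "')", call. = FALSE)
  }
  invisible(lt)
}

#' Read / write a life table as CSV
#'
#' Plain CSV with header `age,sex,qx`. Reading validates the table
#' invariants (contiguous ages per sex, `qx` in `[0, 1]`, terminal `qx = 1`).
#'
#' @param path File path.
#' @return `read_life_table` returns a validated `life_table`;
#'   `write_life_table` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
  structure(lt, class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param lt A `life_table`.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(lt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Blend sex-specific life-table columns into one qx stream
#'
#' The cohort engine consumes a single mortality stream; a two-sex cohort is
#' represented by mixing female and male annual death probabilities at each
#' age with the cohort's female proportion. (The mix is applied to `qx`
#' directly — the standard cohort simplification; the sex composition of
#' survivors is not tracked.)
#'
#' @param lt A `life_table` containing rows for both `"female"` and
#'   `"male"`.
#' @param prop_female Proportion of the cohort that is female, in `[0, 1]`.
#' @return A combined-sex `life_table`.
#' @export
blend_life_table <- function(lt, prop_female) {
  stopifnot(prop_female >= 0, prop_female <= 1)
  f <- lt[lt$sex == "female", ]
  m <- lt[lt$sex == "male", ]
  if (nrow(f) == 0L || nrow(m) == 0L)
    stop("blend_life_table needs both female and male rows", call. = FALSE)
  f <- f[order(f$age), ]; m <- m[order(m$age), ]
  if (!identical(f$age, m$age))
    stop("female and male tables must cover the same ages", call. = FALSE)
  out <- data.frame(age = f$age, sex = "combined",
                    qx = prop_female * f$qx + (1 - prop_female) * m$qx,
                    stringsAsFactors = FALSE)
  out$qx[nrow(out)] <- 1
  structure(out, class = c("life_table", "data.frame"))
}

# single combined-sex qx stream used by the engine
qx_stream <- function(life_table, prop_female = 0.5) {
  sexes <- unique(life_table$sex)
  if ("combined" %in% sexes) {
    lt <- life_table[life_table$sex == "combined", ]
  } else if (all(c("female", "male") %in% sexes)) {
    lt <- blend_life_table(life_table, prop_female)
  } else {
    lt <- life_table[life_table$sex == sexes[1], ]
  }
  lt <- lt[order(lt$age), ]
  list(min_age = lt$age[1], max_age = lt$age[nrow(lt)], qx = lt$qx)
}

qx_at_age <- function(stream, age) {
  idx <- pmin(pmax(floor(age), stream$min_age), stream$max_age) -
    stream$min_age + 1L
  stream$qx[idx]
}

#' Convert an annual death probability to the cycle grid
#'
#' Constant-hazard conversion: `1 - (1 - qx)^(cycle_days/365.25)`.
#' Monotone in `qx`; 0 maps to 0 and 1 maps to 1. A 365.25-day year is used
#' throughout the package.
#'
#' @param qx Annual probability of death in `[0, 1]` (vectorized).
#' @param cycle_days Cycle length in days, positive.
#' @return Per-cycle probability of death.
#' @examples
#' annual_q_to_cycle_q(0.01, 14)
#' @export
annual_q_to_cycle_q <- function(qx, cycle_days) {
  if (cycle_days <= 0) stop("cycle_days must be positive", call. = FALSE)
  stopifnot(all(qx >= 0 & qx <= 1))
  1 - (1 - qx)^(cycle_days / 365.25)
}

#' Analysis scenario: cohort and horizon settings
#'
#' @param start_age Cohort starting age in years (adults; default 18).
#' @param prop_female Proportion female, used only when the life table
#'   carries separate sex columns.
#' @param horizon `"lifetime"` (run to the terminal life-table age or until
#'   the alive mass falls below 1e-9) or a positive integer number of cycles.
#' @param labels Named character vector labelling the two strategies.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(start_age = 18, prop_female = 0.5,
                          horizon = "lifetime",
                          labels = c(comparator = "ICS+LABA",
                                     add_on = "tiotropium+ICS+LABA")) {
  if (!(identical(horizon, "lifetime") ||
        (is.numeric(horizon) && length(horizon) == 1L && horizon >= 1))) {
    stop("horizon must be \"lifetime\" or a number of cycles >= 1",
         call. = FALSE)
  }
  stopifnot(prop_female >= 0, prop_female <= 1, start_age >= 0)
  structure(list(start_age = start_age, prop_female = prop_female,
                 horizon = horizon, labels = labels),
            class = "scenario_spec")
}

#' The packaged base-case parameter set
#'
#' Returns the frozen base-case encoding of the model's published input
#' table (costs, utilities, relative risk, event rates, adherence, economic
#' settings), as shipped in
#' `inst/extdata/table1_parameters.yaml`. Always passes
#' [validate_parameter_set()].
#'
#' @return A `parameter_set`.
#' @examples
#' table1_fixture()$effect$rr_exacerbation$base # 0.72
#' @export
table1_fixture <- function() {
  load_parameter_set(NULL)
}
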