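#' Example roster of eight commercial honey bee populations
#'
#' A bundled roster describing eight domesticated honey bee populations, each
#' defined by the location of the queen breeder it descends from: two
#' Saskatchewan lines, one Ontario line, one New Zealand line, one Hawaiian
#' line, one Chilean line and two Californian lines. Colony counts are those
#' of the original field study design (58 colonies in total); latitudes are
#' the approximate breeder locations in signed decimal degrees.
#'
#' @return A tibble with columns `name`, `n_colonies` and `latitude_deg`.
#' @examples
#' example_roster()
#' @export
example_roster <- function() {
  tibble::tibble(
    name = c("SK1", "SK2", "ON", "NZ", "HI", "CH", "CA1", "CA2"),
    n_colonies = c(4L, 4L, 4L, 8L, 8L, 10L, 11L, 9L),
    latitude_deg = c(52.75, 52.75, 45.22, -39.64, 19.50, -33.45, 39.14, 39.75)
  )
}

#' Validate a population roster
#'
#' Checks the structural invariants of a roster: unique population names,
#' at least one colony per population, and latitudes within \[-90, 90\].
#'
#' @param roster A data frame with columns `name`, `n_colonies`,
#'   `latitude_deg`.
#' @return The roster, invisibly; errors if invalid.
#' @export
validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster))
  required <- c("name", "n_colonies", "latitude_deg")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0) {
    stop("roster is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(roster) == 0) stop("roster must contain at least one population")
  if (anyDuplicated(roster$name)) stop("population names must be unique")
  if (any(roster$n_colonies < 1)) stop("each population needs >= 1 colony")
  if (any(abs(roster$latitude_deg) > 90)) {
    stop("latitudes must lie in [-90, 90] degrees")
  }
  invisible(roster)
}

#' Simulate a population roster
#'
#' Generates a roster of populations with given colony counts and latitudes
#' drawn uniformly from a range. Useful for building synthetic studies of
#' arbitrary size with the same shape as [example_roster()].
#'
#' @param n_populations Number of populations (>= 2).
#' @param colonies_per_pop Either a single count applied to every population
#'   or a vector of length `n_populations`.
#' @param latitude_range Length-2 numeric range the latitudes are drawn from.
#' @param seed Integer seed; the same seed always yields the same roster.
#' @return A tibble with columns `name`, `n_colonies`, `latitude_deg`.
#' @examples
#' simulate_roster(8, c(4, 4, 4, 8, 8, 10, 11, 9), seed = 1)
#' @export
simulate_roster <- function(n_populations, colonies_per_pop,
                            latitude_range = c(-45, 55), seed = 1L) {
  if (n_populations < 2) stop("n_populations must be >= 2")
  if (length(colonies_per_pop) == 1L) {
    colonies_per_pop <- rep(colonies_per_pop, n_populations)
  }
  if (length(colonies_per_pop) != n_populations) {
    stop("colonies_per_pop must have length 1 or n_populations")
  }
  colonies_per_pop <- as.integer(colonies_per_pop)
  if (any(colonies_per_pop < 1)) stop("colony counts must be positive")
  stopifnot(length(latitude_range) == 2)
  roster <- with_seed(seed, {
    tibble::tibble(
      name = sprintf("P%02d", seq_len(n_populations)),
      n_colonies = colonies_per_pop,
      latitude_deg = round(runif(n_populations,
                                 min(latitude_range), max(latitude_range)), 2)
    )
  })
  validate_roster(roster)
  roster
}
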