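#' Assemble a plant dataset
#'
#' Bundles a feeding schedule, the feedstock characterisation, and the
#' observed gas series of one plant campaign. Synthetic campaigns additionally
#' carry the generating truth (noiseless series and true kinetics) for
#' closure tests.
#'
#' @param schedule A \code{\link{feed_schedule}}.
#' @param specs A \code{feedstock_set}.
#' @param biogas Observed daily biogas, m^3/d, one value per schedule day.
#' @param methane Observed daily methane, m^3/d (optional).
#' @param ch4_weekly Optional data.frame \code{day}, \code{ch4_fraction} of
#'   weekly methane-content measurements.
#' @param ground_truth Optional list (synthetic campaigns): \code{params}
#'   (true \code{\link{kinetic_params}}), \code{biogas}, \code{methane}
#'   (noiseless series).
#' @param provenance Optional list of metadata (seed, config hash, ...).
#' @return Object of class \code{plant_dataset}.
#' @export
plant_dataset <- function(schedule, specs, biogas, methane = NULL,
                          ch4_weekly = NULL, ground_truth = NULL,
                          provenance = list()) {
  stopifnot(inherits(schedule, "feed_schedule"))
  if (length(biogas) != nrow(schedule)) {
    stop("biogas series length does not match schedule", call. = FALSE)
  }
  if (any(biogas < 0)) stop("observed biogas must be >= 0", call. = FALSE)
  if (!is.null(methane)) {
    if (length(methane) != nrow(schedule)) {
      stop("methane series length does not match schedule", call. = FALSE)
    }
    if (any(methane < 0)) stop("observed methane must be >= 0", call. = FALSE)
  }
  structure(list(schedule = schedule, specs = specs, biogas = biogas,
                 methane = methane, ch4_weekly = ch4_weekly,
                 ground_truth = ground_truth, provenance = provenance),
            class = "plant_dataset")
}

#' @export
print.plant_dataset <- function(x, ...) {
  cat("Plant dataset:", nrow(x$schedule), "days,",
      length(schedule_feedstocks(x$schedule)), "feedstocks\n")
  cat(sprintf("  observed biogas: mean %.1f m3/d\n", mean(x$biogas)))
  if (!is.null(x$ground_truth)) cat("  synthetic (ground truth attached)\n")
  invisible(x)
}

# Day indices of the first and remaining calendar years of a dataset.
.year_split_idx <- function(dates) {
  yrs <- as.integer(format(dates, "%Y"))
  if (length(unique(yrs)) < 2) {
    stop("chronological split needs at least two calendar years",
         call. = FALSE)
  }
  first <- yrs == min(yrs)
  list(train = which(first), test = which(!first))
}

#' Split a dataset chronologically at the first year boundary
#'
#' The first calendar year becomes the calibration/training period, all later
#' days the validation period; order is preserved and the periods are
#' disjoint.
#'
#' @param dataset A \code{\link{plant_dataset}}.
#' @return List with \code{train} and \code{test} day-index vectors.
#' @export
chronological_indices <- function(dataset) {
  .year_split_idx(dataset$schedule$date)
}

#' Daily methane from biogas and weekly methane-content readings
#'
#' Methane content is measured weekly; daily methane production is
#' reconstructed as daily biogas times the step-interpolated (last
#' observation carried forward) weekly CH4 fraction.
#'
#' @param biogas Daily biogas series, m^3/d.
#' @param ch4_weekly Data.frame \code{day}, \code{ch4_fraction}.
#' @return Daily methane series, m^3/d.
#' @export
methane_from_weekly_ch4 <- function(biogas, ch4_weekly) {
  stopifnot(all(c("day", "ch4_fraction") %in% names(ch4_weekly)))
  idx <- findInterval(seq_along(biogas), ch4_weekly$day)
  idx[idx == 0] <- 1L
  biogas * ch4_weekly$ch4_fraction[idx]
}
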