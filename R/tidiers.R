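#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an outcome delta
#'
#' @param x A `ssbtax_delta` from [compare_runs()] or [tax_impact()].
#' @param ... Unused.
#' @return Long tibble: `sex`, `measure`, `value`.
#' @method tidy ssbtax_delta
#' @export
tidy.ssbtax_delta <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"sex",
                      names_to = "measure", values_to = "value")
}

#' Tidy a Monte Carlo summary
#'
#' @param x A `ssbtax_mc` from [run_mc()] or [tax_impact_mc()].
#' @param ... Unused.
#' @return Tibble: `sex`, `measure`, `mean`, `lo95`, `hi95` (cells not
#'   named `<sex>.<measure>` keep their full name in `measure`).
#' @method tidy ssbtax_mc
#' @export
tidy.ssbtax_mc <- function(x, ...) {
  out <- tibble::as_tibble(x)
  parts <- strsplit(out$cell, ".", fixed = TRUE)
  out$sex <- vapply(parts, function(p) if (length(p) > 1) p[1] else NA_character_,
                    character(1))
  out$measure <- vapply(parts, function(p) paste(p[-1], collapse = "."),
                        character(1))
  out$measure[out$measure == ""] <- out$cell[out$measure == ""]
  dplyr::select(out, "sex", "measure", "mean", "lo95", "hi95")
}

#' Tidy a weight trajectory
#'
#' @param x A `ssbtax_trajectory`.
#' @param ... Unused.
#' @return The trajectory as a plain tibble with a `delta_weight` column.
#' @method tidy ssbtax_trajectory
#' @export
tidy.ssbtax_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$delta_weight <- out$weight - out$weight[1]
  out
}

#' One-row summary of a weight trajectory
#'
#' @param x A `ssbtax_trajectory`.
#' @param ... Unused.
#' @return Tibble with the intake change, final weight change, and the
#'   fraction of the final change achieved at years 1 and 3.
#' @method glance ssbtax_trajectory
#' @export
glance.ssbtax_trajectory <- function(x, ...) {
  s <- trajectory_summary(x)
  tibble::tibble(delta_EI = attr(x, "delta_EI"),
                 delta_weight_final = s$delta_final,
                 fraction_year1 = s$fraction_at(1),
                 fraction_year3 = s$fraction_at(3))
}

#' One-row-per-sex summary of a life-table run
#'
#' @param x A `ssbtax_run`.
#' @param ... Unused.
#' @return Tibble: `sex`, `initial_cohort`, `life_years`, `deaths`,
#'   `conservation_error`.
#' @method glance ssbtax_run
#' @export
glance.ssbtax_run <- function(x, ...) {
  purrr::imap_dfr(x$by_sex, function(rs, sx) {
    tibble::tibble(sex = sx, initial_cohort = rs$init_total,
                   life_years = sum(rs$life_years), deaths = sum(rs$deaths),
                   conservation_error = rs$conservation_error)
  })
}
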