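#' @title Monte Carlo propagation of parametric uncertainty
#'
#' @description
#' Parameters carrying uncertainty (BMI-disease relative risks,
#' diabetes-disease relative risks, utility decrements, healthcare costs, and
#' the intervention effect on energy intake) are resampled per run from
#' standard health-economics sampling laws: lognormal for relative risks
#' (parameterised from a 95% CI), normal truncated to \[0,1\] for utility
#' decrements, gamma matched to mean/SD for costs, and normal for the
#' intervention effect. Each run re-executes the full pipeline; empirical
#' means and 2.5th/97.5th centiles over the runs form the uncertainty
#' intervals. One random-number stream per run, indexed by run id, keeps
#' baseline and intervention scenarios on common draws within a run.
#'
#' @name uncertainty
NULL

#' Specify an uncertain parameter set
#'
#' @param params Tibble with columns `name`, `law` (one of `"lognormal_ci"`,
#'   `"normal_ci"`, `"truncnorm"`, `"gamma_meansd"`, `"fixed"`) and the
#'   law-specific columns `mean`, `lo`, `hi`, `sd` (unused entries `NA`).
#' @param n_runs Number of Monte Carlo runs (default 2000).
#' @param seed Integer seed.
#' @return A `ssbtax_mc_spec` list.
#' @export
mc_spec <- function(params, n_runs = 2000, seed = 1L) {
  stopifnot(is.data.frame(params), all(c("name", "law") %in% names(params)))
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  for (col in c("mean", "lo", "hi", "sd")) {
    if (!col %in% names(params)) params[[col]] <- NA_real_
  }
  bad <- !params$law %in% c("lognormal_ci", "normal_ci", "truncnorm",
                            "gamma_meansd", "fixed")
  if (any(bad)) stop("unknown sampling law: ", paste(params$law[bad], collapse = ", "),
                     call. = FALSE)
  ci <- params$law %in% c("lognormal_ci", "normal_ci")
  if (any(ci & (params$lo > params$hi))) {
    stop("confidence interval with lo > hi", call. = FALSE)
  }
  structure(list(params = params, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "ssbtax_mc_spec")
}

# One value from each law. CI-based laws interpret (lo, hi) as a 95% interval.
.sample_one <- function(law, mean, lo, hi, sd) {
  z <- stats::qnorm(0.975)
  switch(law,
    fixed = mean,
    lognormal_ci = {
      mu <- (log(lo) + log(hi)) / 2
      sig <- (log(hi) - log(lo)) / (2 * z)
      stats::rlnorm(1, mu, sig)
    },
    normal_ci = stats::rnorm(1, (lo + hi) / 2, (hi - lo) / (2 * z)),
    truncnorm = {
      if (is.na(sd) || sd == 0) return(min(max(mean, 0), 1))
      # inverse-CDF truncation to [0, 1]
      a <- stats::pnorm(0, mean, sd); b <- stats::pnorm(1, mean, sd)
      stats::qnorm(a + stats::runif(1) * (b - a), mean, sd)
    },
    gamma_meansd = {
      if (is.na(sd) || sd == 0) return(mean)
      if (mean <= 0) return(0)
      stats::rgamma(1, shape = (mean / sd)^2, rate = mean / sd^2)
    }
  )
}

#' Draw one parameter set
#'
#' Reproducible given the RNG state; all draws fall in their parameter's
#' valid domain.
#'
#' @param spec A [mc_spec()].
#' @return Named list of parameter values.
#' @export
draw_parameters <- function(spec) {
  stopifnot(inherits(spec, "ssbtax_mc_spec"))
  p <- spec$params
  vals <- purrr::pmap_dbl(p[c("law", "mean", "lo", "hi", "sd")],
                          function(law, mean, lo, hi, sd) {
                            .sample_one(law, mean, lo, hi, sd)
                          })
  stats::setNames(as.list(vals), p$name)
}

#' Run the Monte Carlo loop
#'
#' Evaluates `model(draw)` for `n_runs` parameter draws and summarises every
#' output cell by its mean and empirical 2.5th/97.5th centiles (linear
#' interpolation of order statistics). A failing run is logged and re-drawn;
#' more than 1% failed runs aborts.
#'
#' @param model Function taking a named parameter list and returning a named
#'   numeric vector (the output cells); must be deterministic given a draw.
#' @param spec A [mc_spec()].
#' @return A `ssbtax_mc` object: tibble `cell`, `mean`, `lo95`, `hi95`, with
#'   the draws matrix in `attr(, "draws")`.
#' @export
run_mc <- function(model, spec) {
  stopifnot(inherits(spec, "ssbtax_mc_spec"))
  out <- vector("list", spec$n_runs)
  failures <- 0L
  max_fail <- max(1L, ceiling(0.01 * spec$n_runs))
  for (r in seq_len(spec$n_runs)) {
    attempt <- 0L
    repeat {
      set.seed(spec$seed + 7919L * r + 104729L * attempt)
      draw <- draw_parameters(spec)
      val <- tryCatch(model(draw), error = function(e) e)
      if (!inherits(val, "error")) break
      failures <- failures + 1L
      attempt <- attempt + 1L
      message("run ", r, " failed (", conditionMessage(val), "); re-drawing")
      if (failures > max_fail) {
        stop("more than 1% of Monte Carlo runs failed; aborting", call. = FALSE)
      }
    }
    out[[r]] <- val
  }
  m <- do.call(rbind, out)
  summ <- tibble::tibble(
    cell = colnames(m),
    mean = colMeans(m),
    lo95 = apply(m, 2, stats::quantile, probs = 0.025, names = FALSE, type = 7),
    hi95 = apply(m, 2, stats::quantile, probs = 0.975, names = FALSE, type = 7)
  )
  structure(summ, class = c("ssbtax_mc", class(summ)), draws = m,
            n_runs = spec$n_runs, seed = spec$seed)
}
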