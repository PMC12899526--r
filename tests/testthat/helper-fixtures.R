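# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- make_fixture(fixture_config())
  }
  .fixture_cache$bundle
}

null_bundle <- function() {
  if (is.null(.fixture_cache$null)) {
    .fixture_cache$null <- make_null_fixture(fixture_config())
  }
  .fixture_cache$null
}

default_prep <- function() {
  if (is.null(.fixture_cache$prep)) {
    .fixture_cache$prep <- prepare_simulation(default_bundle())
  }
  .fixture_cache$prep
}

# Population-weighted mean of a per-(sex, age_group) column.
pop_weighted_mean <- function(df, col, population) {
  groups <- age_group_labels()
  pg <- population |>
    dplyr::mutate(age_group = groups[pmin(findInterval(age, seq(20, 95, 5)), 16)]) |>
    dplyr::group_by(sex, age_group) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  m <- dplyr::inner_join(df, pg, by = intersect(c("sex", "age_group"), names(df)))
  stats::weighted.mean(m[[col]], m$count)
}
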