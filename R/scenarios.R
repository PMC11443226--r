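#' The 36 planting configurations
#'
#' The embedded sweep table: three planting patterns (double row big ridge
#' DRBR, equidistant row ER, narrow-wide row NWR) crossed with six
#' wide+narrow row sums (0.8-1.8 m), four plant spacings (0.15-0.3 m) and the
#' resulting nominal densities (63,000-100,000 plants per hectare, rounded to
#' the nearest thousand).
#'
#' @return A tibble with 36 rows: `id`, `pattern`, `wide_row`, `narrow_row`,
#'   `wn_sum`, `plant_spacing`, `nominal_density`.
#' @export
scenario_table <- function() {
  triplet <- function(ids, wides, narrows, spacing, density) {
    tibble::tibble(
      id = ids, pattern = c("DRBR", "ER", "NWR"),
      wide_row = wides, narrow_row = narrows,
      wn_sum = wides + narrows,
      plant_spacing = spacing, nominal_density = density
    )
  }
  dplyr::bind_rows(
    triplet(1:3,   c(1.6, 0.9, 1.2), c(0.2, 0.9, 0.6), 0.15, 74000),
    triplet(4:6,   c(1.4, 0.8, 1.1), c(0.2, 0.8, 0.5), 0.15, 83000),
    triplet(7:9,   c(1.2, 0.7, 1.0), c(0.2, 0.7, 0.4), 0.15, 95000),
    triplet(10:12, c(1.4, 0.8, 1.1), c(0.2, 0.8, 0.5), 0.20, 63000),
    triplet(13:15, c(1.2, 0.7, 1.0), c(0.2, 0.7, 0.4), 0.20, 72000),
    triplet(16:18, c(1.0, 0.6, 0.8), c(0.2, 0.6, 0.4), 0.20, 83000),
    triplet(19:21, c(0.8, 0.5, 0.6), c(0.2, 0.5, 0.4), 0.20, 100000),
    triplet(22:24, c(1.0, 0.6, 0.8), c(0.2, 0.6, 0.4), 0.25, 67000),
    triplet(25:27, c(0.8, 0.5, 0.7), c(0.2, 0.5, 0.3), 0.25, 80000),
    triplet(28:30, c(0.6, 0.4, 0.5), c(0.2, 0.4, 0.3), 0.25, 100000),
    triplet(31:33, c(0.8, 0.5, 0.7), c(0.2, 0.5, 0.3), 0.30, 67000),
    triplet(34:36, c(0.6, 0.4, 0.5), c(0.2, 0.4, 0.3), 0.30, 83000)
  )
}

#' Planting density implied by the row geometry
#'
#' ER plants one row per row spacing (`10000 / (wide * spacing)` per ha);
#' DRBR and NWR place two rows per wide+narrow period
#' (`2 * 10000 / ((wide + narrow) * spacing)`).
#'
#' @param pattern "DRBR", "ER" or "NWR" (vectorized).
#' @param wide,narrow Wide and narrow row spacing (m).
#' @param spacing Plant spacing within the row (m).
#' @return A tibble with `density` (plants per hectare, unrounded) and
#'   `density_rounded` (nearest thousand).
#' @export
#' @examples
#' density_from_geometry("ER", 0.8, 0.8, 0.15) # 83,333 -> 83,000
density_from_geometry <- function(pattern, wide, narrow, spacing) {
  if (any(spacing <= 0) || any(wide <= 0)) {
    stop("spacings must be positive", call. = FALSE)
  }
  density <- ifelse(pattern == "ER",
                    1e4 / (wide * spacing),
                    2e4 / ((wide + narrow) * spacing))
  tibble::tibble(density = density,
                 density_rounded = floor(density / 1000 + 0.5 + 1e-9) * 1000)
}

#' Select qualifying and optimal planting scenarios
#'
#' Applies the dual quality criteria to a sweep summary: mean bud length of
#' at least `bud_length_min` (high market quality) and per-hectare yield of
#' at least `yield_min`. The best scenario is the highest-yielding qualifier.
#'
#' @param summary Sweep summary tibble with columns `id`, `mean_bud_len_m`
#'   and `yield_t_ha` (see [run_sweep()]).
#' @param bud_length_min Minimum mean bud length (m).
#' @param yield_min Minimum per-hectare yield (t).
#' @return A list with `qualifying` (tibble of qualifying rows), `ids`
#'   (integer vector) and `best` (id of the top yielder, or `NA` if none
#'   qualify).
#' @export
select_optimal <- function(summary, bud_length_min = 0.12, yield_min = 35) {
  ok <- summary$mean_bud_len_m >= bud_length_min &
    summary$yield_t_ha >= yield_min
  qual <- summary[ok, , drop = FALSE]
  best <- if (nrow(qual)) qual$id[which.max(qual$yield_t_ha)] else NA_integer_
  list(qualifying = qual, ids = qual$id, best = best)
}
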