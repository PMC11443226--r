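#' Default organ phenology and endpoint calibration
#'
#' One row per organ template: 13 leaf ranks per shoot (appearing every 6 days
#' from the start of the spring regrowth on day 91, each expanding for about
#' 42 days, final lengths increasing with rank), one scape per flowering shoot
#' (elongating from day 137 and reaching its final 1.19 m length by day 210),
#' and 40 buds per inflorescence with staggered births through the flowering
#' window and a potential final length of 0.128 m each. Potential dry masses
#' anchor the source-sink demand; leaf dry mass scales with final length
#' through `leaf_dm_per_m` and sets the leaf area via the specific leaf area.
#'
#' @param leaf_ranks Number of leaf ranks per shoot.
#' @param leaf_birth_start First leaf birth day of year.
#' @param leaf_birth_step Days between successive leaf ranks.
#' @param leaf_duration Days from leaf birth to the end of its expansion.
#' @param leaf_len_range Final leaf length of rank 1 and of the top rank (m).
#' @param leaf_dm_per_m Leaf dry mass per metre of final length (g m-1).
#' @param scape_birth,scape_tm,scape_te Scape timing (days of year).
#' @param scape_len,scape_dm Scape final length (m) and dry mass (g).
#' @param buds_per_scape Buds per inflorescence.
#' @param bud_birth_range First and last bud birth day.
#' @param bud_duration Days from bud birth to harvest maturity.
#' @param bud_len,bud_dm Potential final bud length (m) and dry mass (g).
#' @return A tibble with columns `organ`, `rank`, `birth_doy`, `t_m`, `t_e`,
#'   `w_max_len_m`, `w_max_dm_g`.
#' @export
default_phenology <- function(leaf_ranks = 13,
                              leaf_birth_start = 91,
                              leaf_birth_step = 4,
                              leaf_duration = 36,
                              leaf_len_range = c(0.45, 0.80),
                              leaf_dm_per_m = 1.8,
                              scape_birth = 137,
                              scape_tm = 172,
                              scape_te = 210,
                              scape_len = 1.19,
                              scape_dm = 4,
                              buds_per_scape = 40,
                              bud_birth_range = c(168, 212),
                              bud_duration = 24,
                              bud_len = 0.128,
                              bud_dm = 0.4286) {
  r <- seq_len(leaf_ranks)
  leaf_birth <- leaf_birth_start + (r - 1) * leaf_birth_step
  leaf_len <- leaf_len_range[1] +
    (leaf_len_range[2] - leaf_len_range[1]) * (r - 1) / (leaf_ranks - 1)
  leaves <- tibble::tibble(
    organ = "leaf", rank = r,
    birth_doy = leaf_birth,
    t_m = leaf_birth + round(0.45 * leaf_duration),
    t_e = leaf_birth + leaf_duration,
    w_max_len_m = leaf_len,
    w_max_dm_g = leaf_dm_per_m * leaf_len
  )
  scape <- tibble::tibble(
    organ = "scape", rank = 1L,
    birth_doy = scape_birth, t_m = scape_tm, t_e = scape_te,
    w_max_len_m = scape_len, w_max_dm_g = scape_dm
  )
  b <- seq_len(buds_per_scape)
  bud_birth <- round(seq(bud_birth_range[1], bud_birth_range[2],
                         length.out = buds_per_scape))
  buds <- tibble::tibble(
    organ = "bud", rank = b,
    birth_doy = bud_birth,
    t_m = bud_birth + round(bud_duration / 2),
    t_e = bud_birth + bud_duration,
    w_max_len_m = bud_len,
    w_max_dm_g = bud_dm
  )
  dplyr::bind_rows(leaves, scape, buds)
}

#' Read a phenology calibration table
#'
#' CSV with header `organ,rank,birth_doy,t_m,t_e,w_max_len_m,w_max_dm_g`.
#'
#' @param path File path.
#' @return Phenology tibble, validated.
#' @export
read_phenology_csv <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("organ", "rank", "birth_doy", "t_m", "t_e", "w_max_len_m", "w_max_dm_g")
  missing <- setdiff(need, names(ph))
  if (length(missing)) {
    stop("phenology file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!(ph$birth_doy < ph$t_m & ph$t_m < ph$t_e))) {
    stop("phenology rows must satisfy birth_doy < t_m < t_e", call. = FALSE)
  }
  ph[need]
}
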