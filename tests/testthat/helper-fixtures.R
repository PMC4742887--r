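# Small single-plate layout + library used by most unit tests; the
# full two-plate design is exercised in the acceptance suite.
small_layout <- function() {
  list(p1 = c(GM_NEG_CONTROL = 8L, DM_I_POS_CONTROL = 8L, MOCK = 2L,
              UNIVERSAL_CONTROL = 2L, KIF11_CONTROL = 2L, EXPERIMENTAL = 24L))
}

small_library <- function() synthetic_kinase_library(24)

small_sim <- function(seed = 7, ...) {
  simulate_screen(simulation_config(seed = seed, ...),
                  small_library(), small_layout())
}

# one manually built well: a screen_dataset with a single experimental
# well (plus GM references) where every site is specified exactly
flat_dataset <- function(exp_counts = c(100L, 100L, 100L),
                         exp_pos = c(2L, 2L, 2L),
                         n_gm = 4, gm_counts = c(100L, 100L, 100L),
                         gm_pos = c(2L, 2L, 2L)) {
  lib <- kinase_library("Kin1")
  gm_wells <- sprintf("A%d", seq_len(n_gm))
  rows <- list(tibble::tibble(
    plate_id = "p1", well = "B1", role = "EXPERIMENTAL", target_gene = "Kin1",
    arm = "vehicle", replicate = 1L, site_index = seq_along(exp_counts),
    total_nuclei = exp_counts, myogenin_pos_nuclei = exp_pos))
  for (w in gm_wells) {
    rows <- c(rows, list(tibble::tibble(
      plate_id = "p1", well = w, role = "GM_NEG_CONTROL",
      target_gene = NA_character_, arm = "vehicle", replicate = 1L,
      site_index = seq_along(gm_counts), total_nuclei = gm_counts,
      myogenin_pos_nuclei = gm_pos)))
  }
  screen_dataset(dplyr::bind_rows(rows), lib)
}
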