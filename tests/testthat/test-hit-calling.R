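test_that("a well with a clear Myogenin increase and cell loss scores positive", {
  frac <- c(0.30, 0.32, 0.28, 0.31)
  gm_frac <- rep(c(0.015, 0.020, 0.025, 0.020), 8)
  gm_nuclei <- c(800, 900, 1000, 1100, 1200)  # median 1000, raw MAD 100
  s <- score_well(frac, 300, gm_frac, gm_nuclei)
  expect_true(s$myog_positive)
  expect_true(s$cell_positive)   # 300 <= 1000 - 100
  expect_true(s$well_positive)
  # p-value agrees with an independent pooled-t computation
  expect_equal(s$p_value, oracle_pooled_t_p(frac, gm_frac), tolerance = 1e-12)
})

test_that("an exchangeable well is not positive and conjunction semantics hold", {
  gm_frac <- rep(c(0.015, 0.020, 0.025, 0.020), 8)
  gm_nuclei <- c(800, 900, 1000, 1100, 1200)
  same <- score_well(c(0.015, 0.020, 0.025, 0.020), 1000, gm_frac, gm_nuclei)
  expect_gte(same$p_value, 0.5)
  expect_false(same$well_positive)

  # Myogenin up but cell number not down -> not positive
  myog_only <- score_well(c(0.30, 0.32, 0.28, 0.31), 1000, gm_frac, gm_nuclei)
  expect_true(myog_only$myog_positive)
  expect_false(myog_only$cell_positive)
  expect_false(myog_only$well_positive)

  # cell number down without Myogenin up -> not positive either
  cell_only <- score_well(c(0.015, 0.020, 0.025, 0.020), 300, gm_frac, gm_nuclei)
  expect_false(cell_only$myog_positive)
  expect_true(cell_only$cell_positive)
  expect_false(cell_only$well_positive)

  # in the sensitizer arm the cell criterion is dropped
  sens <- score_well(c(0.30, 0.32, 0.28, 0.31), 1000, gm_frac, gm_nuclei,
                     arm = "sensitizer")
  expect_true(sens$well_positive)
})

test_that("degenerate variance limits are well defined", {
  gm_nuclei <- c(800, 900, 1000, 1100, 1200)
  eq <- score_well(rep(0.02, 4), 1000, rep(0.02, 8), gm_nuclei)
  expect_equal(eq$p_value, 1)
  up <- score_well(rep(0.05, 4), 1000, rep(0.02, 8), gm_nuclei)
  expect_equal(up$p_value, 0)
  down <- score_well(rep(0.01, 4), 1000, rep(0.02, 8), gm_nuclei)
  expect_equal(down$p_value, 1)
  short <- score_well(0.02, 1000, rep(0.02, 8), gm_nuclei)
  expect_true(short$insufficient_data)
  expect_false(short$well_positive)
})

test_that("both cell-number dialects are implemented", {
  gm_frac <- rep(c(0.015, 0.020, 0.025, 0.020), 8)
  gm_nuclei <- c(800, 900, 1000, 1100, 1200)   # median 1000, MAD 100
  dmi_nuclei <- c(400, 450, 500, 550, 600)     # median 500, MAD 50
  res_cfg <- hit_call_config(cell_criterion_dialect = "results")
  # 470 is within one DM+I MAD of 500 but not one GM MAD below 900
  s <- score_well(c(0.30, 0.32, 0.28, 0.31), 470, gm_frac, gm_nuclei,
                  config = res_cfg, dmi_mean_nuclei = dmi_nuclei)
  expect_true(s$cell_positive)
  s2 <- score_well(c(0.30, 0.32, 0.28, 0.31), 470, gm_frac, gm_nuclei)
  expect_true(s2$cell_positive)   # methods dialect: 470 <= 900
  s3 <- score_well(c(0.30, 0.32, 0.28, 0.31), 920, gm_frac, gm_nuclei,
                   config = res_cfg, dmi_mean_nuclei = dmi_nuclei)
  expect_false(s3$cell_positive)  # 920 far from the DM+I median
})

test_that("replicate rules differ between arms", {
  base <- tibble::tibble(gene = "Src", arm = "vehicle", replicate = 1:3,
                         p_value = c(0.01, 0.02, 0.5),
                         myog_positive = c(TRUE, TRUE, FALSE),
                         cell_positive = TRUE,
                         well_positive = c(TRUE, TRUE, FALSE))
  expect_true(call_kinase(base)$is_hit)                 # 2 of 3 suffices
  sens <- dplyr::mutate(base, arm = "sensitizer")
  expect_false(call_kinase(sens)$is_hit)                # needs all 3
  sens3 <- dplyr::mutate(sens, well_positive = TRUE)
  expect_true(call_kinase(sens3)$is_hit)
  none <- dplyr::mutate(base, well_positive = FALSE)
  call0 <- call_kinase(none)
  expect_false(call0$is_hit)
  expect_equal(call0$n_positive_replicates, 0)

  expect_error(call_kinase(dplyr::mutate(base, gene = c("A", "A", "B"))),
               "one gene")
  expect_error(call_kinase(base[1:2, ]), "expected 3 replicate scores")
})

test_that("a screen identical to its GM controls yields zero hits", {
  lib <- kinase_library(c("K1", "K2"))
  mk <- function(well, role, gene, arm, rep) tibble::tibble(
    plate_id = "p1", well = well, role = role, target_gene = gene, arm = arm,
    replicate = rep, site_index = 1:4, total_nuclei = 100L,
    myogenin_pos_nuclei = 2L)
  rows <- list()
  for (arm in c("vehicle", "sensitizer")) for (rep in 1:3) {
    rows <- c(rows,
              lapply(sprintf("A%d", 1:4), mk, role = "GM_NEG_CONTROL",
                     gene = NA_character_, arm = arm, rep = rep),
              list(mk("B1", "EXPERIMENTAL", "K1", arm, rep),
                   mk("B2", "EXPERIMENTAL", "K2", arm, rep)))
  }
  ds <- screen_dataset(dplyr::bind_rows(rows), lib)
  calls <- call_screen(ds)
  expect_true(all(!calls$is_hit))
  expect_true(all(calls$min_p == 1))
})

test_that("hit calls are deterministic and order-invariant", {
  ph <- data.frame(gene = small_library()$genes[1:3], odds_multiplier = 40,
                   proliferation_multiplier = 0.3)
  sim <- small_sim(seed = 41, planted_hits = ph)
  calls1 <- call_screen(sim$dataset)
  shuffled <- sim$dataset$data[sample(nrow(sim$dataset$data)), ]
  calls2 <- call_screen(screen_dataset(shuffled, small_library()))
  expect_equal(calls1, calls2)
  hits_v <- calls1$gene[calls1$arm == "vehicle" & calls1$is_hit]
  expect_true(all(ph$gene %in% hits_v))
})

test_that("sensitizer-arm hits ignore cell-number perturbations", {
  ph <- data.frame(gene = small_library()$genes[1:3], odds_multiplier = 40,
                   proliferation_multiplier = 0.3)
  sim <- small_sim(seed = 42, planted_hits = ph)
  calls <- call_screen(sim$dataset)
  d <- sim$dataset$data
  sens <- d$arm == "sensitizer"
  d$total_nuclei[sens] <- d$total_nuclei[sens] * 3L  # keeps pos <= total
  calls_pert <- call_screen(screen_dataset(d, small_library()))
  sel <- function(x) x[x$arm == "sensitizer",
                       c("gene", "n_positive_replicates", "is_hit")]
  expect_equal(sel(calls), sel(calls_pert))
})

test_that("adding the cell criterion never adds hits", {
  sim <- small_sim(seed = 43)
  scores <- score_wells(sim$dataset)
  by_gene <- dplyr::summarise(
    dplyr::group_by(scores[scores$arm == "vehicle", ], .data$gene),
    myog_only = sum(.data$myog_positive) >= 2,
    conjoined = sum(.data$well_positive) >= 2, .groups = "drop")
  expect_true(all(!by_gene$conjoined | by_gene$myog_only))
  expect_lte(sum(by_gene$conjoined), sum(by_gene$myog_only))
})

test_that("one-sided per-well test keeps its size on exchangeable data", {
  # implementation-level validity check on symmetric null data
  set.seed(77)
  n <- 4000
  hits <- logical(n)
  gm <- stats::rnorm(128, mean = 2, sd = 0.5)
  gm_nuclei <- stats::rnorm(32, 250, 20)
  for (i in seq_len(n)) {
    x <- stats::rnorm(4, mean = 2, sd = 0.5)
    hits[i] <- score_well(x, 250, gm, gm_nuclei)$myog_positive
  }
  expect_lte(mean(hits), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n))
})

test_that("cross-arm comparison does exact set algebra", {
  lib <- synthetic_kinase_library(571)
  a <- lib$genes[1:19]
  b <- c(lib$genes[14:19], lib$genes[100:135])  # 6 overlap, 42 total
  cmp <- compare_arms(a, b, 571)
  expect_equal(unname(cmp$counts), c(19L, 42L, 6L, 55L))
  expect_equal(cmp$counts[["union"]],
               cmp$counts[["vehicle"]] + cmp$counts[["sensitizer"]] -
                 cmp$counts[["double"]])
  same <- compare_arms(a, a, 571)
  expect_equal(same$double_hits, same$union_hits)
  disjoint <- compare_arms(lib$genes[1:10], lib$genes[11:30], 571)
  expect_equal(disjoint$counts[["union"]], 30L)
  expect_equal(disjoint$counts[["double"]], 0L)
})

test_that("cross-arm comparison rejects mismatched universes", {
  calls_v <- tibble::tibble(gene = c("A", "B"), arm = "vehicle",
                            is_hit = c(TRUE, FALSE))
  calls_s <- tibble::tibble(gene = c("A", "C"), arm = "sensitizer",
                            is_hit = c(TRUE, FALSE))
  expect_error(compare_arms(calls_v, calls_s, 2), "different gene universes")
})

test_that("anti-proliferative-only genes appear in the cell-only report, not the hits", {
  lib <- small_library()
  ph <- data.frame(gene = lib$genes[1:3],
                   odds_multiplier = c(1, 1, 40),
                   proliferation_multiplier = c(0.3, 0.3, 0.3))
  sim <- small_sim(seed = 44, planted_hits = ph)
  rep_ <- cell_number_only_report(sim$dataset)
  cell_only_v <- rep_$genes$gene[rep_$genes$arm == "vehicle"]
  expect_true(all(lib$genes[1:2] %in% cell_only_v))
  calls <- call_screen(sim$dataset)
  hits_v <- calls$gene[calls$arm == "vehicle" & !is.na(calls$is_hit) &
                         calls$is_hit]
  expect_false(any(lib$genes[1:2] %in% hits_v))
  expect_true(lib$genes[3] %in% hits_v)          # both effects -> a hit
  expect_false(lib$genes[3] %in% cell_only_v)    # and so not in this report
})

test_that("alternative scoring options stay coherent", {
  sim <- small_sim(seed = 45, planted_hits = data.frame(
    gene = small_library()$genes[1:2], odds_multiplier = 40,
    proliferation_multiplier = 0.3))
  hits_of <- function(cfg) {
    calls <- call_screen(sim$dataset, cfg)
    sort(calls$gene[calls$arm == "vehicle" & !is.na(calls$is_hit) & calls$is_hit])
  }
  default_hits <- hits_of(hit_call_config())
  bh_hits <- hits_of(hit_call_config(bh_correct = TRUE))
  expect_true(all(bh_hits %in% default_hits))
  rm_hits <- hits_of(hit_call_config(t_test_unit = "replicate_means"))
  expect_true(all(small_library()$genes[1:2] %in% rm_hits))
})
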