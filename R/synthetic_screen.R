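#' Simulation configuration for a synthetic screen
#'
#' Encodes the generative stand-in for the screen's statistical
#' structure: negative-binomial total-nuclei counts per imaged site,
#' beta-binomial Myogenin-positive counts per site, a low baseline
#' Myogenin fraction in growth medium (GM) and a high fraction in the
#' differentiation-medium positive controls (DM+I), knockdown effects
#' that act multiplicatively on the Myogenin odds and on the expected
#' cell number, and a sensitizer arm that suppresses proliferation in
#' every well without a detectable Myogenin shift of its own.
#'
#' @param seed integer seed; a fixed seed makes [simulate_screen()]
#'   bit-reproducible.
#' @param n_sites_per_well imaged sites per well (default 4).
#' @param n_replicates replicate plates per arm (default 3).
#' @param gm_myog_fraction baseline Myogenin-positive fraction in GM
#'   wells (default 0.02).
#' @param dmi_myog_fraction Myogenin-positive fraction in DM+I positive
#'   controls (default 0.40).
#' @param gm_mean_nuclei_per_site expected nuclei per site in an
#'   unperturbed GM well (default 250).
#' @param nuclei_dispersion negative-binomial size parameter for site
#'   nuclei counts; smaller is noisier (default 10).
#' @param site_overdispersion beta-binomial correlation rho for the
#'   per-site Myogenin fraction, in `[0, 1)` (default 0.01). Each
#'   site's positive count is drawn with its own beta variate, so sites
#'   stay exchangeable across wells.
#' @param dmi_proliferation_multiplier cell-number multiplier for DM+I
#'   wells, reflecting the cell-cycle exit that accompanies
#'   differentiation (default 0.5).
#' @param kif11_proliferation_multiplier cell-number multiplier for the
#'   lethal Kif11 knockdown control (default 0.2).
#' @param sensitizer_proliferation_multiplier cell-number multiplier
#'   applied to every well of the sensitizer (CDK4/6-inhibitor) arm
#'   (default 0.5).
#' @param sensitizer_myog_shift odds multiplier on the Myogenin
#'   fraction in the sensitizer arm; the default 1.0 encodes that the
#'   inhibitor's own Myogenin increase is below the assay's detection
#'   limit.
#' @param planted_hits `NULL`, or a data frame with columns `gene`,
#'   `odds_multiplier` (> 0, applied to the Myogenin odds in that
#'   gene's wells) and `proliferation_multiplier` (in (0, 1], applied
#'   to expected nuclei).
#' @param plate_effects optional list of additive positional offsets:
#'   `row_logit`/`col_logit` (length 16/24, added to the Myogenin
#'   logit) and `row_log_nuclei`/`col_log_nuclei` (added to log mean
#'   nuclei). All default to zero; plate-level normalization is the
#'   analysis default, so positional structure is off unless requested.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_sites_per_well = 4L,
                              n_replicates = 3L,
                              gm_myog_fraction = 0.02,
                              dmi_myog_fraction = 0.40,
                              gm_mean_nuclei_per_site = 250,
                              nuclei_dispersion = 10,
                              site_overdispersion = 0.01,
                              dmi_proliferation_multiplier = 0.5,
                              kif11_proliferation_multiplier = 0.2,
                              sensitizer_proliferation_multiplier = 0.5,
                              sensitizer_myog_shift = 1.0,
                              planted_hits = NULL,
                              plate_effects = NULL) {
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
            is_count(n_sites_per_well), n_sites_per_well >= 1,
            is_count(n_replicates), n_replicates >= 1)
  probs <- c(gm_myog_fraction = gm_myog_fraction,
             dmi_myog_fraction = dmi_myog_fraction)
  if (any(probs <= 0 | probs >= 1)) {
    stop_format("myogenin fractions must lie strictly in (0, 1)")
  }
  if (gm_mean_nuclei_per_site <= 0 || nuclei_dispersion <= 0) {
    stop_format("gm_mean_nuclei_per_site and nuclei_dispersion must be positive")
  }
  if (site_overdispersion < 0 || site_overdispersion >= 1) {
    stop_format("site_overdispersion must lie in [0, 1)")
  }
  mult <- c(dmi_proliferation_multiplier, kif11_proliferation_multiplier,
            sensitizer_proliferation_multiplier)
  if (any(mult <= 0 | mult > 1)) {
    stop_format("proliferation multipliers must lie in (0, 1]")
  }
  if (sensitizer_myog_shift <= 0) {
    stop_format("sensitizer_myog_shift must be a positive odds multiplier")
  }
  if (!is.null(planted_hits)) {
    planted_hits <- tibble::as_tibble(planted_hits)
    need <- c("gene", "odds_multiplier", "proliferation_multiplier")
    if (!all(need %in% names(planted_hits))) {
      stop_format("planted_hits needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(planted_hits$odds_multiplier <= 0) ||
        any(planted_hits$proliferation_multiplier <= 0) ||
        any(planted_hits$proliferation_multiplier > 1)) {
      stop_format("planted effects: odds_multiplier > 0, proliferation_multiplier in (0, 1]")
    }
    if (anyDuplicated(norm_symbol(planted_hits$gene))) {
      stop_format("planted_hits lists a gene twice")
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_sites_per_well = as.integer(n_sites_per_well),
    n_replicates = as.integer(n_replicates),
    gm_myog_fraction = gm_myog_fraction,
    dmi_myog_fraction = dmi_myog_fraction,
    gm_mean_nuclei_per_site = gm_mean_nuclei_per_site,
    nuclei_dispersion = nuclei_dispersion,
    site_overdispersion = site_overdispersion,
    dmi_proliferation_multiplier = dmi_proliferation_multiplier,
    kif11_proliferation_multiplier = kif11_proliferation_multiplier,
    sensitizer_proliferation_multiplier = sensitizer_proliferation_multiplier,
    sensitizer_myog_shift = sensitizer_myog_shift,
    planted_hits = planted_hits,
    plate_effects = plate_effects
  ), class = "simulation_config")
}

# Deterministic role placement on one 384-well plate: GM and the other
# control roles fill the leading column-major coordinates, DM+I controls
# fill the trailing ones, and experimental wells sit in the middle
# columns -- the usual edge-column control arrangement.
assign_plate_wells <- function(plate_id, role_counts, genes) {
  # configs loaded from YAML/JSON carry counts as named lists
  role_counts <- vapply(role_counts, as.integer, integer(1))
  roles <- names(role_counts)
  bad <- setdiff(roles, well_roles())
  if (length(bad) > 0) stop_format("unknown role in layout: %s", bad[1])
  n_exp <- length(genes)
  declared_exp <- unname(role_counts["EXPERIMENTAL"])
  if (is.na(declared_exp)) declared_exp <- 0L
  if (n_exp > declared_exp) {
    stop_format("plate %s: %d genes assigned but layout allows %d experimental wells",
                plate_id, n_exp, declared_exp)
  }
  front_roles <- intersect(c("GM_NEG_CONTROL", "MOCK", "UNIVERSAL_CONTROL",
                             "KIF11_CONTROL"), roles)
  n_front <- sum(role_counts[front_roles])
  n_back <- if ("DM_I_POS_CONTROL" %in% roles) role_counts[["DM_I_POS_CONTROL"]] else 0L
  if (n_front + n_back + n_exp > 384) {
    stop_format("plate %s layout exceeds 384 wells", plate_id)
  }
  coords <- well_coordinates("column")
  front <- rep(front_roles, times = role_counts[front_roles])
  wells <- tibble::tibble(
    plate_id = plate_id,
    well = c(coords[seq_len(n_front)],
             coords[n_front + seq_len(n_exp)],
             if (n_back > 0) coords[385 - seq_len(n_back)]),
    role = c(front, rep("EXPERIMENTAL", n_exp), rep("DM_I_POS_CONTROL", n_back)),
    target_gene = NA_character_
  )
  wells$target_gene[wells$role == "EXPERIMENTAL"] <- genes
  wells
}

#' Simulate a full screen with planted ground truth
#'
#' Generates a [screen_dataset()] under the plate design in
#' `layout_spec`: each library plate is replicated `n_replicates` times
#' in each of the two arms. Per site, total nuclei are drawn from a
#' negative binomial whose mean is the GM baseline scaled by the
#' well's role, arm and knockdown multipliers; Myogenin-positive nuclei
#' are drawn beta-binomially around a fraction obtained by shifting the
#' baseline logit by the log odds multipliers, so composed effects stay
#' inside (0, 1). Planted hits perturb only their own experimental
#' wells. The returned ground truth records the planted effect for
#' every library gene.
#'
#' @param config a [simulation_config()].
#' @param library a [kinase_library()]; genes are assigned to plates in
#'   library order, filling each plate's experimental capacity in turn.
#' @param layout_spec per-plate role counts (see
#'   [default_screen_layout()]).
#' @return list with elements `dataset` (a [screen_dataset()]) and
#'   `truth` (tibble: `gene`, `is_hit`, `odds_multiplier`,
#'   `proliferation_multiplier`).
#' @export
simulate_screen <- function(config = simulation_config(),
                            library = synthetic_kinase_library(),
                            layout_spec = default_screen_layout()) {
  stopifnot(inherits(config, "simulation_config"))
  capacity <- vapply(layout_spec, function(x) {
    if ("EXPERIMENTAL" %in% names(x)) as.integer(x[["EXPERIMENTAL"]]) else 0L
  }, integer(1))
  if (length(library) > sum(capacity)) {
    stop_format("library has %d genes but the layout holds only %d experimental wells",
                length(library), sum(capacity))
  }
  if (!is.null(config$planted_hits)) {
    unknown <- setdiff(norm_symbol(config$planted_hits$gene),
                       norm_symbol(library$genes))
    if (length(unknown) > 0) {
      stop_format("planted_hits genes not in library: %s",
                  paste(utils::head(unknown, 5), collapse = ", "))
    }
  }

  # deterministic gene -> plate assignment by library order
  splits <- pmin(capacity, pmax(0L, length(library) - c(0L, cumsum(capacity))[seq_along(capacity)]))
  gene_chunks <- split(library$genes, rep(seq_along(capacity), times = splits))
  plates <- dplyr::bind_rows(lapply(seq_along(layout_spec), function(i) {
    genes <- if (as.character(i) %in% names(gene_chunks)) gene_chunks[[as.character(i)]] else character()
    assign_plate_wells(names(layout_spec)[i], layout_spec[[i]], genes)
  }))

  grid <- tidyr::expand_grid(
    arm = screen_arms(),
    replicate = seq_len(config$n_replicates)
  )
  wells <- tidyr::expand_grid(plates, grid)
  coord <- parse_well(wells$well)
  ord <- order(wells$plate_id, wells$arm, wells$replicate, coord$col, coord$row)
  wells <- wells[ord, ]

  # effect multipliers per well
  prolif <- rep(1, nrow(wells))
  odds <- rep(1, nrow(wells))
  base_p <- rep(config$gm_myog_fraction, nrow(wells))
  is_dmi <- wells$role == "DM_I_POS_CONTROL"
  base_p[is_dmi] <- config$dmi_myog_fraction
  prolif[is_dmi] <- prolif[is_dmi] * config$dmi_proliferation_multiplier
  is_kif <- wells$role == "KIF11_CONTROL"
  prolif[is_kif] <- prolif[is_kif] * config$kif11_proliferation_multiplier
  if (!is.null(config$planted_hits)) {
    idx <- match(norm_symbol(wells$target_gene),
                 norm_symbol(config$planted_hits$gene))
    hit <- !is.na(idx) & wells$role == "EXPERIMENTAL"
    odds[hit] <- odds[hit] * config$planted_hits$odds_multiplier[idx[hit]]
    prolif[hit] <- prolif[hit] * config$planted_hits$proliferation_multiplier[idx[hit]]
  }
  sens <- wells$arm == "sensitizer"
  prolif[sens] <- prolif[sens] * config$sensitizer_proliferation_multiplier
  odds[sens] <- odds[sens] * config$sensitizer_myog_shift

  logit_p <- stats::qlogis(base_p) + log(odds)
  log_mu <- log(config$gm_mean_nuclei_per_site) + log(prolif)
  if (!is.null(config$plate_effects)) {
    pe <- config$plate_effects
    row_i <- match(coord$row[ord], plate_rows())
    col_i <- coord$col[ord]
    if (!is.null(pe$row_logit)) logit_p <- logit_p + pe$row_logit[row_i]
    if (!is.null(pe$col_logit)) logit_p <- logit_p + pe$col_logit[col_i]
    if (!is.null(pe$row_log_nuclei)) log_mu <- log_mu + pe$row_log_nuclei[row_i]
    if (!is.null(pe$col_log_nuclei)) log_mu <- log_mu + pe$col_log_nuclei[col_i]
  }
  p_well <- stats::plogis(logit_p)
  mu_well <- exp(log_mu)

  n_sites <- config$n_sites_per_well
  sites <- wells[rep(seq_len(nrow(wells)), each = n_sites), ]
  sites$site_index <- rep(seq_len(n_sites), times = nrow(wells))
  mu <- rep(mu_well, each = n_sites)
  p <- rep(p_well, each = n_sites)

  set.seed(config$seed)
  total <- stats::rnbinom(length(mu), size = config$nuclei_dispersion, mu = mu)
  rho <- config$site_overdispersion
  if (rho > 0) {
    p_site <- stats::rbeta(length(p), shape1 = p * (1 - rho) / rho,
                           shape2 = (1 - p) * (1 - rho) / rho)
  } else {
    p_site <- p
  }
  pos <- stats::rbinom(length(total), size = total, prob = p_site)
  sites$total_nuclei <- as.integer(total)
  sites$myogenin_pos_nuclei <- as.integer(pos)

  dataset <- screen_dataset(
    sites[, screen_data_columns()],
    library,
    metadata = list(generator = "simulate_screen", seed = config$seed,
                    config = unclass(config))
  )

  lib_norm <- norm_symbol(library$genes)
  truth <- tibble::tibble(gene = library$genes, is_hit = FALSE,
                          odds_multiplier = 1, proliferation_multiplier = 1)
  if (!is.null(config$planted_hits)) {
    idx <- match(norm_symbol(config$planted_hits$gene), lib_norm)
    truth$odds_multiplier[idx] <- config$planted_hits$odds_multiplier
    truth$proliferation_multiplier[idx] <- config$planted_hits$proliferation_multiplier
    # a "true hit" in the screen's sense must increase the Myogenin odds
    truth$is_hit[idx] <- config$planted_hits$odds_multiplier > 1
  }
  list(dataset = dataset, truth = truth)
}

#' Compare called hits with planted ground truth
#'
#' @param calls hit table from [call_screen()] (columns `gene`, `arm`,
#'   `is_hit`), or a subset of its rows for one arm.
#' @param truth ground-truth tibble from [simulate_screen()].
#' @return tibble with one row per arm: TP/FP/TN/FN counts,
#'   sensitivity and specificity. Genes whose calls are incomplete
#'   (`is_hit` missing) are counted as not called.
#' @export
truth_recovery_report <- function(calls, truth) {
  calls <- tibble::as_tibble(calls)
  need <- c("gene", "arm", "is_hit")
  if (!all(need %in% names(calls))) {
    stop_format("calls needs columns: %s", paste(need, collapse = ", "))
  }
  universe_calls <- sort(unique(norm_symbol(calls$gene)))
  universe_truth <- sort(unique(norm_symbol(truth$gene)))
  if (!identical(universe_calls, universe_truth)) {
    stop_format("calls and truth cover different gene universes (%d vs %d genes)",
                length(universe_calls), length(universe_truth))
  }
  truth_hit <- truth$is_hit[match(norm_symbol(calls$gene), norm_symbol(truth$gene))]
  called <- !is.na(calls$is_hit) & calls$is_hit
  per_arm <- dplyr::group_by(tibble::tibble(arm = calls$arm, called = called,
                                            truth = truth_hit), .data$arm)
  dplyr::summarise(per_arm,
                   tp = sum(.data$called & .data$truth),
                   fp = sum(.data$called & !.data$truth),
                   tn = sum(!.data$called & !.data$truth),
                   fn = sum(!.data$called & .data$truth),
                   sensitivity = ifelse(.data$tp + .data$fn > 0,
                                        .data$tp / (.data$tp + .data$fn), NA_real_),
                   specificity = ifelse(.data$tn + .data$fp > 0,
                                        .data$tn / (.data$tn + .data$fp), NA_real_),
                   .groups = "drop")
}
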