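#' Hit-calling configuration
#'
#' Parameters of the two-criterion, replicate-aware hit-calling
#' procedure. A well scores positive when (a) its per-site Myogenin
#' fractions are significantly above the pooled GM reference fractions
#' by a pooled-variance Student's t-test (one-sided for an increase,
#' `p < alpha`, no multiple-testing correction across the library), and
#' (b) its mean nuclei count satisfies the cell-number criterion. A
#' kinase is a hit when enough replicate wells are positive: 2 of 3
#' in the vehicle arm, all 3 in the sensitizer arm. In the sensitizer
#' arm the cell-number criterion is disabled because the CDK4/6
#' inhibitor suppresses cell number in every well regardless of the
#' knockdown.
#'
#' The cell-number criterion exists in two dialects:
#' * `"methods"` (default) — well mean nuclei must fall at least one
#'   raw MAD below the GM reference median;
#' * `"results"` — well mean nuclei must lie within one raw MAD of the
#'   DM+I positive-control median.
#'
#' @param alpha per-well significance level (default 0.05).
#' @param replicate_rule_vehicle minimum positive replicates in the
#'   vehicle arm (default 2 of 3).
#' @param replicate_rule_sensitizer minimum positive replicates in the
#'   sensitizer arm (default 3 of 3).
#' @param cell_criterion_dialect `"methods"` or `"results"` (above).
#' @param cell_criterion_in_sensitizer apply the cell-number criterion
#'   in the sensitizer arm too (default `FALSE`).
#' @param t_test_unit `"sites"` (default): each well's site fractions
#'   are tested against the pooled GM site fractions, giving the
#'   well-level decisions the replicate rule needs. `"replicate_means"`:
#'   a single gene-level test of the replicate well percent values
#'   against GM well percent values; the Myogenin decision is then
#'   shared across that gene's replicates.
#' @param t_test_sided `"greater"` (one-sided increase, default) or
#'   `"two.sided"` (with an increase in means still required).
#' @param bh_correct apply Benjamini-Hochberg correction across wells
#'   before thresholding at `alpha` (off by default; the screen's
#'   procedure uses uncorrected per-well tests).
#' @param z_reference reference population for the reporting robust
#'   Z-score: `"experimental"` (default; all experimental wells of the
#'   plate and arm) or `"gm"` (GM control wells).
#' @return an object of class `hit_call_config`.
#' @export
hit_call_config <- function(alpha = 0.05,
                            replicate_rule_vehicle = 2L,
                            replicate_rule_sensitizer = 3L,
                            cell_criterion_dialect = c("methods", "results"),
                            cell_criterion_in_sensitizer = FALSE,
                            t_test_unit = c("sites", "replicate_means"),
                            t_test_sided = c("greater", "two.sided"),
                            bh_correct = FALSE,
                            z_reference = c("experimental", "gm")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_format("alpha must lie strictly in (0, 1)")
  }
  stopifnot(is_count(replicate_rule_vehicle), replicate_rule_vehicle >= 1,
            is_count(replicate_rule_sensitizer), replicate_rule_sensitizer >= 1)
  structure(list(
    alpha = alpha,
    replicate_rule_vehicle = as.integer(replicate_rule_vehicle),
    replicate_rule_sensitizer = as.integer(replicate_rule_sensitizer),
    cell_criterion_dialect = match.arg(cell_criterion_dialect),
    cell_criterion_in_sensitizer = isTRUE(cell_criterion_in_sensitizer),
    t_test_unit = match.arg(t_test_unit),
    t_test_sided = match.arg(t_test_sided),
    bh_correct = isTRUE(bh_correct),
    z_reference = match.arg(z_reference)
  ), class = "hit_call_config")
}

replicate_rule <- function(config, arm) {
  if (arm == "sensitizer") config$replicate_rule_sensitizer
  else config$replicate_rule_vehicle
}

cell_criterion_active <- function(config, arm) {
  arm != "sensitizer" || config$cell_criterion_in_sensitizer
}

# Pooled-variance Student's t p-value with well-defined degenerate
# limits: both samples constant and equal -> 1; constant and different
# -> 0 in the favourable direction (1 otherwise for one-sided).
pooled_t_p <- function(x, y, alternative = "greater") {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(1)
    if (alternative == "two.sided") return(0)
    return(if (d > 0) 0 else 1)
  }
  stats::t.test(x, y, alternative = alternative, var.equal = TRUE)$p.value
}

cell_criterion_met <- function(mean_nuclei, ref_mean_nuclei, dmi_mean_nuclei,
                               dialect) {
  if (dialect == "methods") {
    threshold <- stats::median(ref_mean_nuclei) - mad_raw(ref_mean_nuclei)
    mean_nuclei <= threshold
  } else {
    if (is.null(dmi_mean_nuclei) || length(dmi_mean_nuclei) < 1) {
      stop_format("'results' cell-criterion dialect needs DM+I reference wells")
    }
    abs(mean_nuclei - stats::median(dmi_mean_nuclei)) <= mad_raw(dmi_mean_nuclei)
  }
}

#' Score one well against its GM reference
#'
#' The elementary positivity decision. The Myogenin criterion tests the
#' well's per-site Myogenin fractions against the pooled per-site
#' fractions of the same plate's GM control wells; the cell-number
#' criterion compares the well's mean nuclei count with the reference
#' per the configured dialect. `well_positive` is the conjunction,
#' with the cell criterion dropped in the sensitizer arm (by default).
#'
#' @param site_fractions the well's per-site Myogenin fractions
#'   (empty sites excluded).
#' @param mean_nuclei the well's mean nuclei per site.
#' @param ref_site_fractions pooled GM per-site fractions.
#' @param ref_mean_nuclei per-well mean nuclei of the GM reference
#'   wells.
#' @param config a [hit_call_config()].
#' @param arm `"vehicle"` or `"sensitizer"`.
#' @param dmi_mean_nuclei per-well mean nuclei of the DM+I controls
#'   (needed only for the `"results"` dialect).
#' @return one-row tibble: `p_value`, `myog_positive`, `cell_positive`,
#'   `well_positive`, `insufficient_data`. Wells with fewer than two
#'   usable site fractions on either side are scored not-positive with
#'   `insufficient_data = TRUE`.
#' @export
score_well <- function(site_fractions, mean_nuclei, ref_site_fractions,
                       ref_mean_nuclei, config = hit_call_config(),
                       arm = "vehicle", dmi_mean_nuclei = NULL) {
  stopifnot(arm %in% screen_arms())
  insufficient <- length(site_fractions) < 2 || length(ref_site_fractions) < 2
  if (insufficient) {
    p <- NA_real_
    myog <- FALSE
  } else {
    p <- pooled_t_p(site_fractions, ref_site_fractions, config$t_test_sided)
    increase <- mean(site_fractions) > mean(ref_site_fractions)
    myog <- !is.na(p) && p < config$alpha &&
      (config$t_test_sided == "greater" || increase)
  }
  cell <- cell_criterion_met(mean_nuclei, ref_mean_nuclei, dmi_mean_nuclei,
                             config$cell_criterion_dialect)
  positive <- myog && (!cell_criterion_active(config, arm) || cell)
  tibble::tibble(p_value = p, myog_positive = myog, cell_positive = cell,
                 well_positive = positive, insufficient_data = insufficient)
}

#' Score every experimental well of a dataset
#'
#' Runs [score_well()] for each experimental well against the GM
#' control wells of the same physical plate (same library plate, arm
#' and replicate). With `t_test_unit = "replicate_means"` the Myogenin
#' decision is made once per gene (replicate well percent values vs GM
#' well percent values) and shared across that gene's wells, while the
#' cell criterion stays per-well.
#'
#' @param dataset a [screen_dataset()].
#' @param config a [hit_call_config()].
#' @return tibble with one row per experimental well: identifiers plus
#'   `percent_myogenin`, `mean_nuclei`, `p_value`, `myog_positive`,
#'   `cell_positive`, `well_positive`, `insufficient_data`.
#' @export
score_wells <- function(dataset, config = hit_call_config()) {
  stopifnot(inherits(dataset, "screen_dataset"),
            inherits(config, "hit_call_config"))
  ws <- summarize_wells(dataset)
  fr <- site_fraction_table(dataset)
  exp_ws <- ws[ws$role == "EXPERIMENTAL", ]
  if (nrow(exp_ws) == 0) {
    stop_format("dataset has no experimental wells to score")
  }
  plates <- dplyr::distinct(exp_ws, .data$plate_id, .data$arm, .data$replicate)
  out <- vector("list", nrow(plates))
  for (i in seq_len(nrow(plates))) {
    pid <- plates$plate_id[i]; arm <- plates$arm[i]; rep_i <- plates$replicate[i]
    on_plate <- ws$plate_id == pid & ws$arm == arm & ws$replicate == rep_i
    gm <- ws[on_plate & ws$role == "GM_NEG_CONTROL" & ws$summarizable, ]
    if (nrow(gm) < 2) {
      stop_format("plate %s (%s, replicate %d) has < 2 usable GM reference wells",
                  pid, arm, rep_i)
    }
    dmi <- ws[on_plate & ws$role == "DM_I_POS_CONTROL" & ws$summarizable, ]
    fr_sel <- fr[fr$plate_id == pid & fr$arm == arm & fr$replicate == rep_i, ]
    gm_fracs <- fr_sel$fraction[fr_sel$well %in% gm$well]
    wells <- exp_ws[exp_ws$plate_id == pid & exp_ws$arm == arm &
                      exp_ws$replicate == rep_i, ]
    frac_by_well <- split(fr_sel$fraction, fr_sel$well)
    scores <- lapply(seq_len(nrow(wells)), function(j) {
      score_well(frac_by_well[[wells$well[j]]] %||% numeric(),
                 wells$mean_nuclei[j], gm_fracs, gm$mean_nuclei,
                 config = config, arm = arm,
                 dmi_mean_nuclei = if (nrow(dmi) > 0) dmi$mean_nuclei)
    })
    out[[i]] <- dplyr::bind_cols(
      wells[, c("plate_id", "well", "arm", "replicate", "target_gene",
                "percent_myogenin", "mean_nuclei")],
      dplyr::bind_rows(scores)
    )
  }
  scores <- dplyr::bind_rows(out)
  names(scores)[names(scores) == "target_gene"] <- "gene"
  if (config$t_test_unit == "replicate_means") {
    scores <- gene_level_myog_rescore(scores, ws, config)
  }
  if (config$bh_correct) {
    q <- bh_adjust(ifelse(is.na(scores$p_value), 1, scores$p_value))
    scores$myog_positive <- scores$myog_positive & q < config$alpha
    active <- vapply(scores$arm, cell_criterion_active, logical(1),
                     config = config)
    scores$well_positive <- scores$myog_positive &
      (!active | scores$cell_positive)
  }
  dplyr::arrange(scores, .data$plate_id, .data$arm, .data$replicate, .data$well)
}

# gene-level Myogenin test: the gene's replicate well percents against
# the GM well percents of the same plate and arm, shared across wells
gene_level_myog_rescore <- function(scores, ws, config) {
  genes <- dplyr::distinct(scores, .data$plate_id, .data$arm, .data$gene)
  for (i in seq_len(nrow(genes))) {
    sel <- scores$plate_id == genes$plate_id[i] & scores$arm == genes$arm[i] &
      scores$gene == genes$gene[i]
    gm <- ws[ws$plate_id == genes$plate_id[i] & ws$arm == genes$arm[i] &
               ws$role == "GM_NEG_CONTROL" & ws$summarizable, ]
    x <- scores$percent_myogenin[sel]
    p <- pooled_t_p(x[!is.na(x)], gm$percent_myogenin, config$t_test_sided)
    myog <- !is.na(p) && p < config$alpha &&
      (config$t_test_sided == "greater" ||
         mean(x, na.rm = TRUE) > mean(gm$percent_myogenin))
    scores$p_value[sel] <- p
    scores$myog_positive[sel] <- myog
  }
  active <- vapply(scores$arm, cell_criterion_active, logical(1), config = config)
  scores$well_positive <- scores$myog_positive & (!active | scores$cell_positive)
  scores
}

#' Aggregate one gene's replicate well scores into a kinase call
#'
#' @param well_scores tibble of [score_wells()] rows for a single gene
#'   and arm, one per replicate.
#' @param config a [hit_call_config()].
#' @param n_replicates expected replicate count (default 3).
#' @return one-row tibble: `gene`, `arm`, `n_positive_replicates`,
#'   `n_replicates_scored`, `is_hit`, `min_p`.
#' @export
call_kinase <- function(well_scores, config = hit_call_config(),
                        n_replicates = 3L) {
  well_scores <- tibble::as_tibble(well_scores)
  if (length(unique(well_scores$gene)) != 1 ||
      length(unique(well_scores$arm)) != 1) {
    stop_format("call_kinase expects scores for exactly one gene and arm")
  }
  if (nrow(well_scores) != n_replicates) {
    stop_format("gene %s (%s): expected %d replicate scores, got %d",
                well_scores$gene[1], well_scores$arm[1], n_replicates,
                nrow(well_scores))
  }
  arm <- well_scores$arm[1]
  n_pos <- sum(well_scores$well_positive)
  tibble::tibble(
    gene = well_scores$gene[1], arm = arm,
    n_positive_replicates = n_pos,
    n_replicates_scored = nrow(well_scores),
    is_hit = n_pos >= replicate_rule(config, arm),
    min_p = if (all(is.na(well_scores$p_value))) NA_real_
            else min(well_scores$p_value, na.rm = TRUE)
  )
}

#' Call hits across the whole screen
#'
#' Scores every experimental well, aggregates replicate decisions per
#' gene and arm under the replicate rule, and attaches the reporting
#' robust Z-score of each kinase's mean percent Myogenin against its
#' plate's robust scale. Genes with missing or extra replicate wells
#' are flagged `incomplete` and receive `is_hit = NA`; the reporting
#' Z-score never gates hit status.
#'
#' @param dataset a [screen_dataset()].
#' @param config a [hit_call_config()].
#' @return tibble with one row per (library gene, arm): `gene`, `arm`,
#'   `plate_id`, `n_positive_replicates`, `n_replicates_scored`,
#'   `is_hit`, `min_p`, `kinase_z`, `incomplete`. Deterministic given
#'   `(dataset, config)` and invariant to input row order.
#' @export
call_screen <- function(dataset, config = hit_call_config()) {
  scores <- score_wells(dataset, config)
  n_rep <- max(scores$replicate)
  grouped <- dplyr::group_by(scores, .data$gene, .data$arm)
  calls <- dplyr::summarise(
    grouped,
    plate_id = .data$plate_id[1],
    n_positive_replicates = sum(.data$well_positive),
    n_replicates_scored = dplyr::n(),
    mean_percent_myogenin = mean(.data$percent_myogenin, na.rm = TRUE),
    min_p = if (all(is.na(.data$p_value))) NA_real_
            else min(.data$p_value, na.rm = TRUE),
    n_plates = dplyr::n_distinct(.data$plate_id),
    .groups = "drop"
  )
  calls$incomplete <- calls$n_replicates_scored != n_rep | calls$n_plates > 1
  calls$is_hit <- ifelse(
    calls$incomplete, NA,
    calls$n_positive_replicates >=
      vapply(calls$arm, replicate_rule, integer(1), config = config)
  )

  # library genes absent from the data: incomplete by definition
  lib_norm <- norm_symbol(dataset$library$genes)
  seen <- unique(norm_symbol(calls$gene))
  absent <- dataset$library$genes[!lib_norm %in% seen]
  if (length(absent) > 0) {
    calls <- dplyr::bind_rows(calls, tidyr::expand_grid(
      gene = absent, arm = screen_arms()[screen_arms() %in% unique(scores$arm)]
    ))
    calls$incomplete[is.na(calls$n_replicates_scored)] <- TRUE
  }

  # reporting robust Z of per-kinase mean percent Myogenin
  calls$kinase_z <- NA_real_
  ws <- summarize_wells(dataset)
  ref_role <- if (config$z_reference == "gm") "GM_NEG_CONTROL" else "EXPERIMENTAL"
  refs <- dplyr::distinct(calls[!is.na(calls$plate_id), ], .data$plate_id, .data$arm)
  for (i in seq_len(nrow(refs))) {
    ref_vals <- ws$percent_myogenin[ws$plate_id == refs$plate_id[i] &
                                      ws$arm == refs$arm[i] &
                                      ws$role == ref_role & ws$summarizable]
    sel <- which(calls$plate_id %in% refs$plate_id[i] & calls$arm == refs$arm[i])
    if (length(unique(ref_vals)) >= 2) {
      rs <- robust_scale(ref_vals)
      if (rs$scale > 0) {
        calls$kinase_z[sel] <- (calls$mean_percent_myogenin[sel] - rs$center) /
          rs$scale
      }
    }
  }
  calls <- calls[, c("gene", "arm", "plate_id", "n_positive_replicates",
                     "n_replicates_scored", "is_hit", "min_p", "kinase_z",
                     "incomplete")]
  dplyr::arrange(calls, .data$arm, .data$gene)
}

#' Cross-arm hit comparison
#'
#' Set algebra over the vehicle and sensitizer hit sets: double hits
#' (intersection), the union, and percentage rates relative to the
#' library size, reported to one decimal place.
#'
#' @param calls_vehicle,calls_sensitizer call tables from
#'   [call_screen()] (rows of one arm each), or bare character vectors
#'   of hit gene symbols.
#' @param library_size number of genes screened.
#' @return object of class `hit_comparison`: hit sets, `counts`
#'   (named: vehicle, sensitizer, double, union) and `rates_percent`
#'   (same names, 100 x count / library_size, one decimal).
#' @export
compare_arms <- function(calls_vehicle, calls_sensitizer, library_size) {
  stopifnot(is_count(library_size), library_size >= 1)
  extract <- function(x, arm) {
    if (is.character(x)) return(unique(norm_symbol(x)))
    x <- tibble::as_tibble(x)
    if ("arm" %in% names(x)) x <- x[x$arm == arm, ]
    unique(norm_symbol(x$gene[!is.na(x$is_hit) & x$is_hit]))
  }
  universe <- function(x) {
    if (is.character(x)) NULL else sort(unique(norm_symbol(tibble::as_tibble(x)$gene)))
  }
  uv <- universe(calls_vehicle); us <- universe(calls_sensitizer)
  if (!is.null(uv) && !is.null(us) && !identical(uv, us)) {
    stop_format("vehicle and sensitizer call tables cover different gene universes")
  }
  hits_v <- extract(calls_vehicle, "vehicle")
  hits_s <- extract(calls_sensitizer, "sensitizer")
  double <- intersect(hits_v, hits_s)
  union_ <- union(hits_v, hits_s)
  counts <- c(vehicle = length(hits_v), sensitizer = length(hits_s),
              double = length(double), union = length(union_))
  structure(list(
    hits_vehicle = sort(hits_v), hits_sensitizer = sort(hits_s),
    double_hits = sort(double), union_hits = sort(union_),
    library_size = as.integer(library_size),
    counts = counts,
    rates_percent = round(100 * counts / library_size, 1)
  ), class = "hit_comparison")
}

#' @export
print.hit_comparison <- function(x, ...) {
  cat(sprintf(paste0("<hit_comparison> library %d genes\n",
                     "  vehicle hits:    %d (%.1f%%)\n",
                     "  sensitizer hits: %d (%.1f%%)\n",
                     "  double hits:     %d\n",
                     "  union:           %d (%.1f%%)\n"),
              x$library_size,
              x$counts["vehicle"], x$rates_percent["vehicle"],
              x$counts["sensitizer"], x$rates_percent["sensitizer"],
              x$counts["double"],
              x$counts["union"], x$rates_percent["union"]))
  invisible(x)
}

#' Wells and genes meeting only the cell-number criterion
#'
#' Cell-cycle arrest alone does not start the differentiation program:
#' many knockdowns deplete cells without raising Myogenin. This report
#' isolates them — wells whose mean nuclei count satisfies the
#' cell-number criterion while the Myogenin criterion fails, and genes
#' for which that dissociation holds at the replicate rule without the
#' gene ever being a hit. The cell criterion is evaluated in both arms
#' here (even where hit calling disables it) because the dissociation
#' is a biological observation, not a hit rule.
#'
#' @param dataset a [screen_dataset()].
#' @param config a [hit_call_config()].
#' @return list: `wells` (per-well rows with `cell_positive` and not
#'   `myog_positive`), `genes` (tibble gene/arm meeting the replicate
#'   rule on cell-only wells and absent from the hit set),
#'   `well_counts` (tibble arm / n_cell_only_wells).
#' @export
cell_number_only_report <- function(dataset, config = hit_call_config()) {
  scores <- score_wells(dataset, config)
  calls <- call_screen(dataset, config)
  hits <- calls[!is.na(calls$is_hit) & calls$is_hit, c("gene", "arm")]
  cell_only <- scores[scores$cell_positive & !scores$myog_positive, ]
  grouped <- dplyr::group_by(scores, .data$gene, .data$arm)
  gene_tbl <- dplyr::summarise(grouped,
                               n_cell_only = sum(.data$cell_positive &
                                                   !.data$myog_positive),
                               .groups = "drop")
  gene_tbl <- gene_tbl[gene_tbl$n_cell_only >=
                         vapply(gene_tbl$arm, replicate_rule, integer(1),
                                config = config), ]
  gene_tbl <- dplyr::anti_join(gene_tbl, hits, by = c("gene", "arm"))
  counts <- dplyr::count(cell_only, .data$arm, name = "n_cell_only_wells")
  list(wells = cell_only,
       genes = dplyr::arrange(gene_tbl, .data$arm, .data$gene),
       well_counts = counts)
}
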