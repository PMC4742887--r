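#' Summarize one well from its site counts
#'
#' The well's readout is the percentage of Myogenin-positive nuclei
#' pooled over its imaged sites: `100 * sum(pos) / sum(total)`.
#' Pooling counts weights each site by its cell content, which is less
#' noisy than averaging per-site fractions when wells are sparse;
#' the per-site fractions are returned as well because the positivity
#' t-test operates on them. Sites with zero nuclei contribute no
#' fraction but still enter `mean_nuclei`.
#'
#' @param total_nuclei integer vector of per-site total nuclei.
#' @param myogenin_pos_nuclei integer vector of per-site positive
#'   nuclei, same length.
#' @return list: `percent_myogenin`, `site_fractions` (non-empty sites
#'   only), `mean_nuclei`, `n_sites`, `n_sites_used`, `summarizable`
#'   (FALSE when every site is empty; such wells are excluded from
#'   fraction-based statistics downstream).
#' @export
summarize_well <- function(total_nuclei, myogenin_pos_nuclei) {
  stopifnot(length(total_nuclei) == length(myogenin_pos_nuclei),
            length(total_nuclei) >= 1)
  if (any(myogenin_pos_nuclei > total_nuclei)) {
    stop_format("myogenin_pos_nuclei exceeds total_nuclei in a site")
  }
  nonempty <- total_nuclei > 0
  pooled_total <- sum(total_nuclei)
  list(
    percent_myogenin = if (pooled_total > 0)
      100 * sum(myogenin_pos_nuclei) / pooled_total else NA_real_,
    site_fractions = myogenin_pos_nuclei[nonempty] / total_nuclei[nonempty],
    mean_nuclei = mean(total_nuclei),
    n_sites = length(total_nuclei),
    n_sites_used = sum(nonempty),
    summarizable = any(nonempty)
  )
}

#' Per-well summary table for a whole dataset
#'
#' @param dataset a [screen_dataset()].
#' @return tibble with one row per well: `plate_id`, `well`, `role`,
#'   `target_gene`, `arm`, `replicate`, `n_sites`, `n_sites_used`,
#'   `percent_myogenin`, `mean_nuclei`, `summarizable`.
#' @export
summarize_wells <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  grouped <- dplyr::group_by(dataset$data, .data$plate_id, .data$well,
                             .data$role, .data$target_gene, .data$arm,
                             .data$replicate)
  out <- dplyr::summarise(
    grouped,
    n_sites = dplyr::n(),
    n_sites_used = sum(.data$total_nuclei > 0),
    percent_myogenin = ifelse(sum(.data$total_nuclei) > 0,
                              100 * sum(.data$myogenin_pos_nuclei) /
                                sum(.data$total_nuclei), NA_real_),
    mean_nuclei = mean(.data$total_nuclei),
    .groups = "drop"
  )
  out$summarizable <- out$n_sites_used > 0
  dplyr::arrange(out, .data$plate_id, .data$arm, .data$replicate, .data$well)
}

#' Median absolute deviation, unscaled
#'
#' The raw MAD: the median of absolute deviations from the median,
#' without the 1.4826 normal-consistency factor. This raw form is the
#' unit of the cell-number hit criterion; the scaled form lives inside
#' [robust_z()].
#'
#' @param values numeric vector, at least one value.
#' @return non-negative scalar.
#' @export
mad_raw <- function(values) {
  if (length(values) < 1 || anyNA(values)) {
    stop_format("mad_raw needs at least one non-missing value")
  }
  stats::mad(values, constant = 1)
}

#' Robust scale of a reference population
#'
#' @param reference numeric vector with at least two distinct values.
#' @return list with `center` (median) and `scale`
#'   (1.4826 x raw MAD).
#' @export
robust_scale <- function(reference) {
  if (length(unique(reference)) < 2) {
    stop_format("robust scale needs a reference with >= 2 distinct values")
  }
  list(center = stats::median(reference), scale = stats::mad(reference))
}

#' Robust Z-scores against a reference population
#'
#' `z = (x - median(ref)) / (1.4826 * mad(ref))`, the outlier-resistant
#' analogue of the Z-score used to normalize plate-based screening
#' data. Affine-invariant: rescaling or shifting values and reference
#' together leaves the scores unchanged.
#'
#' @param values numeric vector to score.
#' @param reference numeric reference population (>= 2 distinct
#'   values).
#' @param epsilon optional fallback scale used when the reference MAD
#'   is zero; the default (`NULL`) raises a degenerate-scale error
#'   instead.
#' @return numeric vector of robust Z-scores, one per value.
#' @export
robust_z <- function(values, reference, epsilon = NULL) {
  rs <- robust_scale(reference)
  if (rs$scale == 0) {
    if (is.null(epsilon)) {
      stop_format("degenerate robust scale: reference MAD is zero")
    }
    rs$scale <- epsilon
  }
  (values - rs$center) / rs$scale
}

#' Z-factor assay-window statistic
#'
#' `1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' (n-1) standard deviations. Values above ~0.5 indicate a screening
#' window wide enough to separate positive and negative controls;
#' the statistic is at most 1 and symmetric in the two groups.
#'
#' @param positive_values numeric vector of positive-control readouts
#'   (>= 2 values).
#' @param negative_values numeric vector of negative-control readouts
#'   (>= 2 values).
#' @return scalar Z-factor (<= 1).
#' @export
z_factor <- function(positive_values, negative_values) {
  if (length(positive_values) < 2 || length(negative_values) < 2) {
    stop_format("z_factor needs >= 2 values in each control group")
  }
  mu_p <- mean(positive_values)
  mu_n <- mean(negative_values)
  if (mu_p == mu_n) {
    stop_format("z_factor undefined: control group means are equal")
  }
  1 - 3 * (stats::sd(positive_values) + stats::sd(negative_values)) / abs(mu_p - mu_n)
}

#' Score control wells with the hit-calling criteria
#'
#' Applies the per-well positivity criteria to the plate controls: each
#' DM+I positive-control well and each GM negative-control well is
#' scored exactly like an experimental well against the GM wells of its
#' own physical plate (GM wells are scored leave-one-out so a well is
#' never its own reference). The fraction of positive controls scoring
#' positive measures assay sensitivity; negative controls scoring
#' positive measure the false-call floor.
#'
#' @param dataset a [screen_dataset()].
#' @param config a [hit_call_config()].
#' @return tibble with one row per arm: `n_positive_wells`,
#'   `positive_scoring_fraction`, `n_negative_wells`,
#'   `negative_scoring_fraction`.
#' @export
score_controls <- function(dataset, config = hit_call_config()) {
  stopifnot(inherits(dataset, "screen_dataset"))
  ws <- summarize_wells(dataset)
  if (!any(ws$role == "GM_NEG_CONTROL") || !any(ws$role == "DM_I_POS_CONTROL")) {
    stop_format("dataset has no GM / DM+I control wells to score")
  }
  fr <- site_fraction_table(dataset)
  plates <- dplyr::distinct(ws, .data$plate_id, .data$arm, .data$replicate)
  res <- vector("list", nrow(plates))
  for (i in seq_len(nrow(plates))) {
    sel <- ws$plate_id == plates$plate_id[i] & ws$arm == plates$arm[i] &
      ws$replicate == plates$replicate[i]
    plate_ws <- ws[sel, ]
    gm <- plate_ws[plate_ws$role == "GM_NEG_CONTROL" & plate_ws$summarizable, ]
    dmi <- plate_ws[plate_ws$role == "DM_I_POS_CONTROL" & plate_ws$summarizable, ]
    gm_fr <- fraction_lookup(fr, plates$plate_id[i], plates$arm[i],
                             plates$replicate[i], gm$well)
    dmi_ref_means <- dmi$mean_nuclei
    score_one <- function(well_row, ref_wells, ref_fracs) {
      well_fr <- fraction_lookup(fr, plates$plate_id[i], plates$arm[i],
                                 plates$replicate[i], well_row$well)[[1]]
      s <- score_well(well_fr, well_row$mean_nuclei,
                      unlist(ref_fracs), ref_wells$mean_nuclei,
                      config = config, arm = plates$arm[i],
                      dmi_mean_nuclei = dmi_ref_means)
      s$well_positive
    }
    pos_hits <- vapply(seq_len(nrow(dmi)), function(j) {
      score_one(dmi[j, ], gm, gm_fr)
    }, logical(1))
    neg_hits <- vapply(seq_len(nrow(gm)), function(j) {
      score_one(gm[j, ], gm[-j, ], gm_fr[-j])
    }, logical(1))
    res[[i]] <- tibble::tibble(arm = plates$arm[i],
                               n_pos = nrow(dmi), pos_scoring = sum(pos_hits),
                               n_neg = nrow(gm), neg_scoring = sum(neg_hits))
  }
  per_arm <- dplyr::group_by(dplyr::bind_rows(res), .data$arm)
  dplyr::summarise(per_arm,
                   n_positive_wells = sum(.data$n_pos),
                   positive_scoring_fraction = sum(.data$pos_scoring) / sum(.data$n_pos),
                   n_negative_wells = sum(.data$n_neg),
                   negative_scoring_fraction = sum(.data$neg_scoring) / sum(.data$n_neg),
                   .groups = "drop")
}

#' Assay-window QC report
#'
#' Per library plate and arm, the Z-factor of the Myogenin window
#' (DM+I positive controls vs GM negative controls, on well-level
#' percent Myogenin pooled over replicates) and of the cell-number
#' window, plus the control-scoring fractions of [score_controls()].
#'
#' @param dataset a [screen_dataset()].
#' @param config a [hit_call_config()] used for control scoring.
#' @return list with `z_factors` (tibble: plate_id, arm,
#'   z_factor_myogenin, z_factor_nuclei, n_pos_wells, n_neg_wells) and
#'   `control_scoring` (tibble from [score_controls()]).
#' @export
qc_report <- function(dataset, config = hit_call_config()) {
  ws <- summarize_wells(dataset)
  ws <- ws[ws$summarizable, ]
  groups <- dplyr::distinct(ws, .data$plate_id, .data$arm)
  zrows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- ws$plate_id == groups$plate_id[i] & ws$arm == groups$arm[i]
    gm <- ws[sel & ws$role == "GM_NEG_CONTROL", ]
    dmi <- ws[sel & ws$role == "DM_I_POS_CONTROL", ]
    tibble::tibble(
      plate_id = groups$plate_id[i], arm = groups$arm[i],
      z_factor_myogenin = if (nrow(gm) >= 2 && nrow(dmi) >= 2)
        z_factor(dmi$percent_myogenin, gm$percent_myogenin) else NA_real_,
      z_factor_nuclei = if (nrow(gm) >= 2 && nrow(dmi) >= 2)
        z_factor(dmi$mean_nuclei, gm$mean_nuclei) else NA_real_,
      n_pos_wells = nrow(dmi), n_neg_wells = nrow(gm)
    )
  })
  list(z_factors = dplyr::bind_rows(zrows),
       control_scoring = score_controls(dataset, config))
}

# site fractions keyed by (plate, arm, replicate, well); empty sites dropped
site_fraction_table <- function(dataset) {
  d <- dataset$data[dataset$data$total_nuclei > 0, ]
  d$fraction <- d$myogenin_pos_nuclei / d$total_nuclei
  d[, c("plate_id", "arm", "replicate", "well", "fraction")]
}

fraction_lookup <- function(fr, plate_id, arm, replicate, wells) {
  sel <- fr$plate_id == plate_id & fr$arm == arm & fr$replicate == replicate
  sub <- fr[sel, ]
  lapply(wells, function(w) sub$fraction[sub$well == w])
}
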