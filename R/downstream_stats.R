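#' Relative expression by the delta-delta-Ct method
#'
#' Classic qRT-PCR relative quantification with amplification efficiency
#' fixed at 2: per sample, `dCt = Ct_target - Ct_control`; per strain,
#' `ddCt = mean(dCt) - mean(dCt_reference)`; fold change = `2^-ddCt`,
#' normalized so the reference strain is 1.
#'
#' @param data Tidy Ct table with columns `strain`, `gene_id`, `replicate`,
#'   `ct` (cycles, > 0).
#' @param gene Target gene id.
#' @param control_gene Control (housekeeping) gene id, present in every
#'   sample.
#' @param reference_strain Strain against which fold changes are expressed.
#' @return Tibble with one row per strain: `strain`, `n_replicates`,
#'   `mean_delta_ct`, `fold_change`.
#' @export
relative_expression <- function(data, gene, control_gene, reference_strain) {
  data <- as_tibble(data)
  stopifnot(all(c("strain", "gene_id", "replicate", "ct") %in% names(data)),
            all(data$ct > 0))
  target <- data[data$gene_id == gene, ]
  control <- data[data$gene_id == control_gene, ]
  if (nrow(control) == 0L) {
    stop("control gene '", control_gene, "' absent from Ct table",
         call. = FALSE)
  }
  if (nrow(target) == 0L) {
    stop("target gene '", gene, "' absent from Ct table", call. = FALSE)
  }
  dct <- dplyr::inner_join(
    dplyr::select(target, "strain", "replicate", ct_target = "ct"),
    dplyr::select(control, "strain", "replicate", ct_control = "ct"),
    by = c("strain", "replicate"))
  if (!reference_strain %in% dct$strain) {
    stop("reference strain '", reference_strain, "' absent", call. = FALSE)
  }
  per_strain <- dct |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_control) |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_delta_ct = mean(.data$delta_ct), .groups = "drop")
  ref <- per_strain$mean_delta_ct[per_strain$strain == reference_strain]
  per_strain$fold_change <- 2^(-(per_strain$mean_delta_ct - ref))
  per_strain
}

#' Enzyme activity in units per millilitre
#'
#' One unit is the amount of enzyme producing 1 umol of product (glucose,
#' xylose or p-nitrophenol depending on the assay) per minute:
#' `U/mL = product_umol / reaction_minutes / enzyme_volume_ml * dilution_factor`.
#'
#' @param product_umol Product formed, umol.
#' @param reaction_minutes Reaction time, min.
#' @param enzyme_volume_ml Enzyme solution volume in the reaction, mL.
#' @param dilution_factor Dilution of the enzyme solution (>= 1).
#' @return Activity in U/mL (vectorized).
#' @export
enzyme_units <- function(product_umol, reaction_minutes, enzyme_volume_ml,
                         dilution_factor = 1) {
  if (any(reaction_minutes <= 0) || any(enzyme_volume_ml <= 0)) {
    stop("reaction time and enzyme volume must be positive", call. = FALSE)
  }
  stopifnot(all(product_umol >= 0), all(dilution_factor >= 1))
  product_umol / reaction_minutes / enzyme_volume_ml * dilution_factor
}

#' Percent change with a two-tailed two-sample t-test
#'
#' Percent change of group B relative to group A,
#' `(mean_B - mean_A) / mean_A * 100`, with a classic pooled-variance
#' Student t-test (Welch available via `var_equal = FALSE`). Degenerate
#' zero-variance inputs are handled explicitly: equal means give `t = 0,
#' p = 1`; unequal means give a p-value at the smallest representable
#' double, flagged in the `degenerate` column.
#'
#' @param group_a,group_b Numeric replicate vectors (>= 2 values each).
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return One-row tibble: `percent_change`, `t`, `df`, `p_value`,
#'   `degenerate`.
#' @export
percent_change_test <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  pct <- (mean(group_b) - mean(group_a)) / mean(group_a) * 100
  pooled_var <- ((length(group_a) - 1) * stats::var(group_a) +
                   (length(group_b) - 1) * stats::var(group_b)) /
    (length(group_a) + length(group_b) - 2)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(percent_change = pct, t = 0,
                    df = length(group_a) + length(group_b) - 2L,
                    p_value = 1, degenerate = FALSE))
    }
    return(tibble(percent_change = pct, t = Inf * sign(mean(group_a) -
                                                         mean(group_b)),
                  df = length(group_a) + length(group_b) - 2L,
                  p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble(percent_change = pct, t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE)
}

#' Dry biomass from intracellular protein
#'
#' Converts a measured intracellular protein concentration to dry cell mass
#' assuming a fixed protein content per gram of dry biomass (default
#' 0.28 g/g).
#'
#' @param protein_g_per_l Protein concentration, g/L (>= 0).
#' @param protein_per_dry_mass Protein per dry mass, g/g, in (0, 1].
#' @return Dry weight, g/L (vectorized).
#' @export
biomass_from_protein <- function(protein_g_per_l, protein_per_dry_mass = 0.28) {
  stopifnot(all(protein_g_per_l >= 0),
            protein_per_dry_mass > 0, protein_per_dry_mass <= 1)
  protein_g_per_l / protein_per_dry_mass
}
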