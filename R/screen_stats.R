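#' Viability filter for screen treatments
#'
#' A treatment is discarded for lack of viability if any of its wells has
#' fewer than \code{min_per_well} analyzed cells, or if the total across
#' its replicate wells is below \code{min_total} ("less than" is strict:
#' exactly 50 per well and 150 in total passes).
#'
#' @param wells WellRecord data.frame with \code{treatment_id} and
#'   \code{n_cells_analyzed}.
#' @param min_per_well per-well minimum cell count (default 50).
#' @param min_total minimum total over the replicates (default 150).
#' @return data.frame: \code{treatment_id}, \code{total_cells},
#'   \code{min_well_cells}, \code{viable}.
#' @examples
#' w <- data.frame(treatment_id = "t", n_cells_analyzed = c(49, 80, 80))
#' viability_filter(w)$viable   # FALSE: one well below 50
#' @export
viability_filter <- function(wells, min_per_well = 50, min_total = 150) {
  stopifnot("n_cells_analyzed" %in% names(wells))
  sp <- split(wells$n_cells_analyzed, wells$treatment_id)
  out <- data.frame(
    treatment_id = names(sp),
    total_cells = vapply(sp, sum, 0),
    min_well_cells = vapply(sp, min, 0))
  out$viable <- out$min_well_cells >= min_per_well &
    out$total_cells >= min_total
  rownames(out) <- NULL
  out
}

#' Normalize well ratios to the negative control
#'
#' Divides every well's LAMP1-associated NP ratio by the mean ratio of the
#' non-targeting (NEG) wells of its normalization scope. The default scope
#' is per plate and replicate, so plate- and replicate-wide effects cancel.
#' Control statistics (mean and SD of the normalized NEG wells, pooled
#' across the screen) are returned for phenotype calling; by construction
#' the normalized NEG mean is 1 within every scope.
#'
#' @param wells WellRecord data.frame with \code{lamp1_np_ratio} and
#'   \code{is_negative_control}.
#' @param scope \code{"plate_replicate"}, \code{"plate"} or
#'   \code{"screen"}.
#' @return list: \code{wells} (input plus \code{normalized_ratio}),
#'   \code{controls} (\code{neg_mean}, \code{neg_sd}, \code{n_neg_wells},
#'   \code{scope}).
#' @export
normalize_to_neg <- function(wells,
                             scope = c("plate_replicate", "plate",
                                       "screen")) {
  scope <- match.arg(scope)
  stopifnot(all(c("lamp1_np_ratio", "is_negative_control") %in%
                  names(wells)))
  key <- switch(scope,
                plate_replicate = paste(wells$plate_id, wells$replicate_id),
                plate = as.character(wells$plate_id),
                screen = rep("screen", nrow(wells)))
  wells$normalized_ratio <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    negs <- wells$lamp1_np_ratio[sel & wells$is_negative_control]
    negs <- negs[!is.na(negs)]
    if (!length(negs))
      stop("no negative-control wells in scope: ", k, call. = FALSE)
    wells$normalized_ratio[sel] <- wells$lamp1_np_ratio[sel] / mean(negs)
  }
  normneg <- wells$normalized_ratio[wells$is_negative_control]
  normneg <- normneg[!is.na(normneg)]
  controls <- data.frame(neg_mean = mean(normneg),
                         neg_sd = if (length(normneg) >= 2)
                           stats::sd(normneg) else NA_real_,
                         n_neg_wells = length(normneg), scope = scope)
  list(wells = wells, controls = controls)
}

PHENOTYPE_LEVELS <- c("strong_decrease", "mild_decrease", "none",
                      "mild_increase", "strong_increase", "not_viable")

#' Call a phenotype class from a normalized ratio
#'
#' Classifies a treatment's cross-replicate normalized ratio against the
#' negative-control distribution: reductions of at least 2 or 3 control
#' SDs below the NEG mean are mild or strong decreases; increases mirror
#' the same cutoffs above the mean. Boundaries are closed toward the more
#' extreme class (a ratio exactly at mu - 2 sd is a mild decrease).
#'
#' @param normalized_ratio normalized ratio(s) to classify.
#' @param controls one-row data.frame with \code{neg_mean} and
#'   \code{neg_sd} (see \code{\link{normalize_to_neg}}).
#' @return character vector of phenotype classes.
#' @examples
#' ctl <- data.frame(neg_mean = 1, neg_sd = 0.1)
#' call_phenotype(c(0.65, 0.75, 0.95, 1.35), ctl)
#' @export
call_phenotype <- function(normalized_ratio, controls) {
  mu <- controls$neg_mean; sd <- controls$neg_sd
  if (is.na(sd) || sd <= 0)
    stop("degenerate control distribution: sd undefined or zero",
         call. = FALSE)
  vapply(normalized_ratio, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x <= mu - 3 * sd) "strong_decrease"
    else if (x <= mu - 2 * sd) "mild_decrease"
    else if (x >= mu + 3 * sd) "strong_increase"
    else if (x >= mu + 2 * sd) "mild_increase"
    else "none"
  }, "")
}

#' Validate a gene across independent siRNAs
#'
#' A gene is validated when at least \code{k} of its independent siRNAs
#' reproduce a phenotype in the screened direction (any decrease for a
#' decrease screen, any increase for an increase screen).
#'
#' @param phenotypes character vector of per-siRNA phenotype calls.
#' @param k minimum number of confirming siRNAs (default 2).
#' @param direction \code{"decrease"} or \code{"increase"}.
#' @return list: \code{n_confirming}, \code{n_sirnas}, \code{validated}.
#' @examples
#' validate_gene(c("strong_decrease", "mild_decrease", "none"))$validated
#' @export
validate_gene <- function(phenotypes, k = 2L,
                          direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(length(phenotypes) >= 1L)
  confirming <- if (direction == "decrease")
    phenotypes %in% c("strong_decrease", "mild_decrease")
  else phenotypes %in% c("strong_increase", "mild_increase")
  list(n_confirming = sum(confirming), n_sirnas = length(phenotypes),
       validated = sum(confirming) >= k)
}

#' One-tailed two-sample Student's t-test
#'
#' Thin wrapper over the standard two-sample t-test returning the
#' one-tailed p-value in the requested direction (default: treatment lower
#' than control). Pooled-variance Student by default, Welch optional. When
#' both groups are constant the test is degenerate: equal means give
#' p = 0.5 by convention, otherwise p is 0 or 1 depending on direction.
#'
#' @param treatment_values,control_values numeric vectors (length >= 2).
#' @param direction \code{"less"}, \code{"greater"} or \code{"two.sided"}.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return the p-value.
#' @export
one_tailed_ttest <- function(treatment_values, control_values,
                             direction = c("less", "greater", "two.sided"),
                             var_equal = TRUE) {
  direction <- match.arg(direction)
  if (length(treatment_values) < 2 || length(control_values) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  if (stats::sd(treatment_values) == 0 && stats::sd(control_values) == 0) {
    d <- mean(treatment_values) - mean(control_values)
    if (d == 0) return(0.5)
    hit <- switch(direction, less = d < 0, greater = d > 0,
                  two.sided = TRUE)
    return(if (hit) 0 else 1)
  }
  stats::t.test(treatment_values, control_values, alternative = direction,
                var.equal = var_equal)$p.value
}

#' Summarize screen results per treatment
#'
#' Full statistics stage: NEG normalization, viability filtering,
#' cross-replicate normalized mean and SEM per treatment, SD-based
#' phenotype calling on the replicate-averaged normalized ratio, and a
#' one-tailed t-test of each treatment's normalized wells against the
#' normalized NEG wells.
#'
#' @param wells WellRecord data.frame (image pipeline output or
#'   \code{\link{simulate_well_table}}).
#' @param scope normalization scope (see \code{\link{normalize_to_neg}}).
#' @param min_per_well,min_total viability thresholds.
#' @param test_direction direction of the per-treatment t-test.
#' @return list: \code{treatments} (TreatmentResult data.frame),
#'   \code{controls}, \code{wells} (with normalized ratios).
#' @export
screen_statistics <- function(wells, scope = "plate_replicate",
                              min_per_well = 50, min_total = 150,
                              test_direction = "less") {
  nz <- normalize_to_neg(wells, scope)
  wells <- nz$wells; controls <- nz$controls
  viab <- viability_filter(wells, min_per_well, min_total)
  neg_norm <- wells$normalized_ratio[wells$is_negative_control]
  neg_norm <- neg_norm[!is.na(neg_norm)]
  trts <- unique(wells$treatment_id[!wells$is_negative_control])
  rows <- lapply(trts, function(tid) {
    w <- wells[wells$treatment_id == tid, ]
    v <- viab$viable[viab$treatment_id == tid]
    x <- w$normalized_ratio[!is.na(w$normalized_ratio)]
    m <- if (length(x)) mean(x) else NA_real_
    sem <- if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
    ph <- if (!v) "not_viable" else call_phenotype(m, controls)
    p <- if (v && length(x) >= 2 && length(neg_norm) >= 2)
      one_tailed_ttest(x, neg_norm, test_direction) else NA_real_
    data.frame(treatment_id = tid, gene = w$gene[1], sirna_id = w$sirna_id[1],
               normalized_ratio_mean = m, normalized_ratio_sem = sem,
               n_replicates = nrow(w), total_cells = sum(w$n_cells_analyzed),
               viable = v, phenotype = ph, p_value = p)
  })
  treatments <- do.call(rbind, rows)
  rownames(treatments) <- NULL
  list(treatments = treatments, controls = controls, wells = wells)
}

#' Validate all genes of a screen
#'
#' Applies the k-of-n siRNA confirmation rule per gene to a
#' TreatmentResult table (one row per siRNA).
#'
#' @param treatments TreatmentResult data.frame from
#'   \code{\link{screen_statistics}}.
#' @param k minimum confirming siRNAs.
#' @param direction screened direction.
#' @return data.frame: gene, n_sirnas, n_confirming, validated.
#' @export
validate_screen <- function(treatments, k = 2L, direction = "decrease") {
  sp <- split(treatments$phenotype, treatments$gene)
  out <- data.frame(gene = names(sp),
                    n_sirnas = vapply(sp, length, 0L),
                    n_confirming = vapply(sp, function(p)
                      validate_gene(p, k, direction)$n_confirming, 0L))
  out$validated <- out$n_confirming >= k
  rownames(out) <- NULL
  out
}

#' Control readouts per treatment
#'
#' Summarizes lysosome-integrity controls per treatment (mean LAMP1
#' intensity per cell; LysoTracker spot count and intensity when present)
#' with a one-tailed t-test against the NEG wells, supporting the check
#' that ratio phenotypes are not driven by gross changes in lysosome
#' amount or organization.
#'
#' @param wells WellRecord data.frame; uses
#'   \code{mean_lamp1_intensity_per_cell} and, when present,
#'   \code{mean_lyso_spot_count} / \code{mean_lyso_intensity}.
#' @param direction direction of the t-test (default \code{"greater"}:
#'   flags increases over NEG).
#' @param alpha significance level for the \code{flagged} column.
#' @return data.frame with one row per treatment and, per available
#'   readout, mean, sem, p-value and flag columns.
#' @export
control_readouts <- function(wells, direction = "greater", alpha = 0.05) {
  readouts <- intersect(c("mean_lamp1_intensity_per_cell",
                          "mean_lyso_spot_count", "mean_lyso_intensity"),
                        names(wells))
  readouts <- readouts[vapply(readouts, function(r)
    any(!is.na(wells[[r]])), TRUE)]
  trts <- unique(wells$treatment_id[!wells$is_negative_control])
  out <- data.frame(treatment_id = trts)
  for (r in readouts) {
    neg <- wells[[r]][wells$is_negative_control]
    neg <- neg[!is.na(neg)]
    short <- sub("^mean_", "", r)
    m <- s <- p <- rep(NA_real_, length(trts))
    for (i in seq_along(trts)) {
      x <- wells[[r]][wells$treatment_id == trts[i]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      m[i] <- mean(x)
      if (length(x) >= 2) s[i] <- stats::sd(x) / sqrt(length(x))
      if (length(x) >= 2 && length(neg) >= 2)
        p[i] <- one_tailed_ttest(x, neg, direction)
    }
    out[[paste0(short, "_mean")]] <- m
    out[[paste0(short, "_sem")]] <- s
    out[[paste0(short, "_p")]] <- p
    out[[paste0(short, "_flagged")]] <- !is.na(p) & p < alpha
  }
  out
}
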