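DEFAULT_CHIP_CAPACITY <- 20000L
DEFAULT_PARTITION_VOLUME_NL <- 0.755

#' Per-reaction partition count tally
#'
#' The raw observable of a duplex chip run after fluorescence
#' thresholding: how many valid wells were positive in FAM only, VIC
#' only, both channels, or negative. The four categories must sum to
#' `n_valid`.
#'
#' @param n_valid Wells passing quality.
#' @param n_fam_only,n_vic_only,n_double,n_negative Category tallies.
#' @param chip_capacity Total wells on the chip (default 20,000).
#' @return An object of class `partition_counts`.
#' @export
#' @examples
#' partition_counts(20000, 100, 200, 50, 19650)
partition_counts <- function(n_valid, n_fam_only, n_vic_only, n_double,
                             n_negative, chip_capacity = DEFAULT_CHIP_CAPACITY) {
  vals <- c(n_valid = n_valid, n_fam_only = n_fam_only,
            n_vic_only = n_vic_only, n_double = n_double,
            n_negative = n_negative)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("partition counts must be non-negative integers")
  }
  if (n_fam_only + n_vic_only + n_double + n_negative != n_valid) {
    stop("category counts (", n_fam_only + n_vic_only + n_double + n_negative,
         ") do not sum to n_valid (", n_valid, ")")
  }
  if (n_valid > chip_capacity) {
    stop("n_valid (", n_valid, ") exceeds chip capacity (", chip_capacity, ")")
  }
  structure(as.list(setNames(as.integer(vals), names(vals))),
            class = "partition_counts")
}

#' Count channel-positive wells
#'
#' A well positive in both channels counts for each target independently:
#' FAM positives = fam-only + double, VIC positives = vic-only + double.
#'
#' @param counts A `partition_counts`.
#' @param channel "FAM" or "VIC".
#' @return Integer well count.
#' @export
channel_positives <- function(counts, channel) {
  stopifnot(inherits(counts, "partition_counts"))
  switch(channel,
    FAM = counts$n_fam_only + counts$n_double,
    VIC = counts$n_vic_only + counts$n_double,
    stop("unknown dye channel '", channel, "'; must be FAM or VIC")
  )
}

#' Quality-control policy for chip runs
#'
#' @param min_valid_partitions Minimum valid wells for a usable chip.
#' @param ntc_max_positive_wells Maximum positives tolerated in any channel
#'   of a no-template control before declaring contamination.
#' @param saturation_min_negative_wells Minimum negative wells below which
#'   the Poisson estimate is flagged saturated (its variance explodes as
#'   negatives vanish).
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_valid_partitions = 10000L,
                      ntc_max_positive_wells = 5L,
                      saturation_min_negative_wells = 20L) {
  vals <- c(min_valid_partitions, ntc_max_positive_wells,
            saturation_min_negative_wells)
  if (any(vals < 0)) stop("QC thresholds must be >= 0")
  structure(list(min_valid_partitions = as.integer(min_valid_partitions),
                 ntc_max_positive_wells = as.integer(ntc_max_positive_wells),
                 saturation_min_negative_wells = as.integer(saturation_min_negative_wells)),
            class = "qc_policy")
}

#' Poisson estimate of copies per partition
#'
#' Standard digital-PCR estimator: with p_neg the observed fraction of
#' channel-negative wells, lambda-hat = -ln(p_neg). The standard error is
#' the delta-method transform of the binomial variance of p_neg,
#' se = sqrt((1 - p_neg) / (n_valid * p_neg)), and the 95% CI is
#' lambda-hat +/- 1.96 se (lower bound clamped at 0). An exact interval
#' obtained by inverting the binomial CI for p_neg (Clopper-Pearson) is
#' available with `ci = "exact"`; at 20,000 partitions the two are
#' practically indistinguishable.
#'
#' @param n_positive Channel-positive wells.
#' @param n_valid Valid wells (> 0).
#' @param ci "delta" (default) or "exact".
#' @return A `quant_result` with fields `lambda_hat`, `se_lambda`, `ci95`,
#'   `n_valid`, `flags` (subset of ABSENT, SATURATED).
#' @export
#' @examples
#' estimate_lambda(10000, 20000)$lambda_hat  # log(2)
estimate_lambda <- function(n_positive, n_valid, ci = c("delta", "exact")) {
  ci <- match.arg(ci)
  if (n_valid <= 0) stop("n_valid must be > 0: no data")
  if (n_positive < 0 || n_positive > n_valid) {
    stop("n_positive must lie in [0, n_valid]")
  }
  n_negative <- n_valid - n_positive
  if (n_negative == 0) {
    stop(structure(class = c("dpcr_saturated", "error", "condition"),
                   list(message = "all wells positive: lambda undefined (SATURATED)",
                        call = sys.call())))
  }
  p_neg <- n_negative / n_valid
  lambda_hat <- -log(p_neg)
  flags <- character()
  if (n_positive == 0) flags <- c(flags, "ABSENT")
  se <- sqrt((1 - p_neg) / (n_valid * p_neg))
  if (ci == "delta") {
    lo <- max(0, lambda_hat - 1.96 * se)
    hi <- lambda_hat + 1.96 * se
  } else {
    # invert an exact binomial CI for p_neg; lambda = -log(p_neg) is decreasing
    pneg_ci <- binomial_ci(n_negative, n_valid, method = "clopper_pearson")
    lo <- max(0, -log(pneg_ci[2]))
    hi <- if (pneg_ci[1] <= 0) Inf else -log(pneg_ci[1])
  }
  structure(list(lambda_hat = lambda_hat, se_lambda = se,
                 ci95 = c(lo, hi), n_valid = as.integer(n_valid),
                 flags = flags),
            class = "quant_result")
}

quant_absent <- function(n_valid) {
  structure(list(lambda_hat = 0, se_lambda = 0, ci95 = c(0, 0),
                 n_valid = as.integer(n_valid), flags = "ABSENT"),
            class = "quant_result")
}

#' Convert copies per partition to copies per microliter
#'
#' copies/uL = lambda / (partition volume in uL) * dilution factor. The
#' partition volume is instrument-specific (default 0.755 nL for the
#' 20,000-well chip); it cancels in every chromosomal ratio, so it only
#' affects absolute concentrations.
#'
#' @param lambda_hat Copies per partition.
#' @param partition_volume_nl Well volume in nanoliters (> 0).
#' @param dilution_factor Pre-partition dilution (> 0).
#' @return Concentration in copies/uL.
#' @export
#' @examples
#' copies_per_microliter(log(2))  # ~918 copies/uL
copies_per_microliter <- function(lambda_hat,
                                  partition_volume_nl = DEFAULT_PARTITION_VOLUME_NL,
                                  dilution_factor = 1) {
  if (partition_volume_nl <= 0) stop("partition volume must be > 0")
  if (dilution_factor <= 0) stop("dilution factor must be > 0")
  if (any(lambda_hat < 0)) stop("lambda must be >= 0")
  lambda_hat / (partition_volume_nl / 1000) * dilution_factor
}

#' Relative precision of a quantification
#'
#' 100 * (upper CI bound - lambda-hat) / lambda-hat: the half-width of the
#' 95% CI as a percentage of the estimate. Decreases with the number of
#' valid wells at fixed occupancy.
#'
#' @param result A `quant_result`.
#' @return Percentage, or NA with an ABSENT flag message when lambda = 0.
#' @export
precision_percent <- function(result) {
  stopifnot(inherits(result, "quant_result"))
  if (result$lambda_hat == 0) return(NA_real_)
  100 * (result$ci95[2] - result$lambda_hat) / result$lambda_hat
}

#' QC verdict for a chip run
#'
#' Returns the verdicts applying to a partition-count record: LOW_QC when
#' too few valid wells, SATURATED when too few negative wells remain for a
#' stable Poisson estimate, CONTAMINATED when a no-template control shows
#' more positives than tolerated in either channel, and PASS otherwise.
#'
#' @param counts A `partition_counts`.
#' @param policy A `qc_policy`.
#' @param is_ntc Is this record a no-template control?
#' @return Character vector of verdicts ("PASS" if none apply).
#' @export
qc_check <- function(counts, policy = qc_policy(), is_ntc = FALSE) {
  stopifnot(inherits(counts, "partition_counts"), inherits(policy, "qc_policy"))
  verdicts <- character()
  if (counts$n_valid < policy$min_valid_partitions) {
    verdicts <- c(verdicts, "LOW_QC")
  }
  if (counts$n_negative < policy$saturation_min_negative_wells) {
    verdicts <- c(verdicts, "SATURATED")
  }
  if (is_ntc) {
    pos <- c(channel_positives(counts, "FAM"), channel_positives(counts, "VIC"))
    if (any(pos > policy$ntc_max_positive_wells)) {
      verdicts <- c(verdicts, "CONTAMINATED")
    }
  }
  if (!length(verdicts)) "PASS" else verdicts
}

#' Quantify both channels of a duplex chip
#'
#' Runs the Poisson estimator on each dye channel of a partition-count
#' record and attaches concentrations and QC verdicts. Channels are
#' quantified independently; double-positive wells contribute to both.
#'
#' @param counts A `partition_counts`.
#' @param reaction The `dpcr_duplex` the chip ran (maps channels to
#'   chromosomes).
#' @param policy A `qc_policy`.
#' @param partition_volume_nl,dilution_factor Passed to
#'   [copies_per_microliter()].
#' @return Named list (by chromosome) of `quant_result`s, each augmented
#'   with `copies_per_ul`, `precision_pct` and QC flags; attribute
#'   `qc` holds the chip-level verdicts.
#' @export
quantify_reaction <- function(counts, reaction, policy = qc_policy(),
                              partition_volume_nl = DEFAULT_PARTITION_VOLUME_NL,
                              dilution_factor = 1) {
  stopifnot(inherits(reaction, "dpcr_duplex"))
  verdicts <- qc_check(counts, policy)
  quant_one <- function(channel) {
    n_pos <- channel_positives(counts, channel)
    q <- if (n_pos == counts$n_valid) {
      q0 <- structure(list(lambda_hat = Inf, se_lambda = Inf,
                           ci95 = c(Inf, Inf), n_valid = counts$n_valid,
                           flags = "SATURATED"),
                      class = "quant_result")
      q0
    } else {
      estimate_lambda(n_pos, counts$n_valid)
    }
    if (counts$n_valid - n_pos < policy$saturation_min_negative_wells &&
        !"SATURATED" %in% q$flags) {
      q$flags <- c(q$flags, "SATURATED")
    }
    if (any(verdicts == "LOW_QC")) q$flags <- c(q$flags, "LOW_QC")
    q$copies_per_ul <- if (is.finite(q$lambda_hat)) {
      copies_per_microliter(q$lambda_hat, partition_volume_nl, dilution_factor)
    } else NA_real_
    q$precision_pct <- if (is.finite(q$lambda_hat)) precision_percent(q) else NA_real_
    q
  }
  res <- list()
  res[[reaction$fam_assay$target_chromosome]] <- quant_one("FAM")
  res[[reaction$vic_assay$target_chromosome]] <- quant_one("VIC")
  attr(res, "qc") <- verdicts
  attr(res, "reaction_id") <- reaction$reaction_id
  res
}
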