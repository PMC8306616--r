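#' Default classification thresholds
#'
#' Interval bounds separating euploid from aneuploid chromosomal ratios.
#' The bands bracket the observed clinical group ranges with midpoint
#' gaps: trisomy-type ratios (r13, r21, r18X in females, rX18 for a
#' 3-copy X) use euploid [0.80, 1.25] and trisomic [1.35, 1.70]; the 18/X
#' ratio needs a second pair of intervals for male fetuses (one X copy):
#' euploid [1.65, 2.48] and trisomic [2.52, 3.30]. Monosomy X is called
#' from the X/18 ratio band [0.45, 0.60]. The X/Y ratio is banded by X:Y
#' copy ratio: ~1 [0.75, 1.35], ~2 [1.6, 2.4], ~3 [2.6, 3.4] and
#' ~0.5 [0.4, 0.65]. Y presence requires lambda_Y / lambda_X above
#' `y_presence_min` (default 0.1), so stray false-positive wells do not
#' masquerade as a Y chromosome.
#'
#' Values between the euploid and aneuploid bands are intermediate; under
#' `mosaic_policy = "flag"` they yield a MOSAIC call with an estimated
#' aberrant-cell fraction, under "reject" an INDETERMINATE call.
#'
#' @param mosaic_policy "flag" or "reject".
#' @return A `threshold_set` list; all bounds configurable.
#' @export
default_thresholds <- function(mosaic_policy = c("flag", "reject")) {
  mosaic_policy <- match.arg(mosaic_policy)
  structure(list(
    trisomy       = list(euploid = c(0.80, 1.25), aneuploid = c(1.35, 1.70)),
    r18X_female   = list(euploid = c(0.80, 1.25), aneuploid = c(1.35, 1.70)),
    r18X_male     = list(euploid = c(1.65, 2.48), aneuploid = c(2.52, 3.30)),
    rX18_x0       = c(0.45, 0.60),
    rXY           = list(one = c(0.75, 1.35), two = c(1.6, 2.4),
                         three = c(2.6, 3.4), half = c(0.4, 0.65)),
    y_presence_min = 0.1,
    mosaic_policy = mosaic_policy
  ), class = "threshold_set")
}

#' Load thresholds from a config, falling back to defaults
#'
#' @param config Parsed config list or NULL.
#' @return A `threshold_set`.
#' @export
load_thresholds <- function(config = NULL) {
  th <- default_thresholds()
  blk <- if (is.null(config)) NULL else config$thresholds
  if (is.null(blk)) return(th)
  for (key in names(blk)) {
    if (!key %in% names(th)) stop("unknown threshold key '", key, "'")
    v <- blk[[key]]
    th[[key]] <- if (is.list(th[[key]])) {
      sub <- th[[key]]
      for (k2 in names(v)) {
        if (!k2 %in% names(sub)) stop("unknown threshold key '", key, ".", k2, "'")
        sub[[k2]] <- as.numeric(unlist(v[[k2]]))
      }
      sub
    } else if (key == "mosaic_policy") as.character(v) else as.numeric(unlist(v))
  }
  validate_thresholds(th)
  th
}

validate_thresholds <- function(th) {
  band_ok <- function(b) length(b) == 2 && all(b > 0) && b[1] < b[2]
  stopifnot(band_ok(th$trisomy$euploid), band_ok(th$trisomy$aneuploid),
            th$trisomy$euploid[2] < th$trisomy$aneuploid[1],
            band_ok(th$r18X_female$euploid), band_ok(th$r18X_female$aneuploid),
            band_ok(th$r18X_male$euploid), band_ok(th$r18X_male$aneuploid),
            band_ok(th$rX18_x0), th$y_presence_min >= 0)
  invisible(th)
}

in_band <- function(x, band) !is.na(x) && x >= band[1] && x <= band[2]

#' Ratio of two chromosome quantifications
#'
#' value = lambda_target / lambda_reference; partition volume and
#' dilution cancel, so the ratio is taken on the per-partition occupancy
#' scale. The 95% CI is a delta-method interval on log(ratio) assuming
#' the two channels are independent (the covariance induced by shared
#' double-positive wells is ignored; conservative at occupancies <= 1.5).
#'
#' @param target_quant,reference_quant `quant_result`s from the same
#'   duplex reaction.
#' @param name Ratio identifier carried on the result.
#' @return A `chromosomal_ratio` with fields `name`, `value`, `ci95`.
#' @export
compute_ratio <- function(target_quant, reference_quant, name = "ratio") {
  stopifnot(inherits(target_quant, "quant_result"),
            inherits(reference_quant, "quant_result"))
  if ("SATURATED" %in% target_quant$flags || "SATURATED" %in% reference_quant$flags) {
    stop("cannot form ratio '", name, "': saturated quantification")
  }
  if (reference_quant$lambda_hat == 0) {
    stop("cannot form ratio '", name, "': reference chromosome absent (lambda = 0)")
  }
  value <- target_quant$lambda_hat / reference_quant$lambda_hat
  if (target_quant$lambda_hat > 0) {
    sd_log <- sqrt((target_quant$se_lambda / target_quant$lambda_hat)^2 +
                   (reference_quant$se_lambda / reference_quant$lambda_hat)^2)
    ci <- value * exp(c(-1.96, 1.96) * sd_log)
  } else {
    ci <- c(0, 0)
  }
  structure(list(name = name, value = value, ci95 = ci),
            class = "chromosomal_ratio")
}

#' Fetal sex from the X/Y duplex
#'
#' Male iff lambda_Y / lambda_X exceeds `y_presence_min`; female when Y
#' is absent or below that floor (stray false-positive wells); the floor
#' makes the call robust to contamination-level Y signal. X absent (or
#' both absent) yields "indeterminate".
#'
#' @param quant_X,quant_Y `quant_result`s from the X/Y reaction.
#' @param thresholds A `threshold_set`.
#' @return "male", "female" or "indeterminate".
#' @export
sex_call <- function(quant_X, quant_Y, thresholds = default_thresholds()) {
  if (quant_X$lambda_hat == 0 || "ABSENT" %in% quant_X$flags) {
    return("indeterminate")
  }
  if (quant_Y$lambda_hat == 0 || "ABSENT" %in% quant_Y$flags) return("female")
  if (quant_Y$lambda_hat / quant_X$lambda_hat > thresholds$y_presence_min) {
    "male"
  } else {
    "female"
  }
}

#' Interval verdict for one chromosomal ratio
#'
#' Places the ratio in its euploid or aneuploid interval; values falling
#' between or outside the intervals are "intermediate". The 18/X ratio is
#' judged against sex-specific intervals (euploid females carry two X
#' copies, males one). The rX18 name is judged against the monosomy-X
#' band (aneuploid) and the inverse of the female euploid band.
#'
#' @param ratio A `chromosomal_ratio` (or a bare number plus `name`).
#' @param sex "male" or "female" (required for r18X / rX18).
#' @param thresholds A `threshold_set`.
#' @param name Ratio name override when `ratio` is numeric.
#' @return "euploid", "aneuploid" or "intermediate".
#' @export
classify_ratio <- function(ratio, sex = NULL, thresholds = default_thresholds(),
                           name = NULL) {
  if (inherits(ratio, "chromosomal_ratio")) {
    value <- ratio$value
    if (is.null(name)) name <- ratio$name
  } else {
    value <- as.numeric(ratio)
    if (is.null(name)) stop("ratio name required")
  }
  th <- thresholds
  bands <- switch(name,
    r13 = , r21 = th$trisomy,
    r18X = {
      if (is.null(sex) || !sex %in% c("male", "female")) {
        stop("classifying r18X requires fetal sex")
      }
      if (sex == "male") th$r18X_male else th$r18X_female
    },
    rX18 = list(euploid = rev(1 / th$r18X_female$euploid),
                aneuploid = th$rX18_x0),
    stop("no thresholds defined for ratio '", name, "'")
  )
  if (in_band(value, bands$aneuploid)) return("aneuploid")
  if (in_band(value, bands$euploid)) return("euploid")
  "intermediate"
}

#' X/Y copy-ratio band
#'
#' Maps the X/Y ratio to its nearest integer-copy interpretation:
#' "one" (X:Y about 1:1), "two", "three" or "half" (two Y per X);
#' off-band values return "intermediate".
#' @param value X/Y ratio.
#' @param thresholds A `threshold_set`.
#' @return Band label.
#' @export
classify_xy <- function(value, thresholds = default_thresholds()) {
  b <- thresholds$rXY
  if (in_band(value, b$one)) return("one")
  if (in_band(value, b$two)) return("two")
  if (in_band(value, b$three)) return("three")
  if (in_band(value, b$half)) return("half")
  "intermediate"
}

#' Aberrant cell fraction from an intermediate ratio
#'
#' A mosaic sample mixes euploid and aneuploid cell populations; the
#' measured ratio moves linearly with the aneuploid fraction f. For a
#' trisomy against a disomic reference r = (2 + f)/2, so f = 2(r - 1);
#' for monosomy X measured as X/18, r = (2 - f)/2, so f = 2(1 - r).
#' The estimate is clamped to [0, 1].
#'
#' @param ratio_value Measured ratio.
#' @param base_class "T13", "T18", "T21" (trisomy model) or "X0".
#' @return Estimated aberrant fraction in [0, 1].
#' @export
#' @examples
#' mosaic_fraction(1.25, "T21")  # 0.5
mosaic_fraction <- function(ratio_value, base_class) {
  f <- switch(base_class,
    T13 = , T18 = , T21 = 2 * (ratio_value - 1),
    X0 = 2 * (1 - ratio_value),
    stop("no mosaic model for class '", base_class, "'")
  )
  min(1, max(0, f))
}

karyotype_classes <- c("EUPLOID_FEMALE", "EUPLOID_MALE", "T13", "T18", "T21",
                       "X0", "XXX", "XXY", "XYY", "XXXY", "TRIPLOID_MALE",
                       "MOSAIC", "INDETERMINATE")

new_karyotype_call <- function(call_class, sex, ratios, qc = "PASS",
                               base_class = NA_character_,
                               mosaic_fraction = NA_real_) {
  stopifnot(call_class %in% karyotype_classes)
  structure(list(call_class = call_class, sex = sex,
                 base_class = base_class, mosaic_fraction = mosaic_fraction,
                 evidence = ratios, qc = qc),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  lab <- x$call_class
  if (lab == "MOSAIC") {
    lab <- sprintf("MOSAIC %s (f = %.2f)", x$base_class, x$mosaic_fraction)
  }
  cat(sprintf("karyotype call: %s (sex %s; qc %s)\n", lab, x$sex,
              paste(x$qc, collapse = ",")))
  ev <- vapply(x$evidence, function(r)
    if (is.null(r)) NA_real_ else r$value, 0)
  cat("  ratios:", paste(sprintf("%s=%.3f", names(ev), ev), collapse = "  "), "\n")
  invisible(x)
}

# autosomal reaction verdict from the reciprocal pair r13/r21
autosomal_status <- function(r13, r21, thresholds) {
  gap <- c(thresholds$trisomy$euploid[2], thresholds$trisomy$aneuploid[1])
  in_gap <- function(x) !is.na(x) && x > gap[1] && x < gap[2]
  v13 <- classify_ratio(r13, thresholds = thresholds, name = "r13")
  v21 <- classify_ratio(r21, thresholds = thresholds, name = "r21")
  if (v21 == "aneuploid") return(list(status = "T21"))
  if (v13 == "aneuploid") return(list(status = "T13"))
  if (in_gap(r21)) return(list(status = "mosaic", base = "T21", ratio = r21))
  if (in_gap(r13)) return(list(status = "mosaic", base = "T13", ratio = r13))
  if (v13 == "euploid" && v21 == "euploid") return(list(status = "normal"))
  list(status = "indeterminate")
}

# sex-chromosome verdict for a female sample (Y absent)
female_sex_status <- function(r18X, rX18, thresholds) {
  th <- thresholds
  if (in_band(r18X, th$r18X_female$euploid)) return(list(status = "normal"))
  if (in_band(r18X, th$r18X_female$aneuploid)) return(list(status = "T18"))
  if (in_band(rX18, th$rX18_x0)) return(list(status = "X0"))
  if (in_band(rX18, th$trisomy$aneuploid)) return(list(status = "XXX"))
  # between the euploid and monosomy-X bands on the X/18 axis the design
  # cannot distinguish an X-loss from a chr18-gain mosaic; the zone is
  # reported as an X0-type mosaic (the class observed clinically on this
  # axis), to be confirmed by karyotype
  gapx0 <- c(th$rX18_x0[2], 1 / th$r18X_female$euploid[2])
  if (!is.na(rX18) && rX18 > gapx0[1] && rX18 < gapx0[2]) {
    return(list(status = "mosaic", base = "X0", ratio = rX18))
  }
  gap18 <- c(th$r18X_female$euploid[2], th$r18X_female$aneuploid[1])
  if (!is.na(r18X) && r18X > gap18[1] && r18X < gap18[2]) {
    return(list(status = "mosaic", base = "T18", ratio = r18X))
  }
  list(status = "indeterminate")
}

# sex-chromosome verdict for a male sample: joint (18/X band, X/Y band)
# lookup. Bands checked euploid-first so the small overlap between the
# 1.5-copy and 2-copy 18/X intervals resolves to euploid.
male_sex_status <- function(r18X, rXY, thresholds) {
  th <- thresholds
  x18_band <- if (in_band(r18X, th$r18X_male$euploid)) "2"
    else if (in_band(r18X, th$r18X_male$aneuploid)) "3"
    else if (in_band(r18X, th$r18X_female$euploid)) "1"
    else if (in_band(r18X, th$r18X_female$aneuploid)) "1.5"
    else if (in_band(1 / r18X, th$trisomy$aneuploid)) "2/3"
    else "intermediate"
  xy_band <- classify_xy(rXY, th)
  key <- paste(x18_band, xy_band, sep = "|")
  status <- switch(key,
    "2|one"    = "normal",
    "3|one"    = "T18",
    "1|two"    = "XXY",
    "1.5|two"  = "TRIPLOID_MALE",  # 69,XXY
    "2|half"   = "XYY",
    "3|half"   = "TRIPLOID_MALE",  # 69,XYY
    "2/3|three" = "XXXY",
    "indeterminate"
  )
  list(status = status)
}

#' Integrate the three duplex reactions into a karyotype call
#'
#' Applies the decision table over expected copy-number ratios: autosomal
#' trisomies from the 13/21 duplex, chromosome 18 and the sex-chromosome
#' aneuploidies from the 18/X and X/Y duplexes with sex-specific 18/X
#' intervals, male triploidy from the joint (18/X about 1.5 or 3, X/Y
#' about 2 or 0.5) pattern. Monosomy X is distinguished from the euploid
#' male (both have 18/X about 2) by Y absence. A single intermediate
#' trisomy-type ratio with all other evidence euploid yields a MOSAIC
#' call with estimated fraction (policy "flag") or INDETERMINATE (policy
#' "reject"); conflicting abnormal evidence yields INDETERMINATE. A
#' triploid female (69,XXX) leaves every ratio at its euploid value and
#' is called EUPLOID_FEMALE — a documented blind spot of the ratio
#' design.
#'
#' @param ratios Named list with elements `r13`, `r21`, `r18X`, `rX18`
#'   and (when Y is present) `rXY`: `chromosomal_ratio` objects or bare
#'   numbers; missing/NULL rXY is interpreted with Y absence.
#' @param sex "male", "female" or "indeterminate" (from [sex_call()]).
#' @param thresholds A `threshold_set`.
#' @param qc Character vector of QC verdicts; anything other than "PASS"
#'   forces INDETERMINATE.
#' @return A `karyotype_call`.
#' @export
integrate_calls <- function(ratios, sex, thresholds = default_thresholds(),
                            qc = "PASS") {
  val <- function(nm) {
    r <- ratios[[nm]]
    if (is.null(r)) return(NA_real_)
    if (inherits(r, "chromosomal_ratio")) r$value else as.numeric(r)
  }
  ev <- lapply(ratios, function(r) {
    if (inherits(r, "chromosomal_ratio")) r
    else if (is.null(r)) NULL
    else structure(list(name = NA, value = as.numeric(r), ci95 = c(NA, NA)),
                   class = "chromosomal_ratio")
  })
  bad_qc <- !all(qc == "PASS")
  if (bad_qc || identical(sex, "indeterminate")) {
    return(new_karyotype_call("INDETERMINATE", sex, ev, qc))
  }
  auto <- autosomal_status(val("r13"), val("r21"), thresholds)
  sx <- if (sex == "female") {
    female_sex_status(val("r18X"), val("rX18"), thresholds)
  } else {
    male_sex_status(val("r18X"), val("rXY"), thresholds)
  }
  reject <- identical(thresholds$mosaic_policy, "reject")
  make_mosaic <- function(base, ratio) {
    if (reject) return(new_karyotype_call("INDETERMINATE", sex, ev, qc))
    new_karyotype_call("MOSAIC", sex, ev, qc, base_class = base,
                       mosaic_fraction = mosaic_fraction(ratio, base))
  }
  if (auto$status == "normal") {
    cls <- switch(sx$status,
      normal = if (sex == "female") "EUPLOID_FEMALE" else "EUPLOID_MALE",
      T18 = "T18", X0 = "X0", XXX = "XXX", XXY = "XXY", XYY = "XYY",
      XXXY = "XXXY", TRIPLOID_MALE = "TRIPLOID_MALE",
      mosaic = return(make_mosaic(sx$base, sx$ratio)),
      "INDETERMINATE"
    )
    return(new_karyotype_call(cls, sex, ev, qc))
  }
  if (auto$status %in% c("T13", "T21")) {
    if (sx$status == "normal") {
      return(new_karyotype_call(auto$status, sex, ev, qc))
    }
    return(new_karyotype_call("INDETERMINATE", sex, ev, qc))
  }
  if (auto$status == "mosaic" && sx$status == "normal") {
    return(make_mosaic(auto$base, auto$ratio))
  }
  new_karyotype_call("INDETERMINATE", sex, ev, qc)
}

#' Call one sample from its three quantified reactions
#'
#' Convenience wrapper: computes the five standard ratios from
#' per-reaction quantifications, determines sex from the X/Y duplex,
#' and integrates the evidence into a karyotype call.
#'
#' @param quants Named list of [quantify_reaction()] outputs keyed by
#'   reaction id ("R1", "R2", "R3" for the default panel).
#' @param panel A `dpcr_panel`.
#' @param thresholds A `threshold_set`.
#' @return A `karyotype_call`.
#' @export
call_sample <- function(quants, panel = default_panel(),
                        thresholds = default_thresholds()) {
  qc <- unique(unlist(lapply(quants, attr, "qc")))
  qc_bad <- setdiff(qc, "PASS")
  qc_bad <- setdiff(qc_bad, "CONTAMINATED")  # NTC verdicts handled upstream
  get_q <- function(rid, chr) quants[[rid]][[chr]]
  defs <- panel$ratio_definitions
  safe_ratio <- function(nm) {
    d <- defs[[nm]]
    if (is.null(d)) return(NULL)
    tq <- get_q(d$reaction_id, d$target)
    rq <- get_q(d$reaction_id, d$reference)
    if (is.null(tq) || is.null(rq)) return(NULL)
    tryCatch(compute_ratio(tq, rq, name = nm), error = function(e) NULL)
  }
  rxy_def <- defs[["rXY"]]
  sex <- if (is.null(rxy_def)) "indeterminate" else {
    sex_call(get_q(rxy_def$reaction_id, "X"), get_q(rxy_def$reaction_id, "Y"),
             thresholds)
  }
  ratios <- list(r13 = safe_ratio("r13"), r21 = safe_ratio("r21"),
                 r18X = safe_ratio("r18X"), rX18 = safe_ratio("rX18"))
  ratios$rXY <- if (identical(sex, "male")) safe_ratio("rXY") else NULL
  if (length(qc_bad) == 0) qc_bad <- "PASS"
  integrate_calls(ratios, sex, thresholds, qc = qc_bad)
}
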