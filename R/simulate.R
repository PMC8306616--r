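#' Ground-truth karyotype state
#'
#' Chromosome copy numbers for the five screened chromosomes, optionally
#' as a mosaic mixture of component states (cell fractions summing to 1).
#'
#' @param copy_numbers Named vector/list over "13", "18", "21", "X", "Y";
#'   missing autosomes default to 2 copies, missing sex chromosomes to 0.
#' @param mosaic_components Optional list of `list(state =, fraction =)`
#'   entries; fractions in (0, 1] and summing to 1. When supplied,
#'   `copy_numbers` is ignored for the mixture (effective copies are the
#'   fraction-weighted component copies).
#' @param label Optional karyotype label carried along (e.g. "47,XY,+21").
#' @return A `karyotype_state`.
#' @export
#' @examples
#' karyotype_state(c("13" = 2, "18" = 2, "21" = 3, X = 2, Y = 0))
karyotype_state <- function(copy_numbers = NULL, mosaic_components = NULL,
                            label = NULL) {
  if (!is.null(mosaic_components)) {
    fr <- vapply(mosaic_components, `[[`, 0, "fraction")
    if (any(fr <= 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
      stop("mosaic fractions must lie in (0,1] and sum to 1")
    }
    for (mc in mosaic_components) stopifnot(inherits(mc$state, "karyotype_state"))
    return(structure(list(copy_numbers = NULL,
                          mosaic_components = mosaic_components,
                          label = label),
                     class = "karyotype_state"))
  }
  cn <- setNames(c(2, 2, 2, 0, 0), CHROMOSOMES)
  supplied <- setNames(as.numeric(unlist(copy_numbers)), names(copy_numbers))
  unknown <- setdiff(names(supplied), CHROMOSOMES)
  if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  cn[names(supplied)] <- supplied
  if (any(cn < 0) || any(cn != round(cn))) {
    stop("copy numbers must be non-negative integers")
  }
  if (all(cn == 0)) stop("at least one chromosome must have copy number > 0")
  structure(list(copy_numbers = cn, mosaic_components = NULL, label = label),
            class = "karyotype_state")
}

# fraction-weighted effective copy number of one chromosome
effective_copies <- function(state, chromosome) {
  chromosome <- as.character(chromosome)
  if (!is.null(state$mosaic_components)) {
    sum(vapply(state$mosaic_components, function(mc)
      mc$fraction * effective_copies(mc$state, chromosome), 0))
  } else {
    unname(state$copy_numbers[[chromosome]])
  }
}

#' Parse an ISCN-like karyotype string
#'
#' Grammar: `<count>,<sex chromosomes>[,+<chr>...]`, e.g. "46,XX",
#' "47,XY,+21", "45,X", "48,XXXY", "69,XXY". Counts of 67–71 are treated
#' as triploid (all autosomes at 3 copies). Mosaics are written as
#' slash-joined components with bracketed percentages:
#' "47,XX,+21[40]/46,XX[60]".
#'
#' @param text Karyotype string.
#' @return A `karyotype_state`.
#' @export
#' @examples
#' parse_karyotype("47,XY,+21")
#' parse_karyotype("47,XX,+21[40]/46,XX[60]")
parse_karyotype <- function(text) {
  text <- gsub("\\s", "", text)
  if (grepl("/", text, fixed = TRUE)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1]]
    comps <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(.*)\\[([0-9.]+)\\]$", p))[[1]]
      if (length(m) != 3) {
        stop("mosaic component '", p, "' needs a bracketed percentage, e.g. 46,XX[60]")
      }
      list(state = parse_karyotype(m[2]), fraction = as.numeric(m[3]) / 100)
    })
    return(karyotype_state(mosaic_components = comps, label = text))
  }
  fields <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(fields) < 2) stop("cannot parse karyotype '", text, "'")
  count <- suppressWarnings(as.integer(fields[1]))
  if (is.na(count)) stop("cannot parse chromosome count in '", text, "'")
  sex_field <- toupper(fields[2])
  if (!grepl("^[XY0]+$", sex_field)) {
    stop("cannot parse sex chromosomes '", fields[2], "' in '", text, "'")
  }
  n_x <- lengths(regmatches(sex_field, gregexpr("X", sex_field)))
  n_y <- lengths(regmatches(sex_field, gregexpr("Y", sex_field)))
  auto_base <- if (count >= 67 && count <= 71) 3L else 2L
  cn <- setNames(c(auto_base, auto_base, auto_base, n_x, n_y), CHROMOSOMES)
  extras <- fields[-(1:2)]
  for (e in extras) {
    m <- regmatches(e, regexec("^([+-])(13|18|21|X|Y)$", e))[[1]]
    if (length(m) != 3) stop("cannot parse karyotype token '", e, "'")
    chr <- m[3]
    cn[chr] <- cn[chr] + if (m[2] == "+") 1L else -1L
  }
  if (any(cn < 0)) stop("karyotype '", text, "' implies negative copy number")
  karyotype_state(cn, label = text)
}

#' Chip simulation parameters
#'
#' The noise model of the simulated 20,000-well chip: wells fail quality
#' independently with `invalid_fraction`; molecules of each target land
#' in wells as independent Poissons with mean `lambda_base * copies/2 *
#' assay efficiency`; each deposited molecule is detected with
#' `per_molecule_detection_prob`; each well-channel additionally turns
#' positive spuriously with `false_positive_rate`. `lambda_base` is the
#' mean occupancy contributed by a two-copy autosome, so a single-copy
#' chromosome (one X in males) loads at half of it.
#'
#' @param n_partitions Wells per chip.
#' @param lambda_base Mean copies/partition for a 2-copy autosome.
#' @param invalid_fraction Fraction of wells failing quality.
#' @param per_molecule_detection_prob Detection probability per molecule.
#' @param false_positive_rate Per-well, per-channel spurious-positive rate.
#' @param seed Optional integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_partitions = 20000L, lambda_base = 0.8,
                       invalid_fraction = 0.01,
                       per_molecule_detection_prob = 0.98,
                       false_positive_rate = 1e-4, seed = NULL) {
  stopifnot(n_partitions > 0, lambda_base >= 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            per_molecule_detection_prob >= 0, per_molecule_detection_prob <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1)
  structure(list(n_partitions = as.integer(n_partitions),
                 lambda_base = lambda_base,
                 invalid_fraction = invalid_fraction,
                 per_molecule_detection_prob = per_molecule_detection_prob,
                 false_positive_rate = false_positive_rate,
                 seed = seed),
            class = "sim_params")
}

#' Build simulation parameters from a config "simulation" block
#'
#' @param config Parsed config list (or NULL for defaults).
#' @param seed Optional seed override.
#' @return A `sim_params`.
#' @export
sim_params_from_config <- function(config = NULL, seed = NULL) {
  blk <- if (is.null(config)) NULL else config$simulation
  args <- list(seed = seed)
  known <- c("n_partitions", "lambda_base", "invalid_fraction",
             "per_molecule_detection_prob", "false_positive_rate", "seed")
  unknown <- setdiff(names(blk), known)
  if (length(unknown)) stop("unknown simulation config key(s): ",
                            paste(unknown, collapse = ", "))
  for (k in setdiff(known, "seed")) {
    if (!is.null(blk[[k]])) args[[k]] <- blk[[k]]
  }
  if (is.null(seed) && !is.null(blk$seed)) args$seed <- blk$seed
  do.call(sim_params, args)
}

#' Expected per-channel occupancy for a karyotype state
#'
#' lambda = lambda_base * (effective copies / 2) * assay efficiency,
#' where effective copies is the cell-fraction-weighted copy number for
#' mosaic states (mixing acts at the concentration level).
#'
#' @param state A `karyotype_state`.
#' @param chromosome Chromosome label.
#' @param params A `sim_params`.
#' @param assay Optional `dpcr_assay` supplying the efficiency factor.
#' @return Mean copies per partition.
#' @export
#' @examples
#' effective_lambda(parse_karyotype("47,XX,+21"), "21", sim_params())  # 1.2
effective_lambda <- function(state, chromosome, params, assay = NULL) {
  eff <- if (is.null(assay)) 1.0 else assay$efficiency
  params$lambda_base * effective_copies(state, chromosome) / 2 * eff
}

#' Simulate one duplex chip
#'
#' Draws a partition-count record for one duplex reaction run on a
#' sample with the given karyotype: valid-well count binomial in the
#' invalid fraction, then per-well channel positivity with probability
#' 1 - exp(-lambda * detection_prob) (detection-thinned Poisson
#' occupancy) OR a spurious positive; the two channels are independent,
#' and the four categories are drawn jointly from the implied
#' multinomial. Reproducible when a seed is given (in `seed` or in
#' `params$seed`); otherwise consumes the current RNG stream.
#'
#' @param state A `karyotype_state`.
#' @param reaction A `dpcr_duplex`.
#' @param params A `sim_params`.
#' @param seed Optional seed overriding `params$seed`.
#' @return A `partition_counts`.
#' @export
simulate_chip <- function(state, reaction, params = sim_params(), seed = NULL) {
  stopifnot(inherits(state, "karyotype_state"), inherits(reaction, "dpcr_duplex"),
            inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  n_valid <- params$n_partitions -
    rbinom(1L, params$n_partitions, params$invalid_fraction)
  p_pos <- function(a) {
    lam <- effective_lambda(state, a$target_chromosome, params, a)
    p_det <- 1 - exp(-lam * params$per_molecule_detection_prob)
    1 - (1 - p_det) * (1 - params$false_positive_rate)
  }
  pf <- p_pos(reaction$fam_assay)
  pv <- p_pos(reaction$vic_assay)
  tally <- as.vector(rmultinom(1L, n_valid,
                               c(pf * (1 - pv), (1 - pf) * pv,
                                 pf * pv, (1 - pf) * (1 - pv))))
  partition_counts(n_valid, tally[1], tally[2], tally[3], tally[4],
                   chip_capacity = params$n_partitions)
}

#' Simulate a cohort of samples
#'
#' Runs every reaction of the panel once per sample and emits the chip
#' count table plus truth labels. Per-sample seeds are derived
#' deterministically from the master seed, so identical
#' (composition, params, seed) yield bit-identical tables.
#'
#' @param composition Named integer vector: karyotype string -> number of
#'   samples (e.g. `c("46,XX" = 190, "47,XY,+21" = 33)`).
#' @param params A `sim_params` (its `seed` is the master seed unless
#'   `seed` is given).
#' @param panel A `dpcr_panel`.
#' @param seed Master seed override.
#' @param id_prefix Sample-id prefix.
#' @return List with `counts` (data.frame: sample_id, reaction_id,
#'   n_valid, n_fam_only, n_vic_only, n_double, n_negative) and `truth`
#'   (data.frame: sample_id, true_karyotype).
#' @export
#' @examples
#' sim <- simulate_cohort(c("46,XX" = 2), sim_params(seed = 1))
#' nrow(sim$counts)  # 6: 2 samples x 3 reactions
simulate_cohort <- function(composition, params = sim_params(),
                            panel = default_panel(), seed = NULL,
                            id_prefix = "S") {
  if (!length(composition)) stop("composition is empty")
  if (is.null(seed)) seed <- params$seed
  karyos <- rep(names(composition), times = as.integer(composition))
  n <- length(karyos)
  if (!is.null(seed)) set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  states <- lapply(setNames(nm = unique(karyos)), parse_karyotype)
  chip_params <- params
  chip_params$seed <- NULL  # chips consume the per-sample RNG stream
  rows <- vector("list", n * length(panel$reactions))
  truth <- data.frame(sample_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                      true_karyotype = karyos, stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(n)) {
    set.seed(sample_seeds[i])
    for (r in panel$reactions) {
      cts <- simulate_chip(states[[karyos[i]]], r, chip_params, seed = NULL)
      k <- k + 1L
      rows[[k]] <- data.frame(sample_id = truth$sample_id[i],
                              reaction_id = r$reaction_id,
                              n_valid = cts$n_valid,
                              n_fam_only = cts$n_fam_only,
                              n_vic_only = cts$n_vic_only,
                              n_double = cts$n_double,
                              n_negative = cts$n_negative,
                              stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, rows), truth = truth)
}

#' Expected karyotype call for a true state
#'
#' Maps a ground-truth karyotype to the call class the ratio design
#' should produce: the within-reaction expected ratios are computed
#' noise-free from the copy numbers and pushed through the decision
#' table. This realizes the design's blind spots honestly (69,XXX maps
#' to EUPLOID_FEMALE).
#'
#' @param state A `karyotype_state` or karyotype string.
#' @param thresholds A `threshold_set`.
#' @return Call-class string.
#' @export
#' @examples
#' expected_call("47,XY,+21")  # "T21"
#' expected_call("69,XXX")     # "EUPLOID_FEMALE"
expected_call <- function(state, thresholds = default_thresholds()) {
  if (is.character(state)) state <- parse_karyotype(state)
  cc <- vapply(setNames(nm = CHROMOSOMES), function(ch)
    effective_copies(state, ch), 0)
  rat <- function(a, b) if (cc[b] > 0) cc[a] / cc[b] else NA_real_
  sex <- if (cc["X"] == 0) "indeterminate"
         else if (cc["Y"] / cc["X"] > thresholds$y_presence_min) "male"
         else "female"
  ratios <- list(r13 = rat("13", "21"), r21 = rat("21", "13"),
                 r18X = rat("18", "X"), rX18 = rat("X", "18"),
                 rXY = if (identical(sex, "male")) rat("X", "Y") else NULL)
  integrate_calls(ratios, sex, thresholds)$call_class
}
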