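#' @importFrom stats qbeta qnorm pnorm rbinom rmultinom setNames rpois runif
#' @importFrom utils read.csv write.csv packageVersion
NULL

CHROMOSOMES <- c("13", "18", "21", "X", "Y")
DYE_CHANNELS <- c("FAM", "VIC")

#' Define a single TaqMan assay
#'
#' An assay is one labelled probe: it measures one chromosome in one dye
#' channel of a duplex reaction. The `efficiency` factor models
#' assay-specific deviation from ideal detection (1.0 = ideal); euploid
#' ratio means slightly off 1 or 2 in clinical data are consistent with
#' such per-assay offsets.
#'
#' @param target_chromosome One of "13", "18", "21", "X", "Y" (numbers are
#'   coerced to character).
#' @param dye_channel "FAM" or "VIC".
#' @param efficiency Positive relative detection/amplification factor.
#' @return An object of class `dpcr_assay`.
#' @export
#' @examples
#' assay("21", "FAM")
assay <- function(target_chromosome, dye_channel, efficiency = 1.0) {
  target_chromosome <- as.character(target_chromosome)
  if (!target_chromosome %in% CHROMOSOMES) {
    stop("unknown chromosome '", target_chromosome, "'; must be one of ",
         paste(CHROMOSOMES, collapse = ", "))
  }
  if (!dye_channel %in% DYE_CHANNELS) {
    stop("unknown dye channel '", dye_channel, "'; must be FAM or VIC")
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L || efficiency <= 0) {
    stop("efficiency must be a single positive number")
  }
  structure(
    list(target_chromosome = target_chromosome,
         dye_channel = dye_channel,
         efficiency = as.numeric(efficiency)),
    class = "dpcr_assay"
  )
}

#' Define a duplex reaction
#'
#' A duplex reaction carries exactly one VIC- and one FAM-labelled assay
#' targeting two different chromosomes; within-well ratios are only
#' defined between the two targets of the same reaction.
#'
#' @param reaction_id Short identifier, e.g. "R1".
#' @param vic_assay,fam_assay `dpcr_assay` objects in the matching channel.
#' @return An object of class `dpcr_duplex`.
#' @export
duplex_reaction <- function(reaction_id, vic_assay, fam_assay) {
  stopifnot(inherits(vic_assay, "dpcr_assay"), inherits(fam_assay, "dpcr_assay"))
  if (vic_assay$dye_channel != "VIC") stop("vic_assay must be in the VIC channel")
  if (fam_assay$dye_channel != "FAM") stop("fam_assay must be in the FAM channel")
  if (vic_assay$target_chromosome == fam_assay$target_chromosome) {
    stop("duplex reaction '", reaction_id,
         "': the two assays target the same chromosome (",
         vic_assay$target_chromosome, ")")
  }
  structure(
    list(reaction_id = as.character(reaction_id),
         vic_assay = vic_assay, fam_assay = fam_assay),
    class = "dpcr_duplex"
  )
}

#' The default three-reaction aneuploidy panel
#'
#' R1 pairs VIC:chr13 with FAM:chr21, R2 pairs VIC:chrX with FAM:chr18,
#' and R3 pairs VIC:chrX with FAM:chrY. Together the three duplexes cover
#' chromosomes 13, 18, 21, X and Y without an external reference assay.
#'
#' @param efficiencies Optional named numeric vector of per-assay
#'   efficiency overrides keyed by "reaction_id.chromosome"
#'   (e.g. `c("R1.13" = 1.02)`).
#' @return A `dpcr_panel`.
#' @export
#' @examples
#' default_panel()
default_panel <- function(efficiencies = NULL) {
  eff <- function(rid, chr) {
    key <- paste(rid, chr, sep = ".")
    if (!is.null(efficiencies) && key %in% names(efficiencies)) {
      as.numeric(efficiencies[[key]])
    } else 1.0
  }
  reactions <- list(
    duplex_reaction("R1", assay("13", "VIC", eff("R1", "13")),
                    assay("21", "FAM", eff("R1", "21"))),
    duplex_reaction("R2", assay("X", "VIC", eff("R2", "X")),
                    assay("18", "FAM", eff("R2", "18"))),
    duplex_reaction("R3", assay("X", "VIC", eff("R3", "X")),
                    assay("Y", "FAM", eff("R3", "Y")))
  )
  new_panel(reactions)
}

new_panel <- function(reactions, strict = TRUE) {
  stopifnot(is.list(reactions), all(vapply(reactions, inherits, TRUE, "dpcr_duplex")))
  if (length(reactions) != 3L) {
    msg <- sprintf("panel has %d duplex reactions; the standard design has 3",
                   length(reactions))
    if (strict) stop(msg) else warning(msg)
  }
  ids <- vapply(reactions, `[[`, "", "reaction_id")
  if (anyDuplicated(ids)) stop("duplicate reaction_id in panel")
  names(reactions) <- ids
  covered <- sort(unique(unlist(lapply(reactions, function(r)
    c(r$vic_assay$target_chromosome, r$fam_assay$target_chromosome)))))
  missing_chr <- setdiff(CHROMOSOMES, covered)
  if (length(missing_chr) && strict) {
    warning("panel does not cover chromosome(s): ",
            paste(missing_chr, collapse = ", "))
  }
  panel <- structure(list(reactions = reactions, ratio_definitions = NULL),
                     class = "dpcr_panel")
  panel$ratio_definitions <- default_ratio_definitions(panel)
  panel
}

#' @export
print.dpcr_panel <- function(x, ...) {
  cat("dPCR aneuploidy panel:", length(x$reactions), "duplex reactions\n")
  for (r in x$reactions) {
    cat(sprintf("  %s: VIC:chr%s / FAM:chr%s\n", r$reaction_id,
                r$vic_assay$target_chromosome, r$fam_assay$target_chromosome))
  }
  cat("ratios:", paste(vapply(x$ratio_definitions, function(d)
    sprintf("%s=%s/%s", d$name, d$target, d$reference), ""), collapse = ", "), "\n")
  invisible(x)
}

# reaction whose duplex carries both chromosomes, or NULL
find_reaction <- function(panel, chr_a, chr_b) {
  for (r in panel$reactions) {
    targets <- c(r$vic_assay$target_chromosome, r$fam_assay$target_chromosome)
    if (all(c(chr_a, chr_b) %in% targets)) return(r)
  }
  NULL
}

#' Ratio definitions evaluated by the caller
#'
#' Returns the standard five within-reaction ratio definitions: r13 =
#' 13/21 and r21 = 21/13 (trisomy 13/21 detection, reaction R1), r18X =
#' 18/X (trisomy 18, R2), rX18 = X/18 (monosomy X, R2) and rXY = X/Y
#' (sex-chromosome copy comparison, R3). Definitions whose chromosomes are
#' not co-resident in any reaction of `panel` are omitted with a warning.
#'
#' @param panel A `dpcr_panel`.
#' @return A named list of `(name, target, reference, reaction_id)` triples.
#' @export
default_ratio_definitions <- function(panel) {
  wanted <- list(
    list(name = "r13",  target = "13", reference = "21"),
    list(name = "r21",  target = "21", reference = "13"),
    list(name = "r18X", target = "18", reference = "X"),
    list(name = "rX18", target = "X",  reference = "18"),
    list(name = "rXY",  target = "X",  reference = "Y")
  )
  defs <- list()
  for (w in wanted) {
    rx <- find_reaction(panel, w$target, w$reference)
    if (is.null(rx)) {
      warning("ratio ", w$name, " (", w$target, "/", w$reference,
              ") omitted: chromosomes not paired in any duplex reaction")
      next
    }
    w$reaction_id <- rx$reaction_id
    defs[[w$name]] <- w
  }
  defs
}

#' Define an additional within-reaction ratio
#'
#' Within-well ratios are only meaningful between the two targets of one
#' duplex reaction (volume, loading and chip effects cancel); requesting a
#' ratio across reactions is an error.
#'
#' @param panel A `dpcr_panel`.
#' @param name Ratio identifier.
#' @param target,reference Chromosome labels.
#' @return The ratio definition (invisible errors otherwise).
#' @export
ratio_definition <- function(panel, name, target, reference) {
  target <- as.character(target); reference <- as.character(reference)
  rx <- find_reaction(panel, target, reference)
  if (is.null(rx)) {
    stop("ratio ", name, ": chromosomes ", target, " and ", reference,
         " are measured in different reactions; cross-chip ratios are not defined")
  }
  list(name = name, target = target, reference = reference,
       reaction_id = rx$reaction_id)
}

panel_to_list <- function(panel) {
  list(reactions = lapply(unname(panel$reactions), function(r) list(
    reaction_id = r$reaction_id,
    vic = list(chromosome = r$vic_assay$target_chromosome,
               efficiency = r$vic_assay$efficiency),
    fam = list(chromosome = r$fam_assay$target_chromosome,
               efficiency = r$fam_assay$efficiency)
  )))
}

panel_from_list <- function(x, strict = TRUE) {
  if (is.null(x$reactions) || !length(x$reactions)) {
    stop("panel config has no 'reactions' block")
  }
  reactions <- lapply(x$reactions, function(r) {
    for (k in c("reaction_id", "vic", "fam")) {
      if (is.null(r[[k]])) stop("panel reaction missing field '", k, "'")
    }
    eff <- function(a) if (is.null(a$efficiency)) 1.0 else a$efficiency
    duplex_reaction(r$reaction_id,
                    assay(r$vic$chromosome, "VIC", eff(r$vic)),
                    assay(r$fam$chromosome, "FAM", eff(r$fam)))
  })
  new_panel(reactions, strict = strict)
}

#' Load a panel from a JSON configuration
#'
#' With `config = NULL` (or a config lacking a "panel" block) the default
#' three-reaction panel is returned. In strict mode the panel must have
#' exactly three duplex reactions; in relaxed mode a different count is
#' accepted with a warning.
#'
#' @param config Path to a JSON config file, a parsed config list, or NULL.
#' @param strict Enforce the three-reaction design.
#' @return A `dpcr_panel`.
#' @export
#' @examples
#' load_panel(NULL)
load_panel <- function(config = NULL, strict = TRUE) {
  if (is.null(config)) return(default_panel())
  if (is.character(config)) config <- read_config(config, strict = strict)
  if (is.null(config$panel)) return(default_panel())
  panel_from_list(config$panel, strict = strict)
}

#' Serialize a panel to JSON
#'
#' @param panel A `dpcr_panel`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
write_panel <- function(panel, path = NULL) {
  js <- jsonlite::toJSON(list(panel = panel_to_list(panel)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

CONFIG_BLOCKS <- c("panel", "thresholds", "simulation", "qc")

#' Read a JSON run configuration
#'
#' The configuration is a single JSON document with optional "panel",
#' "thresholds", "simulation" and "qc" blocks. In strict mode unknown
#' top-level keys are rejected (they usually indicate a typo).
#'
#' @param path JSON file path.
#' @param strict Reject unknown top-level keys.
#' @return A named list.
#' @export
read_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(cfg), CONFIG_BLOCKS)
  if (length(unknown)) {
    msg <- paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                  " (expected: ", paste(CONFIG_BLOCKS, collapse = ", "), ")")
    if (strict) stop(msg) else warning(msg)
  }
  cfg
}
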