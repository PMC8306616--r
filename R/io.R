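COUNT_COLUMNS <- c("sample_id", "reaction_id", "n_valid", "n_fam_only",
                   "n_vic_only", "n_double", "n_negative")

#' Read a chip count table
#'
#' CSV with header `sample_id, reaction_id, n_valid, n_fam_only,
#' n_vic_only, n_double, n_negative`, one row per (sample, reaction).
#' Row-level violations (negative counts, category sums not matching
#' n_valid) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COUNT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("count table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[COUNT_COLUMNS]
  if (!nrow(df)) {
    warning("count table is empty")
    return(df)
  }
  num_cols <- COUNT_COLUMNS[3:7]
  problems <- character()
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    vals <- as.numeric(df[i, num_cols])
    if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
      problems <- c(problems, sprintf("line %d: non-integer or negative count", line))
      next
    }
    if (sum(vals[2:5]) != vals[1]) {
      problems <- c(problems,
                    sprintf("line %d: categories sum to %d but n_valid is %d",
                            line, sum(vals[2:5]), vals[1]))
    }
  }
  if (length(problems)) {
    stop("invalid count table:\n  ", paste(problems, collapse = "\n  "))
  }
  df
}

#' Write a chip count table
#'
#' @param counts Data frame in the count-table schema.
#' @param path Output CSV path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(all(COUNT_COLUMNS %in% names(counts)))
  write.csv(counts[COUNT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate a per-well call export to partition counts
#'
#' Converter for generic per-well exports (columns `well`, `fam_call`,
#' `vic_call`, logical or 0/1): tallies the four duplex categories.
#'
#' @param wells Data frame with fam_call and vic_call columns.
#' @return A `partition_counts`.
#' @export
wells_to_counts <- function(wells) {
  stopifnot(all(c("fam_call", "vic_call") %in% names(wells)))
  f <- as.logical(wells$fam_call); v <- as.logical(wells$vic_call)
  partition_counts(nrow(wells), sum(f & !v), sum(!f & v), sum(f & v),
                   sum(!f & !v))
}

#' Quantify every reaction of a count table
#'
#' @param counts Count-table data.frame (see [read_count_table()]).
#' @param panel A `dpcr_panel`.
#' @param policy A `qc_policy`.
#' @param ntc_pattern Regex marking no-template-control sample ids.
#' @param partition_volume_nl,dilution_factor See [copies_per_microliter()].
#' @return Data frame with one row per (sample, reaction, channel):
#'   chromosome, lambda_hat, se, CI, copies/uL, precision, flags; plus a
#'   `quants` attribute holding the nested quant objects keyed by sample
#'   then reaction.
#' @export
quantify_counts <- function(counts, panel = default_panel(),
                            policy = qc_policy(), ntc_pattern = "^NTC",
                            partition_volume_nl = DEFAULT_PARTITION_VOLUME_NL,
                            dilution_factor = 1) {
  rows <- list(); quants <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    reaction <- panel$reactions[[row$reaction_id]]
    if (is.null(reaction)) {
      stop("row ", i, ": reaction_id '", row$reaction_id, "' not in panel")
    }
    pc <- partition_counts(row$n_valid, row$n_fam_only, row$n_vic_only,
                           row$n_double, row$n_negative)
    is_ntc <- grepl(ntc_pattern, row$sample_id)
    q <- quantify_reaction(pc, reaction, policy, partition_volume_nl,
                           dilution_factor)
    if (is_ntc) {
      v <- qc_check(pc, policy, is_ntc = TRUE)
      attr(q, "qc") <- v
    }
    quants[[row$sample_id]][[row$reaction_id]] <- q
    for (chr in names(q)) {
      qq <- q[[chr]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = row$sample_id, reaction_id = row$reaction_id,
        chromosome = chr,
        lambda_hat = qq$lambda_hat, se_lambda = qq$se_lambda,
        ci_lo = qq$ci95[1], ci_hi = qq$ci95[2],
        copies_per_ul = qq$copies_per_ul,
        precision_pct = qq$precision_pct,
        flags = paste(qq$flags, collapse = ";"),
        qc = paste(attr(q, "qc"), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "quants") <- quants
  out
}

#' Call every sample of a count table
#'
#' Runs quantification and karyotype calling over a chip count table.
#' NTC rows (matched by `ntc_pattern`) are checked for contamination and
#' excluded from calling.
#'
#' @inheritParams quantify_counts
#' @param thresholds A `threshold_set`.
#' @return Data frame: sample_id, call_class, sex, r13, r21, r18X, rX18,
#'   rXY, base_class, mosaic_fraction, qc_flags; attribute
#'   `ntc_contaminated` lists contaminated NTC ids.
#' @export
call_samples <- function(counts, panel = default_panel(),
                         thresholds = default_thresholds(),
                         policy = qc_policy(), ntc_pattern = "^NTC") {
  qtab <- quantify_counts(counts, panel, policy, ntc_pattern)
  quants <- attr(qtab, "quants")
  ids <- unique(counts$sample_id)
  ntc_ids <- grep(ntc_pattern, ids, value = TRUE)
  contaminated <- ntc_ids[vapply(ntc_ids, function(id)
    any(unlist(lapply(quants[[id]], attr, "qc")) == "CONTAMINATED"), TRUE)]
  rows <- lapply(setdiff(ids, ntc_ids), function(id) {
    call <- call_sample(quants[[id]], panel, thresholds)
    rv <- function(nm) {
      r <- call$evidence[[nm]]
      if (is.null(r)) NA_real_ else r$value
    }
    data.frame(sample_id = id, call_class = call$call_class, sex = call$sex,
               r13 = rv("r13"), r21 = rv("r21"), r18X = rv("r18X"),
               rX18 = rv("rX18"), rXY = rv("rXY"),
               base_class = call$base_class,
               mosaic_fraction = call$mosaic_fraction,
               qc_flags = paste(call$qc, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ntc_contaminated") <- contaminated
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, seed, config digest, package version, inputs and
#' outputs so a run can be reproduced bit-identically.
#'
#' @param out_dir Output directory.
#' @param command Subcommand name.
#' @param seed Master seed (or NA).
#' @param inputs,outputs Named character vectors of paths.
#' @param config The effective config list (digested into the manifest).
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, seed = NA, inputs = character(),
                           outputs = character(), config = NULL) {
  manifest <- list(
    command = command,
    seed = seed,
    config_digest = if (is.null(config)) NA_character_ else {
      paste0("sum", sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE))))
    },
    package_version = as.character(packageVersion("dpcrscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs), outputs = as.list(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' quantify -> call (-> validate when truth labels are given) over a
#' count table, writing quantification and call TSVs, an optional
#' validation report JSON, and a run manifest into `out_dir`. In strict
#' mode a contaminated NTC aborts the run.
#'
#' @param counts_path Chip count table CSV.
#' @param out_dir Output directory (created if missing).
#' @param truth_path Optional truth CSV (`sample_id, true_karyotype`).
#' @param config Optional config file path or parsed list (panel,
#'   thresholds, qc blocks).
#' @param strict Abort on contaminated NTCs.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisible list of artifact paths; errors on contamination in
#'   strict mode.
#' @export
run_pipeline <- function(counts_path, out_dir, truth_path = NULL,
                         config = NULL, strict = TRUE, seed = NA) {
  if (is.character(config)) config <- read_config(config, strict = strict)
  panel <- load_panel(config, strict = strict)
  thresholds <- load_thresholds(config)
  policy <- qc_policy_from_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_table(counts_path)
  qtab <- quantify_counts(counts, panel, policy)
  calls <- call_samples(counts, panel, thresholds, policy)
  contaminated <- attr(calls, "ntc_contaminated")
  if (length(contaminated)) {
    msg <- paste("contaminated NTC(s):", paste(contaminated, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  quant_path <- file.path(out_dir, "quantification.tsv")
  calls_path <- file.path(out_dir, "calls.tsv")
  write_tsv(qtab, quant_path)
  write_tsv(calls, calls_path)
  outputs <- c(quantification = quant_path, calls = calls_path)
  if (!is.null(truth_path)) {
    truth <- read.csv(truth_path, stringsAsFactors = FALSE)
    report <- validate_calls(calls, truth)
    report_path <- file.path(out_dir, "validation.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
    outputs <- c(outputs, validation = report_path)
  }
  write_manifest(out_dir, "pipeline", seed = seed,
                 inputs = c(counts = counts_path,
                            truth = if (is.null(truth_path)) character() else truth_path),
                 outputs = outputs, config = config)
  invisible(as.list(outputs))
}

qc_policy_from_config <- function(config) {
  blk <- if (is.null(config)) NULL else config$qc
  if (is.null(blk)) return(qc_policy())
  args <- list()
  for (k in c("min_valid_partitions", "ntc_max_positive_wells",
              "saturation_min_negative_wells")) {
    if (!is.null(blk[[k]])) args[[k]] <- blk[[k]]
  }
  unknown <- setdiff(names(blk), names(args))
  if (length(unknown)) stop("unknown qc config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(qc_policy, args)
}
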