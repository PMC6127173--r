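## cli_io: tidy CSV interchange and the end-to-end pipeline driver ---------
##
## Long/tidy CSV is the single interchange format. Every file written by
## the pipeline embeds the seed and a configuration hash in '#' comment
## headers, so a run can be reproduced from its own outputs.

#' Read a tumour volume table
#'
#' Strict schema validation of the long-format volume CSV (columns
#' `mouse_id`, `arm`, `day`, `volume_cm3`): missing columns,
#' non-numeric volumes and duplicate `(mouse, arm, day)` rows are
#' rejected with line-numbered parse errors. Leading `#` comment lines
#' (metadata headers) are skipped.
#'
#' @param path CSV file path.
#' @return data.frame with the validated columns (extra columns are
#'   preserved).
#' @export
read_volume_table <- function(path) {
  if (!file.exists(path)) .parse_error("file not found: %s", path)
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  body <- lines[!meta]
  if (!length(body) || (length(body) == 1 && !nzchar(body)))
    .parse_error("empty volume table: %s", path)
  d <- tryCatch(read.csv(text = body, stringsAsFactors = FALSE),
                error = function(e) .parse_error("malformed CSV: %s",
                                                 conditionMessage(e)))
  if (!nrow(d)) .parse_error("empty volume table: %s", path)
  need <- c("mouse_id", "arm", "day", "volume_cm3")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .parse_error("missing column(s): %s", paste(miss, collapse = ", "))
  ## data line numbers in the original file (1-based, counting header)
  lineno <- which(!meta)[-1][seq_len(nrow(d))]
  for (col in c("day", "volume_cm3")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      .parse_error("non-numeric %s at line %d", col, lineno[bad[1]])
    d[[col]] <- v
  }
  key <- paste(d$mouse_id, d$arm, d$day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    .parse_error("duplicate (mouse, arm, day) row at line %d", lineno[dup[1]])
  d
}

#' Write a tumour volume table
#'
#' Full-precision CSV (round-trips bit-exactly through
#' [read_volume_table()]) with optional `# seed:` / `# config:` metadata
#' headers.
#'
#' @param d data.frame with at least the volume-table columns.
#' @param path output path.
#' @param seed,config_hash optional provenance headers.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(d, path, seed = NULL, config_hash = NULL) {
  .write_csv(d, path, seed = seed, config_hash = config_hash)
}

.fmt_field <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

.write_csv <- function(d, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config_hash)) writeLines(sprintf("# config: %s", config_hash),
                                        con)
  writeLines(paste(names(d), collapse = ","), con)
  if (nrow(d)) {
    cols <- lapply(d, .fmt_field)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

## small stable config fingerprint (polynomial rolling hash mod 2^31-1)
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full in silico trial pipeline
#'
#' Executes sample -> exclude -> trial -> metrics -> survival ->
#' thresholds for one case and writes every stage's tidy CSV plus a
#' summary (median survivals, hazard-ratio table, threshold ranges)
#' under `out_dir`. Fully reproducible from `(config, seed)`; the seed
#' and a config hash are embedded in every output header.
#'
#' @param config list with elements `ranges` (a [case_ranges()]), `n`
#'   (population size), `seed`, `protocol` (name or [protocol()]
#'   object), `out_dir`, and optional `model`, `selector`
#'   (threshold sweep selector, default `"ratio"`), `alpha`,
#'   `cutoff`, `stages` (character subset of
#'   `c("metrics", "survival", "thresholds")`).
#' @return invisible list with the stage objects and output paths.
#' @export
run_pipeline <- function(config) {
  for (f in c("ranges", "n", "seed", "out_dir"))
    if (is.null(config[[f]]))
      .config_error("missing pipeline configuration field '%s'", f)
  if (!inherits(config$ranges, "case_ranges"))
    .config_error("config$ranges must be a case_ranges object")
  proto <- config$protocol
  if (is.null(proto)) proto <- "A"
  if (is.character(proto)) proto <- make_protocol(proto)
  stages <- config$stages
  if (is.null(stages)) stages <- c("metrics", "survival", "thresholds")
  selector <- if (is.null(config$selector)) "ratio" else config$selector
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  cutoff <- if (is.null(config$cutoff)) 2 else config$cutoff
  model <- config$model
  if (is.null(model)) model <- build_default_network()

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  emit <- function(d, name) {
    p <- file.path(config$out_dir, name)
    .write_csv(d, p, seed = config$seed, config_hash = hash)
    p
  }

  pop <- sample_population(config$ranges, config$n, seed = config$seed)
  paths <- list(population = emit(pop, "population.csv"))

  trial <- run_trial(pop, proto, model = model, seed = config$seed)
  paths$trajectories <- emit(trial$trajectories, "trajectories.csv")
  paths$exclusions <- emit(trial$excluded, "exclusions.csv")
  out <- list(population = pop, trial = trial, paths = paths)

  if ("metrics" %in% stages) {
    rtv <- rtv_timecourse(trial)
    tc <- timepoint_comparison(trial, alpha = alpha)
    metrics <- merge(rtv, tc, by = "day")
    out$metrics <- metrics
    paths$rtv <- emit(metrics, "rtv.csv")
  }
  if (any(c("survival", "thresholds") %in% stages)) {
    recs <- derive_survival(trial, cutoff = cutoff)
    out$records <- recs
    paths$survival <- emit(recs, "survival_records.csv")
  }
  if ("survival" %in% stages) {
    ctrl <- out$records[out$records$group == "control", ]
    trt <- out$records[out$records$group == "treated", ]
    comp <- survival_comparison(trt, ctrl, "treated (all) vs control (all)")
    out$comparison <- comp
    km <- rbind(cbind(group = "control", km_estimate(ctrl)),
                cbind(group = "treated", km_estimate(trt)))
    paths$km <- emit(km, "km_curves.csv")
    paths$comparison <- emit(comp, "comparisons.csv")
  }
  if ("thresholds" %in% stages) {
    recs <- merge(out$records, trial$params[, c("mouse_id", "k0", "k1")],
                  by = "mouse_id")
    scan <- threshold_scan(recs, selector = selector, alpha = alpha)
    rng <- valid_range(scan)
    out$scan <- scan
    out$range <- rng
    paths$scan <- emit(as.data.frame(scan), "threshold_scan.csv")
    paths$ranges <- emit(as.data.frame(rng), "threshold_ranges.csv")
  }

  summary <- data.frame(
    item = c("case", "n_sampled", "n_retained", "n_excluded", "horizon_days",
             if (!is.null(out$metrics)) "endpoint_rtv",
             if (!is.null(out$comparison)) c("hr_treated_vs_control",
                                             "logrank_p"),
             if (!is.null(out$range) && nrow(out$range)) c("threshold_low",
                                                           "threshold_high")),
    value = c(config$ranges$case_label, config$n, nrow(trial$params),
              nrow(trial$excluded), trial$horizon,
              if (!is.null(out$metrics))
                .fmt_field(out$metrics$rtv[nrow(out$metrics)]),
              if (!is.null(out$comparison))
                c(.fmt_field(out$comparison$hr),
                  .fmt_field(out$comparison$p_value)),
              if (!is.null(out$range) && nrow(out$range))
                c(.fmt_field(out$range$low[which(out$range$primary)[1]]),
                  .fmt_field(out$range$high[which(out$range$primary)[1]]))),
    stringsAsFactors = FALSE)
  paths$summary <- emit(summary, "summary.csv")
  out$paths <- paths
  invisible(out)
}
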