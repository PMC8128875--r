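# ---------------------------------------------------------------------------
# End-to-end orchestration: generate or load a stream, fit popularity tail
# models, build the three network formulations, compute centrality series,
# run the evolution analyses and the rolling predictor, and write every
# artifact plus a hashed run manifest under one output directory.
# ---------------------------------------------------------------------------

# stable per-stage seed derivation from one global seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 9176L) %% 2147483647L
}

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds derive from it stably.
#' @param n_days,embedding_dim,arrival_rate,dispersion,shift_day synthetic
#'   stream shape (see \code{\link{example_stream_config}}).
#' @param stream_path optional JSONL path; when set the synthetic stage is
#'   skipped and the stream is loaded instead.
#' @param daily_threshold,growth_threshold,delta network formulation knobs.
#' @param run_predictor,run_second_order,predict_horizon stage toggles.
#' @param top_k positive-class cutoff for the predictor.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir = "misinfonet-run", seed = 1L, n_days = 60L,
                       embedding_dim = 768L, arrival_rate = 15,
                       dispersion = 0.35, shift_day = 30L,
                       stream_path = NULL, daily_threshold = 0.7,
                       growth_threshold = 0.8, delta = 3L,
                       run_predictor = TRUE, run_second_order = TRUE,
                       predict_horizon = 5L, top_k = 20L) {
  stopifnot(daily_threshold > 0, daily_threshold < 1,
            growth_threshold > 0, growth_threshold < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' \code{\link{run_config}}.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

stage_log <- function(manifest, name, t0, ...) {
  info <- list(...)
  info$wall_seconds <- round(as.numeric(Sys.time()) - t0, 3)
  manifest$stages[[name]] <- info
  message(sprintf("[%s] done in %.2fs %s", name, info$wall_seconds,
                  paste(names(info)[names(info) != "wall_seconds"],
                        unlist(info[names(info) != "wall_seconds"]),
                        sep = "=", collapse = " ")))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes all artifacts
#' (stream JSONL, tail-fit report JSON, edge lists/GraphML, centrality and
#' evolution CSV tables, prediction report JSON) under
#' \code{config$out_dir}, and returns a manifest with a content hash and
#' wall-clock time per artifact, written as \code{run_manifest.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  outfile <- function(...) file.path(config$out_dir, ...)

  # stage 1: stream
  t0 <- as.numeric(Sys.time())
  if (is.null(config$stream_path)) {
    sc <- example_stream_config(
      n_days = config$n_days, embedding_dim = config$embedding_dim,
      arrival_rate = config$arrival_rate, dispersion = config$dispersion,
      shift_day = config$shift_day, seed = derive_seed(config$seed, 1L))
    stream <- generate_stream(sc)
  } else {
    stream <- read_stream_jsonl(config$stream_path)
  }
  write_stream_jsonl(stream, outfile("stream.jsonl"))
  manifest <- stage_log(manifest, "stream", t0,
                        records = nrow(stream$records))

  # stage 2: heavy-tail popularity fits
  t0 <- as.numeric(Sys.time())
  pops <- stream$records$popularity
  fit_report <- NULL
  if (!all(is.na(pops))) {
    rep_ <- heavytail_report(pops[!is.na(pops)],
                             seed = derive_seed(config$seed, 2L))
    fit_report <- list(
      lognormal = rep_$lognormal[c("xmin", "params", "D", "n_tail")],
      powerlaw = rep_$powerlaw[c("xmin", "params", "D", "n_tail")],
      p_KS_lognormal = rep_$gof_lognormal$p_KS,
      p_KS_powerlaw = rep_$gof_powerlaw$p_KS,
      R = rep_$lrt$R, p = rep_$lrt$p)
    jsonlite::write_json(fit_report, outfile("tail_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- stage_log(manifest, "fit_tail", t0,
                        fitted = !is.null(fit_report))

  # stage 3: networks
  t0 <- as.numeric(Sys.time())
  daily <- build_daily_networks(stream, config$daily_threshold)
  tg2 <- grow_cumulative(stream, config$growth_threshold)
  tg3 <- grow_with_deletion(stream, config$growth_threshold, config$delta)
  export_edges_tsv(tg3, outfile("deletion_edges.tsv"))
  export_graphml(tg3, outfile("deletion_graph.graphml"))
  export_edges_tsv(tg2, outfile("cumulative_edges.tsv"))
  manifest <- stage_log(manifest, "networks", t0,
                        daily_days = length(daily),
                        cumulative_nodes = nrow(tg2$nodes),
                        deletion_alive = sum(is.na(tg3$nodes$death_day)))

  # stage 4: centrality series on daily networks
  t0 <- as.numeric(Sys.time())
  measures <- c("degree", "closeness",
                if (config$run_second_order) "second_order")
  ser <- lapply(measures, function(ms)
    suppressWarnings(cbind(measure = ms, centrality_series(daily, ms))))
  ser <- do.call(rbind, ser)
  write.csv(ser, outfile("centrality_series.csv"), row.names = FALSE)
  manifest <- stage_log(manifest, "centrality", t0,
                        measures = paste(measures, collapse = "+"))

  # stage 5: evolution analyses on the deletion network
  t0 <- as.numeric(Sys.time())
  counts <- alive_counts(tg3)
  write.csv(data.frame(day = seq_along(counts) - 1L, alive = counts),
            outfile("network_size.csv"), row.names = FALSE)
  cycles <- detect_cycles(tg3)
  write.csv(cycles, outfile("cycle_events.csv"), row.names = FALSE)
  ft <- fitness_table(tg3)
  write.csv(ft, outfile("fitness.csv"), row.names = FALSE)
  pa <- tryCatch(estimate_pa_function(tg3), error = function(e) NULL)
  if (!is.null(pa))
    write.csv(data.frame(k = as.numeric(names(pa$A_k)), A_k = pa$A_k,
                         alpha = pa$alpha),
              outfile("pa_kernel.csv"), row.names = FALSE)
  # survivor sets and their top terms
  shift <- if (!is.null(config$shift_day)) config$shift_day
  else tg3$current_day %/% 2L
  surv_ids <- survivors(tg3, 0L, min(shift, tg3$current_day))
  writeLines(surv_ids, outfile("survivors_day0.txt"))
  if (length(surv_ids) && length(stream$tokens)) {
    docs <- stream$tokens[surv_ids]
    docs <- docs[lengths(docs) > 0]
    if (length(docs)) {
      tt <- tfidf_top_terms(docs)
      write.csv(tt, outfile("top_terms_survivors.csv"), row.names = FALSE)
    }
  }
  manifest <- stage_log(manifest, "evolution", t0,
                        cycles = nrow(cycles), survivors = length(surv_ids))

  # stage 6: predictor
  t0 <- as.numeric(Sys.time())
  if (isTRUE(config$run_predictor)) {
    cfg <- mlp_config(seed = derive_seed(config$seed, 6L))
    er <- rolling_evaluate(daily, stream, "degree",
                           horizon = config$predict_horizon,
                           k = config$top_k, n_seeds = 3L, config = cfg,
                           min_train_days = max(10L,
                                                config$predict_horizon))
    jsonlite::write_json(
      list(measure = er$measure, horizon = er$horizon,
           accuracy = er$accuracy, balanced_accuracy = er$balanced_accuracy,
           auroc = er$auroc),
      outfile("eval_report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(er$per_block, outfile("eval_blocks.csv"), row.names = FALSE)
    manifest <- stage_log(manifest, "predictor", t0,
                          accuracy = round(er$accuracy[["mean"]], 4))
  } else {
    manifest$stages$predictor <- list(skipped = TRUE)
    message("[predictor] skipped by config")
  }

  # manifest with content hashes
  arts <- list.files(config$out_dir, full.names = TRUE)
  arts <- arts[!basename(arts) %in% "run_manifest.json"]
  manifest$artifacts <- lapply(stats::setNames(arts, basename(arts)),
                               function(f) list(
                                 md5 = unname(tools::md5sum(f)),
                                 bytes = file.size(f)))
  jsonlite::write_json(manifest, outfile("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Validate a stream JSONL file
#'
#' Checks the header, per-record schema, unit embedding norms and
#' non-decreasing day order.
#'
#' @param path JSONL file.
#' @return list: \code{n_records}, \code{violations} (data.frame line,
#'   problem).
#' @export
validate_stream <- function(path) {
  lines <- readLines(path)
  probs <- list()
  flag <- function(line, problem)
    probs[[length(probs) + 1L]] <<- data.frame(line = line,
                                               problem = problem)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$type, "header"))
    flag(1L, "missing or malformed header")
  last_day <- -1L
  n <- 0L
  for (i in seq_along(lines)[-1]) {
    o <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(o)) { flag(i, "unparseable JSON"); next }
    n <- n + 1L
    if (is.null(o$id) || is.null(o$day) || is.null(o$embedding)) {
      flag(i, "missing required field (id/day/embedding)")
      next
    }
    nrm <- sqrt(sum(as.numeric(o$embedding)^2))
    if (abs(nrm - 1) > 1e-6) flag(i, sprintf("non-unit embedding (%.4f)",
                                             nrm))
    if (!is.null(hdr$embedding_dim) &&
        length(o$embedding) != hdr$embedding_dim)
      flag(i, "embedding dimension mismatch")
    if (o$day < last_day) flag(i, "out-of-order day")
    last_day <- max(last_day, o$day)
  }
  violations <- if (length(probs)) do.call(rbind, probs)
  else data.frame(line = integer(), problem = character())
  list(n_records = n, violations = violations)
}

#' Command-line entry point
#'
#' Subcommands: \code{generate}, \code{fit-tail}, \code{build-net},
#' \code{centrality}, \code{evolution}, \code{predict}, \code{validate},
#' \code{run-all}.  All of them are thin wrappers over
#' \code{\link{run_pipeline}} stage toggles; see
#' \code{inst/scripts/misinfonet} for the installed launcher.
#'
#' @param args character vector of CLI arguments (default: command line).
#' @return exit status, invisibly.
#' @export
misinfonet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: misinfonet <command> [--config FILE] [--out DIR] [--seed N]",
    "commands: generate | fit-tail | build-net | centrality | evolution |",
    "          predict | validate | run-all", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(config = NULL, out = "misinfonet-run", seed = 1L,
              stream = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option --", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
  else run_config(out_dir = opt$out, seed = as.integer(opt$seed))
  cfg$out_dir <- opt$out
  if (!is.null(opt$stream)) cfg$stream_path <- opt$stream
  if (cmd == "validate") {
    if (is.null(opt$stream)) stop("validate requires --stream FILE")
    v <- validate_stream(opt$stream)
    message(sprintf("%d records, %d violations", v$n_records,
                    nrow(v$violations)))
    if (nrow(v$violations)) print(v$violations)
    return(invisible(as.integer(nrow(v$violations) > 0)))
  }
  toggles <- switch(cmd,
    "generate" = list(run_predictor = FALSE, run_second_order = FALSE,
                      only = "stream"),
    "fit-tail" = list(run_predictor = FALSE, run_second_order = FALSE),
    "build-net" = list(run_predictor = FALSE, run_second_order = FALSE),
    "centrality" = list(run_predictor = FALSE),
    "evolution" = list(run_predictor = FALSE),
    "predict" = list(),
    "run-all" = list(),
    stop("unknown command: ", cmd, "\n", usage))
  if (!is.null(toggles$run_predictor))
    cfg$run_predictor <- toggles$run_predictor
  if (!is.null(toggles$run_second_order))
    cfg$run_second_order <- toggles$run_second_order
  run_pipeline(cfg)
  invisible(0L)
}
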