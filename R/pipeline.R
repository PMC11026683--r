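## End-to-end orchestration: simulate -> condition -> extract -> statistics
## -> classify -> transitions -> report, from a single YAML (or JSON)
## configuration, with seeds and a config hash embedded in every output for
## byte-reproducible reruns.

#' Default run configuration
#'
#' @return named list of configuration defaults; see the fields themselves
#'   for units. Paths are `NULL` until filled from a config file or a
#'   simulated cohort.
#' @export
default_run_config <- function() {
  list(
    manifest = NULL, mask = NULL, out_dir = "capdyn-run",
    simulate = list(enabled = TRUE, n_per_cell = 2L, n_frames = 980L,
                    noise_sd = 0.3, n_states = 6L, n_voxels = 500L,
                    persistence = 0.85, raw_mode = FALSE),
    conditioning = list(enabled = FALSE, trim_pre = 6L, band = c(0.01, 0.2),
                        order = 2L, trim_post = 4L, detrend_order = 2L),
    extraction = list(k_range = c(2L, 12L), K = NULL, top_pct = 10,
                      bottom_pct = 5, n_restarts = 10L,
                      gain_threshold = 0.005),
    statistics = list(alpha_t = 0.01, min_cluster = 10L, fdr_q = 0.05),
    classify = list(enabled = FALSE, mode = "spatial", classes = "2class",
                    age = "4M", n_iter = 50L, lambda = 1),
    transitions = list(n_surrogates = 10000L, fdr_q = 0.05),
    seed = 1L)
}

#' Read a run configuration from YAML
#'
#' Values present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_run_config(), user)
}

config_hash <- function(config) {
  ## the hash identifies the analysis, not where it is written
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# capdyn config_hash=%s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' Load a cohort from a manifest of NIfTI scans
#'
#' @param manifest_path CSV with columns `subject_id, genotype, age, path`.
#' @param mask_path NIfTI binary mask.
#' @param tr repetition time in seconds (used if the scan header lacks one).
#' @return list with `manifest`, `scans` (named `subject.age`), mask
#'   `coords`.
#' @export
load_cohort <- function(manifest_path, mask_path, tr = 0.6) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  mask <- read_nifti(mask_path)
  coords <- which(mask$data != 0, arr.ind = TRUE)
  coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), , drop = FALSE]
  scans <- list()
  for (i in seq_len(nrow(manifest))) {
    vol <- read_nifti(manifest$path[i])
    d3 <- dim(vol$data)[1:3]
    tt <- dim(vol$data)[4]
    dat <- matrix(NA_real_, nrow(coords), tt)
    for (t in seq_len(tt)) {
      frame <- array(vol$data[, , , t], dim = d3)
      dat[, t] <- frame[coords]
    }
    tr_i <- if (length(vol$pixdim) >= 4 && vol$pixdim[4] > 0) vol$pixdim[4] else tr
    key <- paste(manifest$subject_id[i], manifest$age[i], sep = ".")
    scans[[key]] <- voxel_time_series(dat, coords, tr = tr_i,
                                      subject_id = manifest$subject_id[i],
                                      genotype = manifest$genotype[i],
                                      age = manifest$age[i])
  }
  list(manifest = manifest, scans = scans, coords = coords)
}

#' Run the full CAP analysis pipeline
#'
#' Executes the configured stages in order and writes every table with the
#' configuration hash in its header; rerunning the same configuration
#' reproduces identical CSVs. Stage failures abort with a stage-tagged
#' error, preserving partial outputs.
#'
#' @param config configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @return the run directory, invisibly; outputs: `labels.csv`,
#'   `ev_curve.csv`, `cap_occurrence.csv`, `temporal_metrics.csv`,
#'   `temporal_anova.csv`, `transition_*.csv`, `classification.csv` (when
#'   enabled), `run_info.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  hash <- config_hash(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## --- inputs ------------------------------------------------------------
  cohort <- stage("input", {
    if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      states <- state_spec(n_states = sim$n_states, n_voxels = sim$n_voxels,
                           seed = config$seed)
      design <- cohort_design(
        n_per_cell = sim$n_per_cell, n_frames = sim$n_frames,
        noise_sd = sim$noise_sd, states = states,
        markov = uniform_persistence_markov(sim$n_states, sim$persistence),
        raw_mode = isTRUE(sim$raw_mode), seed = config$seed)
      generate_cohort(design)
    } else {
      if (is.null(config$manifest) || !file.exists(config$manifest))
        stop("manifest not found: ", config$manifest %||% "<missing>")
      if (is.null(config$mask) || !file.exists(config$mask))
        stop("mask not found: ", config$mask %||% "<missing>")
      load_cohort(config$manifest, config$mask)
    }
  })

  scans <- cohort$scans
  if (isTRUE(config$conditioning$enabled)) {
    cc <- config$conditioning
    cfg <- conditioning_config(cc$trim_pre, cc$band, cc$order, cc$trim_post,
                               cc$detrend_order)
    scans <- stage("condition", lapply(scans, condition_series, cfg = cfg))
  }

  ## --- extraction --------------------------------------------------------
  ex <- stage("extract", {
    e <- config$extraction
    kr <- seq(e$k_range[1], e$k_range[2])
    suppressMessages(extract_caps(scans, k_range = kr, K = e$K,
                                  top_pct = e$top_pct,
                                  bottom_pct = e$bottom_pct,
                                  seed = config$seed,
                                  n_restarts = e$n_restarts,
                                  gain_threshold = e$gain_threshold))
  })
  lab_df <- data.frame(subject_id = ex$prov$subject_id,
                       genotype = ex$prov$genotype, age = ex$prov$age,
                       frame = ex$prov$frame, cap = ex$labels)
  write_stamped_csv(lab_df, file.path(out, "labels.csv"), hash)
  if (!is.null(ex$curve))
    write_stamped_csv(ex$curve, file.path(out, "ev_curve.csv"), hash)
  write_stamped_csv(data.frame(cap = seq_len(ex$K),
                               occurrence_pct = ex$maps$occurrence_pct),
                    file.path(out, "cap_occurrence.csv"), hash)

  ## --- temporal statistics ----------------------------------------------
  metrics <- stage("stats", temporal_metrics(ex$sequences, cohort$manifest,
                                             ex$K))
  write_stamped_csv(metrics, file.path(out, "temporal_metrics.csv"), hash)
  anova_tab <- stage("stats", rm_anova_temporal(metrics))
  write_stamped_csv(anova_tab, file.path(out, "temporal_anova.csv"), hash)

  ## --- transitions per genotype-age group --------------------------------
  trans_tables <- stage("transitions", {
    keys <- paste(cohort$manifest$genotype, cohort$manifest$age, sep = ".")
    tabs <- list()
    for (cl in sort(unique(keys))) {
      scan_keys <- paste(cohort$manifest$subject_id,
                         cohort$manifest$age, sep = ".")[keys == cl]
      seqs <- ex$sequences[scan_keys]
      tabs[[cl]] <- analyze_transitions(
        seqs, ex$K, n_surrogates = config$transitions$n_surrogates,
        seed = config$seed + match(cl, sort(unique(keys))),
        q = config$transitions$fdr_q)
    }
    tabs
  })
  edges <- do.call(rbind, lapply(names(trans_tables), function(cl) {
    e <- transition_edge_list(trans_tables[[cl]])
    cbind(group = cl, e)
  }))
  write_stamped_csv(edges, file.path(out, "transition_edges.csv"), hash)
  pers <- do.call(rbind, lapply(names(trans_tables), function(cl)
    data.frame(group = cl, cap = seq_len(ex$K),
               persistence = trans_tables[[cl]]$persistence)))
  write_stamped_csv(pers, file.path(out, "transition_persistence.csv"), hash)

  ## --- classification (optional) -----------------------------------------
  if (isTRUE(config$classify$enabled)) {
    cl <- config$classify
    res <- stage("classify", train_eval(
      scans, cohort$manifest, mode = cl$mode, classes = cl$classes,
      age = cl$age, n_iter = cl$n_iter, seed = config$seed, K = ex$K,
      lambda = cl$lambda))
    write_stamped_csv(data.frame(iteration = seq_along(res$accuracy),
                                 accuracy = res$accuracy,
                                 chance = res$chance),
                      file.path(out, "classification.csv"), hash)
    jsonlite::write_json(list(p_value = res$p_value,
                              confusion = res$confusion),
                         file.path(out, "classification_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(
    list(config = config, config_hash = hash, K = ex$K,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         package_version = as.character(utils::packageVersion("capdyn"))),
    file.path(out, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Summarize a completed run as a markdown report
#'
#' Writes `report.md` (EV curve and elbow, CAP occurrence, anti-pair
#' summary, temporal effects, transition matrices with significance and
#' directionality marks) plus a PDF with the EV curve when a curve was
#' computed. Incomplete runs produce a partial report with warnings.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return path to `report.md`, invisibly.
#' @export
make_report <- function(run_dir) {
  path <- file.path(run_dir, "report.md")
  lines <- c("# CAP analysis report", "")
  read_run_csv <- function(name) {
    f <- file.path(run_dir, name)
    if (!file.exists(f)) {
      warning("missing output: ", name, call. = FALSE)
      return(NULL)
    }
    read.csv(f, comment.char = "#")
  }
  curve <- read_run_csv("ev_curve.csv")
  if (!is.null(curve)) {
    lines <- c(lines, "## Explained variance",
               "", "| K | EV | fractional gain |", "|---|----|----|",
               sprintf("| %d | %.4f | %s |", curve$K, curve$EV,
                       ifelse(is.na(curve$gain), "-",
                              sprintf("%.4f", curve$gain))), "")
    grDevices::pdf(file.path(run_dir, "ev_curve.pdf"), width = 5, height = 4)
    graphics::plot(curve$K, curve$EV, type = "b", xlab = "K",
                   ylab = "explained variance")
    grDevices::dev.off()
  }
  occ <- read_run_csv("cap_occurrence.csv")
  if (!is.null(occ))
    lines <- c(lines, "## CAP occurrence (cohort)", "",
               sprintf("- CAP %d: %.2f%%", occ$cap, occ$occurrence_pct), "")
  edges <- read_run_csv("transition_edges.csv")
  if (!is.null(edges)) {
    lines <- c(lines, "## Significant transitions", "")
    sig <- edges[edges$significant, ]
    if (!nrow(sig)) {
      lines <- c(lines, "No transition is significant at the configured FDR level.", "")
    } else {
      lines <- c(lines,
                 "| group | i -> j | p_ij | FDR p | directional |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %d -> %d | %.3f | %.4f | %s |",
                         sig$group, sig$i, sig$j, sig$p_ij, sig$p_fdr,
                         ifelse(sig$directional, "yes", "")), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches `capdyn <subcommand> --config <yaml>`; subcommands:
#' `simulate`, `all` (full pipeline), `report`. Installed as
#' `inst/cli/capdyn.R`, runnable with `Rscript`.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return exit status, invisibly.
#' @export
capdyn_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: capdyn <simulate|all|report> [--config file.yaml] [--out dir] [--seed N]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- list(config = NULL, out = NULL, seed = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stop("bad argument: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opt$config)) read_run_config(opt$config)
            else default_run_config()
  if (!is.null(opt$out)) config$out_dir <- opt$out
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  switch(cmd,
    simulate = {
      sim <- config$simulate
      states <- state_spec(n_states = sim$n_states, n_voxels = sim$n_voxels,
                           seed = config$seed)
      design <- cohort_design(n_per_cell = sim$n_per_cell,
                              n_frames = sim$n_frames,
                              noise_sd = sim$noise_sd, states = states,
                              raw_mode = isTRUE(sim$raw_mode),
                              seed = config$seed)
      generate_cohort(design, dir = config$out_dir)
      message("cohort written to ", config$out_dir)
    },
    all = {
      dir <- run_pipeline(config)
      make_report(dir)
      message("run complete: ", dir)
    },
    report = make_report(config$out_dir),
    stop("unknown subcommand: ", cmd, "\n", usage, call. = FALSE))
  invisible(0L)
}
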