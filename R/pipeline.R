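# End-to-end orchestration: QC -> intrinsic -> synaptic -> correlation ->
# group statistics, plus the command-line entry point.

#' Pipeline configuration
#'
#' Every analysis parameter defaults to its documented value, so an empty
#' call reproduces the canonical settings.
#'
#' @param input cohort directory (as written by [generate_cohort()]).
#' @param out output directory for result tables.
#' @param seed master seed (used only when `simulate = TRUE`).
#' @param simulate if `TRUE`, generate the cohort into `input` first.
#' @param sim_args list of arguments forwarded to [generate_cohort()].
#' @param dvdt_threshold spike-detection criterion, mV/ms.
#' @param k connection noise-SD multiplier.
#' @param latency_center,latency_tol monosynaptic latency window, ms.
#' @param corr_method `"filtered_voltage"` or `"binned_spikes"`.
#' @param corr_window_min correlation window, minutes.
#' @param baseline_hz low-pass baseline cutoff, Hz.
#' @param amp_min,amp_max spontaneous EPSP acceptance window, mV.
#' @param stages character subset of
#'   `c("qc", "intrinsic", "synaptic", "correlate", "stats")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out, seed = 1, simulate = FALSE,
                            sim_args = list(), dvdt_threshold = 1.5,
                            k = 1.5, latency_center = 2, latency_tol = 1,
                            corr_method = "filtered_voltage",
                            corr_window_min = 3, baseline_hz = 1,
                            amp_min = 0.3, amp_max = 10,
                            stages = c("qc", "intrinsic", "synaptic",
                                       "correlate", "stats")) {
  structure(list(input = input, out = out, seed = seed, simulate = simulate,
                 sim_args = sim_args, dvdt_threshold = dvdt_threshold,
                 k = k, latency_center = latency_center,
                 latency_tol = latency_tol, corr_method = corr_method,
                 corr_window_min = corr_window_min,
                 baseline_hz = baseline_hz, amp_min = amp_min,
                 amp_max = amp_max, stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline over a cohort directory
#'
#' Walks `config$input` (layout `pair_XX/<condition>/{evoked,spont,iv_*}`),
#' runs the requested stages per pair, and writes result tables to
#' `config$out`: `qc.csv`, `pairs.csv` (evoked amplitudes, PPR, latency,
#' connection call), `intrinsic.csv`, `epsp_summary.csv`, `events.csv`,
#' `correlations.csv`, `comparisons.csv` (paired before/after contrasts
#' per measurement) and `run_manifest.json`.  Per-pair failures are
#' recorded in the manifest and do not abort the run; configuration errors
#' do.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list of the result data frames.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$simulate) {
    args <- config$sim_args
    args$dir <- config$input
    args$seed <- config$seed
    do.call(generate_cohort, args)
  }
  if (!dir.exists(config$input))
    stop("run_pipeline: input directory '", config$input, "' does not exist")
  pair_dirs <- sort(list.dirs(config$input, recursive = FALSE))
  pair_dirs <- pair_dirs[grepl("pair_", basename(pair_dirs))]
  if (length(pair_dirs) == 0)
    stop("run_pipeline: no pair directories under '", config$input, "'")
  if (!dir.exists(config$out) && !dir.create(config$out, recursive = TRUE))
    stop("run_pipeline: cannot create output directory")

  qc_rows <- list(); pair_rows <- list(); corr_rows <- list()
  intr_rows <- list(); epsp_rows <- list(); event_rows <- list()
  errors <- list()
  stage <- function(s) s %in% config$stages

  for (pd in pair_dirs) {
    pid <- basename(pd)
    for (cd in sort(list.dirs(pd, recursive = FALSE))) {
      cond <- basename(cd)
      res <- tryCatch({
        out <- list()
        ev_dir <- file.path(cd, "evoked")
        sp_dir <- file.path(cd, "spont")
        if (dir.exists(ev_dir)) {
          pair <- read_pair_recording(ev_dir)
          if (stage("qc")) {
            for (rec in list(pair$pre, pair$post)) {
              q <- qc_recording(rec)
              qc_rows[[length(qc_rows) + 1]] <- data.frame(
                pair_id = pid, condition = cond, cell_id = q$cell_id,
                leak_pA = q$leak_current, seal_Gohm = q$seal_resistance,
                pass = q$pass,
                reasons = paste(q$reasons, collapse = ";"))
            }
          }
          if (stage("synaptic")) {
            resp <- evoked_response(pair,
                                    dvdt_threshold = config$dvdt_threshold)
            call <- classify_connection(resp, k = config$k,
                                        latency_center = config$latency_center,
                                        latency_tol = config$latency_tol)
            ppr <- tryCatch(paired_pulse_ratio(resp), error = function(e) NA_real_)
            pair_rows[[length(pair_rows) + 1]] <- data.frame(
              pair_id = pid, condition = cond,
              mean_epsc1_pA = resp$mean_epsc1,
              mean_epsc2_pA = resp$mean_epsc2, ppr = ppr,
              latency_ms = resp$latency, connected = call$connected,
              noise_sd_pA = resp$noise_sd)
          }
        }
        if (dir.exists(sp_dir)) {
          spair <- read_pair_recording(sp_dir)
          dur_min <- trace_duration(spair$pre$sweeps[[1]]$signal) / 60000
          if (stage("correlate")) {
            cr <- pair_correlation(spair,
                                   window_min = min(config$corr_window_min,
                                                    floor(dur_min * 1e9) / 1e9),
                                   method = config$corr_method,
                                   baseline_hz = config$baseline_hz)
            corr_rows[[length(corr_rows) + 1]] <- data.frame(
              pair_id = pid, condition = cond, method = cr$method,
              window_s = cr$window_s, coefficient = cr$coefficient)
          }
          if (stage("synaptic") && dur_min >= 1) {
            for (role in c("pre", "post")) {
              rec <- spair[[role]]
              det <- detect_spontaneous_epsps(rec$sweeps[[1]]$signal,
                                              amp_min = config$amp_min,
                                              amp_max = config$amp_max,
                                              baseline_hz = config$baseline_hz)
              epsp_rows[[length(epsp_rows) + 1]] <- data.frame(
                pair_id = pid, condition = cond, cell_id = rec$cell_id,
                freq_per_min = det$summary$frequency_per_min,
                mean_amp_mV = det$summary$mean_amplitude_mV,
                n_events = det$summary$n_events)
              if (nrow(det$events))
                event_rows[[length(event_rows) + 1]] <- data.frame(
                  cell_id = rec$cell_id, condition = cond,
                  t_ms = det$events$t_ms, amp_mV = det$events$amp_mV)
            }
          }
        }
        if (stage("intrinsic")) {
          for (role in c("iv_pre", "iv_post")) {
            iv_dir <- file.path(cd, role)
            if (!dir.exists(iv_dir)) next
            rec <- read_recording(iv_dir)
            fi <- fi_curve(rec, dvdt_threshold = config$dvdt_threshold)
            pp <- input_resistance(rec, dvdt_threshold = config$dvdt_threshold)
            thr <- tryCatch(firing_threshold_60pA(
              rec, dvdt_threshold = config$dvdt_threshold),
              error = function(e) NA_real_)
            intr_rows[[length(intr_rows) + 1]] <- data.frame(
              pair_id = pid, condition = cond, cell_id = rec$cell_id,
              rm_Mohm = pp$input_resistance_Mohm,
              vrest_mV = pp$resting_potential_mV,
              threshold_mV = as.numeric(thr),
              rheobase_pA = fi$rheobase_pA,
              mean_spikes = mean(fi$table$n_spikes),
              mean_if_Hz = mean(fi$table$mean_if_Hz, na.rm = TRUE),
              first2_Hz = mean(fi$table$first2_Hz, na.rm = TRUE))
          }
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        errors[[length(errors) + 1]] <- list(pair = pid, condition = cond,
                                             stage = "analysis", message = res)
    }
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  tables <- list(qc = bind(qc_rows), pairs = bind(pair_rows),
                 intrinsic = bind(intr_rows), epsp_summary = bind(epsp_rows),
                 events = bind(event_rows), correlations = bind(corr_rows))

  if (stage("stats")) {
    comp <- list()
    add_contrasts <- function(tab, id_col, measure_cols) {
      if (is.null(tab)) return()
      conds <- unique(tab$condition)
      pairs_of_conds <- list(c("before", "after_stim"),
                             c("after_stim", "rest_post"),
                             c("before", "rest_post"))
      for (pc in pairs_of_conds) {
        if (!all(pc %in% conds)) next
        a <- tab[tab$condition == pc[1], ]
        b <- tab[tab$condition == pc[2], ]
        ids <- intersect(a[[id_col]], b[[id_col]])
        if (length(ids) < 2) next
        a <- a[match(ids, a[[id_col]]), ]
        b <- b[match(ids, b[[id_col]]), ]
        for (m in measure_cols) {
          va <- a[[m]]; vb <- b[[m]]
          ok <- is.finite(va) & is.finite(vb)
          if (sum(ok) < 2) next
          gc <- group_comparison(va[ok], vb[ok], labels = pc, paired = TRUE)
          comp[[length(comp) + 1]] <<- data.frame(
            measure = m, group_a = pc[1], group_b = pc[2],
            median_a = gc$median[1], sem_a = gc$sem[1],
            median_b = gc$median[2], sem_b = gc$sem[2],
            n = sum(ok), test = gc$test, p_value = gc$p_value)
        }
      }
    }
    add_contrasts(tables$pairs, "pair_id",
                  c("mean_epsc1_pA", "mean_epsc2_pA", "ppr", "latency_ms"))
    add_contrasts(tables$correlations, "pair_id", "coefficient")
    add_contrasts(tables$epsp_summary, "cell_id",
                  c("freq_per_min", "mean_amp_mV"))
    add_contrasts(tables$intrinsic, "cell_id",
                  c("rm_Mohm", "vrest_mV", "threshold_mV", "rheobase_pA",
                    "mean_spikes"))
    tables$comparisons <- bind(comp)
  }

  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]))
      data.table::fwrite(tables[[nm]], file.path(config$out,
                                                 paste0(nm, ".csv")))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("pairpatch")),
                   seed = config$seed,
                   parameters = config[!(names(config) %in% c("sim_args"))],
                   n_pairs = length(pair_dirs),
                   errors = errors)
  jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(tables)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic cohort), `qc`, `intrinsic`,
#' `synaptic`, `correlate`, `stats` (single stages) and `run` (all
#' stages).  Flags: `--input DIR`, `--out DIR`, `--seed INT`,
#' `--n-pairs INT`, `--n-connected INT`, `--method
#' filtered_voltage|binned_spikes`, `--dvdt-threshold FLOAT`,
#' `--config PATH` (JSON overriding any of the above).
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the pipeline result tables (or the cohort for
#'   `simulate`).
#' @export
pairpatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: pairpatch <simulate|qc|intrinsic|synaptic|correlate|stats|run> ",
         "[--input DIR] [--out DIR] [--seed INT] ...")
  cmd <- args[1]
  opts <- list(input = "cohort", out = "results", seed = 1L,
               n_pairs = 28L, n_connected = 7L,
               method = "filtered_voltage", dvdt_threshold = 1.5)
  flags <- args[-1]
  i <- 1
  while (i <= length(flags)) {
    key <- sub("^--", "", flags[i])
    key <- gsub("-", "_", key)
    if (i + 1 > length(flags)) stop("missing value for --", key)
    val <- flags[i + 1]
    if (key == "config") {
      cfg <- jsonlite::read_json(val, simplifyVector = TRUE)
      opts[names(cfg)] <- cfg
    } else {
      opts[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
    i <- i + 2
  }
  if (cmd == "simulate") {
    res <- generate_cohort(n_pairs = as.integer(opts$n_pairs),
                           n_connected = as.integer(opts$n_connected),
                           seed = as.integer(opts$seed), dir = opts$input)
    message("cohort written to ", opts$input)
    return(invisible(res))
  }
  stages <- switch(cmd,
                   qc = "qc", intrinsic = "intrinsic",
                   synaptic = "synaptic", correlate = "correlate",
                   stats = c("synaptic", "correlate", "intrinsic", "stats"),
                   run = c("qc", "intrinsic", "synaptic", "correlate", "stats"),
                   stop("unknown subcommand '", cmd, "'"))
  cfg <- pipeline_config(input = opts$input, out = opts$out,
                         seed = as.integer(opts$seed),
                         corr_method = opts$method,
                         dvdt_threshold = opts$dvdt_threshold,
                         stages = stages)
  res <- run_pipeline(cfg)
  message("tables written to ", opts$out)
  invisible(res)
}
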