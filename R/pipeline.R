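# End-to-end orchestration: scenario -> landscape metrics -> ES
# assessment -> aggregation -> statistics, seed-deterministic, with
# self-describing text outputs.

# 32-bit FNV-1a over the deparsed config (double-safe modular mult)
mulmod32 <- function(a, b) {
  a1 <- a %/% 65536; a0 <- a %% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

config_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default run configuration
#'
#' Bundles everything one pipeline run needs: the scenario generator
#' config, rate table, attractiveness weights, significance level,
#' Dunn adjustment, output directory and master seed.
#'
#' @param out_dir Output directory (created if needed); NULL keeps the
#'   run in memory.
#' @param seed Master integer seed.
#' @param alpha Significance level (default 0.05).
#' @param adjustment Dunn p adjustment ("none", "holm", "bonferroni",
#'   "BH").
#' @return List of class `run_config`.
#' @export
default_run_config <- function(out_dir = NULL, seed = 1, alpha = 0.05,
                               adjustment = "none") {
  structure(list(scenario = default_scenario_config(),
                 rates = default_rate_table(),
                 weights = default_attractiveness_weights(),
                 alpha = alpha, adjustment = adjustment,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = c("run_config", "list"))
}

#' Validate a run configuration
#'
#' Returns diagnostics instead of raising: an empty character vector
#' means the configuration is runnable; each entry names the offending
#' field and the violated constraint.
#'
#' @param config A [default_run_config()] list.
#' @return Character vector of diagnostics (possibly empty).
#' @export
validate_config <- function(config) {
  d <- character(0)
  say <- function(...) d <<- c(d, paste0(...))
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    say("alpha: must lie strictly between 0 and 1")
  }
  if (!config$adjustment %in% c("none", "holm", "bonferroni", "BH")) {
    say("adjustment: must be one of none, holm, bonferroni, BH")
  }
  r <- config$rates
  if (any(unlist(r[c("carbon", "seagrass_epiphyte_increment",
                     "nitrogen_load", "salicornia_biomass",
                     "honey_yield")]) < 0)) {
    say("rates: all process rates must be non-negative")
  }
  if (r$removal_fraction_default < 0 || r$removal_fraction_default > 1) {
    say("rates$removal_fraction_default: must lie in [0, 1]")
  }
  expected_len <- c(lifecycle = 5L, tourism = 4L, cognitive = 5L,
                    birdwatching = 4L)
  for (nm in names(expected_len)) {
    w <- config$weights[[nm]]
    if (is.null(w) || length(w) != expected_len[[nm]]) {
      say("weights$", nm, ": expected ", expected_len[[nm]], " weights")
    } else if (any(w < 0)) {
      say("weights$", nm, ": weights must be non-negative")
    }
  }
  sc <- config$scenario
  if (length(sc$years) == 0) say("scenario$years: empty years window")
  if (!is.numeric(sc$pixel_size) || sc$pixel_size <= 0) {
    say("scenario$pixel_size: must be positive")
  }
  for (g in names(sc$groups)) {
    p <- sc$groups[[g]]$class_props
    if (any(p < 0) || any(p > 1) || sum(p) > 1 + 1e-9) {
      say("scenario$groups$", g,
          "$class_props: proportions must lie in [0,1] and sum to <= 1")
    }
    ro <- sc$groups[[g]]$roughness
    if (any(ro < 0) || any(ro > 1)) {
      say("scenario$groups$", g, "$roughness: must lie in [0, 1]")
    }
  }
  d
}

write_table_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' Reads back a CSV written by [run_pipeline()], skipping the metadata
#' header line.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_output_table <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

run_stats_stage <- function(land_tab, agg, alpha, adjustment) {
  indicators <- c(
    setNames(landscape_indicator_names(),
             paste0("landscape.", landscape_indicator_names())),
    setNames(names(agg)[-(1:2)], paste0("es.", names(agg)[-(1:2)])))
  omnibus <- list(); pairwise <- list(); letters <- list()
  for (nm in names(indicators)) {
    col <- indicators[[nm]]
    src <- if (startsWith(nm, "landscape.")) land_tab else agg
    vals <- src[[col]]
    ok <- !is.na(vals)
    res <- tryCatch(
      compare_groups(vals[ok], src$group[ok], alpha = alpha,
                     adjustment = adjustment),
      error = function(e) NULL)
    if (is.null(res)) next
    lstr <- if (is.null(res$letters)) "" else {
      paste(vapply(names(res$letters), function(g) {
        paste0(g, ":", paste(res$letters[[g]], collapse = ""))
      }, character(1)), collapse = " ")
    }
    omnibus[[nm]] <- data.frame(
      indicator = nm, routing = res$routing$decision,
      shapiro_p = res$routing$shapiro_p,
      bartlett_p = res$routing$bartlett_p,
      statistic = res$omnibus$statistic, value = res$omnibus$value,
      p = res$omnibus$p, letters = lstr, stringsAsFactors = FALSE)
    if (!is.null(res$pairwise)) {
      pw <- res$pairwise
      # harmonise the Dunn (z) and Tukey (diff) statistic columns
      stat_col <- setdiff(names(pw), c("group1", "group2", "p", "p_adj"))
      names(pw)[match(stat_col, names(pw))] <- "statistic"
      pairwise[[nm]] <- cbind(indicator = nm, pw)
      letters[[nm]] <- vapply(res$letters, paste, character(1),
                              collapse = "")
    }
  }
  list(omnibus = do.call(rbind, omnibus),
       pairwise = do.call(rbind, pairwise),
       letters = letters)
}

#' Run the full assessment pipeline
#'
#' Generates the synthetic 31-unit scenario, computes the landscape
#' indicator table, the nine ES capacity/flow indicators, the
#' normalised category aggregates and capacity-flow differences, the
#' routed group statistics for every indicator, and the Spearman
#' correlogram. When `out_dir` is set, all tables are written as CSV
#' (with a metadata header line carrying the seed, config hash and
#' package version) plus a machine-readable `run_summary.json`.
#' Identical (config, seed) give identical output bytes.
#'
#' @param config A [default_run_config()] list.
#' @param quiet Suppress per-stage progress messages on stderr.
#' @return List of class `valli_run`: `scenario`, `landscape`,
#'   `es_indicators`, `aggregated`, `stats`, `correlogram`, `radar`,
#'   `meta`.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  diags <- validate_config(config)
  if (length(diags) > 0) {
    stop("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  }
  hash <- config_hash(config[c("scenario", "rates", "weights", "alpha",
                               "adjustment", "seed")])
  note <- function(stage, t0) {
    if (!quiet) {
      message(sprintf("[valliES] %-12s %6.2f s", stage,
                      as.numeric(Sys.time()) - t0))
    }
  }
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note(name, t0)
    out
  }
  scenario <- stage("generate",
                    generate_scenario(config$scenario, config$seed))
  land_tab <- stage("metrics", landscape_indicator_table(scenario))
  es_tab <- stage("assess",
                  assess_ecosystem_services(scenario, config$rates,
                                            config$weights))
  agg <- stage("aggregate", aggregate_indicators(es_tab))
  stats_res <- stage("stats",
                     run_stats_stage(land_tab, agg, config$alpha,
                                     config$adjustment))
  corr <- stage("correlogram", spearman_correlogram(agg))
  radar <- radar_chart_data(es_tab)
  meta <- list(package = "valliES",
               version = as.character(packageVersion("valliES")),
               seed = config$seed, config_hash = hash,
               alpha = config$alpha, adjustment = config$adjustment)
  run <- structure(list(scenario = scenario, landscape = land_tab,
                        es_indicators = es_tab, aggregated = agg,
                        stats = stats_res, correlogram = corr,
                        radar = radar, meta = meta),
                   class = "valli_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' Write pipeline outputs to a directory
#'
#' @param run A `valli_run` from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("# package=%s version=%s seed=%d config_hash=%s",
                  run$meta$package, run$meta$version, run$meta$seed,
                  run$meta$config_hash)
  wt <- function(df, name) {
    write_table_with_meta(df, file.path(out_dir, name), meta)
  }
  wt(run$landscape, "landscape_indicators.csv")
  wt(run$es_indicators, "es_indicators.csv")
  wt(run$aggregated, "aggregated_indicators.csv")
  if (!is.null(run$stats$omnibus)) wt(run$stats$omnibus, "stats_omnibus.csv")
  if (!is.null(run$stats$pairwise)) {
    wt(run$stats$pairwise, "stats_pairwise.csv")
  }
  rho <- as.data.frame(run$correlogram$rho)
  rho <- cbind(indicator = rownames(run$correlogram$rho), rho)
  wt(rho, "correlogram_rho.csv")
  pm <- as.data.frame(run$correlogram$p)
  pm <- cbind(indicator = rownames(run$correlogram$p), pm)
  wt(pm, "correlogram_p.csv")
  wt(run$radar, "radar_data.csv")
  summary <- c(run$meta,
               list(n_units = nrow(run$scenario$fixture),
                    groups = as.list(table(run$scenario$fixture$group)),
                    outputs = c("landscape_indicators.csv",
                                "es_indicators.csv",
                                "aggregated_indicators.csv",
                                "stats_omnibus.csv", "stats_pairwise.csv",
                                "correlogram_rho.csv", "correlogram_p.csv",
                                "radar_data.csv")))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Recompute the statistics stage from cached tables
#'
#' Re-runs routing, omnibus, post-hoc and letters at a new alpha or
#' adjustment from the cached landscape and aggregated tables in a run
#' directory, without regenerating the scenario.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @param alpha Significance level.
#' @param adjustment Dunn p adjustment.
#' @return The stats result list (also rewritten to `out_dir`).
#' @export
recompute_stats <- function(out_dir, alpha = 0.05, adjustment = "none") {
  land_tab <- read_output_table(file.path(out_dir,
                                          "landscape_indicators.csv"))
  agg <- read_output_table(file.path(out_dir, "aggregated_indicators.csv"))
  res <- run_stats_stage(land_tab, agg, alpha, adjustment)
  first <- readLines(file.path(out_dir, "aggregated_indicators.csv"),
                     n = 1)
  if (!is.null(res$omnibus)) {
    write_table_with_meta(res$omnibus,
                          file.path(out_dir, "stats_omnibus.csv"), first)
  }
  if (!is.null(res$pairwise)) {
    write_table_with_meta(res$pairwise,
                          file.path(out_dir, "stats_pairwise.csv"), first)
  }
  res
}

#' @export
print.valli_run <- function(x, ...) {
  cat(sprintf("<valli_run> seed %d, %d units, %d ES rows\n",
              x$meta$seed, nrow(x$scenario$fixture),
              nrow(x$es_indicators)))
  cat("aggregated capacity/flow (group means):\n")
  gm <- aggregate(x$aggregated[, -(1:2)],
                  by = list(group = x$aggregated$group), FUN = mean)
  print(gm, digits = 3)
  invisible(x)
}
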