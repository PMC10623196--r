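# Base-case orchestration, full runs and the command-line surface ---------

#' Base-case incremental table for one outcome
#'
#' In `"model"` mode, total costs and effectiveness come from the cohort
#' engine. In `"table"` mode, total and incremental costs are taken directly
#' from a published-results fixture (by default [hk2022_base_case()]) while
#' effectiveness is still accrued from the annual effects - the mode used to
#' verify ICER arithmetic against published figures whose cost-aggregation
#' internals are not reproducible.
#'
#' @param spec a `model_spec`.
#' @param strategies named list of `strategy_parameters`.
#' @param outcome `"ser"` or `"al"`.
#' @param mode `"model"` or `"table"`.
#' @param rule a [transition_rule()].
#' @param table results fixture for table mode (format of
#'   [hk2022_base_case()]).
#' @return Incremental table (see [incremental_table()]) with a `who_class`
#'   column.
#' @export
base_case_table <- function(spec, strategies, outcome = c("ser", "al"),
                            mode = c("model", "table"),
                            rule = transition_rule(), table = NULL) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  strategies <- strategies_for_outcome(strategies, outcome)
  if (!spec$reference_strategy %in% names(strategies))
    validation_error("reference_strategy",
                     sprintf("reference '%s' lacks evidence for outcome '%s'",
                             spec$reference_strategy, outcome))

  eff <- vapply(strategies, function(s)
    accrue_effect(annual_benefit(s, outcome), spec$accrual_events), 0)

  if (mode == "model") {
    tc <- vapply(strategies, function(s) run_cohort(spec, s, rule)$accrued_cost, 0)
    res <- data.frame(strategy = names(strategies), total_cost = unname(tc),
                      effectiveness = unname(eff), stringsAsFactors = FALSE)
    out <- incremental_table(res, spec$reference_strategy)
  } else {
    tab <- table %||% hk2022_base_case()
    tab <- tab[tab$outcome == outcome, ]
    idx <- match(names(strategies), tab$strategy)
    if (anyNA(idx))
      validation_error("table",
                       sprintf("fixture lacks strategies: %s",
                               paste(names(strategies)[is.na(idx)], collapse = ", ")))
    res <- data.frame(strategy = names(strategies),
                      total_cost = tab$cost_hkd[idx],
                      effectiveness = unname(eff), stringsAsFactors = FALSE)
    out <- incremental_table(res, spec$reference_strategy)
    # printed incremental costs override the recomputed totals difference
    # (they differ where the source rounds intermediates)
    printed <- tab$incr_cost_hkd[idx]
    keep <- !is.na(printed)
    out$incr_cost[keep] <- printed[keep]
    out$icer <- compute_icer(out$incr_cost, out$incr_effect)
    out$icer[match(spec$reference_strategy, out$strategy)] <- NA_real_
  }
  out$who_class <- who_classify(out$icer)
  rownames(out) <- NULL
  out
}

add_presentation_columns <- function(df, exchange_rate) {
  money <- intersect(c("total_cost", "incr_cost", "icer"), names(df))
  for (m in money) {
    df[[paste0(m, "_usd")]] <- hkd_to_usd(df[[m]], exchange_rate)
    df[[paste0(m, "_hkd_disp")]] <- round(df[[m]])
    df[[paste0(m, "_usd_disp")]] <- round(hkd_to_usd(df[[m]], exchange_rate))
  }
  df
}

resolve_config <- function(config) {
  if (is.null(config)) return(hk2022_parameters())
  if (is.character(config)) {
    if (!file.exists(config))
      validation_error("config", sprintf("file '%s' not found", config))
    return(load_parameters(config))
  }
  if (is.list(config) && all(c("spec", "strategies") %in% names(config)))
    return(config)
  validation_error("config", "must be a path or a list(spec, strategies)")
}

#' Run the base case and export the cost-effectiveness plane
#'
#' @param config path to a YAML configuration, a `list(spec, strategies)`,
#'   or `NULL` for the packaged baseline ([hk2022_parameters()]).
#' @param outcome `"ser"` or `"al"`.
#' @param mode `"model"` or `"table"` (see [base_case_table()]).
#' @param outdir optional directory; when given, `base_case_<outcome>.csv`
#'   and `ce_plane_<outcome>.csv` are written there.
#' @param rule a [transition_rule()].
#' @return List with `base_case` (incremental table with US$ and rounded
#'   presentation columns) and `ce_plane` (per-strategy incremental
#'   effectiveness / incremental cost coordinates), invisibly when writing.
#' @export
run_base_case <- function(config = NULL, outcome = c("ser", "al"),
                          mode = c("model", "table"), outdir = NULL,
                          rule = transition_rule()) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  params <- resolve_config(config)
  bc <- base_case_table(params$spec, params$strategies, outcome, mode, rule)
  bc_out <- add_presentation_columns(bc, params$spec$exchange_rate)
  plane <- data.frame(strategy = bc$strategy,
                      incr_effect = bc$incr_effect,
                      incr_cost = bc$incr_cost,
                      dominance = bc$dominance, stringsAsFactors = FALSE)
  out <- list(base_case = bc_out, ce_plane = plane)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bc_out, file.path(outdir, sprintf("base_case_%s.csv", outcome)),
                     row.names = FALSE)
    utils::write.csv(plane, file.path(outdir, sprintf("ce_plane_%s.csv", outcome)),
                     row.names = FALSE)
    return(invisible(out))
  }
  out
}

config_digest <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Full analysis run: base case, tornado, PSA and acceptability curves
#'
#' Orchestrates every stage for one outcome and writes all artifacts plus a
#' JSON run manifest (config digest, seed, package version, mode, outcome,
#' transition rule, timestamp). Reruns with identical manifests produce
#' identical CSVs.
#'
#' @inheritParams run_base_case
#' @param iterations PSA iterations (default 1000).
#' @param seed RNG seed for the PSA.
#' @param wtp_max,wtp_step willingness-to-pay grid in HK$ (defaults: US$0 to
#'   US$10,000 in US$500 steps at the 7.85 peg).
#' @param tornado_target strategy for the tornado; default: the most
#'   effective non-reference strategy.
#' @param keep_samples also write the raw PSA samples CSV for audit.
#' @param quiet suppress progress messages (written to stderr).
#' @return Invisible list with `base_case`, `ce_plane`, `tornado`, `psa`,
#'   `ceac`, `manifest`.
#' @export
run_full <- function(config = NULL, outcome = c("ser", "al"),
                     mode = c("model", "table"), iterations = 1000, seed = 1,
                     wtp_max = 78500, wtp_step = 3925, outdir = NULL,
                     rule = transition_rule(), tornado_target = NULL,
                     keep_samples = FALSE, quiet = FALSE) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  if (iterations < 1) validation_error("iterations", "must be >= 1")
  params <- resolve_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[base case] outcome=%s mode=%s", outcome, mode)
  bc <- run_base_case(params, outcome, mode, rule = rule)

  strat <- strategies_for_outcome(params$strategies, outcome)
  if (is.null(tornado_target)) {
    eff <- vapply(strat, annual_benefit, 0, outcome = outcome)
    eff[params$spec$reference_strategy] <- -Inf
    tornado_target <- names(which.max(eff))
  }
  say("[tornado] target=%s", tornado_target)
  torn <- tornado(params$spec, params$strategies, tornado_target, outcome, rule)

  say("[psa] %d iterations, seed=%d", iterations, seed)
  psa <- run_psa(params$spec, params$strategies, outcome, iterations, seed, rule)
  grid <- default_wtp_grid(wtp_max, wtp_step)
  curves <- ceac(psa, grid)

  manifest <- list(
    package = "myopiacea",
    version = as.character(utils::packageVersion("myopiacea")),
    config_digest = config_digest(params),
    outcome = outcome, mode = mode,
    iterations = iterations, seed = seed,
    wtp_max = wtp_max, wtp_step = wtp_step,
    transition_rule = as.list(rule$multipliers),
    tornado_target = tornado_target,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out <- list(base_case = bc$base_case, ce_plane = bc$ce_plane,
              tornado = torn, psa = psa, ceac = curves, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    run_base_case(params, outcome, mode, outdir = outdir, rule = rule)
    utils::write.csv(torn, file.path(outdir, sprintf("tornado_%s.csv", outcome)),
                     row.names = FALSE)
    utils::write.csv(curves, file.path(outdir, sprintf("ceac_%s.csv", outcome)),
                     row.names = FALSE)
    if (keep_samples)
      utils::write.csv(psa$samples,
                       file.path(outdir, sprintf("psa_samples_%s.csv", outcome)),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("[done] artifacts in %s", outdir)
  }
  invisible(out)
}

# -- command-line surface -------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list(config = NULL, outcome = "ser", mode = "model",
               iterations = 1000L, seed = 1L, `wtp-max` = 78500,
               `wtp-step` = 3925, outdir = "myopiacea-results",
               currency = "both", quiet = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--"))
      validation_error("args", sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3L)
    if (!key %in% names(opts))
      validation_error("args", sprintf("unknown flag '--%s'", key))
    if (i == length(args))
      validation_error("args", sprintf("flag '--%s' needs a value", key))
    val <- args[[i + 1L]]
    opts[[key]] <- switch(key,
      iterations = as.integer(val), seed = as.integer(val),
      `wtp-max` = as.numeric(val), `wtp-step` = as.numeric(val),
      val)
    i <- i + 2L
  }
  if (!opts$outcome %in% c("ser", "al"))
    validation_error("outcome", sprintf("unknown outcome '%s'", opts$outcome))
  if (!opts$mode %in% c("model", "table"))
    validation_error("mode", sprintf("unknown mode '%s'", opts$mode))
  if (!opts$currency %in% c("hkd", "usd", "both"))
    validation_error("currency", sprintf("unknown currency '%s'", opts$currency))
  opts
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper around [run_full()], used by the shipped
#' script `inst/cli/myopiacea-cli.R`. Flags: `--config`, `--outcome`
#' (`ser`/`al`), `--mode` (`model`/`table`), `--iterations`, `--seed`,
#' `--wtp-max`, `--wtp-step`, `--outdir`, `--currency`
#' (`hkd`/`usd`/`both`), `--quiet`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status: 0 on success, 2 on a validation error, 1 on
#'   any other failure. Diagnostics go to stderr; results go to files only.
#' @export
cea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  tryCatch({
    opts <- parse_cli_args(args)
    run_full(config = opts$config, outcome = opts$outcome, mode = opts$mode,
             iterations = opts$iterations, seed = opts$seed,
             wtp_max = opts$`wtp-max`, wtp_step = opts$`wtp-step`,
             outdir = opts$outdir, quiet = opts$quiet)
    0L
  }, myopiacea_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
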