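# The two-stage study pipeline: (1) network-based analysis of the CPAP
# cohort — compatibility network, communities, severity transitions,
# response-class labels; (2) statistical analysis of the screening cohorts
# — NC ROC/AUC, Youden cutoff, and the evaluation of that cutoff back on
# the CPAP network.

#' Run the full analysis pipeline
#'
#' Simulates (or takes) the CPAP cohort and the OSA/control screening
#' cohorts, builds the risk-compatibility network, detects communities,
#' derives the best/good response classes, runs the NC ROC analysis, and
#' evaluates the Youden-optimal NC cutoff against the response classes. All
#' reports are written as plain CSV/JSON plus GEXF/GraphML graph exports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param d1_records Optional CPAP-cohort records; simulated from
#'   `config$d1` when NULL.
#' @param screening_records Optional screening records (with `osa_label`);
#'   simulated from `config$d2`/`config$d3` when NULL.
#' @return Invisible list with all intermediate objects and the paths of
#'   the written reports.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         d1_records = NULL, screening_records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- stage 1: network-based analysis of the CPAP cohort
  if (is.null(d1_records)) {
    d1_records <- generate_d1_like(config$d1, config$response,
                                   seed = config$seed)
    say("simulated CPAP cohort: %d patients", nrow(d1_records))
  }
  d1_records <- validate_patients(d1_records)
  say("CPAP cohort after validation: %d patients", nrow(d1_records))
  profiles <- discretize_patients(d1_records, config$rules)
  net <- build_network(profiles, config$compatibility_threshold)
  say("network: %d nodes, %d edges at threshold %d", length(net$nodes),
      nrow(net$edges), net$threshold)
  part <- detect_communities(net, seed = config$seed,
                             weighted = config$weighted)
  say("communities: %d, modularity %.4f", part$m, part$modularity)
  layout <- force_layout(net, seed = config$seed)

  utils::write.csv(data.frame(id = names(part$membership),
                              community = unname(part$membership)),
                   path("partition.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(layout$coordinates, path("layout.csv"),
                   row.names = FALSE, quote = FALSE)
  write_edge_csv(net, path("edges.csv"))
  write_gexf(net, path("network.gexf"), partition = part, layout = layout)
  write_graphml(net, path("network.graphml"), partition = part,
                layout = layout)

  transitions <- severity_transition_table(d1_records, part)
  utils::write.csv(transitions, path("table2.csv"), row.names = FALSE)
  improvements <- community_improvements(d1_records, part)
  labeling <- label_response_classes(improvements, config$best_threshold)
  pmap <- parameter_community_map(profiles, part,
                                  config$representative_threshold)
  pmap$ahi_improvement <- round(improvements[as.character(pmap$community)], 2)
  pmap$response_class <- labeling$label[as.character(pmap$community)]
  utils::write.csv(pmap, path("table3.csv"), row.names = FALSE)
  class_pct <- parameter_community_map(profiles, part,
                                       representative_threshold = 0)
  utils::write.csv(class_pct, path("table4.csv"), row.names = FALSE)

  # --- stage 2: statistical analysis of the screening cohorts
  if (is.null(screening_records)) {
    screening_records <- generate_screening_cohorts(config$d2, config$d3,
                                                    seed = config$seed)
    say("simulated screening cohorts: %d OSA / %d control",
        sum(screening_records$osa_label), sum(!screening_records$osa_label))
  }
  nc <- screening_records$neck_circumference
  lab <- screening_records$osa_label
  roc <- roc_auc(nc, lab)
  tab5 <- cutoff_metrics_table(nc, lab, config$roc_cutoffs)
  utils::write.csv(tab5, path("table5.csv"), row.names = FALSE)
  youden <- youden_from_table(tab5)
  rho <- spearman_rho(nc, screening_records$ahi_before)
  mw <- mann_whitney_u(nc[lab], nc[!lab])
  say("AUC %.3f (CI %.3f-%.3f), Youden cutoff %g cm", roc$auc, roc$ci_low,
      roc$ci_high, as.numeric(youden))
  jsonlite::write_json(
    list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
         n_positive = roc$n_positive, n_negative = roc$n_negative,
         youden_cutoff = as.numeric(youden), youden_index = attr(youden, "J"),
         spearman_nc_ahi = rho$rho, spearman_p = rho$p_value,
         mann_whitney_U = mw$U, mann_whitney_p = mw$p_value),
    path("roc.json"), auto_unbox = TRUE, digits = NA)

  # --- NC threshold evaluated against the response classes
  tab7 <- nc_threshold_table(d1_records, part, labeling,
                             config$nc_eval_cutoffs)
  utils::write.csv(tab7, path("table7.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(n_patients = length(net$nodes), n_edges = nrow(net$edges),
         threshold = net$threshold, n_communities = part$m,
         modularity = part$modularity,
         improvement = as.list(improvements),
         response_class = as.list(labeling$label),
         auc = roc$auc, youden_cutoff = as.numeric(youden)),
    path("summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, path("pipeline.log"))

  invisible(list(records = d1_records, profiles = profiles, network = net,
                 partition = part, layout = layout,
                 transitions = transitions, improvements = improvements,
                 labeling = labeling, parameter_map = pmap, roc = roc,
                 table5 = tab5, youden = youden, table7 = tab7,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Thin shell over the pipeline functions. Subcommands: `simulate`
#' (write synthetic cohorts as CSV), `build-network`, `communities`,
#' `response`, `roc`, `evaluate-cutoff`, `run-all`. Options:
#' `--out DIR` (default `.`), `--seed N`, `--config FILE` (YAML),
#' `--input FILE` (patient CSV for the network subcommands),
#' `--cutoff CM` (for `evaluate-cutoff`).
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Integer exit status, 0 on success.
#' @export
cpapnet_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cpapnet <subcommand> [--out DIR] [--seed N] [--config FILE]",
    "               [--input FILE] [--cutoff CM]",
    "subcommands: simulate | build-network | communities | response |",
    "             roc | evaluate-cutoff | run-all", sep = "\n")
  if (length(argv) == 0) { message(usage); return(1L) }
  cmd <- argv[1]
  opts <- list(out = ".", seed = NULL, config = NULL, input = NULL,
               cutoff = 41)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message("bad option: ", argv[i], "\n", usage); return(1L)
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    config <- if (!is.null(opts$config)) read_config(opts$config)
              else pipeline_config()
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    get_d1 <- function() {
      if (!is.null(opts$input)) read_patients(opts$input)
      else generate_d1_like(config$d1, config$response, seed = config$seed)
    }
    network_stage <- function() {
      rec <- get_d1()
      profiles <- discretize_patients(rec, config$rules)
      net <- build_network(profiles, config$compatibility_threshold)
      list(rec = rec, net = net)
    }
    switch(cmd,
      "simulate" = {
        write_patients(generate_d1_like(config$d1, config$response,
                                        seed = config$seed),
                       file.path(opts$out, "d1_cohort.csv"))
        write_patients(generate_screening_cohorts(config$d2, config$d3,
                                                  seed = config$seed),
                       file.path(opts$out, "screening_cohorts.csv"))
        0L
      },
      "build-network" = {
        st <- network_stage()
        write_edge_csv(st$net, file.path(opts$out, "edges.csv"))
        write_gexf(st$net, file.path(opts$out, "network.gexf"))
        0L
      },
      "communities" = {
        st <- network_stage()
        part <- detect_communities(st$net, seed = config$seed,
                                   weighted = config$weighted)
        utils::write.csv(data.frame(id = names(part$membership),
                                    community = unname(part$membership)),
                         file.path(opts$out, "partition.csv"),
                         row.names = FALSE, quote = FALSE)
        0L
      },
      "response" = {
        st <- network_stage()
        part <- detect_communities(st$net, seed = config$seed,
                                   weighted = config$weighted)
        res <- run_pipeline(config, opts$out, d1_records = st$rec)
        0L
      },
      "roc" = {
        sc <- generate_screening_cohorts(config$d2, config$d3,
                                         seed = config$seed)
        tab5 <- cutoff_metrics_table(sc$neck_circumference, sc$osa_label,
                                     config$roc_cutoffs)
        utils::write.csv(tab5, file.path(opts$out, "table5.csv"),
                         row.names = FALSE)
        roc <- roc_auc(sc$neck_circumference, sc$osa_label)
        jsonlite::write_json(
          list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
               youden_cutoff = as.numeric(youden_from_table(tab5))),
          file.path(opts$out, "roc.json"), auto_unbox = TRUE, digits = NA)
        0L
      },
      "evaluate-cutoff" = {
        st <- network_stage()
        part <- detect_communities(st$net, seed = config$seed,
                                   weighted = config$weighted)
        labeling <- label_response_classes(
          community_improvements(st$rec, part), config$best_threshold)
        ev <- evaluate_nc_threshold(st$rec, part, labeling,
                                    as.numeric(opts$cutoff))
        print(ev)
        tab <- nc_threshold_table(st$rec, part, labeling,
                                  as.numeric(opts$cutoff))
        utils::write.csv(tab, file.path(opts$out, "table7.csv"),
                         row.names = FALSE)
        0L
      },
      "run-all" = {
        run_pipeline(config, opts$out)
        0L
      },
      { message("unknown subcommand: ", cmd, "\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
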