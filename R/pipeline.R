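# Every stage generates its own synthetic inputs (with truth sidecars),
# writes them in their plain-text forms, and re-reads them before analysis,
# so simulation and analysis are exercised together.
pipeline_stage_names <- c("morph", "turnover", "qpcr", "screen", "enrich")

pipeline_allowed_keys <- list(
  top = c("out_dir", "seed", "stages", "morph", "turnover", "qpcr", "screen",
          "enrich"),
  morph = c("n_profiles", "n_sarcomeres", "sarcomere_length", "h_zone_width",
            "pixel_size", "psf_sigma", "noise_sd", "smooth_sigma",
            "min_prominence"),
  turnover = c("timepoints", "n_per_timepoint", "noise_sd", "alpha", "lag",
               "rise_end", "decay_halflife", "baseline", "peak",
               "body_fraction"),
  qpcr = c("reference", "target", "knockdown_day", "true_knockdown",
           "control_reduction", "replicate_sd", "n_replicates"),
  screen = c("class_counts", "assay_days"),
  enrich = c("terms", "n_edges")
)

check_config_keys <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_allowed_keys$top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(cfg), names(pipeline_allowed_keys))) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_allowed_keys[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Run the synthetic end-to-end quantification pipeline
#'
#' Generates every synthetic dataset (profiles, pulse-chase time courses,
#' Ct tables, climbing outcomes, screen fixture), writes them to disk in
#' their plain-text forms, runs the corresponding analysis stage on the
#' written files, and records everything in a JSON manifest (files,
#' parameters, seeds, package version). Stages are deterministic for a fixed
#' seed and config.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Recognized top-level keys: `out_dir`, `seed`, `stages`
#'   (subset of `simulate`, `morph`, `turnover`, `qpcr`, `screen`, `enrich`)
#'   and one parameter block per stage. Unknown keys are rejected.
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  check_config_keys(config)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")
  seed <- config$seed %||% 1L
  stages <- config$stages %||% pipeline_stage_names
  bad <- setdiff(stages, pipeline_stage_names)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "sarcotrack",
    version = as.character(utils::packageVersion("sarcotrack")),
    seed = seed,
    stages = stages,
    parameters = list(),
    files = list(),
    results = list()
  )
  fail <- function(stage, msg) {
    stop("[", stage, "] ", msg, call. = FALSE)
  }

  if ("morph" %in% stages) {
    p <- utils::modifyList(
      list(n_profiles = 5, n_sarcomeres = 8, sarcomere_length = 3.36,
           h_zone_width = 0.16, pixel_size = 0.05, psf_sigma = 0.05,
           noise_sd = 0.05, smooth_sigma = NULL, min_prominence = 0.2),
      config$morph %||% list()
    )
    manifest$parameters$morph <- p
    truth <- striation_truth(sarcomere_length = p$sarcomere_length,
                             h_zone_width = p$h_zone_width,
                             pixel_size = p$pixel_size,
                             psf_sigma = p$psf_sigma)
    files <- character(0)
    meas <- list()
    for (i in seq_len(p$n_profiles)) {
      prof <- gen_striation_profile(truth, p$n_sarcomeres, p$noise_sd,
                                    seed = seed * 1000L + i)
      f <- file.path(out_dir, sprintf("profile_%03d.csv", i))
      write_profile_csv(prof, f)
      files <- c(files, f)
      back <- read_profile_csv(f)
      m <- measure_striation(back, p$smooth_sigma, p$min_prominence,
                             id = basename(f))
      if (is.null(m)) fail("morph", paste("no measurement from", f))
      meas[[i]] <- m
    }
    meas <- do.call(rbind, meas)
    mf <- file.path(out_dir, "morphometry.csv")
    write_table_csv(meas, mf)
    manifest$files$morph <- c(files, mf)
    manifest$results$morph <- list(
      n_sarcomeres = nrow(meas),
      sl_mean_um = mean(meas$sl_um),
      tfl_mean_um = mean(meas$tfl_um),
      hz_mean_um = mean(meas$hz_um)
    )
  }

  if ("turnover" %in% stages) {
    p <- utils::modifyList(
      list(timepoints = seq(0, 200, by = 5), n_per_timepoint = 10,
           noise_sd = 4, alpha = 0.05, lag = 20, rise_end = 95,
           decay_halflife = 72, baseline = 10, peak = 100,
           body_fraction = 0.4),
      config$turnover %||% list()
    )
    manifest$parameters$turnover <- p
    kin <- turnover_kinetics(p$lag, p$rise_end, p$decay_halflife, p$baseline,
                             p$peak, p$body_fraction)
    series <- gen_pulse_chase(kin, p$timepoints, p$n_per_timepoint,
                              p$noise_sd, seed = seed * 1000L + 101L)
    summ <- summarize_turnover(series, p$alpha)
    tf <- file.path(out_dir, "turnover_ratio_series.csv")
    write_table_csv(summ$ratio_series, tf)
    manifest$files$turnover <- tf
    manifest$results$turnover <- list(onset_h = summ$onset,
                                      peak_h = summ$peak_time,
                                      halflife_h = summ$halflife)
  }

  if ("qpcr" %in% stages) {
    p <- utils::modifyList(
      list(reference = "GAPDH", target = "Act88F", knockdown_day = 6,
           true_knockdown = 0.98, control_reduction = 0.25,
           replicate_sd = 0.15, n_replicates = 3),
      config$qpcr %||% list()
    )
    manifest$parameters$qpcr <- p
    design <- qpcr_design(
      genes = p$target, reference = p$reference,
      conditions = data.frame(
        genotype = rep(c("RNAi", "control"), each = 2),
        day = rep(c(0, p$knockdown_day), 2)
      ),
      true_relative_expression = data.frame(
        gene = p$target,
        genotype = c("RNAi", "RNAi", "control", "control"),
        day = c(0, p$knockdown_day, 0, p$knockdown_day),
        rel_expr = c(1, 1 - p$true_knockdown, 1, 1 - p$control_reduction)
      ),
      base_ct = stats::setNames(c(22, 16), c(p$target, p$reference)),
      replicate_sd = p$replicate_sd
    )
    ct <- gen_ct_table(design, p$n_replicates, seed = seed * 1000L + 202L)
    cf <- file.path(out_dir, "ct_table.csv")
    write_table_csv(ct, cf)
    rel <- analyze_ct_table(read_ct_csv(cf), reference = p$reference)
    rf <- file.path(out_dir, "relative_expression.csv")
    write_table_csv(rel, rf)
    manifest$files$qpcr <- c(cf, rf)
    kd <- rel[rel$genotype == "RNAi" & rel$day == p$knockdown_day, ]
    manifest$results$qpcr <- list(
      percent_knockdown = kd$percent_vs_calibrator[1]
    )
  }

  if ("screen" %in% stages || "enrich" %in% stages) {
    p <- utils::modifyList(
      list(class_counts = c(Severe = 5, Intermediate = 13, Weak = 28,
                            None = 86),
           assay_days = seq(0, 30, by = 3)),
      config$screen %||% list()
    )
    p$class_counts <- unlist(p$class_counts)
    manifest$parameters$screen <- p
    fixture <- gen_screen_fixture(p$class_counts, p$assay_days,
                                  seed = seed * 1000L + 303L)
    cls <- data.frame(
      gene = fixture$genes$gene,
      day_of_loss = vapply(fixture$trajectories, day_of_loss, 1.0),
      stringsAsFactors = FALSE
    )
    cls$severity <- vapply(cls$day_of_loss, classify_severity, "")
    sf <- file.path(out_dir, "screen_classification.tsv")
    utils::write.table(cls, sf, sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_screen(cls)
    jf <- file.path(out_dir, "screen_summary.json")
    jsonlite::write_json(
      list(counts = as.list(summ$counts), total = summ$total,
           hit_rate_percent = summ$hit_rate_percent),
      jf, auto_unbox = TRUE, digits = NA
    )
    manifest$files$screen <- c(sf, jf)
    manifest$results$screen <- list(counts = as.list(summ$counts),
                                    hit_rate_percent = summ$hit_rate_percent)

    if ("enrich" %in% stages) {
      pe <- utils::modifyList(list(terms = NULL, n_edges = 40),
                              config$enrich %||% list())
      af <- file.path(out_dir, "annotations.tsv")
      write_annotations_tsv(fixture$go_annotations, af)
      ef <- file.path(out_dir, "edges.tsv")
      utils::write.table(fixture$edges, ef, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      ann <- annotation_set(read_annotations_tsv(af), fixture$genes$gene)
      terms <- pe$terms %||% sort(unique(unlist(ann$annotations)))
      classes <- split(cls$gene, cls$severity)
      etab <- enrichment_table(terms, classes, ann)
      etf <- file.path(out_dir, "enrichment_matrix.csv")
      utils::write.csv(etab, etf)
      net <- build_network(cls, read_edges_tsv(ef))
      gf <- file.path(out_dir, "network.graphml")
      export_graph(net, gf, "graphml")
      manifest$files$enrich <- c(af, ef, etf, gf)
      manifest$results$enrich <- list(
        n_terms = length(terms),
        n_nodes = igraph::vcount(net),
        n_edges = igraph::ecount(net)
      )
    }
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Validate input files against their expected schemas
#'
#' A reporting operation: nothing is thrown for malformed content; each
#' problem becomes a row in the returned report (missing files and unknown
#' formats included).
#'
#' @param paths Character vector of file paths.
#' @param formats Matching character vector; each one of `"profile_csv"`,
#'   `"climbing_csv"`, `"ct_csv"`, `"annotations_tsv"`, `"edges_tsv"`.
#' @return Data frame with columns `file`, `row` (NA for file-level issues),
#'   `problem`; zero rows when everything is valid.
#' @export
validate_inputs <- function(paths, formats) {
  stopifnot(length(paths) == length(formats))
  known <- c("profile_csv", "climbing_csv", "ct_csv", "annotations_tsv",
             "edges_tsv")
  report <- list()
  note <- function(file, row, problem) {
    report[[length(report) + 1L]] <<- data.frame(
      file = file, row = row, problem = problem
    )
  }
  for (i in seq_along(paths)) {
    f <- paths[i]
    fmt <- formats[i]
    if (!fmt %in% known) {
      note(f, NA_integer_, paste("unknown format:", fmt))
      next
    }
    if (!file.exists(f)) {
      note(f, NA_integer_, "file not found")
      next
    }
    d <- tryCatch(
      if (grepl("tsv$", fmt)) utils::read.delim(f) else utils::read.csv(f),
      error = function(e) e
    )
    if (inherits(d, "error")) {
      note(f, NA_integer_, paste("unreadable:", conditionMessage(d)))
      next
    }
    need <- switch(fmt,
      profile_csv = c("position_um", "intensity"),
      climbing_csv = c("line", "vial", "day", "rep", "successes", "n_flies"),
      ct_csv = c("genotype", "day", "gene", "replicate", "ct"),
      annotations_tsv = c("gene", "term"),
      edges_tsv = c("from", "to")
    )
    missing <- setdiff(need, names(d))
    if (length(missing)) {
      note(f, NA_integer_,
           paste("missing column(s):", paste(missing, collapse = ", ")))
      next
    }
    if (fmt == "profile_csv" && nrow(d) >= 3) {
      dp <- diff(d$position_um)
      bad <- which(abs(dp - stats::median(dp)) > 1e-9) + 1L
      for (r in bad) note(f, r, "non-uniform profile spacing")
      if (any(d$intensity < 0)) {
        for (r in which(d$intensity < 0)) note(f, r, "negative intensity")
      }
    }
    if (fmt == "climbing_csv") {
      bad <- which(d$successes > d$n_flies | d$successes < 0)
      for (r in bad) note(f, r, "successes outside [0, n_flies]")
    }
    if (fmt == "ct_csv") {
      bad <- which(!is.finite(d$ct) | d$ct <= 0)
      for (r in bad) note(f, r, "non-positive or non-finite Ct")
    }
  }
  if (!length(report)) {
    return(data.frame(file = character(0), row = integer(0),
                      problem = character(0)))
  }
  do.call(rbind, report)
}
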