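#' Pulse-chase turnover kinetics (ground truth)
#'
#' Minimal kinetic shape for a pulse-chase labelled sarcomeric protein: no
#' signal above baseline during a lag, a linear rise to the peak, then (for a
#' protein that is turned over) a single-exponential decay back toward
#' baseline. `decays = FALSE` emulates a stable cytoplasmic label whose signal
#' plateaus after induction is switched off.
#'
#' @param lag Hours before signal rises above baseline.
#' @param rise_end Hour of maximal intensity (must exceed `lag`).
#' @param decay_halflife Post-peak half-life, hours.
#' @param baseline,peak Intensity levels, a.u. (`peak > baseline >= 0`).
#' @param body_fraction Sarcomere-body intensity as a fraction of the Z-disc
#'   intensity, in (0, 1].
#' @param decays If `FALSE`, intensity stays at `peak` after `rise_end`.
#' @return Object of class `turnover_kinetics`.
#' @export
turnover_kinetics <- function(lag = 20, rise_end = 95, decay_halflife = 72,
                              baseline = 10, peak = 100, body_fraction = 0.4,
                              decays = TRUE) {
  stopifnot(
    lag < rise_end, peak > baseline, baseline >= 0,
    decay_halflife > 0, body_fraction > 0, body_fraction <= 1
  )
  structure(
    list(lag = lag, rise_end = rise_end, decay_halflife = decay_halflife,
         baseline = baseline, peak = peak, body_fraction = body_fraction,
         decays = decays),
    class = "turnover_kinetics"
  )
}

# Noise-free Z-disc intensity at time t under a turnover_kinetics record.
kinetic_mean <- function(kin, t) {
  y <- numeric(length(t))
  pre <- t <= kin$lag
  rising <- t > kin$lag & t <= kin$rise_end
  post <- t > kin$rise_end
  y[pre] <- kin$baseline
  y[rising] <- kin$baseline + (kin$peak - kin$baseline) *
    (t[rising] - kin$lag) / (kin$rise_end - kin$lag)
  y[post] <- if (kin$decays) {
    kin$baseline + (kin$peak - kin$baseline) *
      2^(-(t[post] - kin$rise_end) / kin$decay_halflife)
  } else {
    kin$peak
  }
  y
}

#' Generate a synthetic pulse-chase intensity time course
#'
#' For each timepoint, draws `n_sarcomeres_per_tp` Z-disc intensity samples
#' around the kinetic mean and matching sarcomere-body samples at
#' `body_fraction` of the Z-disc level, each with additive Gaussian noise.
#'
#' @param kin A [turnover_kinetics()] record.
#' @param timepoints Non-negative, sorted assay times, hours.
#' @param n_sarcomeres_per_tp Samples per timepoint.
#' @param noise_sd Additive noise standard deviation, a.u.
#' @param seed Integer seed.
#' @param label Dataset label, e.g. `"Act88F_GFP"` or `"eGFP"`.
#' @return A `pulse_chase_series` object: list with `timepoints`,
#'   `z_intensity` and `body_intensity` (lists of per-timepoint sample
#'   vectors), `label`, and the truth record as attribute `kinetics`.
#' @export
gen_pulse_chase <- function(kin, timepoints, n_sarcomeres_per_tp = 10,
                            noise_sd = 0, seed = NULL, label = "Act88F_GFP") {
  stopifnot(inherits(kin, "turnover_kinetics"))
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (any(timepoints < 0) || is.unsorted(timepoints)) {
    stop("timepoints must be non-negative and sorted")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  mu <- kinetic_mean(kin, timepoints)
  out <- with_seed(seed, {
    z <- lapply(mu, function(m) {
      pmax(m + stats::rnorm(n_sarcomeres_per_tp, sd = noise_sd), 0)
    })
    body <- lapply(mu, function(m) {
      pmax(kin$body_fraction * m +
             stats::rnorm(n_sarcomeres_per_tp, sd = noise_sd), 0)
    })
    list(z = z, body = body)
  })
  series <- pulse_chase_series(timepoints, out$z, out$body, label)
  attr(series, "kinetics") <- kin
  series
}

#' Pulse-chase series container
#'
#' @param timepoints Sorted assay times, hours.
#' @param z_intensity,body_intensity Lists (one element per timepoint) of
#'   non-negative sample vectors, a.u.
#' @param label Dataset label.
#' @return Object of class `pulse_chase_series`.
#' @export
pulse_chase_series <- function(timepoints, z_intensity, body_intensity,
                               label = "Act88F_GFP") {
  stopifnot(
    length(timepoints) == length(z_intensity),
    length(timepoints) == length(body_intensity),
    !is.unsorted(timepoints),
    all(vapply(z_intensity, length, 1L) >= 1L),
    all(vapply(z_intensity, function(v) all(v >= 0), TRUE)),
    all(vapply(body_intensity, function(v) all(v >= 0), TRUE))
  )
  structure(
    list(timepoints = as.numeric(timepoints),
         z_intensity = z_intensity,
         body_intensity = body_intensity,
         label = label),
    class = "pulse_chase_series"
  )
}

#' @export
print.pulse_chase_series <- function(x, ...) {
  cat(sprintf("Pulse-chase series '%s': %d timepoints (%g-%g h), %d-%d samples/tp\n",
              x$label, length(x$timepoints), min(x$timepoints),
              max(x$timepoints),
              min(vapply(x$z_intensity, length, 1L)),
              max(vapply(x$z_intensity, length, 1L))))
  invisible(x)
}

#' qPCR experiment design (ground truth)
#'
#' Defines targets plus one reference gene, the (genotype, day) conditions,
#' and the true relative expression of each gene in each condition with the
#' calibrator condition at 1. Ct values are later generated under the
#' doubling model: one cycle earlier per two-fold more template.
#'
#' @param genes Character vector of target gene names.
#' @param reference Reference (internal control) gene name.
#' @param conditions Data frame with columns `genotype`, `day`.
#' @param true_relative_expression Data frame with columns `gene`, `genotype`,
#'   `day`, `rel_expr` (> 0) covering every target x condition. The reference
#'   gene is fixed at 1 everywhere and need not be listed.
#' @param base_ct Named numeric: expected Ct of each gene (targets and
#'   reference) in the calibrator condition, cycles.
#' @param replicate_sd Replicate noise on the Ct scale, cycles.
#' @return Object of class `qpcr_design`.
#' @export
qpcr_design <- function(genes, reference, conditions,
                        true_relative_expression, base_ct,
                        replicate_sd = 0.15) {
  stopifnot(
    is.character(genes), length(genes) >= 1,
    is.character(reference), length(reference) == 1,
    !(reference %in% genes),
    is.data.frame(conditions),
    all(c("genotype", "day") %in% names(conditions)),
    is.data.frame(true_relative_expression),
    all(c("gene", "genotype", "day", "rel_expr") %in%
          names(true_relative_expression)),
    replicate_sd >= 0
  )
  if (any(true_relative_expression$rel_expr <= 0)) {
    stop("all true relative expression values must be positive")
  }
  missing_ct <- setdiff(c(genes, reference), names(base_ct))
  if (length(missing_ct)) {
    stop("base_ct missing for: ", paste(missing_ct, collapse = ", "))
  }
  structure(
    list(genes = genes, reference = reference, conditions = conditions,
         true_relative_expression = true_relative_expression,
         base_ct = base_ct, replicate_sd = replicate_sd),
    class = "qpcr_design"
  )
}

#' Generate a synthetic Ct table under the doubling model
#'
#' `Ct(gene, condition, rep) = base_ct(gene) - log2(rel_expr(gene, condition))
#' + Normal(0, replicate_sd)`. The reference gene has `rel_expr = 1` in every
#' condition, so its Ct is constant in expectation.
#'
#' @param design A [qpcr_design()].
#' @param n_replicates Technical replicates per (gene, condition).
#' @param seed Integer seed.
#' @return Data frame of class `ct_table` with columns `sample`, `genotype`,
#'   `day`, `gene`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(design, n_replicates = 3, seed = NULL) {
  stopifnot(inherits(design, "qpcr_design"), n_replicates >= 1)
  conds <- design$conditions
  all_genes <- c(design$genes, design$reference)
  rows <- with_seed(seed, {
    out <- vector("list", nrow(conds) * length(all_genes))
    k <- 0L
    for (i in seq_len(nrow(conds))) {
      for (g in all_genes) {
        rel <- if (g == design$reference) 1 else {
          hit <- design$true_relative_expression$gene == g &
            design$true_relative_expression$genotype == conds$genotype[i] &
            design$true_relative_expression$day == conds$day[i]
          if (!any(hit)) {
            stop("no true expression for ", g, " in condition ", i)
          }
          design$true_relative_expression$rel_expr[which(hit)[1]]
        }
        ct <- design$base_ct[[g]] - log2(rel) +
          stats::rnorm(n_replicates, sd = design$replicate_sd)
        k <- k + 1L
        out[[k]] <- data.frame(
          sample = sprintf("%s_d%g", conds$genotype[i], conds$day[i]),
          genotype = conds$genotype[i], day = conds$day[i], gene = g,
          replicate = seq_len(n_replicates), ct = ct
        )
      }
    }
    do.call(rbind, out)
  })
  class(rows) <- c("ct_table", "data.frame")
  rows
}

#' Negative-geotaxis assay design (ground truth)
#'
#' @param days Assay-day grid (default every 3 days, day 0 to 30).
#' @param p_success Per-day probability a fly climbs above the scoring line;
#'   one value per day, each in \[0, 1\].
#' @param n_vials Independent vials (biological replicates).
#' @param flies_per_vial Flies per vial.
#' @param tech_reps Technical replicates per vial and day.
#' @return Object of class `climbing_design`.
#' @export
climbing_design <- function(days = seq(0, 30, by = 3),
                            p_success = rep(0.8, length(days)),
                            n_vials = 10, flies_per_vial = 10,
                            tech_reps = 5) {
  stopifnot(
    length(p_success) == length(days),
    all(p_success >= 0 & p_success <= 1),
    n_vials >= 1, flies_per_vial >= 1, tech_reps >= 1
  )
  structure(
    list(days = days, p_success = p_success, n_vials = n_vials,
         flies_per_vial = flies_per_vial, tech_reps = tech_reps),
    class = "climbing_design"
  )
}

#' Generate synthetic climbing-assay outcomes
#'
#' For each (vial, day, technical replicate), the number of successes is drawn
#' from `Binomial(flies_per_vial, p_success(day))`.
#'
#' @param design A [climbing_design()].
#' @param seed Integer seed.
#' @param line Line identifier stored in the output.
#' @return Data frame of class `climbing_dataset` with columns `line`, `vial`,
#'   `day`, `rep`, `successes`, `n_flies`.
#' @export
gen_geotaxis <- function(design, seed = NULL, line = "line1") {
  stopifnot(inherits(design, "climbing_design"))
  grid <- expand.grid(
    rep = seq_len(design$tech_reps),
    day_idx = seq_along(design$days),
    vial = seq_len(design$n_vials)
  )
  succ <- with_seed(seed, stats::rbinom(
    nrow(grid), size = design$flies_per_vial,
    prob = design$p_success[grid$day_idx]
  ))
  out <- data.frame(
    line = line, vial = grid$vial, day = design$days[grid$day_idx],
    rep = grid$rep, successes = succ, n_flies = design$flies_per_vial
  )
  out <- out[order(out$vial, out$day, out$rep), ]
  rownames(out) <- NULL
  class(out) <- c("climbing_dataset", "data.frame")
  out
}

#' Generate a synthetic screen fixture with class-structured outcomes
#'
#' Builds a gene list whose day-of-loss values fall inside the severity-class
#' windows (`Severe`: loss by day 9; `Intermediate`: days 12-21; `Weak`: days
#' 24-30; `None`: climbing never lost), together with normalized climbing
#' trajectories consistent with those outcomes, GO annotations drawn from a
#' small vocabulary with class-dependent weights, and a random interaction
#' edge list.
#'
#' @param class_counts Named counts, e.g.
#'   `c(Severe = 5, Intermediate = 13, Weak = 28, None = 86)`.
#' @param assay_days Assay-day grid.
#' @param go_vocabulary Character vector of GO-term labels to draw from; the
#'   first term is enriched among hit classes (`hit_term_prob` vs
#'   `base_term_prob` in `None` genes).
#' @param hit_term_prob,base_term_prob Probability that a hit / non-hit gene
#'   carries the first vocabulary term.
#' @param n_edges Number of random interaction edges.
#' @param seed Integer seed.
#' @return Object of class `screen_fixture`: list with `genes` (data frame
#'   `gene`, `day_of_loss` (NA = never), `severity`), `trajectories` (named
#'   list of per-day normalized scores), `go_annotations` (named list of term
#'   sets), `edges` (data frame `from`, `to`, `kind`).
#' @export
gen_screen_fixture <- function(class_counts = c(Severe = 5, Intermediate = 13,
                                                Weak = 28, None = 86),
                               assay_days = seq(0, 30, by = 3),
                               go_vocabulary = c("sarcomere",
                                                 "actin cytoskeleton",
                                                 "microtubule",
                                                 "cell adhesion",
                                                 "protein folding"),
                               hit_term_prob = 0.6, base_term_prob = 0.2,
                               n_edges = 40, seed = NULL) {
  stopifnot(all(c("Severe", "Intermediate", "Weak", "None") %in%
                  names(class_counts)))
  windows <- list(
    Severe = assay_days[assay_days >= 3 & assay_days <= 9],
    Intermediate = assay_days[assay_days >= 12 & assay_days <= 21],
    Weak = assay_days[assay_days >= 24]
  )
  for (cl in names(windows)) {
    if (class_counts[[cl]] > 0 && length(windows[[cl]]) == 0) {
      stop("no assay day inside the ", cl, " window")
    }
  }
  with_seed(seed, {
    classes <- rep(names(class_counts), class_counts)
    n <- length(classes)
    gene_ids <- sprintf("g%03d", seq_len(n))
    day_of_loss <- rep(NA_real_, n)
    for (cl in names(windows)) {
      idx <- which(classes == cl)
      if (length(idx)) {
        day_of_loss[idx] <- sample(windows[[cl]], length(idx),
                                   replace = TRUE)
      }
    }
    trajectories <- lapply(seq_len(n), function(i) {
      dol <- day_of_loss[i]
      if (is.na(dol)) {
        # no phenotype: stays near 1, never reaches zero
        sc <- pmax(1 - 0.005 * assay_days +
                     stats::rnorm(length(assay_days), sd = 0.03), 0.2)
      } else {
        # linear fall to zero at day_of_loss, sustained zero afterwards
        sc <- pmax(1 - assay_days / dol, 0)
        sc[assay_days >= dol] <- 0
      }
      sc[1] <- 1 # normalized to day 0 by definition
      stats::setNames(sc, assay_days)
    })
    names(trajectories) <- gene_ids
    go_annotations <- lapply(seq_len(n), function(i) {
      p1 <- if (classes[i] == "None") base_term_prob else hit_term_prob
      terms <- character(0)
      if (stats::runif(1) < p1) terms <- go_vocabulary[1]
      extra <- go_vocabulary[-1][stats::runif(length(go_vocabulary) - 1) < 0.25]
      unique(c(terms, extra))
    })
    names(go_annotations) <- gene_ids
    # draw distinct undirected edges (self-loops allowed) so the assembled
    # network has exactly n_edges edges
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0))
    tries <- 0L
    while (nrow(edges) < n_edges && tries < 50L) {
      need <- n_edges - nrow(edges)
      new <- data.frame(
        from = sample(gene_ids, need, replace = TRUE),
        to = sample(gene_ids, need, replace = TRUE),
        kind = sample(c("genetic", "physical"), need, replace = TRUE)
      )
      edges <- rbind(edges, new)
      key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
                   edges$kind, sep = "\r")
      edges <- edges[!duplicated(key), , drop = FALSE]
      tries <- tries + 1L
    }
    rownames(edges) <- NULL
    structure(
      list(
        genes = data.frame(gene = gene_ids, day_of_loss = day_of_loss,
                           severity = classes),
        trajectories = trajectories,
        go_annotations = go_annotations,
        edges = edges,
        assay_days = assay_days
      ),
      class = "screen_fixture"
    )
  })
}
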