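#' Severity-class labels in screen order
#' @keywords internal
severity_levels <- c("Severe", "Intermediate", "Weak", "None")

#' Score one line and day of a climbing assay
#'
#' Each (vial, technical replicate) record contributes the fraction of flies
#' that climbed above the scoring line; the timepoint score is the mean of
#' those fractions, with the standard error computed over vial means
#' (vials are the independent biological unit; technical replicates are not).
#'
#' @param records Data frame with columns `vial`, `successes`, `n_flies` for
#'   a single line and day.
#' @return List with `mean` (fraction in \[0, 1\] of the per-record
#'   fractions), `sem` (over vial means; 0 with a single vial) and `n_vials`.
#' @export
score_timepoint <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("vial", "successes", "n_flies") %in% names(records)))
  if (any(records$successes < 0 | records$successes > records$n_flies)) {
    stop("successes must lie in [0, n_flies]")
  }
  frac <- records$successes / records$n_flies
  vial_means <- tapply(frac, records$vial, mean)
  nv <- length(vial_means)
  sem <- if (nv > 1) stats::sd(vial_means) / sqrt(nv) else 0
  list(mean = mean(frac), sem = sem, n_vials = nv)
}

#' Per-day climbing trajectory for one line
#'
#' @param dataset A climbing dataset (columns `line`, `vial`, `day`, `rep`,
#'   `successes`, `n_flies`).
#' @param line Line id to extract (default: the only line present).
#' @return Named numeric vector: mean score per assay day (names = days).
#' @export
climbing_trajectory <- function(dataset, line = NULL) {
  stopifnot(is.data.frame(dataset))
  if (!is.null(line)) dataset <- dataset[dataset$line == line, ]
  if (!nrow(dataset)) stop("no records for the requested line")
  days <- sort(unique(dataset$day))
  sc <- vapply(days, function(d) {
    score_timepoint(dataset[dataset$day == d, ])$mean
  }, 1.0)
  stats::setNames(sc, days)
}

#' Normalize a climbing trajectory to day 0
#'
#' @param trajectory Named numeric vector of scores per day (names = days;
#'   must include day 0 with a positive score).
#' @return The trajectory divided by its day-0 value (day 0 becomes exactly
#'   1; later values may exceed 1 and are not clipped).
#' @export
normalize_trajectory <- function(trajectory) {
  days <- as.numeric(names(trajectory))
  if (is.null(names(trajectory)) || !0 %in% days) {
    stop("trajectory must carry day names including day 0")
  }
  d0 <- trajectory[[which(days == 0)[1]]]
  if (d0 <= 0) stop("day-0 score is zero: line unusable for normalization")
  trajectory / d0
}

#' Total percent decline of a normalized trajectory
#'
#' `100 * (1 - final / initial)` between the first and last assay day.
#'
#' @param trajectory Named numeric vector (normalized scores per day).
#' @return Percent decline (negative if climbing improved).
#' @export
percent_decline <- function(trajectory) {
  if (length(trajectory) < 2) stop("need both endpoints of the trajectory")
  initial <- trajectory[[1]]
  final <- trajectory[[length(trajectory)]]
  if (initial <= 0) stop("initial score must be positive")
  100 * (1 - final / initial)
}

#' Day of sustained, complete loss of climbing ability
#'
#' The earliest assay day with score 0 such that every later assayed day is
#' also 0. A single-day dip to zero followed by recovery does not count.
#'
#' @param trajectory Named numeric vector of (normalized) scores per day.
#' @return The day (numeric), or `NA` if climbing is never lost.
#' @export
day_of_loss <- function(trajectory) {
  days <- as.numeric(names(trajectory))
  if (is.null(names(trajectory))) stop("trajectory must carry day names")
  zero <- trajectory == 0
  n <- length(zero)
  sustained <- rev(cumprod(rev(zero))) == 1
  if (!any(sustained)) return(NA_real_)
  days[which(sustained)[1]]
}

#' Classify phenotype severity from the day of loss
#'
#' Loss by day 9 is `Severe`; between days 12 and 21, `Intermediate`; day 24
#' or later, `Weak`; never lost, `None`. On the 3-day assay grid these
#' windows are exhaustive (days 10-11 and 22-23 are never assayed); a day
#' falling in a gap is an error.
#'
#' @param day Day of loss (numeric) or `NA` for never.
#' @return One of `"Severe"`, `"Intermediate"`, `"Weak"`, `"None"`.
#' @export
#' @examples
#' classify_severity(6)   # "Severe"
#' classify_severity(15)  # "Intermediate"
#' classify_severity(NA)  # "None"
classify_severity <- function(day) {
  if (length(day) != 1) stop("one day at a time")
  if (is.na(day)) return("None")
  if (day < 0) stop("day must be non-negative")
  if (day <= 9) return("Severe")
  if (day >= 12 && day <= 21) return("Intermediate")
  if (day >= 24) return("Weak")
  stop("day ", day, " falls outside every severity window (off the assay grid)")
}

#' Per-day comparison of a knockdown line against its control
#'
#' At each shared assay day, vial-level mean scores of the two lines are
#' compared with a two-sample Student's t-test, star-coded as in
#' [compare_groups()].
#'
#' @param line_data,control_data Climbing datasets (single line each) sharing
#'   the same assay-day grid, with at least two vials per day.
#' @param welch Use the Welch unequal-variance test.
#' @return Data frame with `day`, `line_mean`, `control_mean`, `p_value`,
#'   `stars`.
#' @export
compare_to_control <- function(line_data, control_data, welch = FALSE) {
  days_l <- sort(unique(line_data$day))
  days_c <- sort(unique(control_data$day))
  if (!identical(days_l, days_c)) stop("assay-day grids differ")
  rows <- lapply(days_l, function(d) {
    vl <- tapply(line_data$successes[line_data$day == d] /
                   line_data$n_flies[line_data$day == d],
                 line_data$vial[line_data$day == d], mean)
    vc <- tapply(control_data$successes[control_data$day == d] /
                   control_data$n_flies[control_data$day == d],
                 control_data$vial[control_data$day == d], mean)
    if (length(vl) < 2 || length(vc) < 2) {
      stop("need at least two vials per group at day ", d)
    }
    p <- if (stats::sd(vl) == 0 && stats::sd(vc) == 0) {
      if (mean(vl) == mean(vc)) 1 else 0
    } else {
      stats::t.test(vl, vc, var.equal = !welch)$p.value
    }
    data.frame(day = d, line_mean = mean(vl), control_mean = mean(vc),
               p_value = p, stars = star_code(p))
  })
  do.call(rbind, rows)
}

#' Summarize a screen: severity counts and gene lists
#'
#' @param genes Data frame with columns `gene` and `severity` (values among
#'   `Severe`, `Intermediate`, `Weak`, `None`).
#' @return Object of class `screen_summary`: `counts` (named, in class
#'   order), `total`, `n_hits` (Severe + Intermediate + Weak),
#'   `hit_rate_percent`, and `gene_lists` (genes per class).
#' @export
summarize_screen <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gene", "severity") %in% names(genes)))
  bad <- setdiff(unique(genes$severity), severity_levels)
  if (length(bad)) stop("unknown severity class: ", paste(bad, collapse = ", "))
  counts <- vapply(severity_levels, function(cl) sum(genes$severity == cl), 1L)
  total <- nrow(genes)
  n_hits <- sum(counts[c("Severe", "Intermediate", "Weak")])
  structure(
    list(
      counts = counts, total = total, n_hits = n_hits,
      hit_rate_percent = if (total > 0) 100 * n_hits / total else NA_real_,
      gene_lists = lapply(stats::setNames(nm = severity_levels), function(cl) {
        genes$gene[genes$severity == cl]
      })
    ),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary:\n")
  for (cl in names(x$counts)) {
    cat(sprintf("  %-12s %d\n", cl, x$counts[[cl]]))
  }
  cat(sprintf("  total %d; hits %d (%.1f%%)\n", x$total, x$n_hits,
              x$hit_rate_percent))
  invisible(x)
}

#' Classify every line in a climbing dataset
#'
#' Convenience wrapper: builds each line's trajectory, normalizes it to
#' day 0, finds the day of sustained loss and assigns the severity class.
#'
#' @param dataset Climbing dataset with one or more lines.
#' @return Data frame with `gene` (line id), `day_of_loss`, `severity`.
#' @export
classify_lines <- function(dataset) {
  lines <- unique(dataset$line)
  rows <- lapply(lines, function(ln) {
    tr <- normalize_trajectory(climbing_trajectory(dataset, ln))
    dol <- day_of_loss(tr)
    data.frame(gene = ln, day_of_loss = dol,
               severity = classify_severity(dol))
  })
  do.call(rbind, rows)
}
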