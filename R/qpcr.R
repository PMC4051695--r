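#' Mean cycle threshold over technical replicates
#'
#' Replicates are averaged on the Ct scale before any delta-Ct arithmetic
#' (the usual comparative-Ct convention).
#'
#' @param replicates Numeric Ct values (>= 1).
#' @return Arithmetic mean Ct, cycles.
#' @export
mean_ct <- function(replicates) {
  if (length(replicates) == 0) stop("empty replicate set")
  mean(replicates)
}

#' Comparative-Ct relative expression
#'
#' The 2^-ddCt fold change with amplification efficiency fixed at 2:
#' `2^-((target_ct - ref_ct) - (calib_target_ct - calib_ref_ct))`.
#'
#' @param target_ct Mean Ct of the target gene in the sample of interest.
#' @param ref_ct Mean Ct of the reference gene in the same sample.
#' @param calib_target_ct,calib_ref_ct The same two quantities in the
#'   calibrator sample.
#' @return Fold change relative to the calibrator (calibrator = 1).
#' @export
#' @examples
#' relative_expression(20, 15, 18, 15) # 0.25
relative_expression <- function(target_ct, ref_ct,
                                calib_target_ct, calib_ref_ct) {
  stopifnot(is.finite(target_ct), is.finite(ref_ct),
            is.finite(calib_target_ct), is.finite(calib_ref_ct))
  ddct <- (target_ct - ref_ct) - (calib_target_ct - calib_ref_ct)
  2^(-ddct)
}

#' Percent knockdown from a fold change
#'
#' `100 * (1 - fold)`: the percent reduction relative to the calibrator.
#' Knockdown and control arms are each computed against their own day-0
#' calibrator.
#'
#' @param fold Fold change (> 0), calibrator = 1.
#' @return Percent reduction (negative when expression increased).
#' @export
#' @examples
#' percent_knockdown(0.25) # 75
percent_knockdown <- function(fold) {
  if (any(!is.finite(fold)) || any(fold <= 0)) {
    stop("fold changes must be positive")
  }
  100 * (1 - fold)
}

#' Normalize a relative-expression series to its day-0 entry
#'
#' Divides each fold change by the day-0 fold of the same gene and genotype,
#' so day 0 becomes exactly 1.
#'
#' @param series Data frame with columns `gene`, `genotype`, `day`,
#'   `fold_change`.
#' @return The series with `fold_change` rescaled.
#' @export
normalize_to_day0 <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("gene", "genotype", "day", "fold_change") %in% names(series)))
  key <- interaction(series$gene, series$genotype, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    d0 <- sel & series$day == 0
    if (!any(d0)) stop("missing day-0 entry for series ", k)
    series$fold_change[sel] <- series$fold_change[sel] /
      series$fold_change[which(d0)[1]]
  }
  series
}

#' Comparative-Ct analysis of a Ct table
#'
#' Averages replicates on the Ct scale, forms delta-Ct against the reference
#' gene within each (genotype, day) sample, and computes the 2^-ddCt fold
#' change against the day-`calibrator_day` sample of the same genotype
#' (genotype-matched calibration).
#'
#' @param ct_table Data frame with columns `genotype`, `day`, `gene`,
#'   `replicate`, `ct` (as produced by [gen_ct_table()]).
#' @param reference Reference gene name (must be present in every sample).
#' @param calibrator_day Day used as calibrator (default 0).
#' @return Data frame with columns `gene`, `genotype`, `day`, `fold_change`,
#'   `percent_vs_calibrator`.
#' @export
analyze_ct_table <- function(ct_table, reference = "GAPDH",
                             calibrator_day = 0) {
  stopifnot(is.data.frame(ct_table),
            all(c("genotype", "day", "gene", "ct") %in% names(ct_table)))
  if (!any(ct_table$gene == reference)) {
    stop("reference gene '", reference, "' not found")
  }
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  mc <- stats::aggregate(ct ~ genotype + day + gene, data = ct_table,
                         FUN = mean_ct)
  targets <- setdiff(unique(mc$gene), reference)
  rows <- list()
  for (g in targets) {
    for (geno in unique(mc$genotype)) {
      tgt <- mc[mc$gene == g & mc$genotype == geno, ]
      ref <- mc[mc$gene == reference & mc$genotype == geno, ]
      if (!nrow(tgt)) next
      cal_t <- tgt$ct[tgt$day == calibrator_day]
      cal_r <- ref$ct[ref$day == calibrator_day]
      if (!length(cal_t) || !length(cal_r)) {
        stop("missing calibrator (day ", calibrator_day, ") for ", g,
             " in ", geno)
      }
      for (i in seq_len(nrow(tgt))) {
        d <- tgt$day[i]
        r_ct <- ref$ct[ref$day == d]
        if (!length(r_ct)) stop("missing reference Ct for ", geno, " day ", d)
        fc <- relative_expression(tgt$ct[i], r_ct[1], cal_t[1], cal_r[1])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, genotype = geno, day = d, fold_change = fc,
          percent_vs_calibrator = percent_knockdown(fc)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$genotype, out$day), , drop = FALSE]
}
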