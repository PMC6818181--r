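#' Two-criterion Warburg-effect classifier
#'
#' A dataset is called Warburg-positive when both hold:
#' \describe{
#'   \item{criterion i}{lactate dehydrogenase A or B (`LDHA`/`LDHB`) is
#'     up-regulated more than two-fold in cases vs controls, AND a
#'     monocarboxylate lactic-acid exporter (`SLC16A1`/`SLC16A3`) is as
#'     well — i.e. both lactate production and lactate export machinery are
#'     induced.}
#'   \item{criterion ii}{the fraction of glycolytic flux leaving pyruvate
#'     kinase for the TCA cycle via pyruvate dehydrogenase decreases. The
#'     proxy is the per-sample ratio of linear `PDHB` to linear `PKM`
#'     expression; the criterion compares group medians.}
#' }
#'
#' Fold changes and ratios are computed on the linear (de-logged) scale, so
#' the verdict is invariant to multiplying all linear expression by a common
#' positive constant.
#'
#' @param em An `ExpressionMatrix` containing `LDHA`, `LDHB`, `SLC16A1`,
#'   `SLC16A3`, `PDHB` and `PKM`.
#' @param ratio_mode `"per_sample"` (default: median of per-sample
#'   PDHB/PKM ratios per group) or `"group_means"` (ratio of linear group
#'   means).
#' @param fc_cut Fold-change threshold of criterion i (default 2).
#' @param significance_gate If `TRUE`, criterion ii additionally requires a
#'   one-sided rank-sum p < 0.05 on the per-sample ratios (off by default;
#'   only available with `ratio_mode = "per_sample"`).
#' @return A `WarburgVerdict` list: the four linear fold changes,
#'   `criterion_i`, `ratio_case`, `ratio_control`, `criterion_ii`,
#'   `n_ratio_excluded` (samples whose PKM was zero on the linear scale),
#'   and `verdict = criterion_i && criterion_ii`.
#' @export
classify_warburg <- function(em, ratio_mode = c("per_sample", "group_means"),
                             fc_cut = 2, significance_gate = FALSE) {
  ratio_mode <- match.arg(ratio_mode)
  need <- c("LDHA", "LDHB", "SLC16A1", "SLC16A3", "PDHB", "PKM")
  missing <- setdiff(need, em$gene_ids)
  if (length(missing))
    stop_validation(sprintf("genes required by the classifier are absent: %s",
                            paste(missing, collapse = ", ")))
  is_case <- em$groups == "case"
  lin_fc <- function(g) {
    2^(mean(em$values[g, is_case]) - mean(em$values[g, !is_case]))
  }
  fc <- vapply(c("LDHA", "LDHB", "SLC16A1", "SLC16A3"), lin_fc, numeric(1))
  criterion_i <- (fc[["LDHA"]] > fc_cut || fc[["LDHB"]] > fc_cut) &&
                 (fc[["SLC16A1"]] > fc_cut || fc[["SLC16A3"]] > fc_cut)

  pdhb <- delog2(em$values["PDHB", ])
  pkm <- delog2(em$values["PKM", ])
  n_excluded <- 0L
  if (ratio_mode == "per_sample") {
    ok <- pkm > 0
    n_excluded <- sum(!ok)
    if (!any(ok)) stop_validation("all per-sample PDHB/PKM ratios undefined (PKM zero)")
    if (n_excluded) message(sprintf("classify_warburg: %d sample(s) excluded (PKM zero)", n_excluded))
    r <- pdhb[ok] / pkm[ok]
    grp <- is_case[ok]
    ratio_case <- stats::median(r[grp])
    ratio_control <- stats::median(r[!grp])
    criterion_ii <- ratio_case < ratio_control
    if (significance_gate) {
      pval <- suppressWarnings(
        stats::wilcox.test(r[grp], r[!grp], alternative = "less")$p.value)
      criterion_ii <- criterion_ii && pval < 0.05
    }
  } else {
    ratio_case <- mean(pdhb[is_case]) / mean(pkm[is_case])
    ratio_control <- mean(pdhb[!is_case]) / mean(pkm[!is_case])
    criterion_ii <- ratio_case < ratio_control
  }
  structure(list(
    fc_LDHA = fc[["LDHA"]], fc_LDHB = fc[["LDHB"]],
    fc_SLC16A1 = fc[["SLC16A1"]], fc_SLC16A3 = fc[["SLC16A3"]],
    criterion_i = criterion_i,
    ratio_case = ratio_case, ratio_control = ratio_control,
    criterion_ii = criterion_ii,
    n_ratio_excluded = n_excluded,
    verdict = criterion_i && criterion_ii
  ), class = "WarburgVerdict")
}

#' @export
print.WarburgVerdict <- function(x, ...) {
  cat("Warburg classifier\n")
  cat(sprintf("  FC: LDHA %.2f  LDHB %.2f  SLC16A1 %.2f  SLC16A3 %.2f\n",
              x$fc_LDHA, x$fc_LDHB, x$fc_SLC16A1, x$fc_SLC16A3))
  cat(sprintf("  criterion i (lactate production+export up >2x): %s\n", x$criterion_i))
  cat(sprintf("  PDHB/PKM ratio: case %.4f vs control %.4f -> criterion ii: %s\n",
              x$ratio_case, x$ratio_control, x$criterion_ii))
  cat(sprintf("  verdict: Warburg effect %s\n", if (x$verdict) "PRESENT" else "absent"))
  invisible(x)
}
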