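## Reproducibility and group statistics: Bland-Altman agreement between
## scan-rescan sessions, and subregion comparisons with a Shapiro-Wilk
## normality gate selecting one-way ANOVA + Tukey HSD (parametric branch)
## or Kruskal-Wallis + Dunn's test with Benjamini-Hochberg correction.

#' Bland-Altman analysis of paired measurements
#'
#' @param session1,session2 Paired numeric vectors (e.g. voxelwise
#'   metabolite ratios from two sessions); alternatively `session1` may be
#'   a 2-column matrix.
#' @return Object of class `bland_altman` with `bias` (mean difference
#'   session1 - session2), `loa_low`/`loa_high` (bias -/+ 1.96 SD of the
#'   differences), `sd_diff` and `n`.
#' @export
bland_altman <- function(session1, session2 = NULL) {
  if (is.null(session2)) {
    stopifnot(ncol(session1) == 2)
    session2 <- session1[, 2]; session1 <- session1[, 1]
  }
  ok <- stats::complete.cases(session1, session2)
  d <- session1[ok] - session2[ok]
  if (length(d) < 2) stop("need at least 2 pairs")
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> bias", signif(x$bias, 3), " LoA [",
      signif(x$loa_low, 3), ",", signif(x$loa_high, 3), "] n =", x$n, "\n")
  invisible(x)
}

## Dunn's rank-sum post hoc test (two-sided z-tests on mean ranks with the
## tie correction), p-values adjusted by Benjamini-Hochberg.
dunn_test_bh <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mr <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- (mr[[a]] - mr[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_adj = stats::p.adjust(p, method = "BH"))
}

#' Compare metabolite levels across subregions
#'
#' Each group is first tested for normality (Shapiro-Wilk at
#' `shapiro_alpha`).  If every group is consistent with normality, a
#' one-way ANOVA with Tukey's HSD post hoc test is used; otherwise the
#' Kruskal-Wallis test followed by Dunn's test with Benjamini-Hochberg
#' correction.  Groups with fewer than 3 values are dropped with a reason.
#'
#' @param samples Named list of numeric vectors (one per subregion).
#' @param alpha Significance level reported alongside.
#' @param shapiro_alpha Level of the normality gate.
#' @return Object of class `group_comparison` with fields `groups`,
#'   `normality_p`, `test_used`, `omnibus_p`, `pairwise` (data frame:
#'   group1, group2, p_adj, method), `dropped`.
#' @export
compare_subregions <- function(samples, alpha = 0.05,
                               shapiro_alpha = 0.05) {
  dropped <- names(samples)[vapply(samples, length, 1L) < 3]
  samples <- samples[vapply(samples, length, 1L) >= 3]
  if (length(samples) < 2)
    stop("need at least 2 groups with >= 3 values each")
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, 1L)),
                   levels = names(samples))
  norm_p <- vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(0)        # degenerate: route nonparametric
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  parametric <- all(norm_p >= shapiro_alpha)
  degenerate <- stats::sd(values) == 0
  if (degenerate) {
    omnibus_p <- 1
    pairwise <- data.frame(group1 = character(0), group2 = character(0),
                           p_adj = numeric(0), method = character(0))
    test_used <- "degenerate"
  } else if (parametric) {
    fit <- stats::aov(values ~ groups)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(nm, `[`, "", 1),
                           group2 = vapply(nm, `[`, "", 2),
                           p_adj = tk[, "p adj"], method = "tukey",
                           row.names = NULL)
    test_used <- "parametric"
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus_p <- kw$p.value
    dn <- dunn_test_bh(values, groups)
    pairwise <- data.frame(dn[, c("group1", "group2", "p_adj")],
                           method = "dunn_bh")
    test_used <- "nonparametric"
  }
  structure(list(groups = samples, normality_p = norm_p,
                 test_used = test_used, omnibus_p = omnibus_p,
                 pairwise = pairwise, alpha = alpha, dropped = dropped),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  cat("<group_comparison>", x$test_used, "branch, omnibus p =",
      signif(x$omnibus_p, 3), stars(x$omnibus_p), "\n")
  if (nrow(x$pairwise)) {
    pw <- x$pairwise
    pw$sig <- stars(pw$p_adj)
    print(pw, row.names = FALSE)
  }
  invisible(x)
}

#' Scan-rescan quality/fitting summary table
#'
#' Mean and SD of FWHM, SNR and CRLB% of the main reported metabolites
#' over the (QC-accepted) interior voxels of each session.
#'
#' @param sessions Named list of [fit_grid()] results (typically
#'   `scan1`/`scan2`).
#' @param metabolites CRLB columns: individual names or sums expressed as
#'   `tNAA` (NAA + NAAG), `tCr` (Cr), `tCho` (Cho + GPC).
#' @param accepted_only Restrict to QC-accepted voxels.
#' @return Data frame with one row per session and metric.
#' @export
scan_rescan_table <- function(sessions,
                              metabolites = c("Glu", "Gln", "tNAA",
                                              "tCr", "tCho", "mI"),
                              accepted_only = TRUE) {
  sums <- list(tNAA = c("NAA", "NAAG"), tCr = "Cr", tCho = c("Cho", "GPC"))
  rows <- list()
  for (sess in names(sessions)) {
    fits <- sessions[[sess]]
    if (accepted_only) {
      acc <- vapply(fits, function(f) isTRUE(f$accepted) || is.na(f$accepted),
                    logical(1))
      fits <- fits[acc]
    }
    if (length(fits) == 0) {
      warning("no accepted voxels in session ", sess)
      next
    }
    stat_row <- function(metric, values) {
      data.frame(session = sess, metric = metric,
                 mean = mean(values, na.rm = TRUE),
                 sd = stats::sd(values, na.rm = TRUE))
    }
    rows[[length(rows) + 1]] <-
      stat_row("FWHM_ppm", vapply(fits, function(f) f$fwhm, 1))
    rows[[length(rows) + 1]] <-
      stat_row("SNR", vapply(fits, function(f) f$snr, 1))
    for (met in metabolites) {
      vals <- vapply(fits, function(f) {
        if (met %in% names(sums)) crlb_percent_sum(f, sums[[met]])
        else unname(f$crlb_pct[met])
      }, numeric(1))
      rows[[length(rows) + 1]] <- stat_row(paste0("CRLB_", met), vals)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(session = character(0),
                                      metric = character(0),
                                      mean = numeric(0), sd = numeric(0))
  out
}
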