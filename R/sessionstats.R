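#' Pearson correlation between two session metrics
#'
#' Correlates two columns of a session table (one row per subject x
#' session), dropping incomplete pairs. Used to link neural metrics to
#' behavior, e.g. transient-rate AUC vs AIM AUC during the LID onset
#' window, or photometry time-to-baseline vs AIM time-to-resolution.
#'
#' @param table data.frame of session metrics.
#' @param x,y column names.
#' @return list: `r`, `p` (two-sided), `n` complete pairs, `n_dropped`.
#' @export
correlate <- function(table, x, y) {
  if (!all(c(x, y) %in% names(table)))
    stop("columns not found: ", paste(setdiff(c(x, y), names(table)),
                                      collapse = ", "), call. = FALSE)
  xv <- table[[x]]; yv <- table[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  n_dropped <- sum(!ok)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0) {
    warning("zero variance in ", if (sd(xv) == 0) x else y,
            "; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(xv),
                n_dropped = n_dropped))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xv),
       n_dropped = n_dropped)
}

#' Compare a session metric across treatment timepoints
#'
#' Contract-level wrapper around the standard group-comparison designs used
#' for LID progression data: repeated-measures one-way ANOVA with a Tukey
#' post-hoc (`rm_anova_tukey`), Kruskal-Wallis with a Dunn post-hoc
#' (`kruskal_dunn`), and two-way repeated-measures ANOVA with a
#' Greenhouse-Geisser sphericity correction (`rm_two_way_gg`; within-subject
#' factor crossed with timepoint). The statistical internals are delegated
#' to standard routines (`aov`/`emmeans`, `kruskal.test`, `car::Anova`);
#' this function contributes the reshaping, listwise-deletion policy for
#' unbalanced repeated measures (dropped subjects are reported), and a
#' uniform report.
#'
#' @param table data.frame with columns `subject`, `timepoint`, the metric,
#'   and (for the two-way design) the within-subject factor `within`.
#' @param metric metric column name.
#' @param design one of `"rm_anova_tukey"`, `"kruskal_dunn"`,
#'   `"rm_two_way_gg"`.
#' @param within column name of the second within-subject factor
#'   (two-way design only).
#' @return a `timepoint_comparison`: `omnibus` (statistic, df, p),
#'   `posthoc` (pairwise table or NULL), `design`, `dropped_subjects`.
#' @export
compare_timepoints <- function(table, metric,
                               design = c("rm_anova_tukey", "kruskal_dunn",
                                          "rm_two_way_gg"),
                               within = NULL) {
  design <- match.arg(design)
  stopifnot(metric %in% names(table))
  dat <- table
  dat$timepoint <- factor(dat$timepoint)
  dat$.y <- dat[[metric]]
  dropped <- character(0)

  if (design == "kruskal_dunn") {
    dat <- dat[is.finite(dat$.y), ]
    kw <- kruskal.test(.y ~ timepoint, data = dat)
    post <- dunn_posthoc(dat$.y, dat$timepoint)
    omni <- list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value)
  } else if (design == "rm_anova_tukey") {
    dat$subject <- factor(dat$subject)
    keep <- complete_subjects(dat, "timepoint")
    dropped <- setdiff(levels(dat$subject), keep)
    dat <- droplevels(dat[dat$subject %in% keep, ])
    # do.call embeds the data in the call so emmeans can re-fit later
    fit <- do.call(stats::aov,
                   list(.y ~ timepoint + Error(subject / timepoint),
                        data = dat))
    tab <- summary(fit)[["Error: subject:timepoint"]][[1]]
    omni <- list(statistic = tab["timepoint", "F value"],
                 df = tab[c("timepoint", "Residuals"), "Df"],
                 p = tab["timepoint", "Pr(>F)"])
    em <- emmeans::emmeans(fit, "timepoint", data = dat)
    post <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  } else {
    if (is.null(within)) stop("two-way design needs `within`", call. = FALSE)
    dat$subject <- factor(dat$subject)
    dat$.w <- factor(dat[[within]])
    keep <- complete_subjects(dat, c("timepoint", ".w"))
    dropped <- setdiff(levels(dat$subject), keep)
    dat <- droplevels(dat[dat$subject %in% keep, ])
    wide <- stats::reshape(
      dat[, c("subject", "timepoint", ".w", ".y")],
      idvar = c("subject", "timepoint"), timevar = ".w",
      direction = "wide")
    resp <- as.matrix(wide[, grep("^\\.y\\.", names(wide)), drop = FALSE])
    idata <- data.frame(within = factor(sub("^\\.y\\.", "",
                                            grep("^\\.y\\.", names(wide),
                                                 value = TRUE))))
    mod <- lm(resp ~ timepoint, data = wide)
    an <- car::Anova(mod, idata = idata, idesign = ~within, type = 3)
    s <- summary(an, multivariate = FALSE)
    uni <- s$univariate.tests
    gg <- s$pval.adjustments
    p_gg <- if (!is.null(gg) && "timepoint:within" %in% rownames(gg))
      gg["timepoint:within", "Pr(>F[GG])"] else
        uni["timepoint:within", "Pr(>F)"]
    omni <- list(statistic = uni["timepoint:within", "F value"],
                 df = uni["timepoint:within", c("num Df", "den Df")],
                 p_treatment = uni["timepoint", "Pr(>F)"],
                 p = unname(p_gg))
    post <- NULL
  }
  if (length(dropped))
    message("listwise deletion dropped subjects: ",
            paste(dropped, collapse = ", "))
  structure(list(omnibus = omni, posthoc = post, design = design,
                 metric = metric, dropped_subjects = dropped),
            class = "timepoint_comparison")
}

# Subjects observed (finite metric) in every cell of the design.
complete_subjects <- function(df, factors) {
  df <- df[is.finite(df$.y), ]
  cells <- interaction(df[, factors, drop = FALSE], drop = TRUE)
  need <- nlevels(cells)
  tab <- table(df$subject, cells)
  rownames(tab)[rowSums(tab > 0) == need]
}

# Dunn's rank-based post-hoc after Kruskal-Wallis: pairwise z statistics on
# mean ranks with the tie-corrected variance, Holm-adjusted.
dunn_posthoc <- function(y, g, adjust = "holm") {
  g <- factor(g)
  N <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  cmb <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    z[k] <- (mr[[a]] - mr[[b]]) / sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(contrast = paste(cmb[1, ], "-", cmb[2, ]),
             z = z, p_unadj = p, p_adj = p.adjust(p, adjust))
}

#' @export
print.timepoint_comparison <- function(x, ...) {
  cat(sprintf("<timepoint_comparison> %s on '%s': p = %.4g\n",
              x$design, x$metric, x$omnibus$p))
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}
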