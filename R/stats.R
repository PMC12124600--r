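#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical fixed-effects F test across groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons (studentized-range
#' based), the procedure used to compare basal firing rates across estrous
#' stages. Degenerate inputs with zero variance everywhere are reported as
#' F = 0 with no significant pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values)
#' @param alpha significance level for flagging pairs (default 0.05)
#' @return list with `F`, `df_between`, `df_within`, `p`, and `pairwise`
#'   (data.frame: group_i, group_j, diff, adjusted_p, significant)
#' @export
oneway_anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1L)) >= 2L))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1L))),
                                  levels = names(groups)))
  pairs_idx0 <- utils::combn(names(groups), 2L)
  k <- length(groups)
  n_tot <- nrow(df)
  if (stats::var(df$value) == 0) {
    # every observation identical: F defined as 0, nothing significant
    return(list(F = 0, df_between = k - 1L, df_within = n_tot - k, p = 1,
                pairwise = data.frame(group_i = pairs_idx0[1L, ],
                                      group_j = pairs_idx0[2L, ],
                                      diff = 0, adjusted_p = 1,
                                      significant = FALSE)))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  Fv <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  pairs_idx <- utils::combn(names(groups), 2L)
  if (!is.finite(Fv)) {  # zero within-group variance
    if (stats::var(vapply(groups, mean, numeric(1L))) == 0) {
      Fv <- 0
      p <- 1
      pw <- data.frame(group_i = pairs_idx[1L, ], group_j = pairs_idx[2L, ],
                       diff = 0, adjusted_p = 1, significant = FALSE)
      return(list(F = Fv, df_between = tab[["Df"]][1L],
                  df_within = tab[["Df"]][2L], p = p, pairwise = pw))
    }
    stop("degenerate ANOVA input (zero within-group variance, unequal ",
         "means)")
  }
  tk <- stats::TukeyHSD(fit)$group
  lab <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(group_i = vapply(lab, `[`, character(1L), 2L),
                   group_j = vapply(lab, `[`, character(1L), 1L),
                   diff = tk[, "diff"],
                   adjusted_p = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha,
                   row.names = NULL)
  list(F = Fv, df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L],
       p = p, pairwise = pw)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the p-values ascending, applies the Sidak correction with a
#' step-down multiplicity `m - i + 1` at rank i
#' (`p_adj = 1 - (1 - p)^(m - i + 1)`), enforces monotonicity along the
#' sorted order, and restores the input order.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
holm_sidak_adjust <- function(p) {
  stopifnot(all(is.finite(p)), all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1L)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-timepoint group contrasts with Holm-Sidak adjustment
#'
#' The contrast layer used to compare two groups of repeated hourly
#' series (e.g. proestrus vs diestrus firing profiles): a Welch two-sample
#' test at every timepoint, Holm-Sidak adjusted across timepoints. The
#' omnibus repeated-measures fit is delegated to [stats::aov()] with a
#' subject error stratum and reported alongside.
#'
#' @param group_a,group_b numeric matrices (recordings x timepoints) on
#'   the same balanced time grid
#' @param time_labels optional labels for the timepoints
#' @param alpha significance level (default 0.05)
#' @return list with `contrasts` (data.frame: time, p, adjusted_p,
#'   significant) and `omnibus` (group and interaction p-values, or NULL
#'   when inestimable)
#' @export
rm_two_way_compare <- function(group_a, group_b, time_labels = NULL,
                               alpha = 0.05) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stop("unbalanced design: groups must share the same time grid; ",
         "re-bin both groups to a common span first")
  nt <- ncol(group_a)
  if (is.null(time_labels)) time_labels <- seq_len(nt)
  stopifnot(length(time_labels) == nt, nrow(group_a) >= 2L,
            nrow(group_b) >= 2L)
  p <- vapply(seq_len(nt), function(j) {
    a <- group_a[, j]
    b <- group_b[, j]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1L))
  adj <- holm_sidak_adjust(p)
  contrasts <- data.frame(time = time_labels, p = p, adjusted_p = adj,
                          significant = adj < alpha)

  omnibus <- tryCatch({
    long <- data.frame(
      value = c(as.vector(group_a), as.vector(group_b)),
      group = factor(rep(c("a", "b"), c(length(group_a), length(group_b)))),
      time = factor(c(rep(seq_len(nt), each = nrow(group_a)),
                      rep(seq_len(nt), each = nrow(group_b)))),
      subject = factor(c(rep(paste0("a", seq_len(nrow(group_a))), nt),
                         rep(paste0("b", seq_len(nrow(group_b))), nt))))
    fit <- stats::aov(value ~ group * time + Error(subject), data = long)
    sm <- summary(fit)
    within <- sm[["Error: Within"]][[1L]]
    between <- sm[["Error: subject"]][[1L]]
    pick <- function(tab, term) {
      i <- which(trimws(rownames(tab)) == term)
      if (length(i)) tab[["Pr(>F)"]][i] else NA_real_
    }
    list(p_group = pick(between, "group"),
         p_interaction = pick(within, "group:time"))
  }, error = function(e) NULL)
  list(contrasts = contrasts, omnibus = omnibus)
}

#' Assemble a machine-readable analysis report
#'
#' Bundles stage summaries, identification results and surge
#' classifications with the configuration and seeds that produced them.
#' Regenerating the report from the same inputs is byte-identical.
#'
#' @param stage_summary data.frame from [stage_summary()], or NULL
#' @param identification result of [identify_cohort()], or NULL
#' @param surge list of per-unit [classify_surge()] results (named by
#'   unit), or NULL
#' @param config,seed provenance recorded verbatim
#' @param path optional file to write the JSON report to
#' @return the report list, invisibly when written to `path`
#' @export
build_report <- function(stage_summary = NULL, identification = NULL,
                         surge = NULL, config = list(), seed = NULL,
                         path = NULL) {
  missing_in <- c("stage_summary", "identification",
                  "surge")[c(is.null(stage_summary),
                             is.null(identification), is.null(surge))]
  report <- list(
    stage_summary = stage_summary,
    identification = if (!is.null(identification))
      list(classifications = identification$classifications,
           fraction = identification$fraction,
           n_identified = identification$n_identified,
           n_units = identification$n_units),
    surge = if (!is.null(surge))
      list(units = surge,
           n_surge_like = sum(vapply(surge, function(u)
             identical(u$subtype, "surge_like"), TRUE)),
           n_units = length(surge)),
    inputs_missing = as.list(missing_in),
    config = config,
    seed = seed)
  if (!is.null(path)) {
    write_json_file(report, path)
    return(invisible(report))
  }
  report
}
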