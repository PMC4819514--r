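#' @include pk-model.R
NULL

#' Per-group mean, standard error and size
#'
#' Group summaries in the mean-plus-or-minus-SE convention
#' (SE = SD / sqrt(n)). Groups with fewer than two observations get an NA
#' standard error with a warning rather than a number.
#'
#' @param values numeric vector of per-tumor metric values
#' @param groups factor or character vector of group labels
#' @return data.frame with columns group, n, mean, se
#' @examples
#' summarizeGroups(c(1, 2, 3), rep("a", 3))   # mean 2, se 1/sqrt(3)
#' @export
summarizeGroups <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
  }))
  if (any(out$n < 2))
    warning("standard error undefined for groups with n < 2")
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA (equal-variance F test) across the
#' groups. Degenerate inputs — zero within-group variance with equal
#' means — raise a classed condition rather than returning NaN.
#'
#' @param values numeric vector
#' @param groups group labels; at least two groups with n >= 2 each
#' @return list with F, dfBetween, dfWithin, p, msWithin, and the group
#'   means/sizes used
#' @export
oneWayAnova <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- factor(as.character(groups))
  n <- table(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfW <- length(values) - nlevels(groups)
  if (ssw == 0 && stats::var(tapply(values, groups, mean)) == 0)
    undefinedResult("zero within-group variance with equal means: F undefined")
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic),
       dfBetween = unname(ft$parameter[1]),
       dfWithin = unname(ft$parameter[2]),
       p = unname(ft$p.value),
       msWithin = ssw / dfW,
       groupMeans = tapply(values, groups, mean),
       groupN = as.vector(n))
}

#' Newman-Keuls (Student-Newman-Keuls) post-hoc comparisons
#'
#' The stepwise studentized-range procedure after a one-way ANOVA: group
#' means are sorted; each ordered pair spanning r means is tested against
#' the studentized-range distribution q(r, df_within) at level alpha, with
#' the standard error sqrt(MSE / n_h) using the harmonic mean group size
#' n_h for unequal groups. Spans are processed widest first and the
#' containment rule applies: every pair nested inside a non-significant
#' span is declared non-significant without regard to its own statistic.
#' Range-distribution tail probabilities come from [stats::ptukey].
#'
#' @param values numeric vector
#' @param groups group labels; every group n >= 2
#' @param alpha significance criterion (default 0.05)
#' @return data.frame, one row per pair: group1, group2 (group1 has the
#'   smaller mean), meanDiff, q, stepRange (r), pValue, blocked (TRUE when
#'   the containment rule suppressed the comparison), significant
#' @export
newmanKeuls <- function(values, groups, alpha = 0.05) {
  av <- oneWayAnova(values, groups)
  means <- sort(av$groupMeans)
  k <- length(means)
  nh <- k / sum(1 / av$groupN)
  sem <- sqrt(av$msWithin / nh)
  labs <- names(means)
  res <- list()
  nonsigSpan <- matrix(FALSE, k, k)   # [i, j] TRUE: i..j inside a non-significant span
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      diffIJ <- means[j] - means[i]
      q <- diffIJ / sem
      p <- stats::ptukey(q, nmeans = r, df = av$dfWithin,
                         lower.tail = FALSE)
      blocked <- nonsigSpan[i, j]
      sig <- !blocked && p < alpha
      if (!sig) {
        for (a in i:j) for (b in a:j) nonsigSpan[a, b] <- TRUE
      }
      res[[length(res) + 1]] <- data.frame(
        group1 = labs[i], group2 = labs[j], meanDiff = unname(diffIJ),
        q = unname(q), stepRange = r, pValue = unname(p),
        blocked = blocked, significant = sig)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group comparison report for a multi-arm cohort
#'
#' Runs the study's statistical workflow per stratum (metric x tumor line x
#' day): mean-plus-or-minus-SE summaries, one-way ANOVA, and Newman-Keuls
#' pairwise comparisons, with convenience flags for each arm versus the
#' control arm and versus a comparator arm. Strata with a single arm get
#' summaries only; degenerate strata are skipped with a warning.
#'
#' @param table data.frame with columns `arm`, `metric`, `value` and
#'   optionally `line`, `day`, `tumorId`
#' @param alpha significance criterion
#' @param controlArm,comparatorArm arm labels used for the versus-control
#'   and versus-comparator flags
#' @return list of data.frames: `summaries`, `anova`, `posthoc`, `flags`
#' @export
runCohortReport <- function(table, alpha = 0.05, controlArm = "Veh-ctrl",
                            comparatorArm = "DC101") {
  req <- c("arm", "metric", "value")
  if (!all(req %in% names(table)))
    stop("table needs columns: ", paste(req, collapse = ", "))
  strataCols <- intersect(c("metric", "line", "day"), names(table))
  key <- interaction(table[strataCols], drop = TRUE, sep = " | ")
  summaries <- list(); anovas <- list(); posthocs <- list(); flags <- list()
  for (s in levels(key)) {
    sub <- table[key == s, , drop = FALSE]
    lab <- sub[1, strataCols, drop = FALSE]
    sm <- summarizeGroups(sub$value, sub$arm)
    summaries[[s]] <- cbind(lab, sm, row.names = NULL)
    arms <- table(sub$arm)
    if (length(arms) < 2 || any(arms < 2)) next
    av <- tryCatch(oneWayAnova(sub$value, sub$arm),
                   tumorquantUndefined = function(e) {
                     warning("stratum '", s, "' skipped: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(av)) next
    anovas[[s]] <- cbind(lab, data.frame(F = av$F, dfBetween = av$dfBetween,
                                         dfWithin = av$dfWithin, p = av$p),
                         row.names = NULL)
    ph <- newmanKeuls(sub$value, sub$arm, alpha = alpha)
    posthocs[[s]] <- cbind(lab[rep(1, nrow(ph)), , drop = FALSE], ph,
                           row.names = NULL)
    for (arm in setdiff(names(arms), controlArm)) {
      vsCtrl <- ph[(ph$group1 == arm & ph$group2 == controlArm) |
                   (ph$group2 == arm & ph$group1 == controlArm), ]
      vsCmp <- ph[(ph$group1 == arm & ph$group2 == comparatorArm) |
                  (ph$group2 == arm & ph$group1 == comparatorArm), ]
      flags[[paste(s, arm)]] <- cbind(lab, data.frame(
        arm = arm,
        significantVsControl = if (nrow(vsCtrl)) any(vsCtrl$significant) else NA,
        significantVsComparator = if (nrow(vsCmp)) any(vsCmp$significant) else NA),
        row.names = NULL)
    }
  }
  bindOrNull <- function(l) if (length(l)) do.call(rbind, c(l, make.row.names = FALSE)) else NULL
  list(summaries = bindOrNull(summaries), anova = bindOrNull(anovas),
       posthoc = bindOrNull(posthocs), flags = bindOrNull(flags))
}

#' Write a cohort report to CSV and text
#'
#' @param report result of [runCohortReport]
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
writeCohortReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in c("summaries", "anova", "posthoc", "flags")) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("Cohort group-comparison report", con)
  if (!is.null(report$summaries)) {
    writeLines("\n== Group summaries (mean +/- SE) ==", con)
    utils::capture.output(print(report$summaries), file = con, append = TRUE)
  }
  if (!is.null(report$anova)) {
    writeLines("\n== One-way ANOVA ==", con)
    utils::capture.output(print(report$anova), file = con, append = TRUE)
  }
  if (!is.null(report$posthoc)) {
    writeLines("\n== Newman-Keuls pairwise comparisons ==", con)
    utils::capture.output(print(report$posthoc), file = con, append = TRUE)
  }
  invisible(c(paths, txt))
}
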