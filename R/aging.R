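# Per-oocyte timelines, degradation alignment, group classification,
# statistical comparisons and headline summaries for the postovulatory
# aging assay.

#' Construct a per-oocyte timeline
#'
#' Hourly measurements for one oocyte: inner-layer stiffness E2, dissipated
#' viscous energy, optional cortical-granule fluorescence area, and the
#' morphology label. Degradation is absorbing: once an oocyte is labelled
#' degraded it stays degraded.
#'
#' @param oocyte_id Identifier.
#' @param source `"fresh"` or `"thawed"`.
#' @param t_hours Strictly increasing times since retrieval/thawing, in h.
#' @param E2 Inner-layer Young's modulus per timepoint, Pa.
#' @param dissipation Dissipated viscous energy per timepoint, fJ.
#' @param cg_area Optional CG fluorescence peak area, ADU um.
#' @param morphology Per-timepoint label, `"healthy"` or `"degraded"`.
#' @return An object of class `oocyte_timeline`.
#' @export
oocyte_timeline <- function(oocyte_id, source = c("thawed", "fresh"),
                            t_hours, E2, dissipation,
                            cg_area = NULL, morphology) {
  source <- match.arg(source)
  n <- length(t_hours)
  stopifnot(length(E2) == n, length(dissipation) == n,
            length(morphology) == n)
  if (is.null(cg_area)) cg_area <- rep(NA_real_, n)
  if (n > 1L && any(diff(t_hours) <= 0))
    stop("t_hours must be strictly increasing")
  if (!all(morphology %in% c("healthy", "degraded")))
    stop("morphology labels must be 'healthy' or 'degraded'")
  deg <- morphology == "degraded"
  if (any(deg) && any(diff(deg) < 0))
    stop("degraded is absorbing: found a degraded -> healthy transition")
  if (sum(diff(c(FALSE, deg)) == 1L) > 1L)
    stop("at most one healthy -> degraded transition allowed")
  structure(list(oocyte_id = oocyte_id, source = source,
                 t_hours = as.numeric(t_hours), E2 = as.numeric(E2),
                 dissipation = as.numeric(dissipation),
                 cg_area = as.numeric(cg_area),
                 morphology = as.character(morphology)),
            class = "oocyte_timeline")
}

#' Re-time a timeline to the degradation event
#'
#' For oocytes that degrade, the first degraded timepoint becomes time
#' zero and earlier points get negative times ("time before degradation"),
#' so different oocytes become comparable despite different lifespans.
#' Never-degraded oocytes keep absolute time and are flagged.
#'
#' @param tl An [oocyte_timeline()].
#' @return An object of class `aligned_series`: the timeline fields plus
#'   `t_rel` (h) and `degraded` (flag).
#' @export
align_to_degradation <- function(tl) {
  stopifnot(inherits(tl, "oocyte_timeline"))
  deg_idx <- which(tl$morphology == "degraded")
  if (length(deg_idx)) {
    t_deg <- tl$t_hours[deg_idx[1L]]
    t_rel <- tl$t_hours - t_deg
    degraded <- TRUE
  } else {
    t_rel <- tl$t_hours
    degraded <- FALSE
  }
  structure(c(unclass(tl), list(t_rel = t_rel, degraded = degraded)),
            class = "aligned_series")
}

#' Split a cohort into healthy and degraded groups
#'
#' Partitions timelines by whether a degraded label occurs within the
#' observation horizon. An oocyte degraded exactly at the horizon counts
#' as degraded (closed interval).
#'
#' @param tls List of [oocyte_timeline()]s.
#' @param horizon Observation horizon in h, default 6.
#' @return A list with `healthy` and `degraded` sublists (disjoint and
#'   exhaustive).
#' @export
classify_groups <- function(tls, horizon = 6) {
  is_deg <- vapply(tls, function(tl) {
    any(tl$morphology == "degraded" & tl$t_hours <= horizon)
  }, logical(1))
  list(healthy = tls[!is_deg], degraded = tls[is_deg])
}

## ---- statistical tests (implemented from the standard definitions) -----

.rank_ties <- function(x) {
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  list(ranks = r, tie_sizes = as.integer(tab[tab > 1L]))
}

.anova_oneway <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  n <- sum(ns)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ss_between <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1L; df2 <- n - k
  Fst <- (ss_between / df1) / (ss_within / df2)
  list(statistic = Fst, p_value = stats::pf(Fst, df1, df2,
                                            lower.tail = FALSE))
}

.kruskal_wallis <- function(groups) {
  n <- sum(lengths(groups))
  all_x <- unlist(groups)
  rt <- .rank_ties(all_x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rt$ranks, idx, sum)
  H <- 12 / (n * (n + 1)) * sum(rbar^2 / lengths(groups)) - 3 * (n + 1)
  # tie correction
  Ct <- 1 - sum(rt$tie_sizes^3 - rt$tie_sizes) / (n^3 - n)
  H <- H / Ct
  df <- length(groups) - 1L
  list(statistic = H, p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

.mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rt <- .rank_ties(c(x, y))
  U <- sum(rt$ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- sum(rt$tie_sizes^3 - rt$tie_sizes) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, p_value = 1))
  # normal approximation with continuity correction, two-sided
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare measurement groups with the assay's standard tests
#'
#' One-way ANOVA (F statistic), Kruskal-Wallis (H with tie correction) or
#' Mann-Whitney (U with normal approximation and continuity correction),
#' computed from the textbook definitions.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param test `"anova"`, `"kruskal_wallis"` or `"mann_whitney"`.
#' @param alpha Significance level recorded with the result, default 0.05.
#' @return An object of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `group_sizes`, `alpha`, `significant`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("anova", "kruskal_wallis",
                                    "mann_whitney"),
                           alpha = 0.05) {
  test <- match.arg(test)
  groups <- lapply(values_by_group, as.numeric)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (test == "mann_whitney") {
    if (length(groups) != 2L) stop("mann_whitney needs exactly 2 groups")
    if (any(lengths(groups) < 1L)) stop("empty group")
    res <- .mann_whitney(groups[[1L]], groups[[2L]])
  } else {
    if (any(lengths(groups) < 3L))
      stop("each group needs n >= 3 for ", test)
    res <- if (test == "anova") .anova_oneway(groups)
           else .kruskal_wallis(groups)
  }
  structure(list(test = test, statistic = unname(res$statistic),
                 p_value = unname(res$p_value),
                 group_sizes = unname(lengths(groups)), alpha = alpha,
                 significant = res$p_value < alpha),
            class = "group_comparison")
}

#' Embryo-yield percentage table
#'
#' Computes stage-yield percentages from raw counts, rounding half-up to
#' integers (the printed convention). When printed percentages are
#' supplied, arithmetic discrepancies are annotated rather than
#' reproduced.
#'
#' @param counts Data frame with columns `group`, `total` and one column
#'   per stage holding counts (`<= total`).
#' @param printed Optional data frame of the same shape holding the
#'   percentages as printed, for discrepancy annotation.
#' @return Data frame with `group`, `total`, and per-stage `<stage>_pct`
#'   columns; attribute `"discrepancies"` lists printed values that
#'   disagree with the computed ones.
#' @export
yield_table <- function(counts, printed = NULL) {
  stopifnot(is.data.frame(counts), all(c("group", "total") %in%
                                         names(counts)))
  if (any(counts$total == 0)) stop("zero total in yield table")
  stages <- setdiff(names(counts), c("group", "total"))
  if (any(counts[stages] < 0)) stop("negative count")
  if (any(counts[stages] > counts$total)) stop("stage count exceeds total")
  round_half_up <- function(x) floor(x + 0.5)
  out <- counts[c("group", "total")]
  disc <- character(0)
  for (st in stages) {
    pct <- round_half_up(100 * counts[[st]] / counts$total)
    out[[paste0(st, "_pct")]] <- pct
    if (!is.null(printed) && st %in% names(printed)) {
      bad <- which(!is.na(printed[[st]]) & printed[[st]] != pct)
      for (i in bad)
        disc <- c(disc, sprintf(
          "%s/%s: printed %d%% but %d/%d = %d%%", counts$group[i], st,
          printed[[st]][i], counts[[st]][i], counts$total[i], pct[i]))
    }
  }
  attr(out, "discrepancies") <- disc
  out
}

#' Cohort-level aging summary with change-point flags
#'
#' Computes per-hour cohort means and standard errors of E2 and dissipation
#' on the degradation-aligned time axis, then tests each later hour against
#' the baseline (earliest shared) hour with the configured test and flags
#' the first hour at which E2 departs from baseline. Because one flag is
#' chosen among several hourly comparisons, the hourly p-values are
#' Holm-adjusted by default so that the chance of any false flag on a null
#' cohort stays at `alpha`; raw p-values are always reported.
#'
#' @param aligned List of [align_to_degradation()] results (a cohort).
#' @param test Test used for the hourly comparisons, default
#'   `"mann_whitney"`.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust `"holm"` (default) or `"none"`.
#' @param value Which variable drives the flag: `"E2"` or `"dissipation"`.
#' @return An object of class `headline_summary`: `table` (data frame with
#'   `t_rel`, `n`, `mean_E2`, `se_E2`, `mean_dissipation`,
#'   `se_dissipation`, `p_raw`, `p_adj`), `flag_hour` (first significant
#'   aligned hour, `NA` when none), `direction` (+1 rise / -1 fall at the
#'   flag), `alpha`, `test`.
#' @export
headline_summary <- function(aligned, test = "mann_whitney", alpha = 0.05,
                             p_adjust = c("holm", "none"), value = "E2") {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(aligned) > 0, value %in% c("E2", "dissipation"))
  long <- do.call(rbind, lapply(aligned, function(a)
    data.frame(id = a$oocyte_id, t_rel = a$t_rel, E2 = a$E2,
               dissipation = a$dissipation)))
  hours <- sort(unique(long$t_rel))
  tab <- do.call(rbind, lapply(hours, function(h) {
    sub <- long[long$t_rel == h, ]
    data.frame(t_rel = h, n = nrow(sub),
               mean_E2 = mean(sub$E2),
               se_E2 = stats::sd(sub$E2) / sqrt(nrow(sub)),
               mean_dissipation = mean(sub$dissipation),
               se_dissipation = stats::sd(sub$dissipation) /
                 sqrt(nrow(sub)))
  }))

  base_h <- hours[1L]
  base_vals <- long[long$t_rel == base_h, value]
  p_raw <- rep(NA_real_, length(hours))
  for (i in seq_along(hours)[-1L]) {
    vals <- long[long$t_rel == hours[i], value]
    if (length(vals) >= 2L && length(base_vals) >= 2L)
      p_raw[i] <- compare_groups(list(baseline = base_vals, hour = vals),
                                 test = test, alpha = alpha)$p_value
  }
  p_adj <- p_raw
  tested <- !is.na(p_raw)
  if (p_adjust == "holm" && any(tested))
    p_adj[tested] <- stats::p.adjust(p_raw[tested], method = "holm")
  tab$p_raw <- p_raw
  tab$p_adj <- p_adj

  sig <- which(!is.na(p_adj) & p_adj < alpha)
  flag_hour <- if (length(sig)) hours[sig[1L]] else NA_real_
  direction <- if (length(sig)) {
    m <- tab[[paste0("mean_", value)]]
    sign(m[sig[1L]] - m[1L])
  } else NA_real_
  structure(list(table = tab, flag_hour = flag_hour,
                 direction = direction, value = value, alpha = alpha,
                 test = test, p_adjust = p_adjust,
                 n_oocytes = length(aligned)),
            class = "headline_summary")
}

#' @export
print.headline_summary <- function(x, ...) {
  cat(sprintf("<headline_summary> %d oocytes, %s on %s (alpha = %g, %s)\n",
              x$n_oocytes, x$test, x$value, x$alpha, x$p_adjust))
  if (is.na(x$flag_hour))
    cat("  no hour departs from baseline\n")
  else
    cat(sprintf("  first departure at t_rel = %g h (%s)\n", x$flag_hour,
                if (x$direction > 0) "rise" else "fall"))
  print(x$table, digits = 3)
  invisible(x)
}

#' Write a headline summary to CSV and JSON
#'
#' @param x A [headline_summary()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_headline <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "headline_summary"))
  if (!is.null(csv_path))
    utils::write.csv(x$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(flag_hour = x$flag_hour, direction = x$direction,
           value = x$value, alpha = x$alpha, test = x$test,
           n_oocytes = x$n_oocytes),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Read and write the timeline CSV schema
#'
#' Columns: `oocyte_id, source, t_hours, E2_Pa, dissipation_fJ, cg_area,
#' morphology`, one row per oocyte-timepoint.
#'
#' @param tls List of [oocyte_timeline()]s.
#' @param path CSV path.
#' @return `write_timelines()` returns `path` invisibly;
#'   `read_timelines()` returns a list of timelines.
#' @export
write_timelines <- function(tls, path) {
  df <- do.call(rbind, lapply(tls, function(tl)
    data.frame(oocyte_id = tl$oocyte_id, source = tl$source,
               t_hours = tl$t_hours, E2_Pa = tl$E2,
               dissipation_fJ = tl$dissipation, cg_area = tl$cg_area,
               morphology = tl$morphology)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timelines
#' @export
read_timelines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$oocyte_id), function(sub) {
    sub <- sub[order(sub$t_hours), ]
    oocyte_timeline(oocyte_id = sub$oocyte_id[1L],
                    source = sub$source[1L], t_hours = sub$t_hours,
                    E2 = sub$E2_Pa, dissipation = sub$dissipation_fJ,
                    cg_area = sub$cg_area, morphology = sub$morphology)
  })
}
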