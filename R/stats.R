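# Group-comparison workflow: distributional checks, test routing,
# omnibus and post-hoc tests, significance letters, correlogram.

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups differ in length")
  }
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups[ok])
  n <- table(groups)
  if (length(n) < 2) stop("need at least 2 groups")
  if (any(n < 3)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(names(n)[n < 3], collapse = ", "))
  }
  list(values = values, groups = factor(groups, levels = unique(groups)))
}

#' Route between parametric and nonparametric comparison
#'
#' Shapiro-Wilk on the pooled within-group residuals (the normality
#' assumption of ANOVA concerns residuals, not the raw pooled data)
#' and Bartlett's test of homoscedasticity. The parametric route
#' (ANOVA + Tukey) is taken only when both pass at `alpha`; otherwise
#' the nonparametric route (Kruskal-Wallis + Dunn).
#'
#' @param values Numeric vector.
#' @param groups Group labels, >= 2 groups of >= 3 observations.
#' @param alpha Significance level for the assumption checks.
#' @return List with `decision` ("parametric" or "nonparametric"),
#'   `shapiro_p`, `bartlett_p`.
#' @export
route_test <- function(values, groups, alpha = 0.05) {
  d <- check_groups(values, groups)
  resid <- d$values - ave(d$values, d$groups)
  sw <- tryCatch(shapiro.test(resid)$p.value, error = function(e) 0)
  bt <- tryCatch(bartlett.test(d$values, d$groups)$p.value,
                 error = function(e) 0)
  list(decision = if (sw > alpha && bt > alpha) "parametric"
       else "nonparametric",
       shapiro_p = sw, bartlett_p = bt)
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with chi-squared p on k-1 degrees of freedom
#' (through [stats::kruskal.test()]). All-identical values are flagged
#' degenerate: the tie correction makes H undefined.
#'
#' @inheritParams route_test
#' @return List with `H`, `p`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  d <- check_groups(values, groups)
  if (length(unique(d$values)) == 1) {
    return(list(H = NA_real_, p = NA_real_,
                df = nlevels(d$groups) - 1, degenerate = TRUE))
  }
  kt <- kruskal.test(d$values, d$groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Dunn post-hoc pairwise comparisons
#'
#' z statistics from the pooled ranks of all observations with tie
#' correction: for groups i, j,
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
#' with T = sum(t^3 - t) / (12 (N - 1)) over tie groups. Two-sided p,
#' optionally adjusted over all pairs.
#'
#' @inheritParams route_test
#' @param adjustment One of "none", "holm", "bonferroni", "BH".
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`,
#'   covering all unordered group pairs.
#' @export
dunn_posthoc <- function(values, groups, adjustment = "none") {
  adjustment <- match.arg(adjustment, c("none", "holm", "bonferroni", "BH"))
  d <- check_groups(values, groups)
  if (length(unique(d$values)) == 1) {
    stop("all values identical: Dunn comparisons undefined")
  }
  r <- rank(d$values)
  N <- length(r)
  ties <- table(d$values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, d$groups, mean)
  n <- table(d$groups)
  g <- levels(d$groups)
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- p.adjust(p, method = if (adjustment == "none") "none"
                    else adjustment)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p_adj, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' @inheritParams route_test
#' @return List with `F`, `p`, `df`, `pairwise` (data.frame `group1`,
#'   `group2`, `diff`, `p`, `p_adj` — Tukey p is already familywise),
#'   `degenerate`.
#' @export
anova_tukey <- function(values, groups) {
  d <- check_groups(values, groups)
  if (var(d$values - ave(d$values, d$groups)) == 0) {
    return(list(F = NA_real_, p = NA_real_, df = NULL, pairwise = NULL,
                degenerate = TRUE))
  }
  fit <- aov(d$values ~ d$groups)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)[[1]]
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(group1 = vapply(nm, `[`, character(1), 2),
                   group2 = vapply(nm, `[`, character(1), 1),
                   diff = -tk[, "diff"], p = tk[, "p adj"],
                   p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = s[["Df"]], pairwise = pw, degenerate = FALSE)
}

#' Significance letters
#'
#' For each group, the set of other groups it differs from at `alpha`
#' (on the adjusted p), as annotated above group plots.
#'
#' @param pairwise data.frame with `group1`, `group2` and `p_adj` (or
#'   `p`) columns.
#' @param alpha Significance level.
#' @return Named list: for each group, a (possibly empty) sorted
#'   character vector of the groups it differs from.
#' @export
significance_letters <- function(pairwise, alpha = 0.05) {
  p <- if ("p_adj" %in% names(pairwise)) pairwise$p_adj else pairwise$p
  groups <- sort(unique(c(pairwise$group1, pairwise$group2)))
  out <- setNames(vector("list", length(groups)), groups)
  for (g in groups) out[[g]] <- character(0)
  sig <- which(p < alpha)
  for (k in sig) {
    a <- pairwise$group1[k]; b <- pairwise$group2[k]
    out[[a]] <- sort(union(out[[a]], b))
    out[[b]] <- sort(union(out[[b]], a))
  }
  out
}

#' Routed group comparison
#'
#' Full workflow for one indicator: assumption checks and routing,
#' omnibus test (Kruskal-Wallis or ANOVA), pairwise post-hoc (Dunn or
#' Tukey) and significance letters.
#'
#' @inheritParams route_test
#' @param adjustment Dunn p adjustment ("none" by default; Tukey p is
#'   inherently familywise).
#' @return List of class `group_comparison`: `routing`, `omnibus`
#'   (list with statistic name, value, p), `pairwise` (data.frame),
#'   `letters`, `alpha`, `adjustment`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           adjustment = "none") {
  routing <- route_test(values, groups, alpha = alpha)
  if (routing$decision == "parametric") {
    at <- anova_tukey(values, groups)
    omnibus <- list(statistic = "F", value = at$F, p = at$p)
    pairwise <- at$pairwise
  } else {
    kw <- kruskal_wallis(values, groups)
    omnibus <- list(statistic = "H", value = kw$H, p = kw$p)
    pairwise <- if (kw$degenerate) NULL
      else dunn_posthoc(values, groups, adjustment = adjustment)
  }
  letters <- if (is.null(pairwise)) NULL
    else significance_letters(pairwise, alpha = alpha)
  structure(list(routing = routing, omnibus = omnibus,
                 pairwise = pairwise, letters = letters, alpha = alpha,
                 adjustment = adjustment),
            class = "group_comparison")
}

#' Spearman correlogram of the aggregated indicators
#'
#' 6x6 Spearman rank correlation (average ranks for ties) between the
#' category capacity and flow aggregates, with two-sided p-values,
#' pairwise-complete over the units.
#'
#' @param aggregated Table from [aggregate_indicators()].
#' @return List with `rho` and `p` (6x6 matrices over
#'   regulating/provisioning/cultural x capacity/flow).
#' @export
spearman_correlogram <- function(aggregated) {
  vars <- c("regulating_capacity", "regulating_flow",
            "provisioning_capacity", "provisioning_flow",
            "cultural_capacity", "cultural_flow")
  m <- as.matrix(aggregated[, vars])
  if (sum(stats::complete.cases(m)) < 4) {
    stop("need at least 4 units with complete aggregates")
  }
  rho <- cor(m, method = "spearman", use = "pairwise.complete.obs")
  p <- matrix(NA_real_, 6, 6, dimnames = dimnames(rho))
  for (i in 1:6) {
    for (j in 1:6) {
      if (i == j) { p[i, j] <- 0; next }
      ok <- stats::complete.cases(m[, c(i, j)])
      ct <- suppressWarnings(
        cor.test(m[ok, i], m[ok, j], method = "spearman", exact = FALSE))
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}
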