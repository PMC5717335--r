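# Statistics on per-cell summaries: normality-routed two-group tests
# (Student's t vs Mann-Whitney), Kruskal-Wallis with Dunn's post hoc for
# >= 3 groups, and the figure-legend significance-star convention.

#' Significance stars for a p-value
#'
#' \code{***} if p < 0.001, \code{**} if p < 0.01, \code{*} if p < 0.05,
#' \code{ns} otherwise (strict inequalities; p = 0.05 is \code{ns}).
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @return character vector of \code{ns}, \code{*}, \code{**}, \code{***}.
#' @export
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

.shapiro_normal <- function(x, alpha) {
  if (length(unique(x)) < 3L) return(FALSE)   # constant-ish: not testably Gaussian
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Normality-routed two-group comparison
#'
#' Both groups are Shapiro-Wilk tested at \code{alpha_normality}; if both
#' are compatible with a Gaussian, an unpaired two-tailed Student's t-test
#' (pooled variance by default) is run, otherwise a two-sided Mann-Whitney
#' rank-sum test (exact null when both n <= 8 with no ties, tie-corrected
#' normal approximation otherwise). The branch taken is recorded.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param alpha_normality normality-gate level (default 0.05).
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @param force \code{NULL} (route by normality), \code{"t"} or
#'   \code{"mann-whitney"} to bypass the gate.
#' @return a \code{ComparisonResult} list: test_name, statistic, p_value,
#'   stars, group sizes, normality decisions.
#' @export
route_two_group_test <- function(a, b, alpha_normality = 0.05,
                                 welch = FALSE, force = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  if (length(unique(c(a, b))) == 1L) {
    warning("both groups are identical constants; p set to 1")
    res <- list(groups = c("a", "b"), test_name = "t-test", statistic = 0,
                p_value = 1, stars = "ns", n = c(length(a), length(b)),
                normal = c(NA, NA))
    class(res) <- "ComparisonResult"
    return(res)
  }
  norm_a <- .shapiro_normal(a, alpha_normality)
  norm_b <- .shapiro_normal(b, alpha_normality)
  branch <- if (!is.null(force)) match.arg(force, c("t", "mann-whitney"))
            else if (norm_a && norm_b) "t" else "mann-whitney"
  if (branch == "t") {
    ht <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                   error = function(e) NULL)
    if (is.null(ht)) {
      warning("degenerate groups (zero variance); p set to 1")
      stat <- 0; pv <- 1
    } else {
      stat <- unname(ht$statistic); pv <- ht$p.value
    }
    name <- if (welch) "Welch t-test" else "t-test"
  } else {
    ex <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = ex,
                                              correct = !ex))
    stat <- unname(ht$statistic); pv <- ht$p.value
    name <- "Mann-Whitney"
  }
  res <- list(groups = c("a", "b"), test_name = name, statistic = stat,
              p_value = pv, stars = stars(pv),
              n = c(length(a), length(b)), normal = c(norm_a, norm_b))
  class(res) <- "ComparisonResult"
  res
}

#' Kruskal-Wallis ANOVA on ranks with Dunn's post hoc comparisons
#'
#' The omnibus H statistic uses the standard tie correction. Dunn's pairwise
#' z statistics compare mean ranks,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie term \eqn{T = \sum(t^3 - t) / (12(N-1))}; decisions are reported
#' at the 0.05 / 0.01 / 0.001 tiers, unadjusted by default (matching
#' fixed-alpha "Dunn's Method" decisions), or Bonferroni-adjusted.
#'
#' @param groups named list of >= 3 numeric samples, each of length >= 2.
#' @param adjust \code{"none"} (default) or \code{"bonferroni"}.
#' @return a \code{ComparisonResult} with omnibus statistic/p and a
#'   \code{pairwise} data.frame (group_1, group_2, z, p_value, stars).
#' @export
kruskal_dunn <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3L)
    stop("need >= 3 groups; use route_two_group_test() for 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs >= 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  kw <- stats::kruskal.test(x, g)

  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(names(groups), 2L)
  n_pairs <- ncol(combs)
  pw <- data.frame(group_1 = combs[1L, ], group_2 = combs[2L, ],
                   z = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    i <- combs[1L, k]; j <- combs[2L, k]
    se <- sqrt(s2 * (1 / n_i[[i]] + 1 / n_i[[j]]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    if (adjust == "bonferroni") p <- min(1, p * n_pairs)
    pw$z[k] <- z; pw$p_value[k] <- p
  }
  pw$stars <- stars(pw$p_value)
  res <- list(groups = names(groups),
              test_name = "Kruskal-Wallis+Dunn",
              statistic = unname(kw$statistic), p_value = kw$p.value,
              stars = stars(kw$p.value), n = as.integer(n_i),
              pairwise = pw, adjust = adjust)
  class(res) <- "ComparisonResult"
  res
}

#' Compare groups of per-cell summaries, routing by group count
#'
#' Two groups are routed through \code{\link{route_two_group_test}}; three
#' or more through \code{\link{kruskal_dunn}}.
#'
#' @param values numeric vector of per-cell summaries.
#' @param group factor or character of group labels, same length.
#' @param ... passed to the underlying test.
#' @return a \code{ComparisonResult}.
#' @export
compare_groups <- function(values, group, ...) {
  sp <- split(as.numeric(values), group)
  sp <- sp[vapply(sp, length, 0L) > 0L]
  if (length(sp) < 2L) stop("need at least 2 non-empty groups")
  if (length(sp) == 2L) {
    res <- route_two_group_test(sp[[1L]], sp[[2L]], ...)
    res$groups <- names(sp)
    res
  } else {
    kruskal_dunn(sp, ...)
  }
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: groups [%s], n = [%s]\n", x$test_name,
              paste(x$groups, collapse = ", "),
              paste(x$n, collapse = ", ")))
  cat(sprintf("statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Dunn", if (identical(x$adjust, "bonferroni"))
      ", Bonferroni-adjusted" else ", unadjusted", "):\n", sep = "")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize comparison results to a data.frame for CSV export
#'
#' @param x a \code{ComparisonResult}.
#' @param label optional label column (e.g. channel).
#' @return data.frame with one row for the omnibus test and one per
#'   pairwise comparison.
#' @export
comparison_as_table <- function(x, label = NA_character_) {
  rows <- data.frame(label = label, comparison = "omnibus",
                     group_1 = x$groups[1L],
                     group_2 = paste(x$groups[-1L], collapse = "|"),
                     test = x$test_name, statistic = x$statistic,
                     p_value = x$p_value, stars = x$stars,
                     stringsAsFactors = FALSE)
  if (!is.null(x$pairwise)) {
    pw <- data.frame(label = label, comparison = "pairwise",
                     group_1 = x$pairwise$group_1,
                     group_2 = x$pairwise$group_2,
                     test = "Dunn", statistic = x$pairwise$z,
                     p_value = x$pairwise$p_value, stars = x$pairwise$stars,
                     stringsAsFactors = FALSE)
    rows <- rbind(rows, pw)
  }
  rows
}
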