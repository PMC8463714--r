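#' Spearman rank correlation with strength and effect categories
#'
#' Pearson correlation of mid-ranks (average ranks for ties). The asymptotic
#' p-value uses the t approximation `t = r_s sqrt((n-2)/(1-r_s^2))` on `n-2`
#' degrees of freedom; alternatively a seeded permutation p-value is
#' available, which is preferable at the small subgroup sizes this kind of
#' cohort produces. Pairs with a missing value in either variable are
#' dropped (pairwise-complete deletion), and the categories follow Portney's
#' conventions (see [classify_association()]).
#'
#' @param x,y numeric vectors of equal length.
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm permutation replicates.
#' @param seed RNG seed for the permutation p-value.
#' @param labels optional `c(variable, outcome)` labels for the report row.
#' @return a one-row tibble: `variable`, `outcome`, `test`, `statistic`
#'   (r_s), `p_value`, `n`, `strength_category`, `effect_category`, `note`.
#' @examples
#' spearman_assoc(1:5, c(2, 1, 4, 3, 5))$statistic # 0.8
#' @export
spearman_assoc <- function(x, y, p_method = c("asymptotic", "permutation"),
                           n_perm = 10000L, seed = 1L,
                           labels = c("x", "y")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  row <- function(stat, p, note = NA_character_) {
    cats <- if (is.na(stat)) list(strength = NA_character_, effect = NA_character_)
            else classify_association(stat)
    out <- tibble::tibble(variable = labels[1], outcome = labels[2],
                          test = "spearman", statistic = stat, p_value = p,
                          n = n, strength_category = cats$strength,
                          effect_category = cats$effect, note = note)
    class(out) <- c("cast_assoc", class(out))
    out
  }
  if (n < 4) return(row(NA_real_, NA_real_, "fewer than 4 complete pairs"))
  if (var(x) == 0 || var(y) == 0) {
    return(row(NA_real_, NA_real_, "zero variance: correlation undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rs <- cor(rx, ry)
  p <- if (p_method == "asymptotic") {
    if (abs(rs) >= 1) {
      0
    } else {
      tstat <- rs * sqrt((n - 2) / (1 - rs^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    withr::with_seed(seed, {
      ref <- replicate(n_perm, cor(rx, sample(ry)))
      (1 + sum(abs(ref) >= abs(rs) - 1e-12)) / (n_perm + 1)
    })
  }
  row(rs, p)
}

#' Portney strength and effect-size categories for a correlation
#'
#' Strength of relationship on `|r_s|`: 0.00-0.25 little or none, 0.25-0.50
#' fair, 0.50-0.75 moderate, above 0.75 excellent (intervals closed on the
#' left, so 0.75 is already "excellent"). Effect size: greater than 0.10 but
#' below 0.30 small, 0.30-0.50 (inclusive) medium, above 0.50 large.
#'
#' @param r_s correlation in `[-1, 1]`.
#' @return list with `strength` and `effect` character labels.
#' @examples
#' classify_association(0.35) # fair, medium
#' @export
classify_association <- function(r_s) {
  if (!is.finite(r_s) || abs(r_s) > 1) {
    abort("`r_s` must be a finite correlation in [-1, 1]")
  }
  a <- abs(r_s)
  strength <- if (a < 0.25) "little/none" else if (a < 0.50) "fair"
              else if (a < 0.75) "moderate" else "excellent"
  effect <- if (a <= 0.10) "none" else if (a < 0.30) "small"
            else if (a <= 0.50) "medium" else "large"
  list(strength = strength, effect = effect)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way comparison of an outcome across groups, with the
#' standard tie correction `H / (1 - sum(t^3 - t) / (N^3 - N))`. The p-value
#' is chi-squared on `groups - 1` degrees of freedom, or a seeded label
#' permutation.
#'
#' @param values numeric outcome vector.
#' @param groups grouping factor/vector of the same length (or pass a list
#'   of numeric vectors as `values`).
#' @param p_method `"chi_square"` or `"permutation"`.
#' @param n_perm permutation replicates.
#' @param seed RNG seed.
#' @param labels optional `c(variable, outcome)` labels.
#' @return a one-row tibble like [spearman_assoc()] with `test = "kruskal_wallis"`
#'   and `statistic` = H.
#' @examples
#' kruskal_wallis_assoc(1:9, rep(1:3, each = 3))$statistic # 7.2
#' @export
kruskal_wallis_assoc <- function(values, groups = NULL,
                                 p_method = c("chi_square", "permutation"),
                                 n_perm = 10000L, seed = 1L,
                                 labels = c("group", "y")) {
  p_method <- match.arg(p_method)
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 non-empty groups")
  if (any(sizes == 0)) abort("empty group")
  N <- length(values)
  if (N < 5) abort("need total n >= 5")

  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  H <- 12 / (N * (N + 1)) * sum(as.numeric(sizes) * rbar^2) - 3 * (N + 1)
  tie_sizes <- table(values)
  tie_corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  row <- function(stat, p, note = NA_character_) {
    out <- tibble::tibble(variable = labels[1], outcome = labels[2],
                          test = "kruskal_wallis", statistic = stat,
                          p_value = p, n = N,
                          strength_category = NA_character_,
                          effect_category = NA_character_, note = note)
    class(out) <- c("cast_assoc", class(out))
    out
  }
  if (tie_corr <= 0) return(row(0, 1, "all values identical"))
  H <- H / tie_corr
  H <- max(H, 0)
  df <- length(sizes) - 1
  p <- if (p_method == "chi_square") {
    pchisq(H, df = df, lower.tail = FALSE)
  } else {
    withr::with_seed(seed, {
      ref <- replicate(n_perm, {
        rp <- sample(r)
        rb <- tapply(rp, groups, mean)
        (12 / (N * (N + 1)) * sum(as.numeric(sizes) * rb^2) - 3 * (N + 1)) / tie_corr
      })
      (1 + sum(ref >= H - 1e-12)) / (n_perm + 1)
    })
  }
  row(H, p)
}

#' Cohort association report
#'
#' The full analysis grid relating per-cast modification summaries to
#' participant characteristics: Spearman correlations of `{age, height}`
#' against `{pmmd, nmmd, mmmd}` and Kruskal-Wallis tests of
#' `{afo_type, pathology}` against the same outcomes — 12 rows. Missing
#' covariates are dropped pairwise per analysis (so each row carries its own
#' `n`), groups with fewer than 2 members are excluded from the rank tests
#' and noted, and no multiple-testing correction is applied (the number of
#' tests is reported instead).
#'
#' @param records tibble/data frame with columns `age`, `height`,
#'   `afo_type`, `pathology`, `pmmd`, `nmmd`, `mmmd` (missing covariates as
#'   `NA`).
#' @param alpha significance level for the `significant` flag.
#' @param p_method passed to the two tests (`"asymptotic"`/`"chi_square"`
#'   mapped appropriately when `"permutation"` is requested).
#' @param seed RNG seed for permutation p-values.
#' @return a tibble of association rows with additional columns
#'   `significant` and `n_tests`.
#' @export
cohort_report <- function(records, alpha = 0.05,
                          p_method = c("asymptotic", "permutation"),
                          seed = 1L) {
  p_method <- match.arg(p_method)
  records <- as.data.frame(records)
  outcomes <- c("pmmd", "nmmd", "mmmd")
  covars <- c("age", "height")
  groupvars <- c("afo_type", "pathology")
  need <- c(covars, groupvars, outcomes)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(sprintf("cohort records lack columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("empty cohort")

  rows <- list()
  for (cv in covars) {
    for (oc in outcomes) {
      x <- records[[cv]]
      y <- records[[oc]]
      if (all(!is.finite(x))) {
        r <- tibble::tibble(variable = cv, outcome = oc, test = "spearman",
                            statistic = NA_real_, p_value = NA_real_, n = 0L,
                            strength_category = NA_character_,
                            effect_category = NA_character_,
                            note = sprintf("all '%s' values missing", cv))
      } else {
        r <- spearman_assoc(x, y, labels = c(cv, oc),
                            p_method = if (p_method == "permutation")
                              "permutation" else "asymptotic",
                            seed = seed)
      }
      rows[[length(rows) + 1]] <- r
    }
  }
  for (gv in groupvars) {
    for (oc in outcomes) {
      g <- factor(records[[gv]])
      y <- records[[oc]]
      keep_levels <- names(which(table(g[is.finite(y)]) >= 2))
      dropped <- setdiff(levels(droplevels(g)), keep_levels)
      sel <- g %in% keep_levels & is.finite(y)
      note <- if (length(dropped)) {
        sprintf("groups with n < 2 excluded: %s", paste(dropped, collapse = ", "))
      } else {
        NA_character_
      }
      r <- if (length(keep_levels) < 2) {
        tibble::tibble(variable = gv, outcome = oc, test = "kruskal_wallis",
                       statistic = NA_real_, p_value = NA_real_,
                       n = sum(sel), strength_category = NA_character_,
                       effect_category = NA_character_,
                       note = "fewer than 2 usable groups")
      } else {
        out <- kruskal_wallis_assoc(y[sel], droplevels(g[sel]),
                                    labels = c(gv, oc),
                                    p_method = if (p_method == "permutation")
                                      "permutation" else "chi_square",
                                    seed = seed)
        out$note <- note
        out
      }
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$n_tests <- sum(!is.na(out$p_value))
  class(out) <- c("cohort_report", class(out))
  out
}

#' Plot a cohort association grid
#'
#' Tile grid of the report: characteristic rows against outcome columns,
#' filled by the association statistic, starred where significant.
#'
#' @param object a tibble from [cohort_report()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  df <- as.data.frame(object)
  df$label <- ifelse(is.na(df$statistic), "n/a",
                     sprintf("%.2f%s", df$statistic,
                             ifelse(df$significant, " *", "")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$variable)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$p_value), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#ffffbf",
                                 limits = c(0, 1), name = "p") +
    ggplot2::labs(x = "modification outcome", y = "participant characteristic",
                  title = "Cohort associations (* significant)") +
    ggplot2::theme_minimal()
}
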