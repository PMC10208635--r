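#' Dispatch a cohort comparison to the matching standard test
#'
#' Runs the statistical design used for each figure-style comparison through
#' the standard routines and returns a uniform report: the omnibus statistic
#' and p-value, pairwise post hoc p-values where the design has them, and
#' compact-letter annotations at `alpha`. Supported designs:
#'
#' * `oneway_anova_tukey` - one-way ANOVA ([stats::aov()]) with Tukey HSD
#'   post hoc (cycle counts across age groups; per-phase counts).
#' * `rm_anova_tukey` - one-way repeated-measures ANOVA on
#'   `value ~ group` with a random animal intercept ([nlme::lme()]),
#'   Tukey contrasts via [multcomp::glht()] (stage-wise counts/heights
#'   within animals).
#' * `kruskal_mannwhitney` - Kruskal-Wallis omnibus with pairwise
#'   Mann-Whitney U post hoc (aging-phase peak heights).
#' * `twoway_anova_interaction` - two-way ANOVA `value ~ group * period`,
#'   reporting the interaction term (phase x light/dark counts).
#' * `paired_t`, `t_test`, `mannwhitney`, `ks` - the corresponding
#'   two-group tests.
#'
#' Zero-variance degenerate data in the paired/two-sample t designs are
#' resolved deterministically: p = 1 when the means are equal, p = 0
#' otherwise.
#'
#' @param data data.frame with a numeric `value` column and, as the design
#'   requires, `group` (factor-like), `animal_id`, `period`.
#' @param design one of the design names above.
#' @param alpha significance level for letters/stars (default 0.05).
#' @return a `battery_report`: list with `design`, `omnibus`
#'   (statistic, p_value), `pairwise` (data.frame or NULL), `letters`
#'   (named vector or NULL), `alpha`.
#' @export
test_battery <- function(data, design, alpha = 0.05) {
  design <- match.arg(design, c("oneway_anova_tukey", "rm_anova_tukey",
                                "kruskal_mannwhitney", "twoway_anova_interaction",
                                "paired_t", "t_test", "mannwhitney", "ks"))
  res <- switch(design,
    oneway_anova_tukey = {
      d <- data; d$group <- factor(d$group)
      fit <- stats::aov(value ~ group, data = d)
      s <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      pw <- pairwise_from_tukey(tk)
      list(omnibus = list(statistic = s[1, "F value"], p_value = s[1, "Pr(>F)"]),
           pairwise = pw, letters = cld_letters(levels(d$group), pw, alpha))
    },
    rm_anova_tukey = {
      d <- data; d$group <- factor(d$group); d$animal_id <- factor(d$animal_id)
      fit <- nlme::lme(value ~ group, random = ~ 1 | animal_id, data = d)
      an <- stats::anova(fit)
      gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey")))
      pw <- data.frame(
        contrast = rownames(gl$linfct),
        p_value = as.numeric(gl$test$pvalues),
        stringsAsFactors = FALSE
      )
      list(omnibus = list(statistic = an["group", "F-value"],
                          p_value = an["group", "p-value"]),
           pairwise = pw, letters = cld_letters(levels(d$group), pw, alpha))
    },
    kruskal_mannwhitney = {
      d <- data; d$group <- factor(d$group)
      kw <- stats::kruskal.test(value ~ group, data = d)
      lv <- levels(d$group)
      pairs <- utils::combn(lv, 2)
      pw <- data.frame(
        contrast = apply(pairs, 2, paste, collapse = " - "),
        p_value = apply(pairs, 2, function(g) {
          suppressWarnings(stats::wilcox.test(
            d$value[d$group == g[1]], d$value[d$group == g[2]],
            exact = FALSE))$p.value
        }),
        stringsAsFactors = FALSE
      )
      list(omnibus = list(statistic = unname(kw$statistic), p_value = kw$p.value),
           pairwise = pw, letters = cld_letters(lv, pw, alpha))
    },
    twoway_anova_interaction = {
      d <- data; d$group <- factor(d$group); d$period <- factor(d$period)
      fit <- stats::aov(value ~ group * period, data = d)
      s <- summary(fit)[[1]]
      ix <- grep(":", rownames(s))
      list(omnibus = list(statistic = s[ix, "F value"],
                          p_value = s[ix, "Pr(>F)"]),
           pairwise = NULL, letters = NULL)
    },
    paired_t = {
      two_group_t(data, paired = TRUE)
    },
    t_test = {
      two_group_t(data, paired = FALSE)
    },
    mannwhitney = {
      g <- split(data$value, data$group)
      stopifnot(length(g) == 2L)
      w <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]], exact = FALSE))
      list(omnibus = list(statistic = unname(w$statistic), p_value = w$p.value),
           pairwise = NULL, letters = NULL)
    },
    ks = {
      g <- split(data$value, data$group)
      stopifnot(length(g) == 2L)
      k <- suppressWarnings(stats::ks.test(g[[1]], g[[2]]))
      list(omnibus = list(statistic = unname(k$statistic), p_value = k$p.value),
           pairwise = NULL, letters = NULL)
    }
  )
  structure(c(list(design = design, alpha = alpha), res),
            class = "battery_report")
}

two_group_t <- function(data, paired) {
  g <- split(data$value, data$group)
  stopifnot(length(g) == 2L)
  x <- g[[1]]; y <- g[[2]]
  degenerate <- if (paired) stats::sd(x - y) == 0 else
    stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    eq <- if (paired) all(x == y) else mean(x) == mean(y)
    return(list(omnibus = list(statistic = if (eq) 0 else Inf,
                               p_value = if (eq) 1 else 0),
                pairwise = NULL, letters = NULL))
  }
  tt <- stats::t.test(x, y, paired = paired)
  list(omnibus = list(statistic = unname(tt$statistic), p_value = tt$p.value),
       pairwise = NULL, letters = NULL)
}

pairwise_from_tukey <- function(tk) {
  data.frame(contrast = sub("-", " - ", rownames(tk), fixed = TRUE),
             p_value = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Compact letter display: two groups share a letter iff they are NOT
# significantly different. Letters are assigned one per maximal clique of
# the non-significance graph, cliques ordered by their first group.
cld_letters <- function(groups, pairwise, alpha) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    gs <- strsplit(pairwise$contrast[i], " - ", fixed = TRUE)[[1]]
    if (length(gs) == 2 && all(gs %in% groups) &&
        is.finite(pairwise$p_value[i]) && pairwise$p_value[i] < alpha) {
      adj[gs[1], gs[2]] <- adj[gs[2], gs[1]] <- FALSE
    }
  }
  cl <- maximal_cliques(adj)
  cl <- cl[order(vapply(cl, min, numeric(1)))]
  letters_out <- stats::setNames(rep("", k), groups)
  for (j in seq_along(cl)) {
    letters_out[cl[[j]]] <- paste0(letters_out[cl[[j]]], letters[j])
  }
  letters_out
}

# Bron-Kerbosch maximal cliques on a small undirected adjacency matrix.
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      out[[length(out) + 1L]] <<- r
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report> %s: omnibus p = %.4g\n",
              x$design, x$omnibus$p_value))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %-30s p = %.4g%s\n", x$pairwise$contrast[i],
                  x$pairwise$p_value[i],
                  if (x$pairwise$p_value[i] < x$alpha) " *" else ""))
    }
  }
  if (!is.null(x$letters)) {
    cat("  letters:", paste(sprintf("%s=%s", names(x$letters), x$letters),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
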