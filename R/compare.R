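#' Compare maximum invasion distance between conditions
#'
#' Pairwise two-tailed two-sample Student t-tests (pooled variance)
#' between all condition pairs, plus a Tukey honest-significant-difference
#' comparison across all groups (via [stats::TukeyHSD()] on a one-way
#' ANOVA; unequal group sizes use the Tukey-Kramer correction). Group
#' summaries are reported as mean and standard deviation.
#'
#' Degenerate pairs in which both groups have zero variance are flagged:
#' their p-value is 1 when the means are identical and 0 otherwise.
#'
#' @param data A data frame with one observation per sample.
#' @param value Column of measurements (default `d_max_um`), tidy-eval.
#' @param group Column of condition labels (default `condition`),
#'   tidy-eval.
#' @return A `condition_comparison` object with `groups`, `pairwise` and
#'   `tukey` tibbles; see [tidy.condition_comparison()].
#' @export
compare_conditions <- function(data, value = d_max_um, group = condition) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2L) {
    stop_input("need at least two conditions to compare")
  }
  g <- droplevels(g)
  tab <- table(g)
  if (any(tab < 2L)) stop_input("every condition needs at least two observations")
  groups <- tibble::tibble(
    condition = names(tab),
    n = as.integer(tab),
    mean = as.numeric(tapply(v, g, mean)),
    sd = as.numeric(tapply(v, g, sd))
  )
  pairs <- utils::combn(levels(g), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- v[g == pairs[1, i]]
    b <- v[g == pairs[2, i]]
    zero_var <- sd(a) == 0 && sd(b) == 0
    if (zero_var) {
      tibble::tibble(
        group1 = pairs[1, i], group2 = pairs[2, i],
        statistic = if (mean(a) == mean(b)) 0 else Inf,
        df = length(a) + length(b) - 2,
        p_value = if (mean(a) == mean(b)) 1 else 0,
        zero_variance = TRUE
      )
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      tibble::tibble(
        group1 = pairs[1, i], group2 = pairs[2, i],
        statistic = unname(tt$statistic),
        df = unname(tt$parameter),
        p_value = tt$p.value,
        zero_variance = FALSE
      )
    }
  })
  pw <- dplyr::bind_rows(pw)
  tukey <- tryCatch({
    fit <- aov(v ~ g, data = data.frame(v = v, g = g))
    tk <- TukeyHSD(fit)$g
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    tibble::tibble(
      group1 = vapply(parts, `[`, character(1), 2),
      group2 = vapply(parts, `[`, character(1), 1),
      diff = -tk[, "diff"],
      conf_low = -tk[, "upr"],
      conf_high = -tk[, "lwr"],
      p_adj = tk[, "p adj"]
    )
  }, error = function(e) NULL)
  structure(
    list(groups = groups, pairwise = pw, tukey = tukey),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>\n")
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf(
      "  %s: %.2f +/- %.2f (n = %d)\n",
      x$groups$condition[i], x$groups$mean[i], x$groups$sd[i], x$groups$n[i]
    ))
  }
  cat(sprintf("  %d pairwise t-tests; Tukey-Kramer %s\n",
              nrow(x$pairwise), if (is.null(x$tukey)) "unavailable" else "included"))
  invisible(x)
}
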