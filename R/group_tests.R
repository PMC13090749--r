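# Grouped nonparametric comparisons: Kruskal-Wallis with Dunn's post-hoc
# test (rank-based z with tie correction), two-group Wilcoxon rank-sum,
# Fisher's exact test for 2 x k contingency, and a compact letter display
# built by insert-absorb over the pairwise significance graph.

#' Dunn's post-hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction. P-values are unadjusted by default; set `adjust` to
#' any [p.adjust()] method for stepwise adjustment.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param adjust p-adjustment method, `"none"` by default.
#' @return tibble (group1, group2, z, p.value).
#' @export
dunn_test <- function(values, groups, adjust = "none") {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) abort("every group must be non-empty")
  n <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  sizes <- tapply(rk, groups, length)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    tibble(group1 = g1, group2 = g2, z = z, p.value = 2 * pnorm(-abs(z)))
  })
  out <- bind_rows(res)
  out$p.value <- p.adjust(out$p.value, method = adjust)
  out
}

#' Compact letter display by insert-absorb
#'
#' Groups sharing a letter are not significantly different at `alpha`;
#' groups with no letter in common differ. Letter sets start from one block
#' holding every group; each significant pair splits the blocks containing
#' both, and blocks contained in another are absorbed.
#'
#' @param pairwise tibble with `group1`, `group2`, `p.value` (e.g. from
#'   [dunn_test()]).
#' @param groups character vector of all group labels.
#' @param alpha significance level.
#' @return named character vector of letters per group.
#' @export
letter_display <- function(pairwise, groups, alpha = 0.05) {
  groups <- as.character(unique(groups))
  blocks <- list(groups)
  sig <- pairwise[pairwise$p.value < alpha, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    g1 <- as.character(sig$group1[j]); g2 <- as.character(sig$group2[j])
    new_blocks <- list()
    for (b in blocks) {
      if (g1 %in% b && g2 %in% b) {
        new_blocks <- c(new_blocks, list(setdiff(b, g1)), list(setdiff(b, g2)))
      } else {
        new_blocks <- c(new_blocks, list(b))
      }
    }
    # absorb: drop any block contained in another
    keep <- rep(TRUE, length(new_blocks))
    for (i in seq_along(new_blocks)) {
      for (k in seq_along(new_blocks)) {
        if (i != k && keep[i] &&
            all(new_blocks[[i]] %in% new_blocks[[k]]) &&
            (length(new_blocks[[i]]) < length(new_blocks[[k]]) || i > k)) {
          keep[i] <- FALSE
        }
      }
    }
    blocks <- new_blocks[keep]
  }
  blocks <- blocks[order(map_chr(blocks, ~ sort(.x)[1]))]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(blocks)) {
    for (g in blocks[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' Grouped nonparametric test suite
#'
#' Kruskal-Wallis H and p over the groups, Dunn pairwise comparisons, the
#' compact letter display, and (for exactly two groups) the Wilcoxon
#' rank-sum p-value.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @param adjust p-adjustment for Dunn's test.
#' @param alpha significance level for the letter display.
#' @return a `group_test` list: `kruskal` (tibble), `dunn`, `letters`,
#'   `wilcoxon_p` (NA unless two groups).
#' @export
group_tests <- function(values, groups, adjust = "none", alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) == 0)) abort("every group must be non-empty")
  kw <- kruskal.test(values, groups)
  dunn <- dunn_test(values, groups, adjust = adjust)
  wil <- if (nlevels(groups) == 2) {
    suppressWarnings(wilcox.test(values ~ groups)$p.value)
  } else NA_real_
  structure(list(
    kruskal = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p.value = kw$p.value),
    dunn = dunn,
    letters = letter_display(dunn, levels(groups), alpha),
    wilcoxon_p = wil
  ), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test> Kruskal-Wallis H =", signif(x$kruskal$statistic, 4),
      ", p =", signif(x$kruskal$p.value, 4), "\n")
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy group_test
#' @export
tidy.group_test <- function(x, ...) {
  x$dunn %>% mutate(
    kruskal_h = x$kruskal$statistic, kruskal_p = x$kruskal$p.value
  )
}

#' 2 x k contingency comparison by Fisher's exact test
#'
#' @param a,b two categorical vectors of equal length (e.g. reanalyzable
#'   yes/no vs continent).
#' @return p-value of Fisher's exact test on `table(a, b)`.
#' @export
contingency_test <- function(a, b) {
  fisher.test(table(a, b))$p.value
}
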