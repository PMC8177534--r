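# Segregation arithmetic and the group-comparison statistics used for
# phenotype tables: genetic distance, marker co-segregation ratios,
# goodness-of-fit against 1:1, Kruskal-Wallis + Dunn post hoc with
# Benjamini-Hochberg adjustment, and the two-group Mann-Whitney U test.

#' Genetic map distance from recombinant counts
#'
#' Estimates the map distance between two loci as the recombination fraction
#' in centimorgans: `100 * recombinants / total`. With zero recombinants --
#' the co-segregation outcome of allelic mutants -- every mapping function
#' gives 0 cM; the Kosambi mapping function is available for non-zero
#' fractions.
#'
#' @param recombinants number of recombinant progeny (0 <= r <= total).
#' @param total total scored progeny (> 0).
#' @param mapping `"none"` (plain recombination fraction) or `"kosambi"`.
#' @return Distance in centimorgans.
#' @examples
#' genetic_distance(0, 156)  # 0: no recombinants, consistent with allelism
#' genetic_distance(5, 100)  # 5 cM
#' @export
genetic_distance <- function(recombinants, total, mapping = c("none", "kosambi")) {
  mapping <- match.arg(mapping)
  assert_that(total > 0, "total must be > 0")
  assert_that(recombinants >= 0 && recombinants <= total,
              "recombinants must be between 0 and total")
  r <- recombinants / total
  switch(mapping,
         none = 100 * r,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Normalized segregation ratio
#'
#' Expresses two class counts as a ratio normalized to the larger-class-one
#' convention of marker co-segregation tables: `"1/x"` with
#' `x = round(count_a / count_b, decimals)` (e.g. hygromycin-resistant vs
#' -sensitive progeny of a backcross, expected 1/1 for a single T-DNA
#' insertion).
#'
#' @param count_a,count_b class counts; `count_b` must be > 0.
#' @param decimals rounding of the normalized ratio.
#' @return A list with `ratio` (numeric `count_a / count_b`, rounded) and
#'   `label` (the `"1/x"` string).
#' @examples
#' segregation_ratio(136, 145)$label  # "1/0.9"
#' @export
segregation_ratio <- function(count_a, count_b, decimals = 1) {
  assert_that(count_b > 0, "count_b must be > 0 (zero denominator)")
  assert_that(count_a >= 0, "count_a must be >= 0")
  x <- round(count_a / count_b, decimals)
  list(ratio = x, label = sprintf("1/%s", format(x, trim = TRUE)))
}

#' Chi-square goodness of fit against a 1:1 segregation
#'
#' One-degree-of-freedom goodness-of-fit test of two class counts against the
#' 1:1 expectation of a single segregating locus.
#'
#' @param count_a,count_b observed class counts (total > 0).
#' @return A list with `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_1to1(136, 145)$statistic  # 0.288
#' @export
chi_square_1to1 <- function(count_a, count_b) {
  assert_that(count_a >= 0 && count_b >= 0, "counts must be >= 0")
  assert_that(count_a + count_b > 0, "total count must be > 0")
  ht <- suppressWarnings(chisq.test(c(count_a, count_b), p = c(0.5, 0.5),
                                    correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Dunn's post hoc test of pairwise group differences
#'
#' Rank-based z-tests on the pooled ranks after a Kruskal-Wallis omnibus,
#' with the standard tie correction; two-sided p-values from the normal
#' distribution. When `control` is given only control-vs-other pairs are
#' tested (the phenotype-table convention); otherwise all pairs.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length as `values`.
#' @param control optional control group label.
#' @return Data frame with `group1`, `group2`, `z`, `p_value`.
#' @export
dunn_test <- function(values, groups, control = NULL) {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  gl <- unique(groups)
  assert_that(length(gl) >= 2, "need at least two groups")
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  pairs <- if (is.null(control)) {
    utils::combn(gl, 2, simplify = FALSE)
  } else {
    assert_that(control %in% gl, "control group not found")
    lapply(setdiff(gl, control), function(g) c(control, g))
  }
  out <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    z <- unname((mean_rank[pr[1]] - mean_rank[pr[2]]) / se)
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare measurement groups the phenotype-table way
#'
#' With two groups, an exact-where-possible two-sided Mann-Whitney U test.
#' With more, a Kruskal-Wallis omnibus followed by Dunn tests of every group
#' against the control with Benjamini-Hochberg adjustment; stars mark
#' adjusted p < 0.05 (`*`) and < 0.01 (`**`). Groups with fewer than two
#' values are excluded from pairwise testing with a warning.
#'
#' @param values numeric measurements (e.g. per-cell sinuosity percentages).
#' @param groups group labels, same length as `values`.
#' @param control control group label; defaults to the first group.
#' @return A list with `omnibus` (test name, statistic, p_value) and
#'   `pairwise` (data frame with adjusted p-values and stars; `NULL` for the
#'   two-group case).
#' @export
compare_groups <- function(values, groups, control = NULL) {
  groups <- as.character(groups)
  assert_that(length(values) == length(groups),
              "values and groups must have the same length")
  gl <- unique(groups)
  assert_that(length(gl) >= 2, "need at least two groups")
  control <- control %||% gl[1]
  if (length(gl) == 2) {
    ht <- suppressWarnings(wilcox.test(values[groups == gl[1]],
                                       values[groups == gl[2]]))
    return(list(omnibus = list(test = "mann-whitney",
                               statistic = unname(ht$statistic),
                               p_value = ht$p.value),
                pairwise = NULL))
  }
  kw <- kruskal.test(values, factor(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with fewer than two values excluded from pairwise tests: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep <- groups %in% setdiff(gl, small)
  pw <- dunn_test(values[keep], groups[keep], control = control)
  pw$p_adjusted <- p.adjust(pw$p_value, method = "BH")
  pw$stars <- significance_stars(pw$p_adjusted)
  list(omnibus = list(test = "kruskal-wallis",
                      statistic = unname(kw$statistic),
                      p_value = kw$p.value),
       pairwise = pw)
}
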