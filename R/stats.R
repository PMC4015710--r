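#' Spearman correlation between a CT criterion and dN2
#'
#' Rank correlation with midranks for ties and a two-sided p-value
#' (t approximation, as appropriate for moderate cohort sizes with ties).
#'
#' @param table A cohort table (data.frame with a `dn2` column).
#' @param criterion Column name of the CT criterion.
#' @param dn2_col Name of the functional reference column.
#' @return A list with `rho`, `p_value` and `n` complete pairs.
#' @export
spearman_vs_dn2 <- function(table, criterion, dn2_col = "dn2") {
  stopifnot(criterion %in% names(table), dn2_col %in% names(table))
  x <- table[[criterion]]
  y <- table[[dn2_col]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant column: Spearman rho undefined for `", criterion, "`",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Criterion-dN2 dendrogram
#'
#' Agglomerative hierarchical clustering of dN2 and the CT air-trapping
#' criteria with correlation distance `d(u, v) = 1 - |rho_spearman(u, v)|`
#' and average linkage by default, mirroring the use of a cluster tree to
#' read off which criteria sit closest to the functional reference.
#'
#' @param table A cohort table.
#' @param variables Column names to cluster (must include the dN2 column;
#'   at least 3 variables).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param dn2_col Name of the reference variable.
#' @return An object of class `airtrap_dendrogram`: list with the `hclust`
#'   tree, the Spearman matrix `rho`, the distance matrix, and
#'   `closest_to_dn2`, criteria ordered by cophenetic distance from dN2.
#' @export
build_dendrogram <- function(table, variables, linkage = "average",
                             dn2_col = "dn2") {
  stopifnot(all(variables %in% names(table)))
  if (length(variables) < 3L) stop("need at least 3 variables",
                                   call. = FALSE)
  if (!dn2_col %in% variables) {
    stop("`variables` must include the reference column `", dn2_col, "`",
         call. = FALSE)
  }
  X <- as.matrix(table[, variables])
  const <- variables[apply(X, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0]
  if (length(const)) {
    stop("Spearman rho undefined for constant variable(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  rho <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  if (anyNA(rho)) {
    bad <- unique(rownames(which(is.na(rho), arr.ind = TRUE)))
    stop("undefined pairwise rho involving: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- stats::as.dist(1 - abs(rho))
  hc <- stats::hclust(d, method = linkage)
  coph <- as.matrix(stats::cophenetic(hc))
  dd <- sort(coph[dn2_col, setdiff(variables, dn2_col)])
  structure(
    list(hclust = hc, rho = rho, dist = d, closest_to_dn2 = dd,
         linkage = linkage),
    class = "airtrap_dendrogram"
  )
}

#' @export
print.airtrap_dendrogram <- function(x, ...) {
  cat(sprintf("<airtrap_dendrogram> %d leaves, %s linkage, 1-|rho| metric\n",
              length(x$hclust$labels), x$linkage))
  cat("closest to dN2:",
      paste(utils::head(names(x$closest_to_dn2), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram as Newick plus JSON heights
#'
#' @param dend An `airtrap_dendrogram`.
#' @param newick_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the Newick string.
#' @export
write_dendrogram <- function(dend, newick_path = NULL, json_path = NULL) {
  stopifnot(inherits(dend, "airtrap_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(labels = dend$hclust$labels, merge = dend$hclust$merge,
           height = dend$hclust$height,
           closest_to_dn2 = as.list(dend$closest_to_dn2)),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(nwk)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measure ICC from the standard two-way
#' (subjects x readers) mean-square decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`. Systematic
#' between-reader bias inflates the column mean square and is therefore
#' penalised, as absolute agreement requires.
#'
#' @param reader_a,reader_b Paired measurements from the two readers
#'   (equal length, at least 5 subjects).
#' @return An object of class `icc_result`: list with `icc`, `model`,
#'   `n_subjects` and the mean squares. `icc` is `NA` (flagged undefined)
#'   when the data have zero total variance.
#' @examples
#' rp <- generate_reader_pair(rnorm(50, 0, 2), error_sd = c(1, 1), seed = 2)
#' icc_two_readers(rp$reader_a, rp$reader_b)$icc
#' @export
icc_two_readers <- function(reader_a, reader_b) {
  stopifnot(is.numeric(reader_a), is.numeric(reader_b),
            length(reader_a) == length(reader_b))
  ok <- stats::complete.cases(reader_a, reader_b)
  a <- reader_a[ok]
  b <- reader_b[ok]
  n <- length(a)
  if (n < 5L) stop("need at least 5 paired subjects", call. = FALSE)
  k <- 2L
  Y <- cbind(a, b)
  grand <- mean(Y)
  rowm <- rowMeans(Y)
  colm <- colMeans(Y)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- Y - outer(rowm, rep(1, k)) -
    matrix(colm, n, k, byrow = TRUE) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom
  structure(
    list(icc = icc, model = "ICC(2,1)", n_subjects = n,
         ms = c(rows = msr, cols = msc, error = mse),
         undefined = is.na(icc)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %s over %d subjects\n", x$model,
              if (is.na(x$icc)) "undefined (zero variance)"
              else sprintf("%.3f", x$icc), x$n_subjects))
  invisible(x)
}

# Friedman chi-square statistic with tie correction from a matrix of
# within-row midranks. Returns 0 for fully tied data.
friedman_statistic <- function(R) {
  n <- nrow(R)
  k <- ncol(R)
  A <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  tie_term <- sum(apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  C <- 1 - tie_term / (n * k * (k^2 - 1))
  if (C <= 0) 0 else A / C
}

#' Across-level heterogeneity of a repeated criterion
#'
#' Friedman test of whether a criterion measured at the four anatomical
#' levels differs systematically across levels within subjects. For small
#' tables the p-value is exact, from full enumeration of the within-subject
#' rank permutations; larger tables use the chi-square approximation.
#'
#' @param x Either an n x k numeric matrix (subjects x levels) or a cohort
#'   table, in which case the four `<criterion>_l1..l4` columns are used.
#' @param criterion Criterion prefix when `x` is a cohort table.
#' @param exact `"auto"` (exact when the permutation space is at most
#'   `max_perms`), `TRUE` or `FALSE`.
#' @param max_perms Enumeration budget for the exact p-value.
#' @return A list with `statistic`, `p_value`, `method`, `n_subjects` and
#'   `n_dropped` (subjects removed for missing levels).
#' @export
level_heterogeneity_test <- function(x, criterion = "e_over_i_mld",
                                     exact = "auto", max_perms = 5e5) {
  if (is.data.frame(x)) {
    cols <- paste0(criterion, "_l", 1:4)
    if (!all(cols %in% names(x))) {
      stop("cohort table lacks columns ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
    x <- as.matrix(x[, cols])
  }
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 5L && !isTRUE(exact) && exact != "auto") {
    stop("need at least 5 complete subjects", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 complete subjects", call. = FALSE)

  R <- t(apply(x, 1, rank))
  stat <- friedman_statistic(R)

  n_perm <- factorial(k)^n
  use_exact <- isTRUE(exact) || (exact == "auto" && n_perm <= max_perms)
  if (use_exact && n_perm > max_perms) {
    stop("exact enumeration over ", n_perm, " permutations exceeds ",
         "max_perms", call. = FALSE)
  }
  if (use_exact) {
    perms <- all_permutations(k)
    np <- nrow(perms)
    combos <- as.matrix(expand.grid(rep(list(seq_len(np)), n)))
    colsums <- matrix(0, nrow(combos), k)
    for (i in seq_len(n)) {
      colsums <- colsums + matrix(R[i, perms[combos[, i], ]],
                                  nrow(combos), k)
    }
    # tie correction is permutation invariant; compare the raw chi-square
    # numerator, which is monotone in the corrected statistic
    a_obs <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
    a_perm <- 12 / (n * k * (k + 1)) * rowSums(colsums^2) - 3 * n * (k + 1)
    p <- mean(a_perm >= a_obs - 1e-10)
    method <- "Friedman (exact permutation)"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "Friedman (chi-square approximation)"
  }
  list(statistic = stat, p_value = p, method = method, n_subjects = n,
       n_dropped = n_dropped)
}

# all k! permutations of 1:k as rows (k inserted at every position of each
# permutation of 1:(k-1))
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE],
          k,
          if (pos <= k - 1L) sub[, pos:(k - 1L), drop = FALSE])
  }))
}
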