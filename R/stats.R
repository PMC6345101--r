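## Inferential layer: per-animal one-way ANOVA with Tamhane T2 post-hoc,
## group repeated-measures ANOVA with Bonferroni post-hoc, dose-response
## summaries. The omnibus fits call the base R machinery
## (stats::oneway.test, stats::aov, stats::pairwise.t.test); Tamhane T2 is
## implemented here since no installed package provides it.

#' One-way (between-groups) ANOVA
#'
#' Classical between/within decomposition via
#' [stats::oneway.test()] with `var.equal = TRUE`:
#' F = MS_between / MS_within with df = (k - 1, N - k). The Tamhane T2
#' post-hoc matrix is attached.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2), or a
#'   named list whose names label the post-hoc matrix.
#' @return a [StatResult-class] with `posthocMethod = "tamhane"`.
#' @examples
#' onewayAnova(list(a = rnorm(12), b = rnorm(12, 2), c = rnorm(12)))
#' @export
onewayAnova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  k <- length(groups); N <- length(values)
  degenerate <- stats::var(values) == 0
  if (degenerate) {
    Fv <- NA_real_; p <- NA_real_
  } else {
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    Fv <- unname(ow$statistic); p <- unname(ow$p.value)
  }
  new("StatResult", test = "oneway_anova", F = Fv,
      df = c(k - 1, N - k), p = p,
      posthoc = tamhanePosthoc(groups), posthocMethod = "tamhane",
      details = list(groupMeans = vapply(groups, mean, 1),
                     groupN = vapply(groups, length, 1L),
                     degenerate = degenerate))
}

#' Tamhane T2 post-hoc pairwise comparisons
#'
#' For each pair of groups, a Welch-type t statistic with
#' Welch-Satterthwaite degrees of freedom, with Sidak-style familywise
#' adjustment p_adj = 1 - (1 - p)^m over the m pairs (clipped at 1).
#' Appropriate under unequal group variances.
#'
#' @param groups list of numeric vectors.
#' @return symmetric matrix of adjusted p-values with unit diagonal.
#' @export
tamhanePosthoc <- function(groups) {
  k <- length(groups)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  m <- k * (k - 1) / 2
  P <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    vi <- stats::var(xi) / length(xi); vj <- stats::var(xj) / length(xj)
    if (vi + vj == 0) {
      praw <- if (mean(xi) == mean(xj)) 1 else 0
    } else {
      tstat <- (mean(xi) - mean(xj)) / sqrt(vi + vj)
      df <- (vi + vj)^2 /
        (vi^2 / (length(xi) - 1) + vj^2 / (length(xj) - 1))
      praw <- 2 * stats::pt(-abs(tstat), df)
    }
    P[i, j] <- P[j, i] <- min(1, 1 - (1 - praw)^m)
  }
  P
}

#' One-way repeated-measures ANOVA
#'
#' Condition effect with subjects as blocks, fitted with [stats::aov()]
#' and an `Error(subject)` stratum: df = (c - 1, (c - 1)(s - 1)).
#' Bonferroni-adjusted paired t-tests form the post-hoc matrix. The
#' alternative between-groups error df convention (c - 1, N - c) is
#' reported in `details$dfAlt` for comparison with published tables whose
#' df convention is ambiguous; no sphericity correction is applied.
#'
#' @param mat numeric matrix, subjects x conditions, complete (no NA).
#' @return a [StatResult-class] with `posthocMethod = "bonferroni"`.
#' @export
rmAnova <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not supported")
  s <- nrow(mat); cc <- ncol(mat)
  if (s < 2 || cc < 2) stop("need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(cc))
  d <- data.frame(
    value = as.numeric(mat),
    cond = factor(rep(colnames(mat), each = s), levels = colnames(mat)),
    subj = factor(rep(seq_len(s), cc)))
  ## explicit zero-condition-effect guard: when the condition sums of
  ## squares vanish, F is 0 by definition (avoids 0/0 noise from the
  ## numerical fit)
  gm <- mean(mat)
  ssCond <- s * sum((colMeans(mat) - gm)^2)
  ssTot <- sum((mat - gm)^2)
  if (stats::var(d$value) == 0 || ssCond <= 1e-12 * max(ssTot, 1e-300)) {
    Fv <- 0; p <- 1
  } else {
    fit <- stats::aov(value ~ cond + Error(subj), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    Fv <- tab["cond", "F value"]
    p <- tab["cond", "Pr(>F)"]
    if (is.na(Fv)) { Fv <- 0; p <- 1 }
  }
  ## Bonferroni-adjusted paired t-tests; constant differences are handled
  ## explicitly (p = 1 for identical columns, p -> 0 for a constant shift).
  ph <- matrix(1, cc, cc, dimnames = list(colnames(mat), colnames(mat)))
  m <- cc * (cc - 1) / 2
  for (i in seq_len(cc - 1)) for (j in (i + 1):cc) {
    dif <- mat[, i] - mat[, j]
    praw <- if (stats::sd(dif) == 0) {
      if (mean(dif) == 0) 1 else 0
    } else {
      tstat <- mean(dif) / (stats::sd(dif) / sqrt(s))
      2 * stats::pt(-abs(tstat), s - 1)
    }
    ph[i, j] <- ph[j, i] <- min(1, praw * m)
  }
  new("StatResult", test = "rm_anova", F = unname(Fv),
      df = c(cc - 1, (cc - 1) * (s - 1)), p = unname(p), posthoc = ph,
      posthocMethod = "bonferroni",
      details = list(conditionMeans = colMeans(mat),
                     dfAlt = c(cc - 1, s * cc - cc),
                     nSubjects = s))
}

#' Dose-response summary table
#'
#' Mean and standard error of the band z'-coherence per dose, with a
#' repeated-measures ANOVA across doses when at least two doses and two
#' subjects are available.
#'
#' @param zByDose numeric matrix, subjects x doses (columns named by
#'   dose/condition, e.g. AW, K5, K10, K15).
#' @return list with `table` (data.frame dose, meanZ, seZ, n) and `anova`
#'   (a [StatResult-class] or NULL for a single dose).
#' @export
doseResponseTable <- function(zByDose) {
  zByDose <- as.matrix(zByDose)
  if (is.null(colnames(zByDose)))
    colnames(zByDose) <- paste0("d", seq_len(ncol(zByDose)))
  tab <- data.frame(
    dose = colnames(zByDose),
    meanZ = colMeans(zByDose),
    seZ = apply(zByDose, 2, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0),
    n = nrow(zByDose), row.names = NULL)
  anova <- if (ncol(zByDose) >= 2 && nrow(zByDose) >= 2)
    rmAnova(zByDose) else NULL
  list(table = tab, anova = anova)
}
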