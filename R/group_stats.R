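#' Principal component analysis with a fixed sign convention
#'
#' Eigen-decomposition of the covariance (`mode = "center"`) or correlation
#' (`mode = "zscore"`) matrix via [stats::prcomp()]. Component signs are
#' fixed so that the largest-magnitude loading of each component is
#' positive, making scores reproducible across platforms.
#'
#' @param mat Numeric matrix, observations x variables (no missing values).
#' @param mode `"center"` for covariance PCA (variables share units) or
#'   `"zscore"` for correlation PCA (heterogeneous units).
#' @return List of class `component_scores` with `loadings` (variables x
#'   components), `scores` (observations x components), `explained`
#'   (variance fractions, non-increasing), `mode`.
#' @export
pca_components <- function(mat, mode = c("center", "zscore")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("PCA needs at least 2 observations and 2 variables")
  if (anyNA(mat)) stop("PCA input contains missing values")
  if (mode == "zscore") {
    sds <- apply(mat, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable(s): ",
           paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = (mode == "zscore"))
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2), mode = mode),
            class = "component_scores")
}

#' ITPC1 and ITPC2 component scores
#'
#' Covariance PCA of participant-by-condition ITPC values at the stimulus
#' rate and its harmonics (4, 8, 12, 16 Hz). The first component, ITPC1, is
#' expected to be a positively weighted average with 4 Hz weighted highest;
#' a warning is raised if the fitted loadings violate that expectation.
#'
#' @param itpc_df Data frame with columns `participant`, `condition` and
#'   the four harmonic columns `f4`, `f8`, `f12`, `f16` (one row per
#'   participant x condition).
#' @return List with `scores` (the input frame plus `ITPC1`, `ITPC2`),
#'   `loadings`, `explained`.
#' @export
itpc_components <- function(itpc_df) {
  need <- c("f4", "f8", "f12", "f16")
  if (!all(need %in% names(itpc_df)))
    stop("missing harmonic columns: ",
         paste(setdiff(need, names(itpc_df)), collapse = ", "))
  m <- as.matrix(itpc_df[, need])
  pc <- pca_components(m, mode = "center")
  l1 <- pc$loadings[, 1L]
  if (any(l1 <= 0))
    warning("ITPC1 loadings are not all positive")
  if (which.max(l1) != 1L)
    warning("4 Hz does not carry the highest ITPC1 loading")
  out <- itpc_df
  out$ITPC1 <- pc$scores[, 1L]
  out$ITPC2 <- pc$scores[, 2L]
  list(scores = out, loadings = pc$loadings, explained = pc$explained)
}

#' PC1 and PC2 of the retained edge markers
#'
#' z-score PCA of the condition-by-marker matrix; markers have
#' heterogeneous units (amplitude/s, ms, unitless) so covariance PCA would
#' be dominated by the millisecond-scale latencies.
#'
#' @param marker_df Data frame or matrix of conditions x markers. The
#'   default retained set is `md_latency`, `ma_latency`, `sharpness`,
#'   `gini`, `plateau`; pass `markers` to change it (e.g. to add
#'   `ma80_latency`).
#' @param markers Character vector of marker columns to use.
#' @return List with `scores` (conditions x components, first two named
#'   PC1/PC2), `loadings`, `explained`.
#' @export
marker_components <- function(marker_df,
                              markers = c("md_latency", "ma_latency",
                                          "sharpness", "gini",
                                          "plateau")) {
  if (!all(markers %in% colnames(marker_df)))
    stop("missing marker columns: ",
         paste(setdiff(markers, colnames(marker_df)), collapse = ", "))
  m <- as.matrix(as.data.frame(marker_df)[, markers])
  pc <- pca_components(m, mode = "zscore")
  colnames(pc$scores) <- paste0("PC", seq_len(ncol(pc$scores)))
  list(scores = pc$scores, loadings = pc$loadings,
       explained = pc$explained)
}

#' Pearson correlation with its two-sided p-value
#'
#' @param x,y Numeric vectors, n >= 3, finite, non-constant.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input to correlation")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the within-participant one-way design with [stats::aov()]
#' (participant as the blocking factor), computes the Greenhouse-Geisser
#' epsilon from the double-centered covariance of the condition columns,
#' and tests sphericity with [stats::mauchly.test()]. The corrected p-value
#' uses df scaled by epsilon; the reported `p.value` applies the correction
#' only when Mauchly's test rejects at `alpha` (it is always applied when
#' the test cannot be run for want of participants).
#'
#' @param Y Numeric matrix, participants x conditions (balanced, complete),
#'   or a data frame with columns `participant`, `condition`, `value`.
#' @param alpha Sphericity test level (default 0.05).
#' @return List of class `rm_anova` with `F`, `df1`, `df2`, `epsilon`,
#'   `p.uncorrected`, `p.gg`, `mauchly.p`, `gg.applied`, `p.value`.
#' @export
rm_anova_gg <- function(Y, alpha = 0.05) {
  if (is.data.frame(Y)) {
    Y <- stats::xtabs(value ~ participant + condition, data = Y)
    Y <- matrix(Y, nrow = nrow(Y), dimnames = dimnames(Y))
  }
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2L || p < 2L)
    stop("need at least 2 participants and 2 conditions")
  long <- data.frame(
    value = as.vector(Y),
    participant = factor(rep(seq_len(n), times = p)),
    condition = factor(rep(seq_len(p), each = n))
  )
  fit <- stats::aov(value ~ condition + Error(participant), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  Fval <- tab["condition", "F value"]
  df1 <- p - 1L
  df2 <- (n - 1L) * (p - 1L)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(Y)
  Sd <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  eps <- sum(diag(Sd))^2 / ((p - 1) * sum(Sd^2))
  eps <- min(1, max(1 / (p - 1), eps))
  p_unc <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  mau_p <- NA_real_
  if (p == 2L) {
    mau_p <- 1  # a single difference variance: sphericity holds trivially
  } else if (n > p) {
    mlm <- stats::lm(Y ~ 1)
    mau_p <- tryCatch(stats::mauchly.test(mlm, X = ~1)$p.value,
                      error = function(e) NA_real_)
  }
  applied <- is.na(mau_p) || mau_p < alpha
  structure(list(F = unname(Fval), df1 = df1, df2 = df2, epsilon = eps,
                 p.uncorrected = p_unc, p.gg = p_gg, mauchly.p = mau_p,
                 gg.applied = applied,
                 p.value = if (applied) p_gg else p_unc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA: F(%g, %g) = %.3f, GG epsilon = %.3f, p = %.4g%s\n",
    x$df1, x$df2, x$F, x$epsilon, x$p.value,
    if (x$gg.applied) " (GG-corrected)" else ""))
  invisible(x)
}

#' Bonferroni-corrected paired post-hoc t-tests
#'
#' Paired two-tailed t-tests for the requested condition pairs; p-values
#' are multiplied by the number of comparisons in the family and capped at
#' one.
#'
#' @param Y Numeric matrix, participants x conditions, with column names.
#' @param pairs Two-column matrix or list of length-2 vectors of condition
#'   names/indices; default all pairwise comparisons.
#' @return Data frame with columns `a`, `b`, `t`, `df`, `p.raw`,
#'   `p.adjusted`.
#' @export
bonferroni_posthoc <- function(Y, pairs = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 paired observations")
  if (is.null(colnames(Y))) colnames(Y) <- as.character(seq_len(ncol(Y)))
  if (is.null(pairs)) {
    cb <- utils::combn(colnames(Y), 2L)
    pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  if (is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- Y[, pr[1L]] - Y[, pr[2L]]
    if (all(d == 0)) {
      tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
    } else {
      tt <- stats::t.test(d)
    }
    data.frame(a = as.character(pr[1L]), b = as.character(pr[2L]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p.raw = tt$p.value,
               p.adjusted = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' k-means clustering of condition-level component scores
#'
#' Lloyd's algorithm, best of `restarts` seeded initialisations by
#' within-cluster sum of squares; deterministic under `seed`.
#'
#' @param scores Numeric matrix of conditions x score dimensions (e.g.
#'   ITPC1, ITPC2 condition means), with row names naming conditions.
#' @param k Number of clusters (default 3).
#' @param restarts Random restarts (default 100).
#' @param seed Integer seed.
#' @return List with `cluster` (named assignments), `centers`,
#'   `tot.withinss`.
#' @export
kmeans_conditions <- function(scores, k = 3L, restarts = 100L, seed = 1L) {
  scores <- as.matrix(scores)
  if (k > nrow(scores))
    stop("k = ", k, " exceeds the number of conditions (", nrow(scores),
         ")")
  km <- with_seed(seed,
    suppressWarnings(stats::kmeans(scores, centers = k,
                                   nstart = restarts, iter.max = 100L,
                                   algorithm = "Lloyd")))
  list(cluster = stats::setNames(km$cluster, rownames(scores)),
       centers = km$centers, tot.withinss = km$tot.withinss)
}

#' Phoneme-group partitions of the stimulus conditions
#'
#' The linguistic groupings of the 14 syllable-initial consonants: a
#' three-way split by airflow release (stops; fricatives/sibilants;
#' nasals/liquids), a five-way refinement, and the voicing splits within
#' stops and within fricatives/sibilants. The vowel-only condition belongs
#' to none of the consonant partitions.
#'
#' @return Named list of partitions; each partition is a named list of
#'   condition-label vectors.
#' @export
phoneme_groups <- function() {
  list(
    three = list(
      stops = c("b", "d", "g", "k", "p", "t"),
      fricatives_sibilants = c("f", "v", "s", "z"),
      nasals_liquids = c("m", "n", "l", "r")
    ),
    five = list(
      stops = c("b", "d", "g", "k", "p", "t"),
      fricatives = c("f", "v"),
      sibilants = c("s", "z"),
      nasals = c("m", "n"),
      liquids = c("l", "r")
    ),
    voicing_stops = list(
      voiced = c("b", "d", "g"),
      unvoiced = c("k", "p", "t")
    ),
    voicing_fricatives = list(
      voiced = c("v", "z"),
      unvoiced = c("f", "s")
    )
  )
}

#' Aggregate component scores over a phoneme-group partition
#'
#' Averages per-participant scores over the conditions of each group,
#' yielding the participants x groups matrix that feeds [rm_anova_gg()] and
#' [bonferroni_posthoc()], plus group means and standard errors across
#' participants. Conditions absent from the partition (the vowel-only
#' condition, for consonant partitions) are dropped.
#'
#' @param scores Data frame with columns `participant`, `condition` and a
#'   score column.
#' @param partition Named list of condition-label vectors (one element of
#'   [phoneme_groups()]).
#' @param value Name of the score column (default `"ITPC1"`).
#' @return List with `by_participant` (participants x groups matrix) and
#'   `summary` (group, mean, sem).
#' @export
group_aggregate <- function(scores, partition, value = "ITPC1") {
  if (!value %in% names(scores)) stop("no column called ", value)
  lab <- unlist(lapply(names(partition), function(g)
    stats::setNames(rep(g, length(partition[[g]])), partition[[g]])))
  known <- unique(c(names(lab), condition_labels()))
  bad <- setdiff(unique(scores$condition), known)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  keep <- scores$condition %in% names(lab)
  sc <- scores[keep, , drop = FALSE]
  sc$group <- factor(lab[sc$condition], levels = names(partition))
  agg <- stats::aggregate(sc[[value]],
                          by = list(participant = sc$participant,
                                    group = sc$group), FUN = mean)
  by_part <- stats::xtabs(x ~ participant + group, data = agg) /
    stats::xtabs(~ participant + group, data = agg)
  by_part <- matrix(by_part, nrow = nrow(by_part),
                    dimnames = dimnames(by_part))
  mu <- colMeans(by_part)
  sem <- apply(by_part, 2L, stats::sd) / sqrt(nrow(by_part))
  list(by_participant = by_part,
       summary = data.frame(group = names(mu), mean = unname(mu),
                            sem = unname(sem), stringsAsFactors = FALSE))
}
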