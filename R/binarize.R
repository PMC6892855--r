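# Severity thresholding: per-group integer cutoffs on domain sum scores,
# chosen so that endorsement prevalences -- and hence binary variances
# p(1-p) -- are comparable across illness-severity groups. This removes
# severity-driven variance differences as a confound of network structure.

#' Fit per-group severity thresholds that equalise domain prevalences
#'
#' For each group and domain, selects the integer cutoff c (endorsed iff
#' score >= c) whose achieved prevalence is closest to the domain's target
#' prevalence; ties are broken toward the lower cutoff (higher prevalence).
#' When groups are stochastically ordered in severity, the fitted cutoffs
#' are non-decreasing in severity, so the most severe group receives the
#' highest thresholds.
#'
#' The default target per domain is the pooled-sample prevalence at the most
#' severe group's cutoff, where that group's cutoff is first set to the
#' smallest integer giving it a within-group prevalence of at most 0.5
#' (endorsement then marks the clearly elevated half of the scale while
#' keeping binary variance near its maximum).
#'
#' @param domain_scores Integer matrix, individuals x domains.
#' @param groups Per-individual group index (1 = least severe, increasing).
#' @param target_prevalences Optional per-domain targets in (0, 1), recycled.
#' @return A `threshold_scheme`: `cutoffs` and `achieved` (group x domain
#'   matrices), `targets`, and `unreachable` flags for group/domain cells
#'   where no cutoff comes within 0.5 of the target.
#' @export
fit_thresholds <- function(domain_scores, groups, target_prevalences = NULL) {
  domain_scores <- as.matrix(domain_scores)
  if (anyNA(domain_scores)) stop("missing domain scores are not allowed")
  glev <- sort(unique(groups))
  K <- length(glev); D <- ncol(domain_scores)
  dn <- colnames(domain_scores)
  if (is.null(dn)) dn <- paste0("D", seq_len(D))
  for (g in glev) for (d in seq_len(D)) {
    s <- domain_scores[groups == g, d]
    if (length(unique(s)) < 2)
      stop("domain '", dn[d], "' is constant within group ", g,
           "; cannot fit a threshold")
  }
  cand <- seq_len(max(domain_scores))  # integer cutoffs 1..max score
  prev_at <- function(s, c) mean(s >= c)

  if (is.null(target_prevalences)) {
    gK <- glev[K]
    target_prevalences <- vapply(seq_len(D), function(d) {
      sK <- domain_scores[groups == gK, d]
      pK <- vapply(cand, prev_at, 0, s = sK)
      cK <- cand[which(pK <= 0.5)[1]]
      if (is.na(cK)) cK <- max(cand)
      prev_at(domain_scores[, d], cK)
    }, 0)
  }
  target_prevalences <- rep_len(target_prevalences, D)
  if (any(target_prevalences <= 0 | target_prevalences >= 1))
    stop("target_prevalences: must lie strictly in (0, 1)")

  cutoffs <- achieved <- matrix(0, K, D, dimnames = list(glev, dn))
  unreachable <- matrix(FALSE, K, D, dimnames = list(glev, dn))
  for (gi in seq_len(K)) for (d in seq_len(D)) {
    s <- domain_scores[groups == glev[gi], d]
    pv <- vapply(cand, prev_at, 0, s = s)
    dev <- abs(pv - target_prevalences[d])
    best <- which(dev == min(dev))[1]  # tie -> lower cutoff
    cutoffs[gi, d] <- cand[best]
    achieved[gi, d] <- pv[best]
    if (min(dev) > 0.5) unreachable[gi, d] <- TRUE
  }
  if (any(unreachable))
    warning("target prevalence unreachable (deviation > 0.5) for ",
            sum(unreachable), " group/domain cell(s)")
  structure(list(cutoffs = cutoffs, achieved = achieved,
                 targets = stats::setNames(target_prevalences, dn),
                 unreachable = unreachable, group_levels = glev),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("Severity threshold scheme (", nrow(x$cutoffs), " groups x ",
      ncol(x$cutoffs), " domains)\nCutoffs (endorsed iff score >= cutoff):\n",
      sep = "")
  print(x$cutoffs)
  invisible(x)
}

#' Apply a threshold scheme to domain scores
#'
#' @param domain_scores Integer matrix, individuals x domains.
#' @param groups Per-individual group index.
#' @param scheme A `threshold_scheme` covering all groups and domains present.
#' @return A `binary_matrix`: 0/1 `values` plus `groups` and `domains`.
#'   Columns that end up constant within a group are flagged in
#'   `constant_cells` (they must be dropped or handled before estimation).
#' @export
apply_thresholds <- function(domain_scores, groups, scheme) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  domain_scores <- as.matrix(domain_scores)
  if (anyNA(domain_scores)) stop("missing domain scores are not allowed")
  dn <- colnames(scheme$cutoffs)
  if (!is.null(colnames(domain_scores)) &&
      !all(colnames(domain_scores) %in% dn))
    stop("scheme does not cover all domains present")
  if (!all(unique(groups) %in% scheme$group_levels))
    stop("scheme does not cover all groups present")
  gi <- match(groups, scheme$group_levels)
  cut_mat <- scheme$cutoffs[gi, , drop = FALSE]  # row per individual
  values <- (domain_scores >= cut_mat) + 0L
  dimnames(values) <- list(rownames(domain_scores), dn)
  const <- which(vapply(scheme$group_levels, function(g) {
    apply(values[groups == g, , drop = FALSE], 2,
          function(v) length(unique(v)) < 2)
  }, logical(ncol(values))), arr.ind = TRUE)
  binary_matrix(values, groups, constant_cells = const)
}

binary_matrix <- function(values, groups, constant_cells = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L))) stop("values: entries must be 0 or 1")
  storage.mode(values) <- "integer"
  structure(list(values = values, groups = groups,
                 domains = colnames(values), constant_cells = constant_cells),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat("Binary endorsement matrix: ", nrow(x$values), " individuals x ",
      ncol(x$values), " domains, ", length(unique(x$groups)), " group(s)\n",
      sep = "")
  invisible(x)
}

#' Per-group endorsement prevalences
#'
#' @param binary A `binary_matrix`.
#' @return Group x domain matrix of column means, with the maximum
#'   cross-group range per domain as attribute `"range"`.
#' @export
prevalence_table <- function(binary) {
  stopifnot(inherits(binary, "binary_matrix"))
  glev <- sort(unique(binary$groups))
  out <- t(vapply(glev, function(g)
    colMeans(binary$values[binary$groups == g, , drop = FALSE]),
    numeric(ncol(binary$values))))
  rownames(out) <- glev
  attr(out, "range") <- apply(out, 2, function(v) diff(range(v)))
  out
}

#' Discreteness bound on cross-group prevalence agreement
#'
#' Integer cutoffs can only realise a finite ladder of prevalences, so
#' matched prevalences agree at best up to the local spacing of that ladder.
#' For each domain this returns the largest, over groups, gap between the two
#' achievable prevalences that bracket the target -- an upper bound on the
#' cross-group prevalence range after threshold fitting.
#'
#' @param domain_scores Integer matrix, individuals x domains.
#' @param groups Per-individual group index.
#' @param scheme The fitted `threshold_scheme`.
#' @return Named numeric vector, one bound per domain.
#' @export
prevalence_discreteness_bound <- function(domain_scores, groups, scheme) {
  domain_scores <- as.matrix(domain_scores)
  dn <- colnames(scheme$cutoffs)
  vapply(seq_along(dn), function(d) {
    max(vapply(scheme$group_levels, function(g) {
      s <- domain_scores[groups == g, d]
      pv <- sort(unique(c(0, 1, vapply(seq_len(max(domain_scores)),
                                       function(c) mean(s >= c), 0))),
                 decreasing = TRUE)
      tgt <- scheme$targets[d]
      lo <- max(which(pv >= tgt), 1L)
      hi <- min(lo + 1L, length(pv))
      pv[lo] - pv[hi]
    }, 0))
  }, 0, USE.NAMES = FALSE) |> stats::setNames(dn)
}

#' Brown-Forsythe test of equal domain variances across groups
#'
#' Median-centred Levene test: a one-way ANOVA on the absolute deviations
#' from the group median, run per domain across groups. For binary data the
#' variance is p(1-p), so prevalence-matched groups should show
#' non-significant results -- the diagnostic this pipeline uses to confirm
#' the severity correction worked.
#'
#' @param binary A `binary_matrix` with at least two groups.
#' @return Data frame with one row per domain: `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
variance_equality_test <- function(binary) {
  stopifnot(inherits(binary, "binary_matrix"))
  g <- factor(binary$groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  res <- lapply(seq_len(ncol(binary$values)), function(d) {
    x <- binary$values[, d]
    med <- tapply(x, g, stats::median)
    z <- abs(x - med[g])
    if (stats::var(z) == 0)  # identical deviations everywhere
      return(c(statistic = 0, df1 = nlevels(g) - 1,
               df2 = length(z) - nlevels(g), p_value = 1))
    ft <- stats::oneway.test(z ~ g, var.equal = TRUE)
    c(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
      df2 = unname(ft$parameter[2]), p_value = ft$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$domain <- binary$domains %||% paste0("D", seq_len(ncol(binary$values)))
  out[, c("domain", "statistic", "df1", "df2", "p_value")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
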